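#' Root-tip angle relative to the horizontal plane
#'
#' The tip direction is the secant from the point at arc length
#' `L - tip_window_cm` to the tip; the reported angle is the signed angle
#' between that direction and the horizontal axis, in degrees in
#' (-180, 180]: 0 is horizontal (toward gravity's right-hand perpendicular)
#' and +90 points straight down (parallel to gravity). This reproduces the
#' manual protractor measurement of the root tip after gravistimulation with
#' an explicit, reproducible tip window.
#'
#' @param centerline A `resampled_centerline`.
#' @param gravity_direction Gravity vector (default `c(0, -1)`).
#' @param tip_window_cm Arc length of the tip secant (default 0.05 cm).
#' @return List with `root_id`, `group`, `angle_deg`, `tip_window_cm`.
#' @export
tip_angle <- function(centerline, gravity_direction = c(0, -1),
                      tip_window_cm = 0.05) {
  stopifnot(inherits(centerline, "resampled_centerline"))
  if (tip_window_cm <= 0) {
    stop("`tip_window_cm` must be positive.", call. = FALSE)
  }
  L <- centerline$total_length_L
  if (L <= tip_window_cm) {
    stop("Root '", centerline$root_id, "' (L = ", signif(L, 4),
         " cm) is shorter than tip_window_cm = ", tip_window_cm, ".",
         call. = FALSE)
  }
  g <- unit_gravity(gravity_direction)
  h <- perp2(g)
  s <- centerline$arc_pos
  p <- centerline$points
  s0 <- L - tip_window_cm
  x0 <- stats::approx(s, p[, 1], xout = s0, ties = "ordered")$y
  y0 <- stats::approx(s, p[, 2], xout = s0, ties = "ordered")$y
  d <- c(p[nrow(p), 1] - x0, p[nrow(p), 2] - y0)
  ang <- atan2(sum(d * g), sum(d * h)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  list(root_id = centerline$root_id, group = centerline$group,
       angle_deg = ang, tip_window_cm = tip_window_cm)
}

#' Tip angles for every root in a collection
#'
#' @param collection A [trace_collection()].
#' @param tip_window_cm Arc length of the tip secant (default 0.05 cm).
#' @param density Resampling density (default 1000 dots per cm).
#' @return Tibble with root_id, group, angle_deg, tip_window_cm; roots
#'   shorter than the tip window are skipped with a warning.
#' @export
tip_angles <- function(collection, tip_window_cm = 0.05, density = 1000) {
  stopifnot(inherits(collection, "trace_collection"))
  g <- collection$gravity_direction
  rows <- lapply(collection$traces, function(tr) {
    res <- tryCatch({
      cl <- resample_spline(tr, density = density)
      tip_angle(cl, g, tip_window_cm)
    }, error = function(e) {
      warning("Skipping '", tr$root_id, "': ", conditionMessage(e),
              call. = FALSE)
      NULL
    })
    if (is.null(res)) NULL else
      tibble::tibble(root_id = res$root_id, group = res$group,
                     angle_deg = res$angle_deg,
                     tip_window_cm = res$tip_window_cm)
  })
  dplyr::bind_rows(rows)
}

#' Group summaries and circular-class histograms of tip angles
#'
#' Angles are grouped into half-open classes of `class_width_deg` anchored
#' at 0 degrees (..., \[0, 20), \[20, 40), ...) covering (-180, 180] (the
#' single value +180 falls in the last class). Group means and standard
#' deviations are arithmetic on degrees by default (sample SD, n - 1),
#' appropriate while angles stay far from the +/-180 wrap; set
#' `circular = TRUE` for the circular mean and circular SD.
#'
#' @param angles Tibble with columns `group` and `angle_deg` (e.g. from
#'   [tip_angles()]).
#' @param class_width_deg Class width in degrees; must divide 360
#'   (default 20).
#' @param circular Use circular statistics instead of arithmetic ones.
#' @return List with `summary` (tibble: group, n, mean_deg, sd_deg) and
#'   `histogram` (tibble: group, class_lo, class_hi, count).
#' @export
bin_angles <- function(angles, class_width_deg = 20, circular = FALSE) {
  stopifnot(is.data.frame(angles),
            all(c("group", "angle_deg") %in% names(angles)))
  w <- class_width_deg
  if (!is.numeric(w) || length(w) != 1 || w <= 0 || 360 %% w != 0) {
    stop("`class_width_deg` must divide 360.", call. = FALSE)
  }
  if (nrow(angles) == 0) stop("No angles supplied.", call. = FALSE)
  a <- angles$angle_deg
  if (any(a <= -180 | a > 180)) {
    stop("Angles must lie in (-180, 180].", call. = FALSE)
  }
  n_class <- 360 / w
  # class index 1..n_class for [-180,-180+w), ..., [180-w, 180]
  idx <- pmin(floor((a + 180) / w) + 1L, n_class)
  lo <- -180 + (seq_len(n_class) - 1L) * w

  hist_tbl <- dplyr::bind_rows(lapply(split(seq_along(a), angles$group),
    function(i) {
      tibble::tibble(group = angles$group[i[1]], class_lo = lo,
                     class_hi = lo + w,
                     count = tabulate(idx[i], nbins = n_class))
    }))
  summ <- dplyr::bind_rows(lapply(split(a, angles$group), function(v) {
    if (circular) {
      rad <- v * pi / 180
      C <- mean(cos(rad)); S <- mean(sin(rad))
      R <- sqrt(C^2 + S^2)
      m <- atan2(S, C) * 180 / pi
      s <- if (length(v) > 1) sqrt(pmax(-2 * log(R), 0)) * 180 / pi
           else NA_real_
    } else {
      m <- mean(v)
      s <- if (length(v) > 1) stats::sd(v) else NA_real_
    }
    tibble::tibble(n = length(v), mean_deg = m, sd_deg = s)
  }), .id = "group")
  list(summary = summ, histogram = hist_tbl)
}
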