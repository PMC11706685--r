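#' Base-to-tip posture indices
#'
#' Computes the whole-root posture indices from the resampled centerline:
#' total root length `L` (arc length), the signed horizontal and vertical
#' base-to-tip displacements `Lx` and `Ly` (`Ly` positive downward, i.e.
#' along gravity; `Lx` positive to gravity's right-hand perpendicular), the
#' Euclidean base-to-tip distance `Lc`, and their ratios to `L`: the
#' horizontal growth index `HGI = Lx/L`, the vertical growth index
#' `VGI = Ly/L` and the straightness index `SI = Lc/L`. A perfectly straight
#' root has `SI = 1`; `SI = sqrt(HGI^2 + VGI^2)` always holds.
#'
#' @param centerline A `resampled_centerline`.
#' @param gravity_direction 2D gravity vector (normalized internally).
#' @param abs_hgi If `TRUE`, report `|Lx|` and `|HGI|` instead of signed
#'   values.
#' @return Named list with `L`, `Lx`, `Ly`, `Lc`, `HGI`, `VGI`, `SI`.
#' @export
base_tip_indices <- function(centerline, gravity_direction = c(0, -1),
                             abs_hgi = FALSE) {
  stopifnot(inherits(centerline, "resampled_centerline"))
  g <- unit_gravity(gravity_direction)
  h <- perp2(g)
  L <- centerline$total_length_L
  if (L <= 0) stop("Degenerate centerline: L = 0.", call. = FALSE)
  d <- centerline$points[nrow(centerline$points), ] - centerline$points[1, ]
  Lx <- sum(d * h)
  Ly <- sum(d * g)
  if (abs_hgi) Lx <- abs(Lx)
  Lc <- sqrt(sum(d^2))
  list(L = L, Lx = unname(Lx), Ly = unname(Ly), Lc = unname(Lc),
       HGI = unname(Lx / L), VGI = unname(Ly / L), SI = unname(Lc / L))
}

valid_kappa <- function(profile) {
  stopifnot(inherits(profile, "curvature_profile"))
  k <- profile$kappa_smooth[profile$valid_mask]
  if (length(k) == 0 || anyNA(k)) {
    stop("Profile '", profile$root_id,
         "' has no valid smoothed curvature values.", call. = FALSE)
  }
  k
}

#' Trimmed mean of the curvature index
#'
#' Per-root mean curvature index computed as a symmetric trimmed mean over
#' the valid (smoothed, end-trimmed) points: the `trim_fraction_each_side`
#' lowest and highest values each are dropped (0.5% each side by default,
#' i.e. a 1%-trimmed mean), guarding against isolated digitization spikes.
#' The number dropped per side is `floor(n_valid * trim_fraction_each_side)`;
#' for fewer than 200 valid points at the default this is a plain mean.
#'
#' @param profile A trimmed `curvature_profile`.
#' @param trim_fraction_each_side Fraction trimmed at each extreme
#'   (default 0.005).
#' @return Mean curvature index, cm^-1.
#' @export
trimmed_mean_ci <- function(profile, trim_fraction_each_side = 0.005) {
  if (trim_fraction_each_side < 0 || trim_fraction_each_side >= 0.5) {
    stop("`trim_fraction_each_side` must be in [0, 0.5).", call. = FALSE)
  }
  k <- sort(valid_kappa(profile))
  n <- length(k)
  drop <- floor(n * trim_fraction_each_side)
  if (2 * drop >= n) drop <- 0L
  mean(k[seq.int(drop + 1L, n - drop)])
}

#' Count points exceeding a curvature threshold
#'
#' Number of valid points whose smoothed curvature index strictly exceeds
#' `threshold` (50 cm^-1 by default — a level essentially never reached by
#' straight wild-type roots, so the count isolates sharp local bends).
#'
#' @param profile A trimmed `curvature_profile`.
#' @param threshold Curvature threshold, cm^-1 (default 50).
#' @return Integer count.
#' @export
count_exceed <- function(profile, threshold = 50) {
  sum(valid_kappa(profile) > threshold)
}

#' Mean curvature index per arc-length compartment
#'
#' Plain (untrimmed) mean of the valid smoothed curvature index within
#' half-open arc-length bins from the basal point: with the default breaks
#' `c(0.5, 1)` these are \[0, 0.5), \[0.5, 1.0) and \[1.0, Inf) cm. Bins with
#' no valid points are `NA`, not zero.
#'
#' @param profile A trimmed `curvature_profile`.
#' @param breaks Increasing interior break points, cm (default `c(0.5, 1)`).
#' @return Named numeric vector, one mean per bin.
#' @export
compartment_means <- function(profile, breaks = c(0.5, 1)) {
  if (is.unsorted(breaks, strictly = TRUE) || any(breaks <= 0)) {
    stop("`breaks` must be strictly increasing and positive.", call. = FALSE)
  }
  k <- profile$kappa_smooth[profile$valid_mask]
  s <- profile$arc_pos[profile$valid_mask]
  edges <- c(0, breaks, Inf)
  bin <- findInterval(s, edges)  # half-open [edge_i, edge_{i+1})
  lab <- paste0("ci_", edges[-length(edges)], "_",
                ifelse(is.finite(edges[-1]), edges[-1], "plus"))
  out <- vapply(seq_along(lab), function(i) {
    v <- k[bin == i]
    if (length(v) == 0) NA_real_ else mean(v)
  }, numeric(1))
  stats::setNames(out, lab)
}

#' Summarize one root: posture indices plus curvature summaries
#'
#' Runs the full pipeline on one trace and assembles a single results row.
#'
#' @param trace A [root_trace()].
#' @param gravity_direction Gravity vector (default `c(0, -1)`).
#' @param density,half_window_cm,n_trim,denominator Passed to
#'   [curvature_profile()].
#' @param threshold,breaks,trim_fraction Curvature summary parameters.
#' @param tip_window_cm Arc length defining the tip direction for
#'   [tip_angle()]; `NA` tip angle if the root is shorter.
#' @param smoothing Passed to [resample_spline()].
#' @param abs_hgi Report `|HGI|` instead of the signed value.
#' @return One-row tibble of all per-root indices.
#' @export
measure_root <- function(trace, gravity_direction = c(0, -1), density = 1000,
                         half_window_cm = 0.005, n_trim = 20,
                         denominator = "mean_chord", threshold = 50,
                         breaks = c(0.5, 1), trim_fraction = 0.005,
                         tip_window_cm = 0.05, abs_hgi = FALSE,
                         smoothing = c("gcv", "none")) {
  cl <- resample_spline(trace, density = density, smoothing = smoothing)
  prof <- turning_angle_curvature(cl, denominator = denominator)
  prof <- ci_moving_average(prof, half_window_cm = half_window_cm)
  prof <- trim_ends(prof, n_trim = n_trim)
  bt <- base_tip_indices(cl, gravity_direction, abs_hgi = abs_hgi)
  comp <- compartment_means(prof, breaks = breaks)
  ang <- if (cl$total_length_L > tip_window_cm) {
    tip_angle(cl, gravity_direction, tip_window_cm)$angle_deg
  } else NA_real_
  k <- valid_kappa(prof)
  dplyr::bind_cols(
    tibble::tibble(
      root_id = trace$root_id, group = trace$group,
      L = bt$L, Lx = bt$Lx, Ly = bt$Ly, Lc = bt$Lc,
      HGI = bt$HGI, VGI = bt$VGI, SI = bt$SI,
      ci_mean = trimmed_mean_ci(prof, trim_fraction),
      ci_max = max(k),
      n_exceed = count_exceed(prof, threshold),
      n_valid = length(k)
    ),
    tibble::as_tibble(as.list(comp)),
    tibble::tibble(tip_angle_deg = ang)
  )
}

#' Group-wise smoother of curvature versus distance from the base
#'
#' Pools the valid (arc position, smoothed curvature) pairs of every root in
#' each group and fits a regression smoother, evaluated on a uniform grid —
#' the summary view of how local bending varies from the basal point to the
#' tip. The default family is LOESS local regression; `family = "gam"` uses
#' a penalized thin-plate regression spline (mgcv).
#'
#' @param profiles Tibble as from [profile_table()] rows bound together
#'   (columns `group`, `arc_pos`, `kappa_smooth`, `valid`).
#' @param family `"loess"` (default) or `"gam"`.
#' @param span LOESS span (default 0.3).
#' @param grid_n Evaluation grid size (default 200).
#' @return Tibble with `group`, `arc_pos`, `kappa_fit` and attribute
#'   `smoother` recording the family used.
#' @export
ci_distance_smoother <- function(profiles, family = c("loess", "gam"),
                                 span = 0.3, grid_n = 200) {
  family <- match.arg(family)
  stopifnot(is.data.frame(profiles),
            all(c("group", "arc_pos", "kappa_smooth", "valid") %in%
                  names(profiles)))
  dat <- profiles[profiles$valid, , drop = FALSE]
  out <- lapply(split(dat, dat$group), function(d) {
    if (nrow(d) < 10) {
      warning("Group '", d$group[1], "' has too few points; skipped.",
              call. = FALSE)
      return(NULL)
    }
    grid <- seq(min(d$arc_pos), max(d$arc_pos), length.out = grid_n)
    fit <- if (family == "gam" && requireNamespace("mgcv", quietly = TRUE)) {
      m <- mgcv::gam(kappa_smooth ~ s(arc_pos), data = d)
      as.numeric(mgcv::predict.gam(m, newdata = data.frame(arc_pos = grid)))
    } else {
      m <- stats::loess(kappa_smooth ~ arc_pos, data = d, span = span,
                        degree = 2)
      as.numeric(stats::predict(m, newdata = data.frame(arc_pos = grid)))
    }
    tibble::tibble(group = d$group[1], arc_pos = grid, kappa_fit = fit)
  })
  res <- dplyr::bind_rows(out)
  attr(res, "smoother") <- if (family == "gam") "gam" else
    paste0("loess(span=", span, ")")
  res
}
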