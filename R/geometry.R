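#' Resample a trace to uniform arc-length density
#'
#' Fits a cubic spline through the digitized points, parameterized by
#' cumulative chord length, and re-evaluates it at uniform arc-length
#' targets so that the output has `density` dots per cm (1,000 by default).
#' The output point count is `round(L * density) + 1` where `L` is the
#' spline's arc length.
#'
#' By default each coordinate is fitted with a cross-validated smoothing
#' spline (`smoothing = "gcv"`): manually placed dots carry positional
#' error, and an interpolating spline would convert that jitter into large
#' spurious curvature, whereas the data-driven penalty suppresses it while
#' leaving noise-free traces essentially interpolated. `smoothing = "none"`
#' forces exact interpolation (exactly equivariant under rigid motions, but
#' noise-amplifying); traces with fewer than 8 points always interpolate.
#'
#' @param trace A [root_trace()].
#' @param density Dots per cm of the output (default 1000).
#' @param smoothing `"gcv"` (default, denoising smoothing spline) or
#'   `"none"` (pure interpolation).
#' @return A `resampled_centerline`: list with `points` (matrix, cm),
#'   `arc_pos` (cumulative arc length from the basal point, cm), `density`,
#'   `total_length_L`, and the trace's `root_id`/`group`.
#' @export
resample_spline <- function(trace, density = 1000,
                            smoothing = c("gcv", "none")) {
  stopifnot(inherits(trace, "root_trace"))
  smoothing <- match.arg(smoothing)
  if (!is.numeric(density) || length(density) != 1 || density <= 0) {
    stop("`density` must be a positive number of dots per cm.", call. = FALSE)
  }
  pts <- trace$points
  n <- nrow(pts)
  seg <- sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-n, , drop = FALSE])^2))
  u <- c(0, cumsum(seg))

  coord_fun <- function(z) {
    if (smoothing == "gcv" && n >= 8) {
      fit <- tryCatch(stats::smooth.spline(u, z),
                      error = function(e) NULL)
      if (!is.null(fit)) {
        return(function(uu) stats::predict(fit, uu)$y)
      }
    }
    # cubic needs >= 4 support points; natural spline degrades gracefully at 3
    stats::splinefun(u, z, method = if (n >= 4) "fmm" else "natural")
  }
  fx <- coord_fun(pts[, 1])
  fy <- coord_fun(pts[, 2])

  # dense evaluation for arc-length measurement/inversion (~10x the target)
  m <- max(ceiling(10 * u[n] * density), 10L * n) + 1L
  ud <- seq(0, u[n], length.out = m)
  xd <- fx(ud); yd <- fy(ud)
  sd_ <- c(0, cumsum(sqrt(diff(xd)^2 + diff(yd)^2)))
  L <- sd_[m]
  if (L <= 0) stop("Degenerate trace '", trace$root_id, "': zero length.",
                   call. = FALSE)
  n_out <- round(L * density) + 1
  if (n_out < 3) {
    stop("Trace '", trace$root_id, "' too short (", signif(L, 3),
         " cm) for density ", density, ".", call. = FALSE)
  }
  targets <- seq(0, L, length.out = n_out)
  # invert s(u) by monotone linear interpolation on the dense grid
  ut <- stats::approx(sd_, ud, xout = targets, ties = "ordered")$y
  out <- cbind(x = fx(ut), y = fy(ut))
  structure(
    list(points = out, arc_pos = targets, density = density,
         total_length_L = L, root_id = trace$root_id, group = trace$group),
    class = "resampled_centerline"
  )
}

#' @export
print.resampled_centerline <- function(x, ...) {
  cat("<resampled_centerline> ", x$root_id, ": L = ",
      signif(x$total_length_L, 6), " cm, ", length(x$arc_pos),
      " points @ ", x$density, "/cm\n", sep = "")
  invisible(x)
}

#' Per-point curvature index from turning angles
#'
#' For each interior point i the curvature index is the unsigned turning
#' angle (radians) between the chords (p\[i-1\] -> p\[i\]) and
#' (p\[i\] -> p\[i+1\]) divided by a chord-length distance: the mean of the
#' two chord lengths by default (converging to |d theta / ds|), or the
#' p\[i-1\] -> p\[i+1\] distance with `denominator = "endpoint_chord"`.
#' A straight line has curvature index 0; the value grows with the
#' sharpness of the bend. Units: cm^-1. Endpoints copy their neighbour's
#' value; they are removed by [trim_ends()] at default settings anyway.
#'
#' @param centerline A `resampled_centerline` from [resample_spline()].
#' @param denominator `"mean_chord"` (default) or `"endpoint_chord"`.
#' @return A `curvature_profile`: list with `arc_pos`, `kappa_raw`,
#'   `kappa_smooth` (NA until [ci_moving_average()]), `valid_mask` (all TRUE
#'   until [trim_ends()]), `points`, `root_id`, `group`.
#' @export
turning_angle_curvature <- function(centerline,
                                    denominator = c("mean_chord",
                                                    "endpoint_chord")) {
  stopifnot(inherits(centerline, "resampled_centerline"))
  denominator <- match.arg(denominator)
  p <- centerline$points
  n <- nrow(p)
  if (n < 3) stop("Need at least 3 points for curvature.", call. = FALSE)
  v <- p[-1, , drop = FALSE] - p[-n, , drop = FALSE]
  len <- sqrt(rowSums(v^2))
  if (any(len == 0)) {
    stop("Zero-length chord in resampled centerline '",
         centerline$root_id, "'.", call. = FALSE)
  }
  v1 <- v[-(n - 1), , drop = FALSE]
  v2 <- v[-1, , drop = FALSE]
  cross <- v1[, 1] * v2[, 2] - v1[, 2] * v2[, 1]
  dot <- v1[, 1] * v2[, 1] + v1[, 2] * v2[, 2]
  dtheta <- abs(atan2(cross, dot))
  dist <- switch(denominator,
    mean_chord = (len[-(n - 1)] + len[-1]) / 2,
    endpoint_chord = {
      d13 <- p[-(1:2), , drop = FALSE] - p[1:(n - 2), , drop = FALSE]
      sqrt(rowSums(d13^2))
    }
  )
  kappa <- numeric(n)
  kappa[2:(n - 1)] <- dtheta / dist
  kappa[1] <- kappa[2]
  kappa[n] <- kappa[n - 1]
  structure(
    list(arc_pos = centerline$arc_pos, kappa_raw = kappa,
         kappa_smooth = rep(NA_real_, n), valid_mask = rep(TRUE, n),
         points = p, root_id = centerline$root_id, group = centerline$group,
         denominator = denominator),
    class = "curvature_profile"
  )
}

#' @export
print.curvature_profile <- function(x, ...) {
  cat("<curvature_profile> ", x$root_id, ": ", length(x$arc_pos), " points, ",
      sum(x$valid_mask), " valid\n", sep = "")
  invisible(x)
}

#' Moving-average smoothing of the curvature profile
#'
#' Replaces each raw value by the unweighted mean of raw values within
#' `half_window_cm` of arc length before and after (0.005 cm each side,
#' 0.01 cm total, by default: 11 points at 1,000 dots per cm). Windows are
#' inclusive and truncate at the profile ends. The smoothing absorbs the
#' point-to-point jitter introduced by manual placement of the digitizing
#' dots.
#'
#' @param profile A `curvature_profile` with `kappa_raw` filled.
#' @param half_window_cm Half window in cm (default 0.005).
#' @return The profile with `kappa_smooth` filled.
#' @export
ci_moving_average <- function(profile, half_window_cm = 0.005) {
  stopifnot(inherits(profile, "curvature_profile"))
  if (!is.numeric(half_window_cm) || length(half_window_cm) != 1 ||
      half_window_cm < 0) {
    stop("`half_window_cm` must be a non-negative number.", call. = FALSE)
  }
  s <- profile$arc_pos
  k <- profile$kappa_raw
  eps <- half_window_cm * 1e-9 + 1e-12
  lo <- findInterval(s - half_window_cm - eps, s) + 1L
  hi <- findInterval(s + half_window_cm + eps, s)
  cs <- c(0, cumsum(k))
  profile$kappa_smooth <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  profile$half_window_cm <- half_window_cm
  profile
}

#' Trim unreliable profile ends
#'
#' Marks the first and last `n_trim` points invalid (default 20): the spline
#' is least constrained near the manually placed first and last dots, so
#' those curvature values are excluded from all summaries.
#'
#' @param profile A `curvature_profile`.
#' @param n_trim Points to drop at each end (default 20).
#' @return The profile with `valid_mask` set.
#' @export
trim_ends <- function(profile, n_trim = 20) {
  stopifnot(inherits(profile, "curvature_profile"))
  if (!is.numeric(n_trim) || length(n_trim) != 1 || n_trim < 0 ||
      n_trim != round(n_trim)) {
    stop("`n_trim` must be a non-negative integer.", call. = FALSE)
  }
  n <- length(profile$arc_pos)
  if (n <= 2 * n_trim) {
    stop("Root '", profile$root_id, "' too short: ", n,
         " points cannot spare 2 x ", n_trim, " trimmed ends.", call. = FALSE)
  }
  mask <- rep(TRUE, n)
  if (n_trim > 0) {
    mask[seq_len(n_trim)] <- FALSE
    mask[seq(n - n_trim + 1L, n)] <- FALSE
  }
  profile$valid_mask <- mask
  profile$n_trim <- n_trim
  profile
}

#' Full per-root curvature pipeline
#'
#' Convenience wrapper running resample -> turning-angle curvature ->
#' moving average -> end trimming in the canonical order.
#'
#' @inheritParams resample_spline
#' @inheritParams turning_angle_curvature
#' @inheritParams ci_moving_average
#' @inheritParams trim_ends
#' @param smoothing Passed to [resample_spline()].
#' @return A trimmed, smoothed `curvature_profile` with the centerline's
#'   `total_length_L` attached.
#' @export
curvature_profile <- function(trace, density = 1000, half_window_cm = 0.005,
                              n_trim = 20,
                              denominator = c("mean_chord", "endpoint_chord"),
                              smoothing = c("gcv", "none")) {
  cl <- resample_spline(trace, density = density, smoothing = smoothing)
  prof <- turning_angle_curvature(cl, denominator = denominator)
  prof <- ci_moving_average(prof, half_window_cm = half_window_cm)
  prof <- trim_ends(prof, n_trim = n_trim)
  prof$total_length_L <- cl$total_length_L
  prof
}

#' Export a curvature profile as a tibble
#'
#' @param profile A `curvature_profile`.
#' @return Tibble with columns root_id, group, arc_pos, x, y, kappa_raw,
#'   kappa_smooth, valid.
#' @export
profile_table <- function(profile) {
  stopifnot(inherits(profile, "curvature_profile"))
  tibble::tibble(
    root_id = profile$root_id, group = profile$group,
    arc_pos = profile$arc_pos,
    x = profile$points[, 1], y = profile$points[, 2],
    kappa_raw = profile$kappa_raw, kappa_smooth = profile$kappa_smooth,
    valid = profile$valid_mask
  )
}
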