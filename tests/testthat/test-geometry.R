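test_that("a straight trace resamples to exact uniform spacing", {
  cl <- resample_spline(straight_trace(1, 90, n = 5), density = 1000)
  expect_equal(length(cl$arc_pos), 1001L)
  expect_equal(cl$total_length_L, 1, tolerance = 1e-9)
  expect_equal(diff(cl$arc_pos), rep(0.001, 1000), tolerance = 1e-9)
  expect_true(!is.unsorted(cl$arc_pos, strictly = TRUE))
  expect_equal(cl$arc_pos[1], 0)
})

test_that("arc length matches closed forms and is density-consistent", {
  # quarter circle, radius 1: L = pi/2
  th <- seq(0, pi / 2, length.out = 50)
  tr <- root_trace(cbind(cos(th), sin(th)), "qc")
  cl <- resample_spline(tr, density = 1000)
  expect_lt(abs(cl$total_length_L - pi / 2) / (pi / 2), 0.005)
  cl500 <- resample_spline(tr, density = 500)
  expect_lt(abs(cl500$total_length_L - cl$total_length_L) /
              cl$total_length_L, 0.005)
  # spacing within 1% of 1/density
  expect_lt(max(abs(diff(cl$arc_pos) - 1e-3)) / 1e-3, 0.01)
})

test_that("resampling parameter validation", {
  expect_error(resample_spline(straight_trace(), density = -5), "positive")
  expect_error(resample_spline(straight_trace(0.0005, 90, 3)), "short")
})

test_that("turning-angle curvature matches direct formula evaluation", {
  # three points (0,0),(1,0),(1,1): dtheta = pi/2, mean chord = 1
  cl <- structure(list(points = cbind(x = c(0, 1, 1), y = c(0, 0, 1)),
                       arc_pos = c(0, 1, 2), density = 1,
                       total_length_L = 2, root_id = "tri", group = NA),
                  class = "resampled_centerline")
  prof <- turning_angle_curvature(cl)
  expect_equal(prof$kappa_raw[2], pi / 2, tolerance = 1e-12)
  expect_equal(prof$kappa_raw[1], prof$kappa_raw[2])  # endpoint copies

  # endpoint-chord denominator: distance p1 -> p3 = sqrt(2)
  prof2 <- turning_angle_curvature(cl, denominator = "endpoint_chord")
  expect_equal(prof2$kappa_raw[2], pi / 2 / sqrt(2), tolerance = 1e-12)
})

test_that("collinear points give zero curvature everywhere", {
  cl <- resample_spline(straight_trace(2, 45, n = 9), density = 1000)
  prof <- turning_angle_curvature(cl)
  expect_true(all(prof$kappa_raw >= 0))
  expect_lt(max(prof$kappa_raw), 1e-8)
})

test_that("circle curvature equals 1/r pointwise and on average", {
  # r = 0.1 cm: kappa = 10 within 1% at every valid point
  prof <- curvature_profile(circle_trace(0.1, 300, 0.9))
  kv <- prof$kappa_smooth[prof$valid_mask]
  expect_true(all(abs(kv - 10) / 10 < 0.01))
  # circle oracle across radii: mean within 2% of 1/r
  for (r in c(0.05, 0.1, 0.5, 1.0)) {
    p <- curvature_profile(circle_trace(r, 300, 0.9))
    expect_lt(abs(mean(p$kappa_smooth[p$valid_mask]) - 1 / r) * r, 0.02)
  }
})

test_that("moving average matches a brute-force window mean", {
  # spike of height h among zeros: smoothed peak = h / 11 at default density
  k <- rep(0, 201); k[101] <- 7
  prof <- manual_profile(k)
  sm <- ci_moving_average(prof, 0.005)
  expect_equal(max(sm$kappa_smooth), 7 / 11, tolerance = 1e-12)

  # brute-force oracle on an arbitrary profile, including truncated ends
  set.seed(9)
  k2 <- abs(rnorm(101))
  prof2 <- ci_moving_average(manual_profile(k2), 0.005)
  oracle <- vapply(seq_along(k2), function(i) {
    w <- abs(prof2$arc_pos - prof2$arc_pos[i]) <= 0.005 + 1e-12
    mean(k2[w])
  }, numeric(1))
  expect_equal(prof2$kappa_smooth, oracle, tolerance = 1e-12)

  # constant profile is untouched; zero window is the identity
  pc <- ci_moving_average(manual_profile(rep(3, 50)), 0.005)
  expect_equal(pc$kappa_smooth, rep(3, 50))
  p0 <- ci_moving_average(manual_profile(k2), 0)
  expect_equal(p0$kappa_smooth, k2)
  expect_error(ci_moving_average(manual_profile(k2), -1), "non-negative")
})

test_that("smoothed values stay within the raw range of their window", {
  set.seed(4)
  prof <- ci_moving_average(manual_profile(abs(rnorm(300))), 0.005)
  expect_true(all(prof$kappa_smooth <= max(prof$kappa_raw) + 1e-12))
  expect_true(all(prof$kappa_smooth >= min(prof$kappa_raw) - 1e-12))
})

test_that("end trimming sets the valid mask and guards short profiles", {
  prof <- trim_ends(manual_profile(rep(1, 1001)), 20)
  expect_equal(sum(prof$valid_mask), 961L)
  expect_true(all(!prof$valid_mask[1:20]))
  expect_true(all(!prof$valid_mask[982:1001]))
  expect_true(all(prof$valid_mask[21:981]))

  p0 <- trim_ends(manual_profile(rep(1, 30)), 0)
  expect_true(all(p0$valid_mask))
  expect_error(trim_ends(manual_profile(rep(1, 30), root_id = "shorty"), 20),
               "shorty")
})

test_that("curvature is invariant under rigid motions", {
  cv <- make_curve(root_archetype("gradual_wave"))
  tr <- digitize(cv, digitizer_model(200, 0, spacing_jitter = 0, seed = 3))
  moved <- root_trace(tr$points %*% t(rot2(37)) +
                        matrix(c(3, -5), tr$n_points, 2, byrow = TRUE),
                      "moved")
  # interpolating path: exact equivariance
  k0 <- curvature_profile(tr, smoothing = "none")
  k1 <- curvature_profile(moved, smoothing = "none")
  expect_lt(max(abs(k0$kappa_raw - k1$kappa_raw)), 1e-6)
  # denoising path: equivariance only up to the data-driven penalty choice
  g0 <- curvature_profile(tr)
  g1 <- curvature_profile(moved)
  mean_ci <- mean(g0$kappa_smooth[g0$valid_mask])
  expect_lt(max(abs(g0$kappa_smooth - g1$kappa_smooth)), 0.01 * mean_ci)
})

test_that("curvature scales as 1/c under uniform scaling", {
  cv <- make_curve(root_archetype("gradual_wave"))
  tr <- digitize(cv, digitizer_model(200, 0, spacing_jitter = 0, seed = 3))
  big <- root_trace(tr$points * 3, "x3")
  p1 <- curvature_profile(tr)
  p3 <- curvature_profile(big)
  m1 <- mean(p1$kappa_smooth[p1$valid_mask])
  m3 <- mean(p3$kappa_smooth[p3$valid_mask])
  expect_lt(abs(m3 * 3 - m1) / m1, 0.01)
})

test_that("resampling an already-uniform curve reproduces it pointwise", {
  cv <- make_curve(root_archetype("gradual_wave"))
  tr <- digitize(cv, digitizer_model(300, 0, spacing_jitter = 0, seed = 1))
  cl <- resample_spline(tr)
  again <- resample_spline(root_trace(cl$points, "again"))
  n <- min(nrow(cl$points), nrow(again$points))
  dev <- sqrt(rowSums((cl$points[1:n, ] - again$points[1:n, ])^2))
  expect_lt(max(dev), 1e-4)
})

test_that("profile_table exports all pipeline columns", {
  tb <- profile_table(curvature_profile(straight_trace(1, 90, 10)))
  expect_named(tb, c("root_id", "group", "arc_pos", "x", "y",
                     "kappa_raw", "kappa_smooth", "valid"))
  expect_equal(nrow(tb), 1001L)
  expect_equal(sum(tb$valid), 961L)
})
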