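# Geometric fixtures built in code.

# straight root of given length at a given angle from the horizontal
# (degrees, positive toward gravity in the y-up frame), base at `base`
straight_trace <- function(length_cm = 2, angle_deg = 90, n = 5,
                           base = c(0, 0), root_id = "straight",
                           group = NA_character_) {
  th <- angle_deg * pi / 180
  dirv <- c(cos(th), -sin(th))
  t <- seq(0, length_cm, length.out = n)
  root_trace(cbind(base[1] + dirv[1] * t, base[2] + dirv[2] * t),
             root_id = root_id, group = group)
}

# circular arc of radius r covering `turns` full revolutions
circle_trace <- function(r, n = 200, turns = 0.9, root_id = "circle",
                         group = NA_character_, phase = 0) {
  th <- phase + seq(0, 2 * pi * turns, length.out = n)
  root_trace(cbind(r * cos(th), r * sin(th)), root_id = root_id,
             group = group)
}

rot2 <- function(theta_deg) {
  th <- theta_deg * pi / 180
  matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
}

# hand-built curvature profile (bypasses the geometry pipeline) for testing
# the summary operations in isolation
manual_profile <- function(kappa, spacing = 0.001, valid = NULL,
                           root_id = "manual") {
  n <- length(kappa)
  arc <- (seq_len(n) - 1) * spacing
  structure(
    list(arc_pos = arc, kappa_raw = kappa, kappa_smooth = kappa,
         valid_mask = if (is.null(valid)) rep(TRUE, n) else valid,
         points = cbind(x = arc, y = 0), root_id = root_id,
         group = NA_character_),
    class = "curvature_profile"
  )
}
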