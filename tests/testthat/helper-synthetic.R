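# Shared fixtures, all built in code.

# Two-circular-arc meridian: cornea R_cornea joined C0 to sclera R_sclera at
# r_junction (centres on the meridian's own axis, so the junction is a kink).
two_arc_profile <- function(r_junction = 5.9, R_cornea = 7.8, R_sclera = 11.5,
                            step = 0.05, r_max = 10, noise_sd = 0) {
  r <- seq(0, r_max, step)
  z_crn <- sqrt(R_cornea^2 - pmin(r, r_junction)^2) - R_cornea
  z_lim <- sqrt(R_cornea^2 - r_junction^2) - R_cornea
  zc <- z_lim - sqrt(R_sclera^2 - r_junction^2)
  z <- ifelse(r <= r_junction, z_crn, zc + sqrt(R_sclera^2 - r^2))
  if (noise_sd > 0) z <- z + stats::rnorm(length(z), 0, noise_sd)
  mk_profile(r, z)
}

mk_profile <- function(r, z, valid = rep(TRUE, length(r)), angle = 0) {
  structure(list(angle = angle, r = r, z = z, valid = valid),
            class = "meridian_profile")
}

# Dense scattered samples of an upper hemisphere cap, apex at the origin.
hemisphere_cloud <- function(n = 120000, R = 11.5, r_max = 10,
                             noise_sd = 0, center = c(0, 0), laterality = "OD") {
  r <- r_max * sqrt(stats::runif(n))
  th <- stats::runif(n, -pi, pi)
  x <- center[1] + r * cos(th)
  y <- center[2] + r * sin(th)
  z <- sqrt(R^2 - r^2) - R + if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else 0
  eye_cloud(x, y, z, laterality, "anatomical", "helper-hemisphere")
}

# Uniform random points on a spherical cap (upper sheet) of half-angle
# `half_deg` about the +z axis of a sphere centred at `ctr`.
sphere_cap_points <- function(n, ctr = c(0.3, -0.2, -8.0), R = 11.5,
                              half_deg = 60) {
  th <- stats::runif(n, 0, 2 * pi)
  phi <- acos(stats::runif(n, cos(half_deg * pi / 180), 1))
  cbind(x = ctr[1] + R * sin(phi) * cos(th),
        y = ctr[2] + R * sin(phi) * sin(th),
        z = ctr[3] + R * cos(phi))
}

# Independent brute-force oracle for the sliding-window statistic: explicit
# double loop over both window caps, no shared code with the implementation.
naive_moving_stat <- function(values, grid, halfwidth, max_elements, stat) {
  n <- length(values)
  half_idx <- (max_elements - 1) %/% 2
  out <- numeric(n)
  f <- if (stat == "median") stats::median else mean
  for (i in seq_len(n)) {
    w <- c()
    for (j in seq_len(n)) {
      if (abs(j - i) <= half_idx && abs(grid[j] - grid[i]) <= halfwidth + 1e-12)
        w <- c(w, values[j])
    }
    out[i] <- f(w)
  }
  out
}

# An exact analytic polar surface (hemisphere) on the standard grid; every
# meridian is identical, so asymmetry of anything derived from it is exactly
# zero.
analytic_hemisphere_surface <- function(R = 11.5, r_max = 10, step = 0.05) {
  r <- seq(0, r_max, step)
  angles <- seq(-180, 179)
  z <- matrix(rep(sqrt(R^2 - r^2) - R, length(angles)), ncol = length(angles))
  structure(list(angles = angles, r = r, z = z,
                 valid = matrix(TRUE, length(r), length(angles)),
                 angular_step = 1, radial_step = step),
            class = "polar_surface")
}
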