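# Eye levelling: per-meridian limbus detection from the second derivative of
# raw elevation, total-least-squares limbus plane, tilt angles, rigid
# rotation, and apex re-origin.

# Gaussian smoothing of a uniformly gridded signal (reflective ends).
gaussian_smooth <- function(z, step, sigma) {
  if (sigma <= 0) return(z)
  half <- max(1L, ceiling(3 * sigma / step))
  k <- stats::dnorm(seq(-half, half) * step, sd = sigma)
  k <- k / sum(k)
  n <- length(z)
  zp <- c(z[pmin(half:1 + 1L, n)], z, z[pmax(n - (1:half), 1L)])
  stats::filter(zp, k, sides = 2)[(half + 1L):(half + n)]
}

central_diff <- function(z, step) {
  n <- length(z)
  d <- numeric(n)
  if (n >= 3L) d[2:(n - 1)] <- (z[3:n] - z[1:(n - 2)]) / (2 * step)
  d[1] <- (z[2] - z[1]) / step
  d[n] <- (z[n] - z[n - 1]) / step
  d
}

# Contiguous working copy of a meridian profile: the span from the first to
# the last valid node at radii >= r_min, with interior gaps (missing nodes
# from sampling voids) bridged by linear interpolation so that smoothing and
# finite differences see a uniform grid. Leading/trailing invalid stretches
# are dropped, never extrapolated. `r_min` lets callers skip the apex zone,
# where areal sampling is geometrically thin. Returns NULL when unusable.
profile_contiguous <- function(profile, max_gap_frac = 0.25, r_min = 0) {
  v <- profile$valid & profile$r >= r_min
  if (sum(v) < 4L) return(NULL)
  first <- which(v)[1L]
  last <- which(v)[sum(v)]
  sel <- first:last
  if (mean(!v[sel]) > max_gap_frac) return(NULL)
  r <- profile$r[sel]
  z <- profile$z[sel]
  miss <- !v[sel]
  if (any(miss)) {
    z[miss] <- stats::approx(r[!miss], z[!miss], xout = r[miss])$y
  }
  list(r = r, z = z, index = sel, filled = miss)
}

#' Detect the limbus radius on one meridian
#'
#' The cornea and the sclera have different curvatures, and at the
#' corneoscleral junction the meridian's slope changes at its fastest rate.
#' After Gaussian smoothing (`sigma`, default 0.15 mm) of the elevation,
#' the second derivative of z(r) carries a localized excursion at the
#' junction; the limbus is located as the turning point of that second
#' derivative — the interior local extremum deviating most from the
#' window's median level — refined to sub-grid precision by a parabolic
#' fit. A meridian with no prominent interior extremum (e.g. a single
#' sphere, whose curvature varies smoothly) returns `NA`.
#'
#' @param profile A `meridian_profile` (uniform radial grid, apex-relative z).
#' @param search_window Radii in mm to search, default `c(3.5, 8.5)`.
#' @param sigma Smoothing scale in mm applied before each differentiation.
#' @param prominence_factor The winning extremum must deviate from the
#'   window median by at least this multiple of the window's median
#'   absolute deviation (default 6; the junction excursion is an order of
#'   magnitude above the smooth-curvature background).
#' @return Limbus radius in mm, or `NA_real_` when not found.
#' @export
detect_limbus_meridian <- function(profile, search_window = c(3.5, 8.5),
                                   sigma = 0.15, prominence_factor = 6) {
  ct <- profile_contiguous(profile, r_min = max(0, search_window[1] - 1))
  if (is.null(ct)) return(NA_real_)
  r <- ct$r; z <- ct$z
  step <- r[2] - r[1]
  if (length(r) < 15L) return(NA_real_)
  zs <- gaussian_smooth(z, step, sigma)
  d1 <- central_diff(zs, step)
  d2 <- gaussian_smooth(central_diff(d1, step), step, sigma)
  win <- which(r >= search_window[1] & r <= search_window[2])
  win <- win[win > 2L & win < length(r) - 1L]
  if (length(win) < 5L) return(NA_real_)
  med <- stats::median(d2[win])
  mad <- stats::median(abs(d2[win] - med))
  # the corneoscleral transition is always a positive excursion of z'':
  # meridian slope steps from the steeper cornea to the flatter sclera
  dev <- d2 - med
  interior <- win[-c(1L, length(win))]
  is_peak <- dev[interior] >= dev[interior - 1L] & dev[interior] >= dev[interior + 1L]
  peaks <- interior[is_peak]
  peaks <- peaks[dev[peaks] >= prominence_factor * max(mad, 1e-12)]
  if (length(peaks) == 0L) return(NA_real_)
  # innermost prominent excursion: the first curvature transition beyond the
  # cornea is the limbus; edge artefacts produce later (outer) excursions
  best <- peaks[1L]
  # sub-grid refinement: parabola through the extremum and its neighbours
  y0 <- dev[best - 1L]; y1 <- dev[best]; y2 <- dev[best + 1L]
  denom <- y0 - 2 * y1 + y2
  off <- if (abs(denom) > 1e-15) 0.5 * (y0 - y2) / denom else 0
  r[best] + max(-1, min(1, off)) * step
}

#' Fit a plane to limbus points by total least squares
#'
#' Minimises orthogonal distances via the SVD of the centred coordinates;
#' the plane normal is the singular vector of the smallest singular value,
#' oriented so Nz > 0 (out of the eye).
#'
#' @param pts Matrix or data.frame with columns x, y, z (>= 3 points).
#' @return List with unit `normal` (length-3), `offset` (d in n.p = d) and
#'   `rms` orthogonal residual.
#' @export
fit_limbus_plane <- function(pts) {
  pts <- as.matrix(pts)[, 1:3, drop = FALSE]
  if (nrow(pts) < 3L) stop("plane fit needs at least 3 points")
  ctr <- colMeans(pts)
  sv <- svd(sweep(pts, 2, ctr))
  if (sv$d[2] < 1e-12 * max(sv$d[1], 1)) stop("collinear points: plane undefined")
  n <- sv$v[, 3]
  if (n[3] < 0) n <- -n
  if (n[3] == 0) stop("degenerate vertical limbus plane")
  n <- n / sqrt(sum(n^2))
  list(normal = n, offset = sum(n * ctr),
       rms = sqrt(mean((sweep(pts, 2, ctr) %*% n)^2)))
}

#' Tilt angles of a limbus plane
#'
#' The tilt about each lateral axis is obtained from the inverse cosine of
#' the dot product of the unit plane normal with that axis' orthogonal unit
#' vector: `alpha_x = -pi/2 + acos(N . (0,1,0))` and
#' `alpha_y = -pi/2 + acos(N . (1,0,0))`. A level plane (N = e_z) gives
#' (0, 0); N = (0, sin t, cos t) gives alpha_x = -t.
#'
#' @param normal Unit normal with Nz > 0 (normalised with a warning if not
#'   unit length).
#' @return Named numeric `c(alpha_x, alpha_y)` in radians.
#' @export
tilt_angles <- function(normal) {
  stopifnot(length(normal) == 3L)
  nn <- sqrt(sum(normal^2))
  if (abs(nn - 1) > 1e-9) {
    warning("tilt_angles: normal not unit length; normalising")
    normal <- normal / nn
  }
  if (normal[3] <= 0) stop("tilt_angles: normal must point out of the eye (Nz > 0)")
  c(alpha_x = -pi / 2 + acos(sum(normal * c(0, 1, 0))),
    alpha_y = -pi / 2 + acos(sum(normal * c(1, 0, 0))))
}

#' Rotate a surface level
#'
#' Applies the rigid rotation `Ry(alpha_y) Rx(-alpha_x)` (rotation about the
#' z-axis fixed at zero), which maps a limbus-plane normal with tilt angles
#' `(alpha_x, alpha_y)` onto the vertical up to second order in the angles;
#' the pipeline iterates detection and rotation until the refitted normal is
#' vertical to tolerance.
#'
#' @param cloud An [eye_cloud()].
#' @param alpha_x,alpha_y Tilt angles in radians, |alpha| < pi/4.
#' @return The rotated cloud.
#' @export
level_surface <- function(cloud, alpha_x, alpha_y) {
  stopifnot(inherits(cloud, "eye_cloud"),
            is.finite(alpha_x), is.finite(alpha_y),
            abs(alpha_x) < pi / 4, abs(alpha_y) < pi / 4)
  R <- rot_y(alpha_y) %*% rot_x(-alpha_x)
  p <- R %*% rbind(cloud$x, cloud$y, cloud$z)
  cloud$x <- p[1, ]; cloud$y <- p[2, ]; cloud$z <- p[3, ]
  cloud
}

#' Re-origin a levelled cloud at its apex
#'
#' The apex is the surface's highest point, refined by a local quadratic
#' fit over its 0.5 mm neighbourhood so it does not sit on the sampling
#' grid. An apex lying on the convex-hull boundary of the lateral support
#' indicates a decentred measurement and raises an error.
#'
#' @param cloud A levelled [eye_cloud()].
#' @param refine_radius Neighbourhood radius for the quadratic fit (mm).
#' @return The translated cloud, apex at the origin.
#' @export
recenter_apex <- function(cloud, refine_radius = 0.5) {
  stopifnot(inherits(cloud, "eye_cloud"))
  i0 <- which.max(cloud$z)
  hull <- grDevices::chull(cloud$x, cloud$y)
  # distance from the raw apex to the convex-hull boundary of the support
  hx <- cloud$x[hull]; hy <- cloud$y[hull]
  nh <- length(hull)
  seg_dist <- vapply(seq_len(nh), function(j) {
    k <- if (j == nh) 1L else j + 1L
    vx <- hx[k] - hx[j]; vy <- hy[k] - hy[j]
    t <- ((cloud$x[i0] - hx[j]) * vx + (cloud$y[i0] - hy[j]) * vy) /
      max(vx^2 + vy^2, 1e-300)
    t <- min(max(t, 0), 1)
    sqrt((cloud$x[i0] - hx[j] - t * vx)^2 + (cloud$y[i0] - hy[j] - t * vy)^2)
  }, numeric(1))
  if (min(seg_dist) < refine_radius / 2)
    stop("apex-at-edge: highest point lies on the boundary of the lateral support; ",
         "measurement likely decentred")
  dx <- cloud$x - cloud$x[i0]
  dy <- cloud$y - cloud$y[i0]
  nb <- which(dx^2 + dy^2 <= refine_radius^2)
  apex <- c(cloud$x[i0], cloud$y[i0], cloud$z[i0])
  if (length(nb) >= 8L) {
    fit <- stats::lm.fit(cbind(1, dx[nb], dy[nb], dx[nb]^2, dx[nb] * dy[nb], dy[nb]^2),
                         cloud$z[nb])
    b <- fit$coefficients
    A <- matrix(c(2 * b[4], b[5], b[5], 2 * b[6]), 2, 2)
    if (all(is.finite(b)) && det(A) > 1e-12) {   # strictly concave quadric
      st <- -solve(A, b[2:3])
      if (all(abs(st) <= refine_radius)) {
        apex <- c(cloud$x[i0] + st[1], cloud$y[i0] + st[2],
                  b[1] + b[2] * st[1] + b[3] * st[2] + b[4] * st[1]^2 +
                    b[5] * st[1] * st[2] + b[6] * st[2]^2)
      }
    }
  }
  cloud$x <- cloud$x - apex[1]
  cloud$y <- cloud$y - apex[2]
  cloud$z <- cloud$z - apex[3]
  cloud
}

# Circular moving median of per-meridian limbus radii: the limbus is a
# smooth anatomical curve, so isolated detection outliers are suppressed
# before the plane fit.
circular_median_smooth <- function(v, half = 5L) {
  n <- length(v)
  out <- v
  for (i in seq_len(n)) {
    idx <- ((i - half):(i + half) - 1L) %% n + 1L
    w <- v[idx]
    if (all(is.na(w))) next
    out[i] <- stats::median(w, na.rm = TRUE)
  }
  out
}

#' Detect the limbus and level an eye surface
#'
#' Full levelling stage: resample to meridians, detect the limbus on each,
#' smooth the limbal radii circumferentially (moving median over 11
#' meridians), fit the limbus plane, rotate level, and iterate until the
#' refitted plane normal is vertical within `tol` (max `max_iter` passes).
#' Finally the origin is shifted to the refined apex.
#'
#' @param cloud An [eye_cloud()] in the anatomical frame.
#' @param angular_step,radial_step Resampling grid (degrees / mm).
#' @param search_window Limbus search window in mm.
#' @param plausible Acceptance band for limbal radii in mm; detections
#'   outside are flagged and excluded from the plane fit.
#' @param tol Residual normal tilt tolerance in radians (default 1e-6),
#'   assessed on the plane refitted to the rotated limbus points.
#' @param max_iter Maximum geometric rotate-refit iterations per pass.
#' @param redetect_passes Full limbus re-detection passes (default 2: once
#'   on the raw surface, once after levelling).
#' @return List of class `levelled_eye`: `cloud` (levelled, apex at origin),
#'   `limbus` (a `limbus_fit`: per-meridian limbus table, plane normal,
#'   angles in radians with `alpha_z = 0`, mean limbal radius), `surface`
#'   (the final polar resampling), `tilt_applied` (total correction,
#'   radians), `iterations`.
#' @export
level_eye <- function(cloud, angular_step = 1, radial_step = 0.05,
                      search_window = c(3.5, 8.5), plausible = c(3, 9),
                      tol = 1e-6, max_iter = 5, redetect_passes = 2) {
  stopifnot(inherits(cloud, "eye_cloud"))
  total <- c(alpha_x = 0, alpha_y = 0)
  first_tilt <- NULL
  plane <- NULL
  iters <- 0L
  for (pass in seq_len(redetect_passes)) {
    surface <- resample_polar(cloud, angular_step, radial_step,
                              center = if (pass == 1L) "max_z" else "origin")
    det <- detect_limbus_all(surface, search_window, plausible)
    if (sum(det$accepted) < 3L)
      stop("limbus detected on fewer than 3 meridians; cannot level")
    r_s <- circular_median_smooth(ifelse(det$accepted, det$r_limbus, NA_real_))
    acc <- det$accepted & is.finite(r_s)
    pts <- cbind(x = r_s[acc] * cos(det$angle[acc] * pi / 180),
                 y = r_s[acc] * sin(det$angle[acc] * pi / 180),
                 z = interp_meridian_z(surface, which(acc), r_s[acc]))
    pts <- pts[is.finite(pts[, 3]), , drop = FALSE]
    # inner geometric loop: rotate cloud and the detected limbus points
    # together until the plane refitted to those points is vertical — this
    # converges quadratically; re-detection (outer pass) only refreshes the
    # points, whose measurement noise would otherwise floor the tolerance
    for (it in seq_len(max_iter)) {
      plane <- fit_limbus_plane(pts)
      ang <- tilt_angles(plane$normal)
      if (is.null(first_tilt)) first_tilt <- ang
      iters <- iters + 1L
      if (acos(min(1, plane$normal[3])) < tol) break
      cloud <- level_surface(cloud, ang[1], ang[2])
      R <- rot_y(ang[2]) %*% rot_x(-ang[1])
      pts <- t(R %*% t(pts))
      total <- total + ang
    }
  }
  if (acos(min(1, plane$normal[3])) >= tol)
    warning("levelling did not reach tolerance after ", max_iter, " iterations (residual ",
            signif(acos(min(1, plane$normal[3])), 3), " rad)")
  it <- iters
  cloud <- recenter_apex(cloud)
  surface <- resample_polar(cloud, angular_step, radial_step, center = "origin")
  det <- detect_limbus_all(surface, search_window, plausible)
  r_s <- circular_median_smooth(ifelse(det$accepted, det$r_limbus, NA_real_))
  limbus <- structure(list(
    table = data.frame(angle_deg = det$angle, r_limbus_mm = det$r_limbus,
                       r_smoothed_mm = r_s, accepted = det$accepted),
    plane_normal = plane$normal, plane_offset = plane$offset,
    alpha_x = unname(first_tilt[1]), alpha_y = unname(first_tilt[2]), alpha_z = 0,
    mean_limbus_radius = mean(r_s[det$accepted], na.rm = TRUE)),
    class = "limbus_fit")
  structure(list(cloud = cloud, limbus = limbus, surface = surface,
                 tilt_applied = total, iterations = it),
            class = "levelled_eye")
}

detect_limbus_all <- function(surface, search_window = c(3.5, 8.5),
                              plausible = c(3, 9)) {
  r_l <- vapply(seq_along(surface$angles), function(k) {
    detect_limbus_meridian(meridian_profile(surface, surface$angles[k]),
                           search_window)
  }, numeric(1))
  accepted <- is.finite(r_l) & r_l >= plausible[1] & r_l <= plausible[2]
  list(angle = surface$angles, r_limbus = r_l, accepted = accepted)
}

# Elevation at arbitrary radii on given meridians, by linear interpolation
# of the resampled profile (NA outside valid support).
interp_meridian_z <- function(surface, cols, r_at) {
  vapply(seq_along(cols), function(j) {
    k <- cols[j]
    v <- surface$valid[, k]
    if (sum(v) < 2L) return(NA_real_)
    stats::approx(surface$r[v], surface$z[v, k], xout = r_at[j], rule = 1)$y
  }, numeric(1))
}

#' @export
print.limbus_fit <- function(x, ...) {
  cat(sprintf("<limbus_fit> mean radius %.3f mm, tilt (%.3f, %.3f) deg, %d/%d meridians accepted\n",
              x$mean_limbus_radius, x$alpha_x * 180 / pi, x$alpha_y * 180 / pi,
              sum(x$table$accepted), nrow(x$table)))
  invisible(x)
}
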