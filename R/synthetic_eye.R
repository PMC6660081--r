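# Synthetic corneoscleral surfaces with planted ground truth.
#
# The generator emulates the surface class the processing pipeline assumes:
# a convex aspheric cornea joined at the limbus (~12 mm diameter) to a
# near-spherical sclera, measured as a dense elevation point cloud with a
# natural tilt of a few degrees, micrometre-scale height noise, and
# peripheral edge artefacts (lid lift-off, tear pooling, lash spikes).

#' Specify an edge artefact for the synthetic eye
#'
#' @param kind `"liftoff"` (surface ramps up beyond the onset, the way lid
#'   or lash interference lifts the tear surface), `"tearpool"` (a localized
#'   dip at the lid margin) or `"lash_spike"` (narrow high-amplitude bump).
#' @param onset_radius Radius in mm where the artefact starts; must lie
#'   beyond the limbus.
#' @param angular_extent Two angles (degrees, anatomical convention) between
#'   which the artefact applies; the sector runs counter-clockwise from the
#'   first to the second.
#' @param amplitude Height amplitude in mm (nonzero).
#' @param ramp_width Radial scale of the artefact's rise in mm.
#' @return An `artefact_spec` list.
#' @export
artefact_spec <- function(kind = c("liftoff", "tearpool", "lash_spike"),
                          onset_radius, angular_extent = c(-180, 180),
                          amplitude = 0.4, ramp_width = 0.1) {
  kind <- match.arg(kind)
  stopifnot(onset_radius > 0, amplitude != 0, ramp_width > 0,
            length(angular_extent) == 2L)
  structure(list(kind = kind, onset_radius = onset_radius,
                 angular_extent = angular_extent, amplitude = amplitude,
                 ramp_width = ramp_width), class = "artefact_spec")
}

#' Recipe for one synthetic eye
#'
#' Defaults describe a physiologically typical eye: corneal apical radius
#' 7.8 mm with prolate asphericity Q = -0.25, limbus radius 5.95 mm
#' (HVID about 11.9 mm), scleral radius 11.5 mm, height noise 5 um.
#'
#' @param corneal_radius Apical corneal radius of curvature, mm.
#' @param corneal_q Conicoid asphericity Q (negative = prolate).
#' @param limbus_radius Limbal radius, mm.
#' @param scleral_radius Scleral sphere radius, mm.
#' @param scleral_centre_offset Lateral (dx, dy) offset of the scleral
#'   sphere centre in mm; a simple asymmetry control.
#' @param asymmetry_harmonics List of `c(order, amplitude_mm, phase_deg)`
#'   triples modulating scleral height as
#'   `amplitude * cos(order * (theta - phase))`.
#' @param tilt Planted tilt `c(alpha_x, alpha_y)` in degrees: the rotation
#'   the levelling stage must undo.
#' @param noise_sd Gaussian height-noise standard deviation in mm
#'   (applied along z, as a profilometer measures height).
#' @param artefacts List of [artefact_spec()] objects.
#' @param point_count Number of surface samples (>= 1000).
#' @param r_max Scan radius, mm (instrument covers up to 10 mm).
#' @param laterality `"OD"` or `"OS"`.
#' @param c1_blend Half-width in mm of an optional smooth blend of the
#'   corneoscleral junction (0 keeps the plain C0 junction whose curvature
#'   step the limbus detector exploits).
#' @param seed Mandatory integer seed.
#' @return An `eye_recipe` list.
#' @export
eye_recipe <- function(corneal_radius = 7.8, corneal_q = -0.25,
                       limbus_radius = 5.95, scleral_radius = 11.5,
                       scleral_centre_offset = c(0, 0),
                       asymmetry_harmonics = list(),
                       tilt = c(0, 0), noise_sd = 0.005,
                       artefacts = list(), point_count = 120000L,
                       r_max = 10, laterality = "OD", c1_blend = 0,
                       seed) {
  if (missing(seed)) stop("eye_recipe: a seed is mandatory for reproducibility")
  stopifnot(corneal_radius > 0, scleral_radius > 0, limbus_radius > 0,
            limbus_radius < scleral_radius, point_count >= 1000L,
            noise_sd >= 0, r_max > limbus_radius, c1_blend >= 0)
  structure(list(corneal_radius = corneal_radius, corneal_q = corneal_q,
                 limbus_radius = limbus_radius, scleral_radius = scleral_radius,
                 scleral_centre_offset = scleral_centre_offset,
                 asymmetry_harmonics = asymmetry_harmonics,
                 tilt = tilt, noise_sd = noise_sd, artefacts = artefacts,
                 point_count = as.integer(point_count), r_max = r_max,
                 laterality = laterality, c1_blend = c1_blend,
                 seed = as.integer(seed)),
            class = "eye_recipe")
}

# Conicoid sag (height drop from apex): s(r) = r^2 / (R (1 + sqrt(1 - (1+Q) r^2/R^2)))
conicoid_sag <- function(r, R, Q) {
  disc <- 1 - (1 + Q) * r^2 / R^2
  if (any(disc < 0)) stop("conicoid undefined at the requested radius")
  r^2 / (R * (1 + sqrt(disc)))
}

# Noise-free generated height z(r, theta) in the untilted anatomical frame,
# apex at the origin. theta in degrees.
eye_true_height <- function(recipe, r, theta_deg) {
  rl <- recipe$limbus_radius
  Rs <- recipe$scleral_radius
  z_limbus <- -conicoid_sag(rl, recipe$corneal_radius, recipe$corneal_q)
  zc <- z_limbus - sqrt(Rs^2 - rl^2)
  dx <- recipe$scleral_centre_offset[1]
  dy <- recipe$scleral_centre_offset[2]
  z <- numeric(length(r))
  crn <- r <= rl
  z[crn] <- -conicoid_sag(r[crn], recipe$corneal_radius, recipe$corneal_q)
  if (any(!crn)) {
    xs <- r[!crn] * cos(theta_deg[!crn] * pi / 180) - dx
    ys <- r[!crn] * sin(theta_deg[!crn] * pi / 180) - dy
    lat2 <- pmin(xs^2 + ys^2, Rs^2)
    # keep the junction continuous on average when the centre is offset
    if (dx != 0 || dy != 0) {
      phi <- seq(0, 2 * pi, length.out = 90)
      gap <- mean(sqrt(Rs^2 - (rl * cos(phi) - dx)^2 - (rl * sin(phi) - dy)^2))
      zc <- z_limbus - gap
    }
    z[!crn] <- zc + sqrt(Rs^2 - lat2)
  }
  if (recipe$c1_blend > 0) {
    # cosine cross-fade between the two branches across the junction
    w <- recipe$c1_blend
    bl <- abs(r - rl) < w
    if (any(bl)) {
      t <- (r[bl] - (rl - w)) / (2 * w)
      mix <- (1 - cos(pi * t)) / 2
      z_crn <- -conicoid_sag(pmin(r[bl], rl), recipe$corneal_radius, recipe$corneal_q)
      xs <- r[bl] * cos(theta_deg[bl] * pi / 180) - dx
      ys <- r[bl] * sin(theta_deg[bl] * pi / 180) - dy
      z_scl <- zc + sqrt(pmax(Rs^2 - xs^2 - ys^2, 0))
      z[bl] <- (1 - mix) * z_crn + mix * z_scl
    }
  }
  # scleral asymmetry harmonics, faded in smoothly (zero slope at both
  # ends) between 0.75 and 1.75 mm beyond the limbus so neither the limbus
  # circle nor its curvature signature is touched
  if (length(recipe$asymmetry_harmonics) > 0) {
    t_ <- pmin(1, pmax(0, (r - rl - 0.75) / 1))
    w <- t_^2 * (3 - 2 * t_)
    for (h in recipe$asymmetry_harmonics) {
      z <- z + w * h[2] * cos(h[1] * (theta_deg - h[3]) * pi / 180)
    }
  }
  z
}

in_sector <- function(theta_deg, extent) {
  if (diff(extent) >= 360) return(rep(TRUE, length(theta_deg)))
  a <- wrap_angle(extent[1]); b <- wrap_angle(extent[2])
  t <- wrap_angle(theta_deg)
  if (a <= b) t >= a & t <= b else t >= a | t <= b
}

apply_artefacts <- function(z, r, theta_deg, artefacts) {
  onset_by_point <- rep(Inf, length(r))
  for (a in artefacts) {
    sel <- in_sector(theta_deg, a$angular_extent) & r > a$onset_radius
    if (!any(sel)) {
      onset_by_point <- pmin(onset_by_point,
        ifelse(in_sector(theta_deg, a$angular_extent), a$onset_radius, Inf))
      next
    }
    d <- r[sel] - a$onset_radius
    dz <- switch(a$kind,
      liftoff = a$amplitude * pmin(1, d / a$ramp_width),
      # sharp drop just past the onset, slow recovery: the elevation minimum
      # (what strategy 2 cuts at) sits within a few hundredths of a mm of
      # the onset
      tearpool = -abs(a$amplitude) * pmin(1, d / min(a$ramp_width / 3, 0.03)) *
        exp(-pmax(0, d - min(a$ramp_width / 3, 0.03)) / a$ramp_width),
      lash_spike = a$amplitude * exp(-(d / a$ramp_width)^2) * 4 *
        pmin(1, d / (a$ramp_width / 4)))
    z[sel] <- z[sel] + dz
    onset_by_point <- pmin(onset_by_point,
      ifelse(in_sector(theta_deg, a$angular_extent), a$onset_radius, Inf))
  }
  list(z = z, onset = onset_by_point)
}

# Rotation matrices (right-handed, active).
rot_x <- function(a) matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
rot_y <- function(a) matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)

# The levelling stage applies R_level = Ry(ay) Rx(-ax); the generator tilts
# by its inverse so the tilt angles measured on the tilted surface equal the
# planted (ax, ay) up to second order.
tilt_matrix <- function(alpha_x_deg, alpha_y_deg) {
  ax <- alpha_x_deg * pi / 180
  ay <- alpha_y_deg * pi / 180
  rot_x(ax) %*% rot_y(-ay)
}

#' Generate one synthetic eye with ground truth
#'
#' Samples `point_count` positions uniformly over the scan disc, evaluates
#' the noise-free recipe surface, applies artefacts, tilts the whole cloud
#' rigidly, and adds Gaussian height noise. The returned ground truth
#' records everything a validation needs: true limbus radius, per-meridian
#' artefact onset, planted tilt and the analytic asymmetry profile.
#'
#' @param recipe An [eye_recipe()].
#' @return List with `cloud` (an [eye_cloud()] in the anatomical frame) and
#'   `truth` (list: `limbus_radius`, `artefact_onset` per 1-degree meridian,
#'   `tilt`, `asymmetry_diff` for angles 0..179 at the reference radius,
#'   `scleral_radius`, `recipe`).
#' @export
generate_eye <- function(recipe) {
  stopifnot(inherits(recipe, "eye_recipe"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(recipe$seed)
  n <- recipe$point_count
  r <- recipe$r_max * sqrt(stats::runif(n))
  th <- stats::runif(n, -180, 180)
  z <- eye_true_height(recipe, r, th)
  art <- apply_artefacts(z, r, th, recipe$artefacts)
  x <- r * cos(th * pi / 180)
  y <- r * sin(th * pi / 180)
  pts <- rbind(x, y, art$z)
  if (any(recipe$tilt != 0)) {
    pts <- tilt_matrix(recipe$tilt[1], recipe$tilt[2]) %*% pts
  }
  zn <- pts[3, ] + if (recipe$noise_sd > 0) stats::rnorm(n, 0, recipe$noise_sd) else 0
  cloud <- eye_cloud(pts[1, ], pts[2, ], zn, recipe$laterality, "anatomical",
                     sprintf("synthetic-seed-%d", recipe$seed))
  ang <- seq(-180, 179, by = 1)
  onset <- vapply(ang, function(a) {
    v <- Inf
    for (s in recipe$artefacts) if (in_sector(a, s$angular_extent))
      v <- min(v, s$onset_radius)
    v
  }, numeric(1))
  asym <- asymmetry_truth(recipe, seq(0, 179))
  truth <- list(limbus_radius = recipe$limbus_radius,
                artefact_onset = stats::setNames(onset, ang),
                tilt = recipe$tilt,
                asymmetry_diff = asym,
                scleral_radius = recipe$scleral_radius,
                recipe = recipe)
  list(cloud = cloud, truth = truth)
}

# Analytic asymmetry diff v(theta) - v(theta-180) implied by the planted
# harmonics (evaluated where the harmonic fade-in is complete).
asymmetry_truth <- function(recipe, angles_deg) {
  d <- numeric(length(angles_deg))
  for (h in recipe$asymmetry_harmonics) {
    d <- d + h[2] * (cos(h[1] * (angles_deg - h[3]) * pi / 180) -
                     cos(h[1] * (angles_deg - 180 - h[3]) * pi / 180))
  }
  stats::setNames(d, angles_deg)
}

#' Generate a reproducible cohort of synthetic eyes
#'
#' @param n_eyes Number of eyes (>= 2).
#' @param population Named list overriding [eye_recipe()] fields. Each entry
#'   is either a fixed value (shared by all eyes) or a function of `n`
#'   returning one draw per eye — a vector for scalar fields, or a matrix
#'   with one row per eye for vector-valued fields such as `tilt` — to
#'   emulate biological variability.
#' @param seed Integer cohort seed; per-eye seeds are derived from it.
#' @return List of `generate_eye()` results.
#' @export
generate_cohort <- function(n_eyes, population = list(), seed) {
  stopifnot(n_eyes >= 2)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  eye_seeds <- sample.int(2^31 - 2, n_eyes)
  draws <- lapply(population, function(p) {
    if (is.function(p)) p(n_eyes) else NULL
  })
  lapply(seq_len(n_eyes), function(i) {
    args <- list(seed = eye_seeds[i])
    for (nm in names(population)) {
      p <- population[[nm]]
      args[[nm]] <- if (!is.function(p)) p
        else if (is.matrix(draws[[nm]])) draws[[nm]][i, ]
        else draws[[nm]][i]
    }
    generate_eye(do.call(eye_recipe, args))
  })
}
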