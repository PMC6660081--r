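# Best-fit reference sphere and relative elevation maps.

#' Fit a sphere to 3D points by least squares
#'
#' The default objective is the algebraic residual
#' `sum_i ((Xi-Xc)^2 + (Yi-Yc)^2 + (Zi-Zc)^2 - Rs^2)^2`, initialised from
#' the linear (Kasa) solution — which is the exact global minimiser of that
#' objective — and polished by a Levenberg–Marquardt refinement (convergence
#' when the parameter step falls below 1e-10 mm). The geometric objective
#' `sum_i (||p_i - c|| - Rs)^2` is available as an option.
#'
#' @param pts Matrix/data.frame with columns x, y, z (>= 10 points, not
#'   coplanar within 1 um).
#' @param objective `"algebraic"` (default) or `"geometric"`.
#' @param max_iter Refinement iteration cap (default 200).
#' @return A `sphere_fit`: list with `Xc`, `Yc`, `Zc`, `Rs` (mm),
#'   `rms_residual` (mm, radial), `n_points`, `objective`.
#' @export
fit_sphere <- function(pts, objective = c("algebraic", "geometric"),
                       max_iter = 200L) {
  objective <- match.arg(objective)
  pts <- as.matrix(pts)[, 1:3, drop = FALSE]
  storage.mode(pts) <- "double"
  n <- nrow(pts)
  if (n < 10L) stop("sphere fit needs at least 10 points")
  ctr <- colMeans(pts)
  sv <- svd(sweep(pts, 2, ctr), nu = 0)
  if (sv$d[3] < 1e-3 * 1e-3 * sqrt(n))  # coplanar within ~1 um
    if (sv$d[3] / sqrt(n) < 1e-3) stop("degenerate point set: coplanar within tolerance")
  x <- pts[, 1]; y <- pts[, 2]; z <- pts[, 3]
  # Kasa: x^2+y^2+z^2 = 2 Xc x + 2 Yc y + 2 Zc z + (Rs^2 - |c|^2)
  A <- cbind(2 * x, 2 * y, 2 * z, 1)
  b <- x^2 + y^2 + z^2
  beta <- stats::lm.fit(A, b)$coefficients
  c0 <- beta[1:3]
  Rs2 <- beta[4] + sum(c0^2)
  if (!is.finite(Rs2) || Rs2 <= 0) stop("sphere fit failed: degenerate linear solution")
  par <- c(c0, sqrt(Rs2))
  resid_fun <- if (objective == "algebraic") {
    function(p) (x - p[1])^2 + (y - p[2])^2 + (z - p[3])^2 - p[4]^2
  } else {
    function(p) sqrt((x - p[1])^2 + (y - p[2])^2 + (z - p[3])^2) - p[4]
  }
  jac_fun <- if (objective == "algebraic") {
    function(p) cbind(-2 * (x - p[1]), -2 * (y - p[2]), -2 * (z - p[3]), -2 * p[4])
  } else {
    function(p) {
      d <- sqrt((x - p[1])^2 + (y - p[2])^2 + (z - p[3])^2)
      cbind(-(x - p[1]) / d, -(y - p[2]) / d, -(z - p[3]) / d, -1)
    }
  }
  lambda <- 1e-8
  f <- resid_fun(par)
  obj <- sum(f^2)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    J <- jac_fun(par)
    g <- crossprod(J, f)
    H <- crossprod(J)
    step <- tryCatch(solve(H + lambda * diag(diag(H)), -g),
                     error = function(e) NULL)
    if (is.null(step)) { lambda <- lambda * 10; next }
    new_par <- par + as.vector(step)
    new_f <- resid_fun(new_par)
    new_obj <- sum(new_f^2)
    if (new_obj <= obj) {
      moved <- max(abs(new_par - par))
      par <- new_par; f <- new_f; obj <- new_obj
      lambda <- max(lambda / 10, 1e-12)
      if (moved < 1e-10) { converged <- TRUE; break }
    } else {
      lambda <- lambda * 10
      if (lambda > 1e12) { converged <- TRUE; break }  # at machine optimum
    }
  }
  if (!converged && max_iter >= 200L)
    stop("sphere fit did not converge in ", max_iter,
         " iterations (objective ", signif(obj, 6), ", lambda ", signif(lambda, 3), ")")
  d <- sqrt((x - par[1])^2 + (y - par[2])^2 + (z - par[3])^2)
  structure(list(Xc = unname(par[1]), Yc = unname(par[2]), Zc = unname(par[3]),
                 Rs = unname(par[4]), rms_residual = sqrt(mean((d - par[4])^2)),
                 n_points = n, objective = objective),
            class = "sphere_fit")
}

#' @export
print.sphere_fit <- function(x, ...) {
  cat(sprintf("<sphere_fit> centre (%.4f, %.4f, %.4f) mm, Rs = %.4f mm, rms %.2e mm, n = %d\n",
              x$Xc, x$Yc, x$Zc, x$Rs, x$rms_residual, x$n_points))
  invisible(x)
}

#' Height of a fitted sphere at a lateral position
#'
#' `Zs = Zc + sqrt(Rs^2 - (x-Xc)^2 - (y-Yc)^2)` (upper sheet).
#'
#' @param fit A `sphere_fit` (or any list with `Xc`, `Yc`, `Zc`, `Rs`).
#' @param x,y Lateral coordinates in mm (vectorised).
#' @param strict Error on points outside the lateral footprint (default);
#'   with `strict = FALSE` they yield `NA`.
#' @return Sphere height(s) in mm.
#' @export
sphere_height <- function(fit, x, y, strict = TRUE) {
  disc <- fit$Rs^2 - (x - fit$Xc)^2 - (y - fit$Yc)^2
  bad <- disc < 0
  if (any(bad)) {
    if (strict) stop("point(s) outside the sphere's lateral footprint")
    disc[bad] <- NA_real_
  }
  fit$Zc + sqrt(disc)
}

#' Scleral annulus of a trimmed polar surface
#'
#' Valid nodes from `limbus_radius + guard` out to the per-meridian cut,
#' as 3D points with their polar indices.
#'
#' @param surface A (trimmed) `polar_surface`.
#' @param limbus_radius Per-meridian limbal radii (scalar recycled).
#' @param guard Inner guard band in mm beyond the limbus (default 0.25).
#' @return data.frame with `angle_deg`, `r_mm`, `x`, `y`, `z`.
#' @export
scleral_region <- function(surface, limbus_radius, guard = 0.25) {
  n <- length(surface$angles)
  rl <- rep_len(limbus_radius, n)
  keep <- surface$valid &
    outer(surface$r, rl + guard, `>=`)
  idx <- which(keep, arr.ind = TRUE)
  ang <- surface$angles[idx[, 2]]
  rr <- surface$r[idx[, 1]]
  data.frame(angle_deg = ang, r_mm = rr,
             x = rr * cos(ang * pi / 180), y = rr * sin(ang * pi / 180),
             z = surface$z[idx])
}

#' Relative elevation map against a reference sphere
#'
#' `relative = z - Zs(x, y)` at each region node; nodes outside the
#' sphere's lateral footprint are flagged `NA`.
#'
#' @param region A [scleral_region()] data.frame.
#' @param fit The `sphere_fit` computed on this region.
#' @return An `elevation_map`: the region with a `relative_mm` column and
#'   the fit attached as attribute `reference`.
#' @export
relative_elevation <- function(region, fit) {
  zs <- sphere_height(fit, region$x, region$y, strict = FALSE)
  region$relative_mm <- region$z - zs
  attr(region, "reference") <- fit
  class(region) <- c("elevation_map", "data.frame")
  region
}

#' Correlate a scleral region with the anatomical reference sphere
#'
#' The anterior sclera of a typical adult eye is close to a sphere of
#' radius 11.5 mm. This computes the Pearson correlation between observed
#' elevation and the apex-aligned reference sphere height (centre at
#' `(0, 0, -reference_radius)`) per 90-degree quadrant centred on the
#' principal meridians.
#'
#' @param region A [scleral_region()] data.frame.
#' @param reference_radius Reference sphere radius in mm (default 11.5).
#' @return Named numeric: correlations for `nasal`, `superior`, `temporal`,
#'   `inferior` (NA when a quadrant has < 10 nodes).
#' @export
correlate_with_reference <- function(region, reference_radius = 11.5) {
  ref <- list(Xc = 0, Yc = 0, Zc = -reference_radius, Rs = reference_radius)
  zs <- sphere_height(ref, region$x, region$y, strict = FALSE)
  a <- wrap_angle(region$angle_deg)
  quadrant <- ifelse(a >= -45 & a < 45, "nasal",
              ifelse(a >= 45 & a < 135, "superior",
              ifelse(a >= -135 & a < -45, "inferior", "temporal")))
  out <- c(nasal = NA_real_, superior = NA_real_, temporal = NA_real_,
           inferior = NA_real_)
  for (q in names(out)) {
    sel <- quadrant == q & is.finite(zs) & is.finite(region$z)
    if (sum(sel) >= 10L) {
      if (stats::sd(region$z[sel]) == 0 || stats::sd(zs[sel]) == 0) next
      out[q] <- stats::cor(region$z[sel], zs[sel])
    }
  }
  out
}
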