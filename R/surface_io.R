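# Surface containers and I/O: raw point clouds and their polar resampling.

#' Construct an eye-surface point cloud
#'
#' A `eye_cloud` holds the raw (x, y, z) elevation samples of one eye in mm,
#' together with laterality and the coordinate frame. In the instrument
#' frame +x follows the device convention (to the patient's left on the
#' video feed); in the anatomical frame +x points nasally, +y superiorly and
#' +z toward the instrument for both eyes.
#'
#' @param x,y,z Numeric vectors of equal length, coordinates in mm.
#' @param laterality `"OD"` (right eye) or `"OS"` (left eye).
#' @param frame `"instrument"` or `"anatomical"`.
#' @param source_id Opaque provenance string.
#' @param check When `TRUE` (default) enforce the container invariants:
#'   finite coordinates, non-empty, lateral extent below 25 mm. (The
#'   pipeline additionally requires at least 100 points at entry.)
#' @return An object of class `eye_cloud`: a list with fields `x`, `y`, `z`,
#'   `laterality`, `frame`, `source_id`, `n_dropped`.
#' @export
eye_cloud <- function(x, y, z, laterality = c("OD", "OS"),
                      frame = c("instrument", "anatomical"),
                      source_id = "unknown", check = TRUE) {
  laterality <- match.arg(laterality)
  frame <- match.arg(frame)
  stopifnot(length(x) == length(y), length(y) == length(z))
  keep <- is.finite(x) & is.finite(y) & is.finite(z)
  n_dropped <- sum(!keep)
  x <- as.double(x[keep]); y <- as.double(y[keep]); z <- as.double(z[keep])
  if (check) {
    if (length(x) == 0L) stop("empty point cloud after dropping non-finite rows")
    ext <- max(sqrt(x^2 + y^2))
    if (2 * ext > 25) stop("lateral extent ", round(2 * ext, 2),
                           " mm exceeds the 25 mm instrument limit")
  }
  structure(list(x = x, y = y, z = z, laterality = laterality, frame = frame,
                 source_id = source_id, n_dropped = n_dropped),
            class = "eye_cloud")
}

#' @export
print.eye_cloud <- function(x, ...) {
  cat(sprintf("<eye_cloud> %d points, %s, %s frame, source '%s'\n",
              length(x$x), x$laterality, x$frame, x$source_id))
  invisible(x)
}

#' Load an eye-surface point cloud from disk
#'
#' Two dialects are supported: `"xyz-csv"` (columns `x_mm`, `y_mm`, `z_mm`)
#' and `"mat-container"` (a MAT v5 file holding three equal-length double
#' arrays; variable names configurable through `var_map` because vendor
#' exports are not standardised).
#'
#' @param path File to read.
#' @param dialect `"xyz-csv"` or `"mat-container"`.
#' @param laterality `"OD"` or `"OS"`.
#' @param var_map Named character vector mapping the roles `x`, `y`, `z`
#'   to MAT variable names. Defaults to `c(x = "x", y = "y", z = "z")`.
#' @param source_id Provenance string; defaults to the file name.
#' @return An [eye_cloud()] in the instrument frame. Non-finite rows are
#'   dropped; the drop count is kept in field `n_dropped`.
#' @export
load_point_cloud <- function(path, dialect = c("xyz-csv", "mat-container"),
                             laterality = c("OD", "OS"),
                             var_map = c(x = "x", y = "y", z = "z"),
                             source_id = basename(path)) {
  dialect <- match.arg(dialect)
  laterality <- match.arg(laterality)
  if (!file.exists(path)) stop("no such file: ", path)
  if (dialect == "xyz-csv") {
    df <- utils::read.csv(path, comment.char = "#")
    need <- c("x_mm", "y_mm", "z_mm")
    missing <- setdiff(need, names(df))
    if (length(missing) > 0L)
      stop("xyz-csv file ", path, " is missing column(s): ",
           paste(missing, collapse = ", "))
    cl <- eye_cloud(df$x_mm, df$y_mm, df$z_mm, laterality, "instrument", source_id)
  } else {
    vars <- read_mat(path)
    stopifnot(all(c("x", "y", "z") %in% names(var_map)))
    missing <- setdiff(unname(var_map[c("x", "y", "z")]), names(vars))
    if (length(missing) > 0L)
      stop("MAT container ", path, " is missing variable(s): ",
           paste(missing, collapse = ", "))
    cl <- eye_cloud(as.vector(vars[[var_map[["x"]]]]),
                    as.vector(vars[[var_map[["y"]]]]),
                    as.vector(vars[[var_map[["z"]]]]),
                    laterality, "instrument", source_id)
  }
  if (cl$n_dropped > 0L)
    message("load_point_cloud: dropped ", cl$n_dropped, " non-finite row(s) from ", path)
  cl
}

#' Write a point cloud to disk
#'
#' @param cloud An [eye_cloud()].
#' @param path Output file.
#' @param dialect `"xyz-csv"` or `"mat-container"`.
#' @param var_map MAT variable names, as in [load_point_cloud()].
#' @return `path`, invisibly.
#' @export
write_point_cloud <- function(cloud, path, dialect = c("xyz-csv", "mat-container"),
                              var_map = c(x = "x", y = "y", z = "z")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(cloud, "eye_cloud"))
  if (dialect == "xyz-csv") {
    df <- data.frame(x_mm = cloud$x, y_mm = cloud$y, z_mm = cloud$z)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    vars <- list(cloud$x, cloud$y, cloud$z)
    names(vars) <- unname(var_map[c("x", "y", "z")])
    write_mat(vars, path)
  }
  invisible(path)
}

#' Convert a cloud from the instrument to the anatomical frame
#'
#' The anatomical frame has +x nasal for both eyes. For a right eye (OD) the
#' instrument x-axis already points nasally; for a left eye (OS) it points
#' temporally, so x is negated. y and z are untouched; the map is an
#' isometry and an involution (applying it from the anatomical frame
#' converts back).
#'
#' @param cloud An [eye_cloud()].
#' @return The cloud with `frame` toggled.
#' @export
to_anatomical_frame <- function(cloud) {
  stopifnot(inherits(cloud, "eye_cloud"))
  if (!cloud$laterality %in% c("OD", "OS")) stop("unknown laterality: ", cloud$laterality)
  if (cloud$laterality == "OS") cloud$x <- -cloud$x
  cloud$frame <- if (cloud$frame == "instrument") "anatomical" else "instrument"
  cloud
}

#' Resample a scattered point cloud onto the polar meridian grid
#'
#' Every downstream stage works meridian by meridian. Points are binned into
#' non-overlapping angular sectors of width `angular_step` centred on each
#' grid angle, sorted by radius, and interpolated onto a fixed radial grid
#' with monotone piecewise-cubic interpolation (linear fallback below 4
#' sector points). Grid nodes with no supporting point within
#' `radial_step` of their radius, or outside the sector's radial span, are
#' marked invalid — nothing is ever extrapolated.
#'
#' @param cloud An [eye_cloud()] in the anatomical frame.
#' @param angular_step Meridian spacing in degrees (default 1).
#' @param radial_step Radial grid step in mm (default 0.05, fine enough that
#'   the 0.1 mm moving-window half-width spans at least two nodes).
#' @param r_max Outer radius of the grid in mm; defaults to the cloud's
#'   maximal radius rounded up to the grid.
#' @param center `"origin"` (apex already at the origin) or `"max_z"`
#'   (re-origin at the highest raw point first — the default fallback for
#'   unlevelled data).
#' @return A `polar_surface`: list with `angles` (degrees in \[-180, 180)),
#'   `r` (shared radial grid from 0), matrices `z` and `valid` of dimension
#'   `length(r) x length(angles)`, plus the grid steps.
#' @export
resample_polar <- function(cloud, angular_step = 1, radial_step = 0.05,
                           r_max = NULL, center = c("origin", "max_z")) {
  stopifnot(inherits(cloud, "eye_cloud"))
  if (cloud$frame != "anatomical")
    stop("resample_polar expects a cloud in the anatomical frame; call to_anatomical_frame() first")
  center <- match.arg(center)
  x <- cloud$x; y <- cloud$y; z <- cloud$z
  if (center == "max_z") {
    i0 <- which.max(z)
    x <- x - x[i0]; y <- y - y[i0]; z <- z - z[i0]
  }
  r_pt <- sqrt(x^2 + y^2)
  th_pt <- atan2(y, x) * 180 / pi
  n_ang <- as.integer(round(360 / angular_step))
  angles <- seq(-180, by = angular_step, length.out = n_ang)
  sector <- (round((th_pt + 180) / angular_step) %% n_ang) + 1L
  if (is.null(r_max)) r_max <- ceiling(max(r_pt) / radial_step) * radial_step
  r_grid <- seq(0, r_max, by = radial_step)
  nr <- length(r_grid)
  zmat <- matrix(NA_real_, nr, n_ang)
  vmat <- matrix(FALSE, nr, n_ang)
  idx_by_sector <- split(seq_along(r_pt), factor(sector, levels = seq_len(n_ang)))
  for (k in seq_len(n_ang)) {
    ii <- idx_by_sector[[k]]
    if (length(ii) < 2L) next
    rs <- r_pt[ii]; zs <- z[ii]
    o <- order(rs); rs <- rs[o]; zs <- zs[o]
    # collapse duplicate radii (interpolators need strictly increasing x)
    # collapse near-coincident radii (closer than a fifth of the grid step)
    # by averaging: interpolators need separated knots, and noise on nearly
    # duplicate radii would otherwise produce huge spurious tangents
    dedup_tol <- radial_step / 5
    if (any(diff(rs) <= dedup_tol)) {
      grp <- cumsum(c(TRUE, diff(rs) > dedup_tol))
      cnt <- tabulate(grp)
      rs <- rowsum(rs, grp, reorder = TRUE)[, 1] / cnt
      zs <- rowsum(zs, grp, reorder = TRUE)[, 1] / cnt
    }
    if (length(rs) < 2L) next
    in_span <- r_grid >= rs[1L] & r_grid <= rs[length(rs)]
    # support: a data point within one radial step of the node AND the
    # bracketing gap no wider than two steps (or the node essentially on a
    # data point) — keeps interpolation error within the stated tolerance
    nearest <- findInterval(r_grid, rs)
    d_lo <- ifelse(nearest >= 1L, r_grid - rs[pmax(nearest, 1L)], Inf)
    d_hi <- ifelse(nearest < length(rs), rs[pmin(nearest + 1L, length(rs))] - r_grid, Inf)
    supported <- pmin(d_lo, d_hi) <= radial_step &
      (d_lo + d_hi <= 2 * radial_step | pmin(d_lo, d_hi) <= radial_step / 5)
    ok <- in_span & supported
    if (!any(ok)) next
    if (length(rs) >= 4L) {
      f <- stats::splinefun(rs, zs, method = "monoH.FC")
      zmat[ok, k] <- f(r_grid[ok])
    } else {
      zmat[ok, k] <- stats::approx(rs, zs, xout = r_grid[ok])$y
    }
    vmat[ok, k] <- TRUE
  }
  # a meridian needs a minimal backbone to be analysable at all
  too_thin <- colSums(vmat) < 4L
  vmat[, too_thin] <- FALSE
  zmat[, too_thin] <- NA_real_
  structure(list(angles = angles, r = r_grid, z = zmat, valid = vmat,
                 angular_step = angular_step, radial_step = radial_step),
            class = "polar_surface")
}

#' @export
print.polar_surface <- function(x, ...) {
  cat(sprintf("<polar_surface> %d meridians x %d radial nodes (step %g deg / %g mm), %d%% valid\n",
              length(x$angles), length(x$r), x$angular_step, x$radial_step,
              round(100 * mean(x$valid))))
  invisible(x)
}

#' Extract one meridian profile from a polar surface
#'
#' @param surface A `polar_surface`.
#' @param angle Meridian angle in degrees, in \[-180, 180).
#' @return List with `angle`, `r`, `z`, `valid` (class `meridian_profile`).
#' @export
meridian_profile <- function(surface, angle) {
  k <- match(angle, surface$angles)
  if (is.na(k)) stop("no meridian at angle ", angle)
  structure(list(angle = angle, r = surface$r, z = surface$z[, k],
                 valid = surface$valid[, k]),
            class = "meridian_profile")
}

# Index of the meridian opposite angle theta (theta - 180, wrapped).
opposite_index <- function(angles, k) {
  match(wrap_angle(angles[k] - 180), angles)
}

wrap_angle <- function(a) ((a + 180) %% 360) - 180

#' Write a polar surface as long-format CSV
#'
#' Schema `angle_deg, r_mm, z_mm, valid` shared by all downstream modules.
#' A `# config_hash=` comment line is prepended when `hash` is given.
#'
#' @param surface A `polar_surface`.
#' @param path Output CSV.
#' @param hash Optional provenance hash written as a comment header.
#' @return `path`, invisibly.
#' @export
write_polar_csv <- function(surface, path, hash = NULL) {
  df <- data.frame(
    angle_deg = rep(surface$angles, each = length(surface$r)),
    r_mm = rep(surface$r, times = length(surface$angles)),
    z_mm = as.vector(surface$z),
    valid = as.vector(surface$valid))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(hash)) writeLines(paste0("# config_hash=", hash), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a polar surface written by [write_polar_csv()]
#' @param path CSV path.
#' @return A `polar_surface`.
#' @export
read_polar_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  angles <- sort(unique(df$angle_deg))
  r <- sort(unique(df$r_mm))
  o <- order(df$angle_deg, df$r_mm)
  df <- df[o, ]
  z <- matrix(df$z_mm, nrow = length(r), ncol = length(angles))
  v <- matrix(as.logical(df$valid), nrow = length(r), ncol = length(angles))
  structure(list(angles = angles, r = r, z = z, valid = v,
                 angular_step = if (length(angles) > 1) diff(angles[1:2]) else 1,
                 radial_step = if (length(r) > 1) diff(r[1:2]) else NA_real_),
            class = "polar_surface")
}
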