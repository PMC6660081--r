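# Pipeline configuration and the simulate / process / group commands.

#' Pipeline configuration
#'
#' All tunables of the processing chain with defaults equal to the method's
#' stated values: 1-degree meridians, 0.05 mm radial grid, 0.1 mm / 11
#' element moving window with tripled-mean threshold, 8 mm sampling radius.
#' Unknown keys are rejected.
#'
#' @param ... Overrides for any default key.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    angular_step_deg = 1,
    radial_step_mm = 0.05,
    window_halfwidth_mm = 0.1,
    window_max_elements = 11L,
    window_statistic = "median",
    threshold_factor = 3,
    threshold_baseline = "post_limbus",
    min_prominence_mm = 0.02,
    limbus_search_mm = c(3.5, 8.5),
    limbus_plausible_mm = c(3, 9),
    edge_guard_mm = 0.25,
    sampling_radius_mm = 8,
    sampling = "fixed_radius",
    sphere_objective = "algebraic",
    reference_radius_mm = 11.5,
    ttest_var_equal = FALSE,
    alpha = 0.05,
    io_dialect = "xyz-csv",
    seed = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown) > 0L)
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  defaults[names(over)] <- over
  structure(defaults, class = "pipeline_config")
}

config_window <- function(config) {
  moving_window_config(halfwidth = config$window_halfwidth_mm,
                       max_elements = config$window_max_elements,
                       statistic = config$window_statistic,
                       threshold_factor = config$threshold_factor,
                       baseline = config$threshold_baseline,
                       min_prominence = config$min_prominence_mm)
}

#' MD5 hash of a configuration (provenance stamp)
#' @param config A `pipeline_config`.
#' @return Hex string.
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

write_json_out <- function(x, path, hash) {
  x$config_hash <- hash
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
}

#' Process one eye through the full pipeline
#'
#' Levels the surface about the limbus plane, detects and trims edge
#' artefacts, fits the scleral reference sphere, and derives the raw and
#' relative elevation samples feeding the asymmetry analysis.
#'
#' @param cloud An [eye_cloud()] (instrument or anatomical frame; converted
#'   as needed).
#' @param config A [pipeline_config()].
#' @return A `processed_eye`: list with `levelled` ([eye_cloud()]),
#'   `limbus`, `edges`, `surface` (trimmed `polar_surface`), `sphere`,
#'   `elevation` (map), `correlations`, `raw_at_r`, `rel_at_r` (per-meridian
#'   samples at the reporting radius), `laterality`, `source_id`.
#' @export
process_eye <- function(cloud, config = pipeline_config()) {
  stopifnot(inherits(cloud, "eye_cloud"))
  if (length(cloud$x) < 100L)
    stop("point cloud has fewer than 100 points (", length(cloud$x),
         "); not a plausible topography measurement")
  if (cloud$frame == "instrument") cloud <- to_anatomical_frame(cloud)
  lev <- level_eye(cloud, angular_step = config$angular_step_deg,
                   radial_step = config$radial_step_mm,
                   search_window = config$limbus_search_mm,
                   plausible = config$limbus_plausible_mm)
  rl <- lev$limbus$table$r_smoothed_mm
  rl[!is.finite(rl)] <- lev$limbus$mean_limbus_radius
  wcfg <- config_window(config)
  edges <- detect_edges(lev$surface, rl, wcfg, guard = config$edge_guard_mm)
  trimmed <- trim_surface(lev$surface, edges)
  region <- scleral_region(trimmed, rl, guard = config$edge_guard_mm)
  sph <- fit_sphere(region[, c("x", "y", "z")], objective = config$sphere_objective)
  elev <- relative_elevation(region, sph)
  corr <- correlate_with_reference(region, config$reference_radius_mm)
  r0 <- config$sampling_radius_mm
  raw_at_r <- if (config$sampling == "fixed_radius") sample_at_radius(trimmed, r0)
              else annulus_mean(trimmed, rl, config$edge_guard_mm)
  rel_surface <- trimmed
  k <- match(paste(elev$angle_deg, elev$r_mm),
             paste(rep(trimmed$angles, each = length(trimmed$r)),
                   rep(trimmed$r, times = length(trimmed$angles))))
  relz <- matrix(NA_real_, length(trimmed$r), length(trimmed$angles))
  relz[k] <- elev$relative_mm
  rel_surface$z <- relz
  rel_surface$valid <- is.finite(relz)
  rel_at_r <- if (config$sampling == "fixed_radius") sample_at_radius(rel_surface, r0)
              else annulus_mean(rel_surface, rl, config$edge_guard_mm)
  structure(list(levelled = lev$cloud, limbus = lev$limbus, edges = edges,
                 surface = trimmed, sphere = sph, elevation = elev,
                 correlations = corr, raw_at_r = raw_at_r, rel_at_r = rel_at_r,
                 laterality = cloud$laterality, source_id = cloud$source_id),
            class = "processed_eye")
}

#' Process eye files and write per-eye outputs
#'
#' Runs [process_eye()] on each input file and writes, per eye, the
#' levelled cloud, limbus table (+ JSON sidecar with plane and angles),
#' edge report, trimmed polar surface, sphere-fit JSON, relative-elevation
#' CSV and the per-meridian asymmetry inputs. All outputs carry the config
#' hash; outputs are staged in a temporary directory and moved into place
#' only on success, so a failing eye leaves nothing behind.
#'
#' @param files Character vector of input files.
#' @param laterality `"OD"`/`"OS"`, recycled over files.
#' @param out_dir Output directory (one subdirectory per eye).
#' @param config A [pipeline_config()].
#' @return Invisibly, the per-eye output directories.
#' @export
cmd_process <- function(files, laterality, out_dir, config = pipeline_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  lat <- rep_len(laterality, length(files))
  dirs <- character(0)
  for (i in seq_along(files)) {
    stem <- sub("\\.[^.]+$", "", basename(files[i]))
    stage <- file.path(tempfile("stage"))
    dir.create(stage, recursive = TRUE)
    cloud <- load_point_cloud(files[i], dialect = config$io_dialect,
                              laterality = lat[i])
    pe <- process_eye(cloud, config)
    write_processed_eye(pe, stage, hash, config)
    dest <- file.path(out_dir, stem)
    unlink(dest, recursive = TRUE)
    dir.create(dest, recursive = TRUE)
    file.copy(list.files(stage, full.names = TRUE), dest)
    unlink(stage, recursive = TRUE)
    dirs <- c(dirs, dest)
  }
  jsonlite::write_json(unclass(config), file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dirs)
}

write_processed_eye <- function(pe, dir, hash, config) {
  write_point_cloud(pe$levelled, file.path(dir, "levelled.csv"))
  lim <- pe$limbus
  ltab <- lim$table
  ltab$x_mm <- ltab$r_smoothed_mm * cos(ltab$angle_deg * pi / 180)
  ltab$y_mm <- ltab$r_smoothed_mm * sin(ltab$angle_deg * pi / 180)
  write_csv_hashed(ltab, file.path(dir, "limbus.csv"), hash)
  write_json_out(list(normal = lim$plane_normal,
                      alpha_x_deg = lim$alpha_x * 180 / pi,
                      alpha_y_deg = lim$alpha_y * 180 / pi,
                      mean_limbus_radius_mm = lim$mean_limbus_radius),
                 file.path(dir, "limbus.json"), hash)
  write_csv_hashed(as.data.frame(pe$edges), file.path(dir, "edges.csv"), hash)
  write_polar_csv(pe$surface, file.path(dir, "trimmed.csv"), hash)
  write_json_out(list(Xc_mm = pe$sphere$Xc, Yc_mm = pe$sphere$Yc,
                      Zc_mm = pe$sphere$Zc, Rs_mm = pe$sphere$Rs,
                      rms_residual_mm = pe$sphere$rms_residual,
                      n_points = pe$sphere$n_points),
                 file.path(dir, "sphere.json"), hash)
  write_csv_hashed(as.data.frame(pe$elevation), file.path(dir, "elevation.csv"), hash)
  asy <- data.frame(angle_deg = as.numeric(names(pe$raw_at_r)),
                    raw_mm = unname(pe$raw_at_r),
                    relative_mm = unname(pe$rel_at_r),
                    laterality = pe$laterality)
  write_csv_hashed(asy, file.path(dir, "asymmetry_input.csv"), hash)
}

write_csv_hashed <- function(df, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# config_hash=", hash), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Group asymmetry analysis over processed eyes
#'
#' Reads the per-eye asymmetry inputs written by [cmd_process()], keeps the
#' requested laterality (right and left eyes are never pooled), builds raw
#' and relative asymmetry profiles, aggregates them, and writes the group
#' report CSV, a JSON summary and a polar figure of mean +/- sd asymmetry.
#'
#' @param eye_dirs Per-eye output directories from [cmd_process()].
#' @param laterality `"OD"` or `"OS"`.
#' @param out_dir Output directory.
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the raw and relative `group_asym`.
#' @export
cmd_group <- function(eye_dirs, laterality = c("OD", "OS"), out_dir,
                      config = pipeline_config()) {
  laterality <- match.arg(laterality)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  tabs <- lapply(eye_dirs, function(d)
    utils::read.csv(file.path(d, "asymmetry_input.csv"), comment.char = "#"))
  lats <- vapply(tabs, function(t) t$laterality[1], character(1))
  keep <- lats == laterality
  if (sum(keep) < 2L)
    stop("need at least 2 processed ", laterality, " eyes (found ", sum(keep), ")")
  tabs <- tabs[keep]
  sampling <- sprintf("r=%gmm", config$sampling_radius_mm)
  mk_profiles <- function(col, basis) lapply(tabs, function(t)
    asymmetry_profile(stats::setNames(t[[col]], t$angle_deg), basis, sampling))
  grp_raw <- aggregate_group(mk_profiles("raw_mm", "raw"),
                             var_equal = config$ttest_var_equal)
  grp_rel <- aggregate_group(mk_profiles("relative_mm", "relative"),
                             var_equal = config$ttest_var_equal)
  for (g in list(raw = grp_raw, relative = grp_rel)) NULL
  write_csv_hashed(grp_raw$table, file.path(out_dir, "group_raw.csv"), hash)
  write_csv_hashed(grp_rel$table, file.path(out_dir, "group_relative.csv"), hash)
  write_json_out(list(
    laterality = laterality, n_eyes = sum(keep),
    raw = list(argmax_angle_deg = grp_raw$argmax_angle_deg,
               max_mean_diff_mm = grp_raw$max_mean_diff_mm,
               sd_at_max_mm = grp_raw$sd_at_max_mm),
    relative = list(argmax_angle_deg = grp_rel$argmax_angle_deg,
                    max_mean_diff_mm = grp_rel$max_mean_diff_mm,
                    sd_at_max_mm = grp_rel$sd_at_max_mm)),
    file.path(out_dir, "summary.json"), hash)
  plot_group_asymmetry(grp_raw, file.path(out_dir, "asymmetry_raw.pdf"), scale = 5)
  plot_group_asymmetry(grp_rel, file.path(out_dir, "asymmetry_relative.pdf"), scale = 40)
  invisible(list(raw = grp_raw, relative = grp_rel))
}

#' Polar plot of group asymmetry
#'
#' Mean asymmetry (thick line) with +/- one standard deviation (thin lines)
#' drawn as polar rays, the maximum-asymmetry direction marked in red. The
#' display scale factor is recorded in the figure subtitle.
#'
#' @param group A `group_asym`.
#' @param path Output PDF path (`NULL` draws on the current device).
#' @param scale Display scale factor for the ray lengths.
#' @return `path`, invisibly.
#' @export
plot_group_asymmetry <- function(group, path = NULL, scale = 5) {
  if (!is.null(path)) {
    grDevices::pdf(path, width = 6, height = 6)
    on.exit(grDevices::dev.off())
  }
  tab <- group$table
  th <- tab$angle_deg * pi / 180
  m <- abs(tab$mean_diff_mm) * scale
  s <- tab$sd_diff_mm * scale
  lim <- max(m + s, 1e-6, na.rm = TRUE)
  graphics::plot(NA, xlim = c(-lim, lim), ylim = c(-lim, lim), asp = 1,
                 xlab = "", ylab = "", axes = FALSE,
                 main = sprintf("Scleral %s asymmetry", group$basis),
                 sub = sprintf("rays scaled x%g; max at %g deg", scale,
                               group$argmax_angle_deg))
  graphics::symbols(0, 0, circles = lim, inches = FALSE, add = TRUE, fg = "grey")
  graphics::lines(m * cos(th), m * sin(th), lwd = 2)
  graphics::lines((m + s) * cos(th), (m + s) * sin(th), lwd = 0.5)
  graphics::lines(pmax(m - s, 0) * cos(th), pmax(m - s, 0) * sin(th), lwd = 0.5)
  amax <- group$argmax_axis_deg * pi / 180
  graphics::arrows(0, 0, lim * cos(amax), lim * sin(amax), col = "red", length = 0.1)
  invisible(path)
}

#' Simulate a synthetic dataset on disk
#'
#' Writes each generated eye in the configured I/O dialect plus a ground
#' truth JSON sidecar and a cohort truth table, all seeded.
#'
#' @param n_eyes Number of eyes.
#' @param population Population overrides, as in [generate_cohort()].
#' @param out_dir Output directory.
#' @param seed Cohort seed.
#' @param config A [pipeline_config()] (controls the output dialect).
#' @return Invisibly, the written eye file paths.
#' @export
cmd_simulate <- function(n_eyes, population = list(), out_dir,
                         seed, config = pipeline_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- if (n_eyes == 1L) {
    list(generate_eye(do.call(eye_recipe, c(population, list(seed = seed)))))
  } else generate_cohort(n_eyes, population, seed)
  ext <- if (config$io_dialect == "mat-container") ".mat" else ".csv"
  files <- character(0)
  truth_rows <- list()
  for (i in seq_along(cohort)) {
    f <- file.path(out_dir, sprintf("eye_%03d%s", i, ext))
    cl <- cohort[[i]]$cloud
    cl$frame <- "instrument"   # emulate an instrument export (OD convention)
    write_point_cloud(cl, f, dialect = config$io_dialect)
    tr <- cohort[[i]]$truth
    jsonlite::write_json(list(limbus_radius = tr$limbus_radius,
                              tilt = tr$tilt,
                              scleral_radius = tr$scleral_radius,
                              seed = tr$recipe$seed,
                              artefact_onset = as.list(tr$artefact_onset)),
                         file.path(out_dir, sprintf("eye_%03d_truth.json", i)),
                         auto_unbox = TRUE, digits = NA)
    truth_rows[[i]] <- data.frame(eye = i, seed = tr$recipe$seed,
                                  limbus_radius_mm = tr$limbus_radius,
                                  scleral_radius_mm = tr$scleral_radius,
                                  tilt_x_deg = tr$tilt[1], tilt_y_deg = tr$tilt[2])
    files <- c(files, f)
  }
  utils::write.csv(do.call(rbind, truth_rows), file.path(out_dir, "truth.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(files)
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `process`, `group`. See the package README for
#' flags. Designed to be called from an Rscript wrapper; returns the exit
#' status instead of quitting when `exit = FALSE` (used by the tests).
#'
#' @param args Character vector of arguments (default: the command line).
#' @param exit Quit R with the status when `TRUE`.
#' @return Integer exit status, invisibly.
#' @export
scleratopo_cli <- function(args = commandArgs(trailingOnly = TRUE), exit = FALSE) {
  status <- tryCatch({
    if (length(args) == 0L) stop("usage: scleratopo <simulate|process|group> ...")
    cmd <- args[1]
    opts <- parse_cli_opts(args[-1])
    cfg <- pipeline_config(seed = as.integer(opts$flags[["seed"]] %||% 1))
    out_dir <- opts$flags[["out-dir"]] %||% "."
    switch(cmd,
      simulate = {
        n <- as.integer(opts$flags[["n-eyes"]] %||% 1)
        cmd_simulate(n, list(), out_dir, seed = cfg$seed, config = cfg)
      },
      process = {
        lat <- opts$flags[["laterality"]] %||% "OD"
        cmd_process(opts$positional, lat, out_dir, cfg)
      },
      group = {
        lat <- opts$flags[["laterality"]] %||% "OD"
        cmd_group(opts$positional, lat, out_dir, cfg)
      },
      stop("unknown subcommand: ", cmd))
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  if (exit) quit(status = status)
  invisible(status)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

parse_cli_opts <- function(args) {
  flags <- list()
  positional <- character(0)
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (startsWith(a, "--")) {
      flags[[substring(a, 3)]] <- args[i + 1L]
      i <- i + 2L
    } else {
      positional <- c(positional, a)
      i <- i + 1L
    }
  }
  list(flags = flags, positional = positional)
}
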