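# Edge-effect elimination: moving-median screening of meridian slope
# (strategy 1), pre-edge elevation-minimum search (strategy 2), and the
# ultimate cutting edge.

#' Moving-window configuration for the slope screen
#'
#' @param halfwidth Window half-width in mm on each radial side (default 0.1).
#' @param max_elements Maximum window size in elements (odd, >= 3; default 11).
#'   Both caps apply simultaneously: an element enters the window only if it
#'   is within `halfwidth` in radius and within `(max_elements-1)/2`
#'   positions of the centre. Windows shrink at both meridian ends.
#' @param statistic `"median"` (robust default) or `"mean"` (the literal
#'   windowed average).
#' @param threshold_factor Cut-off multiple of the screen's mean (default 3:
#'   a tripled mean flags the artefact zone).
#' @param baseline `"post_limbus"` (default; the mean is taken over the
#'   scleral portion only so the steep limbal slope does not inflate it) or
#'   `"full"`.
#' @param min_prominence Minimum prominence in mm for a strategy-2 elevation
#'   minimum (default 20 um, ignores noise wiggles).
#' @return A `moving_window_config` list.
#' @export
moving_window_config <- function(halfwidth = 0.1, max_elements = 11L,
                                 statistic = c("median", "mean"),
                                 threshold_factor = 3,
                                 baseline = c("post_limbus", "full"),
                                 min_prominence = 0.02) {
  statistic <- match.arg(statistic)
  baseline <- match.arg(baseline)
  max_elements <- as.integer(max_elements)
  stopifnot(halfwidth > 0, max_elements >= 3L, max_elements %% 2L == 1L,
            threshold_factor > 1, min_prominence >= 0)
  structure(list(halfwidth = halfwidth, max_elements = max_elements,
                 statistic = statistic, threshold_factor = threshold_factor,
                 baseline = baseline, min_prominence = min_prominence),
            class = "moving_window_config")
}

#' Numerical slope of a meridian profile
#'
#' Central differences at interior nodes, one-sided at the ends (exact for
#' quadratics), over the meridian's valid span with small interior sampling
#' gaps bridged linearly; leading/trailing invalid stretches are excluded.
#'
#' @param profile A `meridian_profile`.
#' @param r_min Ignore valid nodes inside this radius (mm); the edge screen
#'   only needs the mid-periphery, where sampling is dense.
#' @return List with `r`, `z`, `dzdr` and the node `index` into the profile
#'   grid, or `NULL` when fewer than 3 usable nodes exist.
#' @export
meridian_slope <- function(profile, r_min = 0) {
  ct <- profile_contiguous(profile, r_min = r_min)
  if (is.null(ct) || length(ct$r) < 3L) return(NULL)
  step <- ct$r[2] - ct$r[1]
  list(r = ct$r, z = ct$z, dzdr = central_diff(ct$z, step), index = ct$index)
}

#' Sliding-window statistic with boundary-shrinking windows
#'
#' `m[i]` is the median (or mean) of the values whose grid positions lie
#' within `halfwidth` of `grid[i]` AND within `(max_elements-1)/2` indices
#' of `i`; near the array ends the backward/forward half simply shrinks to
#' what is available, so the window always contains at least the element
#' itself.
#'
#' @param values Numeric array.
#' @param grid Increasing radii aligned with `values`.
#' @param config A [moving_window_config()].
#' @return Numeric array of the same length.
#' @export
moving_statistic <- function(values, grid, config = moving_window_config()) {
  stopifnot(length(values) == length(grid), !is.unsorted(grid))
  n <- length(values)
  half_idx <- (config$max_elements - 1L) %/% 2L
  m <- numeric(n)
  stat <- if (config$statistic == "median") stats::median else mean
  for (i in seq_len(n)) {
    lo <- max(1L, i - half_idx)
    hi <- min(n, i + half_idx)
    w <- lo:hi
    w <- w[abs(grid[w] - grid[i]) <= config$halfwidth + 1e-12]
    m[i] <- stat(values[w])
  }
  m
}

#' First cutting edge: moving-median threshold crossing
#'
#' Scans the screened absolute slope beyond the limbus; the first radius at
#' which the screen exceeds `threshold_factor` times its baseline mean
#' triggers the edge.
#'
#' @param m Screened array (moving statistic of |dz/dr|).
#' @param grid Radii aligned with `m`.
#' @param config A [moving_window_config()].
#' @param r_min Inner search limit in mm (detected limbus radius plus a
#'   guard band, so the limbal transition is never flagged).
#' @return Edge radius in mm, or `NA_real_` when never exceeded.
#' @export
first_cutting_edge <- function(m, grid, config = moving_window_config(),
                               r_min = 0) {
  am <- abs(m)
  base_sel <- if (config$baseline == "post_limbus") grid >= r_min else rep(TRUE, length(grid))
  if (!any(base_sel)) return(NA_real_)
  thr <- config$threshold_factor * mean(am[base_sel])
  hit <- which(am > thr & grid >= r_min)
  if (length(hit) == 0L) NA_real_ else grid[hit[1L]]
}

#' Second cutting edge: pre-edge elevation minimum
#'
#' Strategy 1 misses artefacts that blend in smoothly; those still turn the
#' convex profile upward, leaving a local minimum of elevation. The
#' innermost strict local minimum located beyond `r_min` and before the
#' first edge (or anywhere when no first edge exists) with prominence at
#' least `config$min_prominence` is returned.
#'
#' @param profile A `meridian_profile` (levelled, apex-relative).
#' @param r_edge1 First cutting edge, or `NA`.
#' @param config A [moving_window_config()].
#' @param r_min Inner search limit in mm.
#' @return Edge radius in mm, or `NA_real_`.
#' @export
second_cutting_edge <- function(profile, r_edge1 = NA_real_,
                                config = moving_window_config(), r_min = 0) {
  sl <- meridian_slope(profile, r_min = min(3, r_min))
  if (is.null(sl)) return(NA_real_)
  r <- sl$r
  z <- sl$z
  hi <- if (is.finite(r_edge1)) r_edge1 else Inf
  region <- which(r > r_min & r < hi)
  if (length(region) < 3L) return(NA_real_)
  interior <- region[region > 1L & region < length(r)]
  cand <- interior[z[interior] < z[interior - 1L] & z[interior] < z[interior + 1L]]
  for (i in cand) {   # innermost first: most conservative cut
    left_max <- max(z[region[1L]:max(region[1L], i - 1L)])
    right_max <- max(z[min(i + 1L, region[length(region)]):region[length(region)]])
    if (min(left_max, right_max) - z[i] >= config$min_prominence) return(r[i])
  }
  NA_real_
}

#' Ultimate cutting edge
#'
#' Whichever detected edge lies closest to the apex wins; with neither
#' defined the meridian is kept in full.
#'
#' @param r_edge1,r_edge2 Edge radii in mm or `NA`.
#' @return The minimum of the defined candidates, or `NA_real_`.
#' @export
ultimate_edge <- function(r_edge1, r_edge2) {
  cand <- c(r_edge1, r_edge2)
  cand <- cand[is.finite(cand)]
  if (length(cand) == 0L) NA_real_ else min(cand)
}

#' Detect edge artefacts on every meridian
#'
#' Runs both strategies per meridian. The search starts at the meridian's
#' limbus radius plus `guard` (default 0.25 mm) so the limbal transition is
#' never classified as an artefact; an ultimate edge inside the limbus
#' radius would amputate cornea and is flagged.
#'
#' @param surface A levelled `polar_surface`.
#' @param limbus_radius Per-meridian limbal radii (recycled scalar allowed).
#' @param config A [moving_window_config()].
#' @param guard Guard band beyond the limbus in mm.
#' @return An `edge_profile`: data.frame with `angle_deg`, `r_edge1_mm`,
#'   `r_edge2_mm`, `r_ultimate_mm`, `strategy_fired` ("1", "2", "both",
#'   "none") and `flag_inside_limbus`.
#' @export
detect_edges <- function(surface, limbus_radius, config = moving_window_config(),
                         guard = 0.25) {
  n <- length(surface$angles)
  rl <- rep_len(limbus_radius, n)
  out <- data.frame(angle_deg = surface$angles, r_edge1_mm = NA_real_,
                    r_edge2_mm = NA_real_, r_ultimate_mm = NA_real_,
                    strategy_fired = "none", flag_inside_limbus = FALSE,
                    stringsAsFactors = FALSE)
  for (k in seq_len(n)) {
    prof <- meridian_profile(surface, surface$angles[k])
    sl <- meridian_slope(prof, r_min = 3)
    if (is.null(sl)) next
    r_min <- if (is.finite(rl[k])) rl[k] + guard else guard
    m <- moving_statistic(abs(sl$dzdr), sl$r, config)
    e1 <- first_cutting_edge(m, sl$r, config, r_min)
    e2 <- second_cutting_edge(prof, e1, config, r_min)
    eu <- ultimate_edge(e1, e2)
    out$r_edge1_mm[k] <- e1
    out$r_edge2_mm[k] <- e2
    out$r_ultimate_mm[k] <- eu
    out$strategy_fired[k] <-
      if (is.finite(e1) && is.finite(e2)) "both"
      else if (is.finite(e1)) "1" else if (is.finite(e2)) "2" else "none"
    out$flag_inside_limbus[k] <- is.finite(eu) && is.finite(rl[k]) && eu < rl[k]
  }
  class(out) <- c("edge_profile", "data.frame")
  out
}

#' Trim a surface at the ultimate cutting edges
#'
#' Invalidates all nodes at or beyond each meridian's ultimate edge; nothing
#' is interpolated over the cut. Fails when more than half the meridians
#' would be fully cut (the measurement is unusable).
#'
#' @param surface A `polar_surface`.
#' @param edges An `edge_profile` computed on this surface.
#' @return The trimmed `polar_surface`.
#' @export
trim_surface <- function(surface, edges) {
  stopifnot(inherits(edges, "edge_profile"),
            nrow(edges) == length(surface$angles))
  fully_cut <- 0L
  for (k in seq_len(nrow(edges))) {
    eu <- edges$r_ultimate_mm[k]
    if (!is.finite(eu)) next
    kill <- surface$r >= eu
    surface$valid[kill, k] <- FALSE
    surface$z[kill, k] <- NA_real_
    if (!any(surface$valid[, k])) fully_cut <- fully_cut + 1L
  }
  if (fully_cut > nrow(edges) / 2)
    stop("quality error: more than 50% of meridians fully cut (", fully_cut,
         "/", nrow(edges), ")")
  surface
}
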