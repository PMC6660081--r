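test_that("meridian_slope is exact for quadratics and accurate for smooth signals", {
  r <- seq(0, 5, 0.05)
  sl <- meridian_slope(mk_profile(r, -r^2))
  interior <- 2:(length(r) - 1)
  expect_lt(max(abs(sl$dzdr[interior] + 2 * r[interior])), 1e-9)
  expect_equal(meridian_slope(mk_profile(r, rep(3, length(r))))$dzdr,
               rep(0, length(r)))
  sl2 <- meridian_slope(mk_profile(r, sin(r)))
  expect_lt(max(abs(sl2$dzdr[interior] - cos(r[interior]))), 0.05^2)
  expect_null(meridian_slope(mk_profile(r[1:2], c(0, 1), valid = c(TRUE, TRUE))))
})

test_that("moving_statistic reproduces the worked window examples", {
  v <- c(0, 0, 100, 0, 0)
  g <- (0:4) * 0.1
  cfg_med <- moving_window_config(halfwidth = 0.1, max_elements = 3, statistic = "median")
  cfg_mean <- moving_window_config(halfwidth = 0.1, max_elements = 3, statistic = "mean")
  expect_equal(moving_statistic(v, g, cfg_med), rep(0, 5))          # spike rejected
  expect_equal(moving_statistic(v, g, cfg_mean), c(0, 100, 100, 100, 0) / 3)
  konst <- rep(2.5, 9)
  expect_equal(moving_statistic(konst, (0:8) * 0.05, cfg_med), konst)
  expect_equal(moving_statistic(konst, (0:8) * 0.05, cfg_mean), konst)
})

test_that("moving_statistic equals the brute-force oracle on random arrays (both caps, both statistics)", {
  set.seed(8)
  for (rep in 1:200) {
    n <- sample(5:40, 1)
    vals <- rnorm(n)
    grid <- sort(runif(n, 0, 2))     # non-uniform grid exercises both caps
    hw <- runif(1, 0.05, 0.5)
    me <- sample(c(3, 5, 7, 11), 1)
    cfg <- moving_window_config(halfwidth = hw, max_elements = me,
                                statistic = sample(c("median", "mean"), 1))
    expect_identical(moving_statistic(vals, grid, cfg),
                     naive_moving_stat(vals, grid, hw, me, cfg$statistic))
  }
})

test_that("first cutting edge triggers on a sustained slope discontinuity, not on a smooth sclera", {
  r <- seq(0, 10, 0.05)
  z_smooth <- sqrt(11.5^2 - r^2) - 11.5
  cfg <- moving_window_config()
  sl <- meridian_slope(mk_profile(r, z_smooth))
  m <- moving_statistic(abs(sl$dzdr), sl$r, cfg)
  expect_true(is.na(first_cutting_edge(m, sl$r, cfg, r_min = 6.2)))
  # lift-off with a sustained steep ramp beyond 9.0 mm (the slope screen
  # needs the artefact zone to be a minority of the post-limbus span,
  # because the tripled-mean threshold includes the artefact itself)
  z_art <- z_smooth + pmax(0, r - 9.0) * 20
  sl2 <- meridian_slope(mk_profile(r, z_art))
  m2 <- moving_statistic(abs(sl2$dzdr), sl2$r, cfg)
  e1 <- first_cutting_edge(m2, sl2$r, cfg, r_min = 6.2)
  expect_lt(abs(e1 - 9.0), 0.1 + 1e-9)
  # infinite threshold factor: never triggers
  cfg_inf <- moving_window_config(threshold_factor = 1e9)
  expect_true(is.na(first_cutting_edge(m2, sl2$r, cfg_inf, r_min = 6.2)))
})

test_that("second cutting edge finds the innermost prominent pre-edge minimum", {
  r <- seq(0, 10, 0.05)
  z <- sqrt(11.5^2 - r^2) - 11.5
  cfg <- moving_window_config()
  expect_true(is.na(second_cutting_edge(mk_profile(r, z), NA, cfg, r_min = 6.2)))
  # tear-pool dip at 7.0 before a lift-off edge at 7.8
  dip <- -0.2 * exp(-((r - 7.0) / 0.1)^2)
  e2 <- second_cutting_edge(mk_profile(r, z + dip), 7.8, cfg, r_min = 6.2)
  expect_lt(abs(e2 - 7.0), 0.1 + 1e-9)
  # two minima: the innermost (most conservative) wins
  dip2 <- dip - 0.2 * exp(-((r - 7.4) / 0.1)^2)
  e2b <- second_cutting_edge(mk_profile(r, z + dip2), NA, cfg, r_min = 6.2)
  expect_lt(abs(e2b - 7.0), 0.1 + 1e-9)
  # sub-prominence wiggles are ignored
  tiny <- -0.005 * exp(-((r - 7.0) / 0.1)^2)
  expect_true(is.na(second_cutting_edge(mk_profile(r, z + tiny), NA, cfg, r_min = 6.2)))
})

test_that("ultimate edge is the minimum of the defined candidates", {
  expect_equal(ultimate_edge(7.5, 7.0), 7.0)
  expect_equal(ultimate_edge(7.5, NA), 7.5)
  expect_true(is.na(ultimate_edge(NA, NA)))
})

test_that("trim_surface cuts at the ultimate edge and fails when unusable", {
  s <- analytic_hemisphere_surface()
  edges <- detect_edges(s, 5.95)
  expect_true(all(edges$strategy_fired == "none"))
  trimmed <- trim_surface(s, edges)
  expect_identical(trimmed$valid, s$valid)
  # cut a single meridian at 7.0
  edges$r_ultimate_mm[edges$angle_deg == 30] <- 7.0
  t2 <- trim_surface(s, edges)
  k <- match(30, s$angles)
  expect_true(all(!t2$valid[s$r >= 7.0, k]))
  expect_true(all(t2$valid[s$r < 7.0, k]))
  expect_true(all(t2$valid[, -k]))
  # more than half the meridians fully cut -> quality error
  edges$r_ultimate_mm <- c(rep(0, 200), rep(NA, 160))
  expect_error(trim_surface(s, edges), "50%")
})

test_that("planted artefacts are cut near their onsets; artefact-free eyes are spared; trimming is idempotent", {
  arts <- list(artefact_spec("liftoff", 7.5, c(-30, 80), amplitude = 0.5, ramp_width = 0.1),
               artefact_spec("tearpool", 7.0, c(120, 200), amplitude = 0.4, ramp_width = 0.15),
               artefact_spec("lash_spike", 7.8, c(-120, -60), amplitude = 0.6, ramp_width = 0.08))
  ge <- generate_eye(eye_recipe(artefacts = arts, tilt = c(2, 1), seed = 31))
  lev <- level_eye(ge$cloud)
  rl <- lev$limbus$table$r_smoothed_mm
  rl[!is.finite(rl)] <- lev$limbus$mean_limbus_radius
  edges <- detect_edges(lev$surface, rl)
  truth <- ge$truth$artefact_onset[as.character(edges$angle_deg)]
  has_art <- is.finite(truth)
  err <- edges$r_ultimate_mm - truth
  expect_gt(mean(is.finite(err[has_art])), 0.95)
  expect_lte(median(abs(err[has_art]), na.rm = TRUE), 0.1 + 1e-9)
  expect_false(any(edges$flag_inside_limbus))
  # false cuts inside the true sclera on clean meridians
  clean_cut <- is.finite(edges$r_ultimate_mm[!has_art])
  expect_lt(mean(clean_cut), 0.05)
  # idempotence: a second detection pass on the trimmed surface cuts almost nothing new
  trimmed <- trim_surface(lev$surface, edges)
  edges2 <- detect_edges(trimmed, rl)
  new_cut <- is.finite(edges2$r_ultimate_mm) &
    (!is.finite(edges$r_ultimate_mm) |
       edges2$r_ultimate_mm < edges$r_ultimate_mm - 0.1)
  expect_gte(mean(!new_cut), 0.99)
})
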