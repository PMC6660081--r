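test_that("sample_at_radius matches the closed form and respects cuts", {
  s <- analytic_hemisphere_surface(R = 11.5)
  v <- sample_at_radius(s, 8)
  expect_equal(unname(v), rep(sqrt(11.5^2 - 64) - 11.5, 360), tolerance = 1e-9)
  # node exactly on the grid: no interpolation error
  v2 <- sample_at_radius(s, 7.35)
  expect_equal(unname(v2[1]), sqrt(11.5^2 - 7.35^2) - 11.5)
  # r beyond every cut: all missing
  s$valid[s$r >= 6, ] <- FALSE
  expect_true(all(is.na(sample_at_radius(s, 8))))
})

test_that("asymmetry profiles difference opposite meridians with the stated convention", {
  angles <- -180:179
  # rotationally symmetric surface
  sym <- asymmetry_profile(setNames(rep(-3, 360), angles), "raw")
  expect_equal(unname(sym$diff), rep(0, 180))
  expect_length(sym$diff, 180)
  # tilt-like residual v = c cos(theta) doubles
  v <- setNames(0.05 * cos(angles * pi / 180), angles)
  ap <- asymmetry_profile(v, "raw")
  expect_equal(unname(ap$diff), 0.1 * cos((0:179) * pi / 180), tolerance = 1e-12)
  # planted nasal sector bump
  vb <- setNames(ifelse(abs(angles) <= 10, 0.2, 0), angles)
  apb <- asymmetry_profile(vb, "raw")
  expect_equal(unname(apb$diff[as.character(c(0, 5))]), c(0.2, 0.2))
  expect_equal(unname(apb$diff["90"]), 0)
  # antisymmetry under swapping the roles of theta and theta - 180
  v_sw <- v; names(v_sw) <- as.character(scleratopo:::wrap_angle(angles - 180))
  ap_sw <- asymmetry_profile(v_sw[as.character(angles)], "raw")
  expect_equal(unname(ap_sw$diff), -unname(ap$diff))
  # missing values propagate
  v_na <- v; v_na["10"] <- NA
  expect_true(is.na(asymmetry_profile(v_na, "raw")$diff["10"]))
})

test_that("aggregate_group means, cancels, and locates planted maxima", {
  angles <- -180:179
  v <- setNames(0.05 * cos((angles + 38) * pi / 180), angles)
  p <- asymmetry_profile(v, "raw")
  g_same <- aggregate_group(list(p, p, p))
  expect_equal(g_same$table$mean_diff_mm, unname(p$diff))
  expect_equal(g_same$table$sd_diff_mm, rep(0, 180))
  # +d and -d cancel with sample sd |d| * sqrt(2)
  p_neg <- asymmetry_profile(setNames(-v, angles), "raw")
  g_pm <- aggregate_group(list(p, p_neg))
  expect_equal(g_pm$table$mean_diff_mm, rep(0, 180))
  expect_equal(g_pm$table$sd_diff_mm, abs(unname(p$diff)) * sqrt(2))
  # planted -38 deg axis: signed label reported on the positive side
  set.seed(14)
  profs <- lapply(1:50, function(i) {
    vi <- v + rnorm(360, 0, 0.002)
    names(vi) <- angles
    asymmetry_profile(vi, "raw")
  })
  g <- aggregate_group(profs)
  expect_lte(min(abs(g$argmax_angle_deg - (-38)),
                 abs(g$argmax_angle_deg - 142)), 5)
  expect_equal(g$max_mean_diff_mm, 0.1, tolerance = 0.05)
})

test_that("per-meridian t-test matches the reference implementation and handles edge cases", {
  set.seed(15)
  for (i in 1:20) {
    a <- rnorm(sample(5:40, 1))
    b <- rnorm(sample(5:40, 1), mean = runif(1, -1, 1))
    ours <- per_meridian_ttest(a, b)
    ref <- t.test(a, b)
    expect_equal(ours$t, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
    ref_pool <- t.test(a, b, var.equal = TRUE)
    ours_pool <- per_meridian_ttest(a, b, var_equal = TRUE)
    expect_equal(ours_pool$p, ref_pool$p.value, tolerance = 1e-12)
  }
  # identical groups: p = 1, decision 0
  z <- rep(2, 5)
  expect_equal(per_meridian_ttest(z, z), list(t = 0, p = 1, decision = 0L, df = 8))
  # zero variance, different means
  expect_equal(per_meridian_ttest(z, z + 1)$decision, 1L)
  # clearly separated groups
  set.seed(16)
  expect_equal(per_meridian_ttest(rnorm(30), rnorm(30, 5))$decision, 1L)
  # degenerate n: skipped
  expect_true(is.na(per_meridian_ttest(1, c(1, 2))$decision))
})

test_that("decisions are exactly the p < 0.05 threshold (p = 0.05 is not significant)", {
  set.seed(17)
  angles <- -180:179
  profs <- lapply(1:8, function(i)
    asymmetry_profile(setNames(rnorm(360, 0, 0.02), angles), "raw"))
  g <- aggregate_group(profs)
  ok <- is.finite(g$table$p)
  expect_identical(g$table$decision[ok], as.integer(g$table$p[ok] < 0.05))
})

test_that("decision_ranges pools contiguous same-decision angles", {
  angles <- -180:179
  v <- setNames(0.3 * cos(angles * pi / 180), angles)
  set.seed(18)
  profs <- lapply(1:12, function(i) {
    vi <- v + rnorm(360, 0, 0.05); names(vi) <- angles
    asymmetry_profile(vi, "raw")
  })
  g <- aggregate_group(profs)
  dr <- decision_ranges(g)
  expect_true(nrow(dr) >= 1)
  expect_true(all(dr$decision %in% c(0L, 1L)))
  expect_true(all(dr$from_deg <= dr$to_deg))
  # ranges tile 0..179 without overlap
  expect_equal(sum(dr$to_deg - dr$from_deg + 1), sum(is.finite(g$table$p)))
})
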