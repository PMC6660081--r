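test_that("limbus detection finds a planted two-arc junction and rejects a single arc", {
  expect_equal(detect_limbus_meridian(two_arc_profile()), 5.9, tolerance = 0.15 / 5.9)
  # single circle: curvature varies smoothly, no junction exists
  r <- seq(0, 10, 0.05)
  circ <- mk_profile(r, sqrt(11.5^2 - r^2) - 11.5)
  expect_true(is.na(detect_limbus_meridian(circ)))
})

test_that("limbus detection is robust to measurement noise (50 replicates)", {
  set.seed(11)
  det <- replicate(50, detect_limbus_meridian(two_arc_profile(noise_sd = 0.005)))
  expect_lt(abs(median(det, na.rm = TRUE) - 5.9), 0.2)
  expect_lt(mean(is.na(det)), 0.05)
})

test_that("plane fitting recovers analytic planes and is robust to noise", {
  # exactly horizontal
  th <- seq(0, 2 * pi, length.out = 73)[-73]
  flat <- cbind(6 * cos(th), 6 * sin(th), 2)
  fl <- fit_limbus_plane(flat)
  expect_equal(fl$normal, c(0, 0, 1), tolerance = 1e-12)
  expect_equal(fl$offset, 2)
  # analytic tilted plane z = 0.1 x
  tilted <- cbind(6 * cos(th), 6 * sin(th), 0.6 * cos(th))
  ft <- fit_limbus_plane(tilted)
  expect_equal(ft$normal, c(-0.1, 0, 1) / sqrt(1.01), tolerance = 1e-9)
  # noisy plane: 360 points, 10 um -> normal within 0.05 deg
  set.seed(4)
  n_true <- c(sin(2 * pi / 180), 0, cos(2 * pi / 180))
  x <- 6 * cos(seq(0, 2 * pi, length.out = 361)[-361])
  y <- 6 * sin(seq(0, 2 * pi, length.out = 361)[-361])
  z <- -(n_true[1] * x + n_true[2] * y) / n_true[3] + rnorm(360, 0, 0.01)
  fn <- fit_limbus_plane(cbind(x, y, z))
  ang_err <- acos(min(1, sum(fn$normal * n_true)))
  expect_lt(ang_err * 180 / pi, 0.05)
  expect_error(fit_limbus_plane(cbind(1:5, 2 * (1:5), 3 * (1:5))), "collinear")
  expect_error(fit_limbus_plane(flat[1:2, ]), "at least 3")
})

test_that("tilt angles follow the inverse-cosine construction", {
  expect_equal(tilt_angles(c(0, 0, 1)), c(alpha_x = 0, alpha_y = 0))
  t5 <- 5 * pi / 180
  expect_equal(unname(tilt_angles(c(0, sin(t5), cos(t5)))[1]), -t5)
  expect_equal(unname(tilt_angles(c(sin(t5), 0, cos(t5)))[2]), -t5)
  expect_warning(a <- tilt_angles(c(0, 0, 2)), "normalis")
  expect_equal(unname(a), c(0, 0))
  expect_error(suppressWarnings(tilt_angles(c(0, 1, -0.1))), "Nz > 0")
})

test_that("level_surface is a proper rigid rotation", {
  set.seed(5)
  cl <- hemisphere_cloud(n = 200)
  same <- level_surface(cl, 0, 0)
  expect_equal(same$z, cl$z)
  rot <- level_surface(cl, 0.05, -0.03)
  i <- 1:40
  d0 <- c(dist(cbind(cl$x[i], cl$y[i], cl$z[i])))
  d1 <- c(dist(cbind(rot$x[i], rot$y[i], rot$z[i])))
  expect_lt(max(abs(d0 - d1)), 1e-9)
  # rotation matrices orthonormal to 1e-12, det +1
  R <- scleratopo:::rot_y(-0.03) %*% scleratopo:::rot_x(-0.05)
  expect_lt(max(abs(crossprod(R) - diag(3))), 1e-12)
  expect_equal(det(R), 1)
  expect_error(level_surface(cl, 1.2, 0), "alpha")
})

test_that("recenter_apex finds and re-origins the true apex", {
  set.seed(6)
  cl <- hemisphere_cloud(n = 80000, r_max = 7, center = c(1, -1))
  out <- recenter_apex(cl)
  i0 <- which.max(out$z)
  expect_lt(abs(out$x[i0]), 0.1)
  expect_lt(abs(out$y[i0]), 0.1)
  expect_lt(abs(max(out$z)), 1e-3)
  # already centred: identity within refinement tolerance
  ctr <- hemisphere_cloud(n = 80000, r_max = 7)
  out2 <- recenter_apex(ctr)
  expect_lt(abs(mean(out2$x - ctr$x)), 0.05)
  # noisy apex localisation within 0.1 mm
  set.seed(7)
  noisy <- hemisphere_cloud(n = 80000, r_max = 7, center = c(0.5, 0.25), noise_sd = 0.005)
  out3 <- recenter_apex(noisy)
  shift <- c(mean(noisy$x - out3$x), mean(noisy$y - out3$y))
  expect_lt(max(abs(shift - c(0.5, 0.25))), 0.1)
  # decentred measurement: the true apex is outside the scan, so the
  # highest point sits on the support boundary
  half <- ctr
  keep <- half$x >= 0.2
  half$x <- half$x[keep]; half$y <- half$y[keep]; half$z <- half$z[keep]
  expect_error(recenter_apex(half), "apex-at-edge")
})

test_that("level_eye recovers a planted tilt and is idempotent", {
  ge <- generate_eye(eye_recipe(tilt = c(3, -2), seed = 21))
  lev <- level_eye(ge$cloud)
  expect_lt(abs(lev$limbus$alpha_x * 180 / pi - 3), 0.05)
  expect_lt(abs(lev$limbus$alpha_y * 180 / pi + 2), 0.05)
  expect_identical(lev$limbus$alpha_z, 0)
  expect_lt(abs(1 - sum(lev$limbus$plane_normal^2)), 1e-12)
  # re-running detection + levelling on the levelled eye: residual < 0.05 deg
  lev2 <- level_eye(lev$cloud)
  expect_lt(abs(lev2$limbus$alpha_x) * 180 / pi, 0.05)
  expect_lt(abs(lev2$limbus$alpha_y) * 180 / pi, 0.05)
  # limbus radius recovered across meridians
  err <- abs(lev$limbus$table$r_limbus_mm - 5.95)
  expect_lt(quantile(err, 0.95, na.rm = TRUE), 0.2)
})
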