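test_that("xyz-csv read-back is the identity and drops non-finite rows with a count", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(x_mm = c(1, 2, 3, NA, 5, 6, 7),
                   y_mm = c(0, 0, 0, 0, NaN, 0, 0),
                   z_mm = c(-1, -2, -3, -4, -5, -6, -7))
  write.csv(df, tmp, row.names = FALSE)
  expect_message(cl <- load_point_cloud(tmp, "xyz-csv", "OD"), "dropped 2")
  expect_s3_class(cl, "eye_cloud")
  expect_length(cl$x, 5)
  expect_equal(cl$n_dropped, 2L)
  expect_equal(cl$x, c(1, 2, 3, 6, 7))

  bad <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(a = 1, b = 2), bad, row.names = FALSE)
  expect_error(load_point_cloud(bad, "xyz-csv", "OD"), "missing column.*x_mm")
})

test_that("write/load round-trips reproduce coordinates (csv and mat)", {
  set.seed(42)
  cl <- hemisphere_cloud(n = 500, noise_sd = 0.01)
  for (dialect in c("xyz-csv", "mat-container")) {
    tmp <- withr::local_tempfile(fileext = if (dialect == "xyz-csv") ".csv" else ".mat")
    write_point_cloud(cl, tmp, dialect)
    back <- load_point_cloud(tmp, dialect, "OD")
    tol <- if (dialect == "mat-container") 1e-12 else 1e-9
    expect_lt(max(abs(back$x - cl$x)), tol)
    expect_lt(max(abs(back$y - cl$y)), tol)
    expect_lt(max(abs(back$z - cl$z)), tol)
  }
})

test_that("MAT container honours the variable map and names missing variables", {
  tmp <- withr::local_tempfile(fileext = ".mat")
  write_mat(list(px = c(1, 2), py = c(3, 4), pz = c(5, 6), extra = 1), tmp)
  cl <- load_point_cloud(tmp, "mat-container", "OS",
                         var_map = c(x = "px", y = "py", z = "pz"))
  expect_equal(cl$z, c(5, 6))
  expect_error(load_point_cloud(tmp, "mat-container", "OS"), "missing variable")
})

test_that("anatomical frame conversion negates x for OS only, is an involution and an isometry", {
  set.seed(7)
  od <- hemisphere_cloud(n = 300)
  od$frame <- "instrument"
  a_od <- to_anatomical_frame(od)
  expect_equal(a_od$x, od$x)         # OD: instrument +x already nasal
  expect_equal(a_od$frame, "anatomical")

  os <- od; os$laterality <- "OS"
  # plant a marker on the instrument temporal side (+x for OS)
  os$x[1] <- 9; os$y[1] <- 0
  a_os <- to_anatomical_frame(os)
  expect_equal(a_os$x[1], -9)        # temporal marker now at negative (temporal) x
  expect_equal(a_os$y, os$y)
  back <- to_anatomical_frame(a_os)
  expect_equal(back$x, os$x)
  expect_equal(back$frame, "instrument")
  # pairwise distances preserved exactly (spot-check a subset)
  i <- 1:50
  d0 <- dist(cbind(os$x[i], os$y[i], os$z[i]))
  d1 <- dist(cbind(a_os$x[i], a_os$y[i], a_os$z[i]))
  expect_identical(c(d0), c(d1))
})

test_that("resample_polar matches a closed-form hemisphere within 1e-3 mm", {
  set.seed(1)
  cl <- hemisphere_cloud(n = 150000, R = 11.5)
  s <- resample_polar(cl)
  truth <- sqrt(11.5^2 - s$r^2) - 11.5
  sel <- s$valid & s$r <= 10
  err <- abs(s$z - truth)[sel]
  # mid-periphery (where a real scan is dense) is essentially fully valid;
  # near the apex areal sampling thins out geometrically
  expect_gt(mean(s$valid[s$r >= 3 & s$r <= 9.5, ]), 0.85)
  expect_lt(max(err), 1e-3)
})

test_that("resample_polar never extrapolates into angular gaps and flags thin meridians", {
  set.seed(2)
  cl <- hemisphere_cloud(n = 60000, r_max = 8)
  th <- atan2(cl$y, cl$x) * 180 / pi
  keep <- !(th > 40 & th < 70)       # 30-degree angular void
  cl$x <- cl$x[keep]; cl$y <- cl$y[keep]; cl$z <- cl$z[keep]
  s <- resample_polar(cl)
  gap_cols <- s$angles > 41 & s$angles < 69
  expect_true(all(!s$valid[, gap_cols]))
  expect_gt(mean(s$valid[s$r >= 3 & s$r <= 7, !gap_cols & s$angles > -170]), 0.7)
  # flat plane resamples to exactly zero
  cl0 <- cl; cl0$z <- rep(0, length(cl0$z))
  s0 <- resample_polar(cl0)
  expect_equal(max(abs(s0$z[s0$valid])), 0)
})

test_that("polar CSV writer round-trips the surface", {
  set.seed(3)
  s <- resample_polar(hemisphere_cloud(n = 30000, r_max = 6), angular_step = 10)
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_polar_csv(s, tmp, hash = "abc")
  expect_match(readLines(tmp, n = 1), "config_hash=abc")
  back <- read_polar_csv(tmp)
  expect_equal(back$angles, s$angles)
  expect_equal(back$z[back$valid], s$z[s$valid])
  expect_equal(back$valid, unname(s$valid), ignore_attr = TRUE)
})
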