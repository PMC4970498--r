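test_that("constant dark frames give exact offset, zero noise, full counts", {
  frames <- replicate(100, matrix(120, 8, 8), simplify = FALSE)
  cal <- darkcal_train(frames)
  expect_true(all(cal$offset == 120))
  expect_true(all(cal$noise == 0))
  expect_true(all(cal$counts == 100))
  expect_equal(cal$train_size, 100)
})

test_that("training rejects a single large spike, matching the vector oracle", {
  frames <- replicate(51, matrix(100, 4, 4), simplify = FALSE)
  frames[[51]][2, 3] <- 10000
  cal <- darkcal_train(frames, n_outlier = 3)
  expect_equal(cal$counts[2, 3], 50)
  expect_equal(cal$offset[2, 3], 100)
  expect_equal(cal$noise[2, 3], 0)
  orc <- oracle_reject(c(rep(100, 50), 10000), n_outlier = 3)
  expect_equal(cal$offset[2, 3], orc$mean)
  expect_equal(sum(orc$keep), cal$counts[2, 3])
})

test_that("training needs two identically shaped frames", {
  expect_error(darkcal_train(list(matrix(0, 4, 4))), "at least 2")
  expect_error(darkcal_train(list(matrix(0, 4, 4), matrix(0, 4, 5))),
               "different shape")
})

test_that("offset and noise recover known Gaussian dark statistics", {
  run <- gen_dark_run(shape = c(48, 48), n_frames = 200,
                      outlier_fraction = 0, seed = 11)
  cal <- darkcal_train(run$frames)
  mu <- run$truth$mu; sigma <- run$truth$sigma
  frac_off <- mean(abs(cal$offset - mu) <= 4 * sigma / sqrt(200))
  frac_noi <- mean(abs(cal$noise - sigma) / sigma <= 0.15)
  expect_gte(frac_off, 0.99)
  expect_gte(frac_noi, 0.99)
})

test_that("training is idempotent on its surviving values", {
  # 1x1 frames make the per-pixel value list explicit
  vals <- withr::with_seed(3, c(rnorm(60, 100, 2), 500, 900))
  frames <- lapply(vals, function(v) matrix(v, 1, 1))
  cal <- darkcal_train(frames, n_outlier = 4)
  survivors <- vals[abs(vals - cal$offset[1, 1]) <=
                      4 * max(cal$noise[1, 1], 1e-6)]
  expect_equal(length(survivors), cal$counts[1, 1])
  cal2 <- darkcal_train(lapply(survivors, function(v) matrix(v, 1, 1)),
                        n_outlier = 4)
  expect_equal(cal2$offset[1, 1], cal$offset[1, 1])
  expect_equal(cal2$noise[1, 1], cal$noise[1, 1])
  expect_equal(cal2$counts[1, 1], cal$counts[1, 1])
})

test_that("cumulative update with the offset itself only bumps counts", {
  run <- gen_dark_run(shape = c(8, 8), n_frames = 20, outlier_fraction = 0,
                      seed = 5)
  cal <- darkcal_train(run$frames)
  up <- darkcal_update(cal, cal$offset, "cumulative")
  expect_equal(up$offset, cal$offset)
  expect_equal(up$counts, cal$counts + 1)
})

test_that("cumulative updates equal one big training on outlier-free data", {
  run <- gen_dark_run(shape = c(16, 16), n_frames = 200, outlier_fraction = 0,
                      sigma_range = c(1, 2), seed = 7)
  fl <- lapply(seq_len(200), function(i) run$frames[, , i])
  cal <- darkcal_train(fl[1:100], n_outlier = 50)   # no rejection
  for (i in 101:200) cal <- darkcal_update(cal, fl[[i]], "cumulative",
                                           n_outlier = 50)
  full <- darkcal_train(fl, n_outlier = 50)
  expect_equal(cal$offset, full$offset, tolerance = 1e-10)
  expect_equal(cal$noise, full$noise, tolerance = 1e-8)
  expect_equal(cal$counts, full$counts)
})

test_that("exponential updates converge geometrically to a constant level", {
  cal <- darkcal_train(replicate(10, matrix(100, 4, 4), simplify = FALSE))
  cal$noise[] <- 5   # allow the new level inside the acceptance band
  a <- 0.1
  dev <- numeric(6)
  for (k in 1:6) {
    cal <- darkcal_update(cal, matrix(110, 4, 4), "exponential", alpha = a)
    dev[k] <- 110 - cal$offset[1, 1]
  }
  expect_equal(dev[-1] / dev[-6], rep(1 - a, 5), tolerance = 1e-10)
  expect_error(darkcal_update(cal, matrix(0, 4, 4), "exponential", alpha = 1.5),
               "alpha")
})

test_that("outlying frames are skipped during updates", {
  cal <- darkcal_train(replicate(20, matrix(100, 4, 4), simplify = FALSE))
  cal$noise[] <- 1
  spiked <- matrix(100, 4, 4); spiked[1, 1] <- 5000
  up <- darkcal_update(cal, spiked, "cumulative", n_outlier = 4)
  expect_equal(up$counts[1, 1], 20)   # skipped
  expect_equal(up$counts[2, 2], 21)
  expect_equal(up$offset[1, 1], 100)
})

test_that("automatic boundaries flag exactly the deviant pixel", {
  off <- matrix(100, 16, 16) + withr::with_seed(1, rnorm(256, 0, 1))
  noi <- matrix(3, 16, 16) + withr::with_seed(2, abs(rnorm(256, 0, 0.2)))
  off[5, 9] <- off[5, 9] * 10
  cal <- new_cal_for_test(off, noi)
  cal <- detect_bad_pixels(cal, "auto", n = 4)
  expect_equal(which(cal$mask == 1), (9 - 1) * 16 + 5)
  # idempotent under re-running with identical bounds
  cal2 <- detect_bad_pixels(cal, "auto", n = 4)
  expect_equal(cal2$mask, cal$mask)
})

test_that("uniform maps and explicit bounds behave as documented", {
  cal <- new_cal_for_test(matrix(100, 8, 8), matrix(2, 8, 8))
  cal <- detect_bad_pixels(cal, "auto", n = 4)
  expect_true(all(cal$mask == 0))   # degenerate maps: everyone good
  off <- matrix(100, 4, 4); off[2, 2] <- 120; off[3, 3] <- 120
  cal <- new_cal_for_test(off, matrix(1, 4, 4))
  cal <- detect_bad_pixels(cal, bounds = list(offset = c(90, 110)))
  expect_equal(sum(cal$mask), 2)
  expect_true(all(cal$mask[off == 120] == 1))
})

test_that("correction dialects: crystfel subtracts, nxds only marks", {
  off <- matrix(50, 4, 4)
  cal <- new_cal_for_test(off, matrix(1, 4, 4))
  cal$mask[1, 4] <- 1
  fr <- off
  cor <- apply_correction(fr, cal, "crystfel")
  expect_true(all(cor == 0))
  fr2 <- matrix(rnorm(16, 100), 4, 4)
  nx <- apply_correction(fr2, cal, "nxds")
  expect_identical(nx[cal$mask == 0], fr2[cal$mask == 0])
  expect_equal(nx[1, 4], -1)
  expect_equal(apply_correction(fr2, cal, "crystfel", masked_value = -7)[1, 4], -7)
  expect_error(apply_correction(matrix(0, 2, 2), cal), "shape")
})

test_that("stack and split invert each other with the documented order", {
  run <- gen_dark_run(shape = c(64, 64), n_frames = 10, seed = 9)
  cal <- detect_bad_pixels(darkcal_train(run$frames))
  st <- stack_maps(cal)
  expect_equal(dim(st), c(256, 64))
  expect_equal(st[129:192, ], cal$counts)   # third block is the counts map
  back <- split_maps(st)
  expect_equal(back$offset, cal$offset)
  expect_equal(back$noise, cal$noise)
  expect_equal(back$counts, cal$counts)
  expect_equal(back$mask, cal$mask)
  expect_error(split_maps(st[1:98, ]), "4x")
})

test_that("calibration files round-trip and regenerate missing pieces", {
  dir <- withr::local_tempdir()
  run <- gen_dark_run(shape = c(16, 16), n_frames = 30, seed = 13)
  cal <- detect_bad_pixels(darkcal_train(run$frames))
  p <- file.path(dir, "cal.h5")
  save_calibration(cal, p)
  back <- load_calibration(p)
  expect_equal(back$offset, cal$offset)
  expect_equal(back$noise, cal$noise)
  expect_equal(back$counts, cal$counts)
  expect_equal(back$mask, cal$mask)
  expect_equal(back$train_size, 30)

  # offset/noise-only file: counts substituted by train size, mask regenerated
  p2 <- file.path(dir, "old.h5")
  rhdf5::h5createFile(p2)
  rhdf5::h5write(cal$offset, p2, "offset")
  rhdf5::h5write(cal$noise, p2, "noise")
  rhdf5::h5closeAll()
  back2 <- load_calibration(p2, train_size = 30)
  expect_true(all(back2$counts == 30))
  expect_equal(back2$mask, detect_bad_pixels(back2, "auto", n = 4)$mask)
  expect_error(load_calibration(p2), "train_size")

  p3 <- file.path(dir, "empty.h5")
  rhdf5::h5createFile(p3)
  rhdf5::h5write(1:3, p3, "whatever")
  rhdf5::h5closeAll()
  expect_error(load_calibration(p3), "whatever")
})

test_that("automatic naming produces timestamped files plus a latest alias", {
  dir <- withr::local_tempdir()
  cal <- new_cal_for_test(matrix(1, 4, 4), matrix(1, 4, 4))
  cal$counts[] <- 5
  p1 <- save_calibration(cal, path = NULL, base_name = "dk", dir = dir)
  p2 <- save_calibration(cal, path = NULL, base_name = "dk", dir = dir)
  expect_true(file.exists(p1) && file.exists(p2))
  expect_false(p1 == p2)
  latest <- file.path(dir, "dk_latest.h5")
  expect_true(file.exists(latest))
  expect_equal(load_calibration(latest)$offset, cal$offset)
})

test_that("common-mode utility removes per-row medians", {
  fr <- matrix(rnorm(64), 8, 8) + (1:8) * 10
  cc <- common_mode_correct(fr)
  expect_equal(apply(cc, 1, median), rep(0, 8))
})
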