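test_that("an empty frame yields an empty peak table", {
  pt <- find_peaks(matrix(0, 64, 64), peak_params(pixel_threshold = 50))
  expect_s3_class(pt, "peak_table")
  expect_equal(nrow(pt), 0)
  expect_equal(count_peaks(pt), 0)
})

test_that("a uniform 3x3 block is found with exact statistics", {
  fr <- matrix(0, 64, 64)
  fr[30:32, 30:32] <- 100
  pp <- peak_params(pixel_threshold = 50, box_half_width = 4,
                    snr_background = 2, snr_peak = 3, min_npix = 4)
  pt <- find_peaks(fr, pp)
  expect_equal(nrow(pt), 1)
  expect_equal(pt$npix, 9)
  expect_equal(pt$max_value, 100)
  expect_equal(pt$integrated, 900, tolerance = 1e-9)
  expect_equal(pt$centroid_row, 31)
  expect_equal(pt$centroid_col, 31)
  # raising the membership requirement above the footprint kills the peak
  pp10 <- peak_params(pixel_threshold = 50, box_half_width = 4,
                      snr_background = 2, snr_peak = 3, min_npix = 10)
  expect_equal(nrow(find_peaks(fr, pp10)), 0)
})

test_that("find_peaks matches the brute-force oracle row for row", {
  pp <- peak_params()
  for (s in 1:40) {
    bf <- gen_bragg_frame(n_peaks = sample(0:6, 1), seed = 1000 + s)
    a <- find_peaks(bf$frame, pp)
    b <- oracle_find_peaks(bf$frame, pp)
    expect_equal(nrow(a), nrow(b), info = sprintf("seed %d", s))
    if (nrow(a)) {
      rownames(a) <- rownames(b) <- NULL
      expect_equal(as.data.frame(a), as.data.frame(b), tolerance = 1e-10,
                   info = sprintf("seed %d", s))
    }
  }
})

test_that("oracle agreement holds with masked pixels in play", {
  pp <- peak_params()
  for (s in 1:10) {
    bf <- gen_bragg_frame(seed = 2000 + s)
    mask <- matrix(0, 48, 48)
    mask[withr::with_seed(s, sample.int(48 * 48, 100))] <- 1
    a <- find_peaks(bf$frame, pp, mask = mask)
    b <- oracle_find_peaks(bf$frame, pp, mask = mask)
    rownames(a) <- rownames(b) <- NULL
    expect_equal(as.data.frame(a), as.data.frame(b), tolerance = 1e-10)
    # no peak references a masked pixel as seed
    if (nrow(a)) expect_true(all(mask[cbind(a$seed_row, a$seed_col)] == 0))
  }
})

test_that("injected strong peaks are recovered with sub-pixel centroids", {
  pp <- peak_params()
  found <- 0L; total <- 0L
  for (s in 1:60) {
    bf <- gen_bragg_frame(seed = 3000 + s)
    pt <- find_peaks(bf$frame, pp)
    for (k in seq_len(nrow(bf$truth))) {
      total <- total + 1L
      d <- sqrt((pt$centroid_row - bf$truth$row[k])^2 +
                  (pt$centroid_col - bf$truth$col[k])^2)
      if (sum(d <= 1) == 1) found <- found + 1L
    }
  }
  expect_gte(found / total, 0.95)
})

test_that("pure-noise frames rarely produce peaks at default thresholds", {
  pp <- peak_params()
  clean <- vapply(1:100, function(s) {
    bf <- gen_bragg_frame(n_peaks = 0, seed = 4000 + s)
    nrow(find_peaks(bf$frame, pp)) == 0
  }, logical(1))
  expect_gte(mean(clean), 0.99)
})

test_that("raising the seed threshold never increases the peak count", {
  bf <- gen_bragg_frame(n_peaks = 6, seed = 77)
  counts <- vapply(c(10, 20, 40, 80, 160, 320), function(thr)
    nrow(find_peaks(bf$frame, peak_params(pixel_threshold = thr))), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("hit classification is an inclusive range check", {
  expect_true(is_hit(5, c(5, 10)))
  expect_true(is_hit(10, c(5, 10)))
  expect_false(is_hit(11, c(5, 10)))
  expect_false(is_hit(4, c(5, 10)))
  expect_true(all(is_hit(0:100, c(0, Inf))))
})

test_that("saturation statistics partition the table", {
  pt <- data.frame(max_value = c(10, 200, 300))
  sr <- saturation_ratio(pt, 250)
  expect_equal(sr$n_saturated, 1)
  expect_equal(sr$n_total, 3)
  expect_equal(sr$ratio, 1 / 3)
  expect_equal(saturation_ratio(pt, 5)$ratio, 1)
  empty <- saturation_ratio(pt[0, , drop = FALSE], 250)
  expect_true(is.na(empty$ratio))
  expect_equal(sr$n_saturated + (sr$n_total - sr$n_saturated), count_peaks(pt))
})

test_that("the powder accumulator is a running mean over hit frames", {
  f1 <- matrix(1:4, 2, 2); f2 <- matrix(5:8, 2, 2)
  st <- powder_accumulate(NULL, f1)
  expect_equal(st$mean, f1)
  st2 <- powder_accumulate(st, f2)
  expect_equal(st2$mean, (f1 + f2) / 2)
  expect_equal(st2$n, 2)
  st3 <- powder_accumulate(powder_accumulate(NULL, f1), f1)
  expect_equal(st3$mean, f1)
})

test_that("hit rate looks only at the trailing window", {
  expect_equal(hit_rate(rep(TRUE, 10)), 1)
  expect_equal(hit_rate(rep(c(TRUE, FALSE), 50), window = 100), 0.5)
  expect_equal(hit_rate(c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE), window = 4), 0)
  expect_equal(hit_rate(c(FALSE, TRUE, TRUE), window = 2), 1)
  expect_true(is.na(hit_rate(logical(0))))
})
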