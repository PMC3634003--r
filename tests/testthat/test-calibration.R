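test_that("mean_cumulative_histogram matches empirical CDF oracles", {
  sm <- slope_map_from_values(c(1, 2, 3, 4))
  ch <- mean_cumulative_histogram(list(sm), grid_size = 256L)
  expect_equal(ch$cdf[1], 0.25)            # grid starts at the minimum
  expect_equal(max(ch$cdf), 1)
  expect_true(all(diff(ch$cdf) >= 0))
  f <- approxfun(ch$grid, ch$cdf, method = "constant", yleft = 0, yright = 1)
  expect_equal(f(c(1, 2.5, 3, 3.99)), c(0.25, 0.5, 0.75, 0.75))
  # two identical maps average to the single-map CDF
  ch2 <- mean_cumulative_histogram(list(sm, sm), grid_size = 256L)
  expect_equal(ch2$cdf, ch$cdf)
  # disjoint supports: brute-force average of the two step functions
  a <- slope_map_from_values(c(0, 1))
  b <- slope_map_from_values(c(10, 11))
  chd <- mean_cumulative_histogram(list(a, b), grid_size = 1024L)
  brute <- function(x) (mean(c(0, 1) <= x) + mean(c(10, 11) <= x)) / 2
  for (x in c(0.5, 1, 5, 10.5, 11)) {
    gi <- max(which(chd$grid <= x + 1e-9))
    expect_equal(chd$cdf[gi], brute(x))
  }
  # exclusion masks remove pixels
  ex <- matrix(FALSE, 2, 2); ex[1, 1] <- TRUE
  sm4 <- slope_map(matrix(c(100, 1, 2, 3), 2, 2), matrix(TRUE, 2, 2), 5L)
  che <- mean_cumulative_histogram(list(sm4), list(ex), grid_size = 64L)
  expect_equal(max(che$grid), 3)           # the 100 was masked out
  expect_error(mean_cumulative_histogram(
    list(slope_map(matrix(NA_real_, 2, 2), matrix(FALSE, 2, 2), 5L))),
    "no valid pixels")
})

test_that("derive_threshold agrees with sort-based quantiles", {
  set.seed(31)
  v <- runif(20000)
  ch <- mean_cumulative_histogram(list(slope_map_from_values(v)))
  step <- diff(ch$grid[1:2])
  # uniform sample: the 99.5% point sits near 0.995
  thr <- derive_threshold(ch, 0.995)
  expect_equal(thr$slope_threshold, 0.995, tolerance = 0.01)
  # single subject: matches the empirical quantile within one grid step
  q_oracle <- sort(v)[ceiling(0.995 * length(v))]
  expect_lt(abs(thr$slope_threshold - q_oracle), 2 * step + 1e-12)
  # median oracle at percentile 0.5
  thr50 <- derive_threshold(ch, 0.5)
  expect_lt(abs(thr50$slope_threshold - median(v)), 2 * step + 1e-12)
  expect_error(derive_threshold(ch, 1.5), "percentile")
})

test_that("abnormal_fraction counts supra-threshold pixels and is monotone", {
  v <- seq(0, 1, length.out = 101)
  sm <- slope_map_from_values(v)
  expect_equal(abnormal_fraction(sm, 1.0), 0)
  expect_equal(abnormal_fraction(sm, 0.5), mean(v > 0.5))
  # monotone non-increasing in the threshold
  ths <- seq(-0.1, 1.1, by = 0.1)
  fr <- vapply(ths, function(th) abnormal_fraction(sm, th), numeric(1))
  expect_true(all(diff(fr) <= 0))
  expect_error(abnormal_fraction(sm, 0.5, matrix(TRUE, 11, 11)), "no valid")
})

test_that("render_map colors normal blue and ramps abnormal yellow to red", {
  s <- matrix(0.001, 4, 4)
  valid <- matrix(TRUE, 4, 4)
  valid[1, 1] <- FALSE
  sm <- slope_map(s, valid, 5L)
  rgb <- render_map(sm, threshold = 0.002)
  expect_equal(rgb[2, 2, ], c(0, 0, 1))                 # blue
  expect_equal(rgb[1, 1, ], c(0, 0, 0))                 # invalid -> black
  # ramp endpoints: just-above-threshold is yellow, the top is red
  s2 <- matrix(0, 4, 4)
  s2[2, 2] <- 0.00201; s2[3, 3] <- 0.01
  sm2 <- slope_map(s2, matrix(TRUE, 4, 4), 5L)
  rgb2 <- render_map(sm2, 0.002)
  expect_equal(rgb2[2, 2, ], c(1, 1, 0), tolerance = 0.01)  # yellow
  expect_equal(rgb2[3, 3, ], c(1, 0, 0), tolerance = 0.01)  # red
  expect_equal(rgb2[4, 4, ], c(0, 0, 1))                # rest blue
  # rendering is pure: identical on re-run
  expect_identical(render_map(sm2, 0.002), rgb2)
  # single supra-threshold pixel
  s3 <- matrix(0, 3, 3); s3[2, 2] <- 1
  rgb3 <- render_map(slope_map(s3, matrix(TRUE, 3, 3), 5L), 0.5)
  expect_equal(rgb3[2, 2, 1], 1)
  expect_equal(sum(rgb3[, , 3]), 8)
})

test_that("border_mask and dilate_mask behave geometrically", {
  b <- border_mask(c(10, 12), 2)
  expect_equal(sum(!b), 6 * 8)
  expect_false(any(border_mask(c(5, 5), 0)))
  m <- matrix(FALSE, 7, 7); m[4, 4] <- TRUE
  d <- dilate_mask(m, 2)
  expect_equal(sum(d), 13)                 # city-block ball of radius 2
})
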