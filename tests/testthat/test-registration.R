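test_that("LOG kernel is zero-sum and the filter behaves as convolution", {
  k <- log_kernel(8L, 1.4)
  expect_equal(dim(k), c(8L, 8L))
  expect_lt(abs(sum(k)), 1e-12)
  # constant image -> identically zero response
  expect_equal(log_filter(matrix(5, 32, 32)), matrix(0, 32, 32))
  # unit impulse reproduces the (symmetric) kernel
  img <- matrix(0, 64, 64)
  img[33, 33] <- 1
  out <- log_filter(img)
  cen <- floor(8 / 2) + 1L
  off <- seq_len(8) - cen
  block <- out[33 - off, 33 - off]
  expect_equal(block, k, tolerance = 1e-12)
  # image smaller than kernel
  expect_error(log_filter(matrix(1, 4, 4), size = 8), "smaller")
  expect_error(log_kernel(2), "size")
})

test_that("estimate_shift is exact for circular integer shifts", {
  A <- band_limited_image(48, cutoff = 0.4, seed = 2)
  s0 <- estimate_shift(A, A)
  expect_equal(c(s0$d_row, s0$d_col), c(0, 0))
  expect_equal(s0$peak_corr, 1, tolerance = 1e-6)
  set.seed(5)
  for (i in 1:8) {                         # equivariance property
    s <- c(sample(-23:23, 1), sample(-23:23, 1))
    est <- estimate_shift(A, roll2(A, s))
    expect_equal(c(est$d_row, est$d_col), s)
  }
  expect_error(estimate_shift(matrix(1, 8, 8), matrix(1, 8, 8)),
               "zero-variance")
})

test_that("estimate_shift resolves constructed sub-pixel shifts", {
  A <- band_limited_image(64, cutoff = 0.3, seed = 7)
  B <- apply_shift(A, -c(2.25, -1.75))     # Fourier phase-ramp oracle
  est <- estimate_shift(A, B, upsample = 100)
  expect_equal(est$d_row, 2.25, tolerance = 0.01)
  expect_equal(est$d_col, -1.75, tolerance = 0.01)
  # upsample = 1 falls back to integer resolution
  est1 <- estimate_shift(A, B, upsample = 1)
  expect_equal(c(est1$d_row, est1$d_col), c(2, -2))
})

test_that("apply_shift matches circular rolls and inverts exactly", {
  A <- band_limited_image(40, cutoff = 0.2, seed = 3)
  expect_identical(apply_shift(A, c(0, 0)), A)
  # integer shift equals circular roll (roll oracle)
  expect_equal(apply_shift(roll2(A, c(4, -6)), c(4, -6)), A,
               tolerance = 1e-10)
  # inverse composition on band-limited content
  rt <- apply_shift(apply_shift(A, c(1.3, -0.7)), c(-1.3, 0.7))
  expect_lt(sqrt(mean((rt - A)^2)), 1e-8)
})

test_that("select_reference maximizes correlation with the mean image", {
  base <- band_limited_image(24, cutoff = 0.3, seed = 8) + 10
  mk <- function(imgs) fa_sequence(lapply(seq_along(imgs), function(i)
    fa_frame(pmax(imgs[[i]], 0), t = i - 1)))
  # identical frames: tie broken at the first index
  expect_equal(select_reference(mk(rep(list(base), 4))), 1L)
  # one frame equal to the mean of the others, others noisy
  set.seed(1)
  noisy <- lapply(1:4, function(i) base + matrix(rnorm(576, sd = 3), 24))
  mean_img <- Reduce(`+`, noisy) / 4
  s <- mk(c(noisy[1:2], list(mean_img), noisy[3:4]))
  expect_equal(select_reference(s), 3L)
  # a pure-noise frame is never selected
  set.seed(2)
  with_noise <- mk(c(rep(list(base), 3),
                     list(matrix(runif(576, 9, 11), 24))))
  expect_lt(select_reference(with_noise), 4L)
})

test_that("register_sequence recovers injected drift on a phantom", {
  ph <- small_phantom(seed = 3)
  seq <- flag_noisy_frames(ph$sequence, 0.5)
  reg <- register_sequence(seq)
  ok <- which(vapply(seq$frames, function(f) f$quality == "ok", logical(1)))
  ts <- ph$truth$true_shifts
  ref <- reg$reference_index
  expect_equal(c(reg$shifts[[ref]]$d_row, reg$shifts[[ref]]$d_col), c(0, 0))
  err <- t(vapply(ok, function(i) c(
    reg$shifts[[i]]$d_row - (ts[[i]]$d_row - ts[[ref]]$d_row),
    reg$shifts[[i]]$d_col - (ts[[i]]$d_col - ts[[ref]]$d_col)), numeric(2)))
  expect_lt(quantile(abs(err), 0.95), 0.1)
  # frame count, times and quality flags preserved
  expect_equal(frame_times(reg$registered), frame_times(seq))
  expect_equal(vapply(reg$registered$frames, `[[`, character(1), "quality"),
               vapply(seq$frames, `[[`, character(1), "quality"))
  # excluded frames keep zero shift
  for (i in setdiff(seq_along(seq$frames), ok))
    expect_equal(c(reg$shifts[[i]]$d_row, reg$shifts[[i]]$d_col), c(0, 0))
  # post-hoc residual: registered frames show near-zero pairwise shifts
  mid <- ok[round(length(ok) / 2)]
  resid <- estimate_shift(
    log_filter(reg$registered$frames[[ref]]$pixels) *
      hann_window(seq$pixel_dims),
    log_filter(reg$registered$frames[[mid]]$pixels) *
      hann_window(seq$pixel_dims), band_sigma = 0.15)
  expect_lt(max(abs(c(resid$d_row, resid$d_col))), 0.1)
})

test_that("register_sequence with zero motion stays near zero shift", {
  # noiseless, motionless: any non-zero estimate reflects only the dye
  # kinetics changing the scene between frames
  ph <- small_phantom(seed = 4, motion_sd = 0, noise_sd = 0)
  seq <- flag_noisy_frames(ph$sequence, 0.5)
  reg <- register_sequence(seq)
  d <- vapply(reg$shifts, function(s) max(abs(c(s$d_row, s$d_col))),
              numeric(1))
  expect_lt(max(d), 0.05)
})
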