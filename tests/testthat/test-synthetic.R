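test_that("gamma_variate has the stated support, peak and decay", {
  expect_equal(gamma_variate(10, t0 = 10, alpha = 3, beta = 6,
                             amplitude = 150), 0)
  expect_equal(gamma_variate(5, 10, 3, 6, 150), 0)
  # peak at t0 + alpha*beta with value amplitude
  expect_equal(gamma_variate(10 + 18, 10, 3, 6, 150), 150)
  # monotone decreasing after the peak (dense grid scan)
  tt <- seq(28.01, 400, by = 0.25)
  v <- gamma_variate(tt, 10, 3, 6, 150)
  expect_true(all(diff(v) < 0))
  expect_error(gamma_variate(1, 0, -1, 2, 1), "alpha")
})

test_that("the two-phase protocol yields the stated frame times", {
  spec <- phantom_spec(seed = 1)
  tt <- phantom_times(spec)
  expect_length(tt, 73)                    # 30 early + 43 late frames
  expect_equal(sum(tt < 90), 30)
  expect_equal(diff(tt)[1:29], rep(3, 29))      # 20/min -> every 3 s
  expect_equal(diff(tt)[31:72], rep(12, 42))    # 5/min -> every 12 s
  expect_equal(tt[31], 90)                      # phase switch
  expect_equal(tt[1], 0)
  # protocol arithmetic for other rates
  spec2 <- phantom_spec(phase1_rate = 30, phase2_rate = 6,
                        duration_s = 300, phase1_end_s = 60, seed = 1)
  tt2 <- phantom_times(spec2)
  expect_equal(sum(tt2 < 60), 30)
  expect_equal(sum(tt2 >= 60), 24)
})

test_that("generate_phantom is seed-deterministic and validates input", {
  p1 <- small_phantom(seed = 12)
  p2 <- small_phantom(seed = 12)
  expect_identical(p1$sequence$frames[[10]]$pixels,
                   p2$sequence$frames[[10]]$pixels)
  expect_identical(vapply(p1$truth$true_shifts, `[[`, numeric(1), "d_row"),
                   vapply(p2$truth$true_shifts, `[[`, numeric(1), "d_row"))
  p3 <- small_phantom(seed = 13)
  expect_false(identical(p1$sequence$frames[[10]]$pixels,
                         p3$sequence$frames[[10]]$pixels))
  expect_error(phantom_spec(), "seed")
  expect_error(phantom_spec(seed = 1, leak_regions = list(
    list(mask = matrix(TRUE, 2, 2), k = 1e-3))), "dimensions")
  expect_error(phantom_spec(seed = 1, phase1_end_s = 700), "phase1_end_s")
})

test_that("phantom truth geometry is consistent", {
  ph <- small_phantom(seed = 14)
  tr <- ph$truth
  expect_true(any(tr$artery_mask$mask))
  expect_false(any(tr$artery_mask$mask & tr$disc_mask$mask))
  expect_equal(dim(tr$leak_map), c(64L, 64L))
  # healthy phantom: no leak outside the (dilated) disc
  expect_true(all(tr$leak_map[!tr$disc_mask$mask] == 0))
  # eye lateralization places the disc accordingly
  right <- small_phantom(seed = 15, eye = "right")
  left <- small_phantom(seed = 15, eye = "left")
  expect_gt(right$truth$disc_center[2], 32)
  expect_lt(left$truth$disc_center[2], 32)
  # masks re-rendered at a shift stay consistent with the originals
  mk <- phantom_masks_at(tr, c(0, 0))
  expect_equal(mk$artery_mask$mask, tr$artery_mask$mask)
  mk2 <- phantom_masks_at(tr, c(3, -2))
  expect_equal(sum(mk2$disc_mask$mask), sum(tr$disc_mask$mask),
               tolerance = 0.05)
})

test_that("generate_cohort derives deterministic per-subject phantoms", {
  spec <- phantom_spec(dims = c(48L, 48L), duration_s = 240, seed = 1)
  co <- generate_cohort(spec, n_healthy = 2, n_patient = 3, seed = 9)
  expect_length(co, 5)
  expect_equal(vapply(co, `[[`, character(1), "group"),
               c("healthy", "healthy", rep("patient", 3)))
  # healthy truths carry no extra-disc leak; patients do
  for (s in co[1:2])
    expect_true(all(s$truth$leak_map[!s$truth$disc_mask$mask] == 0))
  for (s in co[3:5])
    expect_gt(sum(s$truth$leak_map[!s$truth$disc_mask$mask]), 0)
  # identical master seed -> identical cohort
  co2 <- generate_cohort(spec, n_healthy = 2, n_patient = 3, seed = 9)
  expect_identical(co[[4]]$sequence$frames[[5]]$pixels,
                   co2[[4]]$sequence$frames[[5]]$pixels)
  # n_patient = 0 -> no leak regions anywhere
  coh <- generate_cohort(spec, n_healthy = 2, n_patient = 0, seed = 3)
  for (s in coh)
    expect_true(all(s$truth$leak_map[!s$truth$disc_mask$mask] == 0))
  expect_error(generate_cohort(spec, 2, 2), "seed")
})
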