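# explicit-summation oracle for Fleiss' kappa (2 categories)
fleiss_oracle <- function(tab) {
  n <- nrow(tab); m <- ncol(tab)
  P <- numeric(n)
  for (i in seq_len(n)) {
    x1 <- sum(tab[i, ] == 1); x0 <- m - x1
    P[i] <- (x1 * (x1 - 1) + x0 * (x0 - 1)) / (m * (m - 1))
  }
  p1 <- sum(tab) / (n * m)
  Pe <- p1^2 + (1 - p1)^2
  (mean(P) - Pe) / (1 - Pe)
}

test_that("fleiss_kappa matches its defining formula and edge cases", {
  # unanimous but mixed categories -> kappa = 1
  tab <- matrix(rep(c(1, 0, 1, 1, 0, 0, 1, 0, 1, 0), each = 3),
                ncol = 3, byrow = TRUE)
  expect_equal(fleiss_kappa(tab), 1)
  # random 4x3 tables match explicit summation
  set.seed(41)
  for (rep in 1:25) {
    tab <- matrix(rbinom(12, 1, runif(1, 0.2, 0.8)), 4, 3)
    k <- fleiss_kappa(tab)
    if (is.na(k)) { expect_true(attr(k, "degenerate")); next }
    expect_equal(as.numeric(k), fleiss_oracle(tab), tolerance = 1e-12)
  }
  # category relabeling and subject permutation invariance
  set.seed(42)
  tab <- matrix(rbinom(30, 1, 0.4), 10, 3)
  expect_equal(fleiss_kappa(1 - tab), fleiss_kappa(tab))
  expect_equal(fleiss_kappa(tab[sample(10), ]), fleiss_kappa(tab))
  # degenerate: one category only
  deg <- fleiss_kappa(matrix(1, 5, 3))
  expect_true(is.na(deg))
  expect_true(attr(deg, "degenerate"))
})

test_that("independent ratings give kappa near zero (chance simulation)", {
  set.seed(43)
  tab <- matrix(rbinom(30000, 1, 0.5), 10000, 3)
  expect_lt(abs(fleiss_kappa(tab)), 0.02)
})

test_that("bootstrap_kappa_diff is paired, seeded and centered", {
  set.seed(44)
  a <- matrix(rbinom(60, 1, 0.5), 20, 3)
  r1 <- bootstrap_kappa_diff(a, a, n_boot = 1000L, seed = 7)
  expect_equal(r1$diff, 0)
  expect_lte(r1$ci_low, 0)
  expect_gte(r1$ci_high, 0)
  expect_equal(c(r1$ci_low, r1$ci_high), c(0, 0))  # identical tables: all 0
  # fixed seed -> bit-identical on rerun; different seed differs
  b <- a; b[1:4, 1] <- 1 - b[1:4, 1]
  r2 <- bootstrap_kappa_diff(a, b, n_boot = 1000L, seed = 7)
  r3 <- bootstrap_kappa_diff(a, b, n_boot = 1000L, seed = 7)
  expect_identical(r2, r3)
  expect_error(bootstrap_kappa_diff(a, b, n_boot = 1000L), "seed")
})

test_that("bootstrap CI covers a zero kappa difference at ~95%", {
  # scaled-down coverage check: 150 simulated paired cohorts, 1000
  # replicates each; both modalities share the generative law, so the
  # true difference is 0
  set.seed(45)
  hits <- 0; total <- 150
  for (i in seq_len(total)) {
    prev <- rbinom(25, 1, 0.5)
    gen <- function() {
      t(vapply(prev, function(p)
        rbinom(3, 1, 0.15 + 0.7 * p), numeric(3)))
    }
    r <- suppressWarnings(
      bootstrap_kappa_diff(gen(), gen(), n_boot = 1000L, seed = i))
    if (r$ci_low <= 0 && r$ci_high >= 0) hits <- hits + 1
  }
  expect_gt(hits / total, 0.88)
})

test_that("sens_spec averages per-rater confusion rates", {
  gold <- c(1, 1, 0, 0)
  one <- matrix(c(1, 0, 0, 0), 4, 1)
  r <- sens_spec(one, gold)
  expect_equal(r$sensitivity, 0.5)
  expect_equal(r$specificity, 1.0)
  # every rater equals gold
  perfect <- cbind(gold, gold, gold)
  expect_equal(sens_spec(perfect, gold)$sensitivity, 1)
  expect_equal(sens_spec(perfect, gold)$specificity, 1)
  # two raters with sensitivities 1.0 and 0.5 average to 0.75
  two <- cbind(c(1, 1, 0, 0), c(1, 0, 0, 0))
  r2 <- sens_spec(two, gold)
  expect_equal(r2$sensitivity, 0.75)
  expect_true(all(r2$sensitivity >= min(r2$per_rater_sensitivity) &
                  r2$sensitivity <= max(r2$per_rater_sensitivity)))
  # undefined sensitivity when gold has no positives
  expect_true(is.na(sens_spec(two, c(0, 0, 0, 0))$sensitivity))
})

test_that("consensus_score requires unanimity per square", {
  g <- rep(list(c(1, 0, 1, 0, 1, 0, 1, 0, 1)), 3)
  r <- consensus_score(g)
  expect_equal(r$square_scores, rep(1, 9))
  expect_equal(r$eye_score, 1)
  # disagreement in exactly one square -> median still 1
  g2 <- g; g2[[2]][5] <- 1 - g2[[2]][5]
  r2 <- consensus_score(g2)
  expect_equal(sum(r2$square_scores), 8)
  expect_equal(r2$eye_score, 1)
  # disagreement in 5 of 9 squares -> median 0
  g3 <- g; g3[[3]][1:5] <- 1 - g3[[3]][1:5]
  expect_equal(consensus_score(g3)$eye_score, 0)
  # symmetric in raters
  expect_equal(consensus_score(rev(g3)), consensus_score(g3))
  expect_error(consensus_score(list(c(1, 0, 1), c(1, 0, 1), c(1, 0, 1))),
               "9 binary squares")
})

test_that("exact one-tailed McNemar equals binomial enumeration", {
  expect_equal(mcnemar_one_tailed(b_count = 5, c_count = 0), 0.03125)
  expect_equal(mcnemar_one_tailed(b_count = 3, c_count = 3), 0.65625)
  expect_equal(mcnemar_one_tailed(b_count = 0, c_count = 0), 1.0)
  # brute-force enumeration oracle for all n <= 25
  for (n in 1:25) for (b in 0:n) {
    brute <- sum(choose(n, b:n)) / 2^n
    expect_equal(mcnemar_one_tailed(b_count = b, c_count = n - b), brute,
                 tolerance = 1e-12)
  }
  # vector interface counts discordant pairs
  a <- c(0, 0, 1, 1, 0, 1, 0)
  b <- c(1, 1, 1, 0, 1, 1, 1)
  expect_equal(mcnemar_one_tailed(a, b),
               mcnemar_one_tailed(b_count = 4, c_count = 1))
  # chi-squared variant is a probability and one-tailed
  p <- mcnemar_one_tailed(b_count = 15, c_count = 5, method = "chisq")
  expect_gt(p, 0); expect_lt(p, 0.05)
})

test_that("rating tables build from grid CSVs", {
  df <- grids_df(eye_ids = c("e1", "e2"), raters = c("r1", "r2", "r3"),
                 square_fun = function(e, r) rep(1, 9),
                 overall_fun = function(e, r) as.integer(e == "e1"))
  dir <- withr::local_tempdir()
  p <- file.path(dir, "grids.csv")
  write.csv(df, p, row.names = FALSE)
  back <- read_rater_grids(p)
  tab <- rating_table(back)
  expect_equal(dim(tab), c(2L, 3L))
  expect_equal(unname(tab["e1", ]), c(1L, 1L, 1L))
  expect_equal(unname(tab["e2", ]), c(0L, 0L, 0L))
  # missing cells are an error
  expect_error(rating_table(back[-1, ]), "missing cells")
  # malformed CSV
  df_bad <- df; df_bad$sq_4[1] <- 2
  write.csv(df_bad, p, row.names = FALSE)
  expect_error(read_rater_grids(p), "binary")
})

test_that("evaluate_raters composes the statistics", {
  set.seed(46)
  gold_v <- c(rep(1, 6), rep(0, 4))
  eyes <- sprintf("e%02d", 1:10)
  g_fa <- grids_df(eyes, c("a", "b", "c"),
                   function(e, r) rbinom(9, 1, 0.5),
                   function(e, r) gold_v[match(e, eyes)])
  res <- evaluate_raters(g_fa, g_fa, setNames(gold_v, eyes),
                         n_boot = 1000L, seed = 2)
  expect_equal(res$kappa_diff, 0)
  expect_equal(res$sensitivity, 1)
  expect_equal(res$specificity, 1)
  expect_equal(res$kappa_map_band, "almost perfect")
  expect_equal(res$mcnemar_p, 1.0)         # identical consensus
})
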