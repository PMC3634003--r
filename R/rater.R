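# Inter-rater agreement and diagnostic-accuracy statistics used to
# validate permeability maps against conventional angiogram reading:
# Fleiss' kappa, bootstrap comparison of correlated kappas, averaged
# sensitivity/specificity, 3x3-grid consensus scoring, and the exact
# one-tailed McNemar test.

#' Fleiss' kappa for multiple raters, two categories
#'
#' \eqn{\kappa = (\bar P - \bar P_e) / (1 - \bar P_e)} with the usual
#' per-subject observed agreement \eqn{\bar P} and chance agreement
#' \eqn{\bar P_e} from the marginal category proportions.  Invariant to
#' relabeling of the two categories and to subject permutation.
#'
#' @param ratings subjects x raters binary matrix (1 = pathologic).
#' @return kappa value; `NA` with attribute `degenerate = TRUE` when every
#'   rating falls in a single category (\eqn{\bar P_e = 1}, kappa
#'   undefined).
#' @export
fleiss_kappa <- function(ratings) {
  ratings <- as.matrix(ratings)
  stopifnot(nrow(ratings) >= 2L, ncol(ratings) >= 2L,
            all(ratings %in% c(0, 1)))
  n <- nrow(ratings); m <- ncol(ratings)
  x <- rowSums(ratings)                       # raters saying 1, per subject
  P_i <- (x * (x - 1) + (m - x) * (m - x - 1)) / (m * (m - 1))
  P_bar <- mean(P_i)
  p1 <- sum(x) / (n * m)
  P_e <- p1^2 + (1 - p1)^2
  if (1 - P_e < .Machine$double.eps)
    return(structure(NA_real_, degenerate = TRUE))
  (P_bar - P_e) / (1 - P_e)
}

#' Landis & Koch qualitative band for a kappa value
#'
#' @param kappa numeric kappa.
#' @return label such as `"substantial"` or `"almost perfect"`.
#' @export
kappa_band <- function(kappa) {
  if (is.na(kappa)) return(NA_character_)
  cuts <- c(-Inf, 0, 0.2, 0.4, 0.6, 0.8, Inf)
  labs <- c("poor", "slight", "fair", "moderate", "substantial",
            "almost perfect")
  labs[findInterval(kappa, cuts, left.open = TRUE)]
}

#' Bootstrap comparison of two correlated Fleiss' kappas
#'
#' The two rating tables are paired by subject (same eyes rated under two
#' modalities, e.g. raw angiograms vs computed maps).  Subjects are
#' resampled with replacement jointly across the two tables, preserving the
#' pairing; the kappa difference is recomputed per replicate and a
#' percentile 95% confidence interval is returned.  Replicates where either
#' kappa is degenerate are dropped; if more than 10% are, a warning is
#' recorded in the result.
#'
#' @param table_a,table_b subjects x raters binary matrices with matching
#'   rows (subjects).
#' @param n_boot number of bootstrap replicates (default 10000).
#' @param seed integer seed; identical seeds give bit-identical intervals.
#' @param conf confidence level (default 0.95).
#' @return list with `diff` (kappa_a - kappa_b observed), `ci_low`,
#'   `ci_high`, `n_used`, `n_dropped`, `warning`.
#' @export
bootstrap_kappa_diff <- function(table_a, table_b, n_boot = 10000L, seed,
                                 conf = 0.95) {
  table_a <- as.matrix(table_a); table_b <- as.matrix(table_b)
  stopifnot(nrow(table_a) == nrow(table_b), n_boot >= 1000L)
  if (missing(seed)) stop("a seed is required for reproducibility")
  n <- nrow(table_a)
  obs <- fleiss_kappa(table_a) - fleiss_kappa(table_b)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  reps <- vapply(seq_len(n_boot), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    fleiss_kappa(table_a[idx, , drop = FALSE]) -
      fleiss_kappa(table_b[idx, , drop = FALSE])
  }, numeric(1))
  dropped <- sum(is.na(reps))
  reps <- reps[!is.na(reps)]
  warn <- if (dropped > 0.1 * n_boot)
    sprintf("degenerate kappa in %d of %d replicates", dropped, n_boot)
  else NULL
  if (!is.null(warn)) warning(warn)
  alpha <- (1 - conf) / 2
  ci <- stats::quantile(reps, c(alpha, 1 - alpha), names = FALSE, type = 7)
  list(diff = obs, ci_low = ci[1], ci_high = ci[2],
       n_used = length(reps), n_dropped = dropped, warning = warn)
}

#' Sensitivity and specificity averaged over raters
#'
#' Per rater, sensitivity = TP/(TP+FN) and specificity = TN/(TN+FP)
#' against the gold-standard diagnosis; the unweighted mean over raters is
#' returned.
#'
#' @param ratings subjects x raters binary matrix.
#' @param gold binary vector over subjects (1 = pathologic).
#' @return list with `sensitivity`, `specificity` (either `NA` when
#'   undefined, i.e. gold has no positives / no negatives) and the
#'   per-rater vectors.
#' @export
sens_spec <- function(ratings, gold) {
  ratings <- as.matrix(ratings)
  stopifnot(nrow(ratings) == length(gold), all(gold %in% c(0, 1)))
  pos <- gold == 1; neg <- !pos
  sens <- if (any(pos)) colMeans(ratings[pos, , drop = FALSE] == 1)
          else rep(NA_real_, ncol(ratings))
  spec <- if (any(neg)) colMeans(ratings[neg, , drop = FALSE] == 0)
          else rep(NA_real_, ncol(ratings))
  list(sensitivity = mean(sens), specificity = mean(spec),
       per_rater_sensitivity = sens, per_rater_specificity = spec)
}

#' Consensus score of one eye's 3x3 grid across three raters
#'
#' Each grid square scores 1 when all raters make the same call for that
#' square (whether "leak" or "no leak"), 0 on any inconsistency; the eye
#' score is the median of the nine square scores.  With nine (odd)
#' squares the median is always 0 or 1; the 0.5 midpoint can only arise if
#' squares were missing, which is an error by default.
#'
#' @param grids list of per-rater grids: each a length-9 binary vector or
#'   3x3 matrix (1 = permeability change present).
#' @return list with `square_scores` (length 9) and `eye_score`.
#' @export
consensus_score <- function(grids) {
  stopifnot(length(grids) >= 2L)
  g <- vapply(grids, function(x) {
    v <- as.vector(as.matrix(x))
    if (length(v) != 9L || anyNA(v) || !all(v %in% c(0, 1)))
      stop("each rater grid must be 9 binary squares with no missing calls")
    v
  }, numeric(9))
  sq <- as.numeric(apply(g, 1L, function(row) all(row == row[1])))
  list(square_scores = sq, eye_score = stats::median(sq))
}

#' Exact one-tailed McNemar test on paired binary outcomes
#'
#' Tests whether outcome B improves on outcome A using only the discordant
#' pairs: with `b` pairs improving under B and `c` worsening, the exact
#' one-tailed p-value is \eqn{P(X \ge b)} for \eqn{X \sim
#' Binomial(b + c, 1/2)}.  With the few discordant pairs typical of small
#' reader studies the exact form is preferred; the continuity-corrected
#' chi-squared approximation is available as an option.
#'
#' @param a,b binary vectors of paired outcomes (same subjects), or pass
#'   `b_count`/`c_count` directly.
#' @param b_count,c_count discordant-pair counts: improving (0 under A, 1
#'   under B) and worsening.
#' @param method `"exact"` (default) or `"chisq"` (continuity-corrected).
#' @return one-tailed p-value; 1.0 when there are no discordant pairs.
#' @export
mcnemar_one_tailed <- function(a = NULL, b = NULL,
                               b_count = NULL, c_count = NULL,
                               method = c("exact", "chisq")) {
  method <- match.arg(method)
  if (is.null(b_count)) {
    stopifnot(length(a) == length(b), all(a %in% c(0, 1)), all(b %in% c(0, 1)))
    b_count <- sum(a == 0 & b == 1)
    c_count <- sum(a == 1 & b == 0)
  }
  n <- b_count + c_count
  if (n == 0L) return(1.0)
  if (method == "exact")
    stats::pbinom(b_count - 1L, n, 0.5, lower.tail = FALSE)
  else {
    stat <- (abs(b_count - c_count) - 1)^2 / n
    stats::pchisq(stat, df = 1, lower.tail = FALSE) / 2
  }
}

#' Read per-rater 3x3 grid evaluations from CSV
#'
#' Expected columns: `rater_id, eye_id, sq_1..sq_9, overall`.
#'
#' @param path CSV file path.
#' @return data.frame with those columns, squares and overall as integers.
#' @export
read_rater_grids <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("rater_id", "eye_id", paste0("sq_", 1:9), "overall")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("grids CSV missing columns: ",
                         paste(miss, collapse = ", "))
  for (cn in c(paste0("sq_", 1:9), "overall")) {
    if (!all(df[[cn]] %in% c(0, 1)))
      stop("column ", cn, " must be binary 0/1")
    df[[cn]] <- as.integer(df[[cn]])
  }
  df
}

#' Build a subjects x raters rating table from a grids data.frame
#'
#' @param grids data.frame as returned by [read_rater_grids()].
#' @return binary matrix with eye_ids as rownames and rater_ids as
#'   colnames, filled from the `overall` column.
#' @export
rating_table <- function(grids) {
  eyes <- sort(unique(grids$eye_id))
  raters <- sort(unique(grids$rater_id))
  m <- matrix(NA_integer_, length(eyes), length(raters),
              dimnames = list(as.character(eyes), as.character(raters)))
  for (i in seq_len(nrow(grids)))
    m[as.character(grids$eye_id[i]), as.character(grids$rater_id[i])] <-
      grids$overall[i]
  if (anyNA(m)) stop("rating table has missing cells")
  m
}
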