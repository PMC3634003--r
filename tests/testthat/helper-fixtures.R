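# shared fixtures: built in code at test time, no binary files

# circular roll of a matrix by integer (row, col)
roll2 <- function(x, s) {
  n <- nrow(x); m <- ncol(x)
  x[((seq_len(n) - 1 - s[1]) %% n) + 1, ((seq_len(m) - 1 - s[2]) %% m) + 1]
}

# band-limited random image: spectrum confined below a fraction of Nyquist,
# so Fourier translation is exact and invertible
band_limited_image <- function(n = 64, cutoff = 0.2, seed = 1) {
  set.seed(seed)
  f <- c(0:(ceiling(n / 2) - 1), -(floor(n / 2)):-1) / n
  keep <- outer(abs(f) < cutoff, abs(f) < cutoff, "&")
  spec <- matrix(complex(real = rnorm(n * n), imaginary = rnorm(n * n)), n)
  spec[!keep] <- 0
  img <- Re(fft(spec, inverse = TRUE)) / (n * n)
  img / sd(img)
}

# tiny fast phantom for unit tests (64 px, short series)
small_phantom <- function(seed = 3, ...) {
  generate_phantom(phantom_spec(dims = c(64L, 64L), duration_s = 300,
                                seed = seed, ...))
}

# a synthetic slope map from a vector of values (square-ish grid)
slope_map_from_values <- function(v) {
  n <- ceiling(sqrt(length(v)))
  pad <- n * n - length(v)
  m <- matrix(c(v, rep(NA_real_, pad)), n, n)
  slope_map(m, is.finite(m), n_points = 10L)
}

# minimal rater-grid data.frame builder
grids_df <- function(eye_ids, raters, square_fun, overall_fun) {
  rows <- list()
  for (e in eye_ids) for (r in raters) {
    sq <- square_fun(e, r)
    rows[[length(rows) + 1L]] <- data.frame(
      rater_id = r, eye_id = e,
      t(setNames(as.integer(sq), paste0("sq_", 1:9))),
      overall = as.integer(overall_fun(e, r)))
  }
  do.call(rbind, rows)
}
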