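# Sub-pixel registration of the FA sequence.
#
# Shift estimation runs on edge-enhanced (Laplacian-of-Gaussian filtered)
# copies of the frames; the estimated translations are applied to the
# original frames, so registered pixel intensities derive solely from the
# raw data.  Sub-pixel refinement uses the upsampled cross-correlation
# approach: the inverse DFT of the cross-power spectrum is evaluated on a
# fine grid (1/upsample px) in a 1.5 px neighborhood of the coarse peak by
# direct matrix-multiply DFTs, avoiding any large zero-padded transform.

# signed DFT frequency indices 0,1,...,-2,-1 for length n
fft_freq_idx <- function(n) c(0:(ceiling(n / 2) - 1L), -(floor(n / 2)):-1L)

#' Laplacian-of-Gaussian convolution kernel
#'
#' Sampled on a `size` x `size` grid centered between pixels for even
#' sizes (offsets -(size-1)/2 .. (size-1)/2), Gaussian-normalized, and
#' mean-subtracted so the kernel sums to exactly zero (a constant image
#' yields an identically zero response).
#'
#' @param size kernel support in pixels (default 8).
#' @param sigma Gaussian standard deviation in pixels (default 1.4).
#' @return `size` x `size` numeric matrix summing to 0.
#' @export
log_kernel <- function(size = 8L, sigma = 1.4) {
  stopifnot(size >= 3L, sigma > 0)
  x <- seq_len(size) - (size + 1) / 2
  g <- exp(-outer(x^2, x^2, "+") / (2 * sigma^2))
  h <- (outer(x^2, x^2, "+") - 2 * sigma^2) / sigma^4 * g / sum(g)
  h - mean(h)
}

#' Edge-enhance an image with a Laplacian-of-Gaussian filter
#'
#' 2D correlation with [log_kernel()] under symmetric (reflect) boundary
#' padding; output has the same dimensions as the input.
#'
#' @param image numeric matrix.
#' @param size,sigma kernel parameters, defaults 8 and 1.4.
#' @return filtered matrix.
#' @export
log_filter <- function(image, size = 8L, sigma = 1.4) {
  if (nrow(image) < size || ncol(image) < size)
    stop("image (", nrow(image), "x", ncol(image),
         ") smaller than filter kernel (", size, "x", size, ")")
  k <- log_kernel(size, sigma)
  cen <- floor(size / 2) + 1L
  off <- seq_len(size) - cen
  pad <- max(abs(off))
  nr <- nrow(image); nc <- ncol(image)
  ridx <- c(pad:1, 1:nr, nr:(nr - pad + 1L))
  cidx <- c(pad:1, 1:nc, nc:(nc - pad + 1L))
  P <- image[ridx, cidx]
  out <- matrix(0, nr, nc)
  for (u in seq_len(size)) for (v in seq_len(size)) {
    if (k[u, v] == 0) next
    out <- out + k[u, v] *
      P[(pad + 1L + off[u]):(pad + nr + off[u]),
        (pad + 1L + off[v]):(pad + nc + off[v])]
  }
  out
}

#' Estimate the translation between two images by phase correlation
#'
#' Returns the (row, col) shift `s` such that `moving` is (circularly) the
#' reference translated by `+s`; equivalently [apply_shift]`(moving, s)`
#' re-aligns it with the reference.  The cross-power spectrum is whitened
#' to unit modulus (classic phase correlation; robust to the global and
#' structure-wise intensity changes of an angiographic series) and
#' optionally weighted by a Gaussian low-pass in frequency, which
#' suppresses noise-dominated high-frequency phase.  The coarse peak of
#' its inverse DFT is refined to 1/`upsample` pixel by an upsampled
#' matrix-multiply DFT restricted to a 1.5 px neighborhood.
#'
#' For an exact circular integer shift the estimate is exact; whitening
#' and band weighting do not move a phase-perfect peak.
#'
#' @param reference,moving equal-sized numeric matrices.
#' @param upsample sub-pixel refinement factor (>= 1, default 100: 0.01 px
#'   resolution).
#' @param whiten normalize the cross-power spectrum to unit modulus
#'   (default `TRUE`).
#' @param band_sigma standard deviation (cycles/pixel) of the Gaussian
#'   spectral weight; `NULL` disables (default 0.25).
#' @return a [shift_vector()]; `peak_corr` is the normalized (Pearson-like,
#'   mean-removed) cross-correlation of the two images at the optimum,
#'   evaluated on the unwhitened spectrum.
#' @export
estimate_shift <- function(reference, moving, upsample = 100L,
                           whiten = TRUE, band_sigma = 0.25) {
  stopifnot(identical(dim(reference), dim(moving)), upsample >= 1)
  a <- reference - mean(reference)
  b <- moving - mean(moving)
  if (sum(a^2) == 0 || sum(b^2) == 0)
    stop("zero-variance input: cannot estimate shift")
  nr <- nrow(a); nc <- ncol(a); N <- nr * nc
  R0 <- Conj(stats::fft(a)) * stats::fft(b)
  R <- if (whiten) R0 / pmax(Mod(R0), 1e-12) else R0
  if (!is.null(band_sigma)) {
    f2 <- outer((fft_freq_idx(nr) / nr)^2, (fft_freq_idx(nc) / nc)^2, "+")
    R <- R * exp(-f2 / (2 * band_sigma^2))
  }
  cc <- Re(stats::fft(R, inverse = TRUE)) / N
  pk <- arrayInd(which.max(cc), dim(cc)) - 1L
  s <- c(ifelse(pk[1] > nr / 2, pk[1] - nr, pk[1]),
         ifelse(pk[2] > nc / 2, pk[2] - nc, pk[2]))
  up_dft <- function(spec, rows_eval, cols_eval) {
    kr <- exp(2i * pi * outer(rows_eval, fft_freq_idx(nr) / nr))
    kc <- exp(2i * pi * outer(cols_eval, fft_freq_idx(nc) / nc))
    Re(kr %*% spec %*% t(kc)) / N
  }
  if (upsample > 1) {
    usfac <- as.numeric(upsample)
    nor <- ceiling(1.5 * usfac)
    half <- floor(nor / 2)
    rows_eval <- s[1] + (seq_len(nor) - 1L - half) / usfac
    cols_eval <- s[2] + (seq_len(nor) - 1L - half) / usfac
    ccu <- up_dft(R, rows_eval, cols_eval)
    pku <- arrayInd(which.max(ccu), dim(ccu))
    s <- c(rows_eval[pku[1]], cols_eval[pku[2]])
  }
  cc_pk <- up_dft(R0, s[1], s[2])[1, 1]
  pc <- cc_pk / sqrt(sum(a^2) * sum(b^2))
  shift_vector(s[1], s[2], peak_corr = min(max(pc, 0), 1))
}

#' Separable Hann window
#'
#' Used by [register_sequence()] to taper the filtered frames before
#' spectral shift estimation, suppressing boundary artifacts of the
#' reflect-padded edge filter.
#'
#' @param dims (rows, cols).
#' @return numeric matrix in \code{[0, 1]}.
#' @export
hann_window <- function(dims) {
  h <- function(n) 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))
  outer(h(dims[1]), h(dims[2]))
}

#' Translate an image by a sub-pixel shift (Fourier interpolation)
#'
#' Applies the translation `(-d_row, -d_col)`: content that had drifted by
#' `+s` is moved back, so `apply_shift(moving, estimate_shift(ref, moving))`
#' aligns `moving` with `ref`.  Implemented as a Fourier-domain phase ramp,
#' which exactly inverts the estimation model; for integer shifts it equals
#' a circular roll of the array.  Content wraps circularly at the borders;
#' downstream analysis masks a border margin out.
#'
#' @param image numeric matrix.
#' @param shift a [shift_vector()] or numeric `(d_row, d_col)`.
#' @return translated matrix (real part; imaginary residue discarded).
#' @export
apply_shift <- function(image, shift) {
  if (inherits(shift, "shift_vector")) shift <- c(shift$d_row, shift$d_col)
  stopifnot(all(is.finite(shift)))
  if (all(shift == 0)) return(image)
  nr <- nrow(image); nc <- ncol(image)
  # per-axis ramps; the unpaired Nyquist bin (even n) is realified so the
  # operator maps real images to real images without an asymmetric phase
  ramp1 <- function(n, d) {
    r <- exp(2i * pi * fft_freq_idx(n) * d / n)
    if (n %% 2 == 0) r[n / 2 + 1L] <- cos(pi * d)
    r
  }
  ramp <- outer(ramp1(nr, shift[1]), ramp1(nc, shift[2]))
  Re(stats::fft(stats::fft(image) * ramp, inverse = TRUE)) / (nr * nc)
}

#' Select the reference frame of a sequence
#'
#' The usable frame with maximal Pearson correlation to the pixel-wise
#' mean of all usable frames; ties break toward the lowest index.
#'
#' @param seq an [fa_sequence()].
#' @return 1-based frame index into `seq$frames`.
#' @export
select_reference <- function(seq) {
  ok <- which(usable_idx(seq))
  if (length(ok) < 2L) stop("need >= 2 usable frames")
  stack <- vapply(ok, function(i) as.vector(seq$frames[[i]]$pixels),
                  numeric(prod(seq$pixel_dims)))
  m <- rowMeans(stack)
  cors <- vapply(seq_len(ncol(stack)), function(j) {
    x <- stack[, j]
    if (stats::sd(x) == 0 || stats::sd(m) == 0) -Inf else stats::cor(x, m)
  }, numeric(1))
  ok[which.max(cors)]
}

#' Register an FA sequence to a common reference
#'
#' The reference frame is chosen by [select_reference()].  Usable frames
#' are then processed outward from the reference (ref-1, ref+1, ref-2,
#' ref+2, ...); each frame's translation is estimated by phase correlation
#' between the LOG-filtered copies of the frame and its inward usable
#' neighbor, and composed cumulatively along the chain.  Excluded frames
#' are bypassed by the chain (links skip to the nearest usable neighbor),
#' receive a zero shift and remain excluded.  The cumulative shifts are
#' applied to the original, unfiltered frames.
#'
#' @param seq an [fa_sequence()] with >= 2 usable frames.
#' @param upsample sub-pixel factor for [estimate_shift()] (default 100).
#' @param log_size,log_sigma parameters of the edge filter (defaults 8,
#'   1.4).
#' @param window taper the filtered frames with a Hann window before
#'   estimation (default `TRUE`; see [hann_window()]).
#' @param band_sigma spectral weight passed to [estimate_shift()]
#'   (default 0.15 cycles/px, a band that favors vessel- and texture-scale
#'   structure over sensor noise).
#' @param refine number of refinement passes (default 1): after the
#'   sequential chain, each registered frame is re-estimated against the
#'   average of all registered frames (the "registered averaged image"),
#'   correcting the slow drift that accumulates along the chain; shifts
#'   are re-anchored so the reference stays exactly at (0, 0).
#' @return list of class `registration_result` with `shifts` (per-frame
#'   [shift_vector()], cumulative, relative to the reference),
#'   `reference_index`, and `registered` (an `fa_sequence`).
#' @export
register_sequence <- function(seq, upsample = 100L,
                              log_size = 8L, log_sigma = 1.4,
                              window = TRUE, band_sigma = 0.15,
                              refine = 1L) {
  ok <- which(usable_idx(seq))
  if (length(ok) < 2L) stop("need >= 2 usable frames")
  ref <- select_reference(seq)
  W <- if (window) hann_window(seq$pixel_dims) else 1
  filt <- vector("list", length(seq$frames))
  for (i in ok) filt[[i]] <- log_filter(seq$frames[[i]]$pixels,
                                        log_size, log_sigma) * W
  n <- length(seq$frames)
  shifts <- replicate(n, shift_vector(0, 0, NA_real_), simplify = FALSE)
  shifts[[ref]]$peak_corr <- 1
  ref_pos <- match(ref, ok)
  # outward processing order over usable-frame positions
  lo <- rev(seq_len(ref_pos - 1L)); hi <- seq_len(length(ok) - ref_pos) + ref_pos
  order_pos <- c(rbind(c(lo, rep(NA, max(0, length(hi) - length(lo)))),
                       c(hi, rep(NA, max(0, length(lo) - length(hi))))))
  order_pos <- order_pos[!is.na(order_pos)]
  for (p in order_pos) {
    i <- ok[p]
    j <- ok[p + if (p < ref_pos) 1L else -1L]  # inward usable neighbor
    s <- tryCatch(estimate_shift(filt[[j]], filt[[i]], upsample,
                                 band_sigma = band_sigma),
                  error = function(e)
                    stop("shift estimation failed at frame ", i, ": ",
                         conditionMessage(e)))
    shifts[[i]] <- shift_vector(shifts[[j]]$d_row + s$d_row,
                                shifts[[j]]$d_col + s$d_col,
                                peak_corr = s$peak_corr)
  }
  for (pass in seq_len(refine)) {
    regs <- lapply(ok, function(i)
      apply_shift(seq$frames[[i]]$pixels, shifts[[i]]))
    avg <- Reduce(`+`, regs) / length(regs)
    favg <- log_filter(avg, log_size, log_sigma) * W
    for (idx in seq_along(ok)) {
      i <- ok[idx]
      e <- estimate_shift(favg, log_filter(regs[[idx]], log_size,
                                           log_sigma) * W,
                          upsample, band_sigma = band_sigma)
      shifts[[i]]$d_row <- shifts[[i]]$d_row + e$d_row
      shifts[[i]]$d_col <- shifts[[i]]$d_col + e$d_col
      shifts[[i]]$peak_corr <- e$peak_corr
    }
    # re-anchor the gauge: the reference frame stays exactly at (0, 0)
    r0 <- shifts[[ref]]$d_row; c0 <- shifts[[ref]]$d_col
    for (i in ok) {
      shifts[[i]]$d_row <- shifts[[i]]$d_row - r0
      shifts[[i]]$d_col <- shifts[[i]]$d_col - c0
    }
    shifts[[ref]]$peak_corr <- 1
  }
  registered <- seq
  for (i in ok)
    registered$frames[[i]]$pixels <-
      apply_shift(seq$frames[[i]]$pixels, shifts[[i]])
  structure(list(shifts = shifts, reference_index = ref,
                 registered = registered),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  d <- vapply(x$shifts, function(s) sqrt(s$d_row^2 + s$d_col^2), numeric(1))
  cat(sprintf("<registration_result> %d frames, reference %d, max |shift| %.2f px\n",
              length(x$shifts), x$reference_index, max(d)))
  invisible(x)
}
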