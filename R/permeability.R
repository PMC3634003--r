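# Arterial-input-function normalization and per-pixel slope fitting.
#
# Each pixel's intensity time course is divided by the mean intensity of
# the major arteries at the same time point (the arterial input function,
# AIF).  In AIF-normalized units, healthy tissue washes out (flat to
# negative late-phase trend) while leaky tissue accumulates dye (positive
# trend); an ordinary-least-squares slope over the late phase summarizes
# each pixel.

#' Compute the arterial input function of a registered sequence
#'
#' Per usable frame, the arithmetic mean of the pixels inside the artery
#' ROI.  The floor attached to the curve (used by [normalize_sequence()]
#' to drop pre-dye frames) defaults to `floor_frac` of the AIF maximum.
#'
#' @param seq a registered [fa_sequence()].
#' @param artery_roi an [roi_mask()] with role `"artery"` (non-empty).
#' @param floor_frac fraction of the AIF maximum below which frames are
#'   considered pre-dye (default 0.1).
#' @return object of class `aif_curve`: list with `t`, `value`, `floor`.
#' @export
compute_aif <- function(seq, artery_roi, floor_frac = 0.1) {
  m <- if (inherits(artery_roi, "roi_mask")) artery_roi$mask else artery_roi
  if (!any(m)) stop("artery ROI is empty")
  stopifnot(identical(dim(m), seq$pixel_dims))
  ok <- which(usable_idx(seq))
  val <- vapply(ok, function(i) mean(seq$frames[[i]]$pixels[m]), numeric(1))
  structure(list(t = frame_times(seq)[ok], value = val,
                 floor = floor_frac * max(val)),
            class = "aif_curve")
}

#' Normalize a sequence to its arterial input function
#'
#' Usable frames whose AIF value is below the floor (pre-dye and
#' transit-onset frames, where division is unstable) are dropped; each
#' retained frame is divided element-wise by its AIF value.  The result is
#' unitless, so the whole pipeline is invariant to the camera's intensity
#' scale.
#'
#' @param seq a registered [fa_sequence()].
#' @param aif the matching [compute_aif()] result.
#' @return object of class `normalized_sequence`: list with `stack`
#'   (rows x cols x n_retained array) and `t` (retained times, seconds).
#' @export
normalize_sequence <- function(seq, aif) {
  ok <- which(usable_idx(seq))
  stopifnot(length(ok) == length(aif$value))
  keep <- aif$value >= aif$floor
  if (!any(keep)) stop("no dye signal: all frames below the AIF floor")
  idx <- ok[keep]
  dims <- seq$pixel_dims
  stack <- array(NA_real_, c(dims[1], dims[2], length(idx)))
  for (j in seq_along(idx))
    stack[, , j] <- seq$frames[[idx[j]]]$pixels / aif$value[keep][j]
  structure(list(stack = stack, t = aif$t[keep]),
            class = "normalized_sequence")
}

#' Fit a per-pixel late-phase slope map
#'
#' Ordinary least squares of normalized intensity against time (seconds)
#' per pixel, restricted to retained time points with `t >= fit_start_s`.
#' The late phase starts after the early transit peak; the default 120 s
#' places it after the acquisition protocol drops to its slow frame rate.
#' Pixels clipped at the sensor ceiling in at least half of the fitted
#' frames are marked invalid (a slope under saturation is meaningless), as
#' are pixels with non-finite values.
#'
#' @param nseq a [normalize_sequence()] result.
#' @param fit_start_s start of the fit window in seconds (default 120).
#' @param min_points minimum number of fitted time points (default 4).
#' @param sensor_max optional sensor ceiling in camera units, mapped into
#'   normalized units internally is not possible, so pass it already in
#'   normalized units or `NULL` to skip saturation masking.
#' @return a [slope_map()]; slope units are normalized intensity per
#'   second.
#' @export
fit_slope_map <- function(nseq, fit_start_s = 120, min_points = 4L,
                          sensor_max = NULL) {
  sel <- which(nseq$t >= fit_start_s)
  if (length(sel) < min_points)
    stop("only ", length(sel), " time points at t >= ", fit_start_s,
         " s; need >= ", min_points)
  t <- nseq$t[sel]
  dims <- dim(nseq$stack)[1:2]
  Y <- matrix(nseq$stack[, , sel], nrow = prod(dims))  # pixels x time
  finite_n <- rowSums(is.finite(Y))
  valid <- finite_n == length(sel)
  w <- t - mean(t)
  slope <- as.vector(Y %*% w) / sum(w^2)
  if (!is.null(sensor_max)) {
    sat <- rowSums(Y >= sensor_max) >= length(sel) / 2
    valid <- valid & !sat
  }
  slope[!valid] <- NA_real_
  slope_map(matrix(slope, dims[1], dims[2]),
            matrix(valid, dims[1], dims[2]),
            n_points = length(sel))
}
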