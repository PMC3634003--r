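# Healthy-cohort calibration and permeability-map rendering.
#
# The pathological threshold is read off the mean cumulative histogram of
# slope values over a healthy cohort: per subject an empirical CDF is
# evaluated on a common grid, the subject CDFs are averaged unweighted
# (equalizing subjects with different pixel counts), and the threshold is
# the smallest slope whose mean CDF reaches the chosen percentile
# (default 99.5%).  The physiologically leaky optic disc and a border
# margin (registration wrap-around) are excluded throughout.

#' Mean cumulative histogram of slope values over a cohort
#'
#' @param slope_maps list of [slope_map()] objects (one per subject).
#' @param exclusion_masks optional list (same length) of logical matrices;
#'   `TRUE` pixels (optic disc, borders) are dropped from each map.  A
#'   single matrix is recycled to all subjects; `NULL` excludes nothing.
#' @param grid_size number of grid points spanning the pooled slope range
#'   (default 2048).
#' @return object of class `cumulative_histogram`: list with `grid`
#'   (ascending slope values) and `cdf` (mean cumulative fraction,
#'   non-decreasing, ending at 1).
#' @export
mean_cumulative_histogram <- function(slope_maps, exclusion_masks = NULL,
                                      grid_size = 2048L) {
  stopifnot(length(slope_maps) >= 1L)
  vals <- lapply(seq_along(slope_maps), function(i) {
    sm <- slope_maps[[i]]
    keep <- sm$valid
    if (!is.null(exclusion_masks)) {
      ex <- if (is.list(exclusion_masks)) exclusion_masks[[i]] else exclusion_masks
      keep <- keep & !ex
    }
    sm$slope[keep]
  })
  if (!any(lengths(vals) > 0)) stop("no valid pixels in any slope map")
  vals <- vals[lengths(vals) > 0]
  rng <- range(unlist(vals))
  grid <- seq(rng[1], rng[2], length.out = grid_size)
  cdfs <- vapply(vals, function(v) stats::ecdf(v)(grid), numeric(grid_size))
  structure(list(grid = grid, cdf = rowMeans(cdfs),
                 n_subjects = length(vals)),
            class = "cumulative_histogram")
}

#' Derive the pathological-permeability threshold from a cumulative
#' histogram
#'
#' The smallest grid value whose mean CDF reaches `percentile`; slopes
#' above it are called pathological.
#'
#' @param cum_hist a [mean_cumulative_histogram()] result.
#' @param percentile fraction in (0, 1), default 0.995 (the top 0.5% of
#'   healthy-cohort slope values is labelled abnormal).
#' @return object of class `permeability_threshold`: list with
#'   `slope_threshold`, `percentile`, `n_subjects`.
#' @export
derive_threshold <- function(cum_hist, percentile = 0.995) {
  stopifnot(percentile > 0, percentile < 1)
  i <- which(cum_hist$cdf >= percentile)[1L]
  if (is.na(i)) i <- length(cum_hist$grid)
  structure(list(slope_threshold = cum_hist$grid[i],
                 percentile = percentile,
                 n_subjects = cum_hist$n_subjects),
            class = "permeability_threshold")
}

#' Fraction of pixels with pathological slope
#'
#' @param smap a [slope_map()].
#' @param threshold a [derive_threshold()] result or a bare slope value.
#' @param exclusion_mask optional logical matrix of pixels to drop (optic
#'   disc, border margin).
#' @return fraction in \code{[0, 1]} of valid, non-excluded pixels with
#'   slope strictly above the threshold.
#' @export
abnormal_fraction <- function(smap, threshold, exclusion_mask = NULL) {
  thr <- if (inherits(threshold, "permeability_threshold"))
    threshold$slope_threshold else threshold
  keep <- smap$valid
  if (!is.null(exclusion_mask)) keep <- keep & !exclusion_mask
  v <- smap$slope[keep]
  if (!length(v)) stop("no valid pixels after exclusion")
  mean(v > thr)
}

#' Logical mask of a border margin
#'
#' Registration by Fourier shift wraps content circularly at the frame
#' edges; a margin (default 8 px) is excluded from calibration and
#' scoring.
#'
#' @param dims (rows, cols).
#' @param margin margin width in pixels.
#' @return logical matrix, `TRUE` on the border.
#' @export
border_mask <- function(dims, margin = 8L) {
  m <- matrix(FALSE, dims[1], dims[2])
  if (margin > 0) {
    m[c(seq_len(margin), dims[1] - seq_len(margin) + 1L), ] <- TRUE
    m[, c(seq_len(margin), dims[2] - seq_len(margin) + 1L)] <- TRUE
  }
  m
}

#' Dilate a binary mask by a number of 4-connected steps
#'
#' @param mask logical matrix.
#' @param steps dilation radius in pixels (city-block metric).
#' @return logical matrix.
#' @export
dilate_mask <- function(mask, steps = 1L) {
  for (i in seq_len(steps)) {
    mask <- mask |
      rbind(mask[-1, , drop = FALSE], FALSE) |
      rbind(FALSE, mask[-nrow(mask), , drop = FALSE]) |
      cbind(mask[, -1, drop = FALSE], FALSE) |
      cbind(FALSE, mask[, -ncol(mask), drop = FALSE])
  }
  mask
}

#' Render a color-coded permeability map
#'
#' Pixels at or below the threshold ("normal slope") are uniform blue;
#' pixels above it ("pathological slope") ramp linearly from yellow at the
#' threshold to red at the 99.9th percentile of supra-threshold slopes
#' (clipped above); invalid pixels are black.  Rendering is a pure
#' function of (slope, threshold): re-rendering is bit-identical.
#'
#' @param smap a [slope_map()].
#' @param threshold a [derive_threshold()] result or bare slope value.
#' @param red_percentile percentile of supra-threshold slopes mapped to
#'   pure red (default 0.999).
#' @return rows x cols x 3 numeric array in \code{[0, 1]} (RGB).
#' @export
render_map <- function(smap, threshold, red_percentile = 0.999) {
  thr <- if (inherits(threshold, "permeability_threshold"))
    threshold$slope_threshold else threshold
  dims <- dim(smap$slope)
  rgb <- array(0, c(dims, 3L))
  s <- smap$slope
  normal <- smap$valid & s <= thr
  abn <- smap$valid & s > thr
  # blue
  b <- matrix(0, dims[1], dims[2]); b[normal] <- 1
  rgb[, , 3] <- b
  if (any(abn)) {
    hi <- stats::quantile(s[abn], red_percentile, names = FALSE, type = 7)
    frac <- if (hi > thr) pmin((s[abn] - thr) / (hi - thr), 1) else rep(1, sum(abn))
    r <- matrix(0, dims[1], dims[2]); g <- matrix(0, dims[1], dims[2])
    r[abn] <- 1              # yellow (1,1,0) -> red (1,0,0)
    g[abn] <- 1 - frac
    rgb[, , 1] <- r; rgb[, , 2] <- g
  }
  rgb
}
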