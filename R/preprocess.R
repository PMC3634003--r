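# Pre-processing: optic-disc localization, left/right eye classification,
# and exclusion of noisy or non-retinal frames.

#' Detect the optic disc by bright-region center of mass
#'
#' The optic disc is the brightest structure of a fundus frame.  Pixels at
#' or above the 99th intensity percentile are kept, reduced to the largest
#' 4-connected component, and the detection reports the intensity-weighted
#' center of mass of that component.  This automatic stand-in supports eye
#' classification; for permeability statistics a manually drawn disc ROI
#' takes precedence when supplied.
#'
#' The detection is invariant to multiplicative intensity scaling.
#'
#' @param frame an [fa_frame()] or a numeric matrix.
#' @return list with `centroid` (0-based (row, col), real-valued) and
#'   `mask` (logical matrix of the selected component).
#' @export
detect_optic_disc <- function(frame) {
  px <- if (inherits(frame, "fa_frame")) frame$pixels else frame
  if (max(px) - min(px) <= 0) stop("no disc signal: constant frame")
  thr <- stats::quantile(px, 0.99, names = FALSE)
  bright <- px >= thr
  lab <- label_components(bright)
  if (max(lab) == 0L) stop("no disc signal: no bright component")
  sizes <- tabulate(lab[lab > 0L])
  comp <- lab == which.max(sizes)
  w <- px[comp]
  idx <- which(comp, arr.ind = TRUE)
  centroid <- c(sum((idx[, 1] - 1) * w), sum((idx[, 2] - 1) * w)) / sum(w)
  list(centroid = centroid, mask = comp)
}

# 4-connected component labelling via iterative flood fill (stack-based;
# frames are small so this is plenty fast).
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  todo <- which(mask)
  for (s in todo) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    stack <- s
    lab[s] <- cur
    while (length(stack)) {
      p <- stack[length(stack)]
      stack <- stack[-length(stack)]
      r <- ((p - 1L) %% nr) + 1L
      cc <- ((p - 1L) %/% nr) + 1L
      nb <- c(if (r > 1L) p - 1L, if (r < nr) p + 1L,
              if (cc > 1L) p - nr, if (cc < nc) p + nr)
      nb <- nb[mask[nb] & lab[nb] == 0L]
      lab[nb] <- cur
      stack <- c(stack, nb)
    }
  }
  lab
}

#' Classify a sequence as a left- or right-eye acquisition
#'
#' The median optic-disc centroid column over frames with a detectable
#' disc is compared to the frame midline.  Under the default convention a
#' disc in the right half labels the image a right eye; cameras differ in
#' display convention, so the mapping is configurable.  A centroid within
#' `ambiguous_frac` of the midline returns `"ambiguous"` rather than a
#' guess.
#'
#' @param seq an [fa_sequence()].
#' @param disc_right_means `"right"` (default) or `"left"`: which eye label
#'   a disc on the right half implies.
#' @param ambiguous_frac half-width of the ambiguity band around the
#'   midline as a fraction of frame width (default 0.02).
#' @return `"left"`, `"right"` or `"ambiguous"`.
#' @export
classify_eye <- function(seq, disc_right_means = "right",
                         ambiguous_frac = 0.02) {
  disc_right_means <- match.arg(disc_right_means, c("right", "left"))
  cols <- c()
  for (f in seq$frames) {
    det <- tryCatch(detect_optic_disc(f), error = function(e) NULL)
    if (!is.null(det)) cols <- c(cols, det$centroid[2])
  }
  if (!length(cols)) stop("optic disc not detectable in any frame")
  mid <- (seq$pixel_dims[2] - 1) / 2
  dev <- stats::median(cols) - mid
  if (abs(dev) <= ambiguous_frac * seq$pixel_dims[2]) return("ambiguous")
  on_right <- dev > 0
  if (on_right == (disc_right_means == "right")) "right" else "left"
}

#' Flag noisy or non-retinal frames
#'
#' Each frame is correlated (Pearson, over all pixels) with the pixel-wise
#' median frame of the sequence; frames with correlation below `min_corr`
#' are flagged `"excluded"` and skipped by every downstream stage.  The
#' median frame is robust to the large intensity swing across the
#' angiographic phases, which is why plain correlation-to-mean is not used.
#'
#' @param seq an [fa_sequence()] with at least 3 frames.
#' @param min_corr exclusion threshold in \code{[0, 1]} (default 0.5).
#' @return the sequence with updated per-frame quality flags.
#' @export
flag_noisy_frames <- function(seq, min_corr = 0.5) {
  if (length(seq$frames) < 3L) stop("need >= 3 frames to assess noise")
  stack <- vapply(seq$frames, function(f) as.vector(f$pixels),
                  numeric(prod(seq$pixel_dims)))
  med <- apply(stack, 1L, stats::median)
  if (stats::sd(med) == 0) stop("sequence unusable: median frame is constant")
  keep <- vapply(seq_len(ncol(stack)), function(i) {
    x <- stack[, i]
    if (stats::sd(x) == 0) return(FALSE)
    stats::cor(x, med) >= min_corr
  }, logical(1))
  if (!any(keep)) stop("sequence unusable: all frames flagged as noisy")
  seq$frames <- lapply(seq_along(seq$frames), function(i) {
    f <- seq$frames[[i]]
    f$quality <- if (keep[i]) f$quality else "excluded"
    f
  })
  seq
}
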