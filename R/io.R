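# Domain containers and file plumbing shared by every pipeline stage.
#
# Coordinate convention (used everywhere, including shift vectors and ROI
# polygons): (row, col), 0-based, origin at the top-left pixel.  Internally
# R matrices are of course 1-based; the 0-based convention applies to
# values exchanged through files and to shift/centroid results.

#' Construct a single FA frame
#'
#' @param pixels numeric matrix of non-negative intensities (arbitrary
#'   camera units).
#' @param t acquisition time in seconds since dye injection.
#' @param quality `"ok"` or `"excluded"`.
#' @param eye `"left"`, `"right"` or `"unknown"`.
#' @return object of class `fa_frame`.
#' @export
fa_frame <- function(pixels, t, quality = "ok", eye = "unknown") {
  stopifnot(is.matrix(pixels))
  if (!all(is.finite(pixels)) || any(pixels < 0))
    stop("frame pixels must be finite and non-negative")
  if (!is.finite(t) || t < 0) stop("frame time must be finite and >= 0")
  quality <- match.arg(quality, c("ok", "excluded"))
  eye <- match.arg(eye, c("left", "right", "unknown"))
  structure(list(pixels = pixels, t = t, quality = quality, eye = eye),
            class = "fa_frame")
}

#' Construct an FA frame sequence
#'
#' Frames are ordered by acquisition time; all frames must share the same
#' pixel dimensions and have strictly increasing times.
#'
#' @param frames list of [fa_frame()] objects.
#' @return object of class `fa_sequence` with elements `frames` and
#'   `pixel_dims` (rows, cols).
#' @export
fa_sequence <- function(frames) {
  stopifnot(length(frames) >= 1L)
  times <- vapply(frames, function(f) f$t, numeric(1))
  frames <- frames[order(times)]
  times <- sort(times)
  if (any(diff(times) <= 0))
    stop("frame acquisition times must be strictly increasing ",
         "(duplicate time ", times[which(diff(times) <= 0)[1L] + 1L], " s)")
  dims <- dim(frames[[1L]]$pixels)
  for (f in frames)
    if (!identical(dim(f$pixels), dims))
      stop("all frames must share pixel dimensions (found ",
           paste(dim(f$pixels), collapse = "x"), " vs ",
           paste(dims, collapse = "x"), ")")
  structure(list(frames = frames, pixel_dims = dims), class = "fa_sequence")
}

#' @export
print.fa_sequence <- function(x, ...) {
  n_ok <- sum(usable_idx(x))
  cat(sprintf("<fa_sequence> %d frames (%d usable), %dx%d px, t = %.0f..%.0f s\n",
              length(x$frames), n_ok, x$pixel_dims[1], x$pixel_dims[2],
              x$frames[[1]]$t, x$frames[[length(x$frames)]]$t))
  invisible(x)
}

#' Frame times of a sequence
#' @param seq an `fa_sequence`.
#' @param usable_only drop frames flagged `"excluded"`.
#' @return numeric vector of seconds since injection.
#' @export
frame_times <- function(seq, usable_only = FALSE) {
  t <- vapply(seq$frames, function(f) f$t, numeric(1))
  if (usable_only) t[usable_idx(seq)] else t
}

# logical index of frames not flagged "excluded"
usable_idx <- function(seq)
  vapply(seq$frames, function(f) f$quality == "ok", logical(1))

#' Construct a region-of-interest mask
#'
#' @param mask logical (or 0/1) matrix.
#' @param role `"artery"`, `"optic_disc"` or `"other"`.
#' @return object of class `roi_mask`.
#' @export
roi_mask <- function(mask, role = "other") {
  role <- match.arg(role, c("artery", "optic_disc", "other"))
  mask <- matrix(as.logical(mask), nrow = nrow(mask))
  if (role == "artery" && !any(mask))
    stop("artery ROI must be non-empty")
  structure(list(mask = mask, role = role), class = "roi_mask")
}

#' Construct a sub-pixel shift vector
#'
#' @param d_row,d_col real-valued translation in pixels (row, col).
#' @param peak_corr normalized correlation score at the optimum, in
#'   \code{[0, 1]}.
#' @return object of class `shift_vector`.
#' @export
shift_vector <- function(d_row, d_col, peak_corr = NA_real_) {
  stopifnot(is.finite(d_row), is.finite(d_col))
  structure(list(d_row = d_row, d_col = d_col, peak_corr = peak_corr),
            class = "shift_vector")
}

#' Construct a slope map
#'
#' @param slope numeric matrix, normalized-intensity change per second.
#' @param valid logical matrix; `FALSE` where the pixel could not be
#'   fitted (slope is `NA` there).
#' @param n_points number of time points used in the fit.
#' @return object of class `slope_map`.
#' @export
slope_map <- function(slope, valid, n_points) {
  stopifnot(identical(dim(slope), dim(valid)))
  if (any(!is.finite(slope[valid])))
    stop("slope must be finite wherever valid")
  slope[!valid] <- NA_real_
  structure(list(slope = slope, valid = valid, n_points = n_points),
            class = "slope_map")
}

#' Read an FA image sequence from a directory plus JSON time metadata
#'
#' The metadata sidecar maps each image filename to its acquisition time in
#' seconds since dye injection: `{"frame_000.tif": 0, "frame_001.tif": 3}`.
#' Frames are returned sorted by time regardless of listing or metadata
#' order.  RGB inputs (PNG) are converted to a single channel by the
#' unweighted mean of the channels: fluorescein emission is effectively
#' monochromatic, so channel weighting carries no information.
#'
#' @param directory directory containing TIFF (`.tif`/`.tiff`) or PNG
#'   frame files.
#' @param metadata_path path to the JSON sidecar; defaults to
#'   `meta.json` inside `directory`.
#' @return an [fa_sequence()].
#' @export
read_fa_sequence <- function(directory,
                             metadata_path = file.path(directory, "meta.json")) {
  if (!dir.exists(directory)) stop("no such directory: ", directory)
  meta <- jsonlite::read_json(metadata_path, simplifyVector = TRUE)
  files <- list.files(directory, pattern = "\\.(tif|tiff|png)$",
                      ignore.case = TRUE)
  if (length(files) < 1L) stop("no image files in ", directory)
  frames <- lapply(files, function(fn) {
    if (is.null(meta[[fn]]))
      stop("metadata has no acquisition time for file: ", fn)
    fa_frame(read_image(file.path(directory, fn)), t = as.numeric(meta[[fn]]))
  })
  fa_sequence(frames)
}

#' Read a single grayscale image (TIFF or PNG)
#'
#' PNG values (decoded in \code{[0, 1]}) are rescaled to 0..255; RGB PNGs
#' are averaged across channels.  TIFF values are returned as stored.
#'
#' @param path image file path.
#' @return numeric matrix.
#' @export
read_image <- function(path) {
  if (grepl("\\.(tif|tiff)$", path, ignore.case = TRUE)) return(read_tiff(path))
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    a <- png::readPNG(path)
    if (length(dim(a)) == 3L) a <- apply(a[, , 1:min(3L, dim(a)[3]), drop = FALSE],
                                         c(1, 2), mean)
    return(a * 255)
  }
  stop("unsupported image format: ", path)
}

#' Read a region-of-interest definition from JSON
#'
#' Two encodings are accepted:
#' \itemize{
#'   \item polygon: `{"role": "artery", "polygon": [[r,c], [r,c], ...]}` with
#'     0-based (row, col) vertex coordinates at pixel centers; a pixel is in
#'     the mask if its center lies inside the polygon or on its boundary;
#'   \item run-length: `{"role": "...", "rle": {"starts": [...], "lengths":
#'     [...]}}` over the row-major 0-based pixel stream.
#' }
#'
#' @param path JSON file path.
#' @param expected_dims integer (rows, cols) the mask must match.
#' @return an [roi_mask()].
#' @export
read_roi <- function(path, expected_dims) {
  spec <- jsonlite::read_json(path, simplifyVector = TRUE)
  role <- spec$role
  if (is.null(role) || !role %in% c("artery", "optic_disc", "other"))
    stop("ROI role must be one of artery/optic_disc/other, got: ",
         if (is.null(role)) "<missing>" else role)
  nr <- expected_dims[1]; nc <- expected_dims[2]
  if (!is.null(spec$polygon)) {
    poly <- spec$polygon
    if (is.list(poly)) poly <- do.call(rbind, poly)
    mask <- rasterize_polygon(poly, c(nr, nc))
  } else if (!is.null(spec$rle)) {
    mask <- matrix(FALSE, nr, nc)
    stream <- rep(FALSE, nr * nc)
    starts <- spec$rle$starts; lens <- spec$rle$lengths
    for (i in seq_along(starts))
      stream[(starts[i] + 1L):(starts[i] + lens[i])] <- TRUE
    mask <- matrix(stream, nrow = nr, byrow = TRUE)
  } else stop("ROI JSON must contain 'polygon' or 'rle'")
  roi_mask(mask, role)
}

#' Write an ROI mask to JSON (run-length encoding)
#'
#' @param roi an [roi_mask()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_roi <- function(roi, path) {
  stream <- as.vector(t(roi$mask))
  r <- rle(stream)
  ends <- cumsum(r$lengths)
  starts0 <- c(0L, ends[-length(ends)])
  keep <- r$values
  jsonlite::write_json(
    list(role = roi$role,
         rle = list(starts = starts0[keep], lengths = r$lengths[keep])),
    path, auto_unbox = TRUE)
  invisible(path)
}

#' Rasterize a polygon into a binary mask
#'
#' A pixel is set if its center (0-based integer (row, col)) is strictly
#' inside the polygon (even-odd rule) or lies on a polygon edge, so
#' boundary pixels are always included.
#'
#' @param vertices n x 2 matrix of 0-based (row, col) vertex coordinates.
#' @param dims (rows, cols) of the target mask.
#' @return logical matrix.
#' @export
rasterize_polygon <- function(vertices, dims) {
  vertices <- as.matrix(vertices)
  stopifnot(ncol(vertices) == 2L)
  nr <- dims[1]; nc <- dims[2]
  vr <- vertices[, 1]; vc <- vertices[, 2]
  n <- length(vr)
  rmin <- max(0L, floor(min(vr))); rmax <- min(nr - 1L, ceiling(max(vr)))
  cmin <- max(0L, floor(min(vc))); cmax <- min(nc - 1L, ceiling(max(vc)))
  mask <- matrix(FALSE, nr, nc)
  if (rmax < rmin || cmax < cmin) return(mask)
  pr <- rep(rmin:rmax, times = cmax - cmin + 1L)
  pc <- rep(cmin:cmax, each = rmax - rmin + 1L)
  inside <- rep(FALSE, length(pr))
  on_edge <- rep(FALSE, length(pr))
  jprev <- n
  for (j in seq_len(n)) {
    r1 <- vr[jprev]; c1 <- vc[jprev]; r2 <- vr[j]; c2 <- vc[j]
    # even-odd crossing test on the horizontal ray in +col direction
    crosses <- ((r1 > pr) != (r2 > pr)) &
      (pc < (c2 - c1) * (pr - r1) / (r2 - r1) + c1)
    crosses[is.na(crosses)] <- FALSE
    inside <- xor(inside, crosses)
    # boundary inclusion: point on segment within tolerance
    dr <- r2 - r1; dc <- c2 - c1
    len2 <- dr * dr + dc * dc
    if (len2 == 0) {
      on_edge <- on_edge | (abs(pr - r1) < 1e-9 & abs(pc - c1) < 1e-9)
    } else {
      tt <- pmin(1, pmax(0, ((pr - r1) * dr + (pc - c1) * dc) / len2))
      d2 <- (pr - (r1 + tt * dr))^2 + (pc - (c1 + tt * dc))^2
      on_edge <- on_edge | (d2 < 1e-18)
    }
    jprev <- j
  }
  set <- inside | on_edge
  mask[cbind(pr[set] + 1L, pc[set] + 1L)] <- TRUE
  mask
}

#' Write a slope map and rendered permeability map to disk
#'
#' The slope map is written as a 32-bit float single-channel TIFF
#' (`<prefix>_slope.tif`, invalid pixels as NaN so that "not fitted" stays
#' distinct from a zero slope) and the rendered map as an 8-bit RGB PNG
#' (`<prefix>_map.png`).  The float TIFF round-trips bit-exactly through
#' [read_tiff()].
#'
#' @param smap a [slope_map()].
#' @param rgb_map rows x cols x 3 array in \code{[0, 1]} (e.g. from
#'   [render_map()]), or `NULL` to skip the PNG.
#' @param out_prefix path prefix for the output files.
#' @return named character vector of paths written, invisibly.
#' @export
write_maps <- function(smap, rgb_map, out_prefix) {
  s <- smap$slope
  s[!smap$valid] <- NaN
  out <- c(slope = paste0(out_prefix, "_slope.tif"))
  dir <- dirname(out_prefix)
  if (!dir.exists(dir)) stop("unwritable output path: ", dir)
  write_tiff(s, out[["slope"]], bits = 32L)
  if (!is.null(rgb_map)) {
    stopifnot(identical(dim(rgb_map)[1:2], dim(s)))
    out[["map"]] <- paste0(out_prefix, "_map.png")
    png::writePNG(rgb_map, out[["map"]])
  }
  invisible(out)
}

#' Read a slope map written by [write_maps()]
#'
#' @param path the `*_slope.tif` file.
#' @param n_points value recorded in the returned object (not stored in the
#'   TIFF); defaults to `NA`.
#' @return a [slope_map()].
#' @export
read_slope_map <- function(path, n_points = NA_integer_) {
  s <- read_tiff(path)
  valid <- is.finite(s)
  slope_map(s, valid, n_points)
}
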