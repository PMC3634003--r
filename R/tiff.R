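# Minimal baseline-TIFF reader/writer.
#
# The analysis stack needs lossless storage of per-pixel slope values
# (32-bit IEEE float, single channel) and ingestion of grayscale camera
# frames.  No TIFF package ships with this toolchain, so a small baseline
# codec is provided: little-endian, single strip, uncompressed, one sample
# per pixel, 8/16-bit unsigned integer or 32-bit float.  This covers every
# file the package itself writes and the plain grayscale exports of common
# scientific tools.

.tiff_tag <- function(id, type, count, value_or_offset) {
  # type 3 = SHORT, 4 = LONG
  c(.le16(id), .le16(type), .le32(count),
    if (type == 3L) c(.le16(value_or_offset), as.raw(c(0, 0)))
    else .le32(value_or_offset))
}

.le16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
.le32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")

#' Write a numeric matrix as a single-channel TIFF
#'
#' Values are stored as 32-bit IEEE floats (the default) or 8/16-bit
#' unsigned integers, uncompressed, little-endian, one strip.  Float
#' storage round-trips finite values and NaN bit-exactly through
#' [read_tiff()].
#'
#' @param x numeric matrix (rows x cols), pixel \code{[1,1]} at top-left.
#' @param path output file path.
#' @param bits one of 32 (float), 16 or 8 (unsigned integer).
#' @return `path`, invisibly.
#' @export
write_tiff <- function(x, path, bits = 32L) {
  stopifnot(is.matrix(x), bits %in% c(8L, 16L, 32L))
  nr <- nrow(x); nc <- ncol(x)
  bytes_px <- bits %/% 8L
  n_ifd <- 10L
  # layout: 8-byte header | pixel data | IFD
  data_offset <- 8L
  data_bytes <- nr * nc * bytes_px
  ifd_offset <- data_offset + data_bytes
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(as.raw(c(0x49, 0x49)), .le16(42L), .le32(ifd_offset)), con)
  # row-major pixel stream
  v <- as.vector(t(x))
  if (bits == 32L) {
    writeBin(as.numeric(v), con, size = 4, endian = "little")
  } else {
    v <- as.integer(round(pmin(pmax(v, 0), 2^bits - 1)))
    if (bits == 16L) {
      lo <- v %% 256L; hi <- v %/% 256L
      writeBin(as.raw(as.vector(rbind(lo, hi))), con)
    } else writeBin(as.raw(v), con)
  }
  tags <- c(
    .tiff_tag(256L, 3L, 1L, nc),                   # ImageWidth
    .tiff_tag(257L, 3L, 1L, nr),                   # ImageLength
    .tiff_tag(258L, 3L, 1L, bits),                 # BitsPerSample
    .tiff_tag(259L, 3L, 1L, 1L),                   # Compression: none
    .tiff_tag(262L, 3L, 1L, 1L),                   # Photometric: BlackIsZero
    .tiff_tag(273L, 4L, 1L, data_offset),          # StripOffsets
    .tiff_tag(277L, 3L, 1L, 1L),                   # SamplesPerPixel
    .tiff_tag(278L, 3L, 1L, nr),                   # RowsPerStrip
    .tiff_tag(279L, 4L, 1L, data_bytes),           # StripByteCounts
    .tiff_tag(339L, 3L, 1L, if (bits == 32L) 3L else 1L)  # SampleFormat
  )
  writeBin(c(.le16(n_ifd), tags, .le32(0L)), con)
  invisible(path)
}

.read_le <- function(raw, off, size, n = 1L) {
  readBin(raw[(off + 1L):(off + size * n)], "integer",
          n = n, size = size, signed = size == 4L, endian = "little")
}

#' Read a single-channel TIFF written by [write_tiff()] (or compatible)
#'
#' Supports little-endian, uncompressed, single-strip (or contiguous
#' multi-strip) grayscale TIFFs with 8/16-bit unsigned or 32-bit float
#' samples.
#'
#' @param path file path.
#' @return numeric matrix of pixel values.
#' @export
read_tiff <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 8L) stop("not a TIFF file: ", path)
  if (!(raw[1] == 0x49 && raw[2] == 0x49))
    stop("unsupported TIFF byte order (need little-endian): ", path)
  if (.read_le(raw, 2L, 2L) != 42L) stop("not a TIFF file: ", path)
  ifd <- .read_le(raw, 4L, 4L)
  n_tags <- .read_le(raw, ifd, 2L)
  tags <- list()
  for (i in seq_len(n_tags)) {
    base <- ifd + 2L + (i - 1L) * 12L
    id <- .read_le(raw, base, 2L)
    type <- .read_le(raw, base + 2L, 2L)
    count <- .read_le(raw, base + 4L, 4L)
    val <- if (type == 3L) .read_le(raw, base + 8L, 2L, min(count, 2L))[1L]
           else .read_le(raw, base + 8L, 4L)
    # multi-valued strip tags: dereference offset
    if (count > 1L && id %in% c(273L, 279L)) {
      off <- .read_le(raw, base + 8L, 4L)
      val <- .read_le(raw, off, if (type == 3L) 2L else 4L, count)
    }
    tags[[as.character(id)]] <- val
  }
  g <- function(id, default = NULL) {
    v <- tags[[as.character(id)]]
    if (is.null(v)) default else v
  }
  nc <- g(256L); nr <- g(257L)
  bits <- g(258L, 1L); comp <- g(259L, 1L)
  fmt <- g(339L, 1L); spp <- g(277L, 1L)
  if (is.null(nc) || is.null(nr)) stop("TIFF missing dimensions: ", path)
  if (comp != 1L) stop("compressed TIFF not supported: ", path)
  if (spp != 1L) stop("only single-channel TIFF supported: ", path)
  offs <- g(273L); cnts <- g(279L, nr * nc * bits %/% 8L)
  stream <- unlist(lapply(seq_along(offs), function(i)
    raw[(offs[i] + 1L):(offs[i] + cnts[i])]), use.names = FALSE)
  n_px <- nr * nc
  v <- if (fmt == 3L && bits == 32L) {
    readBin(stream, "numeric", n = n_px, size = 4, endian = "little")
  } else if (fmt == 1L && bits == 8L) {
    as.numeric(readBin(stream, "integer", n = n_px, size = 1,
                       signed = FALSE, endian = "little"))
  } else if (fmt == 1L && bits == 16L) {
    as.numeric(readBin(stream, "integer", n = n_px, size = 2,
                       signed = FALSE, endian = "little"))
  } else stop("unsupported TIFF sample format (bits=", bits,
              ", format=", fmt, "): ", path)
  matrix(v, nrow = nr, ncol = nc, byrow = TRUE)
}
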