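# Minimal multi-page TIFF I/O for 16-bit unsigned greyscale stacks.
# No TIFF package ships with the target environment, and camera stacks in
# this domain are plain uncompressed grey TIFFs, so a small codec is kept
# here: little-endian, one strip per page, no compression.  The reader
# handles only what the writer produces plus the common single-sample,
# uncompressed, stripped layout.

TIFF_TAGS <- c(ImageWidth = 256L, ImageLength = 257L, BitsPerSample = 258L,
               Compression = 259L, Photometric = 262L, StripOffsets = 273L,
               RowsPerStrip = 278L, StripByteCounts = 279L,
               SampleFormat = 339L)

#' Write a frame stack as a multi-page 16-bit TIFF
#'
#' Writes an uncompressed little-endian greyscale TIFF, one page per frame.
#' Values are rounded and clamped to the 16-bit unsigned range 0..65535.
#'
#' @param stack An [frame_stack()] object, a list of matrices, or a matrix.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_tiff_stack()]
#' @export
write_tiff_stack <- function(stack, path) {
  frames <- if (inherits(stack, "ebc_stack")) stack$frames else stack
  if (is.matrix(frames)) frames <- list(frames)
  stopifnot(length(frames) >= 1L)
  con <- file(path, "wb")
  on.exit(close(con))
  w16 <- function(x) writeBin(as.integer(ifelse(x > 32767L, x - 65536L, x)),
                              con, size = 2L, endian = "little")
  w32 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  # header: II, magic 42, offset of first IFD
  writeBin(charToRaw("II"), con)
  w16(42L)
  nfr <- length(frames)
  h <- nrow(frames[[1L]]); wd <- ncol(frames[[1L]])
  nbytes <- 2L * h * wd
  ntag <- 9L
  ifd_size <- 2L + ntag * 12L + 4L
  # layout: header(8) | nfr * [pixel data | IFD]
  data_off <- integer(nfr); ifd_off <- integer(nfr)
  pos <- 8L
  for (k in seq_len(nfr)) {
    data_off[k] <- pos
    ifd_off[k] <- pos + nbytes
    pos <- pos + nbytes + ifd_size
  }
  w32(ifd_off[1L])
  entry <- function(tag, type, count, value) {
    w16(tag); w16(type); w32(count)
    if (type == 3L) { w16(value); w16(0L) } else w32(value)
  }
  for (k in seq_len(nfr)) {
    v <- round(t(frames[[k]]))          # row-major pixel order
    v[v < 0] <- 0; v[v > 65535] <- 65535
    w16(as.vector(v))
    # IFD
    w16(ntag)
    entry(TIFF_TAGS[["ImageWidth"]], 3L, 1L, wd)
    entry(TIFF_TAGS[["ImageLength"]], 3L, 1L, h)
    entry(TIFF_TAGS[["BitsPerSample"]], 3L, 1L, 16L)
    entry(TIFF_TAGS[["Compression"]], 3L, 1L, 1L)
    entry(TIFF_TAGS[["Photometric"]], 3L, 1L, 1L)   # BlackIsZero
    entry(TIFF_TAGS[["StripOffsets"]], 4L, 1L, data_off[k])
    entry(TIFF_TAGS[["RowsPerStrip"]], 3L, 1L, h)
    entry(TIFF_TAGS[["StripByteCounts"]], 4L, 1L, nbytes)
    entry(TIFF_TAGS[["SampleFormat"]], 3L, 1L, 1L)  # unsigned int
    w32(if (k < nfr) ifd_off[k + 1L] else 0L)       # next IFD
  }
  invisible(path)
}

#' Read a multi-page 16-bit greyscale TIFF as a frame stack
#'
#' Supports uncompressed, stripped, single-sample greyscale TIFFs (both byte
#' orders; 8 or 16 bits per sample) — the layout photon-counting cameras
#' write and [write_tiff_stack()] produces.
#'
#' @param path TIFF file path.
#' @param calibration Optional [camera_calibration()] to attach; default
#'   calibration otherwise.
#' @return An [frame_stack()].
#' @export
read_tiff_stack <- function(path, calibration = camera_calibration()) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 8L) stop("not a TIFF file: ", path)
  endian <- if (rawToChar(raw[1:2]) == "II") "little"
            else if (rawToChar(raw[1:2]) == "MM") "big"
            else stop("not a TIFF file: ", path)
  rd <- function(off, size, n = 1L)
    readBin(raw[(off + 1L):(off + size * n)], "integer", n = n, size = size,
            signed = size > 2L, endian = endian)
  if (rd(2L, 2L) != 42L) stop("not a TIFF file: ", path)
  ifd <- rd(4L, 4L)
  frames <- list()
  while (ifd != 0L) {
    ntag <- rd(ifd, 2L)
    tags <- list()
    for (i in seq_len(ntag)) {
      e <- ifd + 2L + (i - 1L) * 12L
      tag <- rd(e, 2L); type <- rd(e + 2L, 2L); count <- rd(e + 4L, 4L)
      size <- c(1L, 1L, 2L, 4L)[type]  # BYTE/ASCII/SHORT/LONG
      if (is.na(size)) next
      voff <- if (size * count <= 4L) e + 8L else rd(e + 8L, 4L)
      tags[[as.character(tag)]] <- rd(voff, size, count)
    }
    g <- function(tag, default = NULL) {
      v <- tags[[as.character(tag)]]
      if (is.null(v)) default else v
    }
    wd <- g(256L); h <- g(257L)
    bits <- g(258L, 1L); comp <- g(259L, 1L)
    if (is.null(wd) || is.null(h)) stop("malformed TIFF IFD")
    if (comp != 1L) stop("unsupported TIFF: compressed data")
    if (!bits %in% c(8L, 16L)) stop("unsupported TIFF: ", bits, " bits/sample")
    offs <- g(273L); rps <- g(278L, h); cnts <- g(279L)
    px <- integer(0)
    for (s in seq_along(offs)) {
      n <- cnts[s] %/% (bits %/% 8L)
      px <- c(px, rd(offs[s], bits %/% 8L, n))
    }
    px[px < 0] <- px[px < 0] + 65536L  # 16-bit values read as signed shorts
    frames[[length(frames) + 1L]] <- t(matrix(px[seq_len(wd * h)], nrow = wd))
    ifd <- rd(ifd + 2L + ntag * 12L, 4L)
  }
  frame_stack(frames, calibration)
}

#' Write and read ground-truth event tables
#'
#' Plain CSV with columns `frame`, `x_px`, `y_px`, `amplitude_pe`, `kind`.
#'
#' @param truth Ground-truth data frame as returned by [simulate_stack()].
#' @param path CSV path.
#' @return `path` (write) or the data frame (read), invisibly for write.
#' @export
write_ground_truth <- function(truth, path) {
  utils::write.csv(truth[, c("frame", "x_px", "y_px", "amplitude_pe", "kind")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
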