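# Photon-image accumulation and fixed-pattern-noise diagnostics.
#
# A photon-counting image is a 2-d histogram of localisation positions, at
# native (1-pixel) or subdivided (e.g. 1/5-pixel) resolution.  Folding the
# fractional positions of all localisations over a single pixel gives the
# subpixel-occupancy array; the mismatch between event shape and centroiding
# function shows up there as fixed pattern noise (FPN), quantified as
# (Nmax - Nmin) / Nmean * 100 % on the 5x5 folded array.

#' Accumulate localisations into a photon-counting image
#'
#' Each localisation increments the histogram bin
#' `(floor(x_px * s), floor(y_px * s))` at subdivision `s`.  `s = 1` is
#' centroiding with one-pixel accuracy; `s = 5` is 1/5-pixel centroiding.
#' Localisations outside the image bounds are dropped (count recorded in
#' attribute `dropped`).
#'
#' @param locs Localisation data frame with `x_px`, `y_px`.
#' @param dim Native image size `c(width, height)` in pixels.
#' @param subdivision Integer subdivision factor `>= 1`.
#' @return An object of class `ebc_photon_image`: integer count matrix of
#'   size `(height * s) x (width * s)` with attributes `subdivision` and
#'   `dropped`.
#' @export
accumulate_image <- function(locs, dim, subdivision = 1L) {
  stopifnot(subdivision >= 1L, length(dim) == 2L)
  s <- as.integer(subdivision)
  w <- as.integer(dim[1L]); h <- as.integer(dim[2L])
  ix <- floor(locs$x_px * s)
  iy <- floor(locs$y_px * s)
  inb <- ix >= 0 & ix < w * s & iy >= 0 & iy < h * s
  counts <- matrix(0L, h * s, w * s)
  if (any(inb)) {
    lin <- ix[inb] * (h * s) + iy[inb] + 1   # column-major linear index
    tab <- tabulate(lin, nbins = w * s * h * s)
    counts <- matrix(as.integer(tab), h * s, w * s)
  }
  structure(counts, class = "ebc_photon_image", subdivision = s,
            dropped = sum(!inb))
}

#' @export
print.ebc_photon_image <- function(x, ...) {
  s <- attr(x, "subdivision")
  cat(sprintf("photon image: %d x %d bins (1/%d px), %d counts, %d dropped\n",
              ncol(x), nrow(x), s, sum(x), attr(x, "dropped")))
  invisible(x)
}

#' Downsample a photon image by its subdivision factor
#'
#' Sums `s x s` blocks of bins; the result equals accumulation at
#' subdivision 1.
#'
#' @param image An [accumulate_image()] result.
#' @param factor Block size; defaults to the image's subdivision.
#' @return Integer count matrix at native resolution.
#' @export
downsample_image <- function(image, factor = attr(image, "subdivision")) {
  f <- as.integer(factor)
  h <- nrow(image) %/% f; w <- ncol(image) %/% f
  out <- matrix(0L, h, w)
  for (dr in seq_len(f)) for (dc in seq_len(f))
    out <- out + image[seq(dr, by = f, length.out = h),
                       seq(dc, by = f, length.out = w)]
  out
}

#' Sum a frame stack pixel-wise
#'
#' The unprocessed sum image: includes all camera noise, for comparison with
#' centroided photon images.
#'
#' @param stack An [frame_stack()] or list of matrices.
#' @return Matrix of summed grey values.
#' @export
sum_stack <- function(stack) {
  frames <- if (inherits(stack, "ebc_stack")) stack$frames else stack
  if (is.matrix(frames)) frames <- list(frames)
  Reduce(`+`, frames)
}

#' Fold localisation positions into a subpixel-occupancy grid
#'
#' For each localisation the fractional parts `fx = x - floor(x)`,
#' `fy = y - floor(y)` are histogrammed on an `n x n` grid — i.e. the
#' centroid positions of all pixels overlaid on one pixel.  `n = 5` feeds
#' the FPN metric; `n = 13` is the conventional display resolution for
#' centroid-position distributions.
#'
#' @param locs Localisation data frame with `x_px`, `y_px`.
#' @param n Grid subdivision per axis.
#' @return An `n x n` integer matrix of class `ebc_occupancy` (row = y bin,
#'   column = x bin, bin 1 at fractional position 0).
#' @export
subpixel_occupancy <- function(locs, n = 5L) {
  stopifnot(n >= 1L)
  n <- as.integer(n)
  fx <- locs$x_px - floor(locs$x_px)
  fy <- locs$y_px - floor(locs$y_px)
  bx <- pmin(floor(fx * n), n - 1L)
  by <- pmin(floor(fy * n), n - 1L)
  tab <- tabulate(bx * n + by + 1, nbins = n * n)
  structure(matrix(as.integer(tab), n, n), class = "ebc_occupancy")
}

#' Fixed pattern noise of a subpixel-occupancy grid
#'
#' `FPN = (Nmax - Nmin) / Nmean * 100`, with `Nmax`, `Nmin`, `Nmean` the
#' maximum, minimum and average counts over the cells of the (normally 5x5)
#' subpixel array.  0 % for a perfectly uniform distribution of sub-pixel
#' positions; large values indicate that the centroiding method piles
#' localisations into particular sub-pixel cells.
#'
#' @param occ An [subpixel_occupancy()] grid (or any count matrix).
#' @return FPN in percent.
#' @examples
#' compute_fpn(matrix(1, 5, 5))            # 0
#' compute_fpn(matrix(c(2, rep(1, 24)), 5, 5))
#' @export
compute_fpn <- function(occ) {
  if (sum(occ) <= 0) stop("undefined FPN: empty occupancy grid")
  (max(occ) - min(occ)) / mean(occ) * 100
}

#' Line profile of an image region
#'
#' Averages a rectangular region across its short axis, returning the mean
#' intensity along the long axis.
#'
#' @param image Numeric matrix.
#' @param rect Rectangle `c(x, y, width, height)` in zero-based pixel (or
#'   bin) coordinates.
#' @return Numeric vector of length `max(width, height)`.
#' @export
line_profile <- function(image, rect) {
  stopifnot(length(rect) == 4L, rect[3L] >= 1, rect[4L] >= 1)
  x0 <- rect[1L]; y0 <- rect[2L]; w <- rect[3L]; h <- rect[4L]
  if (x0 < 0 || y0 < 0 || x0 + w > ncol(image) || y0 + h > nrow(image))
    stop("rectangle outside the image")
  sub <- image[(y0 + 1):(y0 + h), (x0 + 1):(x0 + w), drop = FALSE]
  if (w >= h) colMeans(sub) else rowMeans(sub)
}
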