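#' Camera calibration for an EBCCD photon-counting setup
#'
#' Bundles the three numbers needed to interpret raw grey values: the image
#' pixel size in nanometres, the gain conversion from A/D counts (ADU) to
#' photoelectrons, and the dark offset (base level) in ADU.  The defaults are
#' the values of the reference setup: 80 nm image pixel size and 36
#' photoelectrons per A/D count, with a base level around 120 ADU (EBCCD base
#' levels drift with sensor temperature, typically within 100--140 ADU; when
#' `base_level_adu` is `NULL` it is estimated per stack with
#' [estimate_base_level()]).
#'
#' @param pixel_size_nm Length of one sensor pixel in the image plane (nm).
#' @param pe_per_adu Gain conversion, photoelectrons per A/D count.
#' @param base_level_adu Dark offset in ADU, or `NULL` to estimate from data.
#' @return An object of class `ebc_calibration`.
#' @examples
#' camera_calibration()
#' camera_calibration(pixel_size_nm = 80, pe_per_adu = 36, base_level_adu = 120)
#' @export
camera_calibration <- function(pixel_size_nm = 80, pe_per_adu = 36,
                               base_level_adu = NULL) {
  if (!is.numeric(pixel_size_nm) || length(pixel_size_nm) != 1L ||
      !is.finite(pixel_size_nm) || pixel_size_nm <= 0)
    stop("invalid calibration: pixel_size_nm must be a positive number")
  if (!is.numeric(pe_per_adu) || length(pe_per_adu) != 1L ||
      !is.finite(pe_per_adu) || pe_per_adu <= 0)
    stop("invalid calibration: pe_per_adu must be a positive number")
  if (!is.null(base_level_adu)) {
    if (!is.numeric(base_level_adu) || length(base_level_adu) != 1L ||
        !is.finite(base_level_adu) || base_level_adu < 0)
      stop("invalid calibration: base_level_adu must be >= 0")
  }
  structure(list(pixel_size_nm = pixel_size_nm,
                 pe_per_adu = pe_per_adu,
                 base_level_adu = base_level_adu),
            class = "ebc_calibration")
}

#' @export
print.ebc_calibration <- function(x, ...) {
  cat("EBCCD camera calibration\n")
  cat(sprintf("  pixel size : %g nm\n", x$pixel_size_nm))
  cat(sprintf("  gain       : %g pe/ADU\n", x$pe_per_adu))
  if (is.null(x$base_level_adu))
    cat("  base level : (estimated per stack)\n")
  else
    cat(sprintf("  base level : %g ADU\n", x$base_level_adu))
  invisible(x)
}

#' Frame stack container
#'
#' A stack of same-sized frames of non-negative grey values (ADU) plus the
#' calibration needed to interpret them.  Frames are stored as a list of
#' numeric matrices, row = y, column = x.
#'
#' Coordinate convention used throughout the package: continuous positions are
#' zero-based, pixel `(ix, iy)` spans `[ix, ix+1) x [iy, iy+1)` with its
#' centre at `(ix + 0.5, iy + 0.5)`; matrix element `[iy + 1, ix + 1]` holds
#' its value.
#'
#' @param frames A list of numeric matrices, or a 3-d array (rows x cols x
#'   frames).
#' @param calibration An [camera_calibration()] object.
#' @return An object of class `ebc_stack`.
#' @export
frame_stack <- function(frames, calibration = camera_calibration()) {
  if (is.array(frames) && length(dim(frames)) == 3L)
    frames <- lapply(seq_len(dim(frames)[3]), function(k) frames[, , k])
  if (is.matrix(frames)) frames <- list(frames)
  if (!is.list(frames) || length(frames) == 0L)
    stop("empty input: a frame stack needs at least one frame")
  if (!all(vapply(frames, is.matrix, logical(1))))
    stop("frames must be matrices")
  d <- dim(frames[[1L]])
  if (!all(vapply(frames, function(f) identical(dim(f), d), logical(1))))
    stop("all frames in a stack must share dimensions")
  if (any(vapply(frames, function(f) any(f < 0), logical(1))))
    stop("grey values must be >= 0")
  stopifnot(inherits(calibration, "ebc_calibration"))
  structure(list(frames = frames, calibration = calibration),
            class = "ebc_stack")
}

#' @export
print.ebc_stack <- function(x, ...) {
  d <- dim(x$frames[[1L]])
  cat(sprintf("EBCCD frame stack: %d frame(s) of %d x %d px\n",
              length(x$frames), d[2L], d[1L]))
  print(x$calibration)
  invisible(x)
}

#' @export
length.ebc_stack <- function(x) length(x$frames)

#' Convert a frame from A/D counts to photoelectrons
#'
#' Subtracts the base level and multiplies by the gain.  Values below the base
#' level are clamped to zero: Poisson photon counts cannot be negative, and
#' the maximum-likelihood fits downstream require non-negative data.
#'
#' @param frame Numeric matrix of grey values (ADU).
#' @param calibration An [camera_calibration()] object.
#' @param base_level_adu Base level override (ADU); defaults to the value in
#'   `calibration`, which must then be set.
#' @return Numeric matrix of photoelectron counts,
#'   `max(0, ADU - base) * pe_per_adu`.
#' @examples
#' calib <- camera_calibration(base_level_adu = 104)
#' adu_to_photoelectrons(matrix(140, 1, 1), calib)  # (140-104)*36 = 1296
#' @export
adu_to_photoelectrons <- function(frame, calibration,
                                  base_level_adu = NULL) {
  stopifnot(inherits(calibration, "ebc_calibration"))
  base <- if (is.null(base_level_adu)) calibration$base_level_adu else base_level_adu
  if (is.null(base))
    stop("no base level: set it in the calibration or pass base_level_adu")
  pmax(frame - base, 0) * calibration$pe_per_adu
}

#' Estimate the camera base level from a stack
#'
#' The base level is taken as the average minimum grey value over the frames
#' of the stack: each frame contributes its minimum, and the minima are
#' averaged.  EBCCD base levels drift with temperature between acquisitions,
#' so the estimate is made per stack (or per chunk of a long acquisition; see
#' [run_pipeline()]'s `chunk_size`).
#'
#' @param stack An [frame_stack()] object, or a list of frame matrices.
#' @return Estimated base level (ADU, scalar).
#' @export
estimate_base_level <- function(stack) {
  frames <- if (inherits(stack, "ebc_stack")) stack$frames else stack
  if (is.matrix(frames)) frames <- list(frames)
  if (length(frames) == 0L)
    stop("empty input: cannot estimate a base level from zero frames")
  mean(vapply(frames, min, numeric(1)))
}
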