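# Ion-event clipping.
#
# Ion events are orders of magnitude brighter than photon events.  Because
# the detection threshold is set per frame from the wavelet-filtered image's
# standard deviation, a single ion event inflates the threshold and the
# genuine photon events in that frame are discarded as noise.  The remedy is
# to clip all pixels brighter than the photon-event maximum to a grey value
# slightly above it before detection.  The clipped ion remnants then get
# localised as (spurious) photon events, but ions are rare enough that this
# has no noticeable effect on the result.

#' Estimate the maximum photon-event grey value of a stack
#'
#' Robust upper bound on photon-event peak brightness: frames whose maximum
#' exceeds 3x the smallest per-frame maximum are flagged as ion-contaminated
#' and excluded, and the given quantile of the remaining per-frame maxima is
#' returned.  The smallest per-frame maximum is the reference because it is
#' photon-level whenever at least one frame is ion-free — a median reference
#' breaks down as soon as half the frames carry an ion, which short stacks
#' at one ion every few frames regularly reach.
#'
#' @param stack An [frame_stack()] or list of frame matrices.
#' @param quantile Quantile of clean per-frame maxima to report
#'   (default 0.999).
#' @return Estimated photon-event maximum (ADU, scalar).
#' @export
estimate_photon_event_max <- function(stack, quantile = 0.999) {
  frames <- if (inherits(stack, "ebc_stack")) stack$frames else stack
  if (is.matrix(frames)) frames <- list(frames)
  if (length(frames) == 0L) stop("empty input: no frames")
  mx <- vapply(frames, max, numeric(1))
  clean <- mx[mx <= 3 * min(mx)]
  if (length(clean) == 0L)
    stop("estimation failed: every frame looks ion-contaminated")
  unname(stats::quantile(clean, quantile))
}

#' Clip ion events in a frame
#'
#' Every pixel brighter than `photon_max` is replaced by
#' `photon_max * (1 + epsilon)` — a grey value slightly above the maximum
#' intensity of the photon events; all other pixels are untouched.
#'
#' @param frame Numeric matrix of grey values (ADU).
#' @param photon_max Photon-event maximum (ADU), e.g. from
#'   [estimate_photon_event_max()].
#' @param epsilon Relative headroom above `photon_max` (default 0.05).
#' @return The clipped frame (same dimensions).
#' @examples
#' f <- matrix(c(120, 4000), 1, 2)
#' clip_ion_events(f, photon_max = 200)  # 4000 -> 210
#' @export
clip_ion_events <- function(frame, photon_max, epsilon = 0.05) {
  stopifnot(photon_max > 0, epsilon >= 0)
  idx <- frame > photon_max
  if (any(idx)) frame[idx] <- photon_max * (1 + epsilon)
  frame
}
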