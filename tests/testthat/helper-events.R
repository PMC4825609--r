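# Shared fixture builders.  All frames go through the same camera chain as
# the simulator: photoelectron patches -> Poisson -> /gain -> + base
# -> + read noise -> rounded ADU.

default_calib <- function() camera_calibration(base_level_adu = 120)

# Render events onto an n x n photoelectron image (no camera chain).
render_pe_frame <- function(events, shape, n = 25) {
  pe <- matrix(0, n, n)
  for (i in seq_len(nrow(events))) {
    r <- render_photon_event(events$x[i], events$y[i], events$amp[i], shape)
    rr <- max(1L, r$origin[2L] + 1L):min(n, r$origin[2L] + nrow(r$patch))
    cc <- max(1L, r$origin[1L] + 1L):min(n, r$origin[1L] + ncol(r$patch))
    pe[rr, cc] <- pe[rr, cc] +
      r$patch[rr - r$origin[2L], cc - r$origin[1L], drop = FALSE]
  }
  pe
}

# Full camera frame in ADU.
camera_frame <- function(events, shape, n = 25, noise_sd = 0.5,
                         calib = default_calib(), poisson = TRUE) {
  pe <- render_pe_frame(events, shape, n)
  if (poisson) {
    nz <- which(pe > 0)
    if (length(nz)) pe[nz] <- stats::rpois(length(nz), pe[nz])
  }
  adu <- 120 + pe / calib$pe_per_adu
  if (noise_sd > 0) adu <- adu + stats::rnorm(n * n, 0, noise_sd)
  pmax(round(adu), 0)
}

# Noise-free region around a single event, in photoelectrons.
event_region <- function(x, y, amp, shape, radius, n = 25) {
  pe <- render_pe_frame(data.frame(x = x, y = y, amp = amp), shape, n)
  extract_region(pe, as.integer(floor(x)), as.integer(floor(y)), radius)
}
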