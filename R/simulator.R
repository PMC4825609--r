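# Synthetic EBCCD frame simulator with ground truth.
#
# Photon events on an electron-bombarded CCD are small (a bright central
# pixel with faint wings, charge spilling into adjacent pixels), have a
# narrow pulse-height distribution, and are widened horizontally by the CCD
# read-out.  Rare ion events — a residual-gas ion accelerated into the
# photocathode — are far brighter and larger.  The simulator reproduces this
# phenomenology on top of a flat base level and Gaussian read noise, and
# returns the true event positions so every pipeline stage can be scored.

run_with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Photon-event shape model
#'
#' Events are pixel-integrated Gaussians of width `sigma_y`, horizontally
#' widened so that the marginal standard deviation along x equals `sigma_x`.
#' Two widening mechanisms are available:
#'
#' * `"smear"` (default): per-pixel charge deferral in the read-out
#'   direction.  A fraction `alpha` of each pixel column's charge is
#'   deferred one pixel toward +x, geometrically (weights
#'   `(1 - alpha) * alpha^k` at `k` pixel shifts), the discrete analogue of
#'   charge-transfer inefficiency during CCD read-out.  `alpha` is solved
#'   from `alpha / (1 - alpha)^2 = sigma_x^2 - sigma_y^2` (in px^2) so the
#'   marginal x SD matches `sigma_x`.  The deferred tail is what biases
#'   centroided positions toward the right pixel edge.
#' * `"elliptical"`: a plain elliptical Gaussian with standard deviations
#'   `(sigma_x, sigma_y)`.  Mirror-symmetric in x, so it widens the event
#'   without introducing any left/right bias.
#'
#' The radial `profile` controls how the event mass is distributed at fixed
#' marginal width:
#'
#' * `"peaked"` (default): a high central peak with small wings — a mixture
#'   of two concentric Gaussians (80 % of the charge in a sharp core of
#'   `0.35 * sigma_y`, 20 % in wings widened so the marginal SD still equals
#'   `sigma_y`).  This is the realistic electron-bombarded event: the
#'   accelerated photoelectron deposits charge in essentially one pixel and
#'   diffusion spills a little into the neighbours.  Because it is more
#'   sharply peaked than any Gaussian, Gaussian-PSF fits show a small
#'   position wobble that depends on the sub-pixel phase — the origin of
#'   fixed pattern noise.
#' * `"gauss"`: a plain (integrated) Gaussian, exactly matching the fitted
#'   PSF models; useful for analytic checks where the estimator model and
#'   the data-generating model must coincide.
#'
#' Event amplitudes (integrated photoelectrons) follow a truncated normal
#' with mean `amplitude_mean` and coefficient of variation `amplitude_cv`,
#' reflecting the narrow, voltage-dependent pulse-height distribution of
#' electron-bombarded sensors.
#'
#' @param sigma_x Marginal PSF standard deviation along x (px); must be
#'   `>= sigma_y`.
#' @param sigma_y PSF standard deviation along y (px).
#' @param amplitude_mean Mean integrated event amplitude (photoelectrons).
#' @param amplitude_cv Coefficient of variation of the amplitude
#'   distribution (small; the pulse-height distribution is narrow).
#' @param widening `"smear"` or `"elliptical"` (see Details).
#' @param profile `"peaked"` or `"gauss"` (see Details).
#' @return An object of class `ebc_shape` with derived fields `asymmetry`
#'   (`sigma_x / sigma_y`) and `alpha` (charge-deferral fraction, 0 if
#'   symmetric or elliptical).
#' @export
event_shape_model <- function(sigma_x = 0.92, sigma_y = 0.8,
                              amplitude_mean = 6000, amplitude_cv = 0.1,
                              widening = c("smear", "elliptical"),
                              profile = c("peaked", "gauss")) {
  widening <- match.arg(widening)
  profile <- match.arg(profile)
  if (!is.finite(sigma_x) || !is.finite(sigma_y) || sigma_x <= 0 || sigma_y <= 0)
    stop("invalid shape: sigma_x and sigma_y must be positive")
  if (sigma_x < sigma_y)
    stop("invalid shape: sigma_x must be >= sigma_y (horizontal widening)")
  if (amplitude_mean <= 0 || amplitude_cv < 0)
    stop("invalid shape: amplitude_mean > 0 and amplitude_cv >= 0 required")
  alpha <- 0
  if (widening == "smear" && sigma_x > sigma_y) {
    v <- sigma_x^2 - sigma_y^2       # added variance of the geometric tail
    alpha <- ((2 * v + 1) - sqrt(4 * v + 1)) / (2 * v)
  }
  structure(list(sigma_x = sigma_x, sigma_y = sigma_y,
                 asymmetry = sigma_x / sigma_y, alpha = alpha,
                 amplitude_mean = amplitude_mean, amplitude_cv = amplitude_cv,
                 widening = widening, profile = profile,
                 core_fraction = 0.80, core_sigma_ratio = 0.35),
            class = "ebc_shape")
}

#' Ion-event model
#'
#' Ion events are rare (of order one every few frames), much brighter and
#' somewhat larger than photon events.  They are rendered as symmetric
#' Gaussians of width `size_factor * sigma_y` with amplitude
#' `amplitude_factor` times a photon-amplitude draw.  The defaults put the
#' ion peak near 4000 ADU above base at the default photon shape and gain —
#' bright enough to corrupt a per-frame detection threshold, which is the
#' failure mode ion clipping exists to fix.
#'
#' @param rate_per_frame Expected ion events per frame (Poisson rate).
#' @param amplitude_factor Brightness multiple relative to photon events.
#' @param size_factor Spatial extent multiple relative to photon events.
#' @return An object of class `ebc_ion_model`.
#' @export
ion_event_model <- function(rate_per_frame = 1 / 3, amplitude_factor = 1400,
                            size_factor = 3) {
  if (rate_per_frame < 0) stop("ion rate_per_frame must be >= 0")
  if (amplitude_factor <= 1) stop("ion amplitude_factor must be > 1")
  if (size_factor < 1) stop("ion size_factor must be >= 1")
  structure(list(rate_per_frame = rate_per_frame,
                 amplitude_factor = amplitude_factor,
                 size_factor = size_factor),
            class = "ebc_ion_model")
}

#' Bar-target scene map
#'
#' A binary bar pattern standing in for a resolution test chart: alternating
#' bright and dark bars of equal width `bar_period / 2`.  `bar_period = Inf`
#' yields a uniform (all-ones) scene.  Scene maps give the relative photon
#' arrival probability per pixel.
#'
#' @param width,height Scene size in pixels.
#' @param bar_period Full period of the bar pattern (px), `>= 2`, or `Inf`
#'   for a uniform scene.
#' @param orientation `"vertical"` (bars are bright columns) or
#'   `"horizontal"` (bright rows).
#' @return An object of class `ebc_scene`: a list with the `weights` matrix.
#' @export
make_bar_target_scene <- function(width, height, bar_period = Inf,
                                  orientation = c("vertical", "horizontal")) {
  orientation <- match.arg(orientation)
  stopifnot(width >= 1, height >= 1)
  if (is.infinite(bar_period)) {
    w <- matrix(1, height, width)
  } else {
    if (bar_period < 2) stop("bar_period must be >= 2")
    extent <- if (orientation == "vertical") width else height
    if (bar_period > extent)
      stop("degenerate scene: bar_period exceeds the image extent")
    coord <- if (orientation == "vertical")
      matrix(rep(0:(width - 1), each = height), height, width)
    else
      matrix(rep(0:(height - 1), width), height, width)
    w <- matrix(as.numeric(floor(coord / (bar_period / 2)) %% 2 == 0),
                height, width)
  }
  if (sum(w) <= 0) stop("degenerate scene: total weight is zero")
  structure(list(weights = w), class = "ebc_scene")
}

#' Sample ground-truth photon arrival positions
#'
#' Per-frame event counts are Poisson with the given mean; positions are
#' drawn pixel-wise proportional to the scene weights and uniformly within
#' the chosen pixel.
#'
#' @param scene An [make_bar_target_scene()] scene (or any `ebc_scene`).
#' @param mean_events_per_frame Poisson mean of events per frame.
#' @param n_frames Number of frames.
#' @param seed Optional RNG seed (restores the RNG state afterwards).
#' @return Data frame with columns `frame` (1-based), `x_px`, `y_px`
#'   (continuous, zero-based pixel coordinates).
#' @export
sample_events <- function(scene, mean_events_per_frame, n_frames,
                          seed = NULL) {
  stopifnot(inherits(scene, "ebc_scene"), mean_events_per_frame >= 0,
            n_frames >= 1)
  run_with_seed(seed, {
    w <- scene$weights
    h <- nrow(w); wd <- ncol(w)
    counts <- stats::rpois(n_frames, mean_events_per_frame)
    ntot <- sum(counts)
    if (ntot == 0L)
      return(data.frame(frame = integer(0), x_px = numeric(0),
                        y_px = numeric(0)))
    idx <- sample.int(h * wd, ntot, replace = TRUE, prob = as.vector(w))
    iy <- (idx - 1L) %% h          # row - 1
    ix <- (idx - 1L) %/% h         # col - 1
    data.frame(frame = rep(seq_len(n_frames), counts),
               x_px = ix + stats::runif(ntot),
               y_px = iy + stats::runif(ntot))
  })
}

# Per-axis pixel integrals of the event profile over unit pixels with left
# edges `edges_lo` (zero-based coordinates).
axis_integral_gauss <- function(edges_lo, x0, sigma) {
  stats::pnorm(edges_lo + 1, x0, sigma) - stats::pnorm(edges_lo, x0, sigma)
}

#' Render a single photon event on the pixel grid
#'
#' Integrates the event profile over whole pixel areas
#' (difference-of-Gaussian-CDF per axis), then applies the horizontal
#' read-out smear if the shape has one: geometric per-pixel charge deferral
#' toward +x, with the echo weights renormalised over the kept terms so the
#' patch sum equals the amplitude.  The patch is truncated where at least
#' 99.9 % of the event mass is retained.
#'
#' @param x,y True event position (continuous, zero-based px).  The position
#'   is the Gaussian core centre — i.e. the photon arrival point, before any
#'   read-out smear.
#' @param amplitude Integrated event amplitude (photoelectrons), `> 0`.
#' @param shape An [event_shape_model()].
#' @return List with `patch` (matrix of photoelectrons) and `origin`
#'   (zero-based `(x, y)` pixel index of the patch's top-left corner).
#' @export
render_photon_event <- function(x, y, amplitude, shape) {
  stopifnot(inherits(shape, "ebc_shape"))
  if (amplitude <= 0) stop("event amplitude must be > 0")
  sx <- if (shape$widening == "elliptical") shape$sigma_x else shape$sigma_y
  sy <- shape$sigma_y
  if (shape$profile == "peaked") {
    # concentric core + wing mixture at the same marginal SD
    fc <- shape$core_fraction
    rc <- shape$core_sigma_ratio
    rw <- sqrt((1 - fc * rc^2) / (1 - fc))
    sxs <- c(rc, rw) * sx; sys <- c(rc, rw) * sy; wts2 <- c(fc, 1 - fc)
  } else {
    sxs <- sx; sys <- sy; wts2 <- 1
  }
  ext_x <- 4 * max(sxs); ext_y <- 4 * max(sys)
  lo_x <- floor(x - ext_x)
  hi_x <- ceiling(x + ext_x) - 1
  lo_y <- floor(y - ext_y)
  hi_y <- ceiling(y + ext_y) - 1
  patch <- 0
  for (i in seq_along(wts2))
    patch <- patch + wts2[i] *
      outer(axis_integral_gauss(lo_y:hi_y, y, sys[i]),
            axis_integral_gauss(lo_x:hi_x, x, sxs[i]))
  patch <- amplitude * patch
  a <- shape$alpha
  if (a > 0) {
    nk <- max(1L, ceiling(log(1e-3) / log(a)))   # echoes beyond keep < 0.1 %
    wts <- (1 - a) * a^(0:nk)
    wts <- wts / sum(wts)
    sm <- matrix(0, nrow(patch), ncol(patch) + nk)
    for (k in 0:nk)
      sm[, (1L + k):(ncol(patch) + k)] <-
        sm[, (1L + k):(ncol(patch) + k)] + wts[k + 1L] * patch
    patch <- sm
  }
  list(patch = patch, origin = c(lo_x, lo_y))
}

add_patch <- function(img, patch, origin) {
  h <- nrow(img); w <- ncol(img)
  r0 <- origin[2L] + 1L; c0 <- origin[1L] + 1L          # 1-based top-left
  rr <- max(1L, r0):min(h, r0 + nrow(patch) - 1L)
  cc <- max(1L, c0):min(w, c0 + ncol(patch) - 1L)
  if (length(rr) == 0L || length(cc) == 0L || rr[1L] > rr[length(rr)] ||
      cc[1L] > cc[length(cc)]) return(img)
  img[rr, cc] <- img[rr, cc] + patch[rr - r0 + 1L, cc - c0 + 1L, drop = FALSE]
  img
}

rtrunc_amplitude <- function(n, mean, cv) {
  if (cv == 0) return(rep(mean, n))
  a <- stats::rnorm(n, mean, cv * mean)
  while (any(bad <- a <= 0)) a[bad] <- stats::rnorm(sum(bad), mean, cv * mean)
  a
}

#' Simulate an EBCCD frame stack with ground truth
#'
#' Each frame is built as base level + Gaussian read noise + the Poisson
#' realisation of the rendered photon and ion events, converted from
#' photoelectrons to ADU by the calibration gain and rounded to integer grey
#' values (clamped to the 16-bit range).  Bitwise reproducible for a fixed
#' seed.
#'
#' @param scene Scene map; its dimensions set the frame size.
#' @param shape Photon-event [event_shape_model()].
#' @param ion_model [ion_event_model()], or `NULL` for no ion events.
#' @param calibration [camera_calibration()] with a set base level.
#' @param mean_events Mean photon events per frame.
#' @param n_frames Number of frames.
#' @param noise_sd_adu Gaussian read-noise standard deviation (ADU).
#' @param seed Optional RNG seed.
#' @return An object of class `ebc_simulation`: list with `stack`
#'   ([frame_stack()]) and `truth` (data frame: `frame`, `x_px`, `y_px`,
#'   `amplitude_pe`, `kind` = `"photon"` or `"ion"`).
#' @examples
#' sim <- simulate_stack(make_bar_target_scene(64, 64), n_frames = 2,
#'                       mean_events = 10, seed = 1)
#' sim$stack
#' head(sim$truth)
#' @export
simulate_stack <- function(scene, shape = event_shape_model(),
                           ion_model = NULL,
                           calibration = camera_calibration(base_level_adu = 120),
                           mean_events = 150, n_frames = 10,
                           noise_sd_adu = 0.5, seed = NULL) {
  stopifnot(inherits(scene, "ebc_scene"), inherits(shape, "ebc_shape"),
            inherits(calibration, "ebc_calibration"))
  if (is.null(calibration$base_level_adu))
    stop("config error: simulation needs a calibration with a base level")
  if (!is.null(ion_model)) stopifnot(inherits(ion_model, "ebc_ion_model"))
  run_with_seed(seed, {
    h <- nrow(scene$weights); w <- ncol(scene$weights)
    truth <- sample_events(scene, mean_events, n_frames)
    truth$amplitude_pe <- rtrunc_amplitude(nrow(truth), shape$amplitude_mean,
                                           shape$amplitude_cv)
    truth$kind <- rep("photon", nrow(truth))
    if (!is.null(ion_model) && ion_model$rate_per_frame > 0) {
      n_ion <- stats::rpois(n_frames, ion_model$rate_per_frame)
      ni <- sum(n_ion)
      if (ni > 0L) {
        ion <- data.frame(
          frame = rep(seq_len(n_frames), n_ion),
          x_px = stats::runif(ni, 0, w),
          y_px = stats::runif(ni, 0, h),
          amplitude_pe = ion_model$amplitude_factor *
            rtrunc_amplitude(ni, shape$amplitude_mean, shape$amplitude_cv),
          kind = rep("ion", ni))
        truth <- rbind(truth, ion)
        truth <- truth[order(truth$frame), , drop = FALSE]
        rownames(truth) <- NULL
      }
    }
    ion_shape <- if (!is.null(ion_model))
      event_shape_model(sigma_x = ion_model$size_factor * shape$sigma_y,
                        sigma_y = ion_model$size_factor * shape$sigma_y,
                        amplitude_mean = shape$amplitude_mean,
                        widening = "elliptical")
    gain <- calibration$pe_per_adu
    base <- calibration$base_level_adu
    frames <- vector("list", n_frames)
    for (k in seq_len(n_frames)) {
      pe <- matrix(0, h, w)
      ev <- truth[truth$frame == k, , drop = FALSE]
      for (i in seq_len(nrow(ev))) {
        sh <- if (ev$kind[i] == "ion") ion_shape else shape
        r <- render_photon_event(ev$x_px[i], ev$y_px[i], ev$amplitude_pe[i], sh)
        pe <- add_patch(pe, r$patch, r$origin)
      }
      nz <- which(pe > 0)
      if (length(nz)) pe[nz] <- stats::rpois(length(nz), pe[nz])
      adu <- base + pe / gain
      if (noise_sd_adu > 0)
        adu <- adu + stats::rnorm(h * w, 0, noise_sd_adu)
      adu <- round(adu)
      adu[adu < 0] <- 0
      adu[adu > 65535] <- 65535
      frames[[k]] <- adu
    }
    structure(list(stack = frame_stack(frames, calibration), truth = truth),
              class = "ebc_simulation")
  })
}

#' @export
print.ebc_simulation <- function(x, ...) {
  cat(sprintf("EBCCD simulation: %d frame(s), %d photon and %d ion events\n",
              length(x$stack), sum(x$truth$kind == "photon"),
              sum(x$truth$kind == "ion")))
  invisible(x)
}
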