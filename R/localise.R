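# Sub-pixel localisation of detected photon events.
#
# Five estimators, mirroring the single-molecule-localisation toolbox the
# pipeline is built on: Poisson maximum-likelihood and least-squares fits of
# a point-sampled symmetric Gaussian PSF, a weighted least-squares fit of
# the pixel-integrated Gaussian, the background-subtracted local centroid,
# and the non-iterative radial-symmetry estimator.  Multi-emitter fitting
# (1 vs 2 Gaussians, likelihood-ratio model selection) separates
# overlapping events.

#' Extract a square fitting region around a candidate
#'
#' @param frame_pe Frame in photoelectrons (matrix).
#' @param cx,cy Candidate pixel (zero-based integer coordinates).
#' @param radius Fitting radius in pixels; the patch is `(2*radius+1)` square,
#'   clipped at the frame borders.
#' @return An object of class `ebc_region`: list with `patch`, `origin`
#'   (zero-based `(x, y)` of the patch's top-left pixel), `radius`, `cx`,
#'   `cy`.
#' @export
extract_region <- function(frame_pe, cx, cy, radius) {
  h <- nrow(frame_pe); w <- ncol(frame_pe)
  if (cx < 0 || cx > w - 1 || cy < 0 || cy > h - 1)
    stop("candidate outside the frame")
  r0 <- max(1L, cy + 1L - radius); r1 <- min(h, cy + 1L + radius)
  c0 <- max(1L, cx + 1L - radius); c1 <- min(w, cx + 1L + radius)
  structure(list(patch = frame_pe[r0:r1, c0:c1, drop = FALSE],
                 origin = c(c0 - 1L, r0 - 1L),
                 radius = radius, cx = cx, cy = cy),
            class = "ebc_region")
}

region_coords <- function(region) {
  nx <- ncol(region$patch); ny <- nrow(region$patch)
  list(xs = region$origin[1L] + seq_len(nx) - 0.5,
       ys = region$origin[2L] + seq_len(ny) - 0.5,
       xe = region$origin[1L] + 0:(nx - 1L),   # left pixel edges
       ye = region$origin[2L] + 0:(ny - 1L))
}

loc_row <- function(x, y, intensity, sigma, background, method, objective,
                    n_emitters = 1L, converged = TRUE, ok = TRUE) {
  data.frame(x_px = x, y_px = y, intensity_pe = intensity,
             sigma_px = sigma, background_pe = background,
             method = method, n_emitters = as.integer(n_emitters),
             objective = objective, converged = converged, ok = ok)
}

# --- model evaluations -------------------------------------------------

# Point-sampled symmetric Gaussian; returns model and (optionally) partials.
gauss_model <- function(xs, ys, x0, y0, I, sigma, b, grad = FALSE) {
  gx <- stats::dnorm(xs, x0, sigma)
  gy <- stats::dnorm(ys, y0, sigma)
  g <- outer(gy, gx)
  m <- b + I * g
  if (!grad) return(list(m = m))
  dgx <- gx * (xs - x0) / sigma^2
  dgy <- gy * (ys - y0) / sigma^2
  sgx <- gx * ((xs - x0)^2 / sigma^3 - 1 / sigma)
  sgy <- gy * ((ys - y0)^2 / sigma^3 - 1 / sigma)
  list(m = m, g = g,
       dx0 = I * outer(gy, dgx),
       dy0 = I * outer(dgy, gx),
       dsig = I * (outer(gy, sgx) + outer(sgy, gx)))
}

# Pixel-integrated symmetric Gaussian (difference of normal CDFs per axis).
igauss_model <- function(xe, ye, x0, y0, I, sigma, b, grad = FALSE) {
  ex <- stats::pnorm(xe + 1, x0, sigma) - stats::pnorm(xe, x0, sigma)
  ey <- stats::pnorm(ye + 1, y0, sigma) - stats::pnorm(ye, y0, sigma)
  g <- outer(ey, ex)
  m <- b + I * g
  if (!grad) return(list(m = m))
  uhx <- (xe + 1 - x0) / sigma; ulx <- (xe - x0) / sigma
  uhy <- (ye + 1 - y0) / sigma; uly <- (ye - y0) / sigma
  dex <- -(stats::dnorm(uhx) - stats::dnorm(ulx)) / sigma
  dey <- -(stats::dnorm(uhy) - stats::dnorm(uly)) / sigma
  sex <- -(uhx * stats::dnorm(uhx) - ulx * stats::dnorm(ulx)) / sigma
  sey <- -(uhy * stats::dnorm(uhy) - uly * stats::dnorm(uly)) / sigma
  list(m = m, g = g,
       dx0 = I * outer(ey, dex),
       dy0 = I * outer(dey, ex),
       dsig = I * (outer(ey, sex) + outer(sey, ex)))
}

poisson_nll <- function(d, m) {
  m <- pmax(m, 1e-12)
  sum(m - d * log(m))
}

init_single <- function(region) {
  co <- region_coords(region)
  p <- region$patch
  b0 <- min(p)
  v <- p - b0
  tot <- sum(v)
  if (tot > 0) {
    x0 <- sum(v %*% co$xs) / tot     # v %*% xs sums rows weighted by column x
    y0 <- sum(co$ys %*% v) / tot
  } else {
    x0 <- mean(co$xs); y0 <- mean(co$ys)
  }
  I0 <- max(tot, 1)
  list(x0 = x0, y0 = y0, I0 = I0, b0 = max(b0, 1e-3))
}

fit_bounds <- function(region, sigma_bounds) {
  co <- region_coords(region)
  list(lower = c(co$xe[1L], co$ye[1L], 1e-6, sigma_bounds[1L], 1e-9),
       upper = c(co$xe[length(co$xe)] + 1, co$ye[length(co$ye)] + 1,
                 Inf, sigma_bounds[2L], Inf))
}

fit_gauss_generic <- function(region, init_sd, objective, model_fun,
                              method_tag, sigma_bounds, fix_sigma) {
  co <- region_coords(region)
  d <- region$patch
  ini <- init_single(region)
  par0 <- c(ini$x0, ini$y0, ini$I0, init_sd, ini$b0)
  bnd <- fit_bounds(region, sigma_bounds)
  if (fix_sigma) { bnd$lower[4L] <- init_sd; bnd$upper[4L] <- init_sd }
  fn <- function(p) objective$value(d, model_fun(p, grad = FALSE)$m)
  gr <- function(p) {
    mm <- model_fun(p, grad = TRUE)
    r <- objective$resid(d, mm$m)   # d(obj)/d(model), elementwise
    c(sum(r * mm$dx0), sum(r * mm$dy0), sum(r * mm$g),
      sum(r * mm$dsig), sum(r))
  }
  opt <- try(stats::optim(par0, fn, gr, method = "L-BFGS-B",
                          lower = bnd$lower, upper = bnd$upper,
                          control = list(maxit = 1000L, factr = 1e4)),
             silent = TRUE)
  if (inherits(opt, "try-error"))
    return(loc_row(ini$x0, ini$y0, NA_real_, NA_real_, NA_real_, method_tag,
                   NA_real_, converged = FALSE, ok = FALSE))
  p <- opt$par
  ok <- opt$convergence == 0L && p[3L] >= 1
  loc_row(p[1L], p[2L], p[3L], p[4L], p[5L], method_tag, opt$value,
          converged = opt$convergence == 0L, ok = ok)
}

obj_poisson <- list(value = function(d, m) poisson_nll(d, m),
                    resid = function(d, m) 1 - d / pmax(m, 1e-12))
obj_ls <- list(value = function(d, m) sum((d - m)^2),
               resid = function(d, m) -2 * (d - m))

#' Maximum-likelihood Gaussian fit of a photon event
#'
#' Maximises the Poisson log-likelihood `sum(d * log(m) - m)` of the model
#' `m = b + I * G(x0, y0, sigma)`, where `G` is a symmetric 2-d Gaussian
#' sampled at pixel centres.  Position and background are initialised from
#' the background-subtracted patch centroid and patch minimum; `sigma`
#' starts at `init_sd` and is fitted within `sigma_bounds` (set
#' `fix_sigma = TRUE` to freeze it at `init_sd`).
#'
#' @param region An [extract_region()] patch in photoelectrons.
#' @param init_sd Initial PSF standard deviation (px); 1.0 is the tuned value
#'   for EBCCD photon events.
#' @param sigma_bounds Allowed `sigma` range (px).
#' @param fix_sigma Freeze `sigma` at `init_sd`?
#' @return One-row data frame (a localisation): `x_px`, `y_px`,
#'   `intensity_pe`, `sigma_px`, `background_pe`, `method`, `n_emitters`,
#'   `objective` (the final fit objective), `converged`, `ok` (`FALSE` for
#'   rejected fits — non-convergence or vanishing intensity).
#' @export
fit_gaussian_mle <- function(region, init_sd = 1.0, sigma_bounds = c(0.3, 3),
                             fix_sigma = FALSE) {
  stopifnot(inherits(region, "ebc_region"))
  co <- region_coords(region)
  model <- function(p, grad) gauss_model(co$xs, co$ys, p[1L], p[2L], p[3L],
                                         p[4L], p[5L], grad)
  fit_gauss_generic(region, init_sd, obj_poisson, model, "mle_gauss",
                    sigma_bounds, fix_sigma)
}

#' Least-squares Gaussian fit
#'
#' As [fit_gaussian_mle()] but minimising the sum of squared residuals.
#'
#' @inheritParams fit_gaussian_mle
#' @return One-row localisation data frame; see [fit_gaussian_mle()].
#' @export
fit_gaussian_ls <- function(region, init_sd = 1.0, sigma_bounds = c(0.3, 3),
                            fix_sigma = FALSE) {
  stopifnot(inherits(region, "ebc_region"))
  co <- region_coords(region)
  model <- function(p, grad) gauss_model(co$xs, co$ys, p[1L], p[2L], p[3L],
                                         p[4L], p[5L], grad)
  fit_gauss_generic(region, init_sd, obj_ls, model, "ls_gauss",
                    sigma_bounds, fix_sigma)
}

#' Weighted least-squares integrated-Gaussian fit
#'
#' The PSF model is the Gaussian integrated over each pixel's area
#' (difference-of-normal-CDF form per axis); residuals are weighted by
#' `1 / max(d, 1)`, approximating inverse-variance weights for counting
#' data.  The tuned defaults for EBCCD events are a 3 px fitting radius with
#' `init_sd = 1.6`.
#'
#' @inheritParams fit_gaussian_mle
#' @param init_sd Initial PSF standard deviation (px); default 1.6.
#' @return One-row localisation data frame; see [fit_gaussian_mle()].
#' @export
fit_integrated_gaussian_wls <- function(region, init_sd = 1.6,
                                        sigma_bounds = c(0.3, 3),
                                        fix_sigma = FALSE) {
  stopifnot(inherits(region, "ebc_region"))
  co <- region_coords(region)
  wts <- 1 / pmax(region$patch, 1)
  obj <- list(value = function(d, m) sum(wts * (d - m)^2),
              resid = function(d, m) -2 * wts * (d - m))
  model <- function(p, grad) igauss_model(co$xe, co$ye, p[1L], p[2L], p[3L],
                                          p[4L], p[5L], grad)
  fit_gauss_generic(region, init_sd, obj, model, "wls_igauss",
                    sigma_bounds, fix_sigma)
}

#' Local-centroid localisation
#'
#' Background-subtracted intensity-weighted mean position, with the
#' background taken as the patch minimum.  Single-pass, no iteration.
#'
#' @param region An [extract_region()] patch.
#' @return One-row localisation data frame; `intensity_pe` is the
#'   background-subtracted patch sum, `sigma_px` is `NA`.
#' @export
localise_local_centroid <- function(region) {
  stopifnot(inherits(region, "ebc_region"))
  co <- region_coords(region)
  p <- region$patch
  v <- p - min(p)
  tot <- sum(v)
  if (tot <= 0) stop("degenerate patch: all values equal")
  x <- sum(v %*% co$xs) / tot
  y <- sum(co$ys %*% v) / tot
  loc_row(x, y, tot, NA_real_, min(p), "centroid", NA_real_)
}

#' Radial-symmetry localisation
#'
#' Non-iterative estimator: intensity gradients are computed on the
#' half-pixel lattice from diagonal differences, and the centre is the
#' least-squares point minimising its distance to the lines through each
#' lattice point along the local gradient, weighted by gradient magnitude
#' squared over distance to an approximate centroid.  Exact for noise-free
#' radially symmetric events.
#'
#' @param region An [extract_region()] patch, at least 3x3.
#' @return One-row localisation data frame; `intensity_pe` is the
#'   background-subtracted patch sum, `sigma_px` is `NA`.
#' @export
localise_radial_symmetry <- function(region) {
  stopifnot(inherits(region, "ebc_region"))
  P <- region$patch
  ny <- nrow(P); nx <- ncol(P)
  if (ny < 3L || nx < 3L) stop("radial symmetry needs at least a 3x3 patch")
  xm <- region$origin[1L] + seq_len(nx - 1L)    # half-pixel lattice, absolute
  ym <- region$origin[2L] + seq_len(ny - 1L)
  dIdu <- P[1:(ny - 1L), 2:nx, drop = FALSE] - P[2:ny, 1:(nx - 1L), drop = FALSE]
  dIdv <- P[1:(ny - 1L), 1:(nx - 1L), drop = FALSE] - P[2:ny, 2:nx, drop = FALSE]
  box3 <- function(a) {  # 3x3 zero-padded mean filter
    h <- nrow(a); w <- ncol(a)
    pad <- matrix(0, h + 2L, w + 2L)
    pad[2:(h + 1L), 2:(w + 1L)] <- a
    out <- matrix(0, h, w)
    for (dr in 0:2) for (dc in 0:2)
      out <- out + pad[(1L + dr):(h + dr), (1L + dc):(w + dc)]
    out / 9
  }
  fdu <- box3(dIdu); fdv <- box3(dIdv)
  dImag2 <- fdu^2 + fdv^2
  sdI2 <- sum(dImag2)
  ctr <- c(region$origin[1L] + nx / 2, region$origin[2L] + ny / 2)
  if (sdI2 <= 0) {
    warning("zero gradient field; returning the patch centre")
    return(loc_row(ctr[1L], ctr[2L], sum(P - min(P)), NA_real_, min(P),
                   "radial", NA_real_))
  }
  m <- -(fdv + fdu) / (fdu - fdv)
  m[is.nan(m)] <- 0
  m[is.infinite(m)] <- 1e9
  xmg <- matrix(rep(xm, each = ny - 1L), ny - 1L, nx - 1L)
  ymg <- matrix(rep(ym, nx - 1L), ny - 1L, nx - 1L)
  b <- ymg - m * xmg
  xcent <- sum(dImag2 * xmg) / sdI2
  ycent <- sum(dImag2 * ymg) / sdI2
  w <- dImag2 / pmax(sqrt((xmg - xcent)^2 + (ymg - ycent)^2), 1e-9)
  wm2p1 <- w / (m^2 + 1)
  sw <- sum(wm2p1)
  smmw <- sum(m^2 * wm2p1)
  smw <- sum(m * wm2p1)
  smbw <- sum(m * b * wm2p1)
  sbw <- sum(b * wm2p1)
  det <- smw^2 - smmw * sw
  if (abs(det) < 1e-300) {
    warning("degenerate gradient geometry; returning the patch centre")
    return(loc_row(ctr[1L], ctr[2L], sum(P - min(P)), NA_real_, min(P),
                   "radial", NA_real_))
  }
  xc <- (smbw * sw - smw * sbw) / det
  yc <- (smbw * smw - smmw * sbw) / det
  loc_row(xc, yc, sum(P - min(P)), NA_real_, min(P), "radial", NA_real_)
}

# --- multi-emitter fitting ---------------------------------------------

two_emitter_model <- function(xs, ys, p, grad = FALSE) {
  # p = (x1, y1, I1, x2, y2, I2, sigma, b)
  m1 <- gauss_model(xs, ys, p[1L], p[2L], p[3L], p[7L], 0, grad)
  m2 <- gauss_model(xs, ys, p[4L], p[5L], p[6L], p[7L], 0, grad)
  m <- p[8L] + m1$m + m2$m
  if (!grad) return(list(m = m))
  list(m = m, g1 = m1$g, g2 = m2$g,
       dx1 = m1$dx0, dy1 = m1$dy0, dx2 = m2$dx0, dy2 = m2$dy0,
       dsig = m1$dsig + m2$dsig)
}

#' Multi-emitter fitting of a region (1 vs 2 events)
#'
#' Fits a one-emitter and a two-emitter Poisson maximum-likelihood Gaussian
#' model (the two emitters share `sigma` and background; the second emitter
#' is initialised at the brightest residual pixel of the one-emitter fit).
#' The two-emitter model is selected iff the likelihood-ratio statistic
#' `2 * (logL2 - logL1)` exceeds the chi-square quantile with 3 degrees of
#' freedom at `p_threshold` — the three added parameters being the second
#' position and intensity.
#'
#' With `max_emitters = 1` this reproduces [fit_gaussian_mle()] exactly.
#'
#' @inheritParams fit_gaussian_mle
#' @param max_emitters 1 or 2.
#' @param p_threshold Model-selection p-value (default `1e-6`).
#' @return Data frame of 1 or 2 localisations, tagged `n_emitters`.
#' @export
fit_multi <- function(region, max_emitters = 2L, p_threshold = 1e-6,
                      init_sd = 1.0, sigma_bounds = c(0.3, 3)) {
  stopifnot(inherits(region, "ebc_region"), max_emitters %in% c(1L, 2L))
  fit1 <- fit_gaussian_mle(region, init_sd, sigma_bounds)
  if (max_emitters == 1L) return(fit1)
  if (!fit1$ok) return(fit1)
  co <- region_coords(region)
  d <- region$patch
  mm1 <- gauss_model(co$xs, co$ys, fit1$x_px, fit1$y_px, fit1$intensity_pe,
                     fit1$sigma_px, fit1$background_pe)$m
  resid <- d - mm1
  j <- which.max(resid)
  x2 <- co$xs[((j - 1L) %/% nrow(d)) + 1L]
  y2 <- co$ys[((j - 1L) %% nrow(d)) + 1L]
  par0 <- c(fit1$x_px, fit1$y_px, max(fit1$intensity_pe, 1),
            x2, y2, max(sum(pmax(resid, 0)), 10),
            fit1$sigma_px, max(fit1$background_pe, 1e-3))
  xlo <- co$xe[1L]; xhi <- co$xe[length(co$xe)] + 1
  ylo <- co$ye[1L]; yhi <- co$ye[length(co$ye)] + 1
  lower <- c(xlo, ylo, 1e-6, xlo, ylo, 1e-6, sigma_bounds[1L], 1e-9)
  upper <- c(xhi, yhi, Inf, xhi, yhi, Inf, sigma_bounds[2L], Inf)
  fn <- function(p) poisson_nll(d, two_emitter_model(co$xs, co$ys, p)$m)
  gr <- function(p) {
    mm <- two_emitter_model(co$xs, co$ys, p, grad = TRUE)
    r <- 1 - d / pmax(mm$m, 1e-12)
    c(sum(r * mm$dx1), sum(r * mm$dy1), sum(r * mm$g1),
      sum(r * mm$dx2), sum(r * mm$dy2), sum(r * mm$g2),
      sum(r * mm$dsig), sum(r))
  }
  opt <- try(stats::optim(par0, fn, gr, method = "L-BFGS-B",
                          lower = lower, upper = upper,
                          control = list(maxit = 1000L, factr = 1e4)),
             silent = TRUE)
  if (inherits(opt, "try-error") || opt$convergence != 0L) return(fit1)
  lrt <- 2 * (fit1$objective - opt$value)   # Poisson NLL difference
  crit <- stats::qchisq(1 - p_threshold, df = 3)
  p <- opt$par
  if (lrt <= crit || p[3L] < 1 || p[6L] < 1) return(fit1)
  rbind(loc_row(p[1L], p[2L], p[3L], p[7L], p[8L], "mle_gauss", opt$value,
                n_emitters = 2L),
        loc_row(p[4L], p[5L], p[6L], p[7L], p[8L], "mle_gauss", opt$value,
                n_emitters = 2L))
}

# --- post-processing ----------------------------------------------------

#' Remove duplicate localisations
#'
#' Within each frame, localisations closer than `distance_nm` are merged
#' greedily, keeping the higher-intensity member: localisations are
#' processed in order of descending intensity (ties broken by frame, x, y)
#' and one is kept only if no already-kept localisation of the same frame
#' lies within the distance threshold.  Used after multi-emitter fitting,
#' where overlapping fit regions can localise the same event twice; at
#' 80 nm/px the 160 nm default is 2 px.
#'
#' @param locs Localisation data frame with columns `frame`, `x_nm`, `y_nm`,
#'   `intensity_pe`.
#' @param distance_nm Merge distance (nm).
#' @return The filtered data frame.
#' @export
remove_duplicates <- function(locs, distance_nm = 160) {
  if (nrow(locs) <= 1L) return(locs)
  ord <- order(-locs$intensity_pe, locs$frame, locs$x_nm, locs$y_nm)
  keep <- logical(nrow(locs))
  for (fr in unique(locs$frame)) {
    cand <- ord[locs$frame[ord] == fr]
    kx <- numeric(0); ky <- numeric(0)
    for (i in cand) {
      if (length(kx) == 0L ||
          min((locs$x_nm[i] - kx)^2 + (locs$y_nm[i] - ky)^2) >= distance_nm^2) {
        keep[i] <- TRUE
        kx <- c(kx, locs$x_nm[i]); ky <- c(ky, locs$y_nm[i])
      }
    }
  }
  out <- locs[sort(which(keep)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter localisations by intensity
#'
#' Keeps localisations with `intensity_pe` strictly greater than `min_pe`.
#' Tuned cut-offs for the reference data are 4000 photoelectrons for sparse
#' transmission imaging and 3000 for fluorescence imaging.
#'
#' @param locs Localisation data frame.
#' @param min_pe Intensity threshold (photoelectrons).
#' @return The filtered data frame.
#' @export
filter_intensity <- function(locs, min_pe) {
  out <- locs[locs$intensity_pe > min_pe, , drop = FALSE]
  rownames(out) <- NULL
  out
}
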