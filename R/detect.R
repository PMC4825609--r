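# Approximate event detection: B-spline wavelet filtering, per-frame
# adaptive threshold, connected components with watershed splitting.

# B-spline basis function of the given order (support [-order/2, order/2]),
# via the truncated-power divided-difference form.
bspline_value <- function(x, order) {
  n <- order
  v <- numeric(length(x))
  for (k in 0:n) {
    t <- x + n / 2 - k
    v <- v + (-1)^k * choose(n, k) * ifelse(t > 0, t^(n - 1), 0)
  }
  v / factorial(n - 1)
}

#' B-spline smoothing kernel
#'
#' 1-d kernel obtained by sampling the B-spline basis of the given order,
#' stretched by `scale`, at integer offsets, normalised to unit sum.  Order 3
#' and scale 2 give the classic binomial kernel `c(1, 4, 6, 4, 1) / 16`.
#'
#' @param order B-spline order (`>= 1`).
#' @param scale Stretch factor (`> 0`).
#' @return Numeric vector of odd length summing to 1.
#' @export
bspline_kernel <- function(order = 3, scale = 2) {
  stopifnot(order >= 1, scale > 0)
  half <- ceiling(order * scale / 2) - 1L
  k <- bspline_value((-half:half) / scale, order)
  k / sum(k)
}

# A-trous dilation: insert `factor - 1` zeros between kernel taps.
dilate_kernel <- function(k, factor) {
  if (factor <= 1L) return(k)
  out <- numeric((length(k) - 1L) * factor + 1L)
  out[seq(1L, length(out), by = factor)] <- k
  out
}

# Separable 2-d convolution with symmetric (edge-repeating) reflection at
# the borders.  `k` must have odd length.
conv_separable <- function(img, k) {
  pad <- (length(k) - 1L) %/% 2L
  h <- nrow(img); w <- ncol(img)
  if (pad >= h || pad >= w)
    stop("degenerate input: kernel larger than the frame")
  out <- img
  if (pad > 0L) {
    ridx <- c(pad:1, 1:h, h:(h - pad + 1L))
    P <- out[ridx, , drop = FALSE]
    out <- matrix(0, h, w)
    for (t in seq_along(k))
      out <- out + k[t] * P[t:(t + h - 1L), , drop = FALSE]
    cidx <- c(pad:1, 1:w, w:(w - pad + 1L))
    P <- out[, cidx, drop = FALSE]
    out <- matrix(0, h, w)
    for (t in seq_along(k))
      out <- out + k[t] * P[, t:(t + w - 1L), drop = FALSE]
  }
  out
}

#' First wavelet level of a frame (B-spline a-trous filter)
#'
#' Computes `F1 = V0 - V1` in the a-trous cascade: `V0` is the separable
#' convolution of the input with the B-spline kernel of the given order, and
#' `V1` convolves `V0` with that kernel dilated by `round(scale)` (zeros
#' inserted between taps).  Dilating against the already-smoothed `V0` is
#' what makes the scheme a proper a-trous decomposition — applying the
#' sparse dilated kernel directly to the raw input instead lets its zero
#' taps straddle events narrower than the tap spacing and rings around
#' sharp peaks.  `F1` is a band-pass image that suppresses both pixel noise
#' and slowly varying background; detection thresholds are set on its
#' standard deviation.  Borders use symmetric reflection.
#'
#' @param frame Numeric matrix.
#' @param order B-spline order (default 3).
#' @param scale Kernel scale (default 2.0); also the a-trous dilation factor.
#' @return Matrix of the same size (`Wave.F1`).
#' @export
wavelet_filter <- function(frame, order = 3, scale = 2) {
  stopifnot(is.matrix(frame), order >= 1, scale > 0)
  k1 <- bspline_kernel(order, scale)
  k2 <- dilate_kernel(k1, max(2L, as.integer(round(scale))))
  v0 <- conv_separable(frame, k1)
  v0 - conv_separable(v0, k2)
}

#' Peak-intensity detection threshold
#'
#' `threshold = multiplier * sd(F1)`, with the standard deviation taken over
#' all pixels of the wavelet-filtered frame — hence per frame, which is what
#' makes the threshold sensitive to unclipped ion events.
#'
#' @param filtered Wavelet-filtered frame (matrix).
#' @param multiplier PIT multiplier (2 for sparse transmission-imaging data,
#'   1.5 for denser fluorescence data).
#' @return Scalar threshold.
#' @export
detection_threshold <- function(filtered, multiplier = 2) {
  s <- stats::sd(as.vector(filtered))
  if (!is.finite(s) || s == 0) {
    warning("zero-variance filtered frame; threshold is 0")
    return(0)
  }
  multiplier * s
}

# 8-connected component labelling of a logical mask (BFS).
label_components <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  idx <- which(mask)
  if (length(idx) == 0L) return(lab)
  dr <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
  dc <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  cur <- 0L
  queue <- integer(length(idx))
  for (s in idx) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    lab[s] <- cur
    queue[1L] <- s; qh <- 1L; qt <- 1L
    while (qh <= qt) {
      p <- queue[qh]; qh <- qh + 1L
      r <- ((p - 1L) %% h) + 1L
      cl <- ((p - 1L) %/% h) + 1L
      for (n in 1:8) {
        rr <- r + dr[n]; cc <- cl + dc[n]
        if (rr >= 1L && rr <= h && cc >= 1L && cc <= w) {
          q <- (cc - 1L) * h + rr
          if (mask[q] && lab[q] == 0L) {
            lab[q] <- cur; qt <- qt + 1L; queue[qt] <- q
          }
        }
      }
    }
  }
  lab
}

# Regional maxima of `values` restricted to the linear indices `comp` of an
# h x w frame: pixels not exceeded by any 8-neighbour.  Adjacent maxima
# (plateaus) are merged; returns a list of index vectors, one per plateau.
regional_maxima <- function(values, comp, h, w) {
  r <- ((comp - 1L) %% h) + 1L
  cl <- ((comp - 1L) %/% h) + 1L
  is_max <- rep(TRUE, length(comp))
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    rr <- r + dr; cc <- cl + dc
    ok <- rr >= 1L & rr <= h & cc >= 1L & cc <= w
    q <- (cc - 1L) * h + rr
    nv <- rep(-Inf, length(comp))
    nv[ok] <- values[q[ok]]
    is_max <- is_max & values[comp] >= nv
  }
  mx <- comp[is_max]
  if (length(mx) <= 1L) return(if (length(mx)) list(mx) else list())
  m <- matrix(FALSE, h, w); m[mx] <- TRUE
  lb <- label_components(m)
  lapply(seq_len(max(lb)), function(l) which(lb == l))
}

# Marker-based watershed: grow seed labels over the component, assigning
# pixels in order of decreasing value to the label of their highest-valued
# already-labelled 8-neighbour.
watershed_split <- function(values, comp, seeds, h, w) {
  lab <- integer(h * w)  # sparse: only comp entries used
  for (i in seq_along(seeds)) lab[seeds[[i]]] <- i
  rest <- comp[lab[comp] == 0L]
  rest <- rest[order(values[rest], decreasing = TRUE)]
  while (length(rest)) {
    assigned <- logical(length(rest))
    for (j in seq_along(rest)) {
      p <- rest[j]
      r <- ((p - 1L) %% h) + 1L
      cl <- ((p - 1L) %/% h) + 1L
      best <- 0L; bestv <- -Inf
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0L && dc == 0L) next
        rr <- r + dr; cc <- cl + dc
        if (rr < 1L || rr > h || cc < 1L || cc > w) next
        q <- (cc - 1L) * h + rr
        if (lab[q] > 0L && values[q] > bestv) { bestv <- values[q]; best <- lab[q] }
      }
      if (best > 0L) { lab[p] <- best; assigned[j] <- TRUE }
    }
    if (!any(assigned)) {  # isolated plateau: attach to first seed
      lab[rest] <- 1L
      break
    }
    rest <- rest[!assigned]
  }
  split(comp, lab[comp])
}

#' Find event candidates in a filtered frame
#'
#' Binarises the filtered frame at the threshold, labels 8-connected
#' components, optionally splits components containing several regional
#' maxima with a marker-based watershed on the filtered intensities, and
#' reports one candidate per region at its intensity-weighted centroid
#' rounded to the containing pixel (ties round toward the smaller index).
#'
#' @param filtered Wavelet-filtered frame.
#' @param threshold Detection threshold (`>= 0`), e.g. from
#'   [detection_threshold()].
#' @param use_watershed Split merged components at their regional maxima?
#' @return Data frame with integer pixel coordinates `cx`, `cy` (zero-based),
#'   `peak_value` (maximum filtered value in the region) and `n_px` (region
#'   size).
#' @export
find_candidates <- function(filtered, threshold, use_watershed = TRUE) {
  stopifnot(is.matrix(filtered), threshold >= 0)
  h <- nrow(filtered); w <- ncol(filtered)
  lab <- label_components(filtered >= threshold)
  ncomp <- max(lab)
  if (ncomp == 0L)
    return(data.frame(cx = integer(0), cy = integer(0),
                      peak_value = numeric(0), n_px = integer(0)))
  comp_idx <- split(which(lab > 0L), lab[lab > 0L])
  regions <- list()
  for (comp in comp_idx) {
    if (use_watershed && length(comp) > 1L) {
      seeds <- regional_maxima(filtered, comp, h, w)
      if (length(seeds) > 1L) {
        regions <- c(regions, watershed_split(filtered, comp, seeds, h, w))
        next
      }
    }
    regions[[length(regions) + 1L]] <- comp
  }
  n <- length(regions)
  cx <- integer(n); cy <- integer(n); pk <- numeric(n); np <- integer(n)
  for (i in seq_len(n)) {
    comp <- regions[[i]]
    v <- filtered[comp]
    if (sum(v) <= 0) v <- rep(1, length(comp))
    x <- ((comp - 1L) %/% h) + 0.5       # pixel-centre x (zero-based + 0.5)
    y <- ((comp - 1L) %% h) + 0.5
    xc <- sum(v * x) / sum(v)
    yc <- sum(v * y) / sum(v)
    cx[i] <- min(max(as.integer(ceiling(xc) - 1L), 0L), w - 1L)
    cy[i] <- min(max(as.integer(ceiling(yc) - 1L), 0L), h - 1L)
    pk[i] <- max(filtered[comp])
    np[i] <- length(comp)
  }
  data.frame(cx = cx, cy = cy, peak_value = pk, n_px = np)
}
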