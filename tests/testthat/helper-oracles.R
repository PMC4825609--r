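# Independent dense-convolution oracle: explicit symmetric padding and a
# direct 2-d kernel sum — no separability shortcut, no shared code with the
# implementation.
ref_conv2 <- function(img, k) {
  p <- (length(k) - 1L) %/% 2L
  h <- nrow(img); w <- ncol(img)
  ridx <- c(p:1, 1:h, h:(h - p + 1L))
  cidx <- c(p:1, 1:w, w:(w - p + 1L))
  pad <- img[ridx, cidx, drop = FALSE]
  K <- outer(k, k)
  out <- matrix(0, h, w)
  for (i in seq_along(k)) for (j in seq_along(k))
    out <- out + K[i, j] * pad[(i):(i + h - 1L), (j):(j + w - 1L)]
  out
}

# A-trous first wavelet plane, cascade form, from the dense oracle.
ref_wavelet_f1 <- function(img, order = 3, scale = 2) {
  k1 <- bspline_kernel(order, scale)
  k2 <- numeric((length(k1) - 1L) * 2L + 1L)
  k2[seq(1L, length(k2), 2L)] <- k1
  v0 <- ref_conv2(img, k1)
  v0 - ref_conv2(v0, k2)
}
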