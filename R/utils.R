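# Internal helpers: condition constructors, 2-D convolution, mask erosion.

abort <- function(message, class) {
  stop(structure(
    class = c(class, "eqctta_error", "error", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

warn <- function(message, class) {
  warning(structure(
    class = c(class, "eqctta_warning", "warning", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

#' @noRd
is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

# Mirror-pad a matrix by (rr, rc) pixels on each side. Mirroring is
# edge-exclusive would need rr < n; the reflected index sequence repeats the
# border row, the standard "reflect" convention.
mirror_pad <- function(img, rr, rc) {
  n <- nrow(img)
  m <- ncol(img)
  if (rr >= n || rc >= m) {
    abort("kernel half-width exceeds image size; image too small for this SSF",
          "eqctta_geometry_error")
  }
  pr <- c(rev(seq_len(rr)), seq_len(n), n + 1L - seq_len(rr))
  pc <- c(rev(seq_len(rc)), seq_len(m), m + 1L - seq_len(rc))
  img[pr, pc, drop = FALSE]
}

# Full 2-D convolution with mirror boundary handling, implemented as a sum of
# kernel-weighted shifted copies (vectorised over the image, looped over the
# kernel). Kernels here are even in both axes so convolution == correlation.
conv2_mirror <- function(img, kernel) {
  rr <- (nrow(kernel) - 1L) %/% 2L
  rc <- (ncol(kernel) - 1L) %/% 2L
  n <- nrow(img)
  m <- ncol(img)
  padded <- mirror_pad(img, rr, rc)
  out <- matrix(0, n, m)
  for (a in seq_len(nrow(kernel))) {
    for (b in seq_len(ncol(kernel))) {
      w <- kernel[a, b]
      if (w == 0) next
      out <- out + w * padded[a + 0:(n - 1L), b + 0:(m - 1L), drop = FALSE]
    }
  }
  out
}

# Binary erosion with a (2*rr+1) x (2*rc+1) rectangular structuring element.
# Pixels beyond the image border count as background, so a mask touching the
# border erodes there too.
erode_mask <- function(mask, rr, rc) {
  if (rr == 0L && rc == 0L) {
    return(mask)
  }
  n <- nrow(mask)
  m <- ncol(mask)
  padded <- matrix(FALSE, n + 2L * rr, m + 2L * rc)
  padded[rr + seq_len(n), rc + seq_len(m)] <- mask
  out <- matrix(TRUE, n, m)
  for (a in 0:(2L * rr)) {
    for (b in 0:(2L * rc)) {
      out <- out & padded[a + seq_len(n), b + seq_len(m)]
    }
  }
  out
}

# Gaussian-smoothed white noise, rescaled to unit standard deviation; the
# parenchymal mottle texture of the phantom generator. Mirror boundary,
# separable 1-D passes, truncation at 3 sigma.
smooth_noise_field <- function(n, m, sigma_px) {
  z <- matrix(stats::rnorm(n * m), n, m)
  if (sigma_px <= 0) {
    return(z)
  }
  r <- max(1L, ceiling(3 * sigma_px))
  g <- stats::dnorm(-r:r, sd = sigma_px)
  g <- g / sum(g)
  zp <- z[c(rev(seq_len(r)), seq_len(n), n + 1L - seq_len(r)), , drop = FALSE]
  s1 <- matrix(0, n, m)
  for (a in seq_along(g)) s1 <- s1 + g[a] * zp[a + 0:(n - 1L), , drop = FALSE]
  sp <- s1[, c(rev(seq_len(r)), seq_len(m), m + 1L - seq_len(r)), drop = FALSE]
  s2 <- matrix(0, n, m)
  for (a in seq_along(g)) s2 <- s2 + g[a] * sp[, a + 0:(m - 1L), drop = FALSE]
  s2 / stats::sd(as.vector(s2))
}
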