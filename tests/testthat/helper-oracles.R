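# Independent oracles, coded from raw definitions with no shared package
# code paths.

# Six histogram statistics from first principles (moments via explicit sums,
# skewness/kurtosis cross-checked against e1071 type-1 in tests, entropy via
# explicit bin indexing + table()).
oracle_metrics <- function(v, bins = 256L) {
  n <- length(v)
  mu <- sum(v) / n
  m2 <- sum((v - mu)^2) / n
  m3 <- sum((v - mu)^3) / n
  m4 <- sum((v - mu)^4) / n
  pos <- v[v > 0]
  mpp <- if (length(pos)) sum(pos) / length(pos) else 0
  if (m2 == 0) {
    return(list(mean = mu, sd = 0, entropy = 0, mpp = mpp,
                skewness = 0, kurtosis = 0))
  }
  mn <- min(v)
  mx <- max(v)
  idx <- as.integer((v - mn) / (mx - mn) * bins) + 1L
  idx[idx > bins] <- bins
  p <- as.numeric(table(idx)) / n
  list(mean = mu, sd = sqrt(m2),
       entropy = -sum(p * log2(p)),
       mpp = mpp,
       skewness = m3 / m2^1.5,
       kurtosis = m4 / m2^2 - 3)
}

# Direct-summation 2-D convolution with mirror boundary: O(n^2 k^2) loops,
# explicit index reflection. Reference for filter_slice on small images.
oracle_conv2 <- function(img, k) {
  reflect <- function(i, n) {
    if (i < 1L) 1L - i else if (i > n) 2L * n + 1L - i else i
  }
  n <- nrow(img)
  m <- ncol(img)
  rr <- (nrow(k) - 1L) %/% 2L
  rc <- (ncol(k) - 1L) %/% 2L
  out <- matrix(0, n, m)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      acc <- 0
      for (a in -rr:rr) {
        for (b in -rc:rc) {
          acc <- acc + k[a + rr + 1L, b + rc + 1L] *
            img[reflect(i + a, n), reflect(j + b, m)]
        }
      }
      out[i, j] <- acc
    }
  }
  out
}

# Spearman r_s from midranks computed by counting (no rank()), plus the
# two-sided t-approximation p-value written out longhand.
oracle_spearman <- function(x, y) {
  n <- length(x)
  midrank <- function(v) {
    sapply(seq_len(n), function(i) sum(v < v[i]) + (sum(v == v[i]) + 1) / 2)
  }
  rx <- midrank(x)
  ry <- midrank(y)
  mx <- sum(rx) / n
  my <- sum(ry) / n
  r <- sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  list(r_s = r, p_value = 2 * pt(-abs(tstat), n - 2))
}

# Small slice/mask constructors for tests.
make_slice <- function(pixels, spacing = c(1, 1), phase = "pre", id = "t") {
  ct_slice(pixels, spacing, phase = phase, patient_id = id)
}

make_map <- function(values_matrix, ssf = 0, spacing = c(1, 1), phase = "pre",
                     id = "t") {
  # filtered_map carrying arbitrary values: route through filter_slice at
  # SSF 0 (identity) after clamping into HU range is not possible for
  # arbitrary values, so construct the structure directly.
  structure(list(pixels = values_matrix, ssf_mm = ssf, spacing_mm = spacing,
                 phase = phase, patient_id = id, slice_label = "t"),
            class = "filtered_map")
}

full_mask <- function(map_or_slice, region = "whole_liver") {
  px <- map_or_slice$pixels
  sl <- if (inherits(map_or_slice, "ct_slice")) map_or_slice else
    ct_slice(matrix(0, nrow(px), ncol(px)), map_or_slice$spacing_mm,
             phase = "pre", patient_id = map_or_slice$patient_id)
  roi_mask(matrix(TRUE, nrow(px), ncol(px)), region, sl)
}
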