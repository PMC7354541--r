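# Histogram-based quantification of a filtered map inside an ROI: the six
# filtration-histogram statistics at each SSF value.

texture_metric_names <- c("mean", "sd", "entropy", "mpp", "skewness", "kurtosis")

#' Compute the six texture statistics of a filtered map inside an ROI
#'
#' Over the pixel values sampled from the (optionally eroded) mask:
#'
#' * `mean` - arithmetic mean,
#' * `sd` - population standard deviation (divisor n),
#' * `entropy` - Shannon entropy in bits of the `bins`-bin equal-width
#'   histogram spanning the observed min-max (0 log 0 := 0; a constant
#'   region has entropy 0),
#' * `mpp` - mean of the strictly positive pixels (0 with a
#'   `no_positive_pixels` flag if none, so feature tables stay rectangular),
#' * `skewness` - Fisher-Pearson g1 = m3 / m2^1.5,
#' * `kurtosis` - excess g2 = m4 / m2^2 - 3 (set `excess = FALSE` for raw
#'   m4 / m2^2).
#'
#' A zero-variance region returns skewness = kurtosis = 0 with a
#' `zero_variance` flag. By default the mask is eroded by `ceil(2 sigma)`
#' pixels per axis at the map's SSF before sampling, suppressing ROI-edge
#' ring artefacts of the band-pass filter.
#'
#' @param map a `filtered_map` (SSF 0 gives the raw-HU control statistics).
#' @param mask a `roi_mask` on the same lattice.
#' @param erode erode the mask by `ceil(2 sigma)` pixels before sampling?
#' @param bins histogram bin count for the entropy estimate.
#' @param min_pixels minimum sampled pixel count; fewer is a sampling error
#'   (higher moments are unstable on small samples).
#' @param excess report kurtosis as excess (Gaussian -> 0)?
#' @return A `texture_vector`: the six statistics plus `n_pixels` and a
#'   character vector of degeneracy flags.
#' @export
compute_metrics <- function(map, mask, erode = TRUE, bins = 256L,
                            min_pixels = 50L, excess = TRUE) {
  stopifnot(inherits(map, "filtered_map"), inherits(mask, "roi_mask"))
  if (!identical(mask$ref_dim, dim(map$pixels))) {
    abort("mask lattice does not match the filtered map", "eqctta_geometry_error")
  }
  m <- mask$mask
  if (erode) {
    rad <- erosion_radii(map$ssf_mm, map$spacing_mm)
    m <- erode_mask(m, rad[1], rad[2])
    if (!any(m)) {
      abort("mask is empty after erosion", "eqctta_geometry_error")
    }
  }
  v <- map$pixels[m]
  if (length(v) < min_pixels) {
    abort(sprintf("only %d pixels sampled (minimum %d)", length(v), min_pixels),
          "eqctta_sampling_error")
  }
  flags <- character(0)
  mu <- mean(v)
  m2 <- mean((v - mu)^2)
  sdv <- sqrt(m2)
  pos <- v[v > 0]
  if (length(pos) == 0L) {
    mpp <- 0
    flags <- c(flags, "no_positive_pixels")
  } else {
    mpp <- mean(pos)
  }
  if (m2 == 0) {
    skew <- 0
    kurt <- 0
    ent <- 0
    flags <- c(flags, "zero_variance")
  } else {
    skew <- mean((v - mu)^3) / m2^1.5
    kurt <- mean((v - mu)^4) / m2^2 - if (excess) 3 else 0
    ent <- shannon_entropy_bits(v, bins)
  }
  structure(
    list(ssf_mm = map$ssf_mm, region = mask$region, phase = map$phase,
         patient_id = map$patient_id,
         mean = mu, sd = sdv, entropy = ent, mpp = mpp,
         skewness = skew, kurtosis = kurt,
         n_pixels = length(v), flags = flags),
    class = "texture_vector"
  )
}

# Shannon entropy (bits) of the equal-width histogram over [min(v), max(v)].
# The top edge closes the last bin so max(v) lands in bin `bins`.
shannon_entropy_bits <- function(v, bins) {
  rng <- range(v)
  idx <- floor((v - rng[1]) / (rng[2] - rng[1]) * bins) + 1
  idx[idx > bins] <- bins
  p <- tabulate(idx, nbins = bins)
  p <- p[p > 0] / length(v)
  -sum(p * log2(p))
}

#' @export
print.texture_vector <- function(x, ...) {
  cat(sprintf(
    "<texture_vector> %s %s/%s SSF %.3g mm (n=%d)%s\n",
    x$patient_id, x$region, x$phase, x$ssf_mm, x$n_pixels,
    if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]") else ""))
  print(round(unlist(x[texture_metric_names]), 4))
  invisible(x)
}

#' @export
as.data.frame.texture_vector <- function(x, ...) {
  data.frame(patient_id = x$patient_id, region = x$region, phase = x$phase,
             ssf_mm = x$ssf_mm,
             metric = texture_metric_names,
             value = unlist(x[texture_metric_names], use.names = FALSE),
             flags = paste(x$flags, collapse = ";"),
             stringsAsFactors = FALSE)
}

#' Equilibrium-minus-pre subtraction features
#'
#' Metric-wise difference (EQ minus pre) of two texture vectors computed at
#' the same SSF and region; the subtracted-enhancement features highlight
#' contrast taken up by the hepatic interstitium. Degeneracy flags are
#' unioned; the result's phase is `"diff"`.
#'
#' @param eq,pre `texture_vector`s with phases `"eq"` and `"pre"`.
#' @return A `texture_vector` with phase `"diff"`.
#' @export
subtract_features <- function(eq, pre) {
  stopifnot(inherits(eq, "texture_vector"), inherits(pre, "texture_vector"))
  if (!identical(eq$ssf_mm, pre$ssf_mm) || !identical(eq$region, pre$region)) {
    abort("texture vectors differ in SSF or region; cannot pair for subtraction",
          "eqctta_pairing_error")
  }
  if (!setequal(c(eq$phase, pre$phase), c("eq", "pre"))) {
    abort("subtract_features expects one eq-phase and one pre-phase vector",
          "eqctta_pairing_error")
  }
  out <- eq
  for (nm in texture_metric_names) out[[nm]] <- eq[[nm]] - pre[[nm]]
  out$phase <- "diff"
  out$n_pixels <- min(eq$n_pixels, pre$n_pixels)
  out$flags <- union(eq$flags, pre$flags)
  out
}
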