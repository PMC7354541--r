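# Synthetic phantom cohorts: paired pre/equilibrium CT slices, ROI masks and
# clinical markers with the statistical structure the analysis assumes, so
# every pipeline stage is testable without any clinical download.

#' Phantom generator parameters
#'
#' Returns the full parameter set of the synthetic liver phantom with its
#' defaults. The phantom is a liver disc with parenchymal background,
#' Gaussian fibrotic blobs whose density grows with a severity parameter
#' `s` in \[0, 1\], hepatocyte mottle, dark vessels (bright at equilibrium),
#' an aorta disc, and an equilibrium enhancement field whose whole-liver ROI
#' mean is pinned exactly to `ecv_true * delta_hu_blood / (1 - haematocrit)`
#' so the ECV partition relation holds by construction. Enhancement is split
#' between a uniform component, an interstitial component painted on the
#' blobs, and a subcapsular rim (fibrosis with peripheral predominance);
#' the split is what lets the equilibrium-minus-pre mean at medium texture
#' scales carry the severity signal through a zero-DC band-pass filter.
#'
#' Clinical markers are monotone noisy links from severity:
#' `elf = 8 + 4 s + N(0, 0.4)`, `cpa = max(0, 2 + 25 s + N(0, 2))`,
#' `ishak = round(6 s + N(0, 0.6))` clamped to \[0, 6\], and
#' `haematocrit ~ N(0.42, 0.03)` truncated to \[0.30, 0.55\].
#'
#' `hepatocyte_loss = TRUE` switches to a mode emulating background
#' hepatocyte loss dominating the pre-contrast signal in advancing fibrosis:
#' the mottle becomes coarser and stronger and fades with severity
#' (`mottle_sd_hu * (1 - loss_rate * s)`), while pre-contrast collagen is
#' nearly isodense (small blob amplitude). This plants a negative
#' coarse-scale SD / entropy / MPP link with severity; it is a modelling
#' hypothesis, not a clinical result.
#'
#' @param severity severity `s` in \[0, 1\].
#' @param seed integer seed for all randomness of one phantom.
#' @param grid_n image side length in pixels.
#' @param spacing_mm mm per pixel (row, col).
#' @param n_sections contiguous sections generated per phase (same anatomy,
#'   independent noise); ECV ROI means are averaged across them.
#' @param hepatocyte_loss switch to the hepatocyte-loss texture mode.
#' @param ... overrides for any parameter listed below.
#' @return A named list of class `phantom_params`.
#' @export
phantom_params <- function(severity = 0.5, seed = 1L, grid_n = 96L,
                           spacing_mm = c(1, 1), n_sections = 3L,
                           hepatocyte_loss = FALSE, ...) {
  p <- list(
    severity = severity, seed = as.integer(seed), grid_n = as.integer(grid_n),
    spacing_mm = if (length(spacing_mm) == 1L) rep(spacing_mm, 2L) else spacing_mm,
    n_sections = as.integer(n_sections),
    hepatocyte_loss = isTRUE(hepatocyte_loss),
    # geometry (mm)
    liver_center_mm = c(48, 44), liver_radius_mm = 40,
    wedge_r_frac = c(0.6, 1.0), wedge_half_angle_deg = 50,
    aorta_center_mm = c(20, 86), aorta_radius_mm = 7,
    vessel_count = 3L, vessel_radius_mm = 2.5, vessel_hu = 45,
    # tissue
    parenchyma_mu_hu = 55, background_hu = 20, noise_sd_hu = 10,
    mottle_sd_hu = 8, mottle_scale_mm = 1.5, loss_rate = 0,
    # fibrotic features
    feature_diameter_mm = 4, blob_amplitude_hu = 12,
    feature_density_base = 0.5, feature_density_gain = 4,  # per cm^2
    # enhancement / ECV
    ecv0 = 0.22, ecv_gain = 0.15, delta_hu_blood = 40,
    hct_mean = 0.42, hct_sd = 0.03, hct_bounds = c(0.30, 0.55),
    interstitial_fraction = 0.15, rim_fraction = 0.50,
    rim_depth_mm = 5, rim_scale_mm = 1.5,
    # marker links
    elf0 = 8, elf_gain = 4, elf_sd = 0.4,
    cpa0 = 2, cpa_gain = 25, cpa_sd = 2,
    ishak_sd = 0.6,
    patient_id = "phantom"
  )
  if (p$hepatocyte_loss) {
    # pre-contrast collagen nearly isodense; coarse hepatocyte mottle fades
    p$mottle_sd_hu <- 12
    p$mottle_scale_mm <- 2.5
    p$loss_rate <- 0.8
    p$blob_amplitude_hu <- 6
  }
  dots <- list(...)
  unknown <- setdiff(names(dots), names(p))
  if (length(unknown) > 0L) {
    abort(sprintf("unknown phantom parameter(s): %s",
                  paste(unknown, collapse = ", ")), "eqctta_parameter_error")
  }
  p[names(dots)] <- dots
  if (p$severity < 0 || p$severity > 1) {
    abort("severity must be in [0, 1]", "eqctta_parameter_error")
  }
  ecv_max <- p$ecv0 + p$ecv_gain
  if (p$ecv0 <= 0 || ecv_max >= 1) {
    abort("ecv_true must stay inside (0, 1)", "eqctta_parameter_error")
  }
  if (p$delta_hu_blood <= 0 || p$noise_sd_hu < 0 || p$blob_amplitude_hu < 0 ||
      p$feature_density_base < 0 || p$feature_density_gain < 0) {
    abort("rates and amplitudes must be non-negative", "eqctta_parameter_error")
  }
  class(p) <- "phantom_params"
  p
}

#' Generate one phantom patient
#'
#' Builds the pre-contrast and equilibrium slice pair (plus extra contiguous
#' sections for ECV averaging), the three ROI masks and the clinical marker
#' draws for a single synthetic patient. All randomness is governed by
#' `params$seed`; two calls with the same parameters are bitwise identical.
#'
#' @param params a [phantom_params()] object.
#' @return A list: `pre`, `eq` (designated texture slices, `ct_slice`),
#'   `pre_sections`, `eq_sections` (lists of `ct_slice`), `masks` (named
#'   list of `roi_mask`: whole_liver, segment7, aorta), `record` (one-row
#'   clinical data.frame) and `truth` (severity, ecv_true, enhancement
#'   target, blob count).
#' @export
generate_phantom <- function(params = phantom_params()) {
  stopifnot(inherits(params, "phantom_params"))
  p <- params
  set.seed(p$seed)
  n <- p$grid_n
  sp <- p$spacing_mm
  s <- p$severity

  rowmm <- matrix((seq_len(n) - 0.5) * sp[1], n, n)
  colmm <- t(matrix((seq_len(n) - 0.5) * sp[2], n, n))
  dxr <- rowmm - p$liver_center_mm[1]
  dxc <- colmm - p$liver_center_mm[2]
  r <- sqrt(dxr^2 + dxc^2)
  liver <- r <= p$liver_radius_mm
  theta <- atan2(dxc, dxr) * 180 / pi
  wedge <- liver & r >= p$wedge_r_frac[1] * p$liver_radius_mm &
    abs(theta) <= p$wedge_half_angle_deg
  aorta <- sqrt((rowmm - p$aorta_center_mm[1])^2 +
                (colmm - p$aorta_center_mm[2])^2) <= p$aorta_radius_mm
  if (any(aorta & liver)) {
    abort("aorta and liver regions overlap; adjust geometry",
          "eqctta_parameter_error")
  }

  # vessels: dark discs in the parenchyma, excluded from the liver masks.
  # The wedge ROI is drawn to avoid visible vessels, so vessel centres are
  # rejected within a safety margin of the wedge sector (their equilibrium
  # brightening would otherwise leak into the subtracted features).
  vessels <- matrix(FALSE, n, n)
  nv <- p$vessel_count
  if (nv > 0L) {
    margin <- 4 * p$vessel_radius_mm
    near_wedge <- function(r_c, th_deg) {
      r_c > p$wedge_r_frac[1] * p$liver_radius_mm - margin &&
        abs(th_deg) <= p$wedge_half_angle_deg +
          asin(min(1, margin / max(r_c, 1e-6))) * 180 / pi
    }
    placed <- 0L
    tries <- 0L
    while (placed < nv && tries < 200L) {
      tries <- tries + 1L
      r_c <- 0.75 * p$liver_radius_mm * sqrt(stats::runif(1))
      th <- stats::runif(1, 0, 2 * pi)
      th_deg <- ((th * 180 / pi + 180) %% 360) - 180
      if (near_wedge(r_c, th_deg)) next
      vc <- p$liver_center_mm + r_c * c(cos(th), sin(th))
      vessels <- vessels |
        (sqrt((rowmm - vc[1])^2 + (colmm - vc[2])^2) <= p$vessel_radius_mm)
      placed <- placed + 1L
    }
    vessels <- vessels & liver
  }
  whole_liver <- liver & !vessels
  segment7 <- wedge & !vessels

  # fibrotic blobs: Poisson count from an areal density that grows with s
  sigma_b <- p$feature_diameter_mm / (2 * sqrt(2))
  area_cm2 <- sum(liver) * sp[1] * sp[2] / 100
  lambda <- (p$feature_density_base + p$feature_density_gain * s) * area_cm2
  n_blobs <- stats::rpois(1L, lambda)
  blob_field <- matrix(0, n, n)
  blob_centers <- matrix(numeric(0), 0L, 2L)
  if (n_blobs > 0L) {
    br <- p$liver_radius_mm * sqrt(stats::runif(n_blobs))
    bth <- stats::runif(n_blobs, 0, 2 * pi)
    cut2 <- (4 * sigma_b)^2
    blob_centers <- cbind(p$liver_center_mm[1] + br * cos(bth),
                          p$liver_center_mm[2] + br * sin(bth))
    for (i in seq_len(n_blobs)) {
      d2 <- (rowmm - blob_centers[i, 1])^2 + (colmm - blob_centers[i, 2])^2
      w <- d2 < cut2
      blob_field[w] <- blob_field[w] + exp(-d2[w] / (2 * sigma_b^2))
    }
  }

  hct <- min(p$hct_bounds[2],
             max(p$hct_bounds[1], stats::rnorm(1, p$hct_mean, p$hct_sd)))
  ecv_true <- p$ecv0 + p$ecv_gain * s
  enh_target <- ecv_true * p$delta_hu_blood / (1 - hct)

  mottle_amp <- p$mottle_sd_hu * (1 - p$loss_rate * s)
  mottle <- if (mottle_amp > 0) {
    smooth_noise_field(n, n, p$mottle_scale_mm / mean(sp)) * mottle_amp
  } else {
    matrix(0, n, n)
  }

  pre_det <- matrix(p$background_hu, n, n)
  pre_det[liver] <- p$parenchyma_mu_hu + mottle[liver] +
    p$blob_amplitude_hu * blob_field[liver]
  pre_det[vessels] <- p$vessel_hu
  pre_det[aorta] <- p$vessel_hu

  # enhancement field: uniform + interstitial (blob-borne) + subcapsular rim,
  # normalised so the whole-liver ROI mean equals enh_target exactly
  depth <- pmax(p$liver_radius_mm - r, 0)
  rim <- exp(-(depth - p$rim_depth_mm)^2 / (2 * p$rim_scale_mm^2))
  rim[!liver] <- 0
  f_i <- p$interstitial_fraction
  f_r <- p$rim_fraction
  if (f_i < 0 || f_r < 0 || f_i + f_r > 1) {
    abort("interstitial_fraction and rim_fraction must be >= 0 and sum <= 1",
          "eqctta_parameter_error")
  }
  blob_norm <- if (mean(blob_field[whole_liver]) > 0) {
    blob_field / mean(blob_field[whole_liver])
  } else {
    matrix(1, n, n)  # no blobs: interstitial share falls back to uniform
  }
  rim_norm <- rim / mean(rim[whole_liver])
  enh <- matrix(0, n, n)
  enh[liver] <- enh_target * ((1 - f_i - f_r) + f_i * blob_norm[liver] +
                              f_r * rim_norm[liver])
  eq_det <- pre_det + enh
  eq_det[vessels] <- p$vessel_hu + p$delta_hu_blood
  eq_det[aorta] <- p$vessel_hu + p$delta_hu_blood
  if (max(eq_det) > 3071 || min(eq_det) < -1024) {
    abort("enhancement drives HU outside the valid range; check parameters",
          "eqctta_parameter_error")
  }

  mk_sections <- function(det, phase) {
    lapply(seq_len(p$n_sections), function(k) {
      ct_slice(det + matrix(stats::rnorm(n * n, 0, p$noise_sd_hu), n, n),
               sp, phase = phase, patient_id = p$patient_id,
               slice_label = if (k == 1L) "hepatic_porta"
                             else sprintf("hepatic_porta+%d", k - 1L))
    })
  }
  pre_sections <- mk_sections(pre_det, "pre")
  eq_sections <- mk_sections(eq_det, "eq")
  ref <- eq_sections[[1L]]

  masks <- list(
    whole_liver = roi_mask(whole_liver, "whole_liver", ref),
    segment7 = roi_mask(segment7, "segment7", ref),
    aorta = roi_mask(aorta, "aorta", ref)
  )

  record <- data.frame(
    patient_id = p$patient_id,
    haematocrit = hct,
    cpa_percent = max(0, p$cpa0 + p$cpa_gain * s + stats::rnorm(1, 0, p$cpa_sd)),
    elf = p$elf0 + p$elf_gain * s + stats::rnorm(1, 0, p$elf_sd),
    ishak = min(6L, max(0L, as.integer(round(6 * s + stats::rnorm(1, 0, p$ishak_sd))))),
    stringsAsFactors = FALSE
  )

  list(pre = pre_sections[[1L]], eq = eq_sections[[1L]],
       pre_sections = pre_sections, eq_sections = eq_sections,
       masks = masks, record = record,
       truth = list(severity = s, ecv_true = ecv_true,
                    enh_target = enh_target, n_blobs = n_blobs,
                    blob_centers_mm = blob_centers, haematocrit = hct))
}

#' Simulate a phantom cohort and write it to disk
#'
#' Generates `n` phantom patients with severities drawn from
#' `severity_sampler`, writes per-patient NIfTI images (one multi-section
#' file per phase) and mask files, a manifest CSV and a clinical CSV.
#' `eq_missing_fraction` drops the equilibrium phase for a deterministic
#' subset of patients (partial phase availability is the norm in practice).
#' Per-patient seeds are derived deterministically from `seed`.
#'
#' @param n number of patients (>= 2).
#' @param out_dir output directory (created if needed).
#' @param seed master seed.
#' @param params base [phantom_params()] (severity/seed/patient_id fields are
#'   overwritten per patient).
#' @param severity_sampler function of `n` returning `n` severities in \[0, 1\].
#' @param eq_missing_fraction fraction of patients without equilibrium data.
#' @return Invisibly, a list with `manifest` and `clinical` data.frames and
#'   the file paths written.
#' @export
simulate_cohort <- function(n, out_dir, seed = 1L, params = phantom_params(),
                            severity_sampler = stats::runif,
                            eq_missing_fraction = 0) {
  if (n < 2L) {
    abort("cohort needs at least 2 patients", "eqctta_parameter_error")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  severities <- severity_sampler(n)
  patient_seeds <- sample.int(.Machine$integer.max - 1L, n)
  n_missing <- round(eq_missing_fraction * n)
  eq_missing <- rep(FALSE, n)
  if (n_missing > 0L) eq_missing[sample.int(n, n_missing)] <- TRUE

  ids <- sprintf("p%03d", seq_len(n))
  manifest <- data.frame(
    patient_id = ids, pre_path = NA_character_, eq_path = NA_character_,
    whole_liver_path = NA_character_, segment7_path = NA_character_,
    aorta_path = NA_character_, stringsAsFactors = FALSE)
  clinical <- NULL
  for (i in seq_len(n)) {
    pi <- params
    pi$severity <- severities[i]
    pi$seed <- patient_seeds[i]
    pi$patient_id <- ids[i]
    ph <- generate_phantom(pi)
    pre_path <- file.path(out_dir, paste0(ids[i], "_pre.nii.gz"))
    write_ct_slice(ph$pre_sections, pre_path)
    manifest$pre_path[i] <- pre_path
    if (!eq_missing[i]) {
      eq_path <- file.path(out_dir, paste0(ids[i], "_eq.nii.gz"))
      write_ct_slice(ph$eq_sections, eq_path)
      manifest$eq_path[i] <- eq_path
    }
    for (rg in names(ph$masks)) {
      mp <- file.path(out_dir, paste0(ids[i], "_mask_", rg, ".nii.gz"))
      write_roi_mask(ph$masks[[rg]], mp)
      manifest[[paste0(rg, "_path")]][i] <- mp
    }
    clinical <- rbind(clinical, ph$record)
  }
  manifest_path <- file.path(out_dir, "manifest.csv")
  clinical_path <- file.path(out_dir, "clinical.csv")
  utils::write.csv(manifest, manifest_path, row.names = FALSE)
  utils::write.csv(clinical, clinical_path, row.names = FALSE)
  invisible(list(manifest = manifest, clinical = clinical,
                 manifest_path = manifest_path, clinical_path = clinical_path,
                 out_dir = out_dir))
}
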