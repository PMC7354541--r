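# Liver extracellular volume fraction from pre/equilibrium ROI mean
# attenuations and haematocrit.

#' Mean HU over an ROI
#'
#' Plain arithmetic mean of the HU values under the mask, mirroring the
#' clinical ROI measurement: no erosion (erosion belongs to texture
#' sampling, not attenuation measurement).
#'
#' @param slice a `ct_slice`.
#' @param mask a `roi_mask` on the same lattice.
#' @return The mean HU, a single number.
#' @export
roi_mean_hu <- function(slice, mask) {
  stopifnot(inherits(slice, "ct_slice"), inherits(mask, "roi_mask"))
  if (!identical(mask$ref_dim, dim(slice$pixels))) {
    abort("mask lattice does not match slice", "eqctta_geometry_error")
  }
  if (!any(mask$mask)) {
    abort("empty mask", "eqctta_geometry_error")
  }
  mean(slice$pixels[mask$mask])
}

#' Extracellular volume fraction from paired ROI attenuations
#'
#' Implements the equilibrium partition relation
#' `ECV = (1 - haematocrit) * dHU_liver / dHU_blood`, where each dHU is the
#' equilibrium-minus-pre change in mean ROI attenuation (liver parenchyma
#' and blood pool / aorta). Iodinated contrast distributes over plasma and
#' interstitium; substituting the plasma volume `1 - haematocrit` converts
#' the tissue:blood partition coefficient into the tissue extracellular
#' volume fraction, which expands with fibrosis.
#'
#' A non-positive blood enhancement means equilibrium was not reached or the
#' ROIs are mixed up, and is an error. An ECV outside \[0, 1\] is returned
#' with an `ecv_out_of_range` flag (and warning), never clipped.
#' Haematocrit given on the percent scale (values in \[1, 100\]) is
#' converted to a fraction with a message.
#'
#' @param pre_liver,eq_liver mean liver HU, pre-contrast and equilibrium.
#' @param pre_blood,eq_blood mean blood-pool (aorta) HU for the same phases.
#' @param haematocrit haematocrit as a fraction in (0, 1) (or percent).
#' @param patient_id identifier carried into the result.
#' @return An `ecv_result`: `ecv`, the two deltas, haematocrit and flags.
#' @export
compute_ecv <- function(pre_liver, eq_liver, pre_blood, eq_blood, haematocrit,
                        patient_id = "unknown") {
  for (v in list(pre_liver, eq_liver, pre_blood, eq_blood, haematocrit)) {
    if (!is_scalar_number(v)) {
      abort("all inputs must be single finite numbers", "eqctta_data_error")
    }
  }
  if (haematocrit >= 1 && haematocrit <= 100) {
    message(sprintf("haematocrit %.3g interpreted as percent -> %.3g",
                    haematocrit, haematocrit / 100))
    haematocrit <- haematocrit / 100
  }
  if (haematocrit <= 0 || haematocrit >= 1) {
    abort("haematocrit must be a fraction in (0, 1)", "eqctta_data_error")
  }
  delta_liver <- eq_liver - pre_liver
  delta_blood <- eq_blood - pre_blood
  if (delta_blood <= 0) {
    abort("non-positive blood enhancement: equilibrium not reached or ROIs mixed up",
          "eqctta_enhancement_error")
  }
  ecv <- (1 - haematocrit) * delta_liver / delta_blood
  flags <- character(0)
  if (ecv < 0 || ecv > 1) {
    flags <- "ecv_out_of_range"
    warn(sprintf("ECV %.3f outside [0, 1] for %s", ecv, patient_id),
         "eqctta_ecv_range_warning")
  }
  structure(
    list(ecv = ecv, delta_hu_liver = delta_liver, delta_hu_blood = delta_blood,
         haematocrit = haematocrit, patient_id = as.character(patient_id),
         flags = flags),
    class = "ecv_result"
  )
}

#' @export
print.ecv_result <- function(x, ...) {
  cat(sprintf("<ecv_result> %s ECV = %.3f (dHU liver %.1f / blood %.1f, hct %.2f)%s\n",
              x$patient_id, x$ecv, x$delta_hu_liver, x$delta_hu_blood,
              x$haematocrit,
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]")
              else ""))
  invisible(x)
}

#' ECV from slice sections and masks
#'
#' Convenience wrapper measuring ROI means on each provided section per
#' phase, averaging them (the clinical protocol measures on three contiguous
#' sections), and applying [compute_ecv()].
#'
#' @param pre_sections,eq_sections lists of `ct_slice`s (>= 1 each).
#' @param liver_mask,aorta_mask `roi_mask`s on the shared lattice.
#' @param haematocrit haematocrit fraction.
#' @param patient_id identifier.
#' @return An `ecv_result`.
#' @export
ecv_from_slices <- function(pre_sections, eq_sections, liver_mask, aorta_mask,
                            haematocrit, patient_id = "unknown") {
  if (inherits(pre_sections, "ct_slice")) pre_sections <- list(pre_sections)
  if (inherits(eq_sections, "ct_slice")) eq_sections <- list(eq_sections)
  mean_over <- function(sections, mask) {
    mean(vapply(sections, roi_mean_hu, numeric(1), mask = mask))
  }
  compute_ecv(
    pre_liver = mean_over(pre_sections, liver_mask),
    eq_liver = mean_over(eq_sections, liver_mask),
    pre_blood = mean_over(pre_sections, aorta_mask),
    eq_blood = mean_over(eq_sections, aorta_mask),
    haematocrit = haematocrit, patient_id = patient_id
  )
}
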