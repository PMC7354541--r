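# Per-patient orchestration (regions x phases x SSFs) and cohort feature
# table assembly.

#' Extract every texture feature and ECV for one patient
#'
#' Runs the filtration-histogram pipeline over both liver ROIs, both phases
#' and every requested SSF value, computes equilibrium-minus-pre subtraction
#' features where both phases are present and registered, and the ECV when
#' both phases, an aorta mask and the haematocrit are available. Partial
#' data is first class: with only a pre-contrast slice the pre features are
#' still emitted and diff/ECV are skipped with a warning.
#'
#' @param pre pre-contrast `ct_slice` (the designated texture section).
#' @param eq equilibrium `ct_slice`, or `NULL` if unavailable.
#' @param masks named list of `roi_mask`s; `whole_liver` and/or `segment7`
#'   are used for texture, `aorta` for ECV.
#' @param record one-row data.frame with at least `patient_id`; a finite
#'   `haematocrit` enables ECV.
#' @param ssf_list SSF values in mm (0 = unfiltered control).
#' @param pre_sections,eq_sections optional lists of contiguous sections per
#'   phase; ROI means for ECV are averaged across them (texture always uses
#'   the designated slice).
#' @param diff_mode `"parameters"` subtracts the six statistics metric-wise
#'   (EQ minus pre); `"image"` filters the voxel-wise EQ-minus-pre image and
#'   computes statistics of that (off-spec alternative, off by default; the
#'   two agree exactly for the mean, by linearity).
#' @param erode,bins,min_pixels,excess passed to [compute_metrics()].
#' @param gamma kernel normalisation exponent, see [log_kernel()].
#' @return A list: `features` (long data.frame: patient_id, region, phase,
#'   ssf_mm, metric, value, flags) and `ecv` (an `ecv_result` or `NULL`).
#' @export
extract_patient <- function(pre, eq = NULL, masks, record = NULL,
                            ssf_list = c(0, 2, 3, 4, 5, 6),
                            pre_sections = NULL, eq_sections = NULL,
                            diff_mode = c("parameters", "image"),
                            erode = TRUE, bins = 256L, min_pixels = 50L,
                            excess = TRUE, gamma = 1.6) {
  diff_mode <- match.arg(diff_mode)
  stopifnot(inherits(pre, "ct_slice"))
  texture_regions <- intersect(c("whole_liver", "segment7"), names(masks))
  if (length(texture_regions) == 0L) {
    abort("need at least one liver mask (whole_liver or segment7)",
          "eqctta_input_error")
  }
  pid <- if (!is.null(record) && "patient_id" %in% names(record)) {
    as.character(record$patient_id[1])
  } else {
    pre$patient_id
  }

  have_eq <- !is.null(eq)
  if (have_eq && !check_registration(pre, eq)) {
    warn(sprintf("%s: pre/eq grids not registered; dropping equilibrium phase",
                 pid), "eqctta_registration_warning")
    eq <- NULL
    have_eq <- FALSE
  }

  rows <- list()
  add <- function(tv) {
    tv$patient_id <- pid
    rows[[length(rows) + 1L]] <<- as.data.frame(tv)
  }

  for (region in texture_regions) {
    mask_pre <- copy_roi(masks[[region]], pre)
    mask_eq <- if (have_eq) copy_roi(masks[[region]], eq) else NULL
    for (ssf in ssf_list) {
      fpre <- filter_slice(pre, ssf, gamma)
      tv_pre <- compute_metrics(fpre, mask_pre, erode = erode, bins = bins,
                                min_pixels = min_pixels, excess = excess)
      add(tv_pre)
      if (have_eq) {
        feq <- filter_slice(eq, ssf, gamma)
        tv_eq <- compute_metrics(feq, mask_eq, erode = erode, bins = bins,
                                 min_pixels = min_pixels, excess = excess)
        add(tv_eq)
        tv_diff <- if (diff_mode == "parameters") {
          subtract_features(tv_eq, tv_pre)
        } else {
          diff_of_images(pre, eq, ssf, mask_pre, gamma = gamma, erode = erode,
                         bins = bins, min_pixels = min_pixels, excess = excess)
        }
        add(tv_diff)
      }
    }
  }

  ecv <- NULL
  hct <- if (!is.null(record) && "haematocrit" %in% names(record)) {
    record$haematocrit[1]
  } else {
    NA_real_
  }
  if (have_eq && "aorta" %in% names(masks) && is.finite(hct)) {
    liver_region <- if ("whole_liver" %in% names(masks)) "whole_liver" else "segment7"
    pre_secs <- if (is.null(pre_sections)) list(pre) else pre_sections
    eq_secs <- if (is.null(eq_sections)) list(eq) else eq_sections
    ecv <- ecv_from_slices(pre_secs, eq_secs,
                           liver_mask = copy_roi(masks[[liver_region]], pre),
                           aorta_mask = copy_roi(masks[["aorta"]], pre),
                           haematocrit = hct, patient_id = pid)
  } else if (!have_eq) {
    warn(sprintf("%s: no equilibrium phase; ECV and diff features skipped", pid),
         "eqctta_missing_phase_warning")
  }

  list(features = do.call(rbind, rows), ecv = ecv)
}

# Texture of the voxel-wise EQ-minus-pre image (alternative diff definition).
diff_of_images <- function(pre, eq, ssf, mask, gamma, erode, bins, min_pixels,
                           excess) {
  dpix <- eq$pixels - pre$pixels
  fpix <- if (ssf == 0) {
    dpix
  } else {
    conv2_mirror(dpix, log_kernel(ssf, pre$spacing_mm, gamma))
  }
  fmap <- structure(
    list(pixels = fpix, ssf_mm = ssf, spacing_mm = pre$spacing_mm,
         phase = "pre", patient_id = pre$patient_id,
         slice_label = pre$slice_label),
    class = "filtered_map")
  tv <- compute_metrics(fmap, mask, erode = erode, bins = bins,
                        min_pixels = min_pixels, excess = excess)
  tv$phase <- "diff"
  tv
}

#' Assemble the cohort feature table
#'
#' Binds per-patient long feature rows into one rectangular wide table: one
#' row per patient, one column per (region, phase, SSF, metric) named
#' `region_phase_ssf<value>_<metric>`. Column order is deterministic:
#' region (whole_liver, segment7), then phase (pre, eq, diff), then SSF
#' ascending, then metric in the canonical order (mean, sd, entropy, mpp,
#' skewness, kurtosis). Rows are sorted by `patient_id`. Combinations a
#' patient lacks (e.g. diff columns without an equilibrium phase) are `NA`.
#'
#' @param feature_rows long data.frame as produced by [extract_patient()]
#'   (rows from several patients bound together).
#' @param clinical optional clinical data.frame merged in by `patient_id`.
#' @return A wide data.frame of features (class `feature_table`).
#' @export
build_feature_table <- function(feature_rows, clinical = NULL) {
  needed <- c("patient_id", "region", "phase", "ssf_mm", "metric", "value")
  if (!is.data.frame(feature_rows) || !all(needed %in% names(feature_rows))) {
    abort("feature_rows must hold patient_id, region, phase, ssf_mm, metric, value",
          "eqctta_input_error")
  }
  ids <- sort(unique(feature_rows$patient_id))
  if (length(ids) < 2L) {
    abort("a cohort table needs at least 2 patients", "eqctta_input_error")
  }
  feature_rows$colname <- sprintf("%s_%s_ssf%g_%s", feature_rows$region,
                                  feature_rows$phase, feature_rows$ssf_mm,
                                  feature_rows$metric)
  if (anyDuplicated(feature_rows[, c("patient_id", "colname")])) {
    abort("duplicate (patient_id, feature) rows", "eqctta_input_error")
  }
  regions <- intersect(c("whole_liver", "segment7"), unique(feature_rows$region))
  phases <- intersect(c("pre", "eq", "diff"), unique(feature_rows$phase))
  ssfs <- sort(unique(feature_rows$ssf_mm))
  grid <- expand.grid(metric = texture_metric_names, ssf_mm = ssfs,
                      phase = phases, region = regions,
                      stringsAsFactors = FALSE)
  colnames_ordered <- sprintf("%s_%s_ssf%g_%s", grid$region, grid$phase,
                              grid$ssf_mm, grid$metric)
  colnames_ordered <- colnames_ordered[colnames_ordered %in%
                                         feature_rows$colname]
  out <- data.frame(patient_id = ids, stringsAsFactors = FALSE)
  for (cn in colnames_ordered) {
    sub <- feature_rows[feature_rows$colname == cn, c("patient_id", "value")]
    out[[cn]] <- sub$value[match(ids, sub$patient_id)]
  }
  if (!is.null(clinical)) {
    out <- merge(out, clinical, by = "patient_id", all.x = TRUE, sort = TRUE)
  }
  class(out) <- c("feature_table", "data.frame")
  out
}

#' Extract a whole cohort from a manifest
#'
#' Reads images and masks for every manifest row, extracts features and ECV
#' per patient, and returns the long feature rows plus the clinical table
#' with the derived `ecv` column appended.
#'
#' @param manifest data.frame with columns `patient_id`, `pre_path`,
#'   `eq_path` (NA allowed), `whole_liver_path`, `segment7_path`,
#'   `aorta_path`.
#' @param clinical clinical data.frame (see [read_clinical_table()]).
#' @param ssf_list,diff_mode,erode,bins,min_pixels,excess,gamma passed to
#'   [extract_patient()].
#' @return A list: `features` (long rows, all patients), `clinical` (with
#'   `ecv` column).
#' @export
extract_cohort <- function(manifest, clinical, ssf_list = c(0, 2, 3, 4, 5, 6),
                           diff_mode = "parameters", erode = TRUE, bins = 256L,
                           min_pixels = 50L, excess = TRUE, gamma = 1.6) {
  if (anyDuplicated(manifest$patient_id)) {
    abort("duplicate patient_id in manifest", "eqctta_input_error")
  }
  clinical$ecv <- NA_real_
  all_rows <- list()
  for (i in seq_len(nrow(manifest))) {
    pid <- manifest$patient_id[i]
    rec <- clinical[clinical$patient_id == pid, , drop = FALSE]
    if (nrow(rec) == 0L) rec <- data.frame(patient_id = pid)
    pre_secs <- read_ct_sections(manifest$pre_path[i], "pre", patient_id = pid)
    pre <- pre_secs[[1L]]
    eq_secs <- NULL
    eq <- NULL
    if (!is.na(manifest$eq_path[i]) && nzchar(manifest$eq_path[i])) {
      eq_secs <- read_ct_sections(manifest$eq_path[i], "eq", patient_id = pid)
      eq <- eq_secs[[1L]]
    }
    ref <- if (is.null(eq)) pre else eq
    masks <- list()
    for (rg in c("whole_liver", "segment7", "aorta")) {
      pcol <- paste0(rg, "_path")
      if (pcol %in% names(manifest) && !is.na(manifest[[pcol]][i]) &&
          nzchar(manifest[[pcol]][i])) {
        masks[[rg]] <- read_roi_mask(manifest[[pcol]][i], rg, ref)
      }
    }
    res <- withCallingHandlers(
      extract_patient(pre, eq, masks, rec, ssf_list = ssf_list,
                      pre_sections = pre_secs, eq_sections = eq_secs,
                      diff_mode = diff_mode, erode = erode, bins = bins,
                      min_pixels = min_pixels, excess = excess, gamma = gamma),
      eqctta_missing_phase_warning = function(w) invokeRestart("muffleWarning"))
    all_rows[[i]] <- res$features
    if (!is.null(res$ecv)) {
      clinical$ecv[clinical$patient_id == pid] <- res$ecv$ecv
    }
  }
  list(features = do.call(rbind, all_rows), clinical = clinical)
}
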