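#' CT slice objects
#'
#' A `ct_slice` is a single 2-D CT section: a matrix of Hounsfield-unit (HU)
#' values with physical pixel spacing in mm and an acquisition phase tag.
#' It is the unit on which texture analysis operates. Pixels are indexed
#' 0-based conceptually but stored as an ordinary R matrix (row, col);
#' masks share the same lattice exactly.
#'
#' @param pixels numeric matrix of HU values. Must be finite and within the
#'   CT representable range \[-1024, 3071\]; out-of-range values are an error,
#'   never clipped silently.
#' @param spacing_mm length-2 positive numeric, mm per pixel along (row, col).
#' @param phase `"pre"` (pre-contrast) or `"eq"` (equilibrium phase).
#' @param patient_id character scalar.
#' @param slice_label free-text label, e.g. `"hepatic_porta"`.
#'
#' @return An object of class `ct_slice`.
#' @export
ct_slice <- function(pixels, spacing_mm, phase = c("pre", "eq"),
                     patient_id = "unknown", slice_label = "hepatic_porta") {
  phase <- match.arg(phase)
  if (!is.matrix(pixels) || !is.numeric(pixels) || length(pixels) == 0L) {
    abort("pixels must be a non-empty numeric matrix", "eqctta_data_error")
  }
  if (anyNA(pixels) || !all(is.finite(pixels))) {
    abort("pixels contain non-finite values", "eqctta_data_error")
  }
  if (any(pixels < -1024) || any(pixels > 3071)) {
    abort("HU values outside [-1024, 3071]; input looks corrupted",
          "eqctta_data_error")
  }
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, 2L)
  if (length(spacing_mm) != 2L || anyNA(spacing_mm) || any(spacing_mm <= 0)) {
    abort("spacing_mm must be two positive numbers (mm per pixel)",
          "eqctta_geometry_error")
  }
  structure(
    list(pixels = pixels, spacing_mm = spacing_mm, phase = phase,
         patient_id = as.character(patient_id),
         slice_label = as.character(slice_label)),
    class = "ct_slice"
  )
}

#' @export
print.ct_slice <- function(x, ...) {
  cat(sprintf("<ct_slice> %s [%s] %dx%d px @ (%.3g, %.3g) mm, HU [%.1f, %.1f]\n",
              x$patient_id, x$phase, nrow(x$pixels), ncol(x$pixels),
              x$spacing_mm[1], x$spacing_mm[2],
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Region-of-interest masks
#'
#' A boolean grid on the same lattice as its reference slice, labelled by
#' anatomical region. The aorta region must be disjoint from the liver
#' regions (blood pool vs parenchyma).
#'
#' @param mask logical matrix; at least one `TRUE` pixel.
#' @param region one of `"whole_liver"`, `"segment7"`, `"aorta"`.
#' @param slice the `ct_slice` whose lattice the mask lives on; shape and
#'   spacing are recorded for registration checks.
#'
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(mask, region = c("whole_liver", "segment7", "aorta"),
                     slice) {
  region <- match.arg(region)
  if (!is.matrix(mask) || !is.logical(mask)) {
    abort("mask must be a logical matrix", "eqctta_data_error")
  }
  if (!any(mask)) {
    abort("mask has no TRUE pixels", "eqctta_geometry_error")
  }
  if (!inherits(slice, "ct_slice")) {
    abort("slice must be a ct_slice", "eqctta_data_error")
  }
  if (!identical(dim(mask), dim(slice$pixels))) {
    abort("mask shape does not match the reference slice", "eqctta_geometry_error")
  }
  structure(
    list(mask = mask, region = region,
         ref_dim = dim(slice$pixels), spacing_mm = slice$spacing_mm,
         patient_id = slice$patient_id),
    class = "roi_mask"
  )
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask> %s [%s] %d px on %dx%d lattice\n",
              x$patient_id, x$region, sum(x$mask), x$ref_dim[1], x$ref_dim[2]))
  invisible(x)
}

#' Read a CT slice from a NIfTI file
#'
#' Reads a 2-D (or single/multi-section 3-D) NIfTI image as a `ct_slice`.
#' Pixel spacing is taken from the NIfTI header unless overridden. For a
#' 3-D file, `section` selects which section to read (texture analysis uses
#' a single designated section; ECV measurement may average several).
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @param phase acquisition phase tag, `"pre"` or `"eq"`.
#' @param spacing_override optional length-2 numeric (mm) replacing the header
#'   spacing; required if the header carries missing or non-positive spacing.
#' @param section 1-based section index for 3-D files.
#' @param patient_id,slice_label metadata passed to [ct_slice()].
#'
#' @return A `ct_slice`.
#' @export
read_ct_slice <- function(path, phase = c("pre", "eq"), spacing_override = NULL,
                          section = 1L, patient_id = "unknown",
                          slice_label = "hepatic_porta") {
  phase <- match.arg(phase)
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), "eqctta_data_error")
  }
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 3L) {
    if (section < 1L || section > dim(arr)[3]) {
      abort("section index out of range", "eqctta_data_error")
    }
    pix <- arr[, , section]
  } else if (length(dim(arr)) == 2L) {
    pix <- arr
  } else {
    abort("expected a 2-D or 3-D NIfTI image", "eqctta_data_error")
  }
  sp <- RNifti::pixdim(img)[1:2]
  if (!is.null(spacing_override)) {
    sp <- as.numeric(spacing_override)
  }
  if (anyNA(sp) || any(sp <= 0)) {
    abort("header spacing missing or non-positive and no spacing_override given",
          "eqctta_geometry_error")
  }
  ct_slice(pix, sp, phase = phase, patient_id = patient_id,
           slice_label = slice_label)
}

#' Read every section of a NIfTI file as a list of CT slices
#'
#' @inheritParams read_ct_slice
#' @return A list of `ct_slice` objects, one per section.
#' @export
read_ct_sections <- function(path, phase = c("pre", "eq"),
                             spacing_override = NULL, patient_id = "unknown",
                             slice_label = "hepatic_porta") {
  phase <- match.arg(phase)
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), "eqctta_data_error")
  }
  img <- RNifti::readNifti(path)
  nz <- if (length(dim(as.array(img))) == 3L) dim(as.array(img))[3] else 1L
  lapply(seq_len(nz), function(k) {
    read_ct_slice(path, phase = phase, spacing_override = spacing_override,
                  section = k, patient_id = patient_id,
                  slice_label = if (k == 1L) slice_label else
                    paste0(slice_label, "+", k - 1L))
  })
}

#' Write CT slices to NIfTI
#'
#' Writes one slice (2-D) or several co-registered sections (3-D) with the
#' pixel spacing in the header, at double precision so a write/read round
#' trip is bitwise exact.
#'
#' @param x a `ct_slice` or a list of co-registered `ct_slice`s (sections).
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_ct_slice <- function(x, path) {
  if (inherits(x, "ct_slice")) x <- list(x)
  stopifnot(length(x) >= 1L, all(vapply(x, inherits, TRUE, "ct_slice")))
  first <- x[[1L]]
  for (s in x) {
    if (!check_registration(first, s)) {
      abort("sections are not co-registered", "eqctta_geometry_error")
    }
  }
  arr <- if (length(x) == 1L) {
    first$pixels
  } else {
    array(unlist(lapply(x, `[[`, "pixels")),
          dim = c(dim(first$pixels), length(x)))
  }
  attr(arr, "pixdim") <- if (length(x) == 1L) first$spacing_mm else
    c(first$spacing_mm, 10)  # nominal 10 mm section thickness, metadata only
  RNifti::writeNifti(RNifti::asNifti(arr), path, datatype = "double")
  invisible(path)
}

#' Write an ROI mask to NIfTI (uint8 0/1)
#'
#' @param mask a `roi_mask`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_roi_mask <- function(mask, path) {
  stopifnot(inherits(mask, "roi_mask"))
  arr <- matrix(as.integer(mask$mask), mask$ref_dim[1], mask$ref_dim[2])
  attr(arr, "pixdim") <- mask$spacing_mm
  RNifti::writeNifti(RNifti::asNifti(arr), path, datatype = "uint8")
  invisible(path)
}

#' Read an ROI mask from NIfTI
#'
#' Non-zero voxels become `TRUE`. The mask must match the lattice of
#' `slice` exactly.
#'
#' @param path file path.
#' @param region region label, see [roi_mask()].
#' @param slice reference `ct_slice`.
#' @return A `roi_mask`.
#' @export
read_roi_mask <- function(path, region, slice) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), "eqctta_data_error")
  }
  arr <- as.array(RNifti::readNifti(path))
  if (length(dim(arr)) == 3L) arr <- arr[, , 1L]
  roi_mask(matrix(arr != 0, nrow(arr), ncol(arr)), region = region,
           slice = slice)
}

#' Check that two slices share a lattice
#'
#' ROIs drawn on the equilibrium images may be copied onto pre-contrast
#' images only when the two acquisitions are on identical grids: equal
#' shapes and spacings agreeing to 1e-6 mm. Registration is asserted, never
#' computed; mis-registered pairs are refused downstream, not corrected.
#'
#' @param a,b `ct_slice` objects.
#' @return `TRUE` or `FALSE`.
#' @export
check_registration <- function(a, b) {
  stopifnot(inherits(a, "ct_slice"), inherits(b, "ct_slice"))
  identical(dim(a$pixels), dim(b$pixels)) &&
    all(abs(a$spacing_mm - b$spacing_mm) <= 1e-6)
}

#' Copy an ROI between co-registered phases
#'
#' Returns the same boolean grid re-referenced to `target`, exactly as a
#' reader copies an ROI from the post-contrast to the matching pre-contrast
#' section. Fails if the grids are not registered.
#'
#' @param mask a `roi_mask`.
#' @param target the `ct_slice` to re-reference the mask to.
#' @return A `roi_mask` on `target`'s lattice with an identical pixel set.
#' @export
copy_roi <- function(mask, target) {
  stopifnot(inherits(mask, "roi_mask"), inherits(target, "ct_slice"))
  if (!identical(mask$ref_dim, dim(target$pixels)) ||
      !all(abs(mask$spacing_mm - target$spacing_mm) <= 1e-6)) {
    abort("mask lattice does not match target slice; refusing to copy ROI",
          "eqctta_geometry_error")
  }
  roi_mask(mask$mask, region = mask$region, slice = target)
}

#' Read the clinical table
#'
#' CSV with columns `patient_id`, `haematocrit`, `cpa_percent`, `elf`,
#' `ishak`. Missing markers are allowed (empty cells become `NA`).
#'
#' @param path CSV path.
#' @return A data.frame with one row per patient.
#' @export
read_clinical_table <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), "eqctta_data_error")
  }
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("patient_id", "haematocrit", "cpa_percent", "elf", "ishak")
  missing_cols <- setdiff(needed, names(tab))
  if (length(missing_cols) > 0L) {
    abort(sprintf("clinical table lacks columns: %s",
                  paste(missing_cols, collapse = ", ")),
          "eqctta_input_error")
  }
  if (anyDuplicated(tab$patient_id)) {
    abort("duplicate patient_id in clinical table", "eqctta_input_error")
  }
  tab
}
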