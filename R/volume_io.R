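#' SUV volume container
#'
#' A 3-D grid of body-weight-normalised standardized uptake values (SUV,
#' unitless) with its voxel spacing and physical origin. This is the imaging
#' substrate for all feature extraction; values are assumed already
#' SUV-calibrated (activity-to-SUV conversion is out of scope).
#'
#' @param voxels 3-D numeric array of SUV values; all finite and >= 0.
#' @param spacing Numeric length-3, voxel spacing (dx, dy, dz) in mm; all > 0.
#' @param origin Numeric length-3, physical offset of voxel (1,1,1) in mm.
#' @param scan_id Character scan identifier.
#' @param timepoint One of `"week0"` (baseline) or `"week3"` (mid-treatment).
#' @return An object of class `suv_volume`.
#' @examples
#' v <- suv_volume(array(1, c(4, 4, 4)), spacing = c(2, 2, 2))
#' v
#' @export
suv_volume <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                       scan_id = "", timepoint = c("week0", "week3")) {
  timepoint <- match.arg(timepoint)
  v <- structure(
    list(voxels = voxels, spacing = as.numeric(spacing),
         origin = as.numeric(origin), scan_id = as.character(scan_id),
         timepoint = timepoint),
    class = "suv_volume")
  validate_suv_volume(v)
  v
}

validate_suv_volume <- function(v) {
  if (!is.array(v$voxels) || length(dim(v$voxels)) != 3L)
    stopf("expected 3-D volume, got %s-D",
          if (is.array(v$voxels)) length(dim(v$voxels)) else 1L)
  if (any(dim(v$voxels) < 1L)) stopf("volume has a zero-length axis")
  if (anyNA(v$voxels) || any(!is.finite(v$voxels)))
    stopf("volume contains %d non-finite voxel value(s)",
          sum(!is.finite(v$voxels)))
  if (any(v$voxels < 0))
    stopf("volume contains negative SUVs (min = %g)", min(v$voxels))
  if (length(v$spacing) != 3L || any(!is.finite(v$spacing)) ||
      any(v$spacing <= 0))
    stopf("spacing must be 3 strictly positive numbers")
  if (length(v$origin) != 3L || any(!is.finite(v$origin)))
    stopf("origin must be 3 finite numbers")
  invisible(v)
}

#' @export
print.suv_volume <- function(x, ...) {
  cat(sprintf("<suv_volume> %s [%s] %s, spacing %s mm, SUV range [%.3g, %.3g]\n",
              if (nzchar(x$scan_id)) x$scan_id else "(unnamed)",
              x$timepoint, paste(dim(x$voxels), collapse = "x"),
              paste(format(x$spacing), collapse = "x"),
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

# Volume of one voxel in mL (spacing is in mm; 1 mL = 1000 mm^3).
voxel_volume_ml <- function(v) prod(v$spacing) / 1000

#' Binary region-of-interest mask
#'
#' A binary labelling of tumour voxels aligned to an [suv_volume()]: same
#' array shape, same spacing and origin (the pipeline never resamples).
#'
#' @param voxels 3-D array; any nonzero voxel becomes foreground.
#' @param reference Optional `suv_volume` the mask must be congruent with;
#'   spacing/origin are inherited from it.
#' @param spacing,origin Grid geometry when no reference is given.
#' @return An object of class `roi_mask` (logical 3-D array plus geometry).
#' @export
roi_mask <- function(voxels, reference = NULL, spacing = c(1, 1, 1),
                     origin = c(0, 0, 0)) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stopf("expected 3-D mask array")
  if (anyNA(voxels)) stopf("mask contains missing values")
  fg <- array(voxels != 0, dim = dim(voxels))
  if (!is.null(reference)) {
    check_congruent(dim(fg), dim(reference$voxels),
                    if (missing(spacing)) reference$spacing else spacing,
                    reference$spacing)
    spacing <- reference$spacing
    origin <- reference$origin
  }
  structure(list(voxels = fg, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask> %s, %d foreground voxel(s) (%.3f mL)\n",
              paste(dim(x$voxels), collapse = "x"), sum(x$voxels),
              sum(x$voxels) * prod(x$spacing) / 1000))
  invisible(x)
}

# Masks must share the grid exactly: identical shape, spacing within
# 1e-3 mm. No silent resampling of SUVs.
check_congruent <- function(dim_a, dim_b, spacing_a, spacing_b,
                            strict_spacing = TRUE) {
  if (!identical(as.integer(dim_a), as.integer(dim_b)))
    stopf("grid shape mismatch: %s vs %s",
          paste(dim_a, collapse = "x"), paste(dim_b, collapse = "x"))
  if (strict_spacing || !missing(spacing_b))
    if (any(abs(spacing_a - spacing_b) > 1e-3))
      stopf("voxel spacing mismatch: (%s) vs (%s) mm",
            paste(format(spacing_a), collapse = ", "),
            paste(format(spacing_b), collapse = ", "))
  invisible(TRUE)
}

# Assert a mask is usable for feature extraction on this volume.
check_mask_for_features <- function(volume, mask) {
  check_congruent(dim(volume$voxels), dim(mask$voxels),
                  volume$spacing, mask$spacing)
  if (!any(mask$voxels)) stopf("ROI contains no voxels")
  invisible(TRUE)
}

#' Read an SUV volume from a NIfTI file
#'
#' Voxel values are taken unchanged from the file and validated as SUVs
#' (finite, non-negative); spacing comes from the NIfTI header.
#'
#' @param path Path to a `.nii` / `.nii.gz` file holding a 3-D scalar image.
#' @param scan_id,timepoint Provenance attached to the returned volume.
#' @return An [suv_volume()].
#' @export
read_suv_volume <- function(path, scan_id = basename(path),
                            timepoint = c("week0", "week3")) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  img <- RNifti::readNifti(path)
  a <- as.array(img)
  if (length(dim(a)) != 3L)
    stopf("expected 3-D volume, got %d-D image in %s", length(dim(a)), path)
  x <- RNifti::xform(img)
  suv_volume(array(as.numeric(a), dim = dim(a)),
             spacing = RNifti::pixdim(img)[1:3],
             origin = as.numeric(x[1:3, 4]),
             scan_id = scan_id, timepoint = match.arg(timepoint))
}

#' Write an SUV volume (or mask) to NIfTI
#'
#' Values are stored as float64 so a write-then-read round trip is
#' bit-exact.
#'
#' @param x An [suv_volume()] or [roi_mask()].
#' @param path Output `.nii` / `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_suv_volume <- function(x, path) {
  a <- if (inherits(x, "roi_mask")) array(as.numeric(x$voxels),
                                          dim = dim(x$voxels)) else x$voxels
  img <- RNifti::asNifti(a)
  RNifti::pixdim(img) <- x$spacing
  RNifti::qform(img) <- structure(
    rbind(cbind(diag(x$spacing), x$origin), c(0, 0, 0, 1)), code = 2L)
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Read a binary ROI mask congruent with a reference volume
#'
#' @param path NIfTI path; any nonzero voxel is foreground.
#' @param reference The [suv_volume()] the mask belongs to; shape must match
#'   exactly and spacing within 1e-3 mm.
#' @return An [roi_mask()].
#' @export
read_roi_mask <- function(path, reference) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  img <- RNifti::readNifti(path)
  a <- as.array(img)
  if (length(dim(a)) != 3L)
    stopf("expected 3-D mask, got %d-D image in %s", length(dim(a)), path)
  m <- roi_mask(a, spacing = RNifti::pixdim(img)[1:3])
  check_congruent(dim(m$voxels), dim(reference$voxels),
                  m$spacing, reference$spacing)
  if (!any(m$voxels)) stopf("ROI contains no voxels")
  m$spacing <- reference$spacing
  m$origin <- reference$origin
  m
}

#' @rdname write_suv_volume
#' @export
write_roi_mask <- function(x, path) write_suv_volume(x, path)

cohort_required_cols <- c("patient_id", "p16", "tnm_stage", "t_stage",
                          "chemo", "followup_months", "lrr_event")

#' Read a cohort metadata table
#'
#' Expects a UTF-8 comma-separated file with a header row and columns
#' `patient_id, p16, tnm_stage, t_stage, chemo, followup_months, lrr_event`.
#' p16 values other than `"positive"`/`"negative"` (case-insensitive) are
#' mapped to `"unknown"`; such patients are later excluded from
#' p16-dependent stratification.
#'
#' @param path CSV path.
#' @return A data frame of patient records (one row per patient).
#' @export
read_cohort_table <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("NA", ""))
  missing_cols <- setdiff(cohort_required_cols, names(df))
  if (length(missing_cols))
    stopf("cohort table missing required column(s): %s",
          paste(missing_cols, collapse = ", "))
  if (nrow(df) == 0L) {
    warnf("cohort table %s has a header but no rows", path)
    return(df)
  }
  as_patient_records(df)
}

# Validate and normalise a cohort data frame (shared by CSV reader and
# the simulator).
as_patient_records <- function(df) {
  p16 <- tolower(trimws(as.character(df$p16)))
  p16[!(p16 %in% c("positive", "negative"))] <- "unknown"
  df$p16 <- p16
  df$patient_id <- as.character(df$patient_id)
  df$followup_months <- suppressWarnings(as.numeric(df$followup_months))
  if (anyNA(df$followup_months))
    stopf("unparseable or missing followup_months for patient(s): %s",
          paste(df$patient_id[is.na(df$followup_months)], collapse = ", "))
  if (any(df$followup_months < 0)) stopf("negative follow-up time")
  if (!all(df$lrr_event %in% c(0, 1)))
    stopf("lrr_event must be 0/1")
  df$lrr_event <- as.integer(df$lrr_event)
  df
}
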