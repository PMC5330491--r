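#' Least-significant-change parameters
#'
#' Single-rater precision error of the semi-automated segmentation method:
#' between-scan volume changes smaller than the LSC fraction of the tumor
#' volume are within measurement noise. Defaults are the published precision
#' of this workflow: 35.2% for contrast-enhancing (CV) and 14.4% for
#' FLAIR (FV) segmentations.
#'
#' @param lsc_cv,lsc_fv LSC fractions in (0, 1).
#' @return list of class \code{lsc_params}.
#' @export
lsc_params <- function(lsc_cv = 0.352, lsc_fv = 0.144) {
  stopifnot(lsc_cv > 0, lsc_cv < 1, lsc_fv > 0, lsc_fv < 1)
  structure(list(lsc_cv = lsc_cv, lsc_fv = lsc_fv), class = "lsc_params")
}

#' Absolute volume change between consecutive scans
#'
#' @param v1 baseline volume (ml, >= 0).
#' @param v2 follow-up volume (ml, >= 0).
#' @return signed delta \code{v2 - v1} in ml.
#' @export
delta_volume <- function(v1, v2) {
  stopifnot(all(v1 >= 0), all(v2 >= 0))
  v2 - v1
}

#' LSC correction of a volume delta
#'
#' Divides a signed volume delta by the absolute least significant change,
#' yielding a dimensionless "corrected" delta: |result| > 1 means the change
#' exceeds single-rater measurement precision. The absolute LSC is the LSC
#' fraction times a reference volume — the baseline volume by default, or
#' the mean of the scan pair via \code{reference = "mean"}.
#'
#' @param delta signed delta in ml.
#' @param baseline baseline volume in ml.
#' @param lsc LSC fraction in (0, 1).
#' @param followup follow-up volume in ml (only used for the pair-mean
#'   reference).
#' @param reference \code{"baseline"} or \code{"mean"}.
#' @param floor_ml floor for the reference volume; scans with (near) zero
#'   tumor volume (e.g. complete resections) would otherwise divide by
#'   zero. Floored values are flagged via the \code{"floored"} attribute.
#' @return dimensionless corrected delta (vectorised).
#' @export
lsc_correct <- function(delta, baseline, lsc,
                        followup = NULL,
                        reference = c("baseline", "mean"),
                        floor_ml = 0.001) {
  reference <- match.arg(reference)
  stopifnot(lsc > 0, lsc < 1, all(baseline >= 0), floor_ml > 0)
  ref <- if (reference == "mean") {
    stopifnot(!is.null(followup))
    (baseline + followup) / 2
  } else baseline
  floored <- ref < floor_ml
  ref <- pmax(ref, floor_ml)
  out <- delta / (lsc * ref)
  attr(out, "floored") <- floored
  out
}

#' Regional segmentation-based subtraction
#'
#' Voxel-wise subtraction of a baseline mask from a registered follow-up
#' mask: the result keeps only voxels present at follow-up and absent at
#' baseline (new tumor), so its volume is always non-negative and the
#' identity |followup| = |followup AND baseline| + |subtraction| holds
#' exactly. The reverse direction (regressed tumor) is returned alongside
#' for visualisation but is not a model input.
#'
#' @param baseline,followup \code{\link{binary_mask}} objects on the same
#'   grid (resample first if needed).
#' @return list: \code{mask} (follow-up \\ baseline), \code{volume_ml},
#'   \code{overlap_ml}, \code{regressed_ml} (baseline \\ follow-up).
#' @export
regional_subtraction <- function(baseline, followup) {
  stopifnot(inherits(baseline, "binary_mask"), inherits(followup, "binary_mask"))
  if (!identical(dim(baseline$grid), dim(followup$grid)))
    stop("masks are on different grids; resample the follow-up mask first")
  if (!isTRUE(all.equal(baseline$voxel_size, followup$voxel_size)))
    stop("masks have different voxel sizes; resample the follow-up mask first")
  sub <- followup$grid & !baseline$grid
  vv <- prod(followup$voxel_size) / 1000
  n_sub <- sum(sub)
  n_overlap <- sum(followup$grid & baseline$grid)
  n_regressed <- sum(baseline$grid & !followup$grid)
  list(mask = binary_mask(sub, followup$voxel_size, followup$compartment,
                          followup$origin),
       volume_ml = n_sub * vv,
       overlap_ml = n_overlap * vv,
       regressed_ml = n_regressed * vv,
       # integer voxel counts: the conservation identity
       # |followup| = |overlap| + |subtraction| is exact on these
       volume_vox = n_sub,
       overlap_vox = n_overlap,
       regressed_vox = n_regressed)
}

#' Dice overlap of two masks
#' @param a,b \code{\link{binary_mask}} objects on the same grid.
#' @return Dice coefficient in [0, 1].
#' @export
dice_overlap <- function(a, b) {
  stopifnot(identical(dim(a$grid), dim(b$grid)))
  na <- sum(a$grid); nb <- sum(b$grid)
  if (na + nb == 0) return(1)
  2 * sum(a$grid & b$grid) / (na + nb)
}

#' Per-pair change records from a cohort volume table
#'
#' Turns a per-scan cohort table into one record per consecutive scan pair,
#' carrying both volumetric change determinants: LSC-corrected absolute
#' deltas (dCV, dFV, dimensionless; raw ml deltas are kept alongside) and
#' regional segmentation-based subtractions (sCV, sFV, ml). In table mode
#' the subtraction columns must already be present on the table (generated
#' or measured upstream); in image mode they come from
#' \code{\link{regional_subtraction}} on registered masks.
#'
#' @param scans data.frame with columns \code{patient_id}, \code{scan_index},
#'   \code{cv_ml}, \code{fv_ml}, optionally \code{scv_ml}, \code{sfv_ml},
#'   \code{rating}, \code{progression}.
#' @param lsc an \code{\link{lsc_params}} object.
#' @param reference LSC reference volume convention, see
#'   \code{\link{lsc_correct}}.
#' @return data.frame of change records, one row per consecutive pair,
#'   keyed by the follow-up scan.
#' @export
change_records <- function(scans, lsc = lsc_params(),
                           reference = c("baseline", "mean")) {
  reference <- match.arg(reference)
  need <- c("patient_id", "scan_index", "cv_ml", "fv_ml")
  if (!all(need %in% names(scans)))
    stop("scans table must have columns: ", paste(need, collapse = ", "))
  scans <- scans[order(scans$patient_id, scans$scan_index), ]
  out <- do.call(rbind, lapply(split(scans, scans$patient_id), function(p) {
    if (nrow(p) < 2) return(NULL)
    i2 <- 2:nrow(p); i1 <- i2 - 1
    data.frame(
      patient_id = p$patient_id[i2],
      scan_index = p$scan_index[i2],
      pair = paste0(p$scan_index[i1], "->", p$scan_index[i2]),
      cv1_ml = p$cv_ml[i1], cv2_ml = p$cv_ml[i2],
      fv1_ml = p$fv_ml[i1], fv2_ml = p$fv_ml[i2],
      dcv_ml = delta_volume(p$cv_ml[i1], p$cv_ml[i2]),
      dfv_ml = delta_volume(p$fv_ml[i1], p$fv_ml[i2]),
      scv_ml = if ("scv_ml" %in% names(p)) p$scv_ml[i2] else NA_real_,
      sfv_ml = if ("sfv_ml" %in% names(p)) p$sfv_ml[i2] else NA_real_,
      rating = if ("rating" %in% names(p)) p$rating[i2] else NA_integer_,
      progression = if ("progression" %in% names(p)) p$progression[i2] else NA,
      stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out$dcv <- as.numeric(lsc_correct(out$dcv_ml, out$cv1_ml, lsc$lsc_cv,
                                    out$cv2_ml, reference))
  out$dfv <- as.numeric(lsc_correct(out$dfv_ml, out$fv1_ml, lsc$lsc_fv,
                                    out$fv2_ml, reference))
  # model-scale aliases: the classifier takes corrected deltas (dcv, dfv)
  # and raw subtraction volumes in ml (scv, sfv)
  out$scv <- out$scv_ml
  out$sfv <- out$sfv_ml
  out
}
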