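# Disease Evolution Map construction and volumetric summaries.

#' Compute a Disease Evolution Map from serial images
#'
#' The DEM is the voxel-wise signed difference `followup - baseline`. For
#' IM/PM inputs every value lies in `[-1, 1]`: positive values mark
#' progression, negative values regression.
#'
#' @param x0 baseline `volume_image` (modality IM or PM).
#' @param x1 follow-up `volume_image`, same subject, grid and modality.
#' @return an `evolution_map` with provenance `"real"`.
#' @export
compute_dem <- function(x0, x1) {
  stopifnot(inherits(x0, "volume_image"), inherits(x1, "volume_image"))
  if (!x0$modality %in% c("IM", "PM"))
    stop("DEM subtraction is defined for IM or PM modalities")
  if (x0$modality != x1$modality) stop("modality mismatch between time points")
  if (!identical(x0$subject_id, x1$subject_id))
    stop("DEM requires two scans of the same subject")
  check_same_grid(x0, x1)
  evolution_map(x1$data - x0$data, x0$voxel_dims, provenance = "real")
}

#' Apply a DEM to a baseline image
#'
#' Produces the (possibly synthetic) follow-up image `x1' = x0 + y`, clipped
#' to `[0, 1]` so that IM/PM semantics remain valid for downstream
#' thresholding.
#'
#' @param x0 baseline `volume_image`.
#' @param y an `evolution_map` on the same grid.
#' @return a follow-up `volume_image`.
#' @export
apply_dem <- function(x0, y) {
  stopifnot(inherits(x0, "volume_image"), inherits(y, "evolution_map"))
  check_same_grid(x0, y)
  dat <- pmin(pmax(x0$data + y$data, 0), 1)
  volume_image(dat, x0$voxel_dims, x0$modality, x0$subject_id, "followup")
}

#' Threshold an IM/PM volume into a WMH mask
#'
#' Inclusive thresholds: a voxel is WMH when its value is greater than or
#' equal to 0.178 (irregularity map) or 0.5 (probability map).
#'
#' @param x a `volume_image` with modality IM or PM.
#' @return a `binary_mask` with role WMH.
#' @export
threshold_wmh <- function(x) {
  stopifnot(inherits(x, "volume_image"))
  if (!x$modality %in% names(WMH_THRESHOLDS))
    stop(sprintf("unsupported modality '%s': thresholding is defined for IM and PM",
                 x$modality))
  thr <- WMH_THRESHOLDS[[x$modality]]
  binary_mask(x$data >= thr, "WMH", x$voxel_dims)
}

#' Exclude stroke-lesion voxels from a WMH mask
#'
#' Stroke lesions are removed from all WMH bookkeeping before labelling and
#' volumetry: the result is `wmh AND NOT sl`.
#'
#' @param wmh a WMH `binary_mask`.
#' @param sl a stroke-lesion `binary_mask` on the same grid, or `NULL` (no-op).
#' @return a WMH `binary_mask`.
#' @export
exclude_stroke_lesions <- function(wmh, sl = NULL) {
  stopifnot(inherits(wmh, "binary_mask"), wmh$role == "WMH")
  if (is.null(sl)) return(wmh)
  stopifnot(inherits(sl, "binary_mask"), sl$role == "SL")
  check_same_grid(wmh, sl)
  binary_mask(wmh$data & !sl$data, "WMH", wmh$voxel_dims)
}

#' Three-class evolution labels from serial WMH masks
#'
#' Exhaustive per-voxel rule on the two binary masks: present only at
#' baseline = shrink; present only at follow-up = grow; present at both =
#' stable; absent at both = background. Defined on integer masks so no
#' floating-point zero test is involved.
#'
#' @param m0 baseline WMH `binary_mask`.
#' @param m1 follow-up WMH `binary_mask` on the same grid.
#' @return an `evolution_label_map`.
#' @export
label_dem_from_masks <- function(m0, m1) {
  stopifnot(inherits(m0, "binary_mask"), inherits(m1, "binary_mask"))
  if (m0$role != "WMH" || m1$role != "WMH")
    stop("both masks must have role WMH")
  check_same_grid(m0, m1)
  a <- m0$data; b <- m1$data
  lab <- array(0L, dim(a))
  lab[a & b] <- DEM_CODES[["stable"]]
  lab[a & !b] <- DEM_CODES[["shrink"]]
  lab[!a & b] <- DEM_CODES[["grow"]]
  evolution_label_map(lab, m0$voxel_dims)
}

#' WMH volume in millilitres
#'
#' @param mask a WMH `binary_mask`.
#' @param voxel_dims optional length-3 voxel size in mm; defaults to the
#'   mask's own.
#' @return volume in ml (`count * dx*dy*dz / 1000`).
#' @export
wmh_volume_ml <- function(mask, voxel_dims = NULL) {
  stopifnot(inherits(mask, "binary_mask"))
  vd <- if (is.null(voxel_dims)) mask$voxel_dims else voxel_dims
  check_voxel_dims(vd)
  sum(mask$data) * prod(vd) / 1000
}

#' Predicted follow-up WMH mask from a three-class label map
#'
#' The predicted follow-up lesion extent is the baseline mask minus voxels
#' labelled shrink, plus voxels labelled grow (equivalently stable-or-grow
#' wherever the labelling is consistent with the baseline mask).
#'
#' @param m0 baseline WMH `binary_mask`.
#' @param labels an `evolution_label_map` on the same grid.
#' @return a WMH `binary_mask`.
#' @export
predicted_followup_mask <- function(m0, labels) {
  stopifnot(inherits(m0, "binary_mask"), inherits(labels, "evolution_label_map"))
  check_same_grid(m0, labels)
  lab <- labels$data
  out <- (m0$data & lab != DEM_CODES[["shrink"]]) | lab == DEM_CODES[["grow"]]
  binary_mask(out, "WMH", m0$voxel_dims)
}
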