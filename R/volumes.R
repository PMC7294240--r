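# Label codes for the three-class evolution map. Foreground codes partition the
# union of the two time-point WMH masks; 0 is everything else.
DEM_CODES <- c(background = 0L, stable = 1L, shrink = 2L, grow = 3L)

# Inclusive WMH thresholds per modality (irregularity map / probability map).
WMH_THRESHOLDS <- c(IM = 0.178, PM = 0.5)

#' Construct a 3D volume image
#'
#' A `volume_image` holds one scalar 3D field for one subject and time point.
#' Irregularity maps (`IM`) and probability maps (`PM`) are constrained to
#' `[0, 1]`; `FLAIR`-like intensity volumes may take any non-negative value.
#'
#' @param data numeric 3D array.
#' @param voxel_dims length-3 positive numeric, voxel size in mm `(dx, dy, dz)`.
#' @param modality one of `"IM"`, `"PM"`, `"FLAIR"`.
#' @param subject_id opaque subject identifier.
#' @param timepoint `"baseline"` or `"followup"`.
#' @return an object of class `volume_image`.
#' @export
volume_image <- function(data, voxel_dims, modality = c("IM", "PM", "FLAIR"),
                         subject_id = "s", timepoint = c("baseline", "followup")) {
  modality <- match.arg(modality)
  timepoint <- match.arg(timepoint)
  data <- check_grid3d(data)
  check_voxel_dims(voxel_dims)
  if (modality %in% c("IM", "PM")) {
    rng <- range(data)
    if (rng[1] < -1e-4 || rng[2] > 1 + 1e-4)
      stop(sprintf("%s values must lie in [0,1]; observed range [%.4g, %.4g]",
                   modality, rng[1], rng[2]))
    data[] <- pmin(pmax(data, 0), 1)
  }
  structure(list(data = data, voxel_dims = as.numeric(voxel_dims),
                 modality = modality, subject_id = subject_id,
                 timepoint = timepoint),
            class = "volume_image")
}

#' Construct a binary mask
#'
#' @param data logical (or 0/1 numeric) 3D array.
#' @param role one of `"WMH"`, `"SL"` (stroke lesion), `"ICV"` (intracranial
#'   volume).
#' @param voxel_dims length-3 positive numeric, mm.
#' @return an object of class `binary_mask`.
#' @export
binary_mask <- function(data, role = c("WMH", "SL", "ICV"), voxel_dims) {
  role <- match.arg(role)
  data <- check_grid3d(data)
  if (!is.logical(data)) {
    if (!all(data %in% c(0, 1)))
      stop("mask data must be logical or 0/1")
    storage.mode(data) <- "logical"
  }
  check_voxel_dims(voxel_dims)
  structure(list(data = data, role = role, voxel_dims = as.numeric(voxel_dims)),
            class = "binary_mask")
}

#' Construct a Disease Evolution Map (DEM)
#'
#' Signed per-voxel change field; when derived from IM/PM pairs the values lie
#' in `[-1, 1]` (positive = progression, negative = regression).
#'
#' @param data numeric 3D array.
#' @param voxel_dims length-3 positive numeric, mm.
#' @param provenance `"real"` (from observed serial images) or `"generated"`
#'   (model output).
#' @return an object of class `evolution_map`.
#' @export
evolution_map <- function(data, voxel_dims, provenance = c("real", "generated")) {
  provenance <- match.arg(provenance)
  data <- check_grid3d(data)
  check_voxel_dims(voxel_dims)
  structure(list(data = data, voxel_dims = as.numeric(voxel_dims),
                 provenance = provenance),
            class = "evolution_map")
}

#' Construct a three-class evolution label map
#'
#' Per-voxel categories: 0 background, 1 stable, 2 shrink, 3 grow.
#'
#' @param data integer 3D array with codes 0--3.
#' @param voxel_dims length-3 positive numeric, mm.
#' @return an object of class `evolution_label_map`.
#' @export
evolution_label_map <- function(data, voxel_dims) {
  data <- check_grid3d(data)
  if (!all(data %in% 0:3))
    stop("label codes must be in {0 background, 1 stable, 2 shrink, 3 grow}")
  storage.mode(data) <- "integer"
  check_voxel_dims(voxel_dims)
  structure(list(data = data, voxel_dims = as.numeric(voxel_dims)),
            class = "evolution_label_map")
}

check_grid3d <- function(data) {
  if (is.null(dim(data)) || length(dim(data)) != 3)
    stop("data must be a 3D array")
  if (anyNA(data)) stop("data contains NA")
  data
}

check_voxel_dims <- function(vd) {
  if (length(vd) != 3 || any(!is.finite(vd)) || any(vd <= 0))
    stop("voxel_dims must be three strictly positive numbers (mm)")
  invisible(vd)
}

# Shared grid contract: all volumes/masks of one subject live on one grid.
check_same_grid <- function(a, b) {
  if (!identical(dim(a$data), dim(b$data)))
    stop(sprintf("grid mismatch: %s vs %s",
                 paste(dim(a$data), collapse = "x"),
                 paste(dim(b$data), collapse = "x")))
  if (max(abs(a$voxel_dims - b$voxel_dims)) > 1e-8)
    stop("voxel_dims mismatch between volumes")
  invisible(TRUE)
}

#' @export
print.volume_image <- function(x, ...) {
  cat(sprintf("<volume_image> %s %s subject=%s  grid %s  voxels %s mm  range [%.3f, %.3f]\n",
              x$modality, x$timepoint, x$subject_id,
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$voxel_dims, 4), collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> role=%s  grid %s  %d foreground voxels\n",
              x$role, paste(dim(x$data), collapse = "x"), sum(x$data)))
  invisible(x)
}

#' @export
print.evolution_map <- function(x, ...) {
  cat(sprintf("<evolution_map> provenance=%s  grid %s  range [%.3f, %.3f]\n",
              x$provenance, paste(dim(x$data), collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.evolution_label_map <- function(x, ...) {
  tb <- tabulate(as.integer(x$data) + 1L, nbins = 4L)
  cat(sprintf("<evolution_label_map> grid %s  bg=%d stable=%d shrink=%d grow=%d\n",
              paste(dim(x$data), collapse = "x"), tb[1], tb[2], tb[3], tb[4]))
  invisible(x)
}

# ---- NIfTI I/O -------------------------------------------------------------

#' Write a volume, mask, DEM or label map to NIfTI
#'
#' Volumes are written as float32 NIfTI; label maps as uint8 with the code
#' table written to a sidecar JSON (`<path>.labels.json`).
#'
#' @param x a `volume_image`, `binary_mask`, `evolution_map` or
#'   `evolution_label_map`.
#' @param path output file path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path) {
  dat <- x$data
  dtype <- "float"
  if (inherits(x, "binary_mask")) {
    dat <- array(as.integer(dat), dim(dat)); dtype <- "uint8"
  }
  if (inherits(x, "evolution_label_map")) {
    dtype <- "uint8"
    jsonlite::write_json(as.list(DEM_CODES), paste0(path, ".labels.json"),
                         auto_unbox = TRUE)
  }
  attr(dat, "pixdim") <- x$voxel_dims
  RNifti::writeNifti(RNifti::asNifti(dat, datatype = dtype), path)
  invisible(path)
}

#' Read a NIfTI volume
#'
#' @param path NIfTI file path.
#' @param as one of `"image"`, `"mask"`, `"labels"`, `"dem"` -- the class to
#'   construct.
#' @param modality,role,timepoint,subject_id metadata for the constructed
#'   object (NIfTI does not carry them).
#' @return the reconstructed object.
#' @export
read_volume <- function(path, as = c("image", "mask", "labels", "dem"),
                        modality = "IM", role = "WMH",
                        timepoint = "baseline", subject_id = "s") {
  as <- match.arg(as)
  img <- RNifti::readNifti(path)
  vd <- RNifti::pixdim(img)[1:3]
  dat <- array(as.vector(img), dim = dim(img))
  switch(as,
         image = volume_image(dat, vd, modality, subject_id, timepoint),
         mask = binary_mask(dat != 0, role, vd),
         labels = evolution_label_map(dat, vd),
         dem = evolution_map(dat, vd, provenance = "real"))
}
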