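# Readers, writers, slice extraction and covariate normalisation.

#' Load one subject directory
#'
#' Expects the layout written by [write_cohort()]: per-modality
#' `<mod>_baseline.nii.gz` / `<mod>_followup.nii.gz`, masks
#' (`wmh_baseline`, `wmh_followup`, `sl`, `icv`), optional
#' `truth_labels.nii.gz`, and a `manifest.csv` in the parent directory with
#' one covariate row per subject.
#'
#' @param dir subject directory; its basename is the subject id.
#' @param modalities which image modalities to read.
#' @return a `subject_record`.
#' @export
load_subject <- function(dir, modalities = c("IM", "PM", "FLAIR")) {
  sid <- basename(normalizePath(dir, mustWork = TRUE))
  images <- list()
  ref <- NULL
  for (mod in modalities) {
    pair <- list()
    for (tp in c("baseline", "followup")) {
      f <- file.path(dir, sprintf("%s_%s.nii.gz", tolower(mod), tp))
      if (!file.exists(f))
        f <- sub("\\.nii\\.gz$", ".nii", f)
      if (!file.exists(f))
        stop(sprintf("missing %s time point for modality %s: %s", tp, mod, f))
      img <- tryCatch(
        read_volume(f, "image", modality = mod, timepoint = tp,
                    subject_id = sid),
        error = function(e)
          stop(sprintf("%s (file: %s)", conditionMessage(e), f), call. = FALSE))
      if (is.null(ref)) ref <- img else check_same_grid(ref, img)
      pair[[tp]] <- img
    }
    images[[mod]] <- pair
  }
  rd_mask <- function(name, role) {
    f <- file.path(dir, paste0(name, ".nii.gz"))
    if (!file.exists(f)) return(NULL)
    m <- read_volume(f, "mask", role = role)
    check_same_grid(ref, m)
    m
  }
  masks <- list(wmh_baseline = rd_mask("wmh_baseline", "WMH"),
                wmh_followup = rd_mask("wmh_followup", "WMH"),
                sl = rd_mask("sl", "SL"),
                icv = rd_mask("icv", "ICV"))
  truth <- NULL
  tf <- file.path(dir, "truth_labels.nii.gz")
  if (file.exists(tf)) truth <- read_volume(tf, "labels")
  covariates <- NULL
  mf <- file.path(dirname(dir), "manifest.csv")
  if (file.exists(mf)) {
    man <- utils::read.csv(mf, stringsAsFactors = FALSE)
    row <- man[man$subject_id == sid, , drop = FALSE]
    if (nrow(row) == 1) covariates <- as.list(row[, -1, drop = FALSE])
  }
  vol0 <- if (!is.null(masks$wmh_baseline)) wmh_volume_ml(masks$wmh_baseline) else NA_real_
  vol1 <- if (!is.null(masks$wmh_followup)) wmh_volume_ml(masks$wmh_followup) else NA_real_
  icv_ml <- if (!is.null(masks$icv)) sum(masks$icv$data) * prod(ref$voxel_dims) / 1000 else NA_real_
  structure(list(subject_id = sid, images = images, masks = masks,
                 covariates = covariates, truth = truth,
                 wmh_baseline_ml = vol0, wmh_followup_ml = vol1,
                 icv_ml = icv_ml),
            class = "subject_record")
}

#' Extract paired 2D training slices from subjects
#'
#' Slices are taken along the last (z) axis; slices without any in-ICV voxel
#' are omitted. Each emitted slice carries the baseline and follow-up image
#' of the requested modality, the ground-truth label slice when available,
#' the baseline WMH mask slice, and the subject id.
#'
#' @param subjects list of `subject_record` (e.g. `cohort$subjects`).
#' @param modality image modality to extract.
#' @return list of slice records with attributes `H`, `W`, `modality`.
#' @export
extract_training_slices <- function(subjects, modality = c("FLAIR", "IM", "PM")) {
  modality <- match.arg(modality)
  out <- list()
  for (s in subjects) {
    img0 <- s$images[[modality]]$baseline$data
    img1 <- s$images[[modality]]$followup$data
    icv <- if (!is.null(s$masks$icv)) s$masks$icv$data else img0 != 0
    truth <- if (!is.null(s$truth)) s$truth$data else NULL
    wmh0 <- if (!is.null(s$masks$wmh_baseline)) s$masks$wmh_baseline$data else NULL
    nz <- dim(img0)[3]
    kept <- 0L
    for (z in seq_len(nz)) {
      icv_z <- icv[, , z]
      if (!any(icv_z)) next
      kept <- kept + 1L
      out[[length(out) + 1L]] <- list(
        x0 = img0[, , z], x1 = img1[, , z],
        labels = if (is.null(truth)) NULL else truth[, , z],
        wmh0 = if (is.null(wmh0)) NULL else wmh0[, , z],
        icv = icv_z, subject_id = s$subject_id, z = z)
    }
    if (kept == 0L)
      warning(sprintf("subject %s has no slices with brain tissue", s$subject_id))
  }
  if (!length(out)) {
    warning("no slices with brain tissue in any subject")
    return(structure(list(), H = NA_integer_, W = NA_integer_,
                     modality = modality))
  }
  structure(out, H = nrow(out[[1]]$x0), W = ncol(out[[1]]$x0),
            modality = modality)
}

#' Z-score lesion loads over a training cohort
#'
#' Population (1/n) variance convention. The fitted centre/scale are
#' returned so test-time data can be normalised with the training
#' parameters (no re-fit).
#'
#' @param loads numeric vector of per-subject loads (ml).
#' @param scaler optional previously fitted scaler (a list with `center`,
#'   `scale`); when supplied it is reused as-is.
#' @return list of class `load_scaler` with `values`, `center`, `scale`.
#' @export
normalise_loads <- function(loads, scaler = NULL) {
  if (is.null(scaler)) {
    if (length(loads) < 2) stop("need at least two subjects to fit a scaler")
    ctr <- mean(loads)
    scl <- sqrt(mean((loads - ctr)^2))
    if (scl == 0) stop("constant loads: zero variance, cannot z-score")
  } else {
    ctr <- scaler$center; scl <- scaler$scale
  }
  structure(list(values = (loads - ctr) / scl, center = ctr, scale = scl),
            class = "load_scaler")
}

#' Write / read a run configuration (YAML round trip)
#'
#' @param cfg a named list.
#' @param path YAML file path.
#' @return `read_run_config` returns the list; `write_run_config` returns
#'   `path` invisibly.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  yaml::read_yaml(path)
}
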