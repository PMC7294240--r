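# Synthetic longitudinal cohort generator.
#
# Each subject is an elliptical "head" (ICV) containing a handful of smooth
# ellipsoidal WMH clusters. Between baseline and follow-up each cluster
# advances or retreats its boundary according to a per-subject logistic
# growth probability driven by clinical covariates. Intensity volumes are
# constructed FROM the binary masks so that thresholding the generated IM at
# 0.178 / PM at 0.5 recovers the masks exactly: interior values keep a guard
# band of 2*noise_sigma above the threshold and exterior values stay the same
# band below it, and additive noise is clipped to that band.
#
# Baseline images additionally carry a rim signature tied to each cluster's
# sampled fate: growing clusters show a faint exterior halo (a stylised WMH
# "penumbra"), shrinking clusters a faded interior rim. This is what makes
# the prediction task solvable from a single time point.

#' Configuration for a synthetic longitudinal cohort
#'
#' Defaults describe the desk-scale study conditions: 40 subjects on a
#' 48x48x8 grid at 0.9375x0.9375x4 mm voxels, 2--4 lesion clusters each,
#' per-cluster growth probability 0.6 and shrink probability 0.3, boundary
#' advance/retreat of 1.5 mm per interval, additive noise sd 0.02. Covariate
#' prevalences mirror a mild-stroke cohort (diabetes 12%, hypertension 75%,
#' smoker 64%, lacunar stroke 46%).
#'
#' @param n_subjects number of subjects.
#' @param grid_shape integer length-3 `(nx, ny, nz)`.
#' @param voxel_dims voxel size in mm.
#' @param clusters_per_subject integer length-2 inclusive range.
#' @param growth_rate,shrink_rate baseline per-cluster probabilities in `[0,1]`
#'   (their sum must not exceed 1).
#' @param boundary_speed mm of lesion border advance/retreat per interval.
#' @param covariate_effects named numeric, additive log-odds effects on the
#'   growth probability. Recognised names: `hypertension`, `diabetes`,
#'   `smoker`, `stroke_lacunar`, `bg_pvs_score`, `baseline_load` (the latter
#'   applies to the standardised baseline WMH load).
#' @param noise_sigma additive intensity noise sd; noise is clipped to
#'   `2*noise_sigma` so it can never flip a threshold decision.
#' @param sl_prob probability that a subject has a (separate) stroke lesion.
#' @param seed integer RNG seed; the whole cohort is a pure function of the
#'   configuration including this seed.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 40L,
                          grid_shape = c(48L, 48L, 8L),
                          voxel_dims = c(0.9375, 0.9375, 4),
                          clusters_per_subject = c(2L, 4L),
                          growth_rate = 0.6,
                          shrink_rate = 0.3,
                          boundary_speed = 1.5,
                          covariate_effects = c(hypertension = 0.7,
                                                diabetes = 0.3,
                                                smoker = 0.3,
                                                baseline_load = 0.2),
                          noise_sigma = 0.02,
                          sl_prob = 0.5,
                          seed = 1L) {
  stopifnot(n_subjects >= 0, length(grid_shape) == 3, all(grid_shape >= 1),
            length(clusters_per_subject) == 2,
            clusters_per_subject[1] >= 1,
            clusters_per_subject[1] <= clusters_per_subject[2])
  check_voxel_dims(voxel_dims)
  if (growth_rate < 0 || growth_rate > 1 || shrink_rate < 0 || shrink_rate > 1)
    stop("growth_rate and shrink_rate must lie in [0,1]")
  if (growth_rate + shrink_rate > 1)
    stop("growth_rate + shrink_rate must not exceed 1")
  if (noise_sigma < 0 || noise_sigma > 0.05)
    stop("noise_sigma must lie in [0, 0.05] to leave room for threshold guard bands")
  structure(list(n_subjects = as.integer(n_subjects),
                 grid_shape = as.integer(grid_shape),
                 voxel_dims = as.numeric(voxel_dims),
                 clusters_per_subject = as.integer(clusters_per_subject),
                 growth_rate = growth_rate, shrink_rate = shrink_rate,
                 boundary_speed = boundary_speed,
                 covariate_effects = covariate_effects,
                 noise_sigma = noise_sigma, sl_prob = sl_prob,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# Run expr with a local, restored RNG stream.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Normalised elliptical distance field of one cluster over the mm grid.
cluster_distance <- function(xs, ys, zs, centre, radii) {
  a1 <- ((xs - centre[1]) / radii[1])^2
  a2 <- ((ys - centre[2]) / radii[2])^2
  a3 <- ((zs - centre[3]) / radii[3])^2
  sqrt(outer(outer(a1, a2, "+"), a3, "+"))
}

# Separable box smoothing of a 3D array (edge-replicated), two passes.
smooth3 <- function(a, passes = 2L) {
  n <- dim(a)
  for (p in seq_len(passes)) {
    a <- (a[c(1, 1:(n[1] - 1)), , , drop = FALSE] + a +
          a[c(2:n[1], n[1]), , , drop = FALSE]) / 3
    a <- (a[, c(1, 1:(n[2] - 1)), , drop = FALSE] + a +
          a[, c(2:n[2], n[2]), , drop = FALSE]) / 3
    if (n[3] > 1)
      a <- (a[, , c(1, 1:(n[3] - 1)), drop = FALSE] + a +
            a[, , c(2:n[3], n[3]), drop = FALSE]) / 3
  }
  a
}

# Smooth tissue texture field: coarse noise, nearest-upsampled, box-smoothed.
smooth_field3 <- function(dims, scale = 8, amp = 1) {
  cd <- pmax(2L, ceiling(dims / scale))
  coarse <- array(rnorm(prod(cd)), cd)
  ix <- pmin(cd[1], ceiling(seq_len(dims[1]) / scale))
  iy <- pmin(cd[2], ceiling(seq_len(dims[2]) / scale))
  iz <- pmin(cd[3], ceiling(seq_len(dims[3]) / scale))
  amp * smooth3(coarse[ix, iy, iz, drop = FALSE], passes = 3L)
}

# Per-cluster intensity profiles. d is the normalised distance field,
# action one of "grow"/"shrink"/"stable"; cue=FALSE builds cue-free
# (follow-up style) crisp rims.
cluster_im_field <- function(d, action, sigma, cue = TRUE) {
  guard <- 2 * sigma
  lo <- WMH_THRESHOLDS[["IM"]] + guard + 0.005
  hi <- 0.95
  g <- pmin(1, pmax(0, (1 - d) / 0.6))
  f <- lo + (hi - lo) * g
  if (cue && action == "shrink") f[d > 0.7 & d <= 1] <- lo
  halo_amp <- if (cue && action == "grow") WMH_THRESHOLDS[["IM"]] - guard - 0.01 else 0.06
  halo_w <- if (cue && action == "grow") 0.5 else 0.25
  h <- halo_amp * pmax(0, 1 - (d - 1) / halo_w)
  ifelse(d <= 1, f, h)
}

cluster_pm_field <- function(d, action, sigma, cue = TRUE) {
  guard <- 2 * sigma
  lo <- WMH_THRESHOLDS[["PM"]] + guard + 0.005
  f <- ifelse(d <= 0.7, 1, lo + (1 - lo) * pmax(0, (1 - d) / 0.3))
  if (cue && action == "shrink") f[d > 0.85 & d <= 1] <- lo
  halo_amp <- if (cue && action == "grow") WMH_THRESHOLDS[["PM"]] - guard - 0.06 else 0.15
  halo_w <- if (cue && action == "grow") 0.5 else 0.25
  h <- halo_amp * pmax(0, 1 - (d - 1) / halo_w)
  ifelse(d <= 1, f, h)
}

cluster_flair_field <- function(d, action, cue = TRUE) {
  g <- pmin(1, pmax(0, (1 - d) / 0.6))
  f <- 0.15 + 0.45 * g
  if (cue && action == "shrink") f[d > 0.7 & d <= 1] <- 0.03
  halo_amp <- if (cue && action == "grow") 0.25 else 0.06
  halo_w <- if (cue && action == "grow") 0.5 else 0.25
  h <- halo_amp * pmax(0, 1 - (d - 1) / halo_w)
  ifelse(d <= 1, f, h)
}

#' Generate one synthetic longitudinal subject
#'
#' Consumes the current RNG stream; [generate_cohort()] seeds it. The
#' returned record carries paired baseline/follow-up IM, PM and FLAIR-like
#' volumes, WMH masks for both time points, stroke-lesion and ICV masks, the
#' clinical covariates, and the ground-truth three-class evolution label map.
#'
#' @param cfg a [cohort_config()].
#' @param subject_id identifier string.
#' @return an object of class `subject_record`.
#' @export
generate_subject <- function(cfg, subject_id = "s001") {
  dims <- cfg$grid_shape; vd <- cfg$voxel_dims
  if (dims[1] < 16 || dims[2] < 16)
    stop("grid too small for the requested lesion clusters (need >= 16 in-plane voxels)")
  xs <- (seq_len(dims[1]) - 0.5) * vd[1]
  ys <- (seq_len(dims[2]) - 0.5) * vd[2]
  zs <- (seq_len(dims[3]) - 0.5) * vd[3]
  fov <- dims * vd
  centre0 <- fov / 2
  ax <- c(0.44 * fov[1], 0.44 * fov[2], max(0.48 * fov[3], vd[3]))
  icv_d <- cluster_distance(xs, ys, zs, centre0, ax)
  icv <- icv_d <= 1

  # covariates
  cov <- list(diabetes = rbinom(1, 1, 0.12),
              hypertension = rbinom(1, 1, 0.75),
              smoker = rbinom(1, 1, 0.64),
              stroke_lacunar = rbinom(1, 1, 0.46),
              bg_pvs_score = sample(0:4, 1, prob = c(.15, .35, .3, .15, .05)))

  # lesion clusters: centres snapped to a slice so every cluster is non-empty
  cl_rng <- cfg$clusters_per_subject
  k <- if (cl_rng[1] == cl_rng[2]) cl_rng[1] else
    sample(seq(cl_rng[1], cl_rng[2]), 1)
  clusters <- vector("list", k)
  for (i in seq_len(k)) {
    repeat {
      cc <- c(runif(1, 0.18, 0.82) * fov[1], runif(1, 0.18, 0.82) * fov[2],
              zs[sample(seq_len(dims[3]), 1)])
      rel <- sum(((cc - centre0) / (0.62 * ax))^2)
      if (rel <= 1) break
    }
    radii <- c(runif(1, 3, 8), runif(1, 3, 8), runif(1, 4.5, 7))
    clusters[[i]] <- list(centre = cc, radii = radii,
                          d = cluster_distance(xs, ys, zs, cc, radii))
  }

  # baseline masks and load (needed for the logistic growth link)
  m0_raw <- Reduce(`|`, lapply(clusters, function(cl) cl$d <= 1))
  m0_arr <- m0_raw & icv
  vol0_tmp <- sum(m0_arr) * prod(vd) / 1000

  # covariate contributions are centred at their population means so the
  # configured growth_rate stays the marginal per-cluster rate
  cov_means <- c(diabetes = 0.12, hypertension = 0.75, smoker = 0.64,
                 stroke_lacunar = 0.46, bg_pvs_score = 1.6)
  eff <- cfg$covariate_effects
  eta <- stats::qlogis(min(max(cfg$growth_rate, 1e-6), 1 - 1e-6))
  for (nm in names(eff)) {
    if (nm == "baseline_load") eta <- eta + eff[[nm]] * (vol0_tmp - 1.5) / 0.75
    else if (!is.null(cov[[nm]]))
      eta <- eta + eff[[nm]] * (cov[[nm]] - cov_means[[nm]])
  }
  p_grow <- min(max(stats::plogis(eta), 0.02), 0.98)
  p_shrink_cond <- if (cfg$growth_rate >= 1) 0 else
    min(1, cfg$shrink_rate / (1 - cfg$growth_rate))

  actions <- character(k)
  for (i in seq_len(k)) {
    if (cfg$growth_rate == 0 && cfg$shrink_rate == 0) { actions[i] <- "stable"; next }
    if (runif(1) < p_grow) actions[i] <- "grow"
    else if (runif(1) < p_shrink_cond) actions[i] <- "shrink"
    else actions[i] <- "stable"
  }
  delta <- vapply(clusters, function(cl) cfg$boundary_speed / mean(cl$radii), 0)
  scale1 <- ifelse(actions == "grow", 1 + delta,
                   ifelse(actions == "shrink", 1 - delta, 1))

  # stroke lesion (removed from all WMH bookkeeping and from the images)
  sl <- array(FALSE, dims)
  if (runif(1) < cfg$sl_prob) {
    repeat {
      cc <- c(runif(1, 0.2, 0.8) * fov[1], runif(1, 0.2, 0.8) * fov[2],
              zs[sample(seq_len(dims[3]), 1)])
      if (sum(((cc - centre0) / (0.62 * ax))^2) <= 1) break
    }
    sl <- cluster_distance(xs, ys, zs, cc, c(runif(1, 3, 6), runif(1, 3, 6),
                                             runif(1, 4.5, 6))) <= 1 & icv
  }

  keep <- icv & !sl
  m0_arr <- m0_arr & keep
  m1_arr <- Reduce(`|`, lapply(seq_len(k), function(i)
    clusters[[i]]$d / scale1[i] <= 1)) & keep

  sigma <- cfg$noise_sigma
  build <- function(field_fun, scales, cue) {
    f <- Reduce(pmax, lapply(seq_len(k), function(i)
      field_fun(clusters[[i]]$d / scales[i], actions[i], cue)))
    f[!keep] <- 0
    f
  }
  imf <- function(d, a, cue) cluster_im_field(d, a, sigma, cue)
  pmf <- function(d, a, cue) cluster_pm_field(d, a, sigma, cue)
  one <- rep(1, k)

  clip_noise <- function(n) pmin(pmax(n, -2 * sigma), 2 * sigma)
  add_im_noise <- function(f) {
    n <- clip_noise(array(rnorm(prod(dims), 0, sigma), dims))
    pmin(pmax(f + ifelse(keep, n, 0), 0), 1)
  }
  add_pm_noise <- function(f) {
    n <- clip_noise(array(rnorm(prod(dims), 0, sigma), dims))
    pmin(pmax(f + ifelse(keep & f < 1, n, 0), 0), 1)
  }

  im0 <- add_im_noise(build(imf, one, cue = TRUE))
  im1 <- add_im_noise(build(imf, scale1, cue = FALSE))
  pm0 <- add_pm_noise(build(pmf, one, cue = TRUE))
  pm1 <- add_pm_noise(build(pmf, scale1, cue = FALSE))

  tissue <- 0.35 + smooth_field3(dims, scale = 8, amp = 0.06)
  fl_build <- function(scales, cue) {
    les <- Reduce(pmax, lapply(seq_len(k), function(i)
      cluster_flair_field(clusters[[i]]$d / scales[i], actions[i], cue)))
    f <- tissue + les + array(rnorm(prod(dims), 0, sigma), dims)
    f[!keep] <- 0
    pmax(f, 0)
  }
  fl0 <- fl_build(one, cue = TRUE)
  fl1 <- fl_build(scale1, cue = FALSE)

  mk_img <- function(dat, mod, tp) volume_image(dat, vd, mod, subject_id, tp)
  m0 <- binary_mask(m0_arr, "WMH", vd)
  m1 <- binary_mask(m1_arr, "WMH", vd)
  icv_m <- binary_mask(icv, "ICV", vd)
  sl_m <- binary_mask(sl, "SL", vd)
  truth <- label_dem_from_masks(m0, m1)

  vol0 <- wmh_volume_ml(m0); vol1 <- wmh_volume_ml(m1)
  sl_vol <- sum(sl) * prod(vd) / 1000
  icv_vol <- sum(icv) * prod(vd) / 1000
  covariates <- c(list(wmh_load_ml = vol0, sl_load_ml = sl_vol),
                  cov,
                  list(index_sl_pct_icv = 100 * sl_vol / icv_vol,
                       old_sl_pct_icv = if (runif(1) < 0.3) runif(1, 0.02, 0.3) else 0))

  structure(list(
    subject_id = subject_id,
    images = list(IM = list(baseline = mk_img(im0, "IM", "baseline"),
                            followup = mk_img(im1, "IM", "followup")),
                  PM = list(baseline = mk_img(pm0, "PM", "baseline"),
                            followup = mk_img(pm1, "PM", "followup")),
                  FLAIR = list(baseline = mk_img(fl0, "FLAIR", "baseline"),
                               followup = mk_img(fl1, "FLAIR", "followup"))),
    masks = list(wmh_baseline = m0, wmh_followup = m1, sl = sl_m, icv = icv_m),
    covariates = covariates,
    truth = truth,
    n_clusters = k,
    cluster_actions = actions,
    wmh_baseline_ml = vol0, wmh_followup_ml = vol1,
    icv_ml = icv_vol),
    class = "subject_record")
}

#' @export
print.subject_record <- function(x, ...) {
  cat(sprintf("<subject_record> %s  %d clusters (%s)  WMH %.3f -> %.3f ml\n",
              x$subject_id, x$n_clusters,
              paste(substr(x$cluster_actions, 1, 2), collapse = ","),
              x$wmh_baseline_ml, x$wmh_followup_ml))
  invisible(x)
}

#' Generate a full synthetic cohort
#'
#' Deterministic given the configuration: the RNG is seeded from
#' `cfg$seed` locally and restored afterwards.
#'
#' @param cfg a [cohort_config()].
#' @return a list of class `synthetic_cohort` with elements `subjects` (list
#'   of `subject_record`), `manifest` (one data.frame row per subject with
#'   covariates and true volumes) and `config`.
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  subjects <- with_seed(cfg$seed, {
    lapply(seq_len(cfg$n_subjects), function(i)
      generate_subject(cfg, sprintf("s%03d", i)))
  })
  manifest <- do.call(rbind, lapply(subjects, function(s) {
    data.frame(subject_id = s$subject_id,
               as.data.frame(s$covariates),
               wmh_baseline_ml = s$wmh_baseline_ml,
               wmh_followup_ml = s$wmh_followup_ml,
               icv_ml = s$icv_ml,
               n_clusters = s$n_clusters,
               n_grow = sum(s$cluster_actions == "grow"),
               n_shrink = sum(s$cluster_actions == "shrink"),
               true_direction = if (s$wmh_followup_ml > s$wmh_baseline_ml) "grow"
                                else if (s$wmh_followup_ml < s$wmh_baseline_ml) "shrink"
                                else "stable",
               stringsAsFactors = FALSE)
  }))
  if (is.null(manifest))
    manifest <- data.frame(subject_id = character(0))
  structure(list(subjects = subjects, manifest = manifest, config = cfg),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d subjects on %s grid (seed %d)\n",
              length(x$subjects),
              paste(x$config$grid_shape, collapse = "x"), x$config$seed))
  if (nrow(x$manifest))
    print(table(direction = x$manifest$true_direction))
  invisible(x)
}

#' Write a cohort to disk
#'
#' One directory per subject with NIfTI volumes and masks, a cohort-level
#' covariate manifest CSV, and a YAML snapshot of the configuration.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in cohort$subjects) {
    sd <- file.path(dir, s$subject_id)
    dir.create(sd, showWarnings = FALSE)
    for (mod in names(s$images)) for (tp in c("baseline", "followup"))
      write_volume(s$images[[mod]][[tp]],
                   file.path(sd, sprintf("%s_%s.nii.gz", tolower(mod), tp)))
    write_volume(s$masks$wmh_baseline, file.path(sd, "wmh_baseline.nii.gz"))
    write_volume(s$masks$wmh_followup, file.path(sd, "wmh_followup.nii.gz"))
    write_volume(s$masks$sl, file.path(sd, "sl.nii.gz"))
    write_volume(s$masks$icv, file.path(sd, "icv.nii.gz"))
    write_volume(s$truth, file.path(sd, "truth_labels.nii.gz"))
  }
  utils::write.csv(cohort$manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  cfg <- cohort$config
  cfg$covariate_effects <- as.list(cfg$covariate_effects)
  yaml::write_yaml(unclass(cfg), file.path(dir, "cohort.yaml"))
  invisible(dir)
}
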