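# Evaluation measurements: spatial agreement (Dice), subject-level direction
# accuracy, Bland-Altman volumetric agreement, volumetric correlation,
# ANCOVA clinical-plausibility models, the 10-sample noise testing protocol
# and subject-level cross-validation bookkeeping.

as_logical_mask <- function(x) {
  if (inherits(x, "binary_mask")) return(x$data)
  if (is.logical(x)) return(x)
  if (is.numeric(x) && all(x %in% c(0, 1))) return(x != 0)
  stop("expected a binary_mask or logical array")
}

#' Dice similarity coefficient
#'
#' `2 TP / (FP + 2 TP + FN)`. Two empty masks agree perfectly (DSC 1);
#' an empty mask against a non-empty one scores 0.
#'
#' @param a,b binary masks (`binary_mask` objects or logical arrays) on the
#'   same grid.
#' @return scalar in `[0, 1]`.
#' @export
dsc <- function(a, b) {
  a <- as_logical_mask(a); b <- as_logical_mask(b)
  if (length(a) != length(b) || !identical(dim(a), dim(b)))
    stop("grid mismatch between masks")
  tp <- sum(a & b)
  fp <- sum(!a & b) + sum(a & !b)  # disagreements in either direction
  if (tp == 0 && fp == 0) return(1)
  2 * tp / (fp + 2 * tp)
}

#' Per-class spatial agreement of two evolution label maps
#'
#' One-vs-rest Dice for the three foreground classes, plus: `change` =
#' Dice of (shrink or grow), and `entire` = Dice of the implied follow-up
#' WMH extent (stable or grow). `dsc_avg` is the mean of the three
#' single-class scores.
#'
#' @param pred,truth `evolution_label_map`s (or integer arrays with codes
#'   0--3) on the same grid.
#' @return named list with `dsc_entire`, `dsc_change`, `dsc_stable`,
#'   `dsc_shrink`, `dsc_grow`, `dsc_avg`.
#' @export
per_class_dsc <- function(pred, truth) {
  p <- if (inherits(pred, "evolution_label_map")) pred$data else pred
  t <- if (inherits(truth, "evolution_label_map")) truth$data else truth
  if (!all(p %in% 0:3) || !all(t %in% 0:3)) stop("invalid label codes")
  if (!identical(dim(p), dim(t))) stop("grid mismatch between label maps")
  st <- DEM_CODES[["stable"]]; sh <- DEM_CODES[["shrink"]]; gr <- DEM_CODES[["grow"]]
  out <- list(
    dsc_entire = dsc(p == st | p == gr, t == st | t == gr),
    dsc_change = dsc(p == sh | p == gr, t == sh | t == gr),
    dsc_stable = dsc(p == st, t == st),
    dsc_shrink = dsc(p == sh, t == sh),
    dsc_grow = dsc(p == gr, t == gr))
  out$dsc_avg <- mean(c(out$dsc_stable, out$dsc_shrink, out$dsc_grow))
  out
}

#' Subject-level direction-of-change accuracy
#'
#' `grow_pct` is the percentage of truly-growing subjects whose predicted
#' follow-up volume exceeds their baseline volume; `shrink_pct` analogous;
#' `avg_pct = (G + S) / 2`. Subjects with exactly zero true change carry no
#' direction and are excluded with a warning. Unit-free: any consistent
#' volume unit gives the same percentages.
#'
#' @param true_baseline,true_followup,pred_followup per-subject volumes
#'   (equal-length numeric vectors).
#' @return list with `grow_pct`, `shrink_pct`, `avg_pct`, `n_grow`,
#'   `n_shrink`.
#' @export
prediction_error <- function(true_baseline, true_followup, pred_followup) {
  stopifnot(length(true_baseline) == length(true_followup),
            length(true_followup) == length(pred_followup))
  d <- true_followup - true_baseline
  zero <- d == 0
  if (any(zero)) {
    warning(sprintf("%d subject(s) with zero true volume change excluded", sum(zero)))
    true_baseline <- true_baseline[!zero]
    pred_followup <- pred_followup[!zero]
    d <- d[!zero]
  }
  growers <- d > 0; shrinkers <- d < 0
  g <- if (any(growers))
    100 * mean(pred_followup[growers] > true_baseline[growers]) else NA_real_
  s <- if (any(shrinkers))
    100 * mean(pred_followup[shrinkers] < true_baseline[shrinkers]) else NA_real_
  list(grow_pct = g, shrink_pct = s, avg_pct = mean(c(g, s), na.rm = TRUE),
       n_grow = sum(growers), n_shrink = sum(shrinkers))
}

#' Bland-Altman volumetric agreement
#'
#' Differences are taken as `ground truth - predicted` (positive bias =
#' under-prediction). Limits of agreement are `bias +/- 1.96 * sd` with the
#' sample (n-1) standard deviation.
#'
#' @param gt_vols_ml,pred_vols_ml paired per-subject volumes in ml
#'   (length >= 2).
#' @return list of class `agreement_report` with `bias_ml`, `sd_ml`,
#'   `loa_lower_ml`, `loa_upper_ml`, `n`, and the paired `differences`.
#' @export
bland_altman <- function(gt_vols_ml, pred_vols_ml) {
  stopifnot(length(gt_vols_ml) == length(pred_vols_ml))
  if (length(gt_vols_ml) < 2) stop("Bland-Altman needs at least two pairs")
  d <- gt_vols_ml - pred_vols_ml
  bias <- mean(d)
  s <- stats::sd(d)
  structure(list(bias_ml = bias, sd_ml = s,
                 loa_lower_ml = bias - 1.96 * s,
                 loa_upper_ml = bias + 1.96 * s,
                 n = length(d), differences = d,
                 means = (gt_vols_ml + pred_vols_ml) / 2),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("Bland-Altman: bias %.3f ml (sd %.3f), LoA [%.3f, %.3f], n=%d\n",
              x$bias_ml, x$sd_ml, x$loa_lower_ml, x$loa_upper_ml, x$n))
  invisible(x)
}

#' Bland-Altman plot
#'
#' @param x an `agreement_report`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.agreement_report <- function(x, ...) {
  graphics::plot(x$means, x$differences, xlab = "mean of GT and predicted (ml)",
                 ylab = "GT - predicted (ml)", main = "Bland-Altman", ...)
  graphics::abline(h = c(x$bias_ml, x$loa_lower_ml, x$loa_upper_ml),
                   lty = c(1, 2, 2))
  invisible(x)
}

#' Volumetric correlation (trend line)
#'
#' Ordinary least squares of predicted on ground-truth volumes;
#' `r_squared` is the squared Pearson correlation.
#'
#' @param gt,pred paired volumes (typically % of ICV), length >= 3.
#' @return list with `r_squared`, `slope`, `intercept`.
#' @export
volumetric_correlation <- function(gt, pred) {
  stopifnot(length(gt) == length(pred))
  if (length(gt) < 3) stop("need at least three pairs")
  if (stats::var(gt) == 0) stop("zero variance in ground-truth volumes")
  fit <- stats::lm(pred ~ gt)
  list(r_squared = stats::cor(gt, pred)^2,
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]))
}

#' Subject-level cross-validation folds
#'
#' Partitions subjects (never slices or individual scans: both time points
#' of a subject stay together) into `k` near-equal folds.
#'
#' @param subject_ids character vector of unique ids.
#' @param k number of folds.
#' @param seed RNG seed.
#' @return named integer vector of fold assignments (1..k).
#' @export
crossval_folds <- function(subject_ids, k = 4L, seed = 1L) {
  if (k < 2) stop("need at least two folds")
  n <- length(subject_ids)
  if (anyDuplicated(subject_ids)) stop("subject ids must be unique")
  if (k > n) stop("more folds than subjects")
  with_seed(seed, {
    ord <- sample(n)
    folds <- integer(n)
    folds[ord] <- rep_len(seq_len(k), n)
    stats::setNames(folds, subject_ids)
  })
}

#' ANCOVA clinical-plausibility model
#'
#' Linear model of follow-up WMH burden (% of ICV) on baseline burden plus
#' the clinical covariates: lacunar stroke subtype, basal-ganglia
#' perivascular-space score, diabetes, hypertension, smoking, and index /
#' old stroke-lesion volumes (% of ICV). Returns per-covariate coefficient
#' estimates with two-sided Wald p-values. Rank deficiency raises an error
#' naming the aliased columns; pairwise-collinear covariates trigger a
#' variance-inflation warning.
#'
#' @param followup_pct_icv outcome: follow-up WMH volume as % of ICV.
#' @param baseline_pct_icv predictor: baseline WMH volume as % of ICV.
#' @param covariate_table data.frame of covariates (one row per subject).
#' @return data.frame of class `ancova_report` with columns `term`, `B`,
#'   `p`, and a formatted `B_p` column.
#' @export
ancova_plausibility <- function(followup_pct_icv, baseline_pct_icv,
                                covariate_table) {
  stopifnot(is.data.frame(covariate_table),
            length(followup_pct_icv) == nrow(covariate_table),
            length(baseline_pct_icv) == nrow(covariate_table))
  df <- data.frame(followup = followup_pct_icv, baseline = baseline_pct_icv,
                   covariate_table)
  cc <- stats::complete.cases(df)
  if (!all(cc)) df <- df[cc, , drop = FALSE]
  if (nrow(df) < ncol(df) + 1) stop("too few complete cases for the model")
  fit <- stats::lm(followup ~ ., data = df)
  cf <- stats::coef(fit)
  if (anyNA(cf))
    stop(sprintf("rank-deficient design: aliased column(s) %s",
                 paste(names(cf)[is.na(cf)], collapse = ", ")))
  X <- stats::model.matrix(fit)[, -1, drop = FALSE]
  if (ncol(X) > 1) {
    r2 <- vapply(seq_len(ncol(X)), function(j) {
      summary(stats::lm(X[, j] ~ X[, -j]))$r.squared
    }, 0)
    vif <- 1 / (1 - pmin(r2, 1 - 1e-12))
    if (any(vif > 10))
      warning(sprintf("high variance inflation (VIF > 10) for: %s",
                      paste(colnames(X)[vif > 10], collapse = ", ")))
  }
  sm <- summary(fit)$coefficients
  terms <- setdiff(rownames(sm), "(Intercept)")
  out <- data.frame(term = terms, B = sm[terms, 1], p = sm[terms, 4],
                    row.names = NULL)
  out$B_p <- sprintf("%.2f(%s)", out$B,
                     ifelse(out$p < 0.001, "<0.001", sprintf("%.2f", out$p)))
  class(out) <- c("ancova_report", "data.frame")
  attr(out, "fit") <- fit
  out
}

#' Paired Wilcoxon comparison of two models' per-subject scores
#'
#' Convenience wrapper around the paired two-sided Wilcoxon signed-rank
#' test.
#'
#' @param scores_a,scores_b paired per-subject metric vectors.
#' @return the `htest` object from [stats::wilcox.test()].
#' @export
compare_models_wilcoxon <- function(scores_a, scores_b) {
  stats::wilcox.test(scores_a, scores_b, paired = TRUE,
                     alternative = "two.sided", exact = FALSE)
}

# ---- model-level evaluation ------------------------------------------------

# Predicted three-class labels for one subject under any fitted DEP model.
predict_subject_labels <- function(model, subject, noise = NULL) {
  if (inherits(model, "dep_uresnet"))
    return(predict(model, subject, noise = noise))
  x1p <- predict(model, subject, noise = noise, type = "followup")
  m1p <- threshold_wmh(x1p)
  m0 <- threshold_wmh(subject$images[[model$modality]]$baseline)
  if (!is.null(subject$masks$sl)) {
    m1p <- exclude_stroke_lesions(m1p, subject$masks$sl)
    m0 <- exclude_stroke_lesions(m0, subject$masks$sl)
  }
  label_dem_from_masks(m0, m1p)
}

# Scores for a set of subjects under one fixed noise draw.
score_subjects_once <- function(model, subjects, noise) {
  per <- lapply(subjects, function(s) {
    lab <- predict_subject_labels(model, s, noise = noise)
    sc <- per_class_dsc(lab, s$truth)
    m0 <- s$masks$wmh_baseline
    pred_m1 <- predicted_followup_mask(m0, lab)
    c(sc, list(pred_vol_ml = wmh_volume_ml(pred_m1)))
  })
  dsc_cols <- c("dsc_entire", "dsc_change", "dsc_stable", "dsc_shrink",
                "dsc_grow", "dsc_avg")
  means <- vapply(dsc_cols, function(k)
    mean(vapply(per, function(x) x[[k]], 0)), 0)
  pe <- prediction_error(
    vapply(subjects, `[[`, 0, "wmh_baseline_ml"),
    vapply(subjects, `[[`, 0, "wmh_followup_ml"),
    vapply(per, `[[`, 0, "pred_vol_ml"))
  c(as.list(means), pe[c("grow_pct", "shrink_pct", "avg_pct")],
    list(pred_vols = vapply(per, `[[`, 0, "pred_vol_ml")))
}

#' Evaluate a Gaussian-auxiliary model with repeated noise sampling
#'
#' Draws `n_samples_test` Gaussian noise sets, scores the whole test set
#' under each, and reports both the average performance over the draws and
#' the metrics of the single draw with the highest average per-class Dice
#' ("best" noise).
#'
#' @param model fitted `dep_model` with `aux_mode = "gaussian"`.
#' @param subjects list of `subject_record`s (with ground truth).
#' @param noise_cfg a [noise_config()]; defaults to the model's.
#' @param seed RNG seed for the noise draws.
#' @return list with `mean` (metric list averaged over draws), `best`
#'   (metrics of the best draw), and `samples` (per-draw data.frame).
#' @export
evaluate_with_noise_sampling <- function(model, subjects,
                                         noise_cfg = model$noise_cfg,
                                         seed = 1L) {
  if (!identical(model$aux$mode, "gaussian"))
    stop("noise-sampling evaluation requires a Gaussian-auxiliary model")
  subjects <- cohort_subjects(subjects)
  with_seed(seed, {
    draws <- lapply(seq_len(noise_cfg$n_samples_test), function(i)
      stats::rnorm(model$aux$dim))
    res <- lapply(draws, function(z) score_subjects_once(model, subjects, z))
    keys <- c("dsc_entire", "dsc_change", "dsc_stable", "dsc_shrink",
              "dsc_grow", "dsc_avg", "grow_pct", "shrink_pct", "avg_pct")
    samples <- as.data.frame(do.call(rbind, lapply(res, function(r)
      unlist(r[keys]))))
    best_i <- which.max(samples$dsc_avg)
    list(mean = as.list(colMeans(samples, na.rm = TRUE)),
         best = res[[best_i]][keys],
         best_index = best_i,
         samples = samples)
  })
}
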