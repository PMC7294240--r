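test_that("Dice similarity follows 2TP / (FP + 2TP + FN)", {
  a <- rand_mask3(c(4, 4, 1), 0.5)
  expect_equal(dsc(a, a), 1)
  expect_equal(dsc(array(FALSE, c(2, 2, 1)), array(FALSE, c(2, 2, 1))), 1)
  expect_equal(dsc(array(FALSE, c(2, 2, 1)), array(TRUE, c(2, 2, 1))), 0)
  # TP=2, FP=1, FN=1 -> 4/6
  p <- array(c(TRUE, TRUE, TRUE, FALSE), c(2, 2, 1))
  t <- array(c(TRUE, TRUE, FALSE, TRUE), c(2, 2, 1))
  expect_equal(dsc(p, t), 2 * 2 / (2 + 2 * 2 + 0), tolerance = 1e-12)
  expect_equal(dsc(p, t), 4 / 6)
  # symmetric and invariant to background padding
  set.seed(1)
  x <- rand_mask3(); y <- rand_mask3()
  expect_equal(dsc(x, y), dsc(y, x))
  pad <- function(m) { out <- array(FALSE, dim(m) + c(4, 4, 0)); out[3:8, 3:8, ] <- m; out }
  expect_equal(dsc(pad(x), pad(y)), dsc(x, y))
  expect_error(dsc(x, rand_mask3(c(5, 5, 2))), "grid mismatch")
})

test_that("per-class Dice matches enumerated confusion counts on a hand-built map", {
  truth <- array(0L, c(4, 4, 1))
  truth[1, 1:2, 1] <- 1L  # stable
  truth[2, 1:2, 1] <- 2L  # shrink
  truth[3, 1:2, 1] <- 3L  # grow
  pred <- truth
  pred[2, 2, 1] <- 0L     # miss one shrink voxel
  pred[4, 4, 1] <- 3L     # spurious grow voxel
  sc <- per_class_dsc(pred, truth)
  expect_equal(sc$dsc_stable, 1)
  expect_equal(sc$dsc_shrink, 2 * 1 / (1 + 2 * 1 + 0))  # TP=1, FN=1
  expect_equal(sc$dsc_grow, 2 * 2 / (1 + 2 * 2 + 0))    # TP=2, FP=1
  expect_equal(sc$dsc_avg, mean(c(sc$dsc_stable, sc$dsc_shrink, sc$dsc_grow)))
  # change = shrink-or-grow one-vs-rest
  expect_equal(sc$dsc_change, dsc(pred == 2 | pred == 3, truth == 2 | truth == 3))
  # entire = implied follow-up extent (stable-or-grow)
  expect_equal(sc$dsc_entire, dsc(pred == 1 | pred == 3, truth == 1 | truth == 3))
  # prediction against itself is perfect everywhere
  self <- per_class_dsc(truth, truth)
  expect_true(all(unlist(self) == 1))
  # all-background prediction scores zero on present classes
  sc0 <- per_class_dsc(array(0L, c(4, 4, 1)), truth)
  expect_equal(sc0$dsc_stable, 0); expect_equal(sc0$dsc_grow, 0)
  expect_error(per_class_dsc(array(5L, c(2, 2, 1)), array(0L, c(2, 2, 1))),
               "invalid label codes")
})

test_that("direction accuracy counts growers and shrinkers separately", {
  # perfect predictions
  pe <- prediction_error(c(1, 2, 3), c(2, 1, 4), c(2.5, 1.2, 5))
  expect_equal(pe$grow_pct, 100); expect_equal(pe$shrink_pct, 100)
  expect_equal(pe$avg_pct, 100)
  # predictions equal to baseline are never counted as correct
  pe0 <- prediction_error(c(1, 2, 3), c(2, 1, 4), c(1, 2, 3))
  expect_equal(pe0$avg_pct, 0)
  # 3 growers (2 correct), 2 shrinkers (1 correct) -> (66.67, 50, 58.33)
  base <- c(1, 1, 1, 2, 2); fup <- c(2, 2, 2, 1, 1)
  pred <- c(1.5, 1.5, 0.5, 1.5, 2.5)
  pe2 <- prediction_error(base, fup, pred)
  expect_equal(pe2$grow_pct, 200 / 3, tolerance = 1e-10)
  expect_equal(pe2$shrink_pct, 50)
  expect_equal(pe2$avg_pct, (200 / 3 + 50) / 2, tolerance = 1e-10)
  # zero-change subjects are excluded with a warning
  expect_warning(pe3 <- prediction_error(c(1, 1), c(1, 2), c(9, 9)),
                 "zero true volume change")
  expect_equal(pe3$n_grow, 1)
  # unit invariance (ml vs mm^3)
  pe_ml <- prediction_error(base, fup, pred)
  pe_mm <- prediction_error(base * 1000, fup * 1000, pred * 1000)
  expect_equal(pe_ml$avg_pct, pe_mm$avg_pct)
})

test_that("Bland-Altman bias and limits of agreement are mean +/- 1.96 sd", {
  ba0 <- bland_altman(c(5, 7, 9), c(5, 7, 9))
  expect_equal(ba0$bias_ml, 0); expect_equal(ba0$loa_lower_ml, 0)
  ba <- bland_altman(c(10, 20), c(12, 18))
  expect_equal(ba$bias_ml, 0)
  expect_equal(ba$sd_ml, 2.8284271, tolerance = 1e-6)
  expect_equal(ba$loa_upper_ml, 1.96 * sqrt(8), tolerance = 1e-10)
  expect_equal(ba$loa_lower_ml, -1.96 * sqrt(8), tolerance = 1e-10)
  # shifting predictions by +c shifts bias by -c, width unchanged
  set.seed(2)
  gt <- stats::runif(20, 1, 10); pr <- gt + stats::rnorm(20)
  b1 <- bland_altman(gt, pr); b2 <- bland_altman(gt, pr + 3)
  expect_equal(b2$bias_ml, b1$bias_ml - 3)
  expect_equal(b2$loa_upper_ml - b2$loa_lower_ml,
               b1$loa_upper_ml - b1$loa_lower_ml)
  expect_error(bland_altman(1, 2), "at least two")
})

test_that("limits of agreement bracket ~95% of normally distributed differences", {
  set.seed(3)
  n <- 1e4
  gt <- stats::runif(n, 5, 15)
  pr <- gt + stats::rnorm(n, 0.5, 2)
  ba <- bland_altman(gt, pr)
  inside <- mean(ba$differences >= ba$loa_lower_ml &
                 ba$differences <= ba$loa_upper_ml)
  expect_equal(inside, 0.95, tolerance = 0.01)
})

test_that("volumetric correlation equals the closed-form OLS solution", {
  expect_equal(volumetric_correlation(1:5, 1:5),
               list(r_squared = 1, slope = 1, intercept = 0))
  out <- volumetric_correlation(1:5, 2 * (1:5) + 3)
  expect_equal(out$r_squared, 1); expect_equal(out$slope, 2)
  expect_equal(out$intercept, 3)
  set.seed(4)
  gt <- stats::runif(30); pr <- 0.8 * gt + stats::rnorm(30, 0, 0.1)
  got <- volumetric_correlation(gt, pr)
  X <- cbind(1, gt)
  beta <- solve(crossprod(X), crossprod(X, pr))  # normal equations oracle
  expect_equal(got$intercept, beta[1], tolerance = 1e-10)
  expect_equal(got$slope, beta[2], tolerance = 1e-10)
  expect_equal(got$r_squared, stats::cor(gt, pr)^2, tolerance = 1e-12)
  expect_error(volumetric_correlation(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(volumetric_correlation(1:2, 1:2), "at least three")
})

test_that("cross-validation folds are subject-level, near-equal and reproducible", {
  ids <- sprintf("s%03d", 1:152)
  f <- crossval_folds(ids, k = 4, seed = 1)
  expect_equal(as.vector(table(f)), rep(38L, 4))
  expect_setequal(names(f), ids)
  expect_identical(f, crossval_folds(ids, k = 4, seed = 1))
  expect_false(identical(f, crossval_folds(ids, k = 4, seed = 2)))
  # uneven division stays within one subject
  f2 <- crossval_folds(sprintf("t%d", 1:10), k = 3, seed = 1)
  expect_lte(diff(range(table(f2))), 1)
  expect_error(crossval_folds(ids, k = 1), "at least two")
  expect_error(crossval_folds(ids[1:3], k = 4), "more folds than subjects")
  expect_error(crossval_folds(c("a", "a", "b"), k = 2), "unique")
})

test_that("ANCOVA recovers the generative model on simulated cohorts", {
  set.seed(5)
  n <- 200
  covs <- data.frame(stroke_lacunar = stats::rbinom(n, 1, 0.46),
                     bg_pvs_score = sample(0:4, n, replace = TRUE),
                     diabetes = stats::rbinom(n, 1, 0.12),
                     hypertension = stats::rbinom(n, 1, 0.75),
                     smoker = stats::rbinom(n, 1, 0.64),
                     index_sl_pct_icv = stats::runif(n, 0, 1),
                     old_sl_pct_icv = stats::runif(n, 0, 0.5))
  base <- stats::runif(n, 0.2, 3)
  # outcome identically the predictor: baseline coefficient 1, covariates null
  # (suppress the perfect-fit note from the underlying least-squares summary)
  out <- suppressWarnings(ancova_plausibility(base, base, covs))
  expect_equal(out$B[out$term == "baseline"], 1, tolerance = 1e-10)
  expect_true(all(out$p[out$term != "baseline"] > 0.05))
  # injected effect recovered within 2 standard errors
  fup <- base + 0.8 * covs$hypertension + stats::rnorm(n, 0, 0.3)
  out2 <- ancova_plausibility(fup, base, covs)
  b <- out2$B[out2$term == "hypertension"]
  fit <- attr(out2, "fit")
  se <- summary(fit)$coefficients["hypertension", 2]
  expect_lt(abs(b - 0.8), 2 * se)
  expect_match(out2$B_p[out2$term == "hypertension"], "^-?\\d+\\.\\d{2}\\(")
  # duplicated covariate column: designed singularity failure
  covs_dup <- covs
  covs_dup$dup <- covs_dup$hypertension
  expect_error(ancova_plausibility(fup, base, covs_dup), "aliased|rank-deficient")
})

test_that("load normalisation is a population z-score with reusable parameters", {
  z <- normalise_loads(c(1, 2, 3))
  expect_equal(z$values, c(-1.22474487, 0, 1.22474487), tolerance = 1e-8)
  expect_equal(mean(z$values), 0)
  expect_equal(mean(z$values^2), 1, tolerance = 1e-12)  # population variance
  # test-time reuse of training parameters: no re-fit
  z2 <- normalise_loads(c(10, 20), scaler = z)
  expect_equal(z2$center, z$center); expect_equal(z2$scale, z$scale)
  expect_equal(z2$values, (c(10, 20) - 2) / z$scale)
  expect_error(normalise_loads(c(5, 5, 5)), "zero variance")
  expect_error(normalise_loads(3), "at least two")
})

test_that("paired Wilcoxon wrapper reports a two-sided signed-rank test", {
  set.seed(6)
  a <- stats::runif(20); b <- a + 0.2 + stats::rnorm(20, 0, 0.05)
  ht <- compare_models_wilcoxon(a, b)
  expect_s3_class(ht, "htest")
  expect_lt(ht$p.value, 0.01)
  expect_match(ht$method, "Wilcoxon")
})
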