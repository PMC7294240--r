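# Adversarial and regularisation losses for the evolution predictor.

#' Regularisation loss weights and gradient-penalty factor
#'
#' Defaults: intensity (L1) weight 100, Dice weight 1, volume (L2) weight
#' 100, gradient-penalty factor 10. Setting a lambda to 0 removes that term
#' exactly.
#'
#' @param lambda1 weight of the mean-absolute-error intensity term.
#' @param lambda2 weight of the (1 - soft Dice) term.
#' @param lambda3 weight of the squared volume-error term (ml^2).
#' @param gp_factor gradient-penalty multiplier for critic training.
#' @return object of class `loss_weights`.
#' @export
loss_weights <- function(lambda1 = 100, lambda2 = 1, lambda3 = 100,
                         gp_factor = 10) {
  if (any(c(lambda1, lambda2, lambda3, gp_factor) < 0))
    stop("loss weights must be non-negative")
  structure(list(lambda1 = lambda1, lambda2 = lambda2, lambda3 = lambda3,
                 gp_factor = gp_factor), class = "loss_weights")
}

#' Adversarial training schedule
#'
#' Each critic is updated `n_critic` times per generator update; in the
#' first `warmup_iters` generator iterations and on every `heavy_every`-th
#' one thereafter, critics are updated `heavy_n_critic` times. `epochs`
#' counts generator updates for the GAN variants and data epochs for the
#' supervised variant.
#'
#' @param n_critic,warmup_iters,heavy_every,heavy_n_critic,epochs positive
#'   integers.
#' @param variant one of `"depgan_2c"`, `"depgan_1c"`, `"vagan"`,
#'   `"wgan_gp"`, `"uresnet"`.
#' @return object of class `dep_schedule`.
#' @export
dep_schedule <- function(n_critic = 5L, warmup_iters = 25L, heavy_every = 100L,
                         heavy_n_critic = 100L, epochs = 200L,
                         variant = c("depgan_2c", "depgan_1c", "vagan",
                                     "wgan_gp", "uresnet")) {
  variant <- match.arg(variant)
  v <- c(n_critic, warmup_iters, heavy_every, heavy_n_critic, epochs)
  if (any(v < 1) || any(v != round(v))) stop("schedule fields must be positive integers")
  structure(list(n_critic = as.integer(n_critic),
                 warmup_iters = as.integer(warmup_iters),
                 heavy_every = as.integer(heavy_every),
                 heavy_n_critic = as.integer(heavy_n_critic),
                 epochs = as.integer(epochs), variant = variant),
            class = "dep_schedule")
}

#' Gaussian-noise auxiliary configuration
#'
#' @param dim noise vector length.
#' @param n_candidates_train candidate sets per training step (Min-of-N
#'   selection keeps only the lowest-loss one).
#' @param n_samples_test noise sets drawn per subject at test time.
#' @return object of class `noise_config`.
#' @export
noise_config <- function(dim = 32L, n_candidates_train = 10L,
                         n_samples_test = 10L) {
  stopifnot(dim >= 1, n_candidates_train >= 1, n_samples_test >= 1)
  structure(list(dim = as.integer(dim),
                 n_candidates_train = as.integer(n_candidates_train),
                 n_samples_test = as.integer(n_samples_test)),
            class = "noise_config")
}

#' Critic loss for the follow-up-image critic D
#'
#' `mean(scores of real follow-ups) - mean(scores of fake follow-ups)`.
#' The critic is trained to maximise this; the generator minimises its
#' negation.
#'
#' @param scores_real,scores_fake numeric score vectors of equal length.
#' @return scalar.
#' @export
critic_loss_D <- function(scores_real, scores_fake) {
  if (!length(scores_real) || !length(scores_fake))
    stop("empty score batch")
  if (length(scores_real) != length(scores_fake))
    stop("mismatched batch sizes")
  mean(scores_real) - mean(scores_fake)
}

#' Critic loss for the DEM critic C
#'
#' Identical form to [critic_loss_D()] but evaluated on DEM scores (real DEM
#' = follow-up minus baseline; fake DEM = generator output).
#'
#' @inheritParams critic_loss_D
#' @return scalar.
#' @export
critic_loss_C <- function(scores_real, scores_fake) {
  critic_loss_D(scores_real, scores_fake)
}

#' Wasserstein gradient penalty
#'
#' For each sample an interpolate `xhat = a*real + (1-a)*fake` (`a` uniform)
#' is scored by the critic, and the penalty is
#' `gp_factor * mean((||grad_x critic(xhat)||_2 - 1)^2)`. The input gradient
#' is computed exactly by reverse-mode differentiation.
#'
#' @param critic a `dep_critic`, or a numeric array `w` standing for the
#'   linear critic `x -> sum(w * x)` (useful for analytic checks).
#' @param real_batch,fake_batch lists of `H x W` slices (or single
#'   matrices/arrays of matching shape).
#' @param gp_factor penalty multiplier.
#' @return scalar penalty (non-negative).
#' @export
gradient_penalty <- function(critic, real_batch, fake_batch, gp_factor = 10) {
  if (!is.list(real_batch)) real_batch <- list(real_batch)
  if (!is.list(fake_batch)) fake_batch <- list(fake_batch)
  stopifnot(length(real_batch) == length(fake_batch))
  n <- length(real_batch)
  alpha <- stats::runif(n)
  xhat <- lapply(seq_len(n), function(i)
    alpha[i] * real_batch[[i]] + (1 - alpha[i]) * fake_batch[[i]])
  if (is.numeric(critic)) {
    # linear critic: gradient is the (constant) weight array
    nrm <- sqrt(sum(critic^2))
    return(gp_factor * mean(rep((nrm - 1)^2, n)))
  }
  stopifnot(inherits(critic, "dep_critic"))
  norms <- critic_input_grad_norms(critic, xhat)$norms
  gp_factor * mean((norms - 1)^2)
}

# Tape pass returning per-sample input-gradient norms and the (normalised)
# gradient directions; shared by gradient_penalty() and the critic trainer.
critic_input_grad_norms <- function(critic, xhat_slices) {
  mult <- 2^(critic$spec$depth - 1L)
  pads <- lapply(xhat_slices, pad_to_multiple, mult = mult)
  H <- nrow(pads[[1]]$m); W <- ncol(pads[[1]]$m)
  N <- length(xhat_slices)
  dims <- list(H = H, W = W, N = N)
  tp <- tape_new()
  x <- nd_leaf(tp, pack_slices(lapply(pads, `[[`, "m")))
  s <- tape_critic(tp, critic, x, dims)
  total <- nd_wsum(tp, s, 1)
  tape_backward(tp, total)
  G <- x$grad
  sidx <- sample_of_row(H, W, N)
  norms <- sqrt(rowsum(G * G, sidx)[, 1])
  list(norms = norms, grad = G, dims = dims,
       xhat_packed = pack_slices(lapply(pads, `[[`, "m")))
}

#' Differentiable (soft) Dice similarity of two IM/PM volumes
#'
#' Voxel memberships are obtained by a steep logistic step at the modality
#' threshold (0.178 for IM, 0.5 for PM); the Dice coefficient is then
#' computed on the soft memberships with an additive smoothing constant. As
#' the step sharpness grows this converges to the hard-mask Dice
#' `2TP / (FP + 2TP + FN)`.
#'
#' @param x1_fake,x1_real numeric arrays on the same grid.
#' @param modality `"IM"` or `"PM"`.
#' @param sharpness logistic steepness `k`.
#' @param eps smoothing constant added to numerator and denominator.
#' @return scalar in `[0, 1]` (up to the epsilon smoothing).
#' @export
soft_dsc <- function(x1_fake, x1_real, modality = c("IM", "PM"),
                     sharpness = 50, eps = 1) {
  modality <- match.arg(modality)
  if (!identical(dim(x1_fake), dim(x1_real)) ||
      length(x1_fake) != length(x1_real))
    stop("grid mismatch between volumes")
  thr <- WMH_THRESHOLDS[[modality]]
  a <- stats::plogis(sharpness * (x1_fake - thr))
  b <- stats::plogis(sharpness * (x1_real - thr))
  (2 * sum(a * b) + eps) / (sum(a) + sum(b) + eps)
}

#' Regularisation loss on a generated follow-up image
#'
#' `lambda1 * MAE(x1', x1) + lambda2 * (1 - softDSC(x1', x1)) +
#'  lambda3 * (vol(x1') - vol(x1))^2`, with volumes in ml obtained from the
#' soft threshold memberships times the voxel volume. The unweighted terms
#' are attached as the `"terms"` attribute so the decomposition is
#' recoverable.
#'
#' @param x1_fake,x1_real numeric arrays on the same grid.
#' @param weights a [loss_weights()].
#' @param modality `"IM"` or `"PM"`.
#' @param voxel_dims voxel size in mm (for the ml volume term).
#' @param sharpness,eps soft-threshold parameters, see [soft_dsc()].
#' @return scalar with attribute `terms = c(intensity, dsc, volume)`.
#' @export
regularisation_loss <- function(x1_fake, x1_real, weights = loss_weights(),
                                modality = c("IM", "PM"),
                                voxel_dims = c(0.9375, 0.9375, 4),
                                sharpness = 50, eps = 1) {
  modality <- match.arg(modality)
  stopifnot(inherits(weights, "loss_weights"))
  if (!identical(dim(x1_fake), dim(x1_real)) ||
      length(x1_fake) != length(x1_real))
    stop("grid mismatch between volumes")
  thr <- WMH_THRESHOLDS[[modality]]
  vox_ml <- prod(voxel_dims) / 1000
  t_int <- mean(abs(x1_fake - x1_real))
  t_dsc <- 1 - soft_dsc(x1_fake, x1_real, modality, sharpness, eps)
  a <- stats::plogis(sharpness * (x1_fake - thr))
  b <- stats::plogis(sharpness * (x1_real - thr))
  t_vol <- (sum(a) * vox_ml - sum(b) * vox_ml)^2
  out <- weights$lambda1 * t_int + weights$lambda2 * t_dsc +
    weights$lambda3 * t_vol
  attr(out, "terms") <- c(intensity = t_int, dsc = t_dsc, volume = t_vol)
  out
}

#' Generator-side objective for a GAN variant
#'
#' Sums the variant's adversarial terms (the negated mean fake scores of the
#' critics it uses) and its regularisation loss. Variants:
#' `wgan_gp` (DEM critic C only, no regularisation), `vagan` (image critic D
#' plus intensity-only regularisation), `depgan_1c` (D plus full
#' regularisation), `depgan_2c` (C and D plus full regularisation).
#'
#' @param variant variant name.
#' @param scores named list with fake-score vectors `D` and/or `C` as the
#'   variant requires.
#' @param reg_loss scalar regularisation loss (see [regularisation_loss()]);
#'   must be `NULL` for `wgan_gp`. For `vagan` pass a loss computed with
#'   `lambda2 = lambda3 = 0`.
#' @return scalar objective (the generator minimises it).
#' @export
generator_objective <- function(variant = c("depgan_2c", "depgan_1c", "vagan",
                                            "wgan_gp"),
                                scores, reg_loss = NULL) {
  variant <- match.arg(variant)
  need <- switch(variant, wgan_gp = "C", vagan = "D", depgan_1c = "D",
                 depgan_2c = c("C", "D"))
  have <- names(scores)[!vapply(scores, is.null, TRUE)]
  if (!setequal(have, need))
    stop(sprintf("variant '%s' requires critic scores {%s}, got {%s}",
                 variant, paste(need, collapse = ","),
                 paste(have, collapse = ",")))
  if (variant == "wgan_gp" && !is.null(reg_loss))
    stop("wgan_gp has no image regularisation term")
  adv <- sum(vapply(need, function(k) -mean(scores[[k]]), 0))
  adv + if (is.null(reg_loss)) 0 else as.numeric(reg_loss)
}

#' Min-of-N Gaussian noise selection
#'
#' Draws `n_candidates` standard-normal auxiliary vectors, evaluates the
#' supplied loss for each, and returns the candidate with the smallest loss
#' (only that candidate is used for the parameter update).
#'
#' @param loss_fun function taking one noise vector and returning a scalar
#'   loss (typically the generator objective on the current minibatch).
#' @param cfg a [noise_config()].
#' @param n_candidates number of candidates (defaults to
#'   `cfg$n_candidates_train`).
#' @return list with `noise` (the selected vector), `loss`, `index` and the
#'   full `losses` vector.
#' @export
select_noise <- function(loss_fun, cfg = noise_config(),
                         n_candidates = cfg$n_candidates_train) {
  stopifnot(n_candidates >= 1)
  cand <- lapply(seq_len(n_candidates), function(i) stats::rnorm(cfg$dim))
  losses <- vapply(cand, function(z) as.numeric(loss_fun(z)), 0)
  i <- which.min(losses)
  list(noise = cand[[i]], loss = losses[i], index = i, losses = losses)
}
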