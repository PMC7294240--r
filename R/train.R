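# Trainers for the supervised (DEP-UResNet) and adversarial (DEP-GAN)
# evolution predictors, exposed as model-fitting functions returning classed
# objects with print/summary/predict/plot methods.

# ---- shared helpers --------------------------------------------------------

rot90m <- function(m) t(m[rev(seq_len(nrow(m))), , drop = FALSE])

apply_geom <- function(m, k, fl) {
  if (is.null(m)) return(NULL)
  if (k > 0) for (i in seq_len(k)) m <- rot90m(m)
  if (fl) m <- m[, rev(seq_len(ncol(m))), drop = FALSE]
  m
}

# Random flip/rotation parameters for one slice (square slices get all four
# rotations, rectangular ones only the 180-degree one).
draw_geom <- function(H, W) {
  k <- if (H == W) sample(0:3, 1) else sample(c(0L, 2L), 1)
  list(k = k, fl = stats::runif(1) < 0.5)
}

# Auxiliary-input state fitted on the training cohort.
fit_aux_state <- function(mode, subjects, aux_dim) {
  st <- list(mode = mode, dim = as.integer(aux_dim))
  getcov <- function(field) vapply(subjects, function(s) {
    v <- s$covariates[[field]]
    if (is.null(v)) stop(sprintf("aux mode '%s' needs covariate '%s'", mode, field))
    as.numeric(v)
  }, 0)
  if (mode %in% c("wmh_load", "wmh_sl_loads"))
    st$wmh_scaler <- normalise_loads(getcov("wmh_load_ml"))[c("center", "scale")]
  if (mode == "wmh_sl_loads")
    st$sl_scaler <- normalise_loads(getcov("sl_load_ml"))[c("center", "scale")]
  st
}

# Per-subject auxiliary vector (constant across that subject's slices);
# load vectors are zero-padded to aux_dim so one branch serves all modes.
aux_for_subject <- function(st, subject, noise = NULL) {
  switch(st$mode,
    none = NULL,
    gaussian = {
      if (is.null(noise)) noise <- stats::rnorm(st$dim)
      as.numeric(noise)
    },
    wmh_load = {
      z <- (subject$covariates$wmh_load_ml - st$wmh_scaler$center) / st$wmh_scaler$scale
      c(z, numeric(st$dim - 1L))
    },
    wmh_sl_loads = {
      z1 <- (subject$covariates$wmh_load_ml - st$wmh_scaler$center) / st$wmh_scaler$scale
      z2 <- (subject$covariates$sl_load_ml - st$sl_scaler$center) / st$sl_scaler$scale
      c(z1, z2, numeric(st$dim - 2L))
    },
    stop("unknown aux mode"))
}

aux_matrix_for_slices <- function(st, slice_subjects, subj_lookup, noise = NULL) {
  if (st$mode == "none") return(NULL)
  do.call(rbind, lapply(slice_subjects, function(sid)
    aux_for_subject(st, subj_lookup[[sid]], noise = noise)))
}

add_grads <- function(a, b) {
  for (nm in names(b)) a[[nm]] <- if (is.null(a[[nm]])) b[[nm]] else a[[nm]] + b[[nm]]
  a
}

cohort_subjects <- function(cohort) {
  if (inherits(cohort, "synthetic_cohort")) return(cohort$subjects)
  if (inherits(cohort, "subject_record")) return(list(cohort))
  if (is.list(cohort) && all(vapply(cohort, inherits, TRUE, "subject_record")))
    return(cohort)
  stop("expected a synthetic_cohort, a subject_record, or a list of subject_records")
}

# ---- DEP-UResNet -----------------------------------------------------------

#' Fit a DEP-UResNet evolution segmenter
#'
#' Supervised three-class prediction of WMH evolution: the network reads a
#' baseline FLAIR-like axial slice and predicts, per voxel, one of
#' background / stable / shrink / grow. Trained with class-weighted
#' categorical cross-entropy (inverse-frequency weights, capped), Adam, and
#' flip/rotation augmentation; with Gaussian auxiliary input the Min-of-N
#' rule evaluates several noise candidates per step and backpropagates only
#' the lowest-loss one.
#'
#' @param cohort a `synthetic_cohort` or list of `subject_record`s with
#'   ground-truth label maps.
#' @param spec a [generator_spec()] with `softmax4` output; the default is a
#'   small 3-level network suited to 48x48 slices.
#' @param epochs data epochs.
#' @param batch_size slices per update.
#' @param lr Adam learning rate.
#' @param aux_mode auxiliary input: `"gaussian"`, `"none"`, `"wmh_load"`,
#'   or `"wmh_sl_loads"`.
#' @param noise_cfg a [noise_config()]; the trainer default uses 3 training
#'   candidates to keep desk-scale CPU cost down while retaining the
#'   Min-of-N mechanics.
#' @param val_fraction fraction of slices held out for validation loss.
#' @param augment apply random flip/rotation augmentation.
#' @param class_weight_cap upper bound on inverse-frequency class weights.
#' @param seed RNG seed; training is deterministic given it.
#' @param verbose print per-epoch losses.
#' @return object of class `c("dep_uresnet", "dep_model")`.
#' @export
dep_uresnet <- function(cohort,
                        spec = generator_spec(depth = 3L, base_channels = 16L,
                                              output_activation = "softmax4",
                                              resblocks_per_level = 1L),
                        epochs = 30L, batch_size = 16L, lr = 1e-3,
                        aux_mode = c("gaussian", "none", "wmh_load",
                                     "wmh_sl_loads"),
                        noise_cfg = noise_config(n_candidates_train = 3L),
                        val_fraction = 0.2, augment = TRUE,
                        class_weight_cap = 20, seed = 1L, verbose = FALSE) {
  aux_mode <- match.arg(aux_mode)
  stopifnot(inherits(spec, "generator_spec"))
  if (spec$output_activation != "softmax4")
    spec <- utils::modifyList(spec, list(output_activation = "softmax4",
                                         out_channels = 4L))
  subjects <- cohort_subjects(cohort)
  slices <- extract_training_slices(subjects, "FLAIR")
  if (!length(slices)) stop("empty training set: no slices with brain tissue")
  if (any(vapply(slices, function(s) is.null(s$labels), TRUE)))
    stop("DEP-UResNet needs ground-truth label maps for every subject")
  H <- attr(slices, "H"); W <- attr(slices, "W")
  mult <- 2^spec$depth
  if (H %% mult || W %% mult)
    stop(sprintf("slice size %dx%d must be divisible by 2^depth = %d", H, W, mult))
  subj_lookup <- stats::setNames(subjects,
                                 vapply(subjects, `[[`, "", "subject_id"))

  fit <- with_seed(seed, {
    st <- fit_aux_state(aux_mode, subjects, spec$aux_dim)
    n <- length(slices)
    val_idx <- if (val_fraction > 0 && n >= 5)
      sample(n, max(1L, round(val_fraction * n))) else integer(0)
    tr_idx <- setdiff(seq_len(n), val_idx)
    if (!length(tr_idx)) stop("no training slices left after validation split")

    counts <- rep(0, 4)
    for (i in tr_idx)
      counts <- counts + tabulate(as.integer(slices[[i]]$labels) + 1L, 4L)
    w <- sum(counts) / (4 * pmax(counts, 1))
    w <- pmin(w / mean(w[counts > 0]), class_weight_cap)
    w[counts == 0] <- class_weight_cap

    gen <- build_generator(spec, seed = sample.int(.Machine$integer.max, 1))
    opt <- adam_new(gen$ps, lr = lr)
    dims_for <- function(N) list(H = H, W = W, N = N)

    batch_tensors <- function(idx, aug) {
      xs <- vector("list", length(idx)); ys <- vector("list", length(idx))
      sids <- character(length(idx))
      for (j in seq_along(idx)) {
        sl <- slices[[idx[j]]]
        g <- if (aug) draw_geom(H, W) else list(k = 0L, fl = FALSE)
        xs[[j]] <- apply_geom(sl$x0, g$k, g$fl)
        ys[[j]] <- apply_geom(sl$labels, g$k, g$fl)
        sids[j] <- sl$subject_id
      }
      list(X = pack_slices(xs),
           target = as.integer(unlist(ys, use.names = FALSE)) + 1L,
           sids = sids)
    }

    ce_tape <- function(bt, auxmat, train) {
      tp <- tape_new()
      x <- nd_leaf(tp, bt$X)
      a <- if (is.null(auxmat)) NULL else nd_leaf(tp, auxmat)
      logits <- tape_generator(tp, gen, x, a, dims_for(length(bt$sids)),
                               train = train, logits = TRUE)
      list(tp = tp, loss = nd_softmax_ce(tp, logits, bt$target, w))
    }

    log <- data.frame(epoch = integer(0), train_loss = numeric(0),
                      val_loss = numeric(0))
    for (ep in seq_len(epochs)) {
      ord <- sample(tr_idx)
      ep_loss <- 0; nb <- 0L
      for (b0 in seq(1L, length(ord), by = batch_size)) {
        idx <- ord[b0:min(b0 + batch_size - 1L, length(ord))]
        bt <- batch_tensors(idx, aug = augment)
        if (st$mode == "gaussian") {
          # rank noise candidates on a subsample of the minibatch: selection
          # only needs the ordering of candidate losses
          sub <- seq_len(min(length(idx), 6L))
          bsub <- list(X = bt$X[seq_len(length(sub) * H * W), , drop = FALSE],
                       target = bt$target[seq_len(length(sub) * H * W)],
                       sids = bt$sids[sub])
          sel <- select_noise(function(z) {
            am <- matrix(rep(z, each = length(sub)), nrow = length(sub))
            ce_tape(bsub, am, train = FALSE)$loss$val
          }, noise_cfg)
          auxmat <- matrix(rep(sel$noise, each = length(idx)), nrow = length(idx))
        } else {
          auxmat <- aux_matrix_for_slices(st, bt$sids, subj_lookup)
        }
        ct <- ce_tape(bt, auxmat, train = TRUE)
        tape_backward(ct$tp, ct$loss)
        adam_step(opt, gen$ps, tape_param_grads(ct$tp, gen$ps))
        ep_loss <- ep_loss + ct$loss$val; nb <- nb + 1L
      }
      vl <- NA_real_
      if (length(val_idx)) {
        vl <- 0; nv <- 0L
        for (b0 in seq(1L, length(val_idx), by = batch_size)) {
          idx <- val_idx[b0:min(b0 + batch_size - 1L, length(val_idx))]
          bt <- batch_tensors(idx, aug = FALSE)
          auxmat <- if (st$mode == "gaussian")
            matrix(0, length(idx), st$dim)
          else aux_matrix_for_slices(st, bt$sids, subj_lookup)
          vl <- vl + ce_tape(bt, auxmat, train = FALSE)$loss$val
          nv <- nv + 1L
        }
        vl <- vl / nv
      }
      log <- rbind(log, data.frame(epoch = ep, train_loss = ep_loss / nb,
                                   val_loss = vl))
      if (verbose)
        message(sprintf("epoch %3d  train %.4f  val %.4f", ep,
                        ep_loss / nb, vl))
    }
    list(gen = gen, aux = st, class_weights = w, loss_log = log)
  })

  structure(list(generator = fit$gen, spec = spec, aux = fit$aux,
                 noise_cfg = noise_cfg, class_weights = fit$class_weights,
                 loss_log = fit$loss_log, seed = seed,
                 variant = "uresnet", call = match.call()),
            class = c("dep_uresnet", "dep_model"))
}

#' Predict evolution labels for subjects
#'
#' Runs the fitted DEP-UResNet slice-by-slice over each subject's baseline
#' FLAIR volume and assembles a three-class evolution label map (argmax of
#' the per-voxel class probabilities); slices without ICV coverage are
#' labelled background.
#'
#' @param object fitted `dep_uresnet`.
#' @param newdata a `subject_record`, list of them, or `synthetic_cohort`.
#' @param noise optional Gaussian auxiliary vector (length `aux_dim`) reused
#'   for all subjects; if `NULL` under Gaussian mode, one vector is drawn
#'   per subject from the current RNG stream.
#' @param prior_correction divide the class probabilities by the training
#'   class weights before the argmax. Training with weighted cross-entropy
#'   tilts the fitted probabilities towards the up-weighted rare classes;
#'   this standard correction removes that tilt and returns calibrated
#'   labels (and hence calibrated volumes).
#' @param ... unused.
#' @return an `evolution_label_map` for a single subject, else a named list
#'   of them.
#' @export
predict.dep_uresnet <- function(object, newdata, noise = NULL,
                                prior_correction = TRUE, ...) {
  subjects <- cohort_subjects(newdata)
  out <- lapply(subjects, function(s) {
    img <- s$images$FLAIR$baseline
    icv <- if (!is.null(s$masks$icv)) s$masks$icv$data else img$data != 0
    nz <- dim(img$data)[3]
    zs <- which(vapply(seq_len(nz), function(z) any(icv[, , z]), TRUE))
    lab <- array(0L, dim(img$data))
    if (length(zs)) {
      aux <- aux_for_subject(object$aux, s, noise = noise)
      amat <- if (is.null(aux)) NULL else
        matrix(rep(aux, each = length(zs)), nrow = length(zs))
      probs <- forward_slices(object$generator,
                              lapply(zs, function(z) img$data[, , z]), amat)
      for (i in seq_along(zs)) {
        p <- matrix(probs[[i]], ncol = 4L)
        if (prior_correction) p <- sweep(p, 2L, object$class_weights, "/")
        cl <- max.col(p) - 1L
        lab[, , zs[i]] <- matrix(cl, dim(img$data)[1], dim(img$data)[2])
      }
    }
    evolution_label_map(lab, img$voxel_dims)
  })
  names(out) <- vapply(subjects, `[[`, "", "subject_id")
  if (length(out) == 1L && inherits(newdata, "subject_record")) out[[1]] else out
}

# ---- DEP-GAN ---------------------------------------------------------------

variant_weights <- function(variant, weights) {
  if (variant == "wgan_gp") return(NULL)
  if (variant == "vagan")
    return(loss_weights(weights$lambda1, 0, 0, weights$gp_factor))
  weights
}

# Full generator-side tape for one minibatch; returns the objective node and
# the individual term values for logging.
gan_generator_tape <- function(gen, critics, variant, wts, x0s, x1s, auxmat,
                               dims, thr, vox_ml, sharpness, eps, train) {
  tp <- tape_new()
  x0 <- nd_leaf(tp, pack_slices(x0s))
  a <- if (is.null(auxmat)) NULL else nd_leaf(tp, auxmat)
  yp <- tape_generator(tp, gen, x0, a, dims, train = train)
  x1p <- nd_add(tp, yp, x0)
  N <- dims$N
  nodes <- list(); coefs <- numeric(0); parts <- list()
  if (!is.null(critics$D)) {
    sD <- tape_critic(tp, critics$D, x1p, dims)
    advD <- nd_wsum(tp, sD, rep(-1 / N, N))
    nodes <- c(nodes, list(advD)); coefs <- c(coefs, 1)
    parts$adv_D <- advD$val
  }
  if (!is.null(critics$C)) {
    sC <- tape_critic(tp, critics$C, yp, dims)
    advC <- nd_wsum(tp, sC, rep(-1 / N, N))
    nodes <- c(nodes, list(advC)); coefs <- c(coefs, 1)
    parts$adv_C <- advC$val
  }
  const <- 0
  if (!is.null(wts)) {
    x1ref <- pack_slices(x1s)
    refm <- stats::plogis(sharpness * (x1ref - thr))
    mae <- nd_mae_const(tp, x1p, x1ref)
    sf <- nd_sigmoid_step(tp, x1p, thr, sharpness)
    dscn <- nd_soft_dsc_const(tp, sf, refm, eps)
    voln <- nd_vol_mse_const(tp, sf, refm, vox_ml, dims)
    nodes <- c(nodes, list(mae, dscn, voln))
    coefs <- c(coefs, wts$lambda1, -wts$lambda2, wts$lambda3)
    const <- wts$lambda2  # lambda2 * (1 - dsc) = lambda2 - lambda2*dsc
    parts$l1 <- mae$val; parts$dsc <- 1 - dscn$val; parts$vol <- voln$val
  }
  obj <- nd_add_scalar_nodes(tp, nodes, coefs)
  parts$objective <- obj$val + const
  list(tp = tp, obj = obj, yp = yp, parts = parts)
}

critic_update <- function(critic, opt, real, fake, gp_factor, fd_eps = 1e-3) {
  N <- length(real)
  tp <- tape_new()
  dims <- list(H = nrow(real[[1]]), W = ncol(real[[1]]), N = N)
  xr <- nd_leaf(tp, pack_slices(real))
  xf <- nd_leaf(tp, pack_slices(fake))
  sr <- tape_critic(tp, critic, xr, dims)
  sf <- tape_critic(tp, critic, xf, dims)
  # minimise mean(fake) - mean(real)  (the negated critic gain)
  loss <- nd_add_scalar_nodes(tp, list(nd_wsum(tp, sf, rep(1 / N, N)),
                                       nd_wsum(tp, sr, rep(-1 / N, N))))
  tape_backward(tp, loss)
  grads <- tape_param_grads(tp, critic$ps)

  # gradient penalty on per-sample interpolates
  alpha <- stats::runif(N)
  xhat <- lapply(seq_len(N), function(i)
    alpha[i] * real[[i]] + (1 - alpha[i]) * fake[[i]])
  gn <- critic_input_grad_norms(critic, xhat)
  norms <- pmax(gn$norms, 1e-12)
  gp_val <- gp_factor * mean((gn$norms - 1)^2)
  coef <- gp_factor * 2 * (gn$norms - 1) / N
  sidx <- sample_of_row(gn$dims$H, gn$dims$W, gn$dims$N)
  u <- gn$grad / norms[sidx]
  for (sgn in c(1, -1)) {
    tp2 <- tape_new()
    xp <- nd_leaf(tp2, gn$xhat_packed + sgn * fd_eps * u)
    sp <- tape_critic(tp2, critic, xp, gn$dims)
    lw <- nd_wsum(tp2, sp, sgn * coef / (2 * fd_eps))
    tape_backward(tp2, lw)
    grads <- add_grads(grads, tape_param_grads(tp2, critic$ps))
  }
  adam_step(opt, critic$ps, grads)
  list(critic_gain = -loss$val, gp = gp_val)
}

#' Fit a DEP-GAN evolution predictor
#'
#' Adversarial prediction of the Disease Evolution Map from a baseline IM or
#' PM volume. The generator (a FiLM-conditioned residual U-Net with tanh
#' output) is trained against up to two gradient-penalty critics: D scores
#' follow-up images, C scores DEMs. Critics are updated `n_critic` times per
#' generator update, with heavy phases (`heavy_n_critic` updates) during the
#' first `warmup_iters` generator iterations and on every `heavy_every`-th
#' one. Variants: `"wgan_gp"` (C only, no image regularisation), `"vagan"`
#' (D + intensity loss), `"depgan_1c"` (D + full regularisation),
#' `"depgan_2c"` (C + D + full regularisation).
#'
#' @param cohort training cohort (`synthetic_cohort` or list of
#'   `subject_record`s).
#' @param modality `"IM"` or `"PM"`.
#' @param variant GAN variant, see above.
#' @param spec generator [generator_spec()] (tanh output enforced).
#' @param critic_depth,critic_base critic architecture.
#' @param weights a [loss_weights()].
#' @param schedule a [dep_schedule()]; `epochs` counts generator updates.
#' @param noise_cfg a [noise_config()] (Gaussian auxiliary mode).
#' @param aux_mode auxiliary input mode.
#' @param batch_size slices per update.
#' @param lr Adam learning rate (betas (0, 0.9), the gradient-penalty
#'   convention).
#' @param augment random flip/rotation augmentation.
#' @param seed RNG seed; the loss log is reproducible given it.
#' @param verbose print per-iteration objectives.
#' @return object of class `c("dep_gan", "dep_model")` with the trained
#'   generator, critics and a per-iteration loss log.
#' @export
dep_gan <- function(cohort, modality = c("IM", "PM"),
                    variant = c("depgan_2c", "depgan_1c", "vagan", "wgan_gp"),
                    spec = generator_spec(depth = 3L, base_channels = 16L,
                                          resblocks_per_level = 1L),
                    critic_depth = 3L, critic_base = 16L,
                    weights = loss_weights(),
                    schedule = dep_schedule(variant = "depgan_2c"),
                    noise_cfg = noise_config(),
                    aux_mode = c("none", "gaussian", "wmh_load", "wmh_sl_loads"),
                    batch_size = 8L, lr = 1e-4, augment = TRUE, seed = 1L,
                    verbose = FALSE) {
  modality <- match.arg(modality)
  variant <- match.arg(variant)
  aux_mode <- match.arg(aux_mode)
  stopifnot(inherits(spec, "generator_spec"), inherits(weights, "loss_weights"),
            inherits(schedule, "dep_schedule"))
  if (spec$output_activation != "tanh")
    stop("DEP-GAN requires a tanh-output generator")
  subjects <- cohort_subjects(cohort)
  slices <- extract_training_slices(subjects, modality)
  if (!length(slices)) stop("empty training set: no slices with brain tissue")
  H <- attr(slices, "H"); W <- attr(slices, "W")
  mult <- 2^max(spec$depth, critic_depth - 1L)
  if (H %% mult || W %% mult)
    stop(sprintf("slice size %dx%d must be divisible by %d", H, W, mult))
  subj_lookup <- stats::setNames(subjects,
                                 vapply(subjects, `[[`, "", "subject_id"))
  thr <- WMH_THRESHOLDS[[modality]]
  vox_ml <- prod(subjects[[1]]$images[[modality]]$baseline$voxel_dims) / 1000
  wts <- variant_weights(variant, weights)
  use_D <- variant %in% c("vagan", "depgan_1c", "depgan_2c")
  use_C <- variant %in% c("wgan_gp", "depgan_2c")

  fit <- with_seed(seed, {
    st <- fit_aux_state(aux_mode, subjects, spec$aux_dim)
    gen <- build_generator(spec, seed = sample.int(.Machine$integer.max, 1))
    critics <- list(
      D = if (use_D) build_critic(critic_spec("image", critic_depth, critic_base),
                                  seed = sample.int(.Machine$integer.max, 1)) else NULL,
      C = if (use_C) build_critic(critic_spec("dem", critic_depth, critic_base),
                                  seed = sample.int(.Machine$integer.max, 1)) else NULL)
    opt_g <- adam_new(gen$ps, lr = lr, beta1 = 0, beta2 = 0.9)
    opts_c <- lapply(critics, function(cr)
      if (is.null(cr)) NULL else adam_new(cr$ps, lr = lr, beta1 = 0, beta2 = 0.9))

    n <- length(slices)
    draw_batch <- function() {
      idx <- sample(n, min(batch_size, n), replace = n < batch_size)
      x0s <- vector("list", length(idx)); x1s <- vector("list", length(idx))
      sids <- character(length(idx))
      for (j in seq_along(idx)) {
        sl <- slices[[idx[j]]]
        g <- if (augment) draw_geom(H, W) else list(k = 0L, fl = FALSE)
        x0s[[j]] <- apply_geom(sl$x0, g$k, g$fl)
        x1s[[j]] <- apply_geom(sl$x1, g$k, g$fl)
        sids[j] <- sl$subject_id
      }
      list(x0 = x0s, x1 = x1s, sids = sids)
    }
    gen_fake <- function(bt, noise = NULL) {
      am <- if (st$mode == "gaussian") {
        z <- if (is.null(noise)) stats::rnorm(st$dim) else noise
        matrix(rep(z, each = length(bt$sids)), nrow = length(bt$sids))
      } else aux_matrix_for_slices(st, bt$sids, subj_lookup)
      dems <- forward_slices(gen, bt$x0, am)
      list(dems = dems,
           x1p = lapply(seq_along(dems), function(i) bt$x0[[i]] + dems[[i]]),
           auxmat = am)
    }

    log <- NULL
    for (t in seq_len(schedule$epochs)) {
      heavy <- t <= schedule$warmup_iters || t %% schedule$heavy_every == 0L
      ncrit <- if (heavy) schedule$heavy_n_critic else schedule$n_critic
      cr_stats <- list()
      for (which_c in c("D", "C")) {
        cr <- critics[[which_c]]
        if (is.null(cr)) next
        for (j in seq_len(ncrit)) {
          bt <- draw_batch()
          fake <- gen_fake(bt)
          if (which_c == "D") {
            real <- bt$x1; fk <- fake$x1p
          } else {
            real <- lapply(seq_along(bt$x0), function(i) bt$x1[[i]] - bt$x0[[i]])
            fk <- fake$dems
          }
          cr_stats[[which_c]] <- critic_update(cr, opts_c[[which_c]], real, fk,
                                               weights$gp_factor)
        }
      }
      bt <- draw_batch()
      dims <- list(H = H, W = W, N = length(bt$sids))
      mk_tape <- function(am, train)
        gan_generator_tape(gen, critics, variant, wts, bt$x0, bt$x1, am,
                           dims, thr, vox_ml, 50, 1, train)
      if (st$mode == "gaussian") {
        sel <- select_noise(function(z) {
          am <- matrix(rep(z, each = dims$N), nrow = dims$N)
          mk_tape(am, train = FALSE)$parts$objective
        }, noise_cfg)
        am <- matrix(rep(sel$noise, each = dims$N), nrow = dims$N)
      } else {
        am <- aux_matrix_for_slices(st, bt$sids, subj_lookup)
      }
      gt <- mk_tape(am, train = TRUE)
      tape_backward(gt$tp, gt$obj)
      adam_step(opt_g, gen$ps, tape_param_grads(gt$tp, gen$ps))
      row <- data.frame(iter = t, objective = gt$parts$objective,
                        adv_D = gt$parts$adv_D %||% NA_real_,
                        adv_C = gt$parts$adv_C %||% NA_real_,
                        l1 = gt$parts$l1 %||% NA_real_,
                        dsc = gt$parts$dsc %||% NA_real_,
                        vol = gt$parts$vol %||% NA_real_,
                        critic_D_gain = if (is.null(cr_stats$D)) NA_real_ else cr_stats$D$critic_gain,
                        critic_C_gain = if (is.null(cr_stats$C)) NA_real_ else cr_stats$C$critic_gain,
                        gp_D = if (is.null(cr_stats$D)) NA_real_ else cr_stats$D$gp,
                        gp_C = if (is.null(cr_stats$C)) NA_real_ else cr_stats$C$gp,
                        n_critic = ncrit)
      log <- if (is.null(log)) row else rbind(log, row)
      if (verbose)
        message(sprintf("iter %4d  obj %.4f  (ncrit %d)", t,
                        gt$parts$objective, ncrit))
    }
    list(gen = gen, critics = critics, aux = st, loss_log = log)
  })

  structure(list(generator = fit$gen, critics = fit$critics, spec = spec,
                 modality = modality, variant = variant, weights = weights,
                 schedule = schedule, noise_cfg = noise_cfg, aux = fit$aux,
                 loss_log = fit$loss_log, seed = seed, call = match.call()),
            class = c("dep_gan", "dep_model"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predict a Disease Evolution Map for a subject
#'
#' Runs the trained generator slice-by-slice over the subject's baseline
#' IM/PM volume.
#'
#' @param object fitted `dep_gan`.
#' @param newdata a `subject_record` (or list / `synthetic_cohort`).
#' @param noise optional Gaussian auxiliary vector.
#' @param type `"dem"` for the evolution map, `"followup"` for the implied
#'   follow-up image (`clip(x0 + DEM, 0, 1)`).
#' @param ... unused.
#' @return an `evolution_map` (or `volume_image`), or a named list of them.
#' @export
predict.dep_gan <- function(object, newdata, noise = NULL,
                            type = c("dem", "followup"), ...) {
  type <- match.arg(type)
  subjects <- cohort_subjects(newdata)
  out <- lapply(subjects, function(s) {
    img <- s$images[[object$modality]]$baseline
    icv <- if (!is.null(s$masks$icv)) s$masks$icv$data else img$data != 0
    nz <- dim(img$data)[3]
    zs <- which(vapply(seq_len(nz), function(z) any(icv[, , z]), TRUE))
    dem <- array(0, dim(img$data))
    if (length(zs)) {
      aux <- aux_for_subject(object$aux, s, noise = noise)
      amat <- if (is.null(aux)) NULL else
        matrix(rep(aux, each = length(zs)), nrow = length(zs))
      res <- forward_slices(object$generator,
                            lapply(zs, function(z) img$data[, , z]), amat)
      for (i in seq_along(zs)) dem[, , zs[i]] <- res[[i]]
    }
    y <- evolution_map(dem, img$voxel_dims, provenance = "generated")
    if (type == "dem") y else apply_dem(img, y)
  })
  names(out) <- vapply(subjects, `[[`, "", "subject_id")
  if (length(out) == 1L && inherits(newdata, "subject_record")) out[[1]] else out
}

# ---- shared S3 methods -----------------------------------------------------

#' @export
print.dep_model <- function(x, ...) {
  np <- sum(vapply(x$generator$ps$val, length, 0L))
  cat(sprintf("<%s> variant=%s  generator depth %d, base %d (%s params)  aux=%s\n",
              class(x)[1], x$variant, x$spec$depth, x$spec$base_channels,
              format(np, big.mark = ","), x$aux$mode))
  n <- nrow(x$loss_log)
  if (!is.null(n) && n > 0) {
    last <- x$loss_log[n, ]
    if (!is.null(last$train_loss))
      cat(sprintf("  trained %d epochs; final train loss %.4f\n",
                  n, last$train_loss))
    else
      cat(sprintf("  trained %d generator iterations; final objective %.4f\n",
                  n, last$objective))
  }
  invisible(x)
}

#' @export
summary.dep_model <- function(object, ...) {
  out <- list(model = class(object)[1], variant = object$variant,
              aux_mode = object$aux$mode,
              n_parameters = sum(vapply(object$generator$ps$val, length, 0L)),
              loss_log = object$loss_log, seed = object$seed)
  class(out) <- "summary.dep_model"
  out
}

#' @export
print.summary.dep_model <- function(x, ...) {
  cat(sprintf("%s (variant %s, aux %s), %s generator parameters, seed %d\n",
              x$model, x$variant, x$aux_mode,
              format(x$n_parameters, big.mark = ","), x$seed))
  ll <- x$loss_log
  if (!is.null(ll) && nrow(ll)) {
    cat("loss trajectory (first/last rows):\n")
    print(utils::head(ll, 2)); print(utils::tail(ll, 2))
  }
  invisible(x)
}

#' @export
plot.dep_model <- function(x, ...) {
  ll <- x$loss_log
  if (is.null(ll) || !nrow(ll)) { warning("no loss log to plot"); return(invisible(x)) }
  if (!is.null(ll$train_loss)) {
    graphics::plot(ll$epoch, ll$train_loss, type = "l", xlab = "epoch",
                   ylab = "loss", main = "training loss", ...)
    if (any(is.finite(ll$val_loss)))
      graphics::lines(ll$epoch, ll$val_loss, lty = 2)
    graphics::legend("topright", c("train", "validation"), lty = 1:2, bty = "n")
  } else {
    graphics::plot(ll$iter, ll$objective, type = "l", xlab = "generator iteration",
                   ylab = "objective", main = "generator objective", ...)
  }
  invisible(x)
}
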