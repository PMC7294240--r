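# Trainer mechanics on deliberately tiny problems.

tiny_train_cohort <- function(n = 4, seed = 21)
  tiny_cohort(n = n, seed = seed)$subjects

test_that("DEP-UResNet training is deterministic and reduces the loss", {
  subjects <- tiny_train_cohort()
  m1 <- dep_uresnet(subjects, spec = tiny_gen_spec("softmax4"), epochs = 4,
                    batch_size = 8, aux_mode = "none", val_fraction = 0,
                    seed = 31)
  m2 <- dep_uresnet(subjects, spec = tiny_gen_spec("softmax4"), epochs = 4,
                    batch_size = 8, aux_mode = "none", val_fraction = 0,
                    seed = 31)
  expect_identical(m1$loss_log, m2$loss_log)
  expect_identical(m1$generator$ps$val, m2$generator$ps$val)
  expect_lt(utils::tail(m1$loss_log$train_loss, 1), m1$loss_log$train_loss[1])
  m3 <- dep_uresnet(subjects, spec = tiny_gen_spec("softmax4"), epochs = 4,
                    batch_size = 8, aux_mode = "none", val_fraction = 0,
                    seed = 32)
  expect_false(identical(m1$loss_log, m3$loss_log))
})

test_that("auxiliary mode changes the trained checkpoint under one seed", {
  subjects <- tiny_train_cohort()
  args <- list(subjects, spec = tiny_gen_spec("softmax4"), epochs = 2,
               batch_size = 8, val_fraction = 0, seed = 33)
  m_none <- do.call(dep_uresnet, c(args, list(aux_mode = "none")))
  m_gauss <- do.call(dep_uresnet, c(args, list(
    aux_mode = "gaussian", noise_cfg = noise_config(dim = 8,
                                                    n_candidates_train = 2))))
  expect_false(identical(m_none$generator$ps$val, m_gauss$generator$ps$val))
})

test_that("load-based auxiliary vectors are constant across a subject's slices", {
  subjects <- tiny_train_cohort()
  m <- dep_uresnet(subjects, spec = tiny_gen_spec("softmax4"), epochs = 1,
                   batch_size = 8, aux_mode = "wmh_load", val_fraction = 0,
                   seed = 34)
  expect_identical(m$aux$mode, "wmh_load")
  a1 <- aux_for_subject(m$aux, subjects[[1]])
  a2 <- aux_for_subject(m$aux, subjects[[1]])
  expect_identical(a1, a2)
  expect_length(a1, m$spec$aux_dim)       # zero-padded to aux_dim
  expect_true(all(a1[-1] == 0))
  # the z-scored loads use the training scaler
  expect_equal(a1[1], (subjects[[1]]$covariates$wmh_load_ml -
                         m$aux$wmh_scaler$center) / m$aux$wmh_scaler$scale)
})

test_that("predicted label maps have valid codes and the subject's grid", {
  subjects <- tiny_train_cohort()
  m <- dep_uresnet(subjects, spec = tiny_gen_spec("softmax4"), epochs = 2,
                   batch_size = 8, aux_mode = "none", val_fraction = 0,
                   seed = 35)
  lab <- predict(m, subjects[[1]])
  expect_s3_class(lab, "evolution_label_map")
  expect_identical(dim(lab$data), dim(subjects[[1]]$truth$data))
  expect_true(all(lab$data %in% 0:3))
})

test_that("DEP-GAN training follows the heavy critic schedule and is reproducible", {
  subjects <- tiny_train_cohort()
  sch <- dep_schedule(n_critic = 2, warmup_iters = 1, heavy_every = 1000,
                      heavy_n_critic = 4, epochs = 3, variant = "depgan_2c")
  fit_once <- function(seed)
    dep_gan(subjects, modality = "IM", variant = "depgan_2c",
            spec = tiny_gen_spec(), critic_depth = 2, critic_base = 4,
            schedule = sch, batch_size = 4, aux_mode = "none", seed = seed)
  g1 <- fit_once(41)
  # first iteration is a warmup (heavy) phase, later ones are not
  expect_equal(g1$loss_log$n_critic, c(4L, 2L, 2L))
  expect_equal(nrow(g1$loss_log), 3L)
  expect_true(all(is.finite(g1$loss_log$objective)))
  expect_true(all(c("adv_C", "adv_D", "l1", "dsc", "vol") %in%
                    names(g1$loss_log)))
  g2 <- fit_once(41)
  expect_identical(g1$loss_log, g2$loss_log)
  # prediction produces a bounded generated DEM on the subject grid
  y <- predict(g1, subjects[[1]])
  expect_s3_class(y, "evolution_map")
  expect_identical(y$provenance, "generated")
  expect_true(all(abs(y$data) <= 1))
  x1p <- predict(g1, subjects[[1]], type = "followup")
  expect_s3_class(x1p, "volume_image")
  expect_true(all(x1p$data >= 0 & x1p$data <= 1))
})

test_that("GAN variants wire up the critics they declare", {
  subjects <- tiny_train_cohort()
  sch <- dep_schedule(n_critic = 1, warmup_iters = 1, heavy_every = 1000,
                      heavy_n_critic = 1, epochs = 1, variant = "wgan_gp")
  g_w <- dep_gan(subjects, modality = "IM", variant = "wgan_gp",
                 spec = tiny_gen_spec(), critic_depth = 2, critic_base = 4,
                 schedule = sch, batch_size = 4, aux_mode = "none", seed = 42)
  expect_null(g_w$critics$D)
  expect_false(is.null(g_w$critics$C))
  expect_true(is.na(g_w$loss_log$l1[1]))  # no image regularisation
  g_v <- dep_gan(subjects, modality = "IM", variant = "vagan",
                 spec = tiny_gen_spec(), critic_depth = 2, critic_base = 4,
                 schedule = sch, batch_size = 4, aux_mode = "none", seed = 42)
  expect_null(g_v$critics$C)
  expect_false(is.null(g_v$critics$D))
  # vagan keeps the intensity term of the regularisation
  expect_true(is.finite(g_v$loss_log$l1[1]))
})

test_that("Gaussian-auxiliary GAN training uses Min-of-N noise selection", {
  subjects <- tiny_train_cohort()
  sch <- dep_schedule(n_critic = 1, warmup_iters = 1, heavy_every = 1000,
                      heavy_n_critic = 1, epochs = 2, variant = "depgan_2c")
  g <- dep_gan(subjects, modality = "IM", variant = "depgan_2c",
               spec = tiny_gen_spec(), critic_depth = 2, critic_base = 4,
               schedule = sch, batch_size = 4, aux_mode = "gaussian",
               noise_cfg = noise_config(dim = 8, n_candidates_train = 3),
               seed = 43)
  expect_identical(g$aux$mode, "gaussian")
  expect_equal(nrow(g$loss_log), 2L)
})

test_that("model methods print, summarise and plot without error", {
  subjects <- tiny_train_cohort()
  m <- dep_uresnet(subjects, spec = tiny_gen_spec("softmax4"), epochs = 2,
                   batch_size = 8, aux_mode = "none", val_fraction = 0.25,
                   seed = 36)
  expect_output(print(m), "dep_uresnet")
  s <- summary(m)
  expect_s3_class(s, "summary.dep_model")
  expect_output(print(s), "generator parameters")
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(m))
})

test_that("noise-sampling evaluation reports mean and best draws coherently", {
  subjects <- tiny_train_cohort()
  m <- dep_uresnet(subjects, spec = tiny_gen_spec("softmax4"), epochs = 2,
                   batch_size = 8, aux_mode = "gaussian",
                   noise_cfg = noise_config(dim = 8, n_candidates_train = 2,
                                            n_samples_test = 3),
                   val_fraction = 0, seed = 37)
  suppressWarnings(res <- evaluate_with_noise_sampling(m, subjects, seed = 5))
  expect_equal(nrow(res$samples), 3)
  expect_gte(res$best$dsc_avg, res$mean$dsc_avg)  # max >= mean
  suppressWarnings(res2 <- evaluate_with_noise_sampling(m, subjects, seed = 5))
  expect_identical(res$samples, res2$samples)     # seed-reproducible
  # single draw: mean == best
  suppressWarnings(res1 <- evaluate_with_noise_sampling(
    m, subjects, noise_cfg = noise_config(dim = 8, n_samples_test = 1), seed = 6))
  expect_equal(res1$mean$dsc_avg, res1$best$dsc_avg)
  m_none <- dep_uresnet(subjects, spec = tiny_gen_spec("softmax4"), epochs = 1,
                        batch_size = 8, aux_mode = "none", val_fraction = 0,
                        seed = 38)
  expect_error(evaluate_with_noise_sampling(m_none, subjects),
               "Gaussian-auxiliary")
})
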