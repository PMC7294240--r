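test_that("critic losses are mean score differences", {
  expect_equal(critic_loss_D(c(2, 2), c(1, 1)), 1)
  expect_equal(critic_loss_D(c(3, 1, 2), c(3, 1, 2)), 0)
  expect_equal(critic_loss_C(c(0.5, -0.5), c(1, 1)), -1)
  set.seed(1)
  for (i in 1:10) {
    r <- stats::rnorm(7); f <- stats::rnorm(7)
    expect_equal(critic_loss_D(r, f), mean(r) - mean(f), tolerance = 1e-12)
    expect_equal(critic_loss_C(r, f), mean(r) - mean(f), tolerance = 1e-12)
  }
  expect_error(critic_loss_D(numeric(0), numeric(0)), "empty")
  expect_error(critic_loss_D(1:3, 1:2), "mismatched")
})

test_that("gradient penalty vanishes for unit-gradient linear critics", {
  set.seed(2)
  w <- array(stats::rnorm(16), c(4, 4, 1))
  w <- w / sqrt(sum(w^2))   # ||w|| = 1
  real <- lapply(1:3, function(i) matrix(stats::runif(16), 4, 4))
  fake <- lapply(1:3, function(i) matrix(stats::runif(16), 4, 4))
  expect_equal(gradient_penalty(w, real, fake), 0, tolerance = 1e-12)
  # f(x) = 2 * sum(x) on a single voxel: (2 - 1)^2 * 10 = 10
  expect_equal(gradient_penalty(2, matrix(0.3), matrix(0.7), gp_factor = 10), 10)
  # non-negative for a real convolutional critic
  cr <- build_critic(critic_spec("dem", depth = 2, base_channels = 4), seed = 3)
  gp <- gradient_penalty(cr, real, fake)
  expect_gte(gp, 0)
})

test_that("soft Dice behaves as a smoothed version of the hard-mask Dice", {
  # identity: exactly 1 for saturated fields, near 1 (up to the epsilon
  # smoothing of partial memberships) for arbitrary ones
  sat <- array(rep(c(0, 1), 32), c(4, 4, 4))
  expect_equal(soft_dsc(sat, sat, "IM", sharpness = 1e3), 1, tolerance = 1e-6)
  x <- array(stats::runif(64), c(4, 4, 4))
  expect_equal(soft_dsc(x, x, "IM"), 1, tolerance = 0.1)
  # disjoint saturated lesions
  a <- array(0, c(4, 4, 1)); a[1:2, , 1] <- 1
  b <- array(0, c(4, 4, 1)); b[3:4, , 1] <- 1
  expect_lt(soft_dsc(a, b, "PM", sharpness = 1e3, eps = 1e-6), 1e-3)
  # convergence to Eq-style hard DSC at high sharpness
  set.seed(4)
  for (i in 1:5) {
    p <- array(stats::runif(125), c(5, 5, 5))
    q <- array(stats::runif(125), c(5, 5, 5))
    hard <- dsc(p >= 0.178, q >= 0.178)
    expect_equal(soft_dsc(p, q, "IM", sharpness = 1e3, eps = 1e-9), hard,
                 tolerance = 5e-3)
  }
})

test_that("regularisation loss decomposes into recoverable lambda-weighted terms", {
  set.seed(5)
  x1 <- array(stats::runif(64), c(4, 4, 4))
  xf <- pmin(pmax(x1 + stats::rnorm(64, 0, 0.1), 0), 1)
  w <- loss_weights()
  out <- regularisation_loss(xf, x1, w, "PM")
  terms <- attr(out, "terms")
  expect_equal(as.numeric(out),
               w$lambda1 * terms[["intensity"]] + w$lambda2 * terms[["dsc"]] +
                 w$lambda3 * terms[["volume"]])
  # identity input: ~0 up to the eps smoothing of the Dice term
  near0 <- regularisation_loss(x1, x1, w, "PM")
  expect_lt(as.numeric(near0), 0.05)
  # all-zero weights remove every term exactly
  expect_equal(as.numeric(regularisation_loss(xf, x1, loss_weights(0, 0, 0), "PM")), 0)
  expect_error(loss_weights(-1, 1, 1), "non-negative")
})

test_that("single-voxel regularisation matches a hand computation", {
  w <- loss_weights(lambda1 = 100, lambda2 = 1, lambda3 = 100)
  k <- 50; eps <- 1
  xf <- array(0.4, c(1, 1, 1)); x1 <- array(0.6, c(1, 1, 1))
  out <- regularisation_loss(xf, x1, w, "PM", voxel_dims = vd_paper,
                             sharpness = k, eps = eps)
  a <- stats::plogis(k * (0.4 - 0.5)); b <- stats::plogis(k * (0.6 - 0.5))
  dsc_soft <- (2 * a * b + eps) / (a + b + eps)
  vox_ml <- prod(vd_paper) / 1000
  by_hand <- 100 * 0.2 + 1 * (1 - dsc_soft) + 100 * ((a - b) * vox_ml)^2
  expect_equal(as.numeric(out), by_hand, tolerance = 1e-12)
})

test_that("generator objectives follow the declared variant algebra", {
  set.seed(6)
  sD <- stats::rnorm(5); sC <- stats::rnorm(5); reg <- 3.7
  expect_equal(generator_objective("wgan_gp", list(C = sC)), -mean(sC))
  expect_equal(generator_objective("vagan", list(D = sD), reg), -mean(sD) + reg)
  expect_equal(generator_objective("depgan_1c", list(D = sD), reg), -mean(sD) + reg)
  expect_equal(generator_objective("depgan_2c", list(C = sC, D = sD), reg),
               -mean(sC) - mean(sD) + reg)
  # zero adversarial scores: objective is the regularisation alone
  expect_equal(generator_objective("depgan_2c", list(C = 0, D = 0), reg), reg)
  # variant/input consistency is enforced
  expect_error(generator_objective("wgan_gp", list(D = sD)), "requires critic scores")
  expect_error(generator_objective("vagan", list(C = sC, D = sD)), "requires")
  expect_error(generator_objective("wgan_gp", list(C = sC), reg), "no image regularisation")
})

test_that("VA-GAN equals DEP-GAN-1C with lambda2 = lambda3 = 0 numerically", {
  set.seed(7)
  x1 <- array(stats::runif(128), c(4, 4, 8))
  xf <- pmin(pmax(x1 + stats::rnorm(128, 0, 0.05), 0), 1)
  sD <- stats::rnorm(4)
  w <- loss_weights()
  reg_vagan <- regularisation_loss(xf, x1, loss_weights(w$lambda1, 0, 0), "PM")
  reg_1c_zeroed <- regularisation_loss(xf, x1, loss_weights(w$lambda1, 0, 0), "PM")
  expect_equal(generator_objective("vagan", list(D = sD), reg_vagan),
               generator_objective("depgan_1c", list(D = sD), reg_1c_zeroed))
})

test_that("reducing any lambda never increases the objective at fixed inputs", {
  set.seed(8)
  x1 <- array(stats::runif(64), c(4, 4, 4))
  xf <- pmin(pmax(x1 + stats::rnorm(64, 0, 0.1), 0), 1)
  sD <- stats::rnorm(3)
  obj <- function(l1, l2, l3)
    generator_objective("depgan_1c", list(D = sD),
                        regularisation_loss(xf, x1, loss_weights(l1, l2, l3), "PM"))
  full <- obj(100, 1, 100)
  expect_lte(obj(50, 1, 100), full)
  expect_lte(obj(100, 0, 100), full)
  expect_lte(obj(100, 1, 10), full)
})

test_that("Min-of-N selection returns the argmin candidate", {
  cfg <- noise_config(dim = 4, n_candidates_train = 3)
  # deterministic loss ranking by first coordinate
  set.seed(9)
  sel <- select_noise(function(z) z[1]^2, cfg)
  expect_equal(sel$index, which.min(sel$losses))
  expect_equal(sel$loss, min(sel$losses))
  expect_true(all(sel$loss <= sel$losses))
  # fixed candidate losses pick the stated index
  i <- 0
  fixed <- c(3.2, 1.1, 2.0)
  sel2 <- select_noise(function(z) { i <<- i + 1; fixed[i] }, cfg)
  expect_equal(sel2$index, 2L)
  expect_equal(sel2$loss, 1.1)
  # single candidate is returned as-is
  sel3 <- select_noise(function(z) 42, cfg, n_candidates = 1)
  expect_equal(sel3$index, 1L)
  # selected loss <= mean candidate loss over random trials
  for (r in 1:20) {
    s <- select_noise(function(z) sum(z^2), cfg)
    expect_lte(s$loss, mean(s$losses))
  }
})
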