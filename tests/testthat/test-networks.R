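test_that("FiLM is the stated per-map affine transform", {
  f <- matrix(0.5, 4, 3)
  expect_equal(film_modulate(f, gamma = c(1, 1, 1), beta = c(0, 0, 0)), f)
  expect_equal(film_modulate(f, gamma = c(0, 0, 0), beta = c(2, 3, 4)),
               matrix(rep(c(2, 3, 4), each = 4), 4, 3))
  expect_equal(film_modulate(matrix(0.5, 1, 1), 2, 1)[1, 1], 2.0)
  arr <- array(stats::runif(2 * 2 * 3), c(2, 2, 3))
  out <- film_modulate(arr, c(2, 1, 0.5), c(0.1, 0, -0.1))
  expect_equal(out[, , 1], arr[, , 1] * 2 + 0.1)
  expect_error(film_modulate(f, gamma = c(1, 1), beta = c(0, 0, 0)),
               "one \\(gamma, beta\\) pair per feature map")
})

test_that("the auxiliary branch is deterministic, well-shaped, and identity at init", {
  spec <- tiny_gen_spec()
  gen <- build_generator(spec, seed = 2)
  aux <- stats::rnorm(spec$aux_dim)
  p1 <- aux_branch(gen, aux)
  p2 <- aux_branch(gen, aux)
  expect_identical(p1, p2)
  expect_equal(length(p1), length(spec$film_ch))
  for (i in seq_along(p1)) {
    expect_equal(length(p1[[i]]$gamma), spec$film_ch[i])
    expect_equal(length(p1[[i]]$beta), spec$film_ch[i])
    # zero-initialised head parameterised as gamma = 1 + delta: identity at init
    expect_equal(p1[[i]]$gamma, rep(1, spec$film_ch[i]))
    expect_equal(p1[[i]]$beta, rep(0, spec$film_ch[i]))
  }
  expect_error(aux_branch(gen, stats::rnorm(3)), "aux vector length")
})

test_that("generator forward is bounded, deterministic, and resolution-preserving", {
  gen <- build_generator(tiny_gen_spec(), seed = 3)
  x <- matrix(stats::runif(16 * 16), 16, 16)
  y1 <- generator_forward(gen, x)
  expect_identical(dim(y1), dim(x))
  expect_true(all(abs(y1) < 1))     # tanh output
  expect_identical(y1, generator_forward(gen, x))
  # non-divisible sizes are reflect-padded and cropped back
  x2 <- matrix(stats::runif(15 * 17), 15, 17)
  expect_identical(dim(generator_forward(gen, x2)), c(15L, 17L))
})

test_that("identity FiLM conditioning is bit-identical to the unconditioned pass", {
  gen <- build_generator(tiny_gen_spec(), seed = 4)
  x <- matrix(stats::runif(16 * 16), 16, 16)
  # aux head is zero-initialised => (gamma, beta) = (1, 0) for any aux input
  expect_identical(generator_forward(gen, x, aux = stats::rnorm(8)),
                   generator_forward(gen, x, aux = NULL))
})

test_that("auxiliary perturbations change the output once FiLM weights are nonzero", {
  gen <- build_generator(tiny_gen_spec(), seed = 5)
  set.seed(5)
  gen$ps$val$aux2_W <- matrix(stats::rnorm(length(gen$ps$val$aux2_W), 0, 0.1),
                              nrow(gen$ps$val$aux2_W))
  x <- matrix(stats::runif(16 * 16), 16, 16)
  y1 <- generator_forward(gen, x, aux = rep(0, 8))
  y2 <- generator_forward(gen, x, aux = rep(1, 8))
  expect_gt(max(abs(y1 - y2)), 1e-6)
})

test_that("DEP-UResNet forward outputs a per-voxel 4-class simplex", {
  net <- build_generator(tiny_gen_spec("softmax4"), seed = 6)
  x <- matrix(stats::runif(16 * 16), 16, 16)
  p <- dep_uresnet_forward(net, x)
  expect_identical(dim(p), c(16L, 16L, 4L))
  expect_equal(apply(p, c(1, 2), sum), matrix(1, 16, 16), tolerance = 1e-6)
  cl <- apply(p, c(1, 2), which.max) - 1L
  expect_true(all(cl %in% 0:3))
  # a zeroed head gives uniform logits, hence probabilities ~ 0.25
  net$ps$val$head_W[] <- 0; net$ps$val$head_b[] <- 0
  p0 <- dep_uresnet_forward(net, x)
  expect_equal(as.vector(p0), rep(0.25, length(p0)), tolerance = 1e-6)
})

test_that("critics return one finite differentiable score per sample", {
  cr <- build_critic(critic_spec("image", depth = 3, base_channels = 4), seed = 7)
  xs <- lapply(1:3, function(i) matrix(stats::runif(256, -1, 1), 16, 16))
  sc <- critic_forward(cr, xs)
  expect_length(sc, 3)
  expect_true(all(is.finite(sc)))
  expect_error(critic_forward(cr, xs[[1]], input_kind = "dem"),
               "does not match")
  # input gradient exists, is nonzero, and matches a directional finite
  # difference (tolerance set by the single-precision conv arithmetic)
  gn <- critic_input_grad_norms(cr, xs)
  expect_true(all(gn$norms > 0))
  eps <- 1e-3
  for (i in c(5L, 100L, 300L)) {
    sl <- (i - 1L) %/% 256L + 1L; pos <- (i - 1L) %% 256L + 1L
    x2 <- xs; x2[[sl]][pos] <- x2[[sl]][pos] + eps
    sp <- sum(critic_forward(cr, x2))
    x2[[sl]][pos] <- x2[[sl]][pos] - 2 * eps
    sm <- sum(critic_forward(cr, x2))
    expect_equal(gn$grad[i, 1], (sp - sm) / (2 * eps), tolerance = 2e-2)
  }
})

test_that("convolution kernels match a double-precision im2col reference", {
  set.seed(8)
  H <- 10L; W <- 12L; N <- 2L; Cin <- 3L; Cout <- 5L
  idx <- conv_idx_mat(H, W, N, 3L)
  A <- matrix(stats::rnorm(H * W * N * Cin), H * W * N, Cin)
  Wt <- matrix(stats::rnorm(9 * Cin * Cout, 0, 0.2), 9 * Cin, Cout)
  b <- stats::rnorm(Cout)
  P <- im2col_cpp(A, idx)
  Yref <- P %*% Wt + rep(b, each = nrow(P))
  expect_equal(conv_fwd_cpp(A, Wt, b, idx), Yref, tolerance = 1e-5)
  g <- matrix(stats::rnorm(length(Yref)), nrow(Yref))
  bw <- conv_bwd_cpp(A, g, Wt, idx)
  expect_equal(bw$dW, crossprod(P, g), tolerance = 1e-5, ignore_attr = TRUE)
  expect_equal(as.numeric(bw$db), colSums(g), tolerance = 1e-8)
  # scatter-add adjoint oracle
  dP <- tcrossprod(g, Wt)
  dAref <- matrix(0, nrow(A), Cin)
  for (o in 1:9) for (cc in 1:Cin) {
    q <- idx[, o]
    v <- dP[, (o - 1) * Cin + cc]
    for (p in which(q > 0)) dAref[q[p], cc] <- dAref[q[p], cc] + v[p]
  }
  expect_equal(bw$dA, dAref, tolerance = 1e-5, ignore_attr = TRUE)
})

test_that("whole-network reverse-mode gradient matches a directional finite difference", {
  gen <- build_generator(tiny_gen_spec(), seed = 9)
  set.seed(9)
  gen$ps$val$aux2_W <- matrix(stats::rnorm(length(gen$ps$val$aux2_W), 0, 0.05),
                              nrow(gen$ps$val$aux2_W))
  dims <- list(H = 16L, W = 16L, N = 2L)
  X <- pack_slices(list(matrix(stats::runif(256), 16, 16),
                        matrix(stats::runif(256), 16, 16)))
  amat <- matrix(stats::rnorm(16), 2, 8)
  loss <- function() {
    tp <- tape_new()
    x <- nd_leaf(tp, X); a <- nd_leaf(tp, amat)
    o <- tape_generator(tp, gen, x, a, dims)
    list(tp = tp, l = nd_mae_const(tp, o, 0.3))
  }
  lv <- loss()
  tape_backward(lv$tp, lv$l)
  gr <- tape_param_grads(lv$tp, gen$ps)
  # random direction over all parameters; <grad, v> vs central difference
  dirs <- lapply(gen$ps$val, function(p) array(stats::rnorm(length(p)), dim(p) %||% length(p)))
  gdotv <- sum(vapply(names(gr), function(nm) sum(gr[[nm]] * dirs[[nm]]), 0))
  eps <- 5e-4
  base <- gen$ps$val
  gen$ps$val <- Map(function(p, d) p + eps * d, base, dirs)
  lp <- loss()$l$val
  gen$ps$val <- Map(function(p, d) p - eps * d, base, dirs)
  lm <- loss()$l$val
  gen$ps$val <- base
  # single-precision conv arithmetic bounds the agreement here
  expect_equal(gdotv, (lp - lm) / (2 * eps), tolerance = 5e-2)
})
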