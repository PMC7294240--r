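# Minimal reverse-mode network engine.
#
# Activations for a batch of N slices of H x W pixels with C channels are
# stored as a (H*W*N) x C matrix, rows ordered column-major within each
# slice, slices stacked. Convolutions are evaluated as a sum of shifted-index
# gathers followed by one BLAS matrix multiply (im2col), which is where
# essentially all the arithmetic happens. Gradients are computed on a tape of
# nodes recorded during the forward pass; each node knows how to push its
# gradient to its parents.

.idx_cache <- new.env(parent = emptyenv())

conv_offsets <- function(k) {
  r <- -((k - 1L) %/% 2L):((k - 1L) %/% 2L)
  out <- vector("list", k * k)
  n <- 0L
  for (dj in r) for (di in r) { n <- n + 1L; out[[n]] <- c(di, dj) }
  out
}

# P x k^2 index matrix: column o maps each output row to the 1-based input
# row read for kernel offset o, 0 meaning zero padding ('same' convolution).
conv_idx_mat <- function(H, W, N, k) {
  key <- paste("conv", H, W, N, k, sep = "_")
  got <- .idx_cache[[key]]
  if (!is.null(got)) return(got)
  offs <- conv_offsets(k)
  i <- seq_len(H); j <- seq_len(W)
  cols <- lapply(offs, function(o) {
    si <- i + o[1]; sj <- j + o[2]
    m <- outer(ifelse(si >= 1 & si <= H, si, NA_integer_),
               ifelse(sj >= 1 & sj <= W, (sj - 1L) * H, NA_integer_), "+")
    base <- as.integer(m)
    idx <- rep(base, N) + rep.int((seq_len(N) - 1L) * H * W, rep.int(H * W, N))
    idx[is.na(idx)] <- 0L
    idx
  })
  out <- do.call(cbind, cols)
  .idx_cache[[key]] <- out
  out
}

# 2x2 pooling index groups: four vectors of length P_out; together they
# partition the input rows (H, W assumed even).
pool_idx <- function(H, W, N) {
  key <- paste("pool", H, W, N, sep = "_")
  got <- .idx_cache[[key]]
  if (!is.null(got)) return(got)
  H2 <- H %/% 2L; W2 <- W %/% 2L
  i2 <- seq_len(H2); j2 <- seq_len(W2)
  corner <- function(a, b)
    as.integer(outer(2L * i2 - 2L + a, (2L * j2 - 2L + b - 1L) * H, "+"))
  per <- lapply(list(c(1, 1), c(2, 1), c(1, 2), c(2, 2)),
                function(ab) corner(ab[1], ab[2]))
  out <- lapply(per, function(base)
    rep(base, N) + rep.int((seq_len(N) - 1L) * H * W, rep.int(H2 * W2, N)))
  # nearest-upsample map: out-row (on the fine grid) -> in-row (coarse grid)
  fine <- as.integer(outer(((seq_len(H) + 1L) %/% 2L),
                           (((seq_len(W) + 1L) %/% 2L) - 1L) * H2, "+"))
  up <- rep(fine, N) + rep.int((seq_len(N) - 1L) * H2 * W2, rep.int(H * W, N))
  res <- list(g = out, up = up)
  .idx_cache[[key]] <- res
  res
}

sample_of_row <- function(H, W, N) {
  key <- paste("samp", H, W, N, sep = "_")
  got <- .idx_cache[[key]]
  if (!is.null(got)) return(got)
  idx <- rep.int(seq_len(N), rep.int(H * W, N))
  .idx_cache[[key]] <- idx
  idx
}

# ---- tape ------------------------------------------------------------------

tape_new <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 256L)
  tp$n <- 0L
  tp$pleaves <- new.env(parent = emptyenv())
  tp
}

nd_new <- function(tp, val, parents = list(), bwd = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$val <- val; nd$grad <- NULL; nd$parents <- parents; nd$bwd <- bwd
  tp$n <- tp$n + 1L
  if (tp$n > length(tp$nodes)) tp$nodes <- c(tp$nodes, vector("list", length(tp$nodes)))
  nd$id <- tp$n
  tp$nodes[[tp$n]] <- nd
  nd
}

nd_leaf <- function(tp, val) nd_new(tp, val)

# Leaf bound to a parameter store entry; grads are collected per store so
# several networks can share one tape without name collisions.
nd_param <- function(tp, ps, name) {
  key <- paste0(ps$tag, ".", name)
  got <- tp$pleaves[[key]]
  if (!is.null(got)) return(got)
  nd <- nd_new(tp, ps$val[[name]])
  nd$pname <- name
  nd$ptag <- ps$tag
  tp$pleaves[[key]] <- nd
  nd
}

# Reverse sweep from `loss` (whose gradient seed defaults to 1).
tape_backward <- function(tp, loss, seed_grad = 1) {
  loss$grad <- seed_grad
  for (i in seq.int(loss$id, 1L)) {
    nd <- tp$nodes[[i]]
    if (is.null(nd$grad) || is.null(nd$bwd)) next
    gs <- nd$bwd(nd$grad)
    ps <- nd$parents
    for (j in seq_along(ps)) {
      g <- gs[[j]]
      if (is.null(g)) next
      p <- ps[[j]]
      p$grad <- if (is.null(p$grad)) g else p$grad + g
    }
    nd$grad <- NULL  # free
  }
  invisible(NULL)
}

# Collect parameter gradients for one store after a backward sweep.
tape_param_grads <- function(tp, ps) {
  out <- list()
  for (key in ls(tp$pleaves)) {
    nd <- tp$pleaves[[key]]
    if (identical(nd$ptag, ps$tag) && !is.null(nd$grad)) out[[nd$pname]] <- nd$grad
  }
  out
}

# ---- ops -------------------------------------------------------------------

nd_conv2d <- function(tp, x, Wn, bn, dims, k = 3L) {
  idx <- conv_idx_mat(dims$H, dims$W, dims$N, k)
  Y <- conv_fwd_cpp(x$val, Wn$val, bn$val, idx)
  nd_new(tp, Y, list(x, Wn, bn), function(g) {
    b <- conv_bwd_cpp(x$val, g, Wn$val, idx)
    list(b$dA, b$dW, b$db)
  })
}

# channel-mixing 1x1 convolution == per-pixel dense layer
nd_dense <- function(tp, x, Wn, bn = NULL) {
  Y <- x$val %*% Wn$val
  if (!is.null(bn)) Y <- Y + rep(bn$val, each = nrow(Y))
  parents <- if (is.null(bn)) list(x, Wn) else list(x, Wn, bn)
  nd_new(tp, Y, parents, function(g) {
    out <- list(tcrossprod(g, Wn$val), crossprod(x$val, g))
    if (!is.null(bn)) out <- c(out, list(colSums(g)))
    out
  })
}

nd_relu <- function(tp, x) {
  m <- x$val > 0
  nd_new(tp, x$val * m, list(x), function(g) list(g * m))
}

nd_lrelu <- function(tp, x, alpha = 0.2) {
  m <- x$val > 0
  s <- ifelse(m, 1, alpha)
  nd_new(tp, x$val * s, list(x), function(g) list(g * s))
}

nd_tanh <- function(tp, x) {
  y <- tanh(x$val)
  nd_new(tp, y, list(x), function(g) list(g * (1 - y * y)))
}

nd_add <- function(tp, a, b) {
  nd_new(tp, a$val + b$val, list(a, b), function(g) list(g, g))
}

nd_add_const <- function(tp, a, k) {
  nd_new(tp, a$val + k, list(a), function(g) list(g))
}

nd_scale <- function(tp, a, k) {
  nd_new(tp, a$val * k, list(a), function(g) list(g * k))
}

nd_concat <- function(tp, a, b) {
  ca <- ncol(a$val)
  nd_new(tp, cbind(a$val, b$val), list(a, b), function(g)
    list(g[, seq_len(ca), drop = FALSE], g[, -seq_len(ca), drop = FALSE]))
}

nd_slice_cols <- function(tp, x, cols) {
  nc <- ncol(x$val)
  nd_new(tp, x$val[, cols, drop = FALSE], list(x), function(g) {
    out <- matrix(0, nrow(g), nc)
    out[, cols] <- g
    list(out)
  })
}

nd_avgpool2 <- function(tp, x, dims) {
  pi <- pool_idx(dims$H, dims$W, dims$N)
  g4 <- pi$g
  Y <- (x$val[g4[[1]], , drop = FALSE] + x$val[g4[[2]], , drop = FALSE] +
        x$val[g4[[3]], , drop = FALSE] + x$val[g4[[4]], , drop = FALSE]) / 4
  Pin <- nrow(x$val)
  nd_new(tp, Y, list(x), function(g) {
    dA <- matrix(0, Pin, ncol(g))
    q <- g / 4
    dA[g4[[1]], ] <- q; dA[g4[[2]], ] <- q
    dA[g4[[3]], ] <- q; dA[g4[[4]], ] <- q
    list(dA)
  })
}

nd_upsample2 <- function(tp, x, dims_out) {
  pi <- pool_idx(dims_out$H, dims_out$W, dims_out$N)
  Y <- x$val[pi$up, , drop = FALSE]
  nd_new(tp, Y, list(x), function(g) {
    g4 <- pi$g
    list(g[g4[[1]], , drop = FALSE] + g[g4[[2]], , drop = FALSE] +
         g[g4[[3]], , drop = FALSE] + g[g4[[4]], , drop = FALSE])
  })
}

# FiLM: per-sample, per-channel affine modulation. gb holds N x 2C values
# [delta_gamma | beta]; gamma = 1 + delta_gamma so a zero-initialised
# auxiliary head starts at the identity.
nd_film <- function(tp, x, gb, dims) {
  C <- ncol(x$val)
  sidx <- sample_of_row(dims$H, dims$W, dims$N)
  G <- 1 + gb$val[sidx, seq_len(C), drop = FALSE]
  B <- gb$val[sidx, C + seq_len(C), drop = FALSE]
  nd_new(tp, x$val * G + B, list(x, gb), function(g) {
    dgamma <- rowsum(g * x$val, sidx)
    dbeta <- rowsum(g, sidx)
    list(g * G, cbind(dgamma, dbeta))
  })
}

nd_dropout <- function(tp, x, rate) {
  if (rate <= 0) return(x)
  keep <- (matrix(stats::runif(length(x$val)), nrow(x$val)) >= rate) / (1 - rate)
  nd_new(tp, x$val * keep, list(x), function(g) list(g * keep))
}

# Global average pooling to one row per sample.
nd_gap <- function(tp, x, dims) {
  sidx <- sample_of_row(dims$H, dims$W, dims$N)
  hw <- dims$H * dims$W
  nd_new(tp, rowsum(x$val, sidx) / hw, list(x), function(g)
    list(g[sidx, , drop = FALSE] / hw))
}

# Channel softmax (per row).
nd_softmax <- function(tp, x) {
  z <- x$val - apply(x$val, 1L, max)
  e <- exp(z)
  p <- e / rowSums(e)
  nd_new(tp, p, list(x), function(g) {
    dot <- rowSums(g * p)
    list(p * (g - dot))
  })
}

# Weighted categorical cross-entropy fused with softmax.
# target: integer vector (1-based class per row); w: per-class weights.
nd_softmax_ce <- function(tp, logits, target, w) {
  z <- logits$val - apply(logits$val, 1L, max)
  e <- exp(z)
  p <- e / rowSums(e)
  n <- nrow(p)
  wi <- w[target]
  sw <- sum(wi)
  picked <- p[cbind(seq_len(n), target)]
  loss <- sum(-wi * log(pmax(picked, 1e-12))) / sw
  nd_new(tp, loss, list(logits), function(g) {
    d <- p * wi
    d[cbind(seq_len(n), target)] <- d[cbind(seq_len(n), target)] - wi
    list(g * d / sw)
  })
}

nd_mean_all <- function(tp, x) {
  n <- length(x$val)
  nd_new(tp, sum(x$val) / n, list(x), function(g)
    list(matrix(g / n, nrow(x$val), ncol(x$val))))
}

# sum(x * w) for a fixed weight matrix/vector w (recycled like R arithmetic)
nd_wsum <- function(tp, x, w) {
  nd_new(tp, sum(x$val * w), list(x), function(g) list(g * w * array(1, dim(x$val))))
}

nd_mae_const <- function(tp, x, ref) {
  d <- x$val - ref
  n <- length(d)
  nd_new(tp, sum(abs(d)) / n, list(x), function(g) list(g * sign(d) / n))
}

# Steep logistic membership around a threshold (soft segmentation).
nd_sigmoid_step <- function(tp, x, thr, k) {
  s <- stats::plogis(k * (x$val - thr))
  nd_new(tp, s, list(x), function(g) list(g * k * s * (1 - s)))
}

# Soft Dice of a membership node against a fixed reference membership.
nd_soft_dsc_const <- function(tp, s, ref, eps = 1) {
  num <- 2 * sum(s$val * ref) + eps
  den <- sum(s$val) + sum(ref) + eps
  nd_new(tp, num / den, list(s), function(g)
    list(g * (2 * ref * den - num) / den^2))
}

# Mean over samples of squared per-slice soft-volume error (ml).
nd_vol_mse_const <- function(tp, s, ref, vox_ml, dims) {
  sidx <- sample_of_row(dims$H, dims$W, dims$N)
  vf <- rowsum(s$val, sidx)[, 1] * vox_ml
  vr <- rowsum(matrix(ref, ncol = 1), sidx)[, 1] * vox_ml
  N <- dims$N
  nd_new(tp, mean((vf - vr)^2), list(s), function(g)
    list(matrix(g * 2 * (vf - vr)[sidx] * vox_ml / N, ncol = 1)))
}

nd_add_scalar_nodes <- function(tp, nodes, coefs = NULL) {
  if (is.null(coefs)) coefs <- rep(1, length(nodes))
  v <- sum(vapply(seq_along(nodes), function(i) coefs[i] * nodes[[i]]$val, 0))
  nd_new(tp, v, nodes, function(g) as.list(g * coefs))
}

# ---- parameters and optimiser ---------------------------------------------

.store_counter <- new.env(parent = emptyenv())
.store_counter$n <- 0L

param_store <- function(init) {
  ps <- new.env(parent = emptyenv())
  ps$val <- init
  .store_counter$n <- .store_counter$n + 1L
  ps$tag <- sprintf("ps%d", .store_counter$n)
  ps
}

he_init <- function(nr, nc, fan_in = nr) {
  matrix(stats::rnorm(nr * nc, 0, sqrt(2 / fan_in)), nr, nc)
}

adam_new <- function(ps, lr = 1e-3, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st <- new.env(parent = emptyenv())
  st$m <- lapply(ps$val, function(v) v * 0)
  st$v <- lapply(ps$val, function(v) v * 0)
  st$t <- 0L
  st$lr <- lr; st$b1 <- beta1; st$b2 <- beta2; st$eps <- eps
  st
}

adam_step <- function(st, ps, grads) {
  st$t <- st$t + 1L
  bc1 <- 1 - st$b1^st$t
  bc2 <- 1 - st$b2^st$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    st$m[[nm]] <- st$b1 * st$m[[nm]] + (1 - st$b1) * g
    st$v[[nm]] <- st$b2 * st$v[[nm]] + (1 - st$b2) * g * g
    ps$val[[nm]] <- ps$val[[nm]] -
      st$lr * (st$m[[nm]] / bc1) / (sqrt(st$v[[nm]] / bc2) + st$eps)
  }
  invisible(NULL)
}
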