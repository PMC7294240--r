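# Architecture contracts: UResNet-style generator with FiLM-modulated
# residual blocks and auxiliary branch; strided-downsampling critics.
#
# The generator is an encoder-decoder with skip connections: `depth`
# resolution levels of residual blocks, a bottleneck, and a mirrored decoder
# (nearest-neighbour upsampling + skip concatenation). Every residual block
# applies FiLM conditioning after its first convolution; the per-block
# (gamma, beta) pairs come from a small dense auxiliary branch whose final
# layer is zero-initialised, so conditioning starts exactly at the identity
# and "no auxiliary" is the frozen-identity special case of the same
# architecture.

#' Generator / DEP-UResNet architecture specification
#'
#' @param depth number of encoder/decoder resolution levels.
#' @param base_channels feature maps at the first level (doubles per level).
#' @param aux_dim length of the auxiliary input vector.
#' @param output_activation `"tanh"` (one signed DEM channel) or
#'   `"softmax4"` (four-class simplex output).
#' @param dropout_rate dropout inside residual blocks during training.
#' @param resblocks_per_level residual blocks per resolution level.
#' @param in_channels input channels (1 for IM/PM/FLAIR slices).
#' @return object of class `generator_spec`.
#' @export
generator_spec <- function(depth = 3L, base_channels = 32L, aux_dim = 32L,
                           output_activation = c("tanh", "softmax4"),
                           dropout_rate = 0, resblocks_per_level = 2L,
                           in_channels = 1L) {
  output_activation <- match.arg(output_activation)
  stopifnot(depth >= 1, base_channels >= 1, aux_dim >= 1,
            resblocks_per_level >= 1, dropout_rate >= 0, dropout_rate < 1)
  enc_ch <- as.integer(base_channels * 2^(seq_len(depth) - 1L))
  bott_ch <- as.integer(base_channels * 2^depth)
  # FiLM block channel plan, in forward order
  film_ch <- c(rep(enc_ch, each = resblocks_per_level),
               rep(bott_ch, resblocks_per_level),
               rep(rev(enc_ch), each = resblocks_per_level))
  structure(list(depth = as.integer(depth),
                 base_channels = as.integer(base_channels),
                 aux_dim = as.integer(aux_dim),
                 output_activation = output_activation,
                 dropout_rate = dropout_rate,
                 resblocks_per_level = as.integer(resblocks_per_level),
                 in_channels = as.integer(in_channels),
                 enc_ch = enc_ch, bott_ch = bott_ch, film_ch = film_ch,
                 out_channels = if (output_activation == "tanh") 1L else 4L),
            class = "generator_spec")
}

#' Critic architecture specification
#'
#' Strided-downsampling convolutional critic with no normalisation layers
#' (gradient-penalty convention) and an unbounded scalar output per sample.
#'
#' @param input_kind `"image"` (critic D, scores follow-up images) or
#'   `"dem"` (critic C, scores evolution maps).
#' @param depth number of resolution levels.
#' @param base_channels feature maps at the first level.
#' @return object of class `critic_spec`.
#' @export
critic_spec <- function(input_kind = c("image", "dem"), depth = 4L,
                        base_channels = 16L) {
  input_kind <- match.arg(input_kind)
  stopifnot(depth >= 1, base_channels >= 1)
  structure(list(input_kind = input_kind, depth = as.integer(depth),
                 base_channels = as.integer(base_channels),
                 ch = as.integer(base_channels * 2^(seq_len(depth) - 1L))),
            class = "critic_spec")
}

# ---- parameter initialisation ---------------------------------------------

init_generator_params <- function(spec) {
  p <- list()
  cv <- function(cin, cout) he_init(9L * cin, cout)
  d <- spec$depth; R <- spec$resblocks_per_level
  ch <- spec$enc_ch; bott <- spec$bott_ch
  p$stem_W <- cv(spec$in_channels, ch[1]); p$stem_b <- numeric(ch[1])
  for (l in seq_len(d)) {
    for (r in seq_len(R)) {
      pre <- sprintf("enc%d_rb%d", l, r)
      p[[paste0(pre, "_c1_W")]] <- cv(ch[l], ch[l])
      p[[paste0(pre, "_c1_b")]] <- numeric(ch[l])
      p[[paste0(pre, "_c2_W")]] <- cv(ch[l], ch[l])
      p[[paste0(pre, "_c2_b")]] <- numeric(ch[l])
    }
    nxt <- if (l < d) ch[l + 1] else bott
    p[[sprintf("down%d_W", l)]] <- he_init(ch[l], nxt)
    p[[sprintf("down%d_b", l)]] <- numeric(nxt)
  }
  for (r in seq_len(R)) {
    pre <- sprintf("bott_rb%d", r)
    p[[paste0(pre, "_c1_W")]] <- cv(bott, bott)
    p[[paste0(pre, "_c1_b")]] <- numeric(bott)
    p[[paste0(pre, "_c2_W")]] <- cv(bott, bott)
    p[[paste0(pre, "_c2_b")]] <- numeric(bott)
  }
  for (l in rev(seq_len(d))) {
    above <- if (l < d) ch[l + 1] else bott
    p[[sprintf("up%d_W", l)]] <- he_init(above, ch[l])
    p[[sprintf("up%d_b", l)]] <- numeric(ch[l])
    # skip-merge as a 1x1 channel projection; the residual blocks that
    # follow provide the spatial mixing
    p[[sprintf("dec%d_merge_W", l)]] <- he_init(2L * ch[l], ch[l])
    p[[sprintf("dec%d_merge_b", l)]] <- numeric(ch[l])
    for (r in seq_len(R)) {
      pre <- sprintf("dec%d_rb%d", l, r)
      p[[paste0(pre, "_c1_W")]] <- cv(ch[l], ch[l])
      p[[paste0(pre, "_c1_b")]] <- numeric(ch[l])
      p[[paste0(pre, "_c2_W")]] <- cv(ch[l], ch[l])
      p[[paste0(pre, "_c2_b")]] <- numeric(ch[l])
    }
  }
  p$head_W <- cv(ch[1], spec$out_channels)
  p$head_b <- numeric(spec$out_channels)
  # auxiliary branch; final layer zero-initialised => identity FiLM at init
  nfilm <- 2L * sum(spec$film_ch)
  p$aux1_W <- he_init(spec$aux_dim, 64L)
  p$aux1_b <- numeric(64L)
  p$aux2_W <- matrix(0, 64L, nfilm)
  p$aux2_b <- numeric(nfilm)
  p
}

init_critic_params <- function(spec) {
  p <- list()
  ch <- spec$ch
  p$stem_W <- he_init(9L, ch[1]); p$stem_b <- numeric(ch[1])
  for (l in seq_len(spec$depth)) {
    p[[sprintf("lvl%d_W", l)]] <- he_init(9L * ch[l], ch[l])
    p[[sprintf("lvl%d_b", l)]] <- numeric(ch[l])
    if (l < spec$depth) {
      p[[sprintf("proj%d_W", l)]] <- he_init(ch[l], ch[l + 1])
      p[[sprintf("proj%d_b", l)]] <- numeric(ch[l + 1])
    }
  }
  p$head_W <- he_init(ch[spec$depth], 1L)
  p$head_b <- numeric(1L)
  p
}

#' Build an untrained generator network
#'
#' @param spec a [generator_spec()].
#' @param seed RNG seed for weight initialisation.
#' @return object of class `dep_generator` (parameter store + spec).
#' @export
build_generator <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "generator_spec"))
  ps <- param_store(with_seed(seed, init_generator_params(spec)))
  structure(list(ps = ps, spec = spec), class = "dep_generator")
}

#' Build an untrained critic network
#'
#' @param spec a [critic_spec()].
#' @param seed RNG seed for weight initialisation.
#' @return object of class `dep_critic`.
#' @export
build_critic <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "critic_spec"))
  ps <- param_store(with_seed(seed, init_critic_params(spec)))
  structure(list(ps = ps, spec = spec), class = "dep_critic")
}

# ---- forward graphs --------------------------------------------------------

# Auxiliary branch on tape: aux (N x aux_dim) -> list of per-block N x 2C
# FiLM parameter nodes (delta-gamma | beta), or NULL when aux is NULL.
tape_aux_branch <- function(tp, ps, spec, aux_node) {
  if (is.null(aux_node)) return(NULL)
  h <- nd_relu(tp, nd_dense(tp, aux_node, nd_param(tp, ps, "aux1_W"),
                            nd_param(tp, ps, "aux1_b")))
  all_gb <- nd_dense(tp, h, nd_param(tp, ps, "aux2_W"),
                     nd_param(tp, ps, "aux2_b"))
  out <- vector("list", length(spec$film_ch))
  off <- 0L
  for (i in seq_along(spec$film_ch)) {
    C <- spec$film_ch[i]
    out[[i]] <- nd_slice_cols(tp, all_gb, off + seq_len(2L * C))
    off <- off + 2L * C
  }
  out
}

tape_resblock <- function(tp, ps, x, prefix, dims, gb, dropout, train) {
  h <- nd_conv2d(tp, x, nd_param(tp, ps, paste0(prefix, "_c1_W")),
                 nd_param(tp, ps, paste0(prefix, "_c1_b")), dims)
  if (!is.null(gb)) h <- nd_film(tp, h, gb, dims)
  h <- nd_relu(tp, h)
  if (train && dropout > 0) h <- nd_dropout(tp, h, dropout)
  h <- nd_conv2d(tp, h, nd_param(tp, ps, paste0(prefix, "_c2_W")),
                 nd_param(tp, ps, paste0(prefix, "_c2_b")), dims)
  nd_relu(tp, nd_add(tp, x, h))
}

# Full generator graph. x_node: (H*W*N) x in_channels leaf. Returns the
# output node (tanh DEM, softmax probabilities, or raw logits).
tape_generator <- function(tp, gen, x_node, aux_node, dims, train = FALSE,
                           logits = FALSE) {
  spec <- gen$spec; ps <- gen$ps
  stopifnot(dims$H %% 2^spec$depth == 0, dims$W %% 2^spec$depth == 0)
  gbs <- tape_aux_branch(tp, ps, spec, aux_node)
  bi <- 0L
  next_gb <- function() {
    bi <<- bi + 1L
    if (is.null(gbs)) NULL else gbs[[bi]]
  }
  d <- spec$depth; R <- spec$resblocks_per_level
  drop <- spec$dropout_rate
  h <- nd_conv2d(tp, x_node, nd_param(tp, ps, "stem_W"),
                 nd_param(tp, ps, "stem_b"), dims)
  h <- nd_relu(tp, h)
  skips <- vector("list", d)
  dlev <- dims
  for (l in seq_len(d)) {
    for (r in seq_len(R))
      h <- tape_resblock(tp, ps, h, sprintf("enc%d_rb%d", l, r), dlev,
                         next_gb(), drop, train)
    skips[[l]] <- list(node = h, dims = dlev)
    h <- nd_avgpool2(tp, h, dlev)
    dlev <- list(H = dlev$H %/% 2L, W = dlev$W %/% 2L, N = dlev$N)
    h <- nd_relu(tp, nd_dense(tp, h, nd_param(tp, ps, sprintf("down%d_W", l)),
                              nd_param(tp, ps, sprintf("down%d_b", l))))
  }
  for (r in seq_len(R))
    h <- tape_resblock(tp, ps, h, sprintf("bott_rb%d", r), dlev,
                       next_gb(), drop, train)
  for (l in rev(seq_len(d))) {
    dup <- skips[[l]]$dims
    h <- nd_upsample2(tp, h, dup)
    h <- nd_relu(tp, nd_dense(tp, h, nd_param(tp, ps, sprintf("up%d_W", l)),
                              nd_param(tp, ps, sprintf("up%d_b", l))))
    h <- nd_concat(tp, h, skips[[l]]$node)
    h <- nd_dense(tp, h, nd_param(tp, ps, sprintf("dec%d_merge_W", l)),
                  nd_param(tp, ps, sprintf("dec%d_merge_b", l)))
    h <- nd_relu(tp, h)
    for (r in seq_len(R))
      h <- tape_resblock(tp, ps, h, sprintf("dec%d_rb%d", l, r), dup,
                         next_gb(), drop, train)
    dlev <- dup
  }
  out <- nd_conv2d(tp, h, nd_param(tp, ps, "head_W"),
                   nd_param(tp, ps, "head_b"), dims)
  if (logits) return(out)
  if (spec$output_activation == "tanh") nd_tanh(tp, out) else nd_softmax(tp, out)
}

# Critic graph: input node -> scores node (N x 1).
tape_critic <- function(tp, critic, x_node, dims) {
  spec <- critic$spec; ps <- critic$ps
  h <- nd_conv2d(tp, x_node, nd_param(tp, ps, "stem_W"),
                 nd_param(tp, ps, "stem_b"), dims)
  h <- nd_lrelu(tp, h)
  dlev <- dims
  for (l in seq_len(spec$depth)) {
    h <- nd_conv2d(tp, h, nd_param(tp, ps, sprintf("lvl%d_W", l)),
                   nd_param(tp, ps, sprintf("lvl%d_b", l)), dlev)
    h <- nd_lrelu(tp, h)
    if (l < spec$depth) {
      if (dlev$H %% 2L || dlev$W %% 2L)
        stop("critic input spatial size must be divisible by 2^(depth-1)")
      h <- nd_avgpool2(tp, h, dlev)
      dlev <- list(H = dlev$H %/% 2L, W = dlev$W %/% 2L, N = dlev$N)
      h <- nd_lrelu(tp, nd_dense(tp, h, nd_param(tp, ps, sprintf("proj%d_W", l)),
                                 nd_param(tp, ps, sprintf("proj%d_b", l))))
    }
  }
  g <- nd_gap(tp, h, dlev)
  nd_dense(tp, g, nd_param(tp, ps, "head_W"), nd_param(tp, ps, "head_b"))
}

# ---- batch packing ---------------------------------------------------------

# Stack a list of H x W matrices into the (H*W*N) x 1 activation layout.
pack_slices <- function(slices) {
  H <- nrow(slices[[1]]); W <- ncol(slices[[1]])
  matrix(unlist(slices, use.names = FALSE), ncol = 1L)
}

unpack_slices <- function(mat, H, W, N, channels = 1L) {
  lapply(seq_len(N), function(n) {
    rows <- (n - 1L) * H * W + seq_len(H * W)
    if (channels == 1L) matrix(mat[rows, 1L], H, W)
    else array(mat[rows, ], c(H, W, channels))
  })
}

# Reflect-pad a slice so both spatial sizes are multiples of `mult`;
# returns the padded matrix plus the crop window.
pad_to_multiple <- function(m, mult) {
  H <- nrow(m); W <- ncol(m)
  H2 <- ceiling(H / mult) * mult
  W2 <- ceiling(W / mult) * mult
  if (H2 == H && W2 == W) return(list(m = m, rows = seq_len(H), cols = seq_len(W)))
  ri <- c(seq_len(H), rev(seq_len(H))[seq_len(H2 - H)])
  ci <- c(seq_len(W), rev(seq_len(W))[seq_len(W2 - W)])
  list(m = m[ri, ci, drop = FALSE], rows = seq_len(H), cols = seq_len(W))
}

# ---- exported forward-pass surface ----------------------------------------

#' Feature-wise linear modulation
#'
#' Applies the per-feature-map affine transform `gamma_m * F_m + beta_m`,
#' spatially uniform within each map.
#'
#' @param f feature maps: a matrix with one column per map (rows = pixels),
#'   or a 3D array `H x W x C`.
#' @param gamma,beta numeric vectors, one entry per feature map.
#' @return modulated feature maps, same shape as `f`.
#' @export
film_modulate <- function(f, gamma, beta) {
  arr <- is.array(f) && length(dim(f)) == 3
  m <- if (arr) matrix(f, ncol = dim(f)[3]) else f
  if (length(gamma) != ncol(m) || length(beta) != ncol(m))
    stop(sprintf("need one (gamma, beta) pair per feature map: got %d/%d for %d maps",
                 length(gamma), length(beta), ncol(m)))
  out <- sweep(sweep(m, 2L, gamma, "*"), 2L, beta, "+")
  if (arr) array(out, dim(f)) else out
}

#' Evaluate the auxiliary branch
#'
#' Maps an auxiliary vector to the per-block FiLM parameters of a generator.
#' Deterministic given the network weights.
#'
#' @param gen a `dep_generator` (or fitted `dep_model`).
#' @param aux numeric vector of length `aux_dim`.
#' @return list with one element per modulated residual block, each a list
#'   `(gamma, beta)` sized to that block's channel count.
#' @export
aux_branch <- function(gen, aux) {
  gen <- as_generator(gen)
  spec <- gen$spec
  if (length(aux) != spec$aux_dim)
    stop(sprintf("aux vector length %d != aux_dim %d", length(aux), spec$aux_dim))
  p <- gen$ps$val
  h <- pmax(rbind(aux) %*% p$aux1_W + rep(p$aux1_b, each = 1L), 0)
  gb <- as.numeric(h %*% p$aux2_W + p$aux2_b)
  out <- vector("list", length(spec$film_ch))
  off <- 0L
  for (i in seq_along(spec$film_ch)) {
    C <- spec$film_ch[i]
    out[[i]] <- list(gamma = 1 + gb[off + seq_len(C)],
                     beta = gb[off + C + seq_len(C)])
    off <- off + 2L * C
  }
  out
}

as_generator <- function(x) {
  if (inherits(x, "dep_generator")) return(x)
  if (inherits(x, "dep_model")) return(x$generator)
  stop("expected a dep_generator or fitted dep_model")
}

# Shared single/batch forward wrapper used by the exported forwards.
forward_slices <- function(gen, slices, aux_mat, train = FALSE) {
  spec <- gen$spec
  mult <- 2^spec$depth
  pads <- lapply(slices, pad_to_multiple, mult = mult)
  H <- nrow(pads[[1]]$m); W <- ncol(pads[[1]]$m)
  N <- length(slices)
  dims <- list(H = H, W = W, N = N)
  tp <- tape_new()
  x <- nd_leaf(tp, pack_slices(lapply(pads, `[[`, "m")))
  auxn <- if (is.null(aux_mat)) NULL else nd_leaf(tp, aux_mat)
  out <- tape_generator(tp, gen, x, auxn, dims, train = train)
  res <- unpack_slices(out$val, H, W, N, channels = spec$out_channels)
  lapply(seq_len(N), function(i) {
    r <- res[[i]]
    if (spec$out_channels == 1L) r[pads[[i]]$rows, pads[[i]]$cols, drop = FALSE]
    else r[pads[[i]]$rows, pads[[i]]$cols, , drop = FALSE]
  })
}

#' Generator forward pass on one 2D slice
#'
#' @param gen a `dep_generator` with tanh output.
#' @param x0_slice baseline IM/PM slice, an `H x W` matrix in `[0,1]`.
#' @param aux auxiliary vector of length `aux_dim`, or `NULL` for the
#'   unconditioned (identity-FiLM) forward pass.
#' @return the generated DEM slice, an `H x W` matrix in `(-1, 1)`.
#' @export
generator_forward <- function(gen, x0_slice, aux = NULL) {
  gen <- as_generator(gen)
  if (gen$spec$output_activation != "tanh")
    stop("generator_forward requires a tanh-output generator")
  amat <- if (is.null(aux)) NULL else {
    if (length(aux) != gen$spec$aux_dim)
      stop(sprintf("aux vector length %d != aux_dim %d",
                   length(aux), gen$spec$aux_dim))
    rbind(as.numeric(aux))
  }
  forward_slices(gen, list(x0_slice), amat)[[1]]
}

#' DEP-UResNet forward pass on one 2D slice
#'
#' @param net a `dep_generator` with softmax4 output (or fitted
#'   `dep_uresnet` model).
#' @param flair_slice FLAIR-like intensity slice, `H x W` matrix.
#' @param aux auxiliary vector or `NULL`.
#' @return `H x W x 4` array of class probabilities (background, stable,
#'   shrink, grow), summing to 1 per voxel.
#' @export
dep_uresnet_forward <- function(net, flair_slice, aux = NULL) {
  gen <- as_generator(net)
  if (gen$spec$output_activation != "softmax4")
    stop("dep_uresnet_forward requires a softmax4-output network")
  amat <- if (is.null(aux)) NULL else rbind(as.numeric(aux))
  forward_slices(gen, list(flair_slice), amat)[[1]]
}

#' Critic forward pass
#'
#' @param critic a `dep_critic`.
#' @param input one `H x W` matrix or a list of them (a batch); images for an
#'   `"image"` critic, DEM slices for a `"dem"` critic.
#' @param input_kind optional declared kind of the input, checked against the
#'   critic's spec.
#' @return numeric vector of unbounded scalar scores, one per input.
#' @export
critic_forward <- function(critic, input, input_kind = NULL) {
  stopifnot(inherits(critic, "dep_critic"))
  if (!is.null(input_kind) && input_kind != critic$spec$input_kind)
    stop(sprintf("input kind '%s' does not match critic kind '%s'",
                 input_kind, critic$spec$input_kind))
  slices <- if (is.list(input)) input else list(input)
  mult <- 2^(critic$spec$depth - 1L)
  pads <- lapply(slices, pad_to_multiple, mult = mult)
  dims <- list(H = nrow(pads[[1]]$m), W = ncol(pads[[1]]$m), N = length(slices))
  tp <- tape_new()
  x <- nd_leaf(tp, pack_slices(lapply(pads, `[[`, "m")))
  as.numeric(tape_critic(tp, critic, x, dims)$val)
}
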