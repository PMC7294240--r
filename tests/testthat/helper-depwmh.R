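# Shared fixtures, all built in code at test time.

vd_paper <- c(0.9375, 0.9375, 4)

# A small cohort configuration that keeps every test fast.
tiny_config <- function(n = 4L, seed = 1L, ...) {
  cohort_config(n_subjects = n, grid_shape = c(16L, 16L, 4L),
                clusters_per_subject = c(1L, 2L), seed = seed, ...)
}

tiny_cohort <- function(n = 4L, seed = 1L, ...) {
  generate_cohort(tiny_config(n = n, seed = seed, ...))
}

tiny_gen_spec <- function(activation = "tanh") {
  generator_spec(depth = 2L, base_channels = 4L, aux_dim = 8L,
                 output_activation = activation, resblocks_per_level = 1L)
}

rand_mask3 <- function(dims = c(6, 6, 3), p = 0.4) {
  array(stats::runif(prod(dims)) < p, dims)
}

rand_image <- function(dims = c(8, 8, 2), modality = "IM", subject = "s",
                       timepoint = "baseline") {
  volume_image(array(stats::runif(prod(dims)), dims), vd_paper, modality,
               subject, timepoint)
}
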