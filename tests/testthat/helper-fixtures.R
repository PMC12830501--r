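# Shared fixtures: small random kernels, a labelled HU block, and a compact
# phantom/model pair, all built in code at test time.

random_kernel <- function(half_width, seed = 1L,
                          voxel_size = c(2.73, 2.73, 2.80)) {
  set.seed(seed)
  side <- 2L * half_width + 1L
  w <- array(stats::runif(side^3), rep(side, 3L))
  w <- w / sum(w)
  k <- delta_kernel(voxel_size)
  k$weights <- w
  k$half_width <- as.integer(half_width)
  k
}

# symmetric (point-reflection invariant) random kernel
symmetric_kernel <- function(half_width, seed = 1L,
                             voxel_size = c(2.73, 2.73, 2.80)) {
  k <- random_kernel(half_width, seed, voxel_size)
  d <- dim(k$weights)
  w <- (k$weights + k$weights[d[1]:1, d[2]:1, d[3]:1]) / 2
  k$weights <- w / sum(w)
  k
}

three_tissue_masks <- function(shape = c(16L, 16L, 16L), seed = 5L,
                               voxel_size = c(2.73, 2.73, 2.80)) {
  set.seed(seed)
  hu <- array(sample(c(-695, 3, 1226), prod(shape), replace = TRUE), shape)
  classify_tissue(ct_volume(hu, voxel_size))
}

small_kernel_set <- function(seed = 7L) {
  list(lung = random_kernel(2L, seed), water = random_kernel(1L, seed + 1L),
       bone = random_kernel(1L, seed + 2L))
}

# tiny water kernel from a real (small-n) transport run, cached per session
cached_water_kernel <- local({
  k <- NULL
  function(n = 2e4) {
    if (is.null(k)) {
      k <<- make_positron_kernel(default_materials()$water, n_decays = n,
                                 seed = 321L)
    }
    k
  }
})
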