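# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) assign(name, builder(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# Small 48^3 phantom cohort used by several module tests.
small_cohort <- function() memo("small_cohort", function() {
  generate_cohort(phantom_config(grid_side = 48L, seed = 101L), 6)
})

small_priors <- function() memo("small_priors", function() {
  build_priors(lapply(small_cohort(), `[[`, "labels"))
})

# A very small phantom (32^3, shrunken structures) for cheap end-to-end runs.
tiny_config <- function() phantom_config(grid_side = 32L, structure_radius = 4,
                                         intersubject_sigma = 6,
                                         intersubject_alpha = 2, seed = 202L)

tiny_cohort <- function() memo("tiny_cohort", function() {
  generate_cohort(tiny_config(), 5)
})

# Ultra-short training run on the tiny cohort, shared by workflow tests.
tiny_train_config <- function(iters = 2L) {
  train_config(voxels_per_iteration = 30L, batch_size = 15L,
               validation_patches_per_subject = 20L,
               max_iterations = iters, patience = 30L, seed = 5L)
}

tiny_model <- function() memo("tiny_model", function() {
  priorseg_fit(tiny_cohort(), variant = "CNN-SP", width = 4L,
               config = tiny_train_config(3L), seed = 9L)
})

# Random blob mask on a small grid (for prior/metric oracles).
random_mask <- function(shape, p = 0.15) {
  array(as.integer(runif(prod(shape)) < p), dim = shape)
}

# Brute-force 3x3x3 dilation oracle, written independently of the C++ path.
dilate_oracle <- function(mask) {
  d <- dim(mask)
  out <- array(0L, dim = d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (mask[i, j, k] == 0) next
    ii <- max(1, i - 1):min(d[1], i + 1)
    jj <- max(1, j - 1):min(d[2], j + 1)
    kk <- max(1, k - 1):min(d[3], k + 1)
    out[ii, jj, kk] <- 1L
  }
  out
}

# Exhaustive pairwise-distance MHD oracle in plain R.
mhd_oracle <- function(a, r, voxel_size = 1) {
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3)
  ca <- sweep(which(a != 0, arr.ind = TRUE), 2, voxel_size, "*")
  cr <- sweep(which(r != 0, arr.ind = TRUE), 2, voxel_size, "*")
  dmat <- outer(seq_len(nrow(ca)), seq_len(nrow(cr)), function(i, j) {
    sqrt((ca[i, 1] - cr[j, 1])^2 + (ca[i, 2] - cr[j, 2])^2 +
           (ca[i, 3] - cr[j, 3])^2)
  })
  max(mean(apply(dmat, 1, min)), mean(apply(dmat, 2, min)))
}
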