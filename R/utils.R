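# Internal helpers shared across modules.

# Deterministic derived seed, kept well below 2^31. Used to give every random
# stream (per-subject anatomy, per-subject noise, augmentation, training) its
# own reproducible substream of a single master seed.
mix_seed <- function(seed, a = 0L, b = 0L) {
  s <- (as.double(seed) %% 1e6) * 10007 + as.double(a) * 1009 + as.double(b) * 101
  as.integer(s %% 2147483647)
}

# Run expr with a temporarily-seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

stopifnot_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
}

as_binary_array <- function(x) {
  a <- array(as.integer(x != 0), dim = dim(x))
  a
}

# Elementwise ELU (shape parameter 1); derivative recovered from the
# activation itself (a + 1 on the negative branch) to avoid caching z.
elu <- function(z) {
  neg <- z < 0
  z[neg] <- expm1(z[neg])
  z
}
elu_grad_from_act <- function(a) {
  g <- a + 1
  g[a > 0] <- 1
  g
}
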