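test_that("shape arithmetic follows out = in - 2 * depth", {
  expect_equal(output_side(25, 8), 9L)
  expect_equal(required_input_side(9, 16), 41L)
  expect_equal(output_side(17, 0), 17L)
  expect_error(output_side(16, 8), "too small")
  # round trips for depths 1..20 against step-by-step simulation
  for (d in 1:20) {
    s <- 2L * d + 9L
    sim <- s
    for (l in seq_len(d)) sim <- sim - 2L
    expect_equal(output_side(s, d), sim)
    expect_equal(required_input_side(sim, d), s)
  }
})

test_that("network specs satisfy their structural invariants", {
  sp <- network_spec(8, 32, 4, 3)
  expect_equal(sp$input_side, 25L)
  expect_equal(sp$output_side, 9L)
  expect_equal(sp$dense_channels, 256L)
  deep <- network_spec(16, 32, 4, 3)
  expect_equal(deep$input_side, 41L)
  expect_equal(deep$dense_channels, 512L)
  tiny <- network_spec(1, 1, 1, 2, input_side = 11L)
  expect_equal(tiny$output_side, 9L)
  expect_equal(tiny$dense_channels, 1L)
  expect_error(network_spec(8, 32, 4, 3, input_side = 15L), "too small")
})

test_that("parameter counts match hand computation", {
  # baseline (N = 4, C = 3): conv 3488 + 7*27680, BN 512, 1x1x1 layers
  # 32896 + 8256 + 195
  expect_equal(count_parameters(network_spec(8, 32, 4, 3)), 239107L)
  # smallest case, hand-summed layer by layer
  expect_equal(count_parameters(network_spec(1, 1, 1, 2, input_side = 11L)),
               28L + 2L + 256L + 8256L + 130L)
  # single first conv layer with N = 1 and 32 filters costs 27*32 + 32 = 896
  d1 <- count_parameters(network_spec(1, 32, 1, 2, input_side = 11L))
  d0_fc <- 2L * 32L + (32L * 128L + 128L) + (128L * 64L + 64L) + (64L * 2L + 2L)
  expect_equal(d1 - d0_fc, 896L)
  # doubling the width multiplies middle conv3 layer parameters ~4x
  mid32 <- 27L * 32L * 32L + 32L
  mid64 <- 27L * 64L * 64L + 64L
  expect_gt(mid64 / mid32, 3.9)
  expect_lt(mid64 / mid32, 4.1)
})

test_that("forward pass emits per-voxel probability distributions", {
  spec <- network_spec(2, 3, 2, 3, input_side = 9L)
  w <- init_weights(spec, seed = 2L)
  set.seed(4)
  x <- array(rnorm(9^3 * 2 * 4), dim = c(9, 9, 9, 2, 4))
  p <- net_forward(spec, w, x)
  expect_equal(dim(p), c(5L, 5L, 5L, 3L, 4L))
  sums <- apply(p, c(1, 2, 3, 5), sum)
  expect_true(all(abs(sums - 1) < 1e-5))
  expect_true(all(p >= 0 & p <= 1))
  # inference mode is deterministic
  expect_identical(p, net_forward(spec, w, x))
  # zero weights give the uniform distribution
  w0 <- rapply(w, function(v) v * 0, how = "replace")
  w0$bn$run_var <- w$bn$run_var
  p0 <- net_forward(spec, w0, x)
  expect_true(all(abs(p0 - 1 / 3) < 1e-12))
  expect_error(net_forward(spec, w, x[1:7, , , , , drop = FALSE]), "layer 1")
})

test_that("the deep variant consumes 41^3 patches and emits 9^3 outputs", {
  spec <- network_spec(16, 2, 1, 2)
  expect_equal(spec$input_side, 41L)
  w <- init_weights(spec, seed = 5L)
  x <- array(rnorm(41^3), dim = c(41, 41, 41, 1, 1))
  p <- net_forward(spec, w, x)
  expect_equal(dim(p), c(9L, 9L, 9L, 2L, 1L))
  sums <- apply(p, c(1, 2, 3, 5), sum)
  expect_true(all(abs(sums - 1) < 1e-5))
})

test_that("loss matches closed forms and a brute-force double sum", {
  # uniform predictions vs one-hot targets: J = ln C
  C <- 3L
  p <- array(1 / C, dim = c(2, 2, 2, C, 2))
  t0 <- array(0, dim = dim(p)); t0[, , , 1, ] <- 1
  expect_equal(as.numeric(net_loss(p, t0, NULL, alpha = 0)), log(C),
               tolerance = 1e-12)
  # perfect predictions: J = -ln(1 - eps) ~ 0
  expect_equal(as.numeric(net_loss(t0, t0, NULL, alpha = 0)), -log(1 - 1e-7),
               tolerance = 1e-12)
  # random toy batch vs an explicit triple loop
  set.seed(9)
  pr <- array(runif(2 * 2 * 2 * C * 2), dim = c(2, 2, 2, C, 2))
  for (b in 1:2) for (v in 1:8) {
    idx <- arrayInd(v, c(2, 2, 2))
    pr[idx[1], idx[2], idx[3], , b] <-
      pr[idx[1], idx[2], idx[3], , b] / sum(pr[idx[1], idx[2], idx[3], , b])
  }
  tg <- array(0, dim = dim(pr))
  for (b in 1:2) for (v in 1:8) {
    idx <- arrayInd(v, c(2, 2, 2))
    tg[idx[1], idx[2], idx[3], sample(C, 1), b] <- 1
  }
  oracle <- 0
  for (c in 1:C) for (b in 1:2) for (v in 1:8) {
    idx <- arrayInd(v, c(2, 2, 2))
    oracle <- oracle - tg[idx[1], idx[2], idx[3], c, b] *
      log(min(max(pr[idx[1], idx[2], idx[3], c, b], 1e-7), 1 - 1e-7))
  }
  oracle <- oracle / (2 * 8)
  expect_equal(as.numeric(net_loss(pr, tg, NULL, alpha = 0)), oracle,
               tolerance = 1e-9)
  # batch-order permutation invariance
  perm <- c(2, 1)
  expect_equal(as.numeric(net_loss(pr[, , , , perm], tg[, , , , perm], NULL, 0)),
               as.numeric(net_loss(pr, tg, NULL, 0)), tolerance = 1e-12)
  # weight-decay term covers filters only
  spec <- network_spec(1, 2, 1, 2, input_side = 11L)
  w <- init_weights(spec, seed = 1L)
  w$conv[[1]]$b <- w$conv[[1]]$b + 100   # biases must not affect the penalty
  pen_expect <- sum(w$conv[[1]]$W^2) + sum(w$fc1$W^2) + sum(w$fc2$W^2) +
    sum(w$clf$W^2)
  p2 <- array(0.5, dim = c(9, 9, 9, 2))
  t2 <- array(0.5, dim = c(9, 9, 9, 2))
  expect_equal(as.numeric(net_loss(p2, t2, w, alpha = 1e-4)),
               log(2) + 1e-4 * pen_expect, tolerance = 1e-10)
  expect_error(net_loss(p2, t2 * 1.5, NULL, 0), "sums")
})

test_that("moving a prediction toward its target decreases the loss", {
  tg <- array(0, dim = c(1, 1, 1, 2)); tg[1, 1, 1, 1] <- 1
  worse <- array(c(0.5, 0.5), dim = c(1, 1, 1, 2))
  better <- array(c(0.8, 0.2), dim = c(1, 1, 1, 2))
  expect_lt(as.numeric(net_loss(better, tg, NULL, 0)),
            as.numeric(net_loss(worse, tg, NULL, 0)))
})
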