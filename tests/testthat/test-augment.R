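test_that("sampled fields have mean displacement magnitude exactly alpha_i", {
  for (alpha in c(0.5, 2, 8)) {
    cfg <- deformation_config(sigma_e = 4, alpha_i = alpha, seed = 31L)
    f <- sample_field(c(16, 16, 16), cfg)
    mag <- sqrt(f$dx^2 + f$dy^2 + f$dz^2)
    expect_equal(mean(mag), alpha, tolerance = 1e-9)
  }
})

test_that("alpha_i = 0 yields the zero field and identity augmentation", {
  cfg <- deformation_config(sigma_e = 4, alpha_i = 0, seed = 1L)
  f <- sample_field(c(8, 8, 8), cfg)
  expect_true(all(f$dx == 0) && all(f$dy == 0) && all(f$dz == 0))
  ch <- array(rnorm(8^3 * 2), dim = c(8, 8, 8, 2))
  tg <- one_hot(array(sample(0:1, 8^3, TRUE), dim = rep(8, 3)), 2L)
  out <- augment_sample(ch, tg, cfg)
  expect_identical(out$channels, ch)
  expect_identical(out$target_onehot, tg)
})

test_that("larger sigma_e produces smoother fields", {
  grad_mag <- function(sigma, seed) {
    cfg <- deformation_config(sigma_e = sigma, alpha_i = 2, seed = seed)
    f <- sample_field(c(24, 24, 24), cfg)
    mean(abs(diff(f$dx))) + mean(abs(diff(f$dy))) + mean(abs(diff(f$dz)))
  }
  g4 <- mean(vapply(1:10, function(s) grad_mag(4, s), numeric(1)))
  g16 <- mean(vapply(1:10, function(s) grad_mag(16, s + 100), numeric(1)))
  expect_lt(g16, g4)
})

test_that("warping respects its interpolation contracts", {
  set.seed(33)
  cfg <- deformation_config(sigma_e = 4, alpha_i = 2, seed = 34L)
  f <- sample_field(c(10, 10, 10), cfg)
  # zero field is the identity
  z <- sample_field(c(10, 10, 10), deformation_config(4, 0))
  img <- array(rnorm(1000), dim = c(10, 10, 10))
  expect_equal(warp_scalar(img, z), img, tolerance = 1e-12)
  # constants are unchanged under any field
  expect_equal(warp_scalar(array(3, dim = c(10, 10, 10)), f),
               array(3, dim = c(10, 10, 10)), tolerance = 1e-12)
  # an integer shift of a ramp equals the explicitly shifted ramp inside
  ramp <- array(rep(1:10, times = 100), dim = c(10, 10, 10))
  shift <- list(dx = array(1, dim = c(10, 10, 10)),
                dy = array(0, dim = c(10, 10, 10)),
                dz = array(0, dim = c(10, 10, 10)), voxel_size = c(1, 1, 1))
  class(shift) <- "deformation_field"
  out <- warp_scalar(ramp, shift)
  expect_equal(out[1:9, , ], ramp[2:10, , ])
  expect_error(warp_scalar(array(0, dim = c(9, 9, 9)), f), "shapes differ")
})

test_that("warped one-hot labels stay on the probability simplex", {
  set.seed(35)
  lab <- array(sample(0:2, 12^3, TRUE), dim = rep(12, 3))
  cfg <- deformation_config(sigma_e = 4, alpha_i = 2, seed = 36L)
  f <- sample_field(rep(12, 3), cfg)
  soft <- warp_labels(lab, f, n_classes = 3L)
  sums <- apply(soft, c(1, 2, 3), sum)
  expect_true(all(abs(sums - 1) < 1e-6))
  expect_true(all(soft >= 0 & soft <= 1))
  # zero field preserves exact one-hot
  z <- sample_field(rep(12, 3), deformation_config(4, 0))
  soft0 <- warp_labels(lab, z, n_classes = 3L)
  expect_equal(soft0, one_hot(lab, 3L), tolerance = 1e-12)
  expect_error(warp_labels(array(0L, dim = rep(4, 3)), z, n_classes = 1L),
               "2 classes")
})

test_that("a half-voxel shift of a step edge gives 0.5 at the boundary", {
  lab <- array(0L, dim = c(10, 6, 6)); lab[6:10, , ] <- 1L
  shift <- list(dx = array(0.5, dim = c(10, 6, 6)),
                dy = array(0, dim = c(10, 6, 6)),
                dz = array(0, dim = c(10, 6, 6)), voxel_size = c(1, 1, 1))
  class(shift) <- "deformation_field"
  soft <- warp_labels(lab, shift, n_classes = 2L)
  expect_equal(unique(as.vector(soft[5, , , 1])), 0.5)
  expect_equal(unique(as.vector(soft[5, , , 2])), 0.5)
  expect_equal(unique(as.vector(soft[2, , , 1])), 1)
})

test_that("one field warps all channels coherently (label tracks intensity)", {
  cfg0 <- phantom_config(grid_side = 32L, structure_radius = 4, noise_sd = 0,
                         intersubject_alpha = 0, seed = 71L)
  s <- generate_subject(cfg0, 1)
  ctr <- round(colMeans(which(s$labels$data == 1L, arr.ind = TRUE)))
  ch <- extract_patch(array(s$image$data, dim = c(dim(s$image$data), 1L)),
                      ctr, 17)
  tg <- extract_patch(one_hot(s$labels$data, 3L), ctr, 17)
  out <- augment_sample(ch, tg, deformation_config(4, 2, seed = 72L))
  warped_fg <- (out$target_onehot[, , , 2] + out$target_onehot[, , , 3]) > 0.5
  # intensity threshold halfway between head (40) and structure (60)
  thresh_mask <- out$channels[, , , 1] > 50
  expect_gte(dice(warped_fg, thresh_mask), 95)
})

test_that("deformation configs validate their parameters", {
  expect_error(deformation_config(sigma_e = 0), "> 0")
  expect_error(deformation_config(alpha_i = -1), ">= 0")
  # two different seeds give different fields
  f1 <- sample_field(rep(8, 3), deformation_config(4, 2, seed = 1L))
  f2 <- sample_field(rep(8, 3), deformation_config(4, 2, seed = 2L))
  expect_false(identical(f1$dx, f2$dx))
})
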