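test_that("identical masks give an empty working volume and P^c = mask", {
  m <- array(0L, dim = rep(8, 3)); m[3:5, 3:5, 3:5] <- 1L
  masks <- list(m, m, m)
  B <- class_working_volume(masks)
  expect_true(all(B == 0L))
  P <- positive_volume(masks, B)
  expect_identical(P, m)
})

test_that("a single-voxel disagreement dilates to the 27-voxel cube", {
  m1 <- array(0L, dim = rep(9, 3)); m1[4:6, 4:6, 4:6] <- 1L
  m2 <- m1; m2[5, 5, 8] <- 1L  # one extra interior voxel
  B <- class_working_volume(list(m1, m2))
  want <- array(0L, dim = rep(9, 3)); want[4:6, 4:6, 7:9] <- 1L
  expect_identical(B, want)
  expect_equal(sum(B), 27)
  # P^c = intersection minus the dilated cube
  P <- positive_volume(list(m1, m2), B)
  inter <- m1  # m1 is the intersection here
  expect_identical(P, array(as.integer(inter == 1L & B == 0L), dim = dim(m1)))
})

test_that("working volume always contains union minus intersection", {
  set.seed(21)
  for (rep in 1:5) {
    masks <- lapply(1:3, function(i) random_mask(c(7, 7, 7), 0.2))
    B <- class_working_volume(masks)
    u <- Reduce(`|`, lapply(masks, `!=`, 0L))
    i <- Reduce(`&`, lapply(masks, `!=`, 0L))
    expect_true(all(B[u & !i] == 1L))
    # and matches the independent dilation oracle exactly
    expect_identical(B, dilate_oracle(array(as.integer(u & !i), dim = dim(B))))
  }
})

test_that("working-volume construction is permutation invariant and monotone", {
  set.seed(22)
  masks <- lapply(1:4, function(i) random_mask(c(6, 6, 6), 0.25))
  expect_identical(class_working_volume(masks),
                   class_working_volume(rev(masks)))
  # adding a subject never shrinks union minus intersection
  d1 <- {
    u <- Reduce(`|`, lapply(masks[1:3], `!=`, 0L))
    i <- Reduce(`&`, lapply(masks[1:3], `!=`, 0L)); u & !i
  }
  d2 <- {
    u <- Reduce(`|`, lapply(masks, `!=`, 0L))
    i <- Reduce(`&`, lapply(masks, `!=`, 0L)); u & !i
  }
  expect_true(all(d2[d1]))
})

test_that("global working volume is the exact union, with edge cases", {
  b1 <- array(0L, dim = rep(6, 3)); b1[1:2, , ] <- 1L
  b2 <- array(0L, dim = rep(6, 3)); b2[5:6, , ] <- 1L
  expect_identical(global_working_volume(list(b1)), b1)
  B <- global_working_volume(list(b1, b2))
  expect_equal(sum(B), sum(b1) + sum(b2))  # disjoint => additive
  expect_error(global_working_volume(list()), "at least one")
  expect_error(class_working_volume(list(b1, array(0L, dim = rep(5, 3)))),
               "shapes differ")
})

test_that("coordinate images match their definition in both modes", {
  ci <- coordinate_images(c(9, 9, 9), mode = "raw")
  expect_equal(ci$x[3, 5, 7], 3)
  expect_equal(ci$y[3, 5, 7], 5)
  expect_equal(ci$z[3, 5, 7], 7)
  cn <- coordinate_images(c(9, 11, 13), mode = "normalized")
  expect_equal(c(cn$x[1, 1, 1], cn$y[1, 1, 1], cn$z[1, 1, 1]), c(-1, -1, -1))
  expect_equal(c(cn$x[9, 11, 13], cn$y[9, 11, 13], cn$z[9, 11, 13]), c(1, 1, 1))
  expect_equal(c(cn$x[5, 6, 7], cn$y[5, 6, 7], cn$z[5, 6, 7]), c(0, 0, 0))
})

test_that("prior sets from phantom cohorts satisfy all set identities", {
  pri <- small_priors()
  C <- pri$n_classes
  union <- array(0L, dim = pri$shape)
  for (c in seq_len(C - 1)) {
    expect_equal(sum(pri$positive[[c]] & pri$working[[c]]), 0)
    union <- pmax(union, pri$working[[c]])
  }
  expect_identical(array(as.integer(union), dim = pri$shape),
                   pri$global_working)
  # distinct classes' positive volumes are disjoint
  expect_equal(sum(pri$positive[[1]] & pri$positive[[2]]), 0)
  # P^c is inside every subject's mask
  for (s in small_cohort()) {
    for (c in 1:2) expect_true(all(s$labels$data[pri$positive[[c]] == 1L] == c))
  }
  expect_gt(sum(pri$global_working), 0)
  for (c in 1:2) expect_equal(sum(pri$global_working & pri$positive[[c]]), 0)
})

test_that("prior sets round trip through their on-disk form", {
  skip_if_not_installed("yaml")
  pri <- small_priors()
  dir <- tempfile()
  write_priors(pri, dir)
  back <- read_priors(dir)
  expect_identical(back$working, pri$working)
  expect_identical(back$positive, pri$positive)
  expect_identical(back$global_working, pri$global_working)
  expect_equal(back$n_classes, pri$n_classes)
  unlink(dir, recursive = TRUE)
})
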