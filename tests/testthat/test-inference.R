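test_that("tile plans cover every working-volume voxel", {
  coverage_ok <- function(region, out_side, stride) {
    centers <- plan_tiles(region, out_side, stride)
    h <- (out_side - 1) %/% 2
    covered <- array(FALSE, dim = dim(region))
    for (r in seq_len(nrow(centers))) {
      c0 <- centers[r, ]
      covered[(c0[1] - h):(c0[1] + h), (c0[2] - h):(c0[2] + h),
              (c0[3] - h):(c0[3] + h)] <- TRUE
    }
    all(covered[region != 0])
  }
  # single-voxel region
  one <- array(0L, dim = rep(20, 3)); one[7, 13, 2] <- 1L
  expect_true(coverage_ok(one, 9, 4))
  expect_lte(nrow(plan_tiles(one, 9, 4)), ceiling(9 / 4)^3)
  # random masks across the full stride range
  set.seed(41)
  for (i in 1:10) {
    region <- array(0L, dim = rep(22, 3))
    n <- sample(1:40, 1)
    region[cbind(sample(22, n, TRUE), sample(22, n, TRUE), sample(22, n, TRUE))] <- 1L
    for (stride in c(1, 4, 9)) expect_true(coverage_ok(region, 9, stride))
  }
  # stride = output side tiles the bounding box without overlap
  blk <- array(0L, dim = rep(30, 3)); blk[3:25, 4:20, 5:18] <- 1L
  centers <- plan_tiles(blk, 9, 9)
  expect_true(coverage_ok(blk, 9, 9))
  d1 <- sort(unique(centers[, 1]))
  expect_true(all(diff(d1) == 9))
  expect_error(plan_tiles(array(0L, dim = rep(8, 3)), 9, 4), "empty")
  expect_error(plan_tiles(one, 9, 10), "stride")
})

test_that("overlap averaging preserves the probability simplex", {
  # zero-weight network emits uniform probabilities everywhere
  spec <- network_spec(2, 2, 1, 3, input_side = 9L)
  w <- init_weights(spec, seed = 1L)
  w <- rapply(w, function(v) v * 0, how = "replace")
  w$bn$run_var <- rep(1, spec$dense_channels)
  vol <- array(rnorm(20^3), dim = rep(20, 3))
  region <- array(0L, dim = rep(20, 3)); region[8:14, 8:14, 8:14] <- 1L
  centers <- plan_tiles(region, spec$output_side, 2)
  pred <- predict_volume(spec, w, array(vol, dim = c(dim(vol), 1L)), centers)
  covered <- pred$count > 0
  sums <- apply(pred$prob, c(1, 2, 3), sum)
  expect_true(all(abs(sums[covered] - 1) < 1e-6))
  expect_true(all(abs(pred$prob[, , , 1][covered] - 1 / 3) < 1e-6))
  expect_true(all(covered[region == 1L]))
  # stride = output side: no overlap, every covered voxel has one estimate
  centers1 <- plan_tiles(region, spec$output_side, spec$output_side)
  pred1 <- predict_volume(spec, w, array(vol, dim = c(dim(vol), 1L)), centers1)
  expect_true(all(pred1$count[region == 1L] == 1L))
})

test_that("prior merging applies argmax, overrides and background rules", {
  d <- c(5, 5, 5)
  C <- 3L
  set.seed(42)
  prob <- array(runif(prod(d) * C), dim = c(d, C))
  sums <- apply(prob, c(1, 2, 3), sum)
  for (c in 1:C) prob[, , , c] <- prob[, , , c] / sums
  count <- array(1L, dim = d)
  B <- array(0L, dim = d); B[2:4, 2:4, 2:4] <- 1L
  P1 <- array(0L, dim = d); P1[1, 1, 1] <- 1L
  P2 <- array(0L, dim = d); P2[5, 5, 5] <- 1L
  priors <- structure(list(working = list(B, B), positive = list(P1, P2),
                           global_working = B, n_classes = C), class = "prior_set")
  lab <- merge_with_priors(list(prob = prob, count = count), priors)
  # voxel-by-voxel hand merge
  for (i in 1:5) for (j in 1:5) for (k in 1:5) {
    want <- if (P1[i, j, k] == 1L) 1L else if (P2[i, j, k] == 1L) 2L
    else if (B[i, j, k] == 1L) which.max(prob[i, j, k, ]) - 1L else 0L
    expect_equal(lab$data[i, j, k], as.integer(want))
  }
  # background-everywhere probabilities leave only the positive volumes
  pb <- array(0, dim = c(d, C)); pb[, , , 1] <- 1
  lab2 <- merge_with_priors(list(prob = pb, count = count), priors)
  expect_identical(lab2$data, array(as.integer(P1 + 2L * P2), dim = d))
  # overlapping positive volumes are rejected
  priors_bad <- priors; priors_bad$positive <- list(P1, P1)
  expect_error(merge_with_priors(list(prob = prob, count = count), priors_bad),
               "overlap")
  # argmax ties resolve to the lowest class index
  ptie <- array(1 / 3, dim = c(d, C))
  lab3 <- merge_with_priors(list(prob = ptie, count = count), priors)
  inb <- B == 1L & P1 == 0L & P2 == 0L
  expect_true(all(lab3$data[inb] == 0L))
})

test_that("largest-component postprocessing removes satellites idempotently", {
  lab <- array(0L, dim = rep(12, 3))
  lab[2:4, 2:4, 2:4] <- 1L            # 27-voxel component
  lab[9:10, 9, 9] <- 1L               # 2-voxel satellite
  lab[6:7, 2:3, 10:11] <- 2L          # single class-2 component
  out <- keep_largest_component(lab)
  expect_equal(sum(out == 1L), 27)
  expect_equal(out[9, 9, 9], 0L)
  expect_equal(sum(out == 2L), 8)     # untouched single component
  # idempotent, removal-only, empty classes unchanged
  expect_identical(keep_largest_component(out), out)
  expect_true(all(out[lab == 0L] == 0L))
  # 6 vs 26 connectivity: diagonal pieces split under 6-connectivity
  diag2 <- array(0L, dim = rep(6, 3))
  diag2[2, 2, 2] <- 1L; diag2[3, 3, 3] <- 1L; diag2[5, 5, 5] <- 1L
  got26 <- keep_largest_component(diag2, 26L)
  expect_equal(sum(got26), 2)         # the diagonal pair survives
  got6 <- keep_largest_component(diag2, 6L)
  expect_equal(sum(got6), 1)          # under 6-connectivity all are singletons
})

test_that("end-to-end segmentation is deterministic and respects overrides", {
  m <- tiny_model()
  s <- tiny_cohort()[[1]]
  g1 <- predict(m, s, stride = 4L)
  g2 <- predict(m, s, stride = 4L)
  expect_identical(g1$labels$data, g2$labels$data)
  # positive volumes always carry their class
  for (c in 1:2)
    expect_true(all(g1$labels$data[m$priors$positive[[c]] == 1L] == c))
  # voxels outside B and the positive volumes stay background
  outside <- m$priors$global_working == 0L &
    m$priors$positive[[1]] == 0L & m$priors$positive[[2]] == 0L
  expect_true(all(g1$labels$data[outside] == 0L))
  # disabling postprocessing can only add voxels
  g3 <- predict(m, s, stride = 4L, postprocess = FALSE)
  expect_true(all(g3$labels$data[g1$labels$data != 0L] ==
                    g1$labels$data[g1$labels$data != 0L]))
})
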