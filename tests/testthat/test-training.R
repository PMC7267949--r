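test_that("subject splitting is seeded, disjoint and covering", {
  ids <- sprintf("s%02d", 1:20)
  sp <- split_subjects(ids, 0.2, seed = 3L)
  expect_length(sp$train_ids, 16)
  expect_length(sp$validation_ids, 4)
  expect_setequal(c(sp$train_ids, sp$validation_ids), ids)
  expect_length(intersect(sp$train_ids, sp$validation_ids), 0)
  expect_identical(sp, split_subjects(ids, 0.2, seed = 3L))
  expect_false(identical(sp$validation_ids,
                         split_subjects(ids, 0.2, seed = 4L)$validation_ids))
  expect_error(split_subjects("a", 0.2), "at least 2")
})

test_that("iteration batches are class balanced inside the working volume", {
  coh <- tiny_cohort()
  pri <- build_priors(lapply(coh, `[[`, "labels"))
  spec <- network_spec(2, 2, 4, 3, input_side = 9L)
  cfg <- train_config(voxels_per_iteration = 30L, seed = 1L)
  set.seed(11)
  batch <- sample_iteration_batch(coh, pri, spec, cfg)
  centers <- attr(batch, "centers")
  # quota: floor(30 / (5 subjects * 3 classes)) = 2 per (subject, class)
  expect_equal(nrow(centers), 30)
  expect_true(all(table(centers$class) == 10))
  expect_true(all(table(centers$subject) == 6))
  # every sampled centre lies inside B and carries its stratum's class
  for (r in seq_len(nrow(centers))) {
    s <- coh[[centers$subject[r]]]
    expect_equal(pri$global_working[centers$center[r]], 1L)
    expect_equal(as.integer(s$labels$data[centers$center[r]]), centers$class[r])
  }
  # emitted arrays have the contracted shapes
  expect_equal(dim(batch$x), c(9, 9, 9, 4, 30))
  expect_equal(dim(batch$t), c(5, 5, 5, 3, 30))
})

test_that("validation sets are fixed, uniform and inside the working volume", {
  coh <- tiny_cohort()
  pri <- build_priors(lapply(coh, `[[`, "labels"))
  spec <- network_spec(2, 2, 4, 3, input_side = 9L)
  cfg <- train_config(validation_patches_per_subject = 150L, seed = 1L)
  v1 <- build_validation_set(coh[1:2], pri, spec, cfg, seed = 8L)
  v2 <- build_validation_set(coh[1:2], pri, spec, cfg, seed = 8L)
  expect_identical(v1$x, v2$x)
  centers <- attr(v1, "centers")
  expect_true(all(pri$global_working[centers] == 1L))
  # class mix approximates the class histogram of B, not a uniform mix
  lab_b <- c(coh[[1]]$labels$data[pri$global_working == 1L],
             coh[[2]]$labels$data[pri$global_working == 1L])
  ref <- table(factor(lab_b, levels = 0:2)) / length(lab_b)
  got_lab <- c(coh[[1]]$labels$data[centers[1:150]],
               coh[[2]]$labels$data[centers[151:300]])
  got <- table(factor(got_lab, levels = 0:2)) / length(got_lab)
  expect_lt(max(abs(got - ref)), 0.12)  # close to B's mix
  expect_gt(max(ref), 0.45)             # and that mix is far from uniform
  expect_error(build_validation_set(list(), pri, spec, cfg), "no validation")
})

test_that("early stopping returns the argmin-validation iteration", {
  # scripted sequence from a patience-2 walkthrough
  tr <- early_stop_trace(c(5, 4, 3, 3.1, 3.1, 3.2), patience = 2)
  expect_equal(tr$best_iteration, 3)
  expect_equal(tr$stop_iteration, 5)
  # strictly decreasing curve runs to the end, best = last
  tr2 <- early_stop_trace(c(5, 4, 3, 2, 1), patience = 2)
  expect_equal(tr2$best_iteration, 5)
  expect_equal(tr2$stop_iteration, 5)
  # property check against the explicit argmin on random sequences
  set.seed(13)
  for (i in 1:25) {
    losses <- round(runif(sample(5:30, 1), 0, 3), 2)
    patience <- sample(1:5, 1)
    tr <- early_stop_trace(losses, patience)
    seen <- losses[seq_len(tr$stop_iteration)]
    expect_equal(tr$best_iteration, which.min(seen))
    # no earlier stop was possible, and the stop is justified
    if (tr$stop_iteration < length(losses))
      expect_gte(tr$stop_iteration - tr$best_iteration, patience)
  }
})

test_that("a short training run decreases the training loss deterministically", {
  coh <- tiny_cohort()
  m <- tiny_model()
  h <- m$history
  expect_equal(nrow(h), 3)
  expect_lt(h$train_loss[3], h$train_loss[1])
  # best weights come from the argmin-validation iteration
  expect_equal(m$best_iteration, which.min(h$val_loss))
  # the whole run reproduces bit-exactly under the same seed
  m2 <- priorseg_fit(coh, variant = "CNN-SP", width = 4L,
                     config = tiny_train_config(3L), seed = 9L)
  expect_identical(m$weights, m2$weights)
  expect_identical(m$history, m2$history)
})

test_that("training configuration invariants are enforced", {
  expect_error(train_config(validation_fraction = 0), "validation_fraction")
  expect_error(train_config(patience = 0L), "patience")
})
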