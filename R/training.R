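#' Training configuration
#'
#' One training "iteration" is an outer cycle: sample approximately
#' `voxels_per_iteration` class-balanced patch centres across the training
#' subjects, consume them in shuffled minibatches of `batch_size` (one
#' gradient step each), then evaluate the cross-entropy on a fixed
#' validation set. Optimization is RMSProp with Nesterov momentum at a
#' static learning rate; training stops when the best validation loss has
#' not decreased for `patience` iterations, and the returned weights are
#' those of the best-validation iteration.
#'
#' @param voxels_per_iteration target number of sampled voxels per iteration
#'   (about 2,000 at full scale; the per-(subject, class) quota is
#'   `floor(voxels_per_iteration / (n_subjects * classes))`).
#' @param batch_size minibatch size B (128 baseline; 32 for deep variants).
#' @param learning_rate static learning rate (2.5e-4).
#' @param momentum Nesterov momentum (0.9).
#' @param rmsprop_decay EMA decay of the squared-gradient accumulator.
#' @param patience early-stopping patience in iterations (30).
#' @param max_iterations hard iteration cap.
#' @param validation_fraction fraction of subjects held out (0.2).
#' @param validation_patches_per_subject fixed validation patches sampled
#'   uniformly (not class-balanced) inside the working volume per
#'   validation subject.
#' @param weight_decay l2 penalty on convolutional filters (1e-4).
#' @param seed integer seed for all training randomness.
#' @return object of class `train_config`.
#' @export
train_config <- function(voxels_per_iteration = 2000L, batch_size = 128L,
                         learning_rate = 2.5e-4, momentum = 0.9,
                         rmsprop_decay = 0.9, patience = 30L,
                         max_iterations = 500L, validation_fraction = 0.2,
                         validation_patches_per_subject = 1000L,
                         weight_decay = 1e-4, seed = 1L) {
  if (validation_fraction <= 0 || validation_fraction >= 1)
    stop("validation_fraction must be in (0, 1)", call. = FALSE)
  if (patience < 1L) stop("patience must be >= 1", call. = FALSE)
  structure(list(voxels_per_iteration = as.integer(voxels_per_iteration),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, momentum = momentum,
                 rmsprop_decay = rmsprop_decay, patience = as.integer(patience),
                 max_iterations = as.integer(max_iterations),
                 validation_fraction = validation_fraction,
                 validation_patches_per_subject = as.integer(validation_patches_per_subject),
                 weight_decay = weight_decay, seed = as.integer(seed)),
            class = "train_config")
}

#' Split subjects into training and validation sets
#'
#' @param subject_ids character or integer vector (length >= 2).
#' @param fraction validation fraction; the validation count is
#'   `round(fraction * n)`, at least 1.
#' @param seed integer seed.
#' @return list with `train_ids` and `validation_ids` (disjoint, covering).
#' @export
split_subjects <- function(subject_ids, fraction = 0.2, seed = 1L) {
  n <- length(subject_ids)
  if (n < 2L) stop("need at least 2 subjects", call. = FALSE)
  n_val <- max(1L, round(fraction * n))
  val <- with_seed(seed, sample(subject_ids, n_val))
  list(train_ids = setdiff(subject_ids, val), validation_ids = val)
}

# Candidate centre indices (linear) per class for one subject: voxels of
# class c intersected with the sampling region.
class_strata <- function(labels, region) {
  C <- labels$n_classes
  lapply(seq_len(C) - 1L, function(c)
    which(labels$data == c & region != 0L))
}

# Build the (appearance [+ coordinates]) channel stack for a subject.
subject_channel_stack <- function(subject, priors, use_coords) {
  img <- subject$image$data
  if (use_coords) {
    d <- dim(img)
    stack <- array(0, dim = c(d, 4L))
    stack[, , , 1] <- img
    stack[, , , 2] <- priors$coords$x
    stack[, , , 3] <- priors$coords$y
    stack[, , , 4] <- priors$coords$z
    stack
  } else {
    array(img, dim = c(dim(img), 1L))
  }
}

# Extract one training/validation sample at a centre: per-patch-normalized
# appearance channel (+ un-normalized coordinate channels) at the input
# side, and the one-hot label patch at the input side (cropped to the
# output side after any augmentation).
extract_sample <- function(stack, labels_onehot, center, input_side) {
  ch <- extract_patch(stack, center, input_side)
  ch[, , , 1] <- normalize_appearance(ch[, , , 1])
  tg <- extract_patch(labels_onehot, center, input_side)
  # zero-filled out-of-volume regions are background
  tg[, , , 1] <- tg[, , , 1] + (1 - apply(tg, c(1, 2, 3), sum))
  list(channels = ch, target = tg)
}

center_crop4 <- function(a, side) {
  off <- (dim(a)[1] - side) %/% 2L
  idx <- (off + 1L):(off + side)
  a[idx, idx, idx, , drop = FALSE]
}

# Precompute per-subject channel stacks, one-hot labels and per-class
# candidate strata once per training run; sampling then only extracts
# patches.
prepare_subjects <- function(subjects, priors, classes, use_coords, use_wv) {
  region <- if (use_wv) priors$global_working else
    array(1L, dim = dim(subjects[[1]]$labels$data))
  prep <- lapply(subjects, function(s) {
    list(stack = subject_channel_stack(s, priors, use_coords),
         oh = one_hot(s$labels$data, classes),
         strata = class_strata(s$labels, region),
         dims = dim(s$labels$data),
         labels = s$labels)
  })
  structure(list(subjects = prep, region = region), class = "prepared_subjects")
}

#' Sample one class-balanced training iteration
#'
#' Draws `floor(voxels_per_iteration / (n_subjects * C))` centres per
#' (subject, class) stratum, uniformly from the voxels of that class inside
#' the sampling region (the global working volume, or the whole grid when
#' the working-volume prior is disabled), with replacement when a stratum is
#' smaller than its quota. Patches are extracted around each centre,
#' appearance channels per-patch normalized, optional elastic augmentation
#' applied per sample, label targets cropped to the output side, and the
#' whole set shuffled.
#'
#' @param subjects list of subjects (each with `image` and `labels`).
#' @param priors a `prior_set` (supplies region and coordinate images).
#' @param spec a [network_spec()].
#' @param config a [train_config()].
#' @param augment_cfg optional [deformation_config()]; NULL disables
#'   augmentation.
#' @param use_coords,use_wv which spatial priors are active.
#' @return list with arrays `x` (in^3, N, n) and `t` (out^3, C, n).
#' @export
sample_iteration_batch <- function(subjects, priors, spec, config,
                                   augment_cfg = NULL, use_coords = TRUE,
                                   use_wv = TRUE) {
  C <- spec$classes
  prep <- if (inherits(subjects, "prepared_subjects")) subjects else
    prepare_subjects(subjects, priors, C, use_coords, use_wv)
  n_sub <- length(prep$subjects)
  quota <- config$voxels_per_iteration %/% (n_sub * C)
  if (quota < 1L) quota <- 1L
  xs <- list()
  ts <- list()
  k <- 0L
  meta <- list()
  si_idx <- 0L
  for (s in prep$subjects) {
    si_idx <- si_idx + 1L
    empty <- vapply(s$strata, length, 1L) == 0L
    for (cl in seq_len(C)) {
      if (empty[cl]) next
      centers <- sample(s$strata[[cl]], quota,
                        replace = length(s$strata[[cl]]) < quota)
      meta[[length(meta) + 1L]] <- data.frame(subject = si_idx,
                                              class = cl - 1L,
                                              center = centers)
      for (ctr in centers) {
        cidx <- arrayInd(ctr, s$dims)[1, ]
        smp <- extract_sample(s$stack, s$oh, cidx, spec$input_side)
        if (!is.null(augment_cfg) && augment_cfg$alpha_i > 0) {
          aug <- augment_sample(smp$channels, smp$target, augment_cfg)
          smp <- list(channels = aug$channels, target = aug$target_onehot)
        }
        k <- k + 1L
        xs[[k]] <- smp$channels
        ts[[k]] <- center_crop4(smp$target, spec$output_side)
      }
    }
  }
  if (k == 0L)
    stop("every sampling stratum is empty in every subject", call. = FALSE)
  # verify class availability across the cohort
  for (cl in seq_len(C)) {
    any_c <- any(vapply(prep$subjects, function(s)
      length(s$strata[[cl]]) > 0L, logical(1)))
    if (!any_c)
      stop(sprintf("class %d has no voxels inside the sampling region", cl - 1L),
           call. = FALSE)
  }
  ord <- sample.int(k)
  si <- spec$input_side
  so <- spec$output_side
  x <- array(0, dim = c(si, si, si, spec$channels, k))
  t <- array(0, dim = c(so, so, so, C, k))
  for (j in seq_len(k)) {
    x[, , , , j] <- xs[[ord[j]]]
    t[, , , , j] <- ts[[ord[j]]]
  }
  out <- list(x = x, t = t)
  attr(out, "centers") <- do.call(rbind, meta)[ord, , drop = FALSE]
  out
}

#' Build the fixed validation set
#'
#' Centres are drawn uniformly from the sampling region of each validation
#' subject (no class balancing, so the class mix approximates the region's
#' true class distribution), once, before training; the set is never
#' resampled.
#'
#' @inheritParams sample_iteration_batch
#' @param seed integer seed.
#' @return list with arrays `x` and `t` as in [sample_iteration_batch()].
#' @export
build_validation_set <- function(subjects, priors, spec, config,
                                 use_coords = TRUE, use_wv = TRUE, seed = 1L) {
  if (length(subjects) == 0L) stop("no validation subjects", call. = FALSE)
  region <- if (use_wv) priors$global_working else {
    array(1L, dim = dim(subjects[[1]]$labels$data))
  }
  if (!any(region != 0L)) stop("sampling region is empty", call. = FALSE)
  with_seed(seed, {
    xs <- list(); ts <- list(); k <- 0L
    all_centers <- integer()
    pool <- which(region != 0L)
    for (s in subjects) {
      centers <- sample(pool, config$validation_patches_per_subject,
                        replace = length(pool) < config$validation_patches_per_subject)
      all_centers <- c(all_centers, centers)
      stack <- subject_channel_stack(s, priors, use_coords)
      oh <- one_hot(s$labels$data, spec$classes)
      d <- dim(s$labels$data)
      for (ctr in centers) {
        cidx <- arrayInd(ctr, d)[1, ]
        smp <- extract_sample(stack, oh, cidx, spec$input_side)
        k <- k + 1L
        xs[[k]] <- smp$channels
        ts[[k]] <- center_crop4(smp$target, spec$output_side)
      }
    }
    si <- spec$input_side; so <- spec$output_side
    x <- array(0, dim = c(si, si, si, spec$channels, k))
    t <- array(0, dim = c(so, so, so, spec$classes, k))
    for (j in seq_len(k)) { x[, , , , j] <- xs[[j]]; t[, , , , j] <- ts[[j]] }
    out <- list(x = x, t = t)
    attr(out, "centers") <- all_centers
    out
  })
}

#' Early-stopping bookkeeping
#'
#' Given a sequence of validation losses, returns the 1-based index of the
#' iteration whose weights would be kept (the argmin; first occurrence on
#' ties) and the iteration at which training stops: the first iteration
#' after which `patience` consecutive iterations have failed to improve on
#' the best loss, or the end of the sequence.
#'
#' @param val_losses numeric vector of per-iteration validation losses.
#' @param patience patience in iterations.
#' @return list with `best_iteration` and `stop_iteration`.
#' @export
early_stop_trace <- function(val_losses, patience) {
  best <- Inf
  best_it <- 0L
  for (it in seq_along(val_losses)) {
    if (val_losses[it] < best) {
      best <- val_losses[it]
      best_it <- it
    }
    if (it - best_it >= patience)
      return(list(best_iteration = best_it, stop_iteration = it))
  }
  list(best_iteration = best_it, stop_iteration = length(val_losses))
}

#' Train the network
#'
#' Runs the full optimization loop: per iteration, a fresh class-balanced
#' sample with on-the-fly elastic augmentation, shuffled minibatch RMSProp +
#' Nesterov steps on the penalized cross-entropy, a validation-loss
#' evaluation on the fixed set, and early-stopping bookkeeping. The
#' returned weights are the snapshot from the best-validation iteration.
#'
#' @param spec a [network_spec()].
#' @param train_subjects,val_subjects subject lists.
#' @param priors a `prior_set` built from train + validation subjects.
#' @param config a [train_config()].
#' @param augment_cfg optional [deformation_config()].
#' @param use_coords,use_wv spatial-prior switches.
#' @param verbose print per-iteration losses.
#' @return list with `weights` (best iteration), `history` (data.frame of
#'   iteration, train_loss, val_loss), `best_iteration`, `stop_iteration`.
#' @export
train_network <- function(spec, train_subjects, val_subjects, priors, config,
                          augment_cfg = NULL, use_coords = TRUE, use_wv = TRUE,
                          verbose = FALSE) {
  val_set <- build_validation_set(val_subjects, priors, spec, config,
                                  use_coords = use_coords, use_wv = use_wv,
                                  seed = mix_seed(config$seed, 2L))
  weights <- init_weights(spec, seed = mix_seed(config$seed, 1L))
  state <- list(r = NULL, v = NULL)
  history <- data.frame(iteration = integer(), train_loss = numeric(),
                        val_loss = numeric())
  best_loss <- Inf
  best_weights <- weights
  best_it <- 0L
  prep <- prepare_subjects(train_subjects, priors, spec$classes, use_coords,
                           use_wv)
  set.seed(mix_seed(config$seed, 3L))
  for (it in seq_len(config$max_iterations)) {
    batch <- sample_iteration_batch(prep, priors, spec, config,
                                    augment_cfg = augment_cfg,
                                    use_coords = use_coords, use_wv = use_wv)
    n <- dim(batch$x)[5]
    mb_starts <- seq(1L, n, by = config$batch_size)
    it_loss <- 0
    for (st in mb_starts) {
      idx <- st:min(st + config$batch_size - 1L, n)
      xb <- batch$x[, , , , idx, drop = FALSE]
      tb <- batch$t[, , , , idx, drop = FALSE]
      fw <- net_forward(spec, weights, xb, training = TRUE, keep_cache = TRUE)
      loss <- net_loss(fw$probs, tb, weights, alpha = config$weight_decay)
      if (!is.finite(loss))
        stop(sprintf("non-finite training loss at iteration %d", it), call. = FALSE)
      it_loss <- it_loss + as.numeric(loss) * length(idx)
      grads <- net_backward(spec, weights, fw, tb, alpha = config$weight_decay)
      weights <- update_bn_running(weights, fw)
      stepped <- optimizer_step(weights, grads, state,
                                lr = config$learning_rate,
                                momentum = config$momentum,
                                rho = config$rmsprop_decay)
      weights <- stepped$weights
      state <- stepped$state
    }
    it_loss <- it_loss / n
    val_loss <- validation_loss(spec, weights, val_set,
                                batch_size = config$batch_size)
    history <- rbind(history, data.frame(iteration = it, train_loss = it_loss,
                                         val_loss = val_loss))
    if (val_loss < best_loss) {
      best_loss <- val_loss
      best_weights <- weights
      best_it <- it
    }
    if (verbose)
      message(sprintf("iter %3d train %.4f val %.4f (best %d)", it, it_loss,
                      val_loss, best_it))
    if (it - best_it >= config$patience) break
  }
  list(weights = best_weights, history = history, best_iteration = best_it,
       stop_iteration = nrow(history))
}

# Mean validation cross-entropy (no penalty, inference mode).
validation_loss <- function(spec, weights, val_set, batch_size = 128L) {
  n <- dim(val_set$x)[5]
  total <- 0
  for (st in seq(1L, n, by = batch_size)) {
    idx <- st:min(st + batch_size - 1L, n)
    probs <- net_forward(spec, weights,
                         val_set$x[, , , , idx, drop = FALSE], training = FALSE)
    l <- net_loss(probs, val_set$t[, , , , idx, drop = FALSE], NULL, alpha = 0)
    total <- total + attr(l, "J") * length(idx)
  }
  total / n
}
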