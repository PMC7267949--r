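#' Fit a spatial-prior-augmented segmentation model
#'
#' The single entry point for training: splits the given (non-test)
#' subjects into training and validation sets, builds the spatial priors
#' from all of them, assembles the network for the chosen variant, and runs
#' the optimization loop with early stopping.
#'
#' Variants toggle the two spatial priors, the architecture depth and the
#' elastic-deformation augmentation:
#' \describe{
#'   \item{CNN-B}{baseline: appearance channel only, whole-grid sampling
#'     and tiling.}
#'   \item{CNN-SC}{+ coordinate channels.}
#'   \item{CNN-WV}{+ working-volume restriction.}
#'   \item{CNN-SP}{both spatial priors (coordinates and working volume).}
#'   \item{CNN-SP-D}{CNN-SP with 16 convolutional layers (41^3 input).}
#'   \item{CNN-SP-D+DA}{CNN-SP-D with elastic-deformation augmentation.}
#' }
#' Augmentation can also be switched on for any variant via `augment`.
#'
#' @param subjects list of subjects, each a list with `subject_id`, `image`
#'   (a [cs_volume()]) and `labels` (a [label_map()]).
#' @param variant model variant name (see Details).
#' @param width filters per 3x3x3 layer.
#' @param config a [train_config()].
#' @param augment logical or NULL (NULL = variant default); TRUE trains
#'   with [deformation_config()] augmentation.
#' @param augment_cfg a [deformation_config()] used when augmentation is on.
#' @param seed master seed; all training randomness derives from it.
#' @param verbose print per-iteration losses.
#' @return an object of class `priorseg_model`.
#' @export
priorseg_fit <- function(subjects, variant = "CNN-SP", width = 32L,
                         config = train_config(), augment = NULL,
                         augment_cfg = deformation_config(), seed = 1L,
                         verbose = FALSE) {
  flags <- variant_flags(variant)
  if (is.null(augment)) augment <- flags$augment
  config$seed <- mix_seed(seed, 11L)
  ids <- vapply(subjects, function(s) s$subject_id, character(1))
  split <- split_subjects(ids, config$validation_fraction,
                          seed = mix_seed(seed, 12L))
  train_subjects <- subjects[ids %in% split$train_ids]
  val_subjects <- subjects[ids %in% split$validation_ids]
  priors <- build_priors(lapply(subjects, `[[`, "labels"),
                         subject_ids = ids)
  C <- subjects[[1]]$labels$n_classes
  spec <- network_spec(depth = flags$depth, width = width,
                       channels = if (flags$use_coords) 4L else 1L,
                       classes = C)
  fit <- train_network(spec, train_subjects, val_subjects, priors, config,
                       augment_cfg = if (augment) augment_cfg else NULL,
                       use_coords = flags$use_coords, use_wv = flags$use_wv,
                       verbose = verbose)
  structure(list(
    spec = spec, weights = fit$weights, priors = priors, variant = variant,
    flags = flags, config = config, augment = augment,
    augment_cfg = if (augment) augment_cfg else NULL,
    history = fit$history, best_iteration = fit$best_iteration,
    stop_iteration = fit$stop_iteration,
    voxel_size = subjects[[1]]$image$voxel_size,
    train_ids = split$train_ids, validation_ids = split$validation_ids,
    seed = seed
  ), class = "priorseg_model")
}

#' Resolve a variant name to its component switches
#'
#' @param variant one of CNN-B, CNN-SC, CNN-WV, CNN-SP, CNN-SP-D,
#'   CNN-SP-D+DA.
#' @return list with `use_coords`, `use_wv`, `depth`, `augment`.
#' @export
variant_flags <- function(variant) {
  variant <- toupper(variant)
  known <- list(
    "CNN-B"       = list(use_coords = FALSE, use_wv = FALSE, depth = 8L, augment = FALSE),
    "CNN-SC"      = list(use_coords = TRUE,  use_wv = FALSE, depth = 8L, augment = FALSE),
    "CNN-WV"      = list(use_coords = FALSE, use_wv = TRUE,  depth = 8L, augment = FALSE),
    "CNN-SP"      = list(use_coords = TRUE,  use_wv = TRUE,  depth = 8L, augment = FALSE),
    "CNN-SP-D"    = list(use_coords = TRUE,  use_wv = TRUE,  depth = 16L, augment = FALSE),
    "CNN-SP-D+DA" = list(use_coords = TRUE,  use_wv = TRUE,  depth = 16L, augment = TRUE))
  if (!variant %in% names(known))
    stop(sprintf("unknown variant '%s'", variant), call. = FALSE)
  known[[variant]]
}

#' @export
print.priorseg_model <- function(x, ...) {
  cat(sprintf("<priorseg_model> variant %s%s\n", x$variant,
              if (x$augment) " + elastic augmentation" else ""))
  print(x$spec)
  cat(sprintf("trained %d iterations (best validation loss %.4f at iteration %d)\n",
              x$stop_iteration, min(x$history$val_loss), x$best_iteration))
  cat(sprintf("priors from %d subjects; working volume %d voxels\n",
              length(x$priors$source_subject_ids),
              sum(x$priors$global_working)))
  invisible(x)
}

#' @export
summary.priorseg_model <- function(object, ...) {
  h <- object$history
  cat(sprintf("Variant:          %s\n", object$variant))
  cat(sprintf("Parameters:       %s\n",
              format(count_parameters(object$spec), big.mark = ",")))
  cat(sprintf("Train/validation: %d / %d subjects\n",
              length(object$train_ids), length(object$validation_ids)))
  cat(sprintf("Iterations:       %d (early-stopped at best = %d)\n",
              nrow(h), object$best_iteration))
  cat(sprintf("Loss:             train %.4f -> %.4f; val %.4f -> best %.4f\n",
              h$train_loss[1], h$train_loss[nrow(h)], h$val_loss[1],
              min(h$val_loss)))
  if (!is.null(object$priors)) {
    pv <- vapply(object$priors$positive, sum, numeric(1))
    cat(sprintf("Priors:           |B| = %d; |P^c| = %s\n",
                sum(object$priors$global_working),
                paste(pv, collapse = ", ")))
  }
  invisible(object)
}

#' @export
coef.priorseg_model <- function(object, ...) object$weights

#' Plot training and validation loss curves
#'
#' @param x a `priorseg_model`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.priorseg_model <- function(x, ...) {
  h <- x$history
  graphics::matplot(h$iteration, cbind(h$train_loss, h$val_loss), type = "l",
                    lty = 1, col = c("grey40", "firebrick"),
                    xlab = "iteration", ylab = "loss", ...)
  graphics::abline(v = x$best_iteration, lty = 3)
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("grey40", "firebrick"), bty = "n")
  invisible(x)
}

#' Segment a new volume with a fitted model
#'
#' @param object a `priorseg_model`.
#' @param newdata a [cs_volume()] or a subject list with an `image` element.
#' @param stride tile stride in voxels.
#' @param postprocess keep only the largest connected component per class.
#' @param batch_size tiles per forward pass.
#' @param ... unused.
#' @return a `segmentation` (see [segment_subject()]).
#' @export
predict.priorseg_model <- function(object, newdata, stride = 4L,
                                   postprocess = TRUE, batch_size = 64L, ...) {
  vol <- if (inherits(newdata, "cs_volume")) newdata else newdata$image
  segment_subject(object$spec, object$weights, vol, priors = object$priors,
                  config = inference_config(stride = stride,
                                            batch_size = batch_size,
                                            apply_postprocessing = postprocess),
                  use_coords = object$flags$use_coords,
                  restrict_to_wv = object$flags$use_wv)
}
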