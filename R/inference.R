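#' Inference configuration
#'
#' @param stride tile stride in voxels (default 4; must be between 1 and the
#'   network output side so that coverage is complete).
#' @param batch_size tiles per forward pass.
#' @param connectivity connected-component connectivity (6 or 26).
#' @param apply_postprocessing keep only the largest connected component per
#'   class.
#' @return object of class `inference_config`.
#' @export
inference_config <- function(stride = 4L, batch_size = 64L, connectivity = 26L,
                             apply_postprocessing = TRUE) {
  if (!connectivity %in% c(6L, 26L)) stop("connectivity must be 6 or 26", call. = FALSE)
  structure(list(stride = as.integer(stride), batch_size = as.integer(batch_size),
                 connectivity = as.integer(connectivity),
                 apply_postprocessing = isTRUE(apply_postprocessing)),
            class = "inference_config")
}

#' Plan sliding-window tiles over a region
#'
#' Returns patch centres on a stride-spaced regular grid such that the
#' union of the output cubes (side `out_side`) covers every nonzero voxel
#' of `region`; tiles whose output cube does not touch the region are
#' dropped. Output cubes always lie inside the grid (input patches may
#' overhang and are zero-filled at extraction).
#'
#' @param region binary 3D array (e.g., the global working volume, or an
#'   all-ones array for whole-volume tiling).
#' @param out_side network output side in voxels.
#' @param stride stride in voxels, `1 <= stride <= out_side`.
#' @return integer matrix of tile centres (one row per tile, 1-based).
#' @export
plan_tiles <- function(region, out_side, stride) {
  if (!any(region != 0)) stop("region is empty", call. = FALSE)
  if (stride < 1L || stride > out_side)
    stop("stride must be in [1, output side]", call. = FALSE)
  d <- dim(region)
  h <- (out_side - 1L) %/% 2L
  idx <- which(region != 0, arr.ind = TRUE)
  axis_centers <- function(ax) {
    lo <- min(idx[, ax]); hi <- max(idx[, ax])
    cmin <- h + 1L; cmax <- d[ax] - h
    cs <- min(max(lo + h, cmin), cmax)
    while (cs[length(cs)] + h < hi && cs[length(cs)] < cmax)
      cs <- c(cs, min(cs[length(cs)] + stride, cmax))
    if (cs[length(cs)] + h < hi)
      cs <- c(cs, min(max(hi - h, cmin), cmax))
    unique(cs)
  }
  cx <- axis_centers(1); cy <- axis_centers(2); cz <- axis_centers(3)
  centers <- as.matrix(expand.grid(x = cx, y = cy, z = cz))
  keep <- logical(nrow(centers))
  for (i in seq_len(nrow(centers))) {
    c0 <- centers[i, ]
    sub <- region[(c0[1] - h):(c0[1] + h), (c0[2] - h):(c0[2] + h),
                  (c0[3] - h):(c0[3] + h)]
    keep[i] <- any(sub != 0)
  }
  centers <- centers[keep, , drop = FALSE]
  storage.mode(centers) <- "integer"
  centers
}

#' Sliding-window probability prediction with overlap averaging
#'
#' Applies the trained network to every planned tile and records, per
#' voxel, the arithmetic mean of all overlapping tile probability
#' estimates, together with the number of contributing tiles. Voxels
#' covered by no tile carry no estimate (count 0).
#'
#' @param spec a [network_spec()].
#' @param weights trained weights.
#' @param stack channel stack (x, y, z, channel) for the subject; the
#'   appearance channel of each extracted patch is per-patch normalized.
#' @param centers tile centres from [plan_tiles()].
#' @param batch_size tiles per forward pass.
#' @return list with `prob` (x, y, z, class probability sums averaged) and
#'   `count` (contributions per voxel).
#' @export
predict_volume <- function(spec, weights, stack, centers, batch_size = 64L) {
  d <- dim(stack)[1:3]
  C <- spec$classes
  so <- spec$output_side
  h <- (so - 1L) %/% 2L
  prob_sum <- array(0, dim = c(d, C))
  count <- array(0L, dim = d)
  n <- nrow(centers)
  si <- spec$input_side
  for (st in seq(1L, n, by = batch_size)) {
    idx <- st:min(st + batch_size - 1L, n)
    xb <- array(0, dim = c(si, si, si, spec$channels, length(idx)))
    for (j in seq_along(idx)) {
      p <- extract_patch(stack, centers[idx[j], ], si)
      p[, , , 1] <- normalize_appearance(p[, , , 1])
      xb[, , , , j] <- p
    }
    probs <- net_forward(spec, weights, xb, training = FALSE)
    for (j in seq_along(idx)) {
      c0 <- centers[idx[j], ]
      rx <- (c0[1] - h):(c0[1] + h); ry <- (c0[2] - h):(c0[2] + h)
      rz <- (c0[3] - h):(c0[3] + h)
      prob_sum[rx, ry, rz, ] <- prob_sum[rx, ry, rz, , drop = FALSE] +
        probs[, , , , j, drop = FALSE][, , , , 1]
      count[rx, ry, rz] <- count[rx, ry, rz] + 1L
    }
  }
  cnz <- pmax(count, 1L)
  for (c in seq_len(C)) prob_sum[, , , c] <- prob_sum[, , , c] / cnz
  list(prob = prob_sum, count = count)
}

#' Merge network probabilities with the spatial priors
#'
#' Inside the global working volume, each covered voxel takes the argmax
#' class (ties resolved to the lowest class index); every voxel of a
#' positive volume `P^c` is labelled `c` regardless of the network output;
#' all remaining voxels are background. With `priors = NULL` (prior-free
#' baseline) the argmax is taken wherever tiles produced an estimate.
#'
#' @param pred result of [predict_volume()].
#' @param priors a `prior_set` or NULL.
#' @return a [label_map()].
#' @export
merge_with_priors <- function(pred, priors = NULL) {
  d <- dim(pred$count)
  C <- dim(pred$prob)[4]
  lab <- array(0L, dim = d)
  region <- if (is.null(priors)) pred$count > 0L else
    priors$global_working != 0L & pred$count > 0L
  best_p <- array(-Inf, dim = d)
  for (c in seq_len(C)) {
    pc <- pred$prob[, , , c]
    take <- region & pc > best_p  # strict: ties keep the lower class index
    lab[take] <- c - 1L
    best_p[take] <- pc[take]
  }
  if (!is.null(priors)) {
    # overlapping positive volumes violate the prior-set invariants
    if (length(priors$positive) > 1L) {
      tot <- Reduce(`+`, priors$positive)
      if (any(tot > 1L)) stop("positive volumes overlap", call. = FALSE)
    }
    for (c in seq_along(priors$positive))
      lab[priors$positive[[c]] != 0L] <- c
  }
  label_map(lab, n_classes = C)
}

#' Largest-connected-component postprocessing
#'
#' For each foreground class independently, labels connected components
#' under the configured connectivity and removes all but the largest
#' (ties broken by the component first encountered in scan order),
#' eliminating isolated clusters of false positives. Idempotent and
#' removal-only.
#'
#' @param labels a [label_map()] or integer array.
#' @param connectivity 6 or 26.
#' @return object of the same type as `labels`.
#' @export
keep_largest_component <- function(labels, connectivity = 26L) {
  lm <- inherits(labels, "label_map")
  arr <- if (lm) labels$data else labels
  classes <- setdiff(sort(unique(as.vector(arr))), 0L)
  for (c in classes) {
    comp <- cpp_components(array(as.integer(arr == c), dim = dim(arr)),
                           as.integer(connectivity))
    if (max(comp) <= 1L) next
    sizes <- tabulate(comp[comp > 0L])
    keep <- which.max(sizes)  # first max in scan order on ties
    arr[arr == c & comp != keep] <- 0L
  }
  if (lm) { labels$data <- arr; labels } else arr
}

#' Segment one subject end to end
#'
#' Plans tiles over the working volume (or the whole grid for the
#' prior-free baseline), predicts with overlap averaging, merges with the
#' positive volumes, and optionally keeps the largest connected component
#' per class. Deterministic for fixed weights.
#'
#' @param spec a [network_spec()].
#' @param weights trained weights.
#' @param volume a [cs_volume()].
#' @param priors a `prior_set`, or NULL for the prior-free baseline.
#' @param config an [inference_config()].
#' @param use_coords whether the model consumes coordinate channels (taken
#'   from `priors` when available, otherwise computed for the grid).
#' @param restrict_to_wv restrict tiling and labelling to the working
#'   volume and apply the positive volumes; FALSE tiles the whole grid
#'   (prior-free and coordinates-only variants).
#' @return object of class `segmentation`: list with `labels`
#'   ([label_map()]), `prob`, `count`.
#' @export
segment_subject <- function(spec, weights, volume, priors = NULL,
                            config = inference_config(), use_coords = TRUE,
                            restrict_to_wv = !is.null(priors)) {
  d <- dim(volume$data)
  if (restrict_to_wv && is.null(priors))
    stop("working-volume restriction requires priors", call. = FALSE)
  region <- if (restrict_to_wv) priors$global_working else array(1L, dim = d)
  coord_src <- if (!is.null(priors)) priors else list(coords = coordinate_images(d))
  stack <- subject_channel_stack(list(image = volume), coord_src, use_coords)
  centers <- plan_tiles(region, spec$output_side, config$stride)
  pred <- predict_volume(spec, weights, stack, centers,
                         batch_size = config$batch_size)
  labels <- merge_with_priors(pred, if (restrict_to_wv) priors else NULL)
  if (config$apply_postprocessing)
    labels <- keep_largest_component(labels, config$connectivity)
  structure(list(labels = labels, prob = pred$prob, count = pred$count,
                 centers = centers), class = "segmentation")
}
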