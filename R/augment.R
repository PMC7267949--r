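#' Elastic deformation configuration
#'
#' Random 3D elastic deformations are generated by smoothing an i.i.d.
#' U(-1,1) displacement field with a Gaussian of SD `sigma_e` (the
#' elasticity, in mm), rescaling it so the mean per-voxel displacement
#' magnitude is one, and multiplying by `alpha_i` (the intensity, in mm).
#' The defaults are the values found best by a coarse grid search over
#' sigma_e in \{4, 8, 16\} mm and alpha_i in \{1, 2, 4, 8\} mm.
#'
#' @param sigma_e Gaussian smoothing SD in mm; must be > 0.
#' @param alpha_i deformation magnitude in mm; 0 disables deformation.
#' @param seed optional integer seed for field sampling.
#' @return an object of class `deformation_config`.
#' @export
deformation_config <- function(sigma_e = 4, alpha_i = 2, seed = NULL) {
  stopifnot_scalar(sigma_e, "sigma_e")
  stopifnot_scalar(alpha_i, "alpha_i")
  if (sigma_e <= 0) stop("sigma_e must be > 0", call. = FALSE)
  if (alpha_i < 0) stop("alpha_i must be >= 0", call. = FALSE)
  structure(list(sigma_e = sigma_e, alpha_i = alpha_i, seed = seed),
            class = "deformation_config")
}

#' Sample a random elastic deformation field
#'
#' Each displacement component starts i.i.d. U(-1,1) per voxel, is smoothed
#' along each axis with a Gaussian kernel of SD `sigma_e` (converted from mm
#' to voxels), and the whole field is rescaled so that the mean Euclidean
#' displacement magnitude equals exactly `alpha_i` mm. With `alpha_i = 0` a
#' zero field is returned.
#'
#' @param shape spatial dims (length 3) of the sample the field will warp.
#' @param config a [deformation_config()].
#' @param voxel_size voxel size in mm (scalar or length 3).
#' @return object of class `deformation_field`: list of 3 arrays `dx`, `dy`,
#'   `dz` (displacements in mm) plus the voxel size.
#' @export
sample_field <- function(shape, config, voxel_size = 1) {
  shape <- as.integer(shape)
  if (length(shape) != 3L) stop("shape must have length 3", call. = FALSE)
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  draw <- function() {
    comps <- lapply(1:3, function(ax) {
      u <- array(runif(prod(shape), -1, 1), dim = shape)
      sig_vox <- config$sigma_e / voxel_size[ax]
      cpp_gauss_smooth(u, sig_vox, 4)
    })
    comps
  }
  sample_once <- function() {
    if (config$alpha_i == 0) {
      z <- array(0, dim = shape)
      return(list(dx = z, dy = z, dz = z))
    }
    for (attempt in 1:10) {
      comps <- draw()
      mag <- sqrt(comps[[1]]^2 + comps[[2]]^2 + comps[[3]]^2)
      mbar <- mean(mag)
      if (mbar > 0) {
        sc <- config$alpha_i / mbar
        return(list(dx = comps[[1]] * sc, dy = comps[[2]] * sc,
                    dz = comps[[3]] * sc))
      }
    }
    stop("degenerate all-zero smoothed field", call. = FALSE)
  }
  f <- if (!is.null(config$seed)) with_seed(config$seed, sample_once()) else sample_once()
  f$voxel_size <- voxel_size
  class(f) <- "deformation_field"
  f
}

#' Warp a scalar channel by a deformation field
#'
#' Trilinear interpolation at position + displacement; sample positions
#' falling outside the grid are clamped to the edge.
#'
#' @param channel 3D numeric array.
#' @param field a [sample_field()] result with matching spatial dims.
#' @return warped array of the same shape.
#' @export
warp_scalar <- function(channel, field) {
  if (!identical(dim(channel), dim(field$dx)))
    stop("channel and field shapes differ", call. = FALSE)
  vs <- field$voxel_size
  cpp_warp_trilinear(channel, field$dx / vs[1], field$dy / vs[2],
                     field$dz / vs[3])
}

#' Warp a label map as soft one-hot channels
#'
#' Labels are one-hot encoded, each channel is trilinearly interpolated with
#' the same field, and the channels are renormalized to sum to one per voxel.
#' The slight blurring this introduces at structure boundaries acts as label
#' smoothing.
#'
#' @param labels a [label_map()], 3D integer array, or a one-hot array
#'   (x, y, z, class).
#' @param field a [sample_field()] result.
#' @param n_classes number of classes (required for plain integer arrays
#'   unless a `label_map` is given).
#' @return soft label array (x, y, z, class) with per-voxel sums of 1.
#' @export
warp_labels <- function(labels, field, n_classes = NULL) {
  oh <- if (inherits(labels, "label_map")) {
    one_hot(labels$data, labels$n_classes)
  } else if (length(dim(labels)) == 4L) {
    labels
  } else {
    if (is.null(n_classes)) n_classes <- max(labels) + 1L
    one_hot(labels, n_classes)
  }
  C <- dim(oh)[4]
  if (C < 2L) stop("need at least 2 classes", call. = FALSE)
  out <- array(0, dim = dim(oh))
  for (c in seq_len(C)) {
    w <- warp_scalar(oh[, , , c], field)
    out[, , , c] <- pmin(pmax(w, 0), 1)
  }
  s <- out[, , , 1]
  for (c in seq_len(C)[-1]) s <- s + out[, , , c]
  s[s == 0] <- 1
  for (c in seq_len(C)) out[, , , c] <- out[, , , c] / s
  out
}

#' One-hot encode an integer label array
#'
#' @param labels 3D integer array with values in `0..n_classes-1`.
#' @param n_classes number of classes including background.
#' @return numeric array (x, y, z, class).
#' @export
one_hot <- function(labels, n_classes) {
  d <- dim(labels)
  out <- array(0, dim = c(d, n_classes))
  for (c in seq_len(n_classes)) out[, , , c] <- as.numeric(labels == c - 1L)
  out
}

#' Elastically deform one multichannel training sample
#'
#' Samples a single random field and applies it coherently to every channel
#' (appearance and coordinate channels) and to the one-hot label target, so
#' that image content and labels stay spatially consistent. With
#' `alpha_i = 0` the sample is returned unchanged.
#'
#' @param channels array (side, side, side, nchan).
#' @param target_onehot array (side, side, side, classes).
#' @param config a [deformation_config()].
#' @param voxel_size voxel size in mm.
#' @return list with warped `channels` and `target_onehot`.
#' @export
augment_sample <- function(channels, target_onehot, config, voxel_size = 1) {
  if (config$alpha_i == 0)
    return(list(channels = channels, target_onehot = target_onehot))
  sp <- dim(channels)[1:3]
  if (!identical(sp, dim(target_onehot)[1:3]))
    stop("channels and target must share spatial dims", call. = FALSE)
  field <- sample_field(sp, config, voxel_size)
  ch <- channels
  for (j in seq_len(dim(channels)[4])) ch[, , , j] <- warp_scalar(channels[, , , j], field)
  tg <- warp_labels(target_onehot, field)
  list(channels = ch, target_onehot = tg)
}
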