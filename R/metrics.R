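#' Dice overlap coefficient
#'
#' `100 * 2|A intersect R| / (|A| + |R|)`, expressed as a percentage with
#' 100 meaning perfect overlap. Two empty masks score 100 (with a warning);
#' exactly one empty mask scores 0.
#'
#' @param a,r binary masks (logical or 0/1 arrays) of the same shape.
#' @return Dice coefficient in percent.
#' @export
dice <- function(a, r) {
  if (!identical(dim(a), dim(r))) stop("mask shapes differ", call. = FALSE)
  na <- sum(a != 0)
  nr <- sum(r != 0)
  if (na == 0 && nr == 0) {
    warning("both masks empty; Dice defined as 100")
    return(100)
  }
  if (na == 0 || nr == 0) return(0)
  100 * 2 * sum(a != 0 & r != 0) / (na + nr)
}

#' Modified Hausdorff distance
#'
#' `max(h(A,R), h(R,A))` where `h(A,R)` is the mean, over all labeled
#' voxels of A, of the Euclidean distance (in mm, respecting anisotropic
#' voxel sizes) to the nearest labeled voxel of R. All mask voxels
#' contribute, not only boundary voxels, so overlapping voxels contribute
#' zero distance. Lower is better; undefined for empty masks.
#'
#' @param a,r binary masks of the same shape, both nonempty.
#' @param voxel_size mm per voxel, scalar or length 3.
#' @return distance in mm.
#' @export
mhd <- function(a, r, voxel_size = 1) {
  if (!identical(dim(a), dim(r))) stop("mask shapes differ", call. = FALSE)
  if (!any(a != 0) || !any(r != 0))
    stop("MHD undefined for empty mask", call. = FALSE)
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  ca <- which(a != 0, arr.ind = TRUE)
  cr <- which(r != 0, arr.ind = TRUE)
  ca <- sweep(ca, 2, voxel_size, "*")
  cr <- sweep(cr, 2, voxel_size, "*")
  h_ar <- mean(cpp_min_nn_dists(ca, cr))
  h_ra <- mean(cpp_min_nn_dists(cr, ca))
  max(h_ar, h_ra)
}

#' Median (modal) filtering of a label map
#'
#' Replaces each voxel by the modal label over its 3x3x3 neighbourhood
#' (edge-truncated); any tie for the mode retains the original voxel
#' label. Used to smooth noisy manual label boundaries before reliability
#' analysis.
#'
#' @param labels a [label_map()] or 3D integer array.
#' @return same type as the input.
#' @export
median_filter_labels <- function(labels) {
  lm <- inherits(labels, "label_map")
  arr <- if (lm) labels$data else labels
  storage.mode(arr) <- "integer"
  out <- cpp_mode_filter3(arr)
  if (lm) { labels$data <- out; labels } else out
}

#' Per-structure segmentation evaluation
#'
#' Extracts each foreground class as a binary mask from the predicted and
#' reference label maps and computes Dice (percent) and MHD (mm) per
#' structure, plus pooled means and SDs. A structure empty in exactly one
#' of the two maps scores Dice 0 and its MHD is reported as NA.
#'
#' @param pred,ref [label_map()] objects of the same shape and class
#'   vocabulary.
#' @param voxel_size mm per voxel.
#' @param subject_id optional id recorded in the report.
#' @return object of class `metrics_report`: data.frame with one row per
#'   structure plus attributes `mean_dice`, `sd_dice`, `mean_mhd`, `sd_mhd`.
#' @export
evaluate_segmentation <- function(pred, ref, voxel_size = 1, subject_id = NA) {
  if (!identical(dim(pred$data), dim(ref$data)))
    stop("label map shapes differ", call. = FALSE)
  if (pred$n_classes != ref$n_classes)
    stop(sprintf("class sets differ: %d vs %d classes", pred$n_classes,
                 ref$n_classes), call. = FALSE)
  rows <- lapply(seq_len(ref$n_classes - 1L), function(c) {
    pa <- pred$data == c
    ra <- ref$data == c
    d <- dice(pa, ra)
    m <- if (any(pa) && any(ra)) mhd(pa, ra, voxel_size) else NA_real_
    data.frame(subject = subject_id, structure = c, dice_pct = d, mhd_mm = m)
  })
  rep <- do.call(rbind, rows)
  structure(rep, class = c("metrics_report", "data.frame"),
            mean_dice = mean(rep$dice_pct), sd_dice = sd(rep$dice_pct),
            mean_mhd = mean(rep$mhd_mm, na.rm = TRUE),
            sd_mhd = sd(rep$mhd_mm, na.rm = TRUE))
}

#' @export
print.metrics_report <- function(x, ...) {
  print.data.frame(x, row.names = FALSE)
  cat(sprintf("mean Dice %.1f%% (SD %.1f), mean MHD %.2f mm\n",
              attr(x, "mean_dice"), attr(x, "sd_dice"), attr(x, "mean_mhd")))
  invisible(x)
}
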