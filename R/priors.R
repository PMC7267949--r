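#' Class-specific working volume
#'
#' The working volume for a structure is the region where training subjects
#' disagree about its presence: the union of all subject masks minus their
#' intersection, conservatively dilated once with a full 3x3x3 structuring
#' element so it remains appropriate for unseen test subjects.
#'
#' @param masks list of binary 3D arrays (one per training subject), all of
#'   the same shape.
#' @return binary integer array `B^c`.
#' @export
class_working_volume <- function(masks) {
  if (length(masks) < 1L) stop("need at least one mask", call. = FALSE)
  d <- dim(masks[[1]])
  for (m in masks)
    if (!identical(dim(m), d)) stop("mask shapes differ", call. = FALSE)
  u <- Reduce(function(a, b) pmax(a, as.numeric(b != 0)), masks,
              array(0, dim = d))
  i <- Reduce(function(a, b) pmin(a, as.numeric(b != 0)), masks,
              array(1, dim = d))
  diff <- array(as.integer(u - i > 0), dim = d)
  cpp_dilate333(diff)
}

#' Positive volume
#'
#' Voxels that belong to the structure in every training subject and are not
#' claimed by the working volume: `P^c = I^c - (I^c intersect B^c)`. These
#' voxels are labelled `c` directly at test time, without evaluating the
#' network.
#'
#' @param masks list of binary 3D arrays for class `c` (same subjects used
#'   to build `working`).
#' @param working the class working volume `B^c` from
#'   [class_working_volume()].
#' @return binary integer array `P^c`.
#' @export
positive_volume <- function(masks, working) {
  d <- dim(masks[[1]])
  if (!identical(dim(working), d)) stop("mask shapes differ", call. = FALSE)
  i <- Reduce(function(a, b) pmin(a, as.numeric(b != 0)), masks,
              array(1, dim = d))
  array(as.integer(i > 0 & working == 0L), dim = d)
}

#' Global working volume
#'
#' Voxelwise union of all class-specific working volumes; the only region in
#' which training patches are sampled and the network is evaluated.
#'
#' @param working_volumes nonempty list of binary arrays `B^c`.
#' @return binary integer array `B`.
#' @export
global_working_volume <- function(working_volumes) {
  if (length(working_volumes) < 1L)
    stop("need at least one class working volume", call. = FALSE)
  d <- dim(working_volumes[[1]])
  for (m in working_volumes)
    if (!identical(dim(m), d)) stop("shapes differ", call. = FALSE)
  out <- Reduce(function(a, b) pmax(a, b), working_volumes)
  array(as.integer(out != 0), dim = d)
}

#' Coordinate images
#'
#' Three scalar volumes whose value at voxel (x, y, z) is that voxel's x, y
#' or z position. In `raw` mode the value is the 1-based voxel index; in
#' `normalized` mode (the default used for network input) each axis is
#' linearly rescaled to \[-1, 1\] across the grid, an invertible affine map
#' that keeps optimization well scaled. Coordinate channels are never
#' per-patch normalized.
#'
#' @param shape grid dims (length 3).
#' @param mode `"normalized"` or `"raw"`.
#' @return list of arrays `x`, `y`, `z`.
#' @export
coordinate_images <- function(shape, mode = c("normalized", "raw")) {
  mode <- match.arg(mode)
  shape <- as.integer(shape)
  axval <- function(n) {
    v <- seq_len(n)
    if (mode == "normalized") {
      if (n == 1L) 0 else 2 * (v - 1) / (n - 1) - 1
    } else as.numeric(v)
  }
  list(
    x = array(rep(axval(shape[1]), times = shape[2] * shape[3]), dim = shape),
    y = array(rep(rep(axval(shape[2]), each = shape[1]), times = shape[3]),
              dim = shape),
    z = array(rep(axval(shape[3]), each = shape[1] * shape[2]), dim = shape)
  )
}

#' Build the full spatial prior set from training label maps
#'
#' Computes, for every foreground class, the working volume `B^c` and
#' positive volume `P^c`, the global working volume `B`, and the three
#' coordinate images. Priors are computed from all non-test subjects
#' (training and validation alike), since validation patches are also drawn
#' within `B`.
#'
#' @param label_maps list of [label_map()] objects from the non-test
#'   subjects.
#' @param coordinate_mode passed to [coordinate_images()].
#' @param subject_ids optional provenance ids stored in the prior set.
#' @return object of class `prior_set` with elements `working` (list indexed
#'   by class), `positive`, `global_working`, `coords`, `n_classes`,
#'   `source_subject_ids`.
#' @export
build_priors <- function(label_maps, coordinate_mode = "normalized",
                         subject_ids = NULL) {
  if (length(label_maps) < 1L) stop("need label maps", call. = FALSE)
  C <- label_maps[[1]]$n_classes
  d <- dim(label_maps[[1]]$data)
  working <- list()
  positive <- list()
  for (c in seq_len(C - 1L)) {
    masks <- lapply(label_maps, function(lm) {
      if (!identical(dim(lm$data), d)) stop("label shapes differ", call. = FALSE)
      array(as.numeric(lm$data == c), dim = d)
    })
    working[[c]] <- class_working_volume(masks)
    positive[[c]] <- positive_volume(masks, working[[c]])
  }
  structure(list(
    working = working,
    positive = positive,
    global_working = global_working_volume(working),
    coords = coordinate_images(d, coordinate_mode),
    coordinate_mode = coordinate_mode,
    n_classes = C,
    shape = d,
    source_subject_ids = subject_ids
  ), class = "prior_set")
}

#' Serialize / load a prior set as NIfTI masks plus a manifest
#'
#' @param priors a `prior_set`.
#' @param dir output directory (created if needed).
#' @param voxel_size voxel size recorded in the NIfTI headers.
#' @return `write_priors` returns `dir` invisibly; `read_priors` the
#'   reconstructed `prior_set`.
#' @export
write_priors <- function(priors, dir, voxel_size = 1) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (c in seq_along(priors$working)) {
    write_volume(list(data = priors$working[[c]], voxel_size = voxel_size),
                 file.path(dir, sprintf("working_c%02d.nii.gz", c)))
    write_volume(list(data = priors$positive[[c]], voxel_size = voxel_size),
                 file.path(dir, sprintf("positive_c%02d.nii.gz", c)))
  }
  write_volume(list(data = priors$global_working, voxel_size = voxel_size),
               file.path(dir, "global_working.nii.gz"))
  manifest <- list(n_classes = priors$n_classes,
                   coordinate_mode = priors$coordinate_mode,
                   shape = priors$shape,
                   source_subject_ids = priors$source_subject_ids)
  writeLines(paste0(
    "n_classes: ", manifest$n_classes, "\n",
    "coordinate_mode: ", manifest$coordinate_mode, "\n",
    "shape: [", paste(manifest$shape, collapse = ", "), "]\n",
    "source_subject_ids: [",
    paste(manifest$source_subject_ids, collapse = ", "), "]"),
    file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' @rdname write_priors
#' @export
read_priors <- function(dir) {
  man <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  C <- man$n_classes
  working <- list()
  positive <- list()
  for (c in seq_len(C - 1L)) {
    working[[c]] <- array(as.integer(
      read_volume(file.path(dir, sprintf("working_c%02d.nii.gz", c)))$data != 0),
      dim = unlist(man$shape))
    positive[[c]] <- array(as.integer(
      read_volume(file.path(dir, sprintf("positive_c%02d.nii.gz", c)))$data != 0),
      dim = unlist(man$shape))
  }
  structure(list(
    working = working, positive = positive,
    global_working = global_working_volume(working),
    coords = coordinate_images(unlist(man$shape), man$coordinate_mode),
    coordinate_mode = man$coordinate_mode,
    n_classes = C, shape = unlist(man$shape),
    source_subject_ids = unlist(man$source_subject_ids)
  ), class = "prior_set")
}
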