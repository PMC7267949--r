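#' Common-space scalar volume
#'
#' A 3D scalar image assumed to be already linearly registered to a cohort
#' common space. Voxel indices are 1-based R array indices with axis order
#' (x, y, z); the voxel-to-world transform, when present, is carried through
#' untouched and never interpreted by the method.
#'
#' @param data 3D numeric array of finite values.
#' @param voxel_size voxel edge lengths in mm, length 1 (isotropic) or 3.
#' @param transform optional 4x4 voxel-to-world matrix, passed through.
#' @return an object of class `cs_volume`.
#' @export
cs_volume <- function(data, voxel_size = 1, transform = NULL) {
  if (length(dim(data)) != 3L) stop("expected 3D volume", call. = FALSE)
  nbad <- sum(!is.finite(data))
  if (nbad > 0L)
    stop(sprintf("volume contains %d non-finite voxels", nbad), call. = FALSE)
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stop("voxel_size must be 1 or 3 positive values", call. = FALSE)
  structure(list(data = data, voxel_size = as.numeric(voxel_size),
                 transform = transform),
            class = "cs_volume")
}

#' Multi-label segmentation volume
#'
#' Integer label volume with mutually exclusive structure labels; 0 is
#' background and classes form the contiguous range `0..n_classes-1`.
#'
#' @param data 3D integer-valued array.
#' @param n_classes total number of classes including background; defaults to
#'   `max(data) + 1`.
#' @return an object of class `label_map`.
#' @export
label_map <- function(data, n_classes = NULL) {
  if (length(dim(data)) != 3L) stop("expected 3D label volume", call. = FALSE)
  storage.mode(data) <- "integer"
  if (is.null(n_classes)) n_classes <- max(data) + 1L
  if (any(data < 0L) || any(data >= n_classes))
    stop("label values must lie in 0..n_classes-1", call. = FALSE)
  structure(list(data = data, n_classes = as.integer(n_classes)),
            class = "label_map")
}

#' Read and write NIfTI volumes
#'
#' Round trips preserve voxel data bit-exactly and voxel sizes to float
#' precision. Only 3D images are accepted.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return `read_volume` returns a [cs_volume()]; `read_label_map` a
#'   [label_map()].
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  a <- as.array(img)
  a <- array(as.vector(a), dim = dim(a))  # strip NIfTI attributes
  if (length(dim(a)) == 4L && dim(a)[4] == 1L) a <- a[, , , 1, drop = TRUE]
  if (length(dim(a)) != 3L) stop("expected 3D volume", call. = FALSE)
  vs <- RNifti::pixdim(img)[1:3]
  cs_volume(a, voxel_size = vs, transform = RNifti::xform(img))
}

#' @rdname read_volume
#' @param vol a [cs_volume()] or [label_map()].
#' @export
write_volume <- function(vol, path) {
  data <- vol$data
  vs <- if (!is.null(vol$voxel_size)) vol$voxel_size else c(1, 1, 1)
  if (length(vs) == 1L) vs <- rep(vs, 3L)
  img <- RNifti::asNifti(data, internal = FALSE)
  attr(img, "pixdim") <- vs
  RNifti::writeNifti(img, path,
                     datatype = if (is.integer(data)) "uint16" else "double")
  invisible(path)
}

#' @rdname read_volume
#' @param n_classes passed to [label_map()].
#' @export
read_label_map <- function(path, n_classes = NULL) {
  v <- read_volume(path)
  lm <- label_map(v$data, n_classes = n_classes)
  lm$voxel_size <- v$voxel_size
  lm
}

#' Extract a cubic patch around a voxel
#'
#' Returns the `side`^3 sub-grid centred on `center` (1-based voxel index).
#' Regions falling outside the volume are zero-filled, so patches may be
#' extracted arbitrarily close to the border; the centre itself must lie
#' inside the volume.
#'
#' @param x 3D array, or 4D array of stacked channels (x, y, z, channel).
#' @param center integer voxel coordinate of length 3.
#' @param side odd patch side in voxels.
#' @return array of dim `c(side, side, side)` or `c(side, side, side, nchan)`.
#' @export
extract_patch <- function(x, center, side) {
  if (side %% 2L != 1L) stop("patch side must be odd", call. = FALSE)
  d <- dim(x)
  nd <- length(d)
  if (!nd %in% c(3L, 4L)) stop("expected 3D array or 4D channel stack", call. = FALSE)
  sp <- d[1:3]
  center <- as.integer(center)
  if (any(center < 1L) || any(center > sp))
    stop("patch center outside volume bounds", call. = FALSE)
  h <- (side - 1L) %/% 2L
  lo <- center - h
  hi <- center + h
  src_lo <- pmax(lo, 1L)
  src_hi <- pmin(hi, sp)
  dst_lo <- src_lo - lo + 1L
  dst_hi <- dst_lo + (src_hi - src_lo)
  nchan <- if (nd == 4L) d[4] else 1L
  out <- array(0, dim = c(side, side, side, nchan))
  xs <- if (nd == 4L) x else array(x, dim = c(sp, 1L))
  out[dst_lo[1]:dst_hi[1], dst_lo[2]:dst_hi[2], dst_lo[3]:dst_hi[3], ] <-
    xs[src_lo[1]:src_hi[1], src_lo[2]:src_hi[2], src_lo[3]:src_hi[3], , drop = FALSE]
  if (nd == 3L) dim(out) <- c(side, side, side)
  attr(out, "center") <- center
  out
}

#' Normalize a patch channel to zero mean and unit SD
#'
#' Appearance patches are normalized individually before being fed to the
#' network. The SD is floored at 1e-8 so that constant patches (e.g., pure
#' background) map to all zeros instead of dividing by zero.
#'
#' @param x numeric array (one scalar channel).
#' @return array of the same shape with mean 0 and population SD 1 (or all
#'   zeros for constant input).
#' @export
normalize_appearance <- function(x) {
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  (x - m) / max(s, 1e-8)
}
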