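#' Phantom cohort configuration
#'
#' Synthetic cohorts emulate T1-weighted-like volumes already aligned to a
#' 1 mm isotropic common space: an ellipsoidal "head" containing mirrored
#' left/right superellipsoid structures whose intensity statistics are
#' identical, so that hemisphere can only be told apart by location. This is
#' precisely the situation in which a purely appearance-based patch
#' classifier confuses the two sides and spatial priors are expected to
#' help. Per-subject anatomical variability is created by warping each
#' subject with a smooth random deformation drawn from the same elastic
#' field sampler used for data augmentation.
#'
#' Intensities live on a 0-100 scale (background 0, head tissue 40,
#' structures 60, i.e., a contrast of 20 against surrounding tissue) with
#' additive Gaussian noise of SD 5 by default.
#'
#' @param grid_side cubic grid side in voxels (>= 32 so a 25^3 patch fits).
#' @param voxel_size isotropic voxel size in mm.
#' @param n_structures_per_side number of mirrored structure pairs.
#' @param structure_radius structure radius in mm.
#' @param mirror_axis axis (1, 2 or 3) across whose mid-plane structures are
#'   mirrored.
#' @param intersubject_sigma smoothness (mm) of the per-subject deformation.
#' @param intersubject_alpha mean displacement magnitude (mm) of the
#'   per-subject deformation; 0 gives identical, perfectly mirrored anatomy.
#' @param noise_sd additive Gaussian noise SD in intensity units.
#' @param tissue_means named intensities for background, head and structure.
#' @param seed master seed; fully determines a cohort.
#' @return object of class `phantom_config`.
#' @export
phantom_config <- function(grid_side = 64L, voxel_size = 1, n_structures_per_side = 1L,
                           structure_radius = 6, mirror_axis = 1L,
                           intersubject_sigma = 8, intersubject_alpha = 3,
                           noise_sd = 5,
                           tissue_means = c(background = 0, head = 40, structure = 60),
                           seed = 1L) {
  if (grid_side < 32L)
    stop("grid_side must be >= 32 so that a 25^3 patch fits", call. = FALSE)
  if (structure_radius <= 0) stop("structure_radius must be > 0", call. = FALSE)
  if (!mirror_axis %in% 1:3) stop("mirror_axis must be 1, 2 or 3", call. = FALSE)
  if (n_structures_per_side < 1L) stop("need >= 1 structure per side", call. = FALSE)
  structure(list(grid_side = as.integer(grid_side), voxel_size = voxel_size,
                 n_structures_per_side = as.integer(n_structures_per_side),
                 structure_radius = structure_radius,
                 mirror_axis = as.integer(mirror_axis),
                 intersubject_sigma = intersubject_sigma,
                 intersubject_alpha = intersubject_alpha,
                 noise_sd = noise_sd, tissue_means = tissue_means,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

# Ellipsoidal head mask and the noise-free tissue geometry of the template
# anatomy (before per-subject deformation). Returns soft (0/1) masks.
phantom_template <- function(config) {
  n <- config$grid_side
  ax <- seq_len(n)
  mid <- (n + 1) / 2
  half <- (n - 1) / 2
  gx <- array(rep(ax, times = n * n), dim = c(n, n, n))
  gy <- array(rep(rep(ax, each = n), times = n), dim = c(n, n, n))
  gz <- array(rep(ax, each = n * n), dim = c(n, n, n))
  semi <- c(0.90, 0.82, 0.82) * half
  head <- ((gx - mid) / semi[1])^2 + ((gy - mid) / semi[2])^2 +
    ((gz - mid) / semi[3])^2 <= 1
  r_vox <- config$structure_radius / config$voxel_size
  # superellipsoid semi-axes: slightly anisotropic so shape is not a sphere
  sa <- c(1, 0.8, 1.2) * r_vox
  p <- 2.5
  offsets <- 0.40 * half
  k <- config$n_structures_per_side
  # multiple pairs are spread along the axis after the mirror axis
  spread_axis <- (config$mirror_axis %% 3L) + 1L
  centers_left <- lapply(seq_len(k), function(i) {
    ctr <- c(mid, mid, mid)
    ctr[config$mirror_axis] <- mid - offsets
    if (k > 1L)
      ctr[spread_axis] <- mid + (i - (k + 1) / 2) * (2.2 * r_vox + 2)
    ctr
  })
  grids <- list(gx, gy, gz)
  super_mask <- function(ctr) {
    v <- abs((grids[[1]] - ctr[1]) / sa[1])^p +
      abs((grids[[2]] - ctr[2]) / sa[2])^p +
      abs((grids[[3]] - ctr[3]) / sa[3])^p
    v <= 1
  }
  masks <- list()
  for (i in seq_len(k)) {
    ctr_l <- centers_left[[i]]
    ctr_r <- ctr_l
    ctr_r[config$mirror_axis] <- 2 * mid - ctr_l[config$mirror_axis]
    masks[[2 * i - 1]] <- super_mask(ctr_l)
    masks[[2 * i]] <- super_mask(ctr_r)
  }
  list(head = head, structures = masks)
}

#' Generate one phantom subject
#'
#' The template anatomy is warped by a smooth random subject-specific
#' deformation (drawn from the elastic field sampler), the noise-free tissue
#' image is assembled from the warped soft masks, and Gaussian noise is
#' added. Labels are the warped, thresholded, noise-free structure masks
#' (class 1 = left of the mirror mid-plane, class 2 = right, and so on in
#' pairs). If a deformation pushes a structure outside the head or against
#' the grid border, a fresh sub-seed is tried (at most 10 times).
#'
#' @param config a [phantom_config()].
#' @param subject_index positive integer; together with `config$seed` it
#'   fully determines the subject.
#' @param session session number for scan-rescan simulation: sessions share
#'   the anatomy (and hence labels) and differ only in the noise draw.
#' @return list with `subject_id`, `image` ([cs_volume()]) and `labels`
#'   ([label_map()]).
#' @export
generate_subject <- function(config, subject_index, session = 1L) {
  tpl <- phantom_template(config)
  n <- config$grid_side
  k2 <- 2L * config$n_structures_per_side
  tm <- config$tissue_means
  for (attempt in 0:9) {
    anat_seed <- mix_seed(config$seed, subject_index, attempt)
    if (config$intersubject_alpha > 0) {
      dcfg <- deformation_config(config$intersubject_sigma,
                                 config$intersubject_alpha, seed = anat_seed)
      field <- sample_field(rep(n, 3L), dcfg, config$voxel_size)
      num3 <- function(m) array(as.numeric(m), dim = dim(m))
      head_w <- warp_scalar(num3(tpl$head), field)
      structs_w <- lapply(tpl$structures, function(m) warp_scalar(num3(m), field))
    } else {
      head_w <- array(as.numeric(tpl$head), dim = dim(tpl$head))
      structs_w <- lapply(tpl$structures, function(m)
        array(as.numeric(m), dim = dim(m)))
    }
    hard <- lapply(structs_w, function(s) s > 0.5)
    ok <- TRUE
    shell <- 2L
    for (s in hard) {
      if (!any(s)) { ok <- FALSE; break }
      idx <- which(s, arr.ind = TRUE)
      if (any(idx <= shell) || any(idx > n - shell)) { ok <- FALSE; break }
      if (any(head_w[s] <= 0.5)) { ok <- FALSE; break }
    }
    if (!ok) next
    labels <- array(0L, dim = rep(n, 3L))
    conf <- array(0, dim = rep(n, 3L))
    for (c in seq_len(k2)) {
      take <- hard[[c]] & structs_w[[c]] > conf
      labels[take] <- c
      conf[take] <- structs_w[[c]][take]
    }
    clean <- array(tm[["background"]], dim = rep(n, 3L)) +
      head_w * (tm[["head"]] - tm[["background"]])
    for (c in seq_len(k2))
      clean <- clean + structs_w[[c]] * (tm[["structure"]] - tm[["head"]])
    noise_seed <- mix_seed(config$seed, subject_index * 131L + session, 57L)
    img <- if (config$noise_sd > 0) {
      clean + with_seed(noise_seed,
                        array(rnorm(n^3, 0, config$noise_sd), dim = rep(n, 3L)))
    } else clean
    return(list(
      subject_id = sprintf("sub-%03d%s", subject_index,
                           if (session != 1L) sprintf("_ses-%d", session) else ""),
      image = cs_volume(img, voxel_size = config$voxel_size),
      labels = label_map(labels, n_classes = k2 + 1L),
      clean = clean))
  }
  stop("structure left the head mask after 10 deformation attempts", call. = FALSE)
}

#' Generate a phantom cohort
#'
#' @param config a [phantom_config()].
#' @param n_subjects number of subjects (>= 2; the priors need at least two
#'   subjects to have a meaningful disagreement region).
#' @param out_dir optional directory; when given, `<id>_T1w.nii.gz` and
#'   `<id>_labels.nii.gz` pairs are written there.
#' @param session see [generate_subject()].
#' @return list of subjects.
#' @export
generate_cohort <- function(config, n_subjects, out_dir = NULL, session = 1L) {
  if (n_subjects < 2L) stop("n_subjects must be >= 2", call. = FALSE)
  subjects <- lapply(seq_len(n_subjects), function(i)
    generate_subject(config, i, session = session))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (s in subjects) {
      write_volume(s$image, file.path(out_dir, paste0(s$subject_id, "_T1w.nii.gz")))
      lab <- s$labels
      lab$voxel_size <- s$image$voxel_size
      write_volume(lab, file.path(out_dir, paste0(s$subject_id, "_labels.nii.gz")))
    }
  }
  subjects
}
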