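#' Cross-validated segmentation experiment
#'
#' Deterministically assigns subjects to folds (fold sizes differ by at
#' most one), then for each fold builds priors from the non-test subjects,
#' trains the chosen variant, segments every test subject, and evaluates
#' against the reference labels. Every subject is segmented exactly once as
#' a test subject.
#'
#' @param subjects list of subjects.
#' @param n_folds number of folds.
#' @param variant model variant (see [variant_flags()]).
#' @param width filters per 3x3x3 layer.
#' @param config a [train_config()].
#' @param stride inference stride.
#' @param seed master seed for fold assignment and training.
#' @param verbose print progress.
#' @return list with `report` (pooled per-subject, per-structure
#'   data.frame) and `folds` (per-fold fitted models' summaries).
#' @export
run_crossvalidation <- function(subjects, n_folds = 5L, variant = "CNN-SP",
                                width = 32L, config = train_config(),
                                stride = 4L, seed = 1L, verbose = FALSE) {
  n <- length(subjects)
  fold_of <- with_seed(mix_seed(seed, 41L),
                       sample(rep(seq_len(n_folds), length.out = n)))
  reports <- list()
  folds <- list()
  for (f in seq_len(n_folds)) {
    test_idx <- which(fold_of == f)
    fit_idx <- which(fold_of != f)
    if (length(fit_idx) < 2L)
      stop(sprintf("fold %d has fewer than 2 non-test subjects", f), call. = FALSE)
    model <- priorseg_fit(subjects[fit_idx], variant = variant, width = width,
                          config = config, seed = mix_seed(seed, 42L + f),
                          verbose = verbose)
    for (i in test_idx) {
      seg <- predict(model, subjects[[i]], stride = stride)
      rep <- evaluate_segmentation(seg$labels, subjects[[i]]$labels,
                                   voxel_size = subjects[[i]]$image$voxel_size,
                                   subject_id = subjects[[i]]$subject_id)
      reports[[length(reports) + 1L]] <- as.data.frame(rep)
    }
    folds[[f]] <- list(fold = f, best_iteration = model$best_iteration,
                       test_subjects = vapply(subjects[test_idx],
                                              `[[`, character(1), "subject_id"))
  }
  report <- do.call(rbind, reports)
  list(report = report, folds = folds,
       mean_dice = mean(report$dice_pct),
       mean_mhd = mean(report$mhd_mm, na.rm = TRUE))
}

#' Spatial-prior ablation on a held-out test set
#'
#' Trains the requested variants on the same training subjects with shared
#' seeds (the variant switches are the only difference between arms),
#' segments the test subjects with and without postprocessing, and tallies
#' Dice, MHD and left/right hemisphere confusions per arm.
#'
#' @param train_subjects,test_subjects subject lists.
#' @param variants character vector of variant names.
#' @param width filters per 3x3x3 layer.
#' @param config a [train_config()].
#' @param stride inference stride.
#' @param mirror_axis axis of the phantom mirror mid-plane (for confusion
#'   counting).
#' @param seed shared master seed.
#' @param verbose print progress.
#' @return list with `table` (one row per variant x postprocessing setting)
#'   and `models`.
#' @export
run_ablation <- function(train_subjects, test_subjects,
                         variants = c("CNN-B", "CNN-WV", "CNN-SC", "CNN-SP"),
                         width = 32L, config = train_config(), stride = 4L,
                         mirror_axis = 1L, seed = 1L, verbose = FALSE) {
  rows <- list()
  models <- list()
  for (v in variants) {
    model <- priorseg_fit(train_subjects, variant = v, width = width,
                          config = config, seed = seed, verbose = verbose)
    models[[v]] <- model
    acc <- list(`TRUE` = list(d = c(), m = c(), cf = 0L),
                `FALSE` = list(d = c(), m = c(), cf = 0L))
    for (s in test_subjects) {
      raw <- predict(model, s, stride = stride, postprocess = FALSE)
      for (pp in c(TRUE, FALSE)) {
        lab <- if (pp) keep_largest_component(raw$labels) else raw$labels
        rep <- evaluate_segmentation(lab, s$labels,
                                     voxel_size = s$image$voxel_size,
                                     subject_id = s$subject_id)
        key <- as.character(pp)
        acc[[key]]$d <- c(acc[[key]]$d, rep$dice_pct)
        acc[[key]]$m <- c(acc[[key]]$m, rep$mhd_mm)
        acc[[key]]$cf <- acc[[key]]$cf + count_lr_confusions(lab, mirror_axis)
      }
    }
    for (pp in c(TRUE, FALSE)) {
      a <- acc[[as.character(pp)]]
      rows[[length(rows) + 1L]] <- data.frame(
        variant = v, postprocessed = pp, mean_dice = mean(a$d),
        sd_dice = sd(a$d), mean_mhd = mean(a$m, na.rm = TRUE),
        lr_confusion_components = a$cf)
    }
  }
  list(table = do.call(rbind, rows), models = models)
}

#' Count left/right hemisphere confusion components
#'
#' Structures come in mirrored pairs: odd classes (1, 3, ...) live in the
#' low-index half of the mirror axis, even classes in the high half. A
#' confusion is a connected component of a predicted class whose centroid
#' lies on the wrong side of the mirror mid-plane — the characteristic
#' error of an appearance-only patch classifier applied to laterally
#' symmetric anatomy.
#'
#' @param labels a [label_map()] or integer array.
#' @param mirror_axis axis of the mirror mid-plane.
#' @param connectivity component connectivity.
#' @return number of wrong-side components.
#' @export
count_lr_confusions <- function(labels, mirror_axis = 1L, connectivity = 26L) {
  arr <- if (inherits(labels, "label_map")) labels$data else labels
  mid <- (dim(arr)[mirror_axis] + 1) / 2
  n_conf <- 0L
  for (c in setdiff(sort(unique(as.vector(arr))), 0L)) {
    comp <- cpp_components(array(as.integer(arr == c), dim = dim(arr)),
                           as.integer(connectivity))
    if (max(comp) == 0L) next
    expected_low <- (c %% 2L) == 1L  # odd classes on the low-index side
    for (k in seq_len(max(comp))) {
      idx <- which(comp == k, arr.ind = TRUE)
      centroid <- mean(idx[, mirror_axis])
      if ((centroid < mid) != expected_low) n_conf <- n_conf + 1L
    }
  }
  n_conf
}

#' Scan-rescan reliability experiment
#'
#' Segments two imaging sessions of each test subject (same anatomy,
#' independent noise) with one trained model and measures the session-1 vs
#' session-2 label agreement per structure — the reliability of the
#' segmenter rather than its accuracy. For comparison, a "simulated
#' manual" reliability can be computed by independently deforming the true
#' labels of each session with small random elastic fields, mimicking
#' rater boundary variability.
#'
#' @param model a fitted `priorseg_model`.
#' @param session1,session2 paired subject lists (same order, same ids up
#'   to session suffix).
#' @param stride inference stride.
#' @return data.frame with per-subject, per-structure reliability Dice and
#'   MHD.
#' @export
run_reliability <- function(model, session1, session2, stride = 4L) {
  if (length(session1) != length(session2))
    stop("unpaired subjects", call. = FALSE)
  rows <- list()
  for (i in seq_along(session1)) {
    s1 <- session1[[i]]; s2 <- session2[[i]]
    if (sub("_ses-.*", "", s1$subject_id) != sub("_ses-.*", "", s2$subject_id))
      stop(sprintf("unpaired subjects at position %d", i), call. = FALSE)
    g1 <- predict(model, s1, stride = stride)
    g2 <- predict(model, s2, stride = stride)
    rep <- evaluate_segmentation(g1$labels, g2$labels,
                                 voxel_size = s1$image$voxel_size,
                                 subject_id = sub("_ses-.*", "", s1$subject_id))
    rows[[i]] <- as.data.frame(rep)
  }
  do.call(rbind, rows)
}

#' Simulated manual-rater reliability of reference labels
#'
#' Applies two independent small random elastic deformations to each
#' subject's true label map (nearest-class relabelling through soft one-hot
#' warping) and measures their mutual agreement, emulating the scan-rescan
#' reliability of human raters with noisy boundary placement.
#'
#' @param subjects subject list with `labels`.
#' @param sigma_e,alpha_i deformation parameters of the rater noise.
#' @param seed integer seed.
#' @return data.frame of per-subject, per-structure Dice/MHD.
#' @export
simulated_manual_reliability <- function(subjects, sigma_e = 4, alpha_i = 1,
                                         seed = 1L) {
  rows <- list()
  for (i in seq_along(subjects)) {
    s <- subjects[[i]]
    relabel <- function(session) {
      cfg <- deformation_config(sigma_e, alpha_i,
                                seed = mix_seed(seed, i, session))
      field <- sample_field(dim(s$labels$data), cfg,
                            s$image$voxel_size[1])
      soft <- warp_labels(s$labels, field)
      hard <- array(0L, dim = dim(s$labels$data))
      best <- soft[, , , 1]
      for (c in seq_len(dim(soft)[4] - 1L)) {
        take <- soft[, , , c + 1L] > best
        hard[take] <- c
        best[take] <- soft[, , , c + 1L][take]
      }
      label_map(hard, s$labels$n_classes)
    }
    rep <- evaluate_segmentation(relabel(1L), relabel(2L),
                                 voxel_size = s$image$voxel_size,
                                 subject_id = s$subject_id)
    rows[[i]] <- as.data.frame(rep)
  }
  do.call(rbind, rows)
}
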