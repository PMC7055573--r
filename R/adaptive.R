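# Adaptive weight learning: per-pixel multipliers derived from the initial
# detection. Correctly classified pixels keep weight 1; in sensitivity-
# focused mode every false-negative pixel gets the detection's sensitivity,
# in specificity-focused mode every false-positive pixel gets its
# specificity. The weighted cubes are then used to retrain the detector from
# scratch, focusing it on the pixels it got wrong.

#' Confusion counts and detection metrics for a predicted mask
#'
#' Pixel-exhaustive comparison of prediction against ground truth.
#' Sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)` and accuracy
#' `(tp+tn)/n` are reported; a metric whose denominator is zero is returned
#' as `NA` with a warning.
#'
#' @param pred,truth [label_mask()]s (or binary matrices) of one shape.
#' @return An object of class `detection_metrics`: `tp`, `fp`, `tn`, `fn`,
#'   `sensitivity`, `specificity`, `accuracy`.
#' @export
compute_metrics <- function(pred, truth) {
  p <- as_mask_matrix(pred)
  t_ <- as_mask_matrix(truth)
  if (!identical(dim(p), dim(t_))) {
    stop("invalid input: prediction and truth shapes differ", call. = FALSE)
  }
  tp <- sum(p == 1L & t_ == 1L)
  fp <- sum(p == 1L & t_ == 0L)
  tn <- sum(p == 0L & t_ == 0L)
  fn <- sum(p == 0L & t_ == 1L)
  ratio <- function(num, den, what) {
    if (den == 0) {
      warning(sprintf("%s undefined (empty denominator); reporting NA", what),
              call. = FALSE)
      return(NA_real_)
    }
    num / den
  }
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 sensitivity = ratio(tp, tp + fn, "sensitivity"),
                 specificity = ratio(tn, tn + fp, "specificity"),
                 accuracy = (tp + tn) / (tp + tn + fp + fn)),
            class = "detection_metrics")
}

#' @export
print.detection_metrics <- function(x, ...) {
  cat(sprintf("<detection_metrics> se=%.4f sp=%.4f acc=%.4f (tp=%d fp=%d tn=%d fn=%d)\n",
              x$sensitivity, x$specificity, x$accuracy, x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

#' Compute the adaptive per-pixel weight map
#'
#' In `se_weighted` mode, correctly classified pixels and false positives
#' get weight 1 while every false-negative pixel gets `se(mask)`, the
#' sensitivity of the initial detection. In `sp_weighted` mode, false
#' positives get `sp(mask)`, the specificity, and everything else gets 1.
#' The modes are mutually exclusive; which one a training set uses is chosen
#' by [select_mode()].
#'
#' @param pred The initial detection [label_mask()].
#' @param truth The ground-truth [label_mask()].
#' @param mode `"se_weighted"` or `"sp_weighted"`.
#' @return An object of class `weight_map`: `weights` (`H x W`, entries in
#'   `{1, factor}`), `mode`, `factor` (the global se or sp value).
#' @export
compute_adaptive_weights <- function(pred, truth,
                                     mode = c("se_weighted", "sp_weighted")) {
  mode <- match.arg(mode)
  p <- as_mask_matrix(pred)
  t_ <- as_mask_matrix(truth)
  if (!identical(dim(p), dim(t_))) {
    stop("invalid input: prediction and truth shapes differ", call. = FALSE)
  }
  m <- withCallingHandlers(compute_metrics(p, t_),
                           warning = function(w) invokeRestart("muffleWarning"))
  factor <- if (mode == "se_weighted") m$sensitivity else m$specificity
  if (is.na(factor)) {
    stop(sprintf(
      "degenerate truth: %s is undefined (truth lacks the %s class)",
      if (mode == "se_weighted") "sensitivity" else "specificity",
      if (mode == "se_weighted") "tumor" else "healthy"), call. = FALSE)
  }
  wgt <- matrix(1, nrow(p), ncol(p))
  if (mode == "se_weighted") {
    wgt[p == 0L & t_ == 1L] <- factor
  } else {
    wgt[p == 1L & t_ == 0L] <- factor
  }
  structure(list(weights = wgt, mode = mode, factor = factor),
            class = "weight_map")
}

#' @export
print.weight_map <- function(x, ...) {
  cat(sprintf("<weight_map> mode=%s factor=%.4f, %d down-weighted pixel(s)\n",
              x$mode, x$factor, sum(x$weights != 1)))
  invisible(x)
}

#' Apply a weight map to a hypercube
#'
#' Every band of pixel `(i, j)` is multiplied by `weights[i, j]`; pixels with
#' weight 1 are bit-identical to the input. Since weights never exceed 1,
#' reflectance stays in `[0, 1]`.
#'
#' @param cube A [hypercube()].
#' @param weights A `weight_map` (or plain `H x W` numeric matrix).
#' @return The updated [hypercube()].
#' @export
update_hypercube <- function(cube, weights) {
  stopifnot(inherits(cube, "hypercube"))
  w <- if (inherits(weights, "weight_map")) weights$weights else weights
  d <- dim(cube$data)
  if (!identical(dim(w), d[1:2])) {
    stop("invalid input: weight map shape does not match the cube",
         call. = FALSE)
  }
  # H*W weights recycle across the band axis (first two dims vary fastest)
  out <- cube$data * as.vector(w)
  hypercube(out, wavelengths = cube$wavelengths, id = cube$id)
}

#' Choose the re-weighting mode from training accuracies
#'
#' Given each training sample's accuracy under both adaptive modes, returns
#' the mode with the higher mean; ties go to `se_weighted` (with a message).
#'
#' @param training_results A list with numeric vectors `se_weighted` and
#'   `sp_weighted` of per-sample training accuracies.
#' @return `"se_weighted"` or `"sp_weighted"`.
#' @export
select_mode <- function(training_results) {
  se <- training_results$se_weighted
  sp <- training_results$sp_weighted
  if (length(se) == 0 || length(sp) == 0) {
    stop("invalid input: accuracies for both modes are required", call. = FALSE)
  }
  if (mean(se) == mean(sp)) {
    message("mode accuracies tie; choosing se_weighted")
    return("se_weighted")
  }
  if (mean(se) > mean(sp)) "se_weighted" else "sp_weighted"
}

# Build pooled training spectra from a set of cubes and masks, optionally
# subsampling pixels per cube (seeded) for desk-scale runs.
pooled_spectra <- function(cubes, masks, pixels_per_cube = Inf, seed = 1L) {
  xs <- vector("list", length(cubes))
  ys <- vector("list", length(cubes))
  for (i in seq_along(cubes)) {
    d <- dim(cubes[[i]]$data)
    n_px <- d[1] * d[2]
    pix <- if (is.finite(pixels_per_cube) && pixels_per_cube < n_px) {
      withr::with_seed(seed + i, sort(sample.int(n_px, pixels_per_cube)))
    } else seq_len(n_px)
    sm <- cube_to_spectra(cubes[[i]], mask = masks[[i]], pixels = pix)
    xs[[i]] <- sm$values
    ys[[i]] <- sm$labels
  }
  list(x = do.call(rbind, xs), y = unlist(ys))
}

#' Train the full detector (auto-encoder + classifier) on cubes
#'
#' Pools (optionally subsampled) labeled pixels from all training cubes,
#' trains the sparse auto-encoder on their spectra, then trains the
#' encoder+softmax classifier. This is the unit that both the initial fit
#' and every adaptive retraining invoke.
#'
#' @param cubes List of [hypercube()]s.
#' @param masks List of matching [label_mask()]s.
#' @param d Hidden size.
#' @param config A [run_config()] (supplies loss/optimizer settings,
#'   threshold and pixel subsampling).
#' @param seed Integer seed for sampling, initialization and batching.
#' @return A [pixel_classifier()].
#' @export
train_detector <- function(cubes, masks, d, config = run_config(), seed = 1L) {
  pool <- pooled_spectra(cubes, masks, config$pixels_per_cube, seed)
  lp <- config$loss_params
  ae <- train_autoencoder(pool$x, d, loss_params = lp,
                          opt_params = list(max_epochs = config$ae_epochs,
                                            learning_rate = config$learning_rate,
                                            batch_size = config$batch_size,
                                            seed = seed))
  train_classifier(pool$x, ae,
                   opt_params = list(max_epochs = config$head_epochs,
                                     finetune_epochs = config$finetune_epochs,
                                     learning_rate = config$head_learning_rate,
                                     batch_size = config$batch_size,
                                     seed = seed),
                   labels = pool$y, threshold = config$threshold)
}

#' One adaptive re-weighting round
#'
#' Predicts every training cube with the current classifier, computes the
#' per-cube weight map against ground truth under the given mode, rescales
#' the cubes, and retrains the auto-encoder and classifier from scratch on
#' the re-weighted cubes (fresh initialization, same seed policy). Held-out
#' cubes are never weighted: the weights require true labels.
#'
#' @param cubes,masks Training [hypercube()]s and [label_mask()]s.
#' @param clf The current (initial) [pixel_classifier()].
#' @param mode `"se_weighted"` or `"sp_weighted"`.
#' @param d Hidden size for the retrained model.
#' @param config A [run_config()].
#' @param seed Seed reused for the retraining (an already-perfect classifier
#'   therefore reproduces itself exactly).
#' @return A list with `classifier` (the adaptive [pixel_classifier()]),
#'   `weight_maps`, `updated_cubes`.
#' @export
adaptive_round <- function(cubes, masks, clf, mode, d,
                           config = run_config(), seed = 1L) {
  weight_maps <- vector("list", length(cubes))
  updated <- vector("list", length(cubes))
  for (i in seq_along(cubes)) {
    pred <- predict_cube(clf, cubes[[i]])
    weight_maps[[i]] <- compute_adaptive_weights(pred$mask, masks[[i]], mode)
    updated[[i]] <- update_hypercube(cubes[[i]], weight_maps[[i]])
  }
  list(classifier = train_detector(updated, masks, d, config, seed),
       weight_maps = weight_maps,
       updated_cubes = updated)
}

#' Export a weight map as a float TIFF for inspection
#'
#' @param wm A `weight_map`.
#' @param path Destination `.tif` path.
#' @return `path`, invisibly.
#' @export
write_weight_map <- function(wm, path) {
  tiff::writeTIFF(wm$weights, path, bits.per.sample = 32)
  invisible(path)
}
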