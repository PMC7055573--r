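#' Configuration for a detection run
#'
#' @param hidden_dim_grid Candidate hidden sizes for tuning (default the
#'   20--60 step-5 grid).
#' @param loss_params Auto-encoder loss hyperparameters (`l2_coeff`,
#'   `sparsity_target`, `sparsity_coeff`).
#' @param ae_epochs,head_epochs,finetune_epochs Epoch budgets for the
#'   auto-encoder, the softmax head, and the joint fine-tune.
#' @param learning_rate,batch_size Adam settings for the auto-encoder.
#' @param head_learning_rate Adam step size for the softmax head, larger by
#'   default because the sparsity penalty compresses the features the head
#'   sees to a small scale (fine-tuning runs at a tenth of it).
#' @param threshold Tumor-probability decision cutoff.
#' @param adaptive_rounds Number of re-weighting rounds (default 1; the
#'   single-pass protocol).
#' @param fg_connectivity,bg_connectivity Connectivities for mask refinement.
#' @param pixels_per_cube Cap on labeled pixels sampled per training cube
#'   (`Inf` = use all pixels).
#' @param seed Run-level seed; a fixed seed makes the whole run
#'   bit-reproducible.
#' @param output_dir Where [report()] writes its files (`NULL` = do not
#'   write).
#' @return An object of class `run_config`.
#' @export
run_config <- function(hidden_dim_grid = seq(20L, 60L, by = 5L),
                       loss_params = NULL,
                       ae_epochs = 200L, head_epochs = 200L,
                       finetune_epochs = 50L,
                       learning_rate = 1e-3, head_learning_rate = 3e-2,
                       batch_size = 256L,
                       threshold = 0.5, adaptive_rounds = 1L,
                       fg_connectivity = 8L, bg_connectivity = 4L,
                       pixels_per_cube = Inf, seed = 1L,
                       output_dir = NULL) {
  if (length(hidden_dim_grid) == 0 || any(hidden_dim_grid < 1)) {
    stop("invalid input: hidden_dim_grid must be nonempty with values >= 1",
         call. = FALSE)
  }
  structure(list(hidden_dim_grid = as.integer(hidden_dim_grid),
                 loss_params = merge_params(default_loss_params(), loss_params),
                 ae_epochs = as.integer(ae_epochs),
                 head_epochs = as.integer(head_epochs),
                 finetune_epochs = as.integer(finetune_epochs),
                 learning_rate = learning_rate,
                 head_learning_rate = head_learning_rate,
                 batch_size = as.integer(batch_size),
                 threshold = threshold,
                 adaptive_rounds = as.integer(adaptive_rounds),
                 fg_connectivity = as.integer(fg_connectivity),
                 bg_connectivity = as.integer(bg_connectivity),
                 pixels_per_cube = pixels_per_cube,
                 seed = as.integer(seed),
                 output_dir = output_dir),
            class = "run_config")
}

#' Desk-scale configuration for phantom cohort experiments
#'
#' The protocol used by the package's own cohort experiments on 64 x 64
#' phantoms with 64 bands: a two-point hidden-dimension grid, 800 training
#' pixels sampled per cube, and reduced epoch budgets, sized so a full
#' 12-fold leave-one-out run completes in minutes on one CPU while leaving
#' the method's behavior intact. For full-fidelity runs build a
#' [run_config()] directly.
#'
#' @param seed Run-level seed.
#' @param ... Further overrides passed to [run_config()].
#' @return A [run_config()].
#' @export
desk_config <- function(seed = 1L, ...) {
  run_config(hidden_dim_grid = c(20L, 35L), ae_epochs = 30L,
             head_epochs = 150L, finetune_epochs = 40L,
             learning_rate = 3e-3, pixels_per_cube = 800,
             seed = seed, ...)
}

cohort_cubes <- function(cohort) lapply(cohort, `[[`, "cube")
cohort_masks <- function(cohort) lapply(cohort, `[[`, "mask")

# Mean resubstitution accuracy of a classifier over a set of cubes.
mean_training_accuracy <- function(clf, cubes, masks) {
  accs <- vapply(seq_along(cubes), function(i) {
    pred <- predict_cube(clf, cubes[[i]])
    suppressWarnings(compute_metrics(pred$mask, masks[[i]])$accuracy)
  }, numeric(1))
  mean(accs)
}

#' Tune the hidden dimension on a training set
#'
#' For each candidate `d`, trains the full detector on the pooled training
#' pixels and scores the mean per-sample detection accuracy back on the same
#' training samples (the resubstitution protocol); returns the argmax, with
#' ties broken toward the smaller (cheaper) model. The fitted model for the
#' chosen `d` is kept so the caller need not retrain it.
#'
#' @param cubes,masks Training cubes and ground-truth masks.
#' @param grid Candidate hidden sizes; defaults to the config grid.
#' @param config A [run_config()].
#' @param seed Seed shared by all candidate fits.
#' @return A list of class `tuning_result`: `hidden_dim`, `model` (the
#'   fitted [pixel_classifier()] at `hidden_dim`), `accuracy` (named vector
#'   over the grid).
#' @export
tune_hidden_dim <- function(cubes, masks, grid = NULL,
                            config = run_config(), seed = 1L) {
  grid <- as.integer(grid %||% config$hidden_dim_grid)
  if (length(grid) == 0) {
    stop("invalid input: the tuning grid is empty", call. = FALSE)
  }
  grid <- sort(grid)
  best <- NULL
  accs <- stats::setNames(numeric(length(grid)), grid)
  for (gi in seq_along(grid)) {
    model <- train_detector(cubes, masks, grid[gi], config, seed)
    accs[gi] <- mean_training_accuracy(model, cubes, masks)
    if (is.null(best) || accs[gi] > best$accuracy) {
      best <- list(hidden_dim = grid[gi], model = model, accuracy = accs[gi])
    }
  }
  structure(list(hidden_dim = best$hidden_dim, model = best$model,
                 accuracy = accs),
            class = "tuning_result")
}

metrics_row <- function(m, prefix) {
  out <- list(m$sensitivity, m$specificity, m$accuracy)
  names(out) <- paste0(prefix, c("_sensitivity", "_specificity", "_accuracy"))
  out
}

#' Leave-one-out cross-validation of the adaptive detection pipeline
#'
#' Each sample is held out once. Per fold: the hidden dimension is tuned on
#' the training samples; the initial detector is trained; both adaptive
#' modes are run on the training set and the one with the higher mean
#' training accuracy is selected; the adaptive detector predicts the held-out
#' cube; the detection is refined morphologically. Initial, adaptive and
#' refined metrics on the held-out sample are all recorded. A failing fold is
#' recorded as an error and the run continues.
#'
#' @param cohort A `phantom_cohort` (or list of `list(cube, mask)` pairs).
#' @param config A [run_config()].
#' @return An object of class `loocv_result`: `folds` (one report per
#'   sample) and `config`. Use [summarize_loocv()] for the per-sample +
#'   average table and [report()] to write files.
#' @export
run_loocv <- function(cohort, config = run_config()) {
  if (length(cohort) < 2) {
    stop("invalid input: leave-one-out needs a cohort of >= 2 samples",
         call. = FALSE)
  }
  cubes <- cohort_cubes(cohort)
  masks <- cohort_masks(cohort)
  ids <- vapply(cubes, `[[`, character(1), "id")
  folds <- vector("list", length(cohort))
  for (i in seq_along(cohort)) {
    folds[[i]] <- tryCatch(
      run_fold(i, cubes, masks, ids, config),
      error = function(e) {
        warning(sprintf("fold %d ('%s') failed: %s", i, ids[i],
                        conditionMessage(e)), call. = FALSE)
        list(id = ids[i], error = conditionMessage(e))
      })
  }
  structure(list(folds = folds, config = config), class = "loocv_result")
}

run_fold <- function(i, cubes, masks, ids, config) {
  tr <- setdiff(seq_along(cubes), i)
  fold_seed <- config$seed + 1000L * i
  tun <- tune_hidden_dim(cubes[tr], masks[tr], config = config,
                         seed = fold_seed)
  initial <- tun$model

  mode_acc <- list()
  rounds <- list()
  for (mode in c("se_weighted", "sp_weighted")) {
    current <- initial
    for (r in seq_len(config$adaptive_rounds)) {
      rounds[[mode]] <- adaptive_round(cubes[tr], masks[tr], current, mode,
                                       tun$hidden_dim, config, fold_seed)
      current <- rounds[[mode]]$classifier
    }
    mode_acc[[mode]] <- vapply(seq_along(tr), function(j) {
      pred <- predict_cube(current, cubes[tr][[j]])
      suppressWarnings(compute_metrics(pred$mask, masks[tr][[j]])$accuracy)
    }, numeric(1))
  }
  mode <- select_mode(mode_acc)
  adaptive_clf <- rounds[[mode]]$classifier

  test_cube <- cubes[[i]]
  test_mask <- masks[[i]]
  init_pred <- predict_cube(initial, test_cube)
  adapt_pred <- predict_cube(adaptive_clf, test_cube)
  refined <- suppressWarnings(refine(adapt_pred$mask,
                                     fg_connectivity = config$fg_connectivity,
                                     bg_connectivity = config$bg_connectivity))
  list(id = ids[i],
       train_ids = ids[tr],
       hidden_dim = tun$hidden_dim,
       tuning_accuracy = tun$accuracy,
       mode = mode,
       mode_accuracy = vapply(mode_acc, mean, numeric(1)),
       initial = suppressWarnings(compute_metrics(init_pred$mask, test_mask)),
       adaptive = suppressWarnings(compute_metrics(adapt_pred$mask, test_mask)),
       refined = suppressWarnings(compute_metrics(refined$mask, test_mask)),
       n_components_refined = refined$n_components_before,
       prob_initial = init_pred$prob,
       prob_adaptive = adapt_pred$prob,
       mask_initial = init_pred$mask,
       mask_adaptive = adapt_pred$mask,
       mask_refined = refined$mask)
}

#' Summarize a LOOCV run as a per-sample table with an average row
#'
#' @param result A `loocv_result`.
#' @return A `data.frame` with one row per successful fold plus an
#'   `"average"` row (arithmetic mean of the per-fold metrics).
#' @export
summarize_loocv <- function(result) {
  ok <- Filter(function(f) is.null(f$error), result$folds)
  if (length(ok) == 0) stop("no successful folds to summarize", call. = FALSE)
  rows <- lapply(ok, function(f) {
    data.frame(id = f$id, hidden_dim = f$hidden_dim, mode = f$mode,
               c(metrics_row(f$initial, "initial"),
                 metrics_row(f$adaptive, "adaptive"),
                 metrics_row(f$refined, "refined")),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  num <- vapply(tab, is.numeric, logical(1)) & names(tab) != "hidden_dim"
  avg <- tab[1, ]
  avg$id <- "average"
  avg$hidden_dim <- NA_integer_
  avg$mode <- ""
  avg[num] <- lapply(tab[num], mean, na.rm = TRUE)
  rbind(tab, avg)
}

#' @export
print.loocv_result <- function(x, ...) {
  failed <- sum(vapply(x$folds, function(f) !is.null(f$error), logical(1)))
  cat(sprintf("<loocv_result> %d folds (%d failed)\n", length(x$folds), failed))
  print(summarize_loocv(x), digits = 4)
  invisible(x)
}

#' Write a LOOCV report to disk
#'
#' Emits `metrics.csv` (per-sample + average), per-fold probability maps
#' (32-bit float TIFF), initial/adaptive/refined masks (PNG), and a
#' `manifest.json` with the configuration and the chosen hidden dimension
#' and mode per fold. Re-running on the same result is byte-identical.
#'
#' @param result A `loocv_result`.
#' @param dir Output directory (default the config's `output_dir`).
#' @return `dir`, invisibly.
#' @export
report <- function(result, dir = result$config$output_dir) {
  if (is.null(dir)) stop("invalid input: no output directory", call. = FALSE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop(sprintf("cannot write to '%s'", dir), call. = FALSE)
  utils::write.csv(summarize_loocv(result), file.path(dir, "metrics.csv"),
                   row.names = FALSE)
  for (f in Filter(function(f) is.null(f$error), result$folds)) {
    tiff::writeTIFF(f$prob_initial,
                    file.path(dir, sprintf("%s-prob-initial.tif", f$id)),
                    bits.per.sample = 32)
    tiff::writeTIFF(f$prob_adaptive,
                    file.path(dir, sprintf("%s-prob-adaptive.tif", f$id)),
                    bits.per.sample = 32)
    write_mask(f$mask_initial, file.path(dir, sprintf("%s-mask-initial.png", f$id)))
    write_mask(f$mask_adaptive, file.path(dir, sprintf("%s-mask-adaptive.png", f$id)))
    write_mask(f$mask_refined, file.path(dir, sprintf("%s-mask-refined.png", f$id)))
  }
  manifest <- list(
    config = result$config[setdiff(names(result$config), "output_dir")],
    package_version = as.character(utils::packageVersion("adapthsi")),
    folds = lapply(result$folds, function(f) {
      if (!is.null(f$error)) return(list(id = f$id, error = f$error))
      list(id = f$id, hidden_dim = f$hidden_dim, mode = f$mode,
           train_ids = f$train_ids)
    }))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
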