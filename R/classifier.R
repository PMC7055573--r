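# Pixel classifier: the trained encoder with its decoder removed and a
# two-class softmax head stacked on the hidden features. Training is
# two-stage: the head is fit on frozen encoded features, then encoder and
# head are fine-tuned jointly at a reduced learning rate.

softmax_rows <- function(logits) {
  m <- apply(logits, 1L, max)
  e <- exp(logits - m)
  e / rowSums(e)
}

#' Construct a pixel classifier from an encoder and softmax head
#'
#' @param w1,b1 Encoder weights (`d x k`) and biases.
#' @param ws,bs Softmax head weights (`2 x d`) and biases (length 2; row/
#'   element 1 = healthy, 2 = tumor).
#' @param threshold Tumor-probability cutoff in `(0, 1)`; probability
#'   `>= threshold` is called tumor (ties go to tumor).
#' @param loss_params Auto-encoder loss hyperparameters carried along for
#'   retraining.
#' @return An object of class `pixel_classifier`.
#' @export
pixel_classifier <- function(w1, b1, ws, bs, threshold = 0.5,
                             loss_params = NULL) {
  if (threshold <= 0 || threshold >= 1) {
    stop("invalid input: threshold must lie in (0, 1)", call. = FALSE)
  }
  stopifnot(nrow(ws) == 2L, ncol(ws) == nrow(w1), length(bs) == 2L)
  structure(list(w1 = w1, b1 = b1, ws = ws, bs = bs,
                 k = ncol(w1), d = nrow(w1),
                 threshold = threshold, loss_params = loss_params),
            class = "pixel_classifier")
}

#' @export
print.pixel_classifier <- function(x, ...) {
  cat(sprintf("<pixel_classifier> %d bands -> %d features -> softmax(2), threshold %.2f\n",
              x$k, x$d, x$threshold))
  invisible(x)
}

# Cross-entropy loss and analytic gradients of the encoder+head stack.
clf_forward <- function(w1, b1, ws, bs, x) {
  h <- sigmoid(tcrossprod(x, w1) + rep(b1, each = nrow(x)))
  logits <- tcrossprod(h, ws) + rep(bs, each = nrow(x))
  list(h = h, p = softmax_rows(logits))
}

clf_loss <- function(w1, b1, ws, bs, x, y) {
  p <- clf_forward(w1, b1, ws, bs, x)$p
  ptrue <- ifelse(y == 1L, p[, 2L], p[, 1L])
  -mean(log(pmax(ptrue, 1e-12)))
}

clf_grad <- function(w1, b1, ws, bs, x, y, through_encoder = TRUE) {
  n <- nrow(x)
  fw <- clf_forward(w1, b1, ws, bs, x)
  onehot <- cbind(1 - y, y)
  d_logits <- (fw$p - onehot) / n
  g <- list(ws = crossprod(d_logits, fw$h), bs = colSums(d_logits))
  if (through_encoder) {
    d_h <- d_logits %*% ws
    d_a1 <- d_h * fw$h * (1 - fw$h)
    g$w1 <- crossprod(d_a1, x)
    g$b1 <- colSums(d_a1)
  }
  g
}

# Shared minibatch-Adam driver over the stack; `train_params` names the
# subset of {w1, b1, ws, bs} being updated. Keeps the best full-data CE.
clf_optimize <- function(params, x, y, train_names, epochs, lr, bs_size,
                         seed) {
  n <- nrow(x)
  bsz <- min(bs_size, n)
  state <- adam_init(params[train_names])
  best <- params
  best_ce <- clf_loss(params$w1, params$b1, params$ws, params$bs, x, y)
  withr::with_seed(seed, {
    for (epoch in seq_len(epochs)) {
      ord <- sample.int(n)
      for (s in seq(1L, n, by = bsz)) {
        rows <- ord[s:min(s + bsz - 1L, n)]
        g <- clf_grad(params$w1, params$b1, params$ws, params$bs,
                      x[rows, , drop = FALSE], y[rows],
                      through_encoder = "w1" %in% train_names)
        upd <- adam_step(params[train_names], g[train_names], state, lr)
        params[train_names] <- upd$params
        state <- upd$state
      }
      ce <- clf_loss(params$w1, params$b1, params$ws, params$bs, x, y)
      if (!is.finite(ce)) {
        stop(sprintf("training diverged: non-finite loss at epoch %d", epoch),
             call. = FALSE)
      }
      if (ce < best_ce) {
        best_ce <- ce
        best <- params
      }
    }
  })
  best
}

#' Train the encoder + softmax pixel classifier
#'
#' Stage 1 fits the two-class softmax head on the frozen encoded features;
#' stage 2 fine-tunes encoder and head jointly at a tenth of the learning
#' rate for `finetune_epochs`. Per-pixel class probabilities sum to 1.
#'
#' @param spectra A `spectra_matrix` with `labels` in `{0, 1}` (both classes
#'   must be present), or an `n x k` matrix with `labels` passed separately.
#' @param ae A trained `autoencoder_model` supplying the encoder.
#' @param opt_params Overrides of `max_epochs`, `learning_rate`,
#'   `batch_size`, `seed`, plus `finetune_epochs` (default 50).
#' @param labels Optional label vector when `spectra` is a plain matrix.
#' @param threshold Tumor-probability decision cutoff (default 0.5).
#' @return A [pixel_classifier()].
#' @export
train_classifier <- function(spectra, ae, opt_params = NULL, labels = NULL,
                             threshold = 0.5) {
  x <- spectra_values(spectra)
  y <- labels %||% spectra$labels
  if (is.null(y)) stop("invalid input: labels are required", call. = FALSE)
  y <- as.integer(y)
  if (length(unique(y)) < 2L) {
    stop("invalid input: both classes must be present in the labels",
         call. = FALSE)
  }
  op <- merge_params(c(default_opt_params(), list(finetune_epochs = 50L)),
                     opt_params)
  d <- ae$d
  withr::with_seed(op$seed, {
    ws <- matrix(stats::runif(2 * d, -1, 1) / sqrt(d), 2L, d)
  })
  params <- list(w1 = ae$w1, b1 = ae$b1, ws = ws, bs = numeric(2))
  params <- clf_optimize(params, x, y, c("ws", "bs"),
                         epochs = op$max_epochs, lr = op$learning_rate,
                         bs_size = op$batch_size, seed = op$seed)
  if (op$finetune_epochs > 0) {
    params <- clf_optimize(params, x, y, c("w1", "b1", "ws", "bs"),
                           epochs = op$finetune_epochs,
                           lr = op$learning_rate / 10,
                           bs_size = op$batch_size, seed = op$seed + 1L)
  }
  pixel_classifier(params$w1, params$b1, params$ws, params$bs,
                   threshold = threshold, loss_params = ae$loss_params)
}

#' Predict tumor probabilities for spectra
#'
#' @param clf A [pixel_classifier()].
#' @param spectra A `spectra_matrix` or `n x k` matrix.
#' @return Numeric vector of per-pixel tumor probabilities.
#' @export
predict_spectra <- function(clf, spectra) {
  x <- spectra_values(spectra)
  if (ncol(x) != clf$k) {
    stop(sprintf("invalid input: spectra have %d bands but the classifier expects %d",
                 ncol(x), clf$k), call. = FALSE)
  }
  clf_forward(clf$w1, clf$b1, clf$ws, clf$bs, x)$p[, 2L]
}

#' Predict a tumor probability map and mask for a whole cube
#'
#' Every pixel's spectrum is classified; the binary mask applies the
#' classifier's threshold (probability `>= threshold` is tumor).
#'
#' @param clf A [pixel_classifier()].
#' @param cube A [hypercube()] with the classifier's band count.
#' @return A list with `prob` (`H x W` matrix in `[0, 1]`) and `mask`
#'   (a [label_mask()]).
#' @export
predict_cube <- function(clf, cube) {
  stopifnot(inherits(cube, "hypercube"))
  d <- dim(cube$data)
  if (d[3] != clf$k) {
    stop(sprintf("invalid input: cube has %d bands but the classifier expects %d",
                 d[3], clf$k), call. = FALSE)
  }
  p <- predict_spectra(clf, matrix(cube$data, d[1] * d[2], d[3]))
  prob <- matrix(p, d[1], d[2])
  list(prob = prob,
       mask = label_mask((prob >= clf$threshold) * 1L, id = cube$id))
}

#' Serialize or restore a pixel classifier
#'
#' The model is stored as an RDS array bundle with a JSON sidecar
#' (`<path>.json`) of metadata (sizes, threshold, loss hyperparameters).
#'
#' @param clf A [pixel_classifier()].
#' @param path Destination `.rds` path.
#' @return [save_classifier()] returns `path` invisibly; [load_classifier()]
#'   returns the restored [pixel_classifier()].
#' @export
save_classifier <- function(clf, path) {
  saveRDS(unclass(clf), path)
  meta <- list(k = clf$k, d = clf$d, threshold = clf$threshold,
               loss_params = clf$loss_params)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  o <- readRDS(path)
  pixel_classifier(o$w1, o$b1, o$ws, o$bs, threshold = o$threshold,
                   loss_params = o$loss_params)
}
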