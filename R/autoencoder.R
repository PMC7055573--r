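# Sparse auto-encoder on per-pixel spectra.
#
# A single sigmoid hidden layer of d units encodes each k-band spectrum and a
# sigmoid output layer reconstructs it:
#   Y = f(w1 X + b1),  Z = f(w2 Y + b2),  f(p) = 1 / (1 + exp(-p)).
# The training loss is the mean squared reconstruction error plus an L2
# weight penalty and a KL-divergence sparsity penalty that pushes each hidden
# unit's mean activation toward a small target rate rho. All gradients are
# analytic (and finite-difference checked in the test suite); optimization is
# minibatch Adam.

#' Logistic sigmoid activation
#'
#' `f(p) = 1 / (1 + exp(-p))`, applied element-wise. Saturates cleanly at 0/1
#' for large `|p|` (no overflow up to the double range).
#'
#' @param p Numeric scalar or array.
#' @return Values in `(0, 1)` with the shape of `p`.
#' @examples
#' sigmoid(0)        # 0.5
#' sigmoid(log(3))   # 0.75
#' @export
sigmoid <- function(p) 1 / (1 + exp(-p))

default_loss_params <- function() {
  list(l2_coeff = 1e-3, sparsity_target = 0.05, sparsity_coeff = 1.0)
}

default_opt_params <- function() {
  list(max_epochs = 200L, learning_rate = 1e-3, batch_size = 256L, seed = 1L)
}

merge_params <- function(defaults, user) {
  if (is.null(user)) return(defaults)
  defaults[names(user)] <- user
  defaults
}

#' Construct a sparse auto-encoder model
#'
#' Weights are initialized from symmetric uniform distributions scaled by
#' fan-in (`1/sqrt(k)` for the encoder, `1/sqrt(d)` for the decoder); biases
#' start at zero. Seeded for reproducibility.
#'
#' @param k Input size (number of spectral bands).
#' @param d Hidden size, `1 <= d < k`.
#' @param loss_params List overriding `l2_coeff` (default `1e-3`),
#'   `sparsity_target` (rho, default 0.05) and `sparsity_coeff` (default 1).
#' @param seed Integer seed for the weight draw.
#' @return An object of class `autoencoder_model` with `w1` (`d x k`), `b1`,
#'   `w2` (`k x d`), `b2`, `k`, `d`, `loss_params`.
#' @export
new_autoencoder <- function(k, d, loss_params = NULL, seed = 1L) {
  if (d < 1 || d >= k) stop("invalid input: need 1 <= d < k", call. = FALSE)
  lp <- merge_params(default_loss_params(), loss_params)
  withr::with_seed(seed, {
    w1 <- matrix(stats::runif(d * k, -1, 1) / sqrt(k), d, k)
    w2 <- matrix(stats::runif(k * d, -1, 1) / sqrt(d), k, d)
  })
  structure(list(w1 = w1, b1 = numeric(d), w2 = w2, b2 = numeric(k),
                 k = as.integer(k), d = as.integer(d), loss_params = lp),
            class = "autoencoder_model")
}

#' @export
print.autoencoder_model <- function(x, ...) {
  cat(sprintf("<autoencoder_model> %d bands -> %d hidden units (rho=%.3g, l2=%.3g, beta=%.3g)\n",
              x$k, x$d, x$loss_params$sparsity_target, x$loss_params$l2_coeff,
              x$loss_params$sparsity_coeff))
  invisible(x)
}

#' Assemble a matrix of pixel spectra from a cube
#'
#' Flattens an `H x W x B` cube into an `n x B` matrix of spectra, keeping
#' the `(row, col)` index of every retained pixel so predictions can be
#' written back into image space. 0-based indices are not used; rows/cols are
#' 1-based as usual in R.
#'
#' @param cube A [hypercube()].
#' @param mask Optional [label_mask()] supplying per-pixel labels.
#' @param pixels Optional integer vector of linear (column-major) pixel
#'   indices to retain; default all pixels.
#' @return An object of class `spectra_matrix`: `values` (`n x B`),
#'   `pixel_index` (`n x 2` of rows/cols), `labels` (length `n` in `{0,1}`,
#'   or `NULL`).
#' @export
cube_to_spectra <- function(cube, mask = NULL, pixels = NULL) {
  stopifnot(inherits(cube, "hypercube"))
  d <- dim(cube$data)
  h <- d[1]; w <- d[2]; b <- d[3]
  flat <- matrix(cube$data, h * w, b)
  if (is.null(pixels)) pixels <- seq_len(h * w)
  pixels <- as.integer(pixels)
  if (anyDuplicated(pixels) || any(pixels < 1L) || any(pixels > h * w)) {
    stop("invalid input: pixel indices must be unique and within the cube",
         call. = FALSE)
  }
  labels <- NULL
  if (!is.null(mask)) {
    mm <- as_mask_matrix(mask)
    if (!identical(dim(mm), c(h, w))) {
      stop("invalid input: mask shape does not match the cube", call. = FALSE)
    }
    labels <- as.integer(mm)[pixels]
  }
  structure(list(values = flat[pixels, , drop = FALSE],
                 pixel_index = cbind(row = ((pixels - 1L) %% h) + 1L,
                                     col = ((pixels - 1L) %/% h) + 1L),
                 labels = labels),
            class = "spectra_matrix")
}

spectra_values <- function(spectra) {
  if (inherits(spectra, "spectra_matrix")) spectra$values else as.matrix(spectra)
}

#' Encode spectra into hidden-layer features
#'
#' Applies the encoder half: row `r` of the result is
#' `f(w1 x_r + b1)`, with all entries in `(0, 1)`.
#'
#' @param model An `autoencoder_model` (or anything carrying `w1`, `b1`).
#' @param spectra A `spectra_matrix` or `n x k` numeric matrix.
#' @return `n x d` feature matrix.
#' @export
encode <- function(model, spectra) {
  x <- spectra_values(spectra)
  if (ncol(x) != ncol(model$w1)) {
    stop(sprintf("invalid input: spectra have %d bands but the model expects %d",
                 ncol(x), ncol(model$w1)), call. = FALSE)
  }
  a1 <- tcrossprod(x, model$w1)
  sigmoid(a1 + rep(model$b1, each = nrow(a1)))
}

#' Decode hidden features back to reconstructed spectra
#'
#' @param model An `autoencoder_model`.
#' @param features `n x d` feature matrix (as produced by [encode()]).
#' @return `n x k` reconstruction with entries in `(0, 1)`.
#' @export
decode <- function(model, features) {
  features <- as.matrix(features)
  if (ncol(features) != model$d) {
    stop(sprintf("invalid input: features have %d columns but the model expects %d",
                 ncol(features), model$d), call. = FALSE)
  }
  a2 <- tcrossprod(features, model$w2)
  sigmoid(a2 + rep(model$b2, each = nrow(a2)))
}

AE_EPS <- 1e-7

# KL(rho || rho_hat) for Bernoulli rates, with rho_hat clamped away from 0/1.
kl_bernoulli <- function(rho, rho_hat) {
  rho_hat <- pmin(pmax(rho_hat, AE_EPS), 1 - AE_EPS)
  rho * log(rho / rho_hat) + (1 - rho) * log((1 - rho) / (1 - rho_hat))
}

#' Composite sparse auto-encoder loss
#'
#' `MSE(X, Z) + l2_coeff * (||w1||^2 + ||w2||^2) / 2 +
#'  sparsity_coeff * sum_j KL(rho || rho_hat_j)`, where `rho_hat_j` is hidden
#' unit `j`'s mean activation over the batch (clamped to
#' `[1e-7, 1 - 1e-7]` so the logs stay finite). MSE is the mean over all
#' `n * k` entries.
#'
#' @param model An `autoencoder_model`.
#' @param spectra A `spectra_matrix` or `n x k` matrix with values in
#'   `[0, 1]`.
#' @param parts If `TRUE`, return the three components alongside the total.
#' @return The scalar loss, or a list with `total`, `mse`, `l2`, `sparsity`.
#' @export
ae_loss <- function(model, spectra, parts = FALSE) {
  x <- spectra_values(spectra)
  h <- encode(model, x)
  z <- decode(model, h)
  lp <- model$loss_params
  mse <- mean((z - x)^2)
  l2 <- lp$l2_coeff * (sum(model$w1^2) + sum(model$w2^2)) / 2
  sparsity <- lp$sparsity_coeff *
    sum(kl_bernoulli(lp$sparsity_target, colMeans(h)))
  total <- mse + l2 + sparsity
  if (parts) list(total = total, mse = mse, l2 = l2, sparsity = sparsity)
  else total
}

# Analytic gradients of ae_loss w.r.t. w1, b1, w2, b2 on a batch.
ae_grad <- function(model, x) {
  n <- nrow(x); k <- ncol(x)
  lp <- model$loss_params
  a1 <- tcrossprod(x, model$w1)
  h <- sigmoid(a1 + rep(model$b1, each = n))
  a2 <- tcrossprod(h, model$w2)
  z <- sigmoid(a2 + rep(model$b2, each = n))

  d_a2 <- (2 / (n * k)) * (z - x) * z * (1 - z)
  g_w2 <- crossprod(d_a2, h) + lp$l2_coeff * model$w2
  g_b2 <- colSums(d_a2)

  d_h <- d_a2 %*% model$w2
  rho <- lp$sparsity_target
  rho_hat <- colMeans(h)
  active <- rho_hat > AE_EPS & rho_hat < 1 - AE_EPS
  rho_hat <- pmin(pmax(rho_hat, AE_EPS), 1 - AE_EPS)
  d_rho <- lp$sparsity_coeff * (-rho / rho_hat + (1 - rho) / (1 - rho_hat)) / n
  d_rho[!active] <- 0  # clamped units contribute no gradient
  d_h <- d_h + rep(d_rho, each = n)

  d_a1 <- d_h * h * (1 - h)
  list(w1 = crossprod(d_a1, x) + lp$l2_coeff * model$w1,
       b1 = colSums(d_a1),
       w2 = g_w2, b2 = g_b2)
}

# Minimal Adam state/update over a named list of parameter arrays.
adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(params)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

#' Train a sparse auto-encoder on pixel spectra
#'
#' Minimizes the composite loss ([ae_loss()]) by minibatch Adam. The
#' parameters with the lowest full-data loss seen at any epoch boundary are
#' returned, so the final loss never exceeds the initial one. Deterministic
#' under a fixed seed.
#'
#' @param spectra A `spectra_matrix` or `n x k` matrix with values in
#'   `[0, 1]`, `n >= d`.
#' @param d Hidden size.
#' @param loss_params,opt_params Overrides of the loss
#'   (`l2_coeff`, `sparsity_target`, `sparsity_coeff`) and optimizer
#'   (`max_epochs`, `learning_rate`, `batch_size`, `seed`) defaults.
#' @return An `autoencoder_model` carrying a `loss_history` attribute
#'   (full-data loss per epoch, element 1 = initial model).
#' @export
train_autoencoder <- function(spectra, d, loss_params = NULL,
                              opt_params = NULL) {
  x <- spectra_values(spectra)
  if (min(x) < 0 || max(x) > 1) {
    stop("invalid input: spectra must lie in [0, 1]", call. = FALSE)
  }
  op <- merge_params(default_opt_params(), opt_params)
  if (nrow(x) < d) stop("invalid input: need n >= d spectra", call. = FALSE)
  model <- new_autoencoder(ncol(x), d, loss_params, seed = op$seed)
  params <- model[c("w1", "b1", "w2", "b2")]
  state <- adam_init(params)
  history <- numeric(op$max_epochs + 1L)
  history[1L] <- ae_loss(model, x)
  best <- params
  best_loss <- history[1L]
  n <- nrow(x)
  bs <- min(op$batch_size, n)
  withr::with_seed(op$seed, {
    for (epoch in seq_len(op$max_epochs)) {
      ord <- sample.int(n)
      starts <- seq(1L, n, by = bs)
      for (s in starts) {
        batch <- x[ord[s:min(s + bs - 1L, n)], , drop = FALSE]
        model[c("w1", "b1", "w2", "b2")] <- params
        g <- ae_grad(model, batch)
        upd <- adam_step(params, g, state, op$learning_rate)
        params <- upd$params
        state <- upd$state
      }
      model[c("w1", "b1", "w2", "b2")] <- params
      cur <- ae_loss(model, x)
      if (!is.finite(cur)) {
        stop(sprintf("training diverged: non-finite loss at epoch %d", epoch),
             call. = FALSE)
      }
      history[epoch + 1L] <- cur
      if (cur < best_loss) {
        best_loss <- cur
        best <- params
      }
    }
  })
  model[c("w1", "b1", "w2", "b2")] <- best
  attr(model, "loss_history") <- history
  model
}
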