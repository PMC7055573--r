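test_that("sigmoid matches hand values, the reflection identity, and saturates", {
  expect_identical(sigmoid(0), 0.5)
  expect_equal(sigmoid(log(3)), 0.75)
  set.seed(1)
  p <- rnorm(50, sd = 10)
  expect_equal(sigmoid(p) + sigmoid(-p), rep(1, 50))
  expect_identical(sigmoid(700), 1)
  expect_lt(sigmoid(-700), 1e-300)
  expect_false(is.nan(sigmoid(-700)))
})

test_that("encode/decode honor their shape contracts and degeneracies", {
  m <- new_autoencoder(4, 2, seed = 1)
  x <- matrix(runif(12), 3, 4)

  m0 <- m
  m0$w1[] <- 0; m0$b1[] <- 0
  expect_identical(unname(encode(m0, x)), matrix(0.5, 3, 2))
  m0$w2[] <- 0; m0$b2[] <- 0
  expect_identical(unname(decode(m0, encode(m0, x))), matrix(0.5, 3, 4))

  # hand evaluation: d=1, k=2, w1=[1,1], b1=0, x=[0.2,0.3] -> f(0.5)
  m1 <- new_autoencoder(2, 1, seed = 1)
  m1$w1 <- matrix(c(1, 1), 1, 2); m1$b1 <- 0
  expect_equal(as.numeric(encode(m1, matrix(c(0.2, 0.3), 1))),
               1 / (1 + exp(-0.5)))

  h <- encode(m, x)
  expect_identical(dim(h), c(3L, 2L))
  expect_true(all(h > 0 & h < 1))
  z <- decode(m, h)
  expect_identical(dim(z), c(3L, 4L))
  expect_error(encode(m, matrix(0, 2, 3)), "bands")
  expect_error(decode(m, matrix(0, 2, 3)), "columns")
  expect_error(new_autoencoder(4, 4), "d < k")
})

test_that("the composite loss reduces to its terms in the degenerate cases", {
  m <- new_autoencoder(3, 2, seed = 1)
  x <- matrix(0.5, 6, 3)

  # KL(rho || rho) = 0
  expect_equal(adapthsi:::kl_bernoulli(0.05, 0.05), 0)

  # zero weights, X all 0.5: MSE and L2 vanish; only sparsity at rho_hat=0.5
  m0 <- m
  m0$w1[] <- 0; m0$b1[] <- 0; m0$w2[] <- 0; m0$b2[] <- 0
  parts <- ae_loss(m0, x, parts = TRUE)
  expect_equal(parts$mse, 0)
  expect_equal(parts$l2, 0)
  rho <- m$loss_params$sparsity_target
  kl_hand <- rho * log(rho / 0.5) + (1 - rho) * log((1 - rho) / 0.5)
  expect_equal(parts$sparsity, 2 * kl_hand)  # d = 2 hidden units

  # with both penalties off the loss is plain MSE
  mplain <- new_autoencoder(3, 2, seed = 1,
                            loss_params = list(l2_coeff = 0,
                                               sparsity_coeff = 0))
  xr <- matrix(runif(18), 6, 3)
  z <- decode(mplain, encode(mplain, xr))
  expect_equal(ae_loss(mplain, xr), mean((z - xr)^2))
  expect_gte(ae_loss(m, xr), 0)
})

test_that("analytic gradients match central finite differences (k=6, d=3)", {
  set.seed(7)
  m <- new_autoencoder(6, 3, seed = 2)
  x <- matrix(runif(60), 10, 6)
  g <- adapthsi:::ae_grad(m, x)
  for (nm in c("w1", "b1", "w2", "b2")) {
    gn <- numeric_grad(function(p) {
      m2 <- m
      m2[[nm]] <- p
      ae_loss(m2, x)
    }, m[[nm]])
    expect_lt(max(abs(gn - g[[nm]])) / max(abs(gn)), 1e-5)
  }
})

test_that("training descends, reconstructs constant spectra, and is seeded", {
  # constant dataset is exactly reconstructable
  xc <- matrix(0.3, 40, 5)
  m <- train_autoencoder(xc, 2,
                         loss_params = list(sparsity_coeff = 0.1),
                         opt_params = list(max_epochs = 300,
                                           learning_rate = 1e-2, seed = 3))
  expect_lt(ae_loss(m, xc, parts = TRUE)$mse, 1e-3)

  hist <- attr(m, "loss_history")
  expect_lte(hist[length(hist)], hist[1])
  expect_lt(hist[2], hist[1])  # strict descent over the first epoch

  # determinism under a fixed seed
  set.seed(9)
  xr <- matrix(runif(200), 40, 5)
  m1 <- train_autoencoder(xr, 2, opt_params = list(max_epochs = 5, seed = 4))
  m2 <- train_autoencoder(xr, 2, opt_params = list(max_epochs = 5, seed = 4))
  expect_identical(m1$w1, m2$w1)
  expect_identical(m1$b2, m2$b2)

  expect_error(train_autoencoder(matrix(2, 10, 4), 2), "\\[0, 1\\]")
  expect_error(train_autoencoder(matrix(0.5, 1, 4), 2), "n >= d")
})

test_that("training loss never increases on phantom spectra", {
  fx <- separable_fixture()
  hist <- attr(fx$ae, "loss_history")
  expect_lte(hist[length(hist)], hist[1])
})
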