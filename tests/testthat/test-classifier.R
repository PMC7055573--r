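test_that("class probabilities are a proper distribution per pixel", {
  fx <- separable_fixture()
  x <- fx$pool$x[1:200, ]
  fw <- adapthsi:::clf_forward(fx$clf$w1, fx$clf$b1, fx$clf$ws, fx$clf$bs, x)
  expect_equal(rowSums(fw$p), rep(1, 200), tolerance = 1e-6)
  expect_true(all(fw$p > 0))
})

test_that("softmax head gradients match finite differences", {
  set.seed(5)
  x <- matrix(runif(40), 10, 4)
  y <- rep(c(0L, 1L), 5)
  w1 <- matrix(rnorm(12, sd = 0.3), 3, 4); b1 <- rnorm(3, sd = 0.1)
  ws <- matrix(rnorm(6, sd = 0.3), 2, 3); bs <- rnorm(2, sd = 0.1)
  g <- adapthsi:::clf_grad(w1, b1, ws, bs, x, y, through_encoder = TRUE)
  for (nm in c("w1", "b1", "ws", "bs")) {
    ref <- list(w1 = w1, b1 = b1, ws = ws, bs = bs)
    gn <- numeric_grad(function(p) {
      a <- ref
      a[[nm]] <- p
      adapthsi:::clf_loss(a$w1, a$b1, a$ws, a$bs, x, y)
    }, ref[[nm]])
    expect_lt(max(abs(gn - g[[nm]])) / max(abs(gn)), 1e-5)
  }
})

test_that("well-separated phantoms are classified near-perfectly, held out", {
  fx <- separable_fixture()
  # training pixels
  expect_gte(mean((predict_spectra(fx$clf, fx$pool$x) >= 0.5) == fx$pool$y),
             0.99)
  # an unseen phantom from the same classes
  pred <- predict_cube(fx$clf, fx$test$cube)
  m <- compute_metrics(pred$mask, fx$test$mask)
  expect_gte(m$accuracy, 0.99)
})

test_that("zero-separation phantoms cannot be learned beyond chance", {
  ph0 <- generate_phantom(phantom_spec(separation = 0, tumor_fraction = 0.5,
                                       vessel_density = 0, margin_px = 0,
                                       seed = 31))
  pool <- adapthsi:::pooled_spectra(list(ph0$cube), list(ph0$mask), 1500, 1)
  ae <- train_autoencoder(pool$x, 8,
                          opt_params = list(max_epochs = 20,
                                            learning_rate = 3e-3, seed = 1))
  clf <- train_classifier(pool$x, ae,
                          opt_params = list(max_epochs = 80,
                                            finetune_epochs = 20,
                                            learning_rate = 3e-2, seed = 1),
                          labels = pool$y)
  acc <- mean((predict_spectra(clf, pool$x) >= 0.5) == pool$y)
  expect_lte(acc, 0.6)  # balanced classes: chance plus sampling error
})

test_that("encoded features separate the classes better than any raw band", {
  fx <- separable_fixture()
  y <- fx$pool$y
  best_band <- max(apply(fx$pool$x, 2, cohen_d, y = y))
  feats <- encode(fx$clf, fx$pool$x)
  best_feat <- max(apply(feats, 2, cohen_d, y = y))
  expect_gt(best_feat, best_band)
  expect_identical(ncol(feats), fx$clf$d)
})

test_that("prediction applies the >= threshold tie rule deterministically", {
  fx <- separable_fixture()
  pred <- predict_cube(fx$clf, fx$test$cube)
  expect_identical(pred$mask$mask,
                   matrix((pred$prob >= 0.5) * 1L, nrow(pred$prob)))
  expect_true(all(pred$prob >= 0 & pred$prob <= 1))
  # ties at exactly the threshold are called tumor
  clf2 <- fx$clf
  clf2$ws[] <- 0; clf2$bs[] <- 0  # every pixel gets probability exactly 0.5
  pred2 <- predict_cube(clf2, fx$test$cube)
  expect_true(all(pred2$mask$mask == 1L))
  expect_error(predict_cube(fx$clf, hypercube(array(0.5, c(2, 2, 3)), 1:3)),
               "bands")
})

test_that("single-class labels are rejected", {
  fx <- separable_fixture()
  expect_error(train_classifier(fx$pool$x[1:10, ], fx$ae,
                                labels = rep(1L, 10)),
               "both classes")
})

test_that("classifiers round-trip through serialization", {
  fx <- separable_fixture()
  td <- withr::local_tempdir()
  p <- file.path(td, "clf.rds")
  save_classifier(fx$clf, p)
  expect_true(file.exists(paste0(p, ".json")))
  back <- load_classifier(p)
  expect_identical(back$w1, fx$clf$w1)
  expect_identical(predict_spectra(back, fx$pool$x[1:20, ]),
                   predict_spectra(fx$clf, fx$pool$x[1:20, ]))
})
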