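# The 10-pixel toy used throughout: truth has 4 tumor / 6 healthy pixels;
# the prediction hits 3 of 4 tumor and 5 of 6 healthy.
toy_masks <- function() {
  truth <- matrix(c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0), 2, 5)
  pred <- truth
  pred[2, 2] <- 0  # one false negative
  pred[1, 3] <- 1  # one false positive
  list(pred = pred, truth = truth)
}

test_that("metrics match hand counts on the 10-pixel toy and edge cases", {
  t_ <- toy_masks()
  m <- compute_metrics(t_$pred, t_$truth)
  expect_identical(c(m$tp, m$fp, m$tn, m$fn), c(3L, 1L, 5L, 1L))
  expect_equal(m$sensitivity, 0.75)
  expect_equal(m$specificity, 5 / 6)
  expect_equal(m$accuracy, 0.8)

  perfect <- compute_metrics(t_$truth, t_$truth)
  expect_equal(c(perfect$sensitivity, perfect$specificity, perfect$accuracy),
               c(1, 1, 1))
  inverted <- compute_metrics(1L - t_$truth, t_$truth)
  expect_equal(c(inverted$sensitivity, inverted$specificity,
                 inverted$accuracy), c(0, 0, 0))

  expect_warning(compute_metrics(matrix(0L, 2, 2), matrix(0L, 2, 2)),
                 "sensitivity undefined")
  expect_error(compute_metrics(matrix(0L, 2, 2), matrix(0L, 3, 2)),
               "shapes differ")
})

test_that("metrics agree with the brute-force oracle on random 8x8 masks", {
  set.seed(11)
  for (rep in 1:300) {
    pred <- random_mask(8, 8)
    truth <- random_mask(8, 8)
    m <- suppressWarnings(compute_metrics(pred, truth))
    o <- oracle_metrics(pred, truth)
    expect_identical(c(m$tp, m$fp, m$tn, m$fn), c(o$tp, o$fp, o$tn, o$fn))
    expect_equal(m$sensitivity, o$se)
    expect_equal(m$specificity, o$sp)
    expect_equal(m$accuracy, o$acc)
  }
})

test_that("adaptive weights place the global factor exactly on the target pixels", {
  t_ <- toy_masks()
  w_se <- compute_adaptive_weights(t_$pred, t_$truth, "se_weighted")
  expect_equal(w_se$factor, 0.75)
  expect_equal(w_se$weights[2, 2], 0.75)  # the FN pixel
  expect_identical(sum(w_se$weights != 1), 1L)

  w_sp <- compute_adaptive_weights(t_$pred, t_$truth, "sp_weighted")
  expect_equal(w_sp$factor, 5 / 6)
  expect_equal(w_sp$weights[1, 3], 5 / 6)  # the FP pixel
  expect_identical(sum(w_sp$weights != 1), 1L)

  # perfect prediction: all-ones map in both modes
  for (mode in c("se_weighted", "sp_weighted")) {
    w <- compute_adaptive_weights(t_$truth, t_$truth, mode)
    expect_identical(w$weights, matrix(1, 2, 5))
  }

  expect_error(compute_adaptive_weights(matrix(0L, 2, 2), matrix(0L, 2, 2),
                                        "se_weighted"),
               "degenerate truth")
})

test_that("weight maps form a two-point set matching confusion counts", {
  set.seed(13)
  for (rep in 1:50) {
    pred <- random_mask(8, 8)
    truth <- random_mask(8, 8)
    o <- oracle_metrics(pred, truth)
    if (o$tp + o$fn == 0 || o$tn + o$fp == 0) next
    w_se <- compute_adaptive_weights(pred, truth, "se_weighted")
    expect_true(all(w_se$weights %in% c(1, w_se$factor)))
    expect_identical(sum(w_se$weights == w_se$factor & w_se$factor != 1),
                     if (w_se$factor != 1) o$fn else 0L)
    w_sp <- compute_adaptive_weights(pred, truth, "sp_weighted")
    expect_identical(sum(w_sp$weights == w_sp$factor & w_sp$factor != 1),
                     if (w_sp$factor != 1) o$fp else 0L)
  }
})

test_that("hypercube updates scale exactly the targeted pixels", {
  set.seed(17)
  cube <- hypercube(array(runif(2 * 5 * 2), c(2, 5, 2)), wavelengths = 1:2)
  t_ <- toy_masks()
  w_se <- compute_adaptive_weights(t_$pred, t_$truth, "se_weighted")
  up <- update_hypercube(cube, w_se)
  expect_identical(up$wavelengths, cube$wavelengths)
  # only the FN pixel changed, by exactly the factor
  changed <- which(up$data != cube$data, arr.ind = TRUE)
  expect_true(all(changed[, 1] == 2 & changed[, 2] == 2))
  expect_equal(up$data[2, 2, ], cube$data[2, 2, ] * 0.75)

  # identity, annihilation, and the hand-scaled spectrum
  ones <- matrix(1, 2, 5)
  expect_identical(update_hypercube(cube, ones)$data, cube$data)
  zw <- ones; zw[1, 1] <- 0
  expect_identical(update_hypercube(cube, zw)$data[1, 1, ], c(0, 0))
  spec2 <- hypercube(array(c(0.4, 0.8), c(1, 1, 2)), wavelengths = 1:2)
  expect_equal(update_hypercube(spec2, matrix(0.75))$data[1, 1, ],
               c(0.3, 0.6))
  expect_error(update_hypercube(cube, matrix(1, 3, 3)), "shape")
})

test_that("mode selection takes the argmax with the documented tie rule", {
  expect_identical(select_mode(list(se_weighted = c(0.95, 0.95),
                                    sp_weighted = c(0.90, 0.90))),
                   "se_weighted")
  expect_identical(select_mode(list(se_weighted = 0.90, sp_weighted = 0.95)),
                   "sp_weighted")
  expect_message(tie <- select_mode(list(se_weighted = 0.9,
                                         sp_weighted = 0.9)), "tie")
  expect_identical(tie, "se_weighted")
  expect_error(select_mode(list(se_weighted = numeric(0),
                                sp_weighted = 0.5)), "both modes")
})

test_that("an already-perfect classifier is a fixed point of the adaptive round", {
  fx <- separable_fixture()
  cubes <- list(fx$train$cube)
  masks <- list(fx$train$mask)
  pred <- predict_cube(fx$clf, cubes[[1]])
  expect_identical(pred$mask$mask, masks[[1]]$mask)  # perfect on this phantom

  cfg <- fast_config()
  ar <- adaptive_round(cubes, masks, fx$clf, "sp_weighted", 8, cfg, seed = 2)
  expect_identical(ar$updated_cubes[[1]]$data, cubes[[1]]$data)
  direct <- train_detector(cubes, masks, 8, cfg, seed = 2)
  expect_identical(ar$classifier$w1, direct$w1)
  expect_identical(ar$classifier$ws, direct$ws)
})

test_that("weight maps export as float TIFF", {
  t_ <- toy_masks()
  w <- compute_adaptive_weights(t_$pred, t_$truth, "se_weighted")
  td <- withr::local_tempdir()
  p <- file.path(td, "w.tif")
  write_weight_map(w, p)
  back <- tiff::readTIFF(p)
  expect_equal(back, w$weights, tolerance = 1e-7)
})
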