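# Shared desk-scale fixtures, built once per test file on first use.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# Fast optimizer settings for desk-scale model fits in tests.
fast_config <- function(...) {
  run_config(hidden_dim_grid = c(8L, 12L), ae_epochs = 30L,
             head_epochs = 150L, finetune_epochs = 40L,
             learning_rate = 3e-3, pixels_per_cube = 800, ...)
}

# A clean, strongly separable phantom (no confounders) plus a trained
# classifier: the fixture for the classifier sanity checks.
separable_fixture <- function() {
  fixture("separable", function() {
    spec <- phantom_spec(separation = 0.3, noise_sd = 0.02,
                         illumination_amplitude = 0, vessel_density = 0,
                         margin_px = 0, seed = 11L)
    train <- generate_phantom(spec, id = "train")
    spec$seed <- 12L
    spec$class_spectra <- train$spectra
    test <- generate_phantom(spec, id = "test")
    pool <- adapthsi:::pooled_spectra(list(train$cube), list(train$mask),
                                      2000, 1L)
    ae <- train_autoencoder(pool$x, 10,
                            opt_params = list(max_epochs = 40L,
                                              learning_rate = 3e-3,
                                              batch_size = 256L, seed = 1L))
    clf <- train_classifier(pool$x, ae,
                            opt_params = list(max_epochs = 150L,
                                              finetune_epochs = 40L,
                                              learning_rate = 3e-2,
                                              batch_size = 256L, seed = 1L),
                            labels = pool$y)
    list(train = train, test = test, pool = pool, ae = ae, clf = clf)
  })
}

random_mask <- function(h, w, p = 0.5) {
  matrix(as.integer(stats::runif(h * w) < p), h, w)
}

# A tiny cohort and config so whole-pipeline behavior can be exercised in
# seconds: 3 phantoms, 24x24 pixels, 12 bands, hidden size 5.
tiny_cohort <- function() {
  fixture("tiny_cohort", function() {
    generate_cohort(3, phantom_spec(height = 24, width = 24, n_bands = 12,
                                    separation = 0.25, noise_sd = 0.02,
                                    vessel_density = 1, margin_px = 1),
                    seed = 41)
  })
}

tiny_config <- function(...) {
  run_config(hidden_dim_grid = 5L, ae_epochs = 10L, head_epochs = 60L,
             finetune_epochs = 10L, learning_rate = 3e-3,
             pixels_per_cube = 300, seed = 17L, ...)
}

tiny_loocv <- function() {
  fixture("tiny_loocv", function() run_loocv(tiny_cohort(), tiny_config()))
}
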