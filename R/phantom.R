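#' Generate mean reflectance curves for the tumor and normal classes
#'
#' Builds two smooth curves in `[0, 1]` over the band axis: a shared baseline
#' (a seeded mixture of broad Gaussian bumps on a gentle slope) and a tumor
#' curve offset from it by `separation` times a smooth, nonnegative difference
#' shape. The mean absolute difference between the curves is monotone
#' nondecreasing in `separation`; at `separation = 0` the curves coincide.
#'
#' @param n_bands Number of spectral bands (>= 2).
#' @param separation Nonnegative scalar scaling the distance between the two
#'   class means (in reflectance units; 0.1--0.3 is a realistic contrast).
#' @param seed Integer seed; fixed seed gives bit-identical curves.
#' @return A list with numeric vectors `tumor` and `normal`, each length
#'   `n_bands`, values in `[0, 1]`.
#' @export
make_class_spectra <- function(n_bands, separation = 0.15, seed = 1L) {
  if (n_bands < 2L) stop("invalid input: n_bands must be >= 2", call. = FALSE)
  if (separation < 0) stop("invalid input: separation must be >= 0", call. = FALSE)
  withr::with_seed(seed, {
    x <- seq(0, 1, length.out = n_bands)
    centers <- stats::runif(3, 0.1, 0.9)
    widths <- stats::runif(3, 0.15, 0.35)
    amps <- stats::runif(3, 0.3, 1)
    base <- 0.2 * x
    for (g in 1:3) base <- base + amps[g] * exp(-((x - centers[g]) / widths[g])^2)
    base <- 0.25 + 0.4 * (base - min(base)) / (max(base) - min(base))
    dc <- stats::runif(1, 0.25, 0.75)
    dw <- stats::runif(1, 0.2, 0.4)
    delta <- exp(-((x - dc) / dw)^2)
    delta <- 0.3 + 0.7 * delta / max(delta)  # smooth, bounded away from zero
  })
  tumor <- pmin(pmax(base + separation * delta, 0), 1)
  list(tumor = tumor, normal = base)
}

#' Specify a synthetic hyperspectral phantom
#'
#' The phantom emulates the statistical structure the detection method
#' assumes: two spectral classes with distinct smooth mean curves, per-pixel
#' Gaussian noise, a smooth multiplicative uneven-illumination field shared
#' across bands, thin dark vessel-like confounder structures, and an optional
#' blurred class-mixing band around the tumor margin. Defaults describe the
#' confounder-rich condition used by the cohort experiments.
#'
#' @param height,width Spatial size in pixels.
#' @param n_bands Number of spectral bands (64 by default for desk-speed runs;
#'   set 251 for full-fidelity cubes).
#' @param tumor_shape `"ellipse"` or `"blob"` (an ellipse distorted by smooth
#'   noise).
#' @param tumor_fraction Target tumor area as a fraction of the image, in
#'   `(0, 1)`; realized area is within about 20% of the target.
#' @param class_spectra Optional list with `tumor` and `normal` mean curves
#'   (length `n_bands`, values in `[0, 1]`); generated from `seed` when `NULL`.
#' @param noise_sd Per-band Gaussian noise standard deviation (reflectance
#'   units).
#' @param illumination_amplitude Peak-to-peak amplitude of the smooth
#'   multiplicative illumination field (0 disables it).
#' @param vessel_density Expected number of dark curvilinear vessel
#'   confounders (Poisson count; 0 disables them).
#' @param separation Spectral contrast between the class means, used when
#'   `class_spectra` is `NULL`.
#' @param margin_px Half-width (pixels) of the class-mixing band at the tumor
#'   boundary emulating an indistinct margin; 0 keeps the margin crisp.
#' @param seed Integer seed; the phantom is bit-reproducible under a fixed
#'   seed.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(height = 64, width = 64, n_bands = 64,
                         tumor_shape = c("blob", "ellipse"),
                         tumor_fraction = 0.2, class_spectra = NULL,
                         noise_sd = 0.03, illumination_amplitude = 0.2,
                         vessel_density = 3, separation = 0.15,
                         margin_px = 2, seed = 1L) {
  tumor_shape <- match.arg(tumor_shape)
  if (tumor_fraction <= 0 || tumor_fraction >= 1) {
    stop("invalid input: tumor_fraction must lie in (0, 1)", call. = FALSE)
  }
  if (noise_sd < 0) stop("invalid input: noise_sd must be >= 0", call. = FALSE)
  if (vessel_density < 0) {
    stop("invalid input: vessel_density must be >= 0", call. = FALSE)
  }
  if (!is.null(class_spectra)) {
    stopifnot(length(class_spectra$tumor) == n_bands,
              length(class_spectra$normal) == n_bands)
    if (min(class_spectra$tumor, class_spectra$normal) < 0 ||
        max(class_spectra$tumor, class_spectra$normal) > 1) {
      stop("invalid input: class mean curves must lie in [0, 1]", call. = FALSE)
    }
  }
  structure(list(height = height, width = width, n_bands = n_bands,
                 tumor_shape = tumor_shape, tumor_fraction = tumor_fraction,
                 class_spectra = class_spectra, noise_sd = noise_sd,
                 illumination_amplitude = illumination_amplitude,
                 vessel_density = vessel_density, separation = separation,
                 margin_px = margin_px, seed = as.integer(seed)),
            class = "phantom_spec")
}

# Smooth low-order scalar field on an H x W grid: plane + one broad Gaussian
# bump, seeded by the caller's RNG state. Returned values are not normalized.
smooth_field <- function(h, w) {
  r <- matrix(seq_len(h) / h, h, w)
  c_ <- matrix(rep(seq_len(w) / w, each = h), h, w)
  ctr <- stats::runif(2, 0.25, 0.75)
  wd <- stats::runif(1, 0.3, 0.6)
  pl <- stats::runif(2, -1, 1)
  pl[1] * r + pl[2] * c_ + 1.5 * exp(-(((r - ctr[1])^2 + (c_ - ctr[2])^2) / wd^2))
}

# Tumor mask from the superlevel set of a smooth anisotropic bump; the
# quantile threshold pins the pixel count, then the largest 4-connected
# component (holes filled) keeps the region simply connected.
phantom_mask <- function(spec) {
  h <- spec$height; w <- spec$width
  n_target <- ceiling(spec$tumor_fraction * h * w)
  r <- matrix(seq_len(h) / h, h, w)
  c_ <- matrix(rep(seq_len(w) / w, each = h), h, w)
  ctr <- stats::runif(2, 0.35, 0.65)
  theta <- stats::runif(1, 0, pi)
  aspect <- stats::runif(1, 1, 2.5)
  u <- cos(theta) * (r - ctr[1]) + sin(theta) * (c_ - ctr[2])
  v <- -sin(theta) * (r - ctr[1]) + cos(theta) * (c_ - ctr[2])
  field <- -(u^2 * aspect + v^2 / aspect)
  if (spec$tumor_shape == "blob") {
    ripple <- cos(2 * pi * (stats::runif(1, 1, 2.5) * r +
                              stats::runif(1, -0.5, 0.5) * c_) +
                    stats::runif(1, 0, 2 * pi)) +
      sin(2 * pi * (stats::runif(1, 1, 2.5) * c_) + stats::runif(1, 0, 2 * pi))
    field <- field + 0.004 * ripple
  }
  thr <- stats::quantile(field, 1 - n_target / (h * w), names = FALSE)
  m <- (field > thr) * 1L
  m <- fill_holes(largest_component(label_mask(m))$mask)$mask
  m
}

# Random-walk polyline vessels dilated to width 1-3 px; returns a {0,1}
# matrix marking vessel pixels.
phantom_vessels <- function(h, w, density) {
  vm <- matrix(0L, h, w)
  n_v <- stats::rpois(1, density)
  if (n_v == 0) return(vm)
  for (v in seq_len(n_v)) {
    pos <- c(stats::runif(1, 1, h), stats::runif(1, 1, w))
    ang <- stats::runif(1, 0, 2 * pi)
    len <- round(0.75 * max(h, w))
    pts <- matrix(NA_real_, len, 2)
    for (s in seq_len(len)) {
      pts[s, ] <- pos
      ang <- ang + stats::rnorm(1, 0, 0.25)
      pos <- pos + c(cos(ang), sin(ang))
      pos <- pmin(pmax(pos, 1), c(h, w))
    }
    ij <- unique(round(pts))
    width <- sample(1:3, 1)
    rad <- (width - 1) %/% 2
    for (dr in -rad:rad) for (dc in -rad:rad) {
      rr <- pmin(pmax(ij[, 1] + dr, 1), h)
      cc <- pmin(pmax(ij[, 2] + dc, 1), w)
      vm[cbind(rr, cc)] <- 1L
    }
  }
  vm
}

# Signed-distance class-mixing weight near the mask boundary: 1 deep inside
# the tumor, 0 far outside, linear ramp within +/- margin_px of the boundary.
margin_blend_weight <- function(mask, margin_px) {
  wgt <- matrix(as.numeric(mask), nrow(mask))
  if (margin_px <= 0) return(wgt)
  din <- mask_distance_steps(mask, margin_px)          # steps inside
  dout <- mask_distance_steps(1L - mask, margin_px)    # steps outside
  sdist <- ifelse(mask == 1L, din, -dout)              # signed, in steps
  pmin(pmax(0.5 + sdist / (2 * margin_px + 1), 0), 1)
}

# Chebyshev distance-to-complement of foreground pixels, saturated at
# `cap + 1`, computed by successive 8-neighbor erosions.
mask_distance_steps <- function(mask, cap) {
  cur <- mask == 1L
  dist <- matrix(ifelse(cur, cap + 1, 0), nrow(mask))
  for (step in seq_len(cap)) {
    er <- erode8(cur)
    dist[cur & !er] <- step
    cur <- er
  }
  dist
}

erode8 <- function(b) {
  h <- nrow(b); w <- ncol(b)
  pad <- matrix(FALSE, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- b
  out <- pad[2:(h + 1), 2:(w + 1)]
  for (dr in -1:1) for (dc in -1:1) {
    out <- out & pad[(2 + dr):(h + 1 + dr), (2 + dc):(w + 1 + dc)]
  }
  out
}

#' Generate a synthetic hyperspectral phantom with a known tumor mask
#'
#' Each pixel's spectrum is a convex blend of the two class mean curves
#' (crisp away from the margin, mixed inside the `margin_px` band), scaled by
#' a smooth multiplicative illumination field shared across bands, darkened by
#' a factor 0.5 on vessel pixels, perturbed by i.i.d. Gaussian noise, and
#' clipped to `[0, 1]`. The ground-truth mask is a single 4-connected,
#' hole-free region covering approximately `tumor_fraction` of the image.
#'
#' @param spec A [phantom_spec()].
#' @param id Identifier for the emitted cube/mask pair.
#' @return A list with elements `cube` ([hypercube()]), `mask`
#'   ([label_mask()]), and `spectra` (the class mean curves used).
#' @export
generate_phantom <- function(spec, id = sprintf("phantom-%d", spec$seed)) {
  stopifnot(inherits(spec, "phantom_spec"))
  h <- spec$height; w <- spec$width; b <- spec$n_bands
  spectra <- spec$class_spectra %||%
    make_class_spectra(b, spec$separation, seed = spec$seed)
  withr::with_seed(spec$seed, {
    m <- phantom_mask(spec)
    if (abs(sum(m) - spec$tumor_fraction * h * w) >
        0.2 * spec$tumor_fraction * h * w) {
      stop("invalid input: tumor_fraction incompatible with the shape bounds",
           call. = FALSE)
    }
    blend <- margin_blend_weight(m, spec$margin_px)
    illum <- matrix(1, h, w)
    if (spec$illumination_amplitude > 0) {
      g <- smooth_field(h, w)
      illum <- 1 + spec$illumination_amplitude *
        ((g - min(g)) / (max(g) - min(g)) - 0.5)
    }
    vfac <- matrix(1, h, w)
    if (spec$vessel_density > 0) {
      vfac[phantom_vessels(h, w, spec$vessel_density) == 1L] <- 0.5
    }
    spatial <- illum * vfac
    data <- array(0, c(h, w, b))
    for (k in seq_len(b)) {
      data[, , k] <- (blend * spectra$tumor[k] +
                        (1 - blend) * spectra$normal[k]) * spatial
    }
    if (spec$noise_sd > 0) {
      data <- data + array(stats::rnorm(h * w * b, 0, spec$noise_sd), c(h, w, b))
    }
  })
  data <- pmin(pmax(data, 0), 1)
  list(cube = hypercube(data, wavelengths = default_wavelengths(b), id = id),
       mask = label_mask(m, id = id),
       spectra = spectra)
}

#' Generate a cohort of phantoms sharing one pair of class spectra
#'
#' The class mean curves are drawn once from the cohort seed (the two tissue
#' classes are the same across samples, as across animals in a study); tumor
#' position, shape, illumination, vessels and noise vary per sample through
#' derived per-sample seeds. Deterministic under a fixed seed.
#'
#' @param n_samples Number of phantoms (>= 2; leave-one-out needs at least 2).
#'   Default 12.
#' @param spec A [phantom_spec()] shared by all samples (its `seed` is
#'   overridden per sample).
#' @param seed Cohort-level integer seed.
#' @return A list of class `phantom_cohort`; each element has `cube`, `mask`,
#'   `spectra`.
#' @export
generate_cohort <- function(n_samples = 12, spec = phantom_spec(), seed = 1L) {
  if (n_samples < 2) {
    stop("invalid input: n_samples must be >= 2 (leave-one-out needs >= 2)",
         call. = FALSE)
  }
  spectra <- spec$class_spectra %||%
    make_class_spectra(spec$n_bands, spec$separation, seed = seed)
  cohort <- lapply(seq_len(n_samples), function(i) {
    s_i <- spec
    s_i$seed <- as.integer(seed + i)
    s_i$class_spectra <- spectra
    generate_phantom(s_i, id = sprintf("sample-%02d", i))
  })
  structure(cohort, class = "phantom_cohort", seed = seed)
}

#' Write a phantom cohort to disk with a manifest
#'
#' Emits each cube (native bundle) and mask (PNG) plus a tab-separated
#' manifest of `id`, `cube`, `mask` paths.
#'
#' @param cohort A `phantom_cohort` from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Path to the manifest file, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(cohort, function(s) {
    cube_path <- file.path(dir, paste0(s$cube$id, ".rds"))
    mask_path <- file.path(dir, paste0(s$cube$id, "-mask.png"))
    write_cube(s$cube, cube_path, format = "bundle")
    write_mask(s$mask, mask_path)
    data.frame(id = s$cube$id, cube = cube_path, mask = mask_path,
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  mp <- file.path(dir, "manifest.tsv")
  utils::write.table(manifest, mp, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(mp)
}

#' Read a phantom cohort back from a manifest
#'
#' @param manifest Path to a `manifest.tsv` written by [write_cohort()].
#' @return A list of class `phantom_cohort` with `cube` and `mask` per sample.
#' @export
read_cohort <- function(manifest) {
  tab <- utils::read.table(manifest, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  base <- dirname(manifest)
  resolve <- function(p) if (file.exists(p)) p else file.path(base, basename(p))
  cohort <- lapply(seq_len(nrow(tab)), function(i) {
    list(cube = read_cube(resolve(tab$cube[i]), format = "bundle"),
         mask = read_mask(resolve(tab$mask[i]), id = tab$id[i]))
  })
  structure(cohort, class = "phantom_cohort")
}
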