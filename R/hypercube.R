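#' Construct a hyperspectral reflectance cube
#'
#' A hypercube is an `H x W x B` array of per-pixel reflectance spectra with a
#' wavelength annotation along the spectral axis. Reflectance is dimensionless
#' and, after calibration with clipping, lies in `[0, 1]`.
#'
#' @param data Numeric `H x W x B` array; all values must be finite.
#' @param wavelengths Length-`B` numeric vector of band centers in nm,
#'   strictly increasing. If `NULL`, an evenly spaced grid over 450--950 nm is
#'   synthesized and a warning is emitted.
#' @param id Sample identifier string.
#' @return An object of class `hypercube` with elements `data`, `wavelengths`
#'   and `id`.
#' @examples
#' cube <- hypercube(array(runif(4 * 5 * 3), c(4, 5, 3)))
#' dim(cube)
#' @export
hypercube <- function(data, wavelengths = NULL, id = "cube") {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("invalid input: `data` must be a 3-d array (H x W x B)", call. = FALSE)
  }
  if (any(dim(data) < 1L)) {
    stop("invalid input: all hypercube dimensions must be >= 1", call. = FALSE)
  }
  if (!all(is.finite(data))) {
    stop("invalid input: hypercube values must all be finite", call. = FALSE)
  }
  b <- dim(data)[3L]
  if (is.null(wavelengths)) {
    warning("no wavelength metadata; synthesizing an even 450-950 nm grid",
            call. = FALSE)
    wavelengths <- default_wavelengths(b)
  }
  wavelengths <- as.numeric(wavelengths)
  if (length(wavelengths) != b) {
    stop("invalid input: length(wavelengths) must equal the band count",
         call. = FALSE)
  }
  if (b > 1L && any(diff(wavelengths) <= 0)) {
    stop("invalid input: wavelengths must be strictly increasing", call. = FALSE)
  }
  structure(list(data = data, wavelengths = wavelengths, id = as.character(id)),
            class = "hypercube")
}

default_wavelengths <- function(n_bands) {
  if (n_bands == 1L) return(450)
  seq(450, 950, length.out = n_bands)
}

#' @export
dim.hypercube <- function(x) dim(x$data)

#' @export
print.hypercube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<hypercube '%s'> %d x %d pixels, %d bands (%.0f-%.0f nm)\n",
              x$id, d[1], d[2], d[3], min(x$wavelengths), max(x$wavelengths)))
  cat(sprintf("  reflectance range [%.4g, %.4g]\n",
              min(x$data), max(x$data)))
  invisible(x)
}

#' Construct a binary tumor mask
#'
#' @param mask `H x W` matrix with values in `{0, 1}` (1 = tumor, 0 = healthy
#'   tissue). Logical matrices are coerced.
#' @param id Sample identifier string.
#' @return An object of class `label_mask`.
#' @export
label_mask <- function(mask, id = "mask") {
  if (is.logical(mask)) mask[] <- as.integer(mask)
  if (!is.matrix(mask)) {
    stop("invalid input: `mask` must be a matrix", call. = FALSE)
  }
  if (!all(mask %in% c(0, 1))) {
    stop("invalid input: mask values must be 0 or 1", call. = FALSE)
  }
  storage.mode(mask) <- "integer"
  structure(list(mask = mask, id = as.character(id)), class = "label_mask")
}

#' @export
dim.label_mask <- function(x) dim(x$mask)

#' @export
print.label_mask <- function(x, ...) {
  cat(sprintf("<label_mask '%s'> %d x %d, %d tumor pixels (%.1f%%)\n",
              x$id, nrow(x$mask), ncol(x$mask), sum(x$mask),
              100 * mean(x$mask)))
  invisible(x)
}

# Coerce a label_mask or plain binary matrix to an integer matrix.
as_mask_matrix <- function(x) {
  if (inherits(x, "label_mask")) return(x$mask)
  label_mask(x)$mask
}

#' Bundle raw/white/dark reference cubes for reflectance calibration
#'
#' @param raw `H x W x B` array of raw camera counts for the sample.
#' @param white Same-shape array acquired from a 100%-reflectance white
#'   reference board.
#' @param dark Same-shape array acquired with the camera shutter closed.
#' @param wavelengths Optional length-`B` wavelength vector passed through to
#'   the calibrated cube.
#' @return An object of class `calibration_refs`.
#' @export
calibration_refs <- function(raw, white, dark, wavelengths = NULL) {
  for (nm in c("raw", "white", "dark")) {
    a <- get(nm)
    if (!is.array(a) || length(dim(a)) != 3L) {
      stop(sprintf("invalid input: `%s` must be a 3-d array", nm), call. = FALSE)
    }
  }
  if (!identical(dim(raw), dim(white)) || !identical(dim(raw), dim(dark))) {
    stop("invalid input: raw, white and dark must share one shape", call. = FALSE)
  }
  structure(list(raw = raw, white = white, dark = dark,
                 wavelengths = wavelengths),
            class = "calibration_refs")
}

#' Calibrate raw counts to relative reflectance
#'
#' Removes the dark-current offset and normalizes by the white reference,
#' voxel-wise: `I = (raw - dark) / (white - dark)`. The white board defines
#' 100% reflectance and the shutter-closed dark frame defines 0%.
#'
#' @param refs A [calibration_refs()] object.
#' @param clip If `TRUE` (default) the reflectance is clamped to `[0, 1]`,
#'   which keeps downstream sigmoid-decoder reconstruction targets well-posed.
#' @param id Identifier for the calibrated cube.
#' @return A [hypercube()].
#' @examples
#' h <- array(500, c(2, 2, 2)); w <- array(1100, c(2, 2, 2))
#' d <- array(100, c(2, 2, 2))
#' cube <- suppressWarnings(calibrate(calibration_refs(h, w, d)))
#' cube$data[1, 1, 1]  # (500-100)/(1100-100) = 0.4
#' @export
calibrate <- function(refs, clip = TRUE, id = "calibrated") {
  stopifnot(inherits(refs, "calibration_refs"))
  denom <- refs$white - refs$dark
  bad <- which(denom == 0)
  if (length(bad) > 0) {
    ijk <- arrayInd(bad[1L], dim(denom))
    stop(sprintf(
      "degenerate reference: white - dark is zero at voxel (row %d, col %d, band %d)",
      ijk[1], ijk[2], ijk[3]), call. = FALSE)
  }
  refl <- (refs$raw - refs$dark) / denom
  if (clip) refl <- pmin(pmax(refl, 0), 1)
  hypercube(refl, wavelengths = refs$wavelengths, id = id)
}
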