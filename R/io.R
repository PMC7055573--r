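#' Read a hyperspectral cube from disk
#'
#' Supported dialects:
#' \describe{
#'   \item{`bundle`}{Native array bundle (an RDS file holding `data`,
#'     `wavelengths`, `id`); lossless round-trip.}
#'   \item{`envi`}{ENVI image + header pair (`<path>.hdr`); `samples`,
#'     `lines`, `bands` and `wavelength` fields are honored, BSQ interleave,
#'     32-bit float.}
#'   \item{`tiff`}{Multi-page TIFF stack, one page per band.}
#' }
#' When the on-disk format carries no wavelength metadata, an evenly spaced
#' 450--950 nm grid is synthesized with a warning.
#'
#' @param path File path (for `envi`, the binary data file; the header is
#'   `<path>.hdr`).
#' @param format One of `"bundle"`, `"envi"`, `"tiff"`; default guesses from
#'   the extension.
#' @return A [hypercube()].
#' @export
read_cube <- function(path, format = c("auto", "bundle", "envi", "tiff")) {
  format <- match.arg(format)
  if (format == "auto") format <- guess_cube_format(path)
  if (!file.exists(path)) {
    stop(sprintf("cannot read %s cube: file '%s' does not exist", format, path),
         call. = FALSE)
  }
  switch(format,
         bundle = read_cube_bundle(path),
         envi = read_cube_envi(path),
         tiff = read_cube_tiff(path))
}

#' Write a hyperspectral cube to disk
#'
#' @param cube A [hypercube()].
#' @param path Destination path.
#' @param format One of `"bundle"`, `"envi"`, `"tiff"` (see [read_cube()]);
#'   default guesses from the extension.
#' @param bits For `tiff`: sample depth, 16 (quantized, max abs error
#'   `1/65535`) or 32 (IEEE float). TIFF and ENVI require values in `[0, 1]`
#'   and `[0, 1e9]` respectively.
#' @return `path`, invisibly.
#' @export
write_cube <- function(cube, path, format = c("auto", "bundle", "envi", "tiff"),
                       bits = 16) {
  stopifnot(inherits(cube, "hypercube"))
  format <- match.arg(format)
  if (format == "auto") format <- guess_cube_format(path)
  if (!all(is.finite(cube$data))) {
    stop("invalid input: cube contains non-finite values", call. = FALSE)
  }
  switch(format,
         bundle = saveRDS(unclass(cube), path),
         envi = write_cube_envi(cube, path),
         tiff = write_cube_tiff(cube, path, bits))
  invisible(path)
}

guess_cube_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("rds", "bundle")) return("bundle")
  if (ext %in% c("tif", "tiff")) return("tiff")
  if (ext %in% c("envi", "img", "dat", "raw", "bsq")) return("envi")
  stop(sprintf("cannot guess cube format from extension '.%s'; pass `format`",
               ext), call. = FALSE)
}

read_cube_bundle <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e) {
    stop(sprintf("ill-formed bundle file '%s': %s", path, conditionMessage(e)),
         call. = FALSE)
  })
  if (!is.list(obj) || is.null(obj$data)) {
    stop(sprintf("ill-formed bundle file '%s': missing `data`", path),
         call. = FALSE)
  }
  hypercube(obj$data, wavelengths = obj$wavelengths,
            id = if (is.null(obj$id)) "cube" else obj$id)
}

# --- ENVI image + header pair (BSQ, float32, byte order 0) -------------------

envi_header_path <- function(path) paste0(path, ".hdr")

write_cube_envi <- function(cube, path) {
  d <- dim(cube$data)
  hdr <- c(
    "ENVI",
    sprintf("description = {%s}", cube$id),
    sprintf("samples = %d", d[2]),
    sprintf("lines = %d", d[1]),
    sprintf("bands = %d", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    "data type = 4",
    "interleave = bsq",
    "byte order = 0",
    sprintf("wavelength = {%s}",
            paste(format(cube$wavelengths, trim = TRUE), collapse = ", "))
  )
  writeLines(hdr, envi_header_path(path))
  con <- file(path, "wb")
  on.exit(close(con))
  # BSQ: samples fastest, then lines, then bands
  writeBin(as.numeric(aperm(cube$data, c(2, 1, 3))), con,
           size = 4, endian = "little")
  invisible(path)
}

envi_header_field <- function(lines, name) {
  # fields may span lines when brace-delimited; collapse first
  txt <- paste(lines, collapse = "\n")
  m <- regmatches(txt, regexec(
    sprintf("(?im)^\\s*%s\\s*=\\s*(\\{[^}]*\\}|[^\n]*)", name), txt,
    perl = TRUE))[[1]]
  if (length(m) < 2) return(NULL)
  val <- gsub("[{}]", "", m[2])
  trimws(val)
}

read_cube_envi <- function(path) {
  hp <- envi_header_path(path)
  if (!file.exists(hp)) {
    stop(sprintf("ill-formed envi cube: header '%s' not found", hp),
         call. = FALSE)
  }
  lines <- readLines(hp, warn = FALSE)
  if (length(lines) == 0 || !grepl("ENVI", lines[1], fixed = TRUE)) {
    stop(sprintf("ill-formed envi header '%s': missing ENVI magic", hp),
         call. = FALSE)
  }
  samples <- as.integer(envi_header_field(lines, "samples"))
  nlines <- as.integer(envi_header_field(lines, "lines"))
  bands <- as.integer(envi_header_field(lines, "bands"))
  dtype <- envi_header_field(lines, "data type")
  interleave <- tolower(envi_header_field(lines, "interleave") %||% "bsq")
  if (anyNA(c(samples, nlines, bands))) {
    stop(sprintf("ill-formed envi header '%s': samples/lines/bands missing", hp),
         call. = FALSE)
  }
  if (!is.null(dtype) && as.integer(dtype) != 4L) {
    stop(sprintf("ill-formed envi cube '%s': only data type 4 (float32) supported",
                 path), call. = FALSE)
  }
  if (interleave != "bsq") {
    stop(sprintf("ill-formed envi cube '%s': only bsq interleave supported",
                 path), call. = FALSE)
  }
  n <- samples * nlines * bands
  vals <- readBin(path, "numeric", n = n, size = 4, endian = "little")
  if (length(vals) != n) {
    stop(sprintf("ill-formed envi cube '%s': expected %d voxels, got %d",
                 path, n, length(vals)), call. = FALSE)
  }
  data <- aperm(array(vals, c(samples, nlines, bands)), c(2, 1, 3))
  wl_txt <- envi_header_field(lines, "wavelength")
  wl <- if (!is.null(wl_txt) && nzchar(wl_txt)) {
    as.numeric(strsplit(wl_txt, ",")[[1]])
  } else NULL
  if (!is.null(wl) && length(wl) != bands) {
    stop(sprintf("invalid input: header lists %d wavelengths for %d bands",
                 length(wl), bands), call. = FALSE)
  }
  id <- envi_header_field(lines, "description") %||% "cube"
  hypercube(data, wavelengths = wl, id = id)
}

# --- TIFF stack (one page per band) ------------------------------------------

write_cube_tiff <- function(cube, path, bits = 16) {
  if (!bits %in% c(16, 32)) {
    stop("invalid input: tiff `bits` must be 16 or 32", call. = FALSE)
  }
  if (min(cube$data) < 0 || max(cube$data) > 1) {
    stop("invalid input: tiff cubes require reflectance in [0, 1]",
         call. = FALSE)
  }
  b <- dim(cube$data)[3L]
  pages <- lapply(seq_len(b), function(i) cube$data[, , i, drop = TRUE])
  pages <- lapply(pages, function(m) matrix(m, dim(cube$data)[1]))
  tiff::writeTIFF(pages, path, bits.per.sample = bits)
  invisible(path)
}

read_cube_tiff <- function(path) {
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE), error = function(e) {
    stop(sprintf("ill-formed tiff cube '%s': %s", path, conditionMessage(e)),
         call. = FALSE)
  })
  if (!is.list(pages)) pages <- list(pages)
  if (any(vapply(pages, function(p) length(dim(p)) != 2L, logical(1)))) {
    stop(sprintf("invalid input: tiff cube '%s' has multi-channel pages", path),
         call. = FALSE)
  }
  data <- array(unlist(pages, use.names = FALSE),
                c(dim(pages[[1]]), length(pages)))
  hypercube(data, wavelengths = NULL,
            id = tools::file_path_sans_ext(basename(path)))
}

# --- Binary masks ------------------------------------------------------------

#' Read or write a binary tumor mask
#'
#' Masks round-trip losslessly as single-channel PNG or TIFF images. On read,
#' any nonzero pixel maps to 1; if values other than `{0, max}` appear, a
#' warning notes the binarization. Multi-channel or float-valued image files
#' are rejected.
#'
#' @param path File path (`.png`, `.tif`/`.tiff`).
#' @param id Identifier for the mask read.
#' @return [read_mask()] returns a [label_mask()]; [write_mask()] returns
#'   `path` invisibly.
#' @export
read_mask <- function(path, id = tools::file_path_sans_ext(basename(path))) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                png = png::readPNG(path),
                tif = ,
                tiff = tiff::readTIFF(path, info = TRUE),
                stop(sprintf("invalid input: unsupported mask format '.%s'", ext),
                     call. = FALSE))
  bps <- attr(img, "bits.per.sample") %||% 8
  if (bps >= 32) {
    # 32-bit TIFF samples are IEEE floats, not label images
    stop(sprintf("invalid input: mask '%s' holds float values", path),
         call. = FALSE)
  }
  if (length(dim(img)) == 3L) {
    if (dim(img)[3L] > 1L) {
      stop(sprintf("invalid input: mask '%s' is multi-channel", path),
           call. = FALSE)
    }
    img <- img[, , 1L, drop = TRUE]
  }
  # readers rescale integer samples to [0,1]; undo to recover raw counts
  img <- round(img * (2^bps - 1))
  vals <- sort(unique(as.vector(img)))
  if (!all(vals %in% c(0, max(vals)))) {
    warning(sprintf("mask '%s' holds values other than {0, max}; binarizing nonzero to 1",
                    path), call. = FALSE)
  }
  label_mask((img != 0) * 1L, id = id)
}

#' @param mask A [label_mask()] (or binary matrix) to write.
#' @rdname read_mask
#' @export
write_mask <- function(mask, path) {
  m <- as_mask_matrix(mask)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         png = png::writePNG(m * 1.0, path),
         tif = ,
         tiff = tiff::writeTIFF(m * 1.0, path, bits.per.sample = 8),
         stop(sprintf("invalid input: unsupported mask format '.%s'", ext),
              call. = FALSE))
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
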