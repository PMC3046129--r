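# Image, mask and model serialization.
#
# Images travel as 8-bit PNG or TIFF; masks as 8-bit grayscale PNG holding the
# raw label codes (0 = background, 1 = tumour, 2 = stroma,
# 3 = lymphoid/necrosis — see `tma_palette`), which round-trips losslessly.
# Stain-amount maps are written min-max scaled with the scaling recorded in a
# sidecar JSON. Class models and run configurations serialize to JSON.

#' Read an RGB (or grayscale) image
#'
#' PNG and TIFF, 8-bit per channel, are supported. 16-bit inputs are either
#' rejected (default) or rescaled to 0-255 per `bit16`.
#'
#' @param path File path (`.png`, `.tif`, `.tiff`).
#' @param bit16 `"reject"` (default) or `"rescale"`.
#' @return Numeric array `H x W x 3` (or `H x W` matrix for grayscale files)
#'   of intensities in 0-255.
#' @export
read_image <- function(path, bit16 = c("reject", "rescale")) {
  bit16 <- match.arg(bit16)
  raw <- read_raster(path)          # [0,1] doubles
  x255 <- raw * 255
  is8 <- max(abs(x255 - round(x255))) < 1e-6
  if (!is8) {
    if (bit16 == "reject")
      stop("'", basename(path), "' is not 8-bit; pass bit16 = \"rescale\" ",
           "to scale it to 0-255", call. = FALSE)
    x255 <- raw / max(raw) * 255
  }
  out <- round(x255)
  if (length(dim(out)) == 3L && dim(out)[3L] == 4L)
    out <- out[, , 1:3, drop = FALSE]   # drop alpha
  if (length(dim(out)) == 3L && dim(out)[3L] == 1L)
    out <- out[, , 1L]
  out
}

read_raster <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") png::readPNG(path)
  else if (ext %in% c("tif", "tiff")) tiff::readTIFF(path)
  else stop("unsupported image format '.", ext, "' (use PNG or TIFF)",
            call. = FALSE)
}

#' Write an RGB image as 8-bit PNG
#'
#' @param img Numeric `H x W x 3` array (or `H x W` matrix) in 0-255.
#' @param path Output path.
#' @export
write_image <- function(img, path) {
  png::writePNG(pmin(pmax(img, 0), 255) / 255, path)
  invisible(path)
}

#' Read / write label masks
#'
#' Masks are 8-bit grayscale PNGs storing label codes directly
#' (`write_mask(mask)(path)` then `read_mask(path)` returns identical
#' integers). `allowed` optionally validates the label set on read.
#'
#' @param mask Integer matrix of label codes in 0-255.
#' @param path File path.
#' @param allowed Optional integer vector; reading a mask containing any other
#'   value is an error that lists the values found.
#' @return `read_mask`: integer `H x W` matrix.
#' @export
write_mask <- function(mask, path) {
  stopifnot(is.matrix(mask), all(mask >= 0L & mask <= 255L))
  png::writePNG(mask / 255, path)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path, allowed = NULL) {
  x <- read_raster(path)
  if (length(dim(x)) == 3L) x <- x[, , 1L]
  m <- matrix(as.integer(round(x * 255)), nrow(x), ncol(x))
  if (!is.null(allowed) && !all(m %in% allowed)) {
    bad <- sort(setdiff(unique(as.vector(m)), allowed))
    stop("mask '", basename(path), "' contains unexpected label values: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  m
}

#' Convert between class labels and the on-disk palette
#'
#' In memory, classes are 1 = tumour .. 4 = background; on disk background is
#' stored as 0 (see `tma_palette`).
#'
#' @param labels Integer matrix in the 4-class coding 1..4.
#' @param codes Integer matrix of on-disk codes 0..3.
#' @export
labels_to_palette <- function(labels) {
  stopifnot(all(labels %in% 1:4))
  matrix(c(1L, 2L, 3L, 0L)[labels], nrow(labels), ncol(labels))
}

#' @rdname labels_to_palette
#' @export
palette_to_labels <- function(codes) {
  stopifnot(all(codes %in% 0:3))
  matrix(ifelse(codes == 0L, 4L, codes), nrow(codes), ncol(codes))
}

#' Write per-stain amount maps
#'
#' One 8-bit grayscale PNG per stain, min-max scaled to 0-255, plus a sidecar
#' `<stem>_scaling.json` recording the per-stain min and max so the true
#' amounts can be reconstructed.
#'
#' @param amounts `H x W x k` stain-amount array from [color_deconvolve()].
#' @param stem Output path stem; files are `<stem>_<stain>.png`.
#' @return Invisibly, the sidecar path.
#' @export
write_amounts <- function(amounts, stem) {
  stains <- dimnames(amounts)[[3L]] %||% paste0("stain", seq_len(dim(amounts)[3L]))
  scaling <- list()
  for (s in seq_along(stains)) {
    m <- amounts[, , s]
    mn <- min(m); mx <- max(m)
    scaled <- if (mx > mn) (m - mn) / (mx - mn) else m * 0
    nm <- gsub("[^A-Za-z0-9_-]+", "_", stains[s])
    png::writePNG(scaled, paste0(stem, "_", nm, ".png"))
    scaling[[stains[s]]] <- list(min = mn, max = mx)
  }
  side <- paste0(stem, "_scaling.json")
  jsonlite::write_json(scaling, side, auto_unbox = TRUE, digits = NA)
  invisible(side)
}

#' Serialize / read a class model as JSON
#'
#' @param model A [learn_class_params()] model.
#' @param path JSON file path.
#' @export
write_model <- function(model, path) {
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  stopifnot(all(c("classes", "mu", "sigma2") %in% names(x)))
  structure(x[c("classes", "mu", "sigma2", "n")], class = "class_model")
}
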