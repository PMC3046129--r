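# Stain separation: optical density conversion and color deconvolution.
#
# Transmitted light through a stained specimen follows the Lambert-Beer law,
# so per-channel optical density OD = -log10(I / I0) is linear in the amount
# of stain. Each stain is a unit-length vector in OD-RGB space; stacking one
# row per stain gives the stain matrix M, and multiplying OD pixels by
# D = M^-1 recovers per-stain amounts (color deconvolution).

#' Convert an RGB image to per-channel optical density
#'
#' `OD_C = -log10(I_C / I0_C)` per channel, with detected intensities floored
#' at 1 intensity level so a fully opaque pixel (value 0) maps to the finite
#' density `log10(I0)` instead of infinity.
#'
#' @param img Numeric `H x W x 3` array (or `H x W` matrix for a single
#'   channel) of intensities in `[0, i0]`.
#' @param i0 Incident ("white") intensity, a positive scalar or length-3
#'   vector per channel. Default 255 (8-bit white).
#' @return Array of the same shape holding unitless optical densities
#'   (0 where the pixel equals `i0`).
#' @examples
#' rgb_to_od(array(255, c(1, 1, 3)))           # full transmission -> 0
#' rgb_to_od(array(25.5, c(1, 1, 3)))[1, 1, 1] # one tenth -> OD 1
#' @export
rgb_to_od <- function(img, i0 = 255) {
  if (any(!is.finite(i0)) || any(i0 <= 0))
    stop("incident intensity `i0` must be positive", call. = FALSE)
  img <- as_image_array(img)
  i0 <- expand_i0(i0, img)
  if (any(img > i0)) {
    warning("pixel values above i0 were clamped to i0")
    img <- pmin(img, i0)
  }
  if (any(img < 0)) stop("negative pixel intensities", call. = FALSE)
  od <- -log10(pmax(img, 1) / i0)
  od[img >= i0] <- 0 # guard: pmax floor must not create od < 0 at white
  od
}

#' Compose an RGB image from stain amounts (forward Lambert-Beer)
#'
#' The synthesis inverse of [color_deconvolve()]:
#' `pixel_C = round(i0 * 10^(-sum_j amounts_j * M[j, C]))`, clipped to
#' `[0, i0]`. Used to build synthetic stained images and to test the
#' deconvolution roundtrip.
#'
#' @param amounts Numeric `H x W x k` array of per-stain amounts (>= 0), `k`
#'   matching `nrow(M)`. A `H x W` matrix is treated as one stain.
#' @param M Stain matrix from [normalize_stain_matrix()] (rows are unit OD
#'   vectors).
#' @param i0 Incident intensity, scalar or per-channel length 3.
#' @return Numeric `H x W x 3` array of integer-valued intensities.
#' @export
compose_rgb <- function(amounts, M, i0 = 255) {
  if (is.matrix(amounts)) dim(amounts) <- c(dim(amounts), 1L)
  stopifnot(length(dim(amounts)) == 3L)
  if (any(amounts < 0)) stop("stain amounts must be non-negative", call. = FALSE)
  k <- dim(amounts)[3L]
  if (k != nrow(M))
    stop("amounts has ", k, " channels but the stain matrix has ", nrow(M),
         " rows", call. = FALSE)
  h <- dim(amounts)[1L]; w <- dim(amounts)[2L]
  od <- matrix(amounts, ncol = k) %*% unclass(M) # N x 3 OD
  img <- array(0, c(h, w, 3L))
  i0 <- rep_len(as.numeric(i0), 3L)
  for (ch in 1:3)
    img[, , ch] <- matrix(round(i0[ch] * 10^(-od[, ch])), h, w)
  array(pmin(pmax(img, 0), rep(i0, each = h * w)), c(h, w, 3L))
}

#' Normalize a stain matrix
#'
#' Divides each stain's OD vector by its Euclidean length. For a two-stain
#' system a third "residual" row — the unit cross product of the two stain
#' vectors — is synthesized so that the 3x3 system is invertible; the residual
#' channel captures whatever the two stains cannot explain.
#'
#' @param raw Numeric `k x 3` matrix, `k` 2 or 3; one un-normalized OD vector
#'   per stain (rows), columns are the R, G, B channels.
#' @param stain_names Optional character vector of `k` stain names (defaults
#'   to rownames or `stain1..k`).
#' @return A `stain_matrix`: 3x3 numeric matrix with unit rows, attributes
#'   `stains` (the real stain names) and `residual` (`TRUE` if a residual row
#'   was padded; it is then named `"residual"`).
#' @examples
#' normalize_stain_matrix(rbind(c(3, 4, 0), c(0, 0, 1)))
#' @export
normalize_stain_matrix <- function(raw, stain_names = NULL) {
  raw <- as.matrix(raw)
  if (ncol(raw) != 3L || !nrow(raw) %in% 2:3)
    stop("stain matrix must be 2x3 or 3x3", call. = FALSE)
  if (is.null(stain_names))
    stain_names <- rownames(raw) %||% paste0("stain", seq_len(nrow(raw)))
  nrm <- sqrt(rowSums(raw^2))
  if (any(nrm == 0)) stop("stain matrix has an all-zero row", call. = FALSE)
  M <- raw / nrm
  padded <- nrow(M) == 2L
  if (padded) {
    res <- cross3(M[1L, ], M[2L, ])
    rn <- sqrt(sum(res^2))
    if (rn < 1e-8)
      stop("the two stain vectors are collinear; cannot build a residual row",
           call. = FALSE)
    M <- rbind(M, res / rn)
  }
  kap <- kappa(M, exact = TRUE)
  if (!is.finite(kap) || kap > 1e6)
    stop("stain matrix is numerically singular (condition number ",
         format(kap, digits = 3), ")", call. = FALSE)
  rownames(M) <- c(stain_names, if (padded) "residual")
  colnames(M) <- c("R", "G", "B")
  structure(M, stains = stain_names, residual = padded,
            class = c("stain_matrix", "matrix", "array"))
}

#' Built-in stain matrices
#'
#' Published Ruifrok-Johnston OD vectors for the two staining systems the
#' pipeline targets: `"h&e"` (Haematoxylin + Eosin) and `"h-dab"`
#' (Haematoxylin + DAB). Both are two-stain systems padded with a residual
#' row. These are generic defaults — stain colours drift between labs and
#' scanners, so a matrix calibrated on your own slides (any user `k x 3`
#' matrix via [normalize_stain_matrix()]) is preferable when available.
#'
#' @param preset `"h&e"` or `"h-dab"`.
#' @return A normalized [normalize_stain_matrix()] result.
#' @export
stain_matrix <- function(preset = c("h&e", "h-dab")) {
  preset <- match.arg(preset)
  haem <- c(0.650, 0.704, 0.286)
  raw <- switch(preset,
    "h&e"   = rbind(Haematoxylin = haem, Eosin = c(0.072, 0.990, 0.105)),
    "h-dab" = rbind(Haematoxylin = haem, DAB   = c(0.268, 0.570, 0.776)))
  normalize_stain_matrix(raw)
}

#' Separate stain contributions by color deconvolution
#'
#' Multiplies each OD pixel by the inverse of the stain matrix,
#' `C(x) = OD(x) %*% M^-1`, giving the amount of each stain at every pixel.
#'
#' @param od Optical-density array from [rgb_to_od()] (`H x W x 3`).
#' @param M Stain matrix from [normalize_stain_matrix()] / [stain_matrix()].
#' @return `H x W x 3` array of stain amounts; the third dimension is named by
#'   stain. If `M` carries a padded residual row, the `"residual"` channel is
#'   retained and the result has attribute `residual = TRUE`.
#' @export
color_deconvolve <- function(od, M) {
  od <- as_image_array(od)
  stopifnot(length(dim(od)) == 3L, dim(od)[3L] == 3L)
  D <- tryCatch(solve(unclass(M)),
                error = function(e) stop("singular stain matrix", call. = FALSE))
  h <- dim(od)[1L]; w <- dim(od)[2L]
  amt <- matrix(od, ncol = 3L) %*% D
  out <- array(amt, c(h, w, 3L),
               dimnames = list(NULL, NULL, rownames(M)))
  attr(out, "residual") <- isTRUE(attr(M, "residual"))
  out
}

# -- small internals ---------------------------------------------------------

`%||%` <- function(a, b) if (is.null(a)) b else a

cross3 <- function(u, v) {
  c(u[2L] * v[3L] - u[3L] * v[2L],
    u[3L] * v[1L] - u[1L] * v[3L],
    u[1L] * v[2L] - u[2L] * v[1L])
}

as_image_array <- function(img) {
  if (is.matrix(img)) return(img)
  if (!is.array(img) || length(dim(img)) != 3L)
    stop("expected an H x W x 3 array or an H x W matrix", call. = FALSE)
  img
}

expand_i0 <- function(i0, img) {
  if (length(i0) == 1L) return(i0)
  if (is.matrix(img)) stop("per-channel i0 needs a 3-channel image", call. = FALSE)
  if (length(i0) != dim(img)[3L])
    stop("i0 must be scalar or one value per channel", call. = FALSE)
  aperm(array(i0, dim(img)[c(3L, 1L, 2L)]), c(2L, 3L, 1L))
}
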