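# Synthetic tissue-core generator.
#
# Real slides are not distributed with this package, so validation runs on
# synthetic cores: a blobby 4-class layout (smoothed Gaussian field cut at
# area quantiles), class-conditional Gaussian blue-channel texture — exactly
# the likelihood the MRF assumes — optional full RGB rendering through the
# Lambert-Beer stain model, eroded pure training cores, and an optional
# blobby exclusion mask. Everything is reproducible from the seed.

#' Specification of a synthetic tissue core
#'
#' Defaults define the standard study conditions used throughout the test
#' suite: blue-channel class means 40/100/160/220 with common sigma 15
#' (well-separated, the "easy" suite); `sigma = 35` gives the overlapping
#' "hard" suite where the Potts prior visibly helps. Area fractions are a
#' plausible carcinoma-core mix.
#'
#' @param height,width Image size in pixels.
#' @param fractions Target area fractions for (tumour, stroma,
#'   lymphoid/necrosis, background); must sum to 1.
#' @param mu,sigma Blue-channel Gaussian mean and sd per class (length 4, or
#'   scalar `sigma`).
#' @param stain_amounts 4 x k matrix of per-class stain amounts for RGB
#'   composition (rows = classes, columns = stains of `stains`); defaults to
#'   an H&E-like mix with Haematoxylin-rich tumour and near-blank background.
#' @param stains Stain matrix used for RGB rendering.
#' @param smooth Gaussian smoothing sd (pixels) of the layout field; larger
#'   values give coarser blobs.
#' @param train_erosion Radius used to erode class cores into guaranteed-pure
#'   training regions.
#' @param exclude_fraction Fraction of the raster to mark as don't-care
#'   (blobby, default 0).
#' @return List of class `synthetic_spec`.
#' @export
synthetic_spec <- function(height = 256L, width = 256L,
                           fractions = c(0.35, 0.30, 0.15, 0.20),
                           mu = c(40, 100, 160, 220), sigma = 15,
                           stain_amounts = default_stain_amounts(),
                           stains = stain_matrix("h&e"),
                           smooth = 8, train_erosion = 2L,
                           exclude_fraction = 0) {
  if (abs(sum(fractions) - 1) > 1e-8)
    stop("class area fractions must sum to 1", call. = FALSE)
  stopifnot(length(fractions) == 4L, length(mu) == 4L,
            all(fractions >= 0), height >= 1L, width >= 1L,
            exclude_fraction >= 0, exclude_fraction < 1)
  sigma <- rep_len(sigma, 4L)
  structure(list(height = as.integer(height), width = as.integer(width),
                 fractions = fractions, mu = mu, sigma = sigma,
                 stain_amounts = stain_amounts, stains = stains,
                 smooth = smooth, train_erosion = as.integer(train_erosion),
                 exclude_fraction = exclude_fraction),
            class = "synthetic_spec")
}

# Haematoxylin / Eosin amounts per class: nuclei-dense tumour and lymphoid
# tissue are Haematoxylin-rich, stroma Eosin-rich, background nearly unstained.
default_stain_amounts <- function() {
  rbind(tumour = c(1.0, 0.30), stroma = c(0.20, 0.80),
        `lymphoid/necrosis` = c(0.75, 0.45), background = c(0.03, 0.03))
}

#' Generate a blobby ground-truth class layout
#'
#' White noise is smoothed with a Gaussian kernel and cut at the empirical
#' quantiles of the target cumulative area fractions, producing contiguous
#' blobs whose areas match the targets almost exactly. Classes are assigned to
#' the field bands in fixed order (tumour = lowest band ... background =
#' highest).
#'
#' @param spec A [synthetic_spec()].
#' @param seed Integer RNG seed (fully determines the layout).
#' @return Integer `H x W` matrix with the 4-class coding 1..4.
#' @export
make_layout <- function(spec, seed = 1L) {
  set.seed(seed)
  h <- spec$height; w <- spec$width
  field <- gauss_smooth(matrix(rnorm(h * w), h, w), spec$smooth)
  keep <- which(spec$fractions > 0)
  cum <- cumsum(spec$fractions[keep])
  cuts <- quantile(field, cum[-length(cum)], names = FALSE, type = 7)
  matrix(keep[findInterval(field, cuts) + 1L], h, w)
}

# Separable Gaussian smoothing with reflected borders.
gauss_smooth <- function(m, sd) {
  if (sd <= 0) return(m)
  r <- max(1L, ceiling(3 * sd))
  k <- exp(-((-r:r)^2) / (2 * sd^2)); k <- k / sum(k)
  m <- conv_axis(m, k)
  t(conv_axis(t(m), k))
}

# 1D convolution of each column with kernel k, edge-reflected.
conv_axis <- function(m, k) {
  r <- (length(k) - 1L) %/% 2L
  h <- nrow(m)
  top <- m[pmin(pmax(1L + (r:1), 1L), h), , drop = FALSE]
  bot <- m[pmin(pmax(h - (1:r), 1L), h), , drop = FALSE]
  pad <- rbind(top, m, bot)
  out <- matrix(0, h, ncol(m))
  for (t in seq_along(k))
    out <- out + k[t] * pad[(t - 1L) + seq_len(h), , drop = FALSE]
  out
}

#' Render a synthetic core from a ground-truth layout
#'
#' The blue channel is drawn i.i.d. `N(mu_class, sigma_class^2)` per pixel and
#' clipped to `[0, 255]`; the full RGB image is composed from per-class stain
#' amounts through [compose_rgb()], then its blue channel is *replaced* by the
#' Gaussian texture so that the feature image obeys the class model exactly.
#' Training regions are eroded class cores (every pixel whose whole
#' `(2e+1)^2` window is one class), guaranteed pure.
#'
#' @param truth Layout from [make_layout()].
#' @param spec The same [synthetic_spec()].
#' @param seed Integer RNG seed for the texture (and exclusion blobs).
#' @return List with `rgb` (`H x W x 3`), `blue` (feature matrix), `truth`,
#'   `train` (0 = unlabelled, 1..4 = class), `exclude` (logical mask) and
#'   `spec`.
#' @export
render_core <- function(truth, spec, seed = 1L) {
  set.seed(seed + 1L)
  h <- nrow(truth); w <- ncol(truth)
  blue <- matrix(spec$mu[truth] + spec$sigma[truth] * rnorm(h * w), h, w)
  blue <- pmin(pmax(round(blue), 0), 255)

  k <- ncol(spec$stain_amounts)
  amounts <- array(0, c(h, w, k))
  for (s in seq_len(k))
    amounts[, , s] <- matrix(spec$stain_amounts[truth, s], h, w)
  M <- spec$stains
  rgb <- compose_rgb(amounts, M[seq_len(k), , drop = FALSE] ,
                     i0 = 255)
  rgb[, , 3L] <- blue

  train <- truth
  e <- spec$train_erosion
  if (e > 0L) {
    area <- (2L * e + 1L)^2
    pure <- matrix(TRUE, h, w)
    # a window fully inside one class has a full count of its own class
    cnt <- box_count_full(truth, e)
    pure <- cnt == area
    train[!pure] <- 0L
  }

  exclude <- matrix(FALSE, h, w)
  if (spec$exclude_fraction > 0) {
    ef <- gauss_smooth(matrix(rnorm(h * w), h, w), spec$smooth)
    exclude <- ef <= quantile(ef, spec$exclude_fraction, names = FALSE)
  }
  list(rgb = rgb, blue = blue, truth = truth, train = train,
       exclude = exclude, spec = spec)
}

# count of same-class-as-centre pixels in the clipped window; pixels near the
# border never reach the full (2e+1)^2 count, so erosion also trims borders
box_count_full <- function(lab, e) {
  cnt <- matrix(0L, nrow(lab), ncol(lab))
  for (v in sort(unique(as.vector(lab)))) {
    sel <- lab == v
    cv <- box_count(sel, e)
    cnt[sel] <- cv[sel]
  }
  cnt
}

#' Generate a complete synthetic core
#'
#' Convenience wrapper: [make_layout()] then [render_core()] with the same
#' seed.
#'
#' @inheritParams make_layout
#' @return See [render_core()].
#' @export
simulate_core <- function(spec = synthetic_spec(), seed = 1L) {
  render_core(make_layout(spec, seed), spec, seed)
}
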