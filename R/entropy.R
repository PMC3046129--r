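# Multistage maximum-entropy segmentation of nuclear architecture.
#
# The Haematoxylin amount map is quantized to 8 bits, its histogram is split
# into four equal-width sub-ranges, a Kapur maximum-entropy cut is found in
# each (-> 8 intensity layers), a second two-class entropy cut on the layer
# histogram separates nuclei from non-nuclei, and a neighborhood mode filter
# cleans the binary mask.

#' Normalized intensity histogram
#'
#' @param img Integer-valued matrix with values in `[0, L-1]`.
#' @param L Number of intensity levels (default 256).
#' @param normalize Return frequencies summing to 1 (default) or raw counts.
#' @return Numeric vector of length `L`; element `i` is level `i - 1`.
#' @export
intensity_histogram <- function(img, L = 256L, normalize = TRUE) {
  v <- as.vector(img)
  if (length(v) == 0L) stop("empty image", call. = FALSE)
  if (any(v < 0 | v > L - 1L)) stop("values outside [0, L-1]", call. = FALSE)
  counts <- tabulate(as.integer(v) + 1L, nbins = L)
  if (normalize) counts / sum(counts) else as.numeric(counts)
}

#' Shannon entropy of a histogram sub-range
#'
#' Restricts the histogram to levels `[lo, hi]`, renormalizes, and returns
#' `-sum(p * log2(p))` in bits (with `0 log 0 = 0`). A sub-range with zero
#' total mass has entropy 0 and attribute `empty = TRUE`.
#'
#' @param p Histogram vector over levels `0 .. length(p) - 1`.
#' @param lo,hi Inclusive level bounds (0-based); default whole range.
#' @return Entropy in bits.
#' @export
shannon_entropy <- function(p, lo = 0L, hi = length(p) - 1L) {
  stopifnot(lo <= hi, lo >= 0L, hi <= length(p) - 1L)
  q <- p[(lo:hi) + 1L]
  s <- sum(q)
  if (s == 0) return(structure(0, empty = TRUE))
  q <- q[q > 0] / s
  -sum(q * log2(q))
}

#' Maximum-entropy (Kapur) cut point
#'
#' Finds the cut `t` in `[lo, hi - 1]` maximizing the sum of the entropies of
#' the two renormalized class histograms `[lo, t]` and `[t + 1, hi]`. Cuts
#' that leave either class with zero mass are not admissible; ties are broken
#' towards the smallest `t`. If all mass sits at a single level no admissible
#' cut exists and that level is returned with `degenerate = TRUE`.
#'
#' @inheritParams shannon_entropy
#' @return List with `cut` (integer level), `criterion` (bits; `NA` when
#'   degenerate) and `degenerate` (logical).
#' @export
max_entropy_cut <- function(p, lo = 0L, hi = length(p) - 1L) {
  stopifnot(hi - lo >= 1L, lo >= 0L, hi <= length(p) - 1L)
  q <- p[(lo:hi) + 1L]
  total <- sum(q)
  if (total == 0) stop("no mass in [lo, hi]", call. = FALSE)
  n <- length(q)
  cs <- cumsum(q)
  lg <- ifelse(q > 0, q * log2(q), 0)
  ch <- cumsum(lg)
  j <- seq_len(n - 1L)                       # cut after level lo + j - 1
  s1 <- cs[j];          h1 <- ch[j]
  s2 <- total - s1;     h2 <- ch[n] - ch[j]
  e1 <- ifelse(s1 > 0, log2(s1) - h1 / s1, -Inf)
  e2 <- ifelse(s2 > 0, log2(s2) - h2 / s2, -Inf)
  crit <- e1 + e2
  valid <- s1 > 0 & s2 > 0
  if (!any(valid)) {
    lev <- lo + which(q > 0)[1L] - 1L        # all mass at one level
    return(list(cut = as.integer(lev), criterion = NA_real_, degenerate = TRUE))
  }
  crit[!valid] <- -Inf
  best <- which.max(crit)                    # first max -> smallest t
  list(cut = as.integer(lo + best - 1L), criterion = crit[best],
       degenerate = FALSE)
}

#' Eight-layer maximum-entropy decomposition
#'
#' Splits the 8-bit histogram into four equal-width sub-ranges
#' `[0,63] [64,127] [128,191] [192,255]`, finds the Kapur cut inside each, and
#' assigns every pixel the index (0-7, ascending intensity) of the interval it
#' falls in among the 8 intervals delimited by the sub-range boundaries plus
#' the four cuts. A sub-range with no mass gets its midpoint as a default cut
#' and is flagged.
#'
#' @param img Integer-valued matrix with values in `[0, 255]`.
#' @return List with `layers` (`H x W` integer matrix, values 0-7), `cuts`
#'   (the four cut levels), `bounds` (the 8 interval upper bounds), `empty`
#'   (flags for zero-mass sub-ranges that fell back to the midpoint) and
#'   `degenerate` (flags for sub-ranges without an admissible cut, including
#'   the empty ones).
#' @export
eight_layer_decompose <- function(img) {
  p <- intensity_histogram(img, 256L)
  sub <- list(c(0L, 63L), c(64L, 127L), c(128L, 191L), c(192L, 255L))
  cuts <- integer(4L); degen <- logical(4L); empty <- logical(4L)
  for (i in 1:4) {
    lo <- sub[[i]][1L]; hi <- sub[[i]][2L]
    if (sum(p[(lo:hi) + 1L]) == 0) {
      cuts[i] <- (lo + hi) %/% 2L
      empty[i] <- degen[i] <- TRUE
    } else {
      mc <- max_entropy_cut(p, lo, hi)
      cuts[i] <- mc$cut
      degen[i] <- mc$degenerate
    }
  }
  bounds <- c(cuts[1L], 63L, cuts[2L], 127L, cuts[3L], 191L, cuts[4L], 255L)
  layers <- matrix(findInterval(as.vector(img) - 0.5, bounds),
                   nrow(img), ncol(img))
  list(layers = layers, cuts = cuts, bounds = bounds, empty = empty,
       degenerate = degen)
}

#' Two-class entropy cut on the layer image
#'
#' Computes the histogram of the 8 layer indices and applies a single Kapur
#' cut on `[0, 7]`; pixels with layer index above the cut (high Haematoxylin
#' density) are called nuclei.
#'
#' @param layers `H x W` integer matrix of layer indices 0-7 (from
#'   [eight_layer_decompose()]).
#' @return List with `mask` (logical `H x W`, `TRUE` = nucleus), `cut` and
#'   `degenerate` (all pixels in one layer: empty mask, flagged).
#' @export
binarize_nuclei <- function(layers) {
  stopifnot(all(layers >= 0L & layers <= 7L))
  p <- intensity_histogram(layers, 8L)
  mc <- max_entropy_cut(p, 0L, 7L)
  list(mask = layers > mc$cut, cut = mc$cut, degenerate = mc$degenerate)
}

#' Neighborhood mode (majority) filter
#'
#' Re-assigns every pixel the most frequent value inside the
#' `(2r+1) x (2r+1)` window centred on it; windows are clipped at the image
#' border and ties are broken towards the smallest value. Reduces spurious
#' isolated detections and fills low-contrast holes in label or binary maps.
#'
#' @param img Matrix with a small number of discrete values (labels, layers,
#'   or 0/1 masks; logical input is returned as logical).
#' @param r Window radius in pixels (default 3, i.e. a 7x7 window).
#' @return Filtered matrix of the same shape and value set.
#' @export
mode_filter <- function(img, r = 3L) {
  stopifnot(r >= 1L)
  logical_in <- is.logical(img)
  m <- if (logical_in) img + 0L else img
  vals <- sort(unique(as.vector(m)))
  if (length(vals) == 1L) return(img)
  best_cnt <- matrix(-1L, nrow(m), ncol(m))
  out <- matrix(vals[1L], nrow(m), ncol(m))
  for (v in vals) {                # ascending order => ties keep smallest
    cnt <- box_count(m == v, r)
    upd <- cnt > best_cnt
    best_cnt[upd] <- cnt[upd]
    out[upd] <- v
  }
  if (logical_in) out > 0 else out
}

# Number of TRUE cells of `ind` in the (2r+1)^2 window around each pixel,
# clipped at borders, via an integral image.
box_count <- function(ind, r) {
  h <- nrow(ind); w <- ncol(ind)
  cs <- ind + 0
  if (h > 1L) cs <- apply(cs, 2L, cumsum)    # down columns
  cs <- t(matrix(cs, h, w))
  if (w > 1L) cs <- apply(cs, 2L, cumsum)    # along rows
  I <- matrix(0, h + 1L, w + 1L)
  I[-1L, -1L] <- t(matrix(cs, w, h))
  r1 <- pmax(seq_len(h) - r, 1L); r2 <- pmin(seq_len(h) + r, h) + 1L
  c1 <- pmax(seq_len(w) - r, 1L); c2 <- pmin(seq_len(w) + r, w) + 1L
  ri2 <- rep(r2, times = w); ri1 <- rep(r1, times = w)
  cj2 <- rep(c2, each = h);  cj1 <- rep(c1, each = h)
  s <- I[cbind(ri2, cj2)] - I[cbind(ri1, cj2)] -
       I[cbind(ri2, cj1)] + I[cbind(ri1, cj1)]
  matrix(as.integer(round(s)), h, w)
}

#' Quantize a real-valued map to 8-bit levels
#'
#' Linear min-max scaling to `[0, 255]` with rounding; the scaling is returned
#' so a run log can record it. A constant map quantizes to all zeros and is
#' flagged.
#'
#' @param x Numeric matrix (e.g. a stain amount map).
#' @return List with `img` (integer matrix, 0-255), `min`, `max`, `constant`.
#' @export
quantize8 <- function(x) {
  mn <- min(x); mx <- max(x)
  if (mx == mn)
    return(list(img = matrix(0L, nrow(x), ncol(x)), min = mn, max = mx,
                constant = TRUE))
  q <- matrix(as.integer(round((x - mn) / (mx - mn) * 255)), nrow(x), ncol(x))
  list(img = q, min = mn, max = mx, constant = FALSE)
}

#' Extract the nuclei mask from a Haematoxylin amount map
#'
#' The full nuclear-architecture pipeline: 8-bit quantization ->
#' [eight_layer_decompose()] -> [binarize_nuclei()] -> [mode_filter()].
#' Nuclei are the *high*-amount side of the final cut (nuclei absorb more
#' Haematoxylin, hence higher optical density); if you supply raw transmitted
#' intensity instead of OD/amounts, invert it first — the polarity matters.
#'
#' @param haem Numeric matrix: the Haematoxylin channel of
#'   [color_deconvolve()] output (or any single-channel density map).
#' @param r Mode-filter radius (default 3).
#' @return List with `mask` (logical nuclei mask), `layers` (8-layer map),
#'   `cuts` (four sub-range cuts), `layer_cut` (nuclei/non-nuclei cut on layer
#'   indices), `quantization` (min/max used) and `degenerate` flags.
#' @export
extract_nuclei <- function(haem, r = 3L) {
  stopifnot(is.matrix(haem))
  q <- quantize8(haem)
  dec <- eight_layer_decompose(q$img)
  bin <- binarize_nuclei(dec$layers)
  mask <- if (bin$degenerate) bin$mask else mode_filter(bin$mask, r)
  list(mask = mask, layers = dec$layers, cuts = dec$cuts,
       layer_cut = bin$cut, quantization = q[c("min", "max", "constant")],
       degenerate = list(sub_ranges = dec$degenerate, binary = bin$degenerate))
}
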