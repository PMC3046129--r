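# MAP labelling on a Markov random field.
#
# A labelling omega assigns one of k classes to every pixel site. Its
# posterior energy is the sum of Gaussian singleton energies (negative log
# class likelihoods of the blue-channel feature) and Potts clique potentials
# over neighboring pairs (-beta if equal labels, +beta otherwise). The MAP
# labelling minimizes the total energy; four relaxation schemes are provided,
# with Metropolis annealing the default (it gave the best segmentations among
# the four in the source experiments).

#' MRF configuration
#'
#' @param beta Weight of the Potts prior (>= 0). Default 0.9, the value found
#'   experimentally for tissue-core segmentation.
#' @param neighborhood 4- or 8-connected pixel neighborhood (default 8).
#' @param relaxer One of `"metropolis"`, `"icm"`, `"gibbs"`, `"mmd"`.
#' @param t0 Initial annealing temperature (> 0).
#' @param cooling Geometric cooling factor per sweep, in (0, 1).
#' @param tol Stop when the fraction of sites changed in a sweep falls below
#'   this (stochastic relaxers; ICM stops at its fixed point).
#' @param max_sweeps Sweep budget; hitting it returns the best labelling seen
#'   with `converged = FALSE`.
#' @param alpha MMD acceptance threshold in (0, 1): an energy-raising move is
#'   accepted iff `exp(-dU/T) >= alpha` (deterministic, no per-move coin).
#' @return List of class `mrf_config`.
#' @export
mrf_config <- function(beta = 0.9, neighborhood = 8L,
                       relaxer = c("metropolis", "icm", "gibbs", "mmd"),
                       t0 = 4, cooling = 0.98, tol = 1e-4,
                       max_sweeps = 1000L, alpha = 0.3) {
  relaxer <- match.arg(relaxer)
  stopifnot(beta >= 0, neighborhood %in% c(4L, 8L), t0 > 0,
            cooling > 0, cooling < 1, tol >= 0, max_sweeps >= 1L,
            alpha > 0, alpha < 1)
  structure(list(beta = beta, neighborhood = as.integer(neighborhood),
                 relaxer = relaxer, t0 = t0, cooling = cooling, tol = tol,
                 max_sweeps = as.integer(max_sweeps), alpha = alpha),
            class = "mrf_config")
}

#' Gaussian singleton energy
#'
#' Negative log density of the feature value under the class Gaussian:
#' `log(sigma) + (f - mu)^2 / (2 sigma^2) + log(2 pi)/2`. The constant is kept
#' so the energy is the exact negative log likelihood (it cancels in any
#' comparison between labels).
#'
#' @param f Feature value(s).
#' @param class Class index (1-based) into `model`.
#' @param model A [learn_class_params()] model.
#' @return Energy value(s), same shape as `f`.
#' @export
singleton_energy <- function(f, class, model) {
  s2 <- model$sigma2[class]
  0.5 * log(2 * pi * s2) + (f - model$mu[class])^2 / (2 * s2)
}

#' Potts clique potential
#'
#' Pairwise energy favouring equal labels on neighboring pixels: `-beta` when
#' the two labels agree, `+beta` otherwise. (The 0 / 2 beta convention differs
#' only by a constant per clique and has the same minimizers.)
#'
#' @param a,b Class labels (any comparable values; vectorized).
#' @param beta Prior weight (>= 0).
#' @export
clique_potential <- function(a, b, beta = 0.9) {
  ifelse(a == b, -beta, beta)
}

#' Local energy of a label at one site
#'
#' Singleton energy plus the clique potentials against all current neighbor
#' labels. The difference of two local energies at the same site equals the
#' corresponding total-energy difference, which is what the relaxers use.
#'
#' @param i,j Site row/column (1-based).
#' @param class Candidate class label (1-based).
#' @param labels Current labelling (integer `H x W` matrix).
#' @param f Feature image.
#' @param model Class model.
#' @param beta,neighborhood Prior weight and connectivity.
#' @export
local_energy <- function(i, j, class, labels, f, model, beta = 0.9,
                         neighborhood = 8L) {
  off <- neighbor_offsets(neighborhood)
  ni <- i + off[, 1L]; nj <- j + off[, 2L]
  ok <- ni >= 1L & nj >= 1L & ni <= nrow(f) & nj <= ncol(f)
  e <- singleton_energy(f[i, j], class, model)
  if (any(ok))
    e <- e + sum(clique_potential(class, labels[cbind(ni[ok], nj[ok])], beta))
  e
}

#' Total energy of a labelling
#'
#' Sum of singleton energies over all sites plus Potts potentials over all
#' unordered neighboring pairs (each clique counted once).
#'
#' @inheritParams local_energy
#' @export
total_energy <- function(labels, f, model, beta = 0.9, neighborhood = 8L) {
  stopifnot(all(dim(labels) == dim(f)))
  u <- sum(singleton_energy(f, labels, model))
  h <- nrow(f); w <- ncol(f)
  fwd <- neighbor_offsets(neighborhood)
  fwd <- fwd[fwd[, 1L] > 0L | (fwd[, 1L] == 0L & fwd[, 2L] > 0L), , drop = FALSE]
  for (t in seq_len(nrow(fwd))) {
    di <- fwd[t, 1L]; dj <- fwd[t, 2L]
    ri <- seq_len(h - abs(di)); rj <- seq_len(w - abs(dj))
    a <- labels[ri + max(di, 0L), rj + max(dj, 0L), drop = FALSE]
    b <- labels[ri - min(di, 0L), rj - min(dj, 0L), drop = FALSE]
    u <- u + sum(clique_potential(a, b, beta))
  }
  u
}

neighbor_offsets <- function(neighborhood) {
  if (neighborhood == 4L)
    cbind(c(-1L, 0L, 0L, 1L), c(0L, -1L, 1L, 0L))
  else
    cbind(rep(-1:1, each = 3L), rep(-1:1, 3L))[-5L, , drop = FALSE]
}

#' Local class posterior at a site
#'
#' Normalized Gibbs conditional `exp(-local_energy / temp)` over all classes —
#' the distribution the Gibbs relaxer samples from.
#'
#' @inheritParams local_energy
#' @param temp Temperature (> 0).
#' @return Numeric vector of probabilities over classes (sums to 1).
#' @export
class_posterior <- function(i, j, labels, f, model, beta = 0.9,
                            neighborhood = 8L, temp = 1) {
  e <- vapply(seq_along(model$classes), function(c)
    local_energy(i, j, c, labels, f, model, beta, neighborhood), numeric(1L))
  w <- exp(-(e - min(e)) / temp)
  w / sum(w)
}

#' Maximum-likelihood (prior-free) labelling
#'
#' Per-site argmin of the singleton energy; ties towards the smaller class
#' index. This is both the relaxers' initial state and the `beta = 0` limit of
#' the MRF.
#'
#' @param f Feature image.
#' @param model Class model.
#' @return Integer `H x W` matrix of class labels (1-based).
#' @export
ml_labelling <- function(f, model) {
  k <- length(model$classes)
  E <- vapply(seq_len(k), function(c) as.vector(singleton_energy(f, c, model)),
              numeric(length(f)))
  matrix(max.col(-E, ties.method = "first"), nrow(f), ncol(f))
}

#' Segment a feature image by MRF relaxation
#'
#' Runs the configured relaxer from the per-site maximum-likelihood
#' initialization. Stochastic relaxers (Metropolis, MMD, Gibbs) visit sites in
#' a fresh random order every sweep and cool the temperature geometrically;
#' ICM is deterministic coordinate descent in raster order. The stochastic
#' relaxers return the best (lowest total energy) labelling encountered, so
#' the result never has higher energy than the initialization. Results are
#' bit-reproducible given `seed` (or the caller's RNG state).
#'
#' @param f Feature image (`H x W` numeric matrix).
#' @param model Class model from [learn_class_params()].
#' @param config An [mrf_config()].
#' @param seed Optional integer; if given, `set.seed(seed)` is called first.
#' @return An `mrf_fit`: list with `labels` (integer `H x W`, 1-based),
#'   `trace` (data.frame: sweep, energy, changed fraction, temperature),
#'   `energy` (of the returned labelling), `converged`, `config`, `model`.
#' @export
segment_mrf <- function(f, model, config = mrf_config(), seed = NULL) {
  stopifnot(is.matrix(f), inherits(config, "mrf_config"))
  if (!is.null(seed)) set.seed(seed)
  init <- ml_labelling(f, model)
  method <- match(config$relaxer, c("icm", "metropolis", "gibbs", "mmd")) - 1L
  res <- cpp_relax(f, init - 1L, model$mu, model$sigma2, config$beta,
                   config$neighborhood, method, config$t0, config$cooling,
                   config$tol, config$max_sweeps, config$alpha)
  if (!res$converged)
    warning("relaxation hit max_sweeps without converging; ",
            "returning best labelling seen")
  trace <- data.frame(sweep = seq_along(res$energy), energy = res$energy,
                      changed = res$changed, temperature = res$temperature)
  structure(list(labels = res$labels + 1L, trace = trace,
                 energy = res$final_energy, converged = res$converged,
                 config = config, model = model),
            class = "mrf_fit")
}

#' @rdname segment_mrf
#' @param ... Passed to [mrf_config()] (all fields except `relaxer`).
#' @export
relax_metropolis <- function(f, model, seed = NULL, ...)
  segment_mrf(f, model, mrf_config(relaxer = "metropolis", ...), seed)

#' @rdname segment_mrf
#' @export
relax_icm <- function(f, model, seed = NULL, ...)
  segment_mrf(f, model, mrf_config(relaxer = "icm", ...), seed)

#' @rdname segment_mrf
#' @export
relax_gibbs <- function(f, model, seed = NULL, ...)
  segment_mrf(f, model, mrf_config(relaxer = "gibbs", ...), seed)

#' @rdname segment_mrf
#' @export
relax_mmd <- function(f, model, seed = NULL, ...)
  segment_mrf(f, model, mrf_config(relaxer = "mmd", ...), seed)

#' @export
print.mrf_fit <- function(x, ...) {
  cat("MRF segmentation (", x$config$relaxer, "), ",
      nrow(x$labels), "x", ncol(x$labels), " sites, ",
      nrow(x$trace), " sweeps, energy ", format(x$energy), ", ",
      if (x$converged) "converged" else "NOT converged", "\n", sep = "")
  invisible(x)
}

#' Merge the two non-tumour subtypes
#'
#' Stroma and lymphoid/necrosis are modelled as separate classes because their
#' morphologies differ, but they are one "non-tumour" class for evaluation.
#' Tumour and background are unchanged.
#'
#' @param labels 4-class labelling (1 = tumour, 2 = stroma,
#'   3 = lymphoid/necrosis, 4 = background).
#' @return 3-class labelling: 1 = tumour, 2 = non-tumour, 3 = background.
#' @export
merge_non_tumour <- function(labels) {
  if (any(!labels %in% 1:4))
    stop("labels must be the 4-class coding 1..4", call. = FALSE)
  m <- matrix(c(1L, 2L, 2L, 3L)[labels], nrow(labels), ncol(labels))
  m
}
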