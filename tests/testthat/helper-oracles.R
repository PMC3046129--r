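# Independent brute-force oracles used to validate the fast implementations.
# These deliberately share no code with the package internals.

# Shannon entropy (bits) of a renormalized histogram slice.
oracle_entropy <- function(p) {
  s <- sum(p)
  if (s == 0) return(0)
  q <- p[p > 0] / s
  -sum(q * log2(q))
}

# Exhaustive Kapur cut: scan every candidate, skipping cuts that leave a side
# empty; first (smallest) maximum wins. Returns NA if no admissible cut.
oracle_cut <- function(p, lo = 0L, hi = length(p) - 1L) {
  best_t <- NA_integer_; best_c <- -Inf
  for (t in lo:(hi - 1L)) {
    left <- p[(lo:t) + 1L]; right <- p[((t + 1L):hi) + 1L]
    if (sum(left) == 0 || sum(right) == 0) next
    crit <- oracle_entropy(left) + oracle_entropy(right)
    if (crit > best_c) { best_c <- crit; best_t <- t }
  }
  list(cut = best_t, criterion = best_c)
}

# Per-pixel window mode with clipped borders and smallest-value tie-break.
oracle_mode_filter <- function(m, r) {
  h <- nrow(m); w <- ncol(m)
  out <- m
  for (i in seq_len(h)) for (j in seq_len(w)) {
    win <- m[max(1, i - r):min(h, i + r), max(1, j - r):min(w, j + r)]
    tab <- table(as.vector(win))
    vals <- as.numeric(names(tab))
    out[i, j] <- min(vals[tab == max(tab)])
  }
  storage.mode(out) <- storage.mode(m)
  out
}

# Total MRF energy by direct summation over sites and unordered pairs.
oracle_total_energy <- function(labels, f, model, beta, neighborhood = 8L) {
  h <- nrow(f); w <- ncol(f)
  u <- 0
  for (i in seq_len(h)) for (j in seq_len(w)) {
    s2 <- model$sigma2[labels[i, j]]
    u <- u + 0.5 * log(2 * pi * s2) +
      (f[i, j] - model$mu[labels[i, j]])^2 / (2 * s2)
  }
  off <- if (neighborhood == 4L) list(c(0, 1), c(1, 0))
         else list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))
  for (d in off)
    for (i in seq_len(h)) for (j in seq_len(w)) {
      ni <- i + d[1]; nj <- j + d[2]
      if (ni < 1 || nj < 1 || ni > h || nj > w) next
      u <- u + if (labels[i, j] == labels[ni, nj]) -beta else beta
    }
  u
}

# Random discrete histogram over L levels (some bins may be empty).
random_histogram <- function(L = 256L, empty_frac = 0.3) {
  p <- runif(L)
  p[runif(L) < empty_frac] <- 0
  if (sum(p) == 0) p[sample.int(L, 2L)] <- 1
  p / sum(p)
}

# Small random Gaussian class model with k well-defined classes.
random_model <- function(k = 4L) {
  structure(list(classes = paste0("c", seq_len(k)),
                 mu = sort(runif(k, 0, 255)),
                 sigma2 = runif(k, 4, 400),
                 n = rep(10L, k)),
            class = "class_model")
}

# Planted-disk Haematoxylin amount image plus its ground-truth mask.
disk_image <- function(h = 128L, w = 128L, n_disks = 6L, radius = 9,
                       amount_fg = 1.2, amount_bg = 0.1, noise_sd = 0.05) {
  cx <- runif(n_disks, radius + 2, h - radius - 2)
  cy <- runif(n_disks, radius + 2, w - radius - 2)
  ii <- matrix(seq_len(h), h, w)
  jj <- matrix(seq_len(w), h, w, byrow = TRUE)
  truth <- matrix(FALSE, h, w)
  for (d in seq_len(n_disks))
    truth <- truth | ((ii - cx[d])^2 + (jj - cy[d])^2 <= radius^2)
  img <- ifelse(truth, amount_fg, amount_bg) + rnorm(h * w, 0, noise_sd)
  list(img = matrix(img, h, w), truth = truth)
}

jaccard <- function(a, b) sum(a & b) / sum(a | b)
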