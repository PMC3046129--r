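# Texture feature extraction and supervised class-model learning.
#
# The single texture feature is the blue channel: Haematoxylin stains nuclei
# blue in both H&E and IHC preparations, and nuclear morphology carries most
# of the discriminative signal for carcinoma, so the blue channel separates
# the four morphology classes better than grey, red or green.

#' Extract the blue channel as the feature image
#'
#' @param img RGB image, numeric `H x W x 3` array.
#' @return `H x W` numeric matrix of blue intensities on the input scale.
#' @export
blue_channel <- function(img) {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3L] < 3L)
    stop("a 3-channel RGB image is required; got a single-channel input",
         call. = FALSE)
  img[, , 3L]
}

#' Learn per-class Gaussian texture parameters from training regions
#'
#' For each class the mean and population variance (denominator `n`) of the
#' feature over its training pixels are estimated; these parameterize the
#' Gaussian singleton energies of the MRF. Variances are floored at
#' `var_floor` so a constant training region cannot produce a degenerate
#' (infinite-precision) class.
#'
#' @param f Feature image (`H x W` matrix, e.g. from [blue_channel()]).
#' @param regions Integer `H x W` matrix of training labels: 0 = unlabelled,
#'   `1..k` = class index. Classes must be pairwise disjoint by construction
#'   and each present at least once.
#' @param classes Character vector of class names, one per label index.
#'   Default: the four morphology classes in fixed order
#'   (tumour, stroma, lymphoid/necrosis, background).
#' @param var_floor Minimum variance in intensity^2 (default 1).
#' @return A `class_model`: list with `classes`, `mu`, `sigma2`, `n`.
#' @examples
#' f <- matrix(c(2, 4, 6, 9), 2)
#' m <- learn_class_params(f, matrix(c(1, 1, 1, 2), 2), classes = c("a", "b"))
#' m$mu      # 4, 9
#' m$sigma2  # 8/3, floored 1
#' @export
learn_class_params <- function(f, regions, classes = names(tma_classes),
                               var_floor = 1) {
  stopifnot(is.matrix(f), all(dim(f) == dim(regions)))
  k <- length(classes)
  if (any(regions < 0L | regions > k))
    stop("training labels must lie in 0..", k, call. = FALSE)
  mu <- sigma2 <- n <- numeric(k)
  for (j in seq_len(k)) {
    x <- f[regions == j]
    if (length(x) == 0L)
      stop("no training pixels for class '", classes[j], "'", call. = FALSE)
    n[j] <- length(x)
    mu[j] <- mean(x)
    v <- mean((x - mu[j])^2)          # population variance
    if (v < var_floor) {
      if (n[j] > 1L)
        warning("variance of class '", classes[j], "' floored at ", var_floor)
      v <- var_floor
    }
    sigma2[j] <- v
  }
  structure(list(classes = classes, mu = mu, sigma2 = sigma2, n = n),
            class = "class_model")
}

#' @export
print.class_model <- function(x, ...) {
  cat("Gaussian class model (", length(x$classes), " classes)\n", sep = "")
  print(data.frame(class = x$classes, mu = x$mu, sigma2 = x$sigma2,
                   n_train = x$n), row.names = FALSE)
  invisible(x)
}
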