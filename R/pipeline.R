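# End-to-end convenience wrapper: feature extraction -> supervised training
# -> MRF segmentation -> merge -> (optional) evaluation.

#' Run the full tumour-segmentation pipeline on one image
#'
#' Extracts the blue-channel feature, learns the 4-class Gaussian model from
#' the training regions, runs the MRF relaxation, merges the two non-tumour
#' subtypes, and — when ground truth is supplied — scores the result pixel by
#' pixel.
#'
#' @param img RGB image (`H x W x 3`, 0-255).
#' @param regions Training-region matrix (0 = unlabelled, 1..4 = class).
#' @param truth Optional ground-truth labelling (4-class coding) for
#'   evaluation.
#' @param exclude Optional logical don't-care mask.
#' @param config An [mrf_config()].
#' @param seed Integer seed passed to [segment_mrf()].
#' @param background Background scoring rule, see [confusion_counts()].
#' @return List with `model`, `fit` (the [segment_mrf()] result), `labels`
#'   (4-class), `merged` (3-class), and, if truth was given, `counts` and
#'   `metrics`.
#' @export
run_pipeline <- function(img, regions, truth = NULL, exclude = NULL,
                         config = mrf_config(), seed = 1L,
                         background = c("exclude", "non_tumour")) {
  background <- match.arg(background)
  f <- blue_channel(img)
  model <- learn_class_params(f, regions)
  fit <- segment_mrf(f, model, config, seed = seed)
  merged <- merge_non_tumour(fit$labels)
  out <- list(model = model, fit = fit, labels = fit$labels, merged = merged)
  if (!is.null(truth)) {
    out$counts <- confusion_counts(merged, truth, exclude, background)
    out$metrics <- segmentation_metrics(out$counts)
  }
  out
}
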