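Package: tmaseg
Title: Tumour Segmentation for Histochemical and Immunohistochemical Tissue Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Supervised pixel-based tumour segmentation for tissue-microarray core
    images stained with H&E or immunohistochemistry (DAB). Separates stains by
    optical-density color deconvolution, extracts nuclear architecture with a
    multistage maximum-entropy (Kapur) thresholding pipeline and a neighborhood
    mode filter, learns per-class Gaussian blue-channel texture models from
    user-drawn training regions, and labels pixels into tumour, stroma,
    lymphoid/necrosis and background classes by MAP estimation on a Markov
    random field with a Potts prior, relaxed by simulated annealing (Metropolis),
    ICM, modified Metropolis dynamics or Gibbs sampling. Includes pixel-based
    confusion-matrix evaluation with exclusion masks and a synthetic tissue-core
    generator with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    png,
    tiff,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
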