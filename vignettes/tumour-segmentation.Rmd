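---
title: "Tumour segmentation on stained tissue cores: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tumour segmentation on stained tissue cores: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmaseg)
```

`tmaseg` segments tissue-microarray core images into tumour, stroma,
lymphoid/inflammatory-necrosis and background, pixel by pixel. This vignette
explains the underlying models, every tunable parameter, what the synthetic
validation data does and does not show, and the numerical decisions taken
where the design was genuinely open.

## Stain separation

A CCD camera's RGB intensities depend nonlinearly on stain concentration, so
raw intensities cannot be unmixed. Optical density
`OD_C = -log10(I_C / I0_C)` is linear in stain amount (Lambert–Beer), which
turns unmixing into linear algebra: with stain OD vectors as the rows of a
matrix `M` (each row normalized to unit length), the OD at a pixel is
`C %*% M` for stain amounts `C`, and `color_deconvolve()` applies `M^-1`.

Decisions and parameters:

* **Logarithm base** is 10, the convention of the color-deconvolution
  literature. Any fixed base would cancel in the compose/deconvolve
  roundtrip; base 10 keeps amount units conventional.
* **Zero-intensity guard.** A pixel value of 0 has infinite OD; detected
  intensities are floored at 1 level, so the maximum OD is `log10(i0)`
  (≈ 2.41 at `i0 = 255`). This avoids a special-cased infinite channel while
  changing no pixel with value ≥ 1.
* **Incident intensity `i0`** defaults to 255 per channel and is overridable;
  white-point calibration is left to the user.
* **Default stain vectors** are the published Ruifrok–Johnston H&E and H-DAB
  vectors (`stain_matrix()`). Stain colour varies between labs and scanners,
  so these are generic defaults, not calibrated truth; any user `k×3` matrix
  is accepted through `normalize_stain_matrix()`.
* **Two-stain systems** are padded with the unit cross product of the two
  stain vectors. The residual channel is returned and flagged rather than
  silently dropped — a large residual signals a poorly matched matrix.
* Nearly collinear stain vectors make the system ill-conditioned; the
  constructor rejects condition numbers above 10⁶ and reports the value.

## Nuclear-architecture extraction

The Haematoxylin amount map is segmented by a multistage maximum-entropy
scheme: quantize to 8 bits, split the histogram into the four equal-width
sub-ranges `[0,63] … [192,255]`, find a Kapur maximum-entropy cut inside
each (yielding eight layers), then apply one more two-class cut to the
histogram of the eight layer indices; pixels above that cut are nuclei.
A mode filter cleans the binary mask.

* **Kapur criterion.** The cut maximizes the sum of Shannon entropies of the
  two renormalized class histograms. Log base 2 is used; the base cancels in
  the argmax. Cuts that leave either class empty are inadmissible — scoring
  an empty class as zero entropy would spuriously reward cutting outside the
  occupied range. Ties break towards the smallest cut, making the result
  deterministic. If all mass sits at one level there is no admissible cut;
  that level is returned with a degenerate flag.
* **Equal sub-ranges** are equal-width intensity intervals, not equal-mass
  quartiles — the literal reading, and the one that keeps layer boundaries
  fixed features of the intensity axis.
* **Second-stage histogram** is taken over the eight layer indices (not over
  raw intensities restricted by layer). The layer index is already the
  rank-compressed intensity, and a cut on it cleanly selects "the darkest k
  layers".
* **Quantization** of real-valued amount maps is linear min–max to 0–255,
  with the scaling recorded in the output. This makes the mask invariant
  under positive affine rescaling of the amounts; a *non-linear* monotone
  transform can move mass across the fixed sub-range boundaries and is not
  an invariance of the method.
* **Polarity.** Nuclei are the *high* side of the final cut because nuclei
  absorb more Haematoxylin, hence higher OD/amount. Users feeding raw
  transmitted intensity (bright nuclei low) must invert first.
* **Mode filter** (`mode_filter()`): each pixel takes the most frequent value
  in the `(2r+1)²` window, `r = 3` by default (set empirically in the source
  experiments). Windows are clipped at borders — no padding value could be
  neutral — and ties break to the smallest value, which is deterministic and
  orientation-free.

## Texture model and MRF segmentation

The single texture feature is the blue channel: Haematoxylin stains nuclei
blue in both H&E and IHC material, and nuclear texture is the dominant cue
for carcinoma, so blue outperforms grey/red/green composites on low-contrast
lung tissue. Each class is a Gaussian `N(μ_λ, σ²_λ)` estimated from
user-drawn training regions.

* **Variance denominator** is `n` (population variance). At realistic
  training-region sizes (hundreds to tens of thousands of pixels) the
  `1/(n−1)` distinction is far below the noise floor of the energy.
* **Variance floor** `σ²_min = 1` intensity² keeps the singleton energy
  finite when a user traces a constant region.
* **Four classes, merged to three.** Stroma and lymphoid/necrosis have
  distinct morphologies; modelling them separately and merging to
  "non-tumour" after labelling segments tumour better than a single
  non-tumour class. The engine itself accepts any k ≥ 2.

The posterior energy of a labelling is the sum of singleton terms
`log σ + (f−μ)²/2σ² + log(2π)/2` (the exact negative log Gaussian density —
the constant cancels between labels but keeps the energy interpretable) and
Potts pair potentials `∓β` over neighboring sites.

* **β = 0.9** weights the prior; this is the experimentally chosen operating
  value. β is a single multiplier on the pairwise term; an equivalent
  reading that scales the potential magnitude differs only by
  reparameterization.
* **Potts form ±β** (reward −β, penalty +β). The 0/+2β convention shifts the
  energy by a constant per clique and has identical minimizers.
* **Neighborhood**: 8-connected by default (richer smoothing for texture),
  4-connected available. Total energy counts each unordered pair once; the
  local energy at a site sums over all its neighbors, so local differences
  equal global differences.
* **Relaxers.** Metropolis annealing is the default (it produced the best
  segmentations among the four schemes in the source experiments): per
  sweep, each site in a fresh random permutation receives a uniformly random
  different label, accepted if ΔU ≤ 0, else with probability `exp(−ΔU/T)`.
  ICM is deterministic raster-order coordinate descent; Gibbs resamples each
  site from its local conditional; MMD replaces the Metropolis coin by a
  fixed threshold α (default 0.3; the source gives none) — a move is
  accepted iff `exp(−ΔU/T) ≥ α`. Proposals are single-site; sweeps visit
  every site once.
* **Schedule** (nothing is prescribed): `T₀ = 4`, geometric cooling 0.98 per
  sweep, stop when fewer than 10⁻⁴ of sites change in a sweep or after 1000
  sweeps. On the synthetic suites this converges in one to a few hundred
  sweeps; megapixel images finish in minutes.
* **Initialization** is the per-site singleton argmin (the maximum-likelihood
  labelling). It is deterministic, a strong start, and makes the β = 0 limit
  exact: with the prior off, every relaxer returns exactly this labelling.
* Stochastic relaxers return the best labelling seen, so the result's energy
  never exceeds the initial energy; all randomness flows from R's RNG, so
  runs are bit-reproducible from a seed.

## Evaluation

Scoring is strictly pixel-based; object-level scoring (an object counts once
k% of it is right) inflates results. `confusion_counts()` takes tumour as
positive, with two open points resolved as follows:

* **False-positive rate** is `FP/(FP+TN)`, the complement of the TN rate.
  The alternative `FP/(FP+TP)` is available under `fp_rate = "vs_tp"` but is
  inconsistent with the rate identities `tp+fn = 1`, `tn+fp = 1` that the
  complement definition satisfies by construction.
* **Background pixels** in the ground truth are excluded from scoring by
  default (the task is cancerous-cell segmentation within tissue);
  `background = "non_tumour"` scores them as negatives instead. Don't-care
  exclusion masks remove regions too ambiguous for an expert to call.

## The synthetic data, and what it shows

No slides ship with the package, so validation uses `simulate_core()`:

* a blobby 4-class layout from a Gaussian random field smoothed with sd 8 px
  and cut at the quantiles of the target area fractions (tumour 0.35,
  stroma 0.30, lymphoid/necrosis 0.15, background 0.20 — a plausible
  carcinoma-core mix), so areas match targets almost exactly;
* blue-channel texture drawn i.i.d. `N(μ_class, σ²)` with means
  40/100/160/220; σ = 15 is the well-separated "easy" condition, σ = 35 the
  overlapping "hard" condition where the Potts prior visibly beats raw
  maximum likelihood;
* full RGB composed through the Lambert–Beer model from per-class H&E
  amounts, with the blue channel replaced by the Gaussian texture so the
  feature obeys the class model exactly;
* training masks eroded 2 px inside each class (guaranteed pure), and
  optional blobby exclusion masks.

The generator matches the segmentation model's assumptions *by
construction*. That makes planted-truth accuracy a clean test of the
machinery — estimator, energies, optimizer, bookkeeping — but it says
nothing about model mismatch on real tissue: real texture is spatially
correlated, class-conditionally non-Gaussian, and stain vectors drift.
Passing the synthetic suites is necessary, not sufficient, for performance
on slides.

Problem sizes used by the test-suite and the acceptance script: 512×512 for
the easy recovery run, 256×256 for the hard suite and the end-to-end
pipeline, 160×160 planted-disk images for nuclei extraction, and 2×2 / 2×3
rasters for exhaustive energy enumeration — sizes at which the brute-force
oracles stay exact and the stochastic checks are comfortably stable.

## Known limitations

* Stain vectors are fixed inputs; there is no unsupervised stain-matrix
  estimation or spectral imaging support.
* The nuclei mask is an auxiliary architectural output; it is not coupled
  into the MRF (no such coupling is defined in the underlying method).
* Single-feature texture: only the blue channel; no multi-feature
  descriptors.
* No nucleus instance splitting or morphometry; no whole-slide pyramidal
  formats; β is fixed, not estimated; no graph-cut or belief-propagation
  optimizers.
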