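# tmaseg

Supervised pixel-based tumour segmentation for tissue-microarray (TMA) core
images, for both routine histochemical (H&E) and bright-field
immunohistochemical (IHC/DAB) staining.

TMA studies stain hundreds of small tissue cores per slide; deciding which
pixels of each core are cancerous cells is the bottleneck both for TMA
construction (verifying that a core still contains tumour) and for automated
biomarker quantification (which must exclude stroma). `tmaseg` implements a
complete segmentation pipeline for this problem, scored pixel by pixel rather
than by blobs or objects.

## Method

**Stain separation.** Transmitted light obeys the Lambert–Beer law, so the
per-channel optical density `OD_C = -log10(I_C / I0_C)` is linear in stain
amount. Each stain is a unit vector in OD–RGB space; stacking them gives the
stain matrix `M`, and multiplying OD pixels by `D = M^-1` (color
deconvolution) recovers per-stain amount maps. Two-stain systems (H&E, H-DAB)
are padded with a unit residual vector orthogonal to both stains.

**Nuclear architecture.** The Haematoxylin amount map is quantized to 8 bits;
its histogram is split into four equal-width sub-ranges and a Kapur
maximum-entropy cut `argmax_t E(P[lo..t]) + E(P[t+1..hi])` is found in each,
giving eight intensity layers; a second two-class entropy cut on the layer
histogram separates nuclei from non-nuclei; a 7×7 neighborhood mode filter
removes spurious detections.

**Texture segmentation.** The blue channel is the texture feature. Four
classes — tumour, stroma, lymphoid/inflammatory-necrosis, background — are
learned from user-drawn training regions as Gaussians (mean, population
variance). A labelling `ω` is scored by the MRF energy

    U(ω) = Σ_s [ log σ_ωs + (f_s − μ_ωs)² / 2σ²_ωs ] + Σ_{s~r} V(ω_s, ω_r),

with Potts potentials `V = −β` for equal neighbor labels and `+β` otherwise
(β = 0.9, 8-connected). The MAP labelling is found by simulated annealing
(Metropolis; ICM, MMD and Gibbs sampling are also provided), and the two
non-tumour subtypes are merged for evaluation.

**Evaluation.** Pixel confusion counts against ground truth, with don't-care
exclusion masks; accuracy, TP/TN/FP/FN rates and precision.

Because the pipeline is supervised and slides are not distributed with the
package, a synthetic tissue-core generator (`simulate_core()`) plants a
blobby 4-class ground truth, Gaussian class textures and Lambert–Beer RGB
rendering, so every stage can be validated against a known answer.

## Worked example

```r
library(tmaseg)
sim <- simulate_core(synthetic_spec(256, 256), seed = 42)
res <- run_pipeline(sim$rgb, sim$train, sim$truth, seed = 42)
res$model
#> Gaussian class model (4 classes)
#>              class        mu   sigma2 n_train
#>             tumour  39.98560 224.9053   15835
#>             stroma  99.53103 222.0576    7461
#>  lymphoid/necrosis 160.26718 223.8035    1703
#>         background 219.81409 224.0083    8278
res$fit
#> MRF segmentation (metropolis), 256x256 sites, 143 sweeps, energy 73831.58, converged
round(res$metrics, 3)
#>  accuracy   tp_rate   fp_rate   fn_rate   tn_rate precision
#>     0.999     0.999     0.000     0.001     1.000     1.000
```

The learned means/variances recover the planted class parameters
(40/100/160/220, σ² = 225), and the merged tumour/non-tumour labelling agrees
with the planted truth at 99.9% of scored pixels. Nuclei extraction works on
any Haematoxylin amount map; on planted disks (amount 1.2 on a 0.1 field,
noise σ = 0.05):

```r
nuc <- extract_nuclei(haem)   # haem: H channel of color_deconvolve()
sum(nuc$mask)                 #> 1763 nuclei pixels, Jaccard 0.94 vs truth
```

A thin command-line front end with subcommands `deconvolve`, `nuclei`,
`train`, `segment`, `evaluate`, `simulate` and `pipeline` is installed at
`inst/cli/tmaseg` (see `system.file("cli", "tmaseg", package = "tmaseg")`).

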