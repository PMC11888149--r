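# wceseg

Pixel-level segmentation of **clean** versus **contaminated** regions in
wireless capsule endoscopy (WCE) frames, for quantifying small-bowel
visualization quality (SBVQ).

During a capsule endoscopy procedure the swallowed camera records hours of
frames, many of which are partly or fully obscured by bubbles, bile, food
residue and turbid fluids. Gastroenterologists comparing bowel-preparation
regimens — or triaging frames for review — need an objective, reproducible
measure of how much mucosa is actually visible. Deep segmentation networks
can provide one, but demand thousands of pixel-annotated frames; annotation
budgets in this domain are tiny. `wceseg` implements the opposite trade-off:
a **two-class tri-variate Gaussian Bayes classifier (GBC)** over raw RGB pixel
intensities with **26 learned parameters**, fit from as few as 20 annotated
frames chosen by a color-clustering selection protocol.

## The model

Each pixel is an observation `x = (r, g, b)` on the 0–255 scale. For the two
classes `k ∈ {clean, contaminated}` the classifier learns:

- the **prior** `p(y = k)` — the fraction of training pixels in class `k`;
- the **class-conditional likelihood** `p(x | y = k) = N(x; μ_k, Σ_k)`, a
  tri-variate Gaussian with a full 3 × 3 covariance (RGB channels are
  correlated in tissue).

A pixel is assigned by the Bayes rule to

```
k* = argmax_k  p(x | y = k) · p(y = k) / p(x)
```

which gives both a hard mask and a posterior probability map (the evidence
`p(x)` is computed, not dropped, so the map is a true probability usable for
AUROC). That is 2 priors + 2 × (3 means + 9 covariances) = **26 numbers**.
The clean-pixel fraction of the predicted mask is the SBVQ score.

Around the classifier the package provides the full experimental pipeline:

| module | what it does |
|---|---|
| `read_image` / `read_mask` / `write_mask` / `circular_fov` | 8-bit PNG I/O, white = clean masks, optional circular field-of-view |
| `rgb_to_cielab`, `histogram_3d`, `cluster_frames`, `select_representatives` | frame selection: 512-bin 3-D CIELAB histograms + K-means (K = 20), one random frame per cluster |
| `gbc_fit`, `gbc_segment`, `gbc_posterior`, `save_gbc` / `load_gbc` | model fitting, pixel classification, JSON serialization |
| `apply_fog`, `apply_gaussian_noise`, `apply_defocus`, `apply_motion_blur`, `apply_brightness`, `apply_color_jitter`, `corrupt_dataset` | six parametric degradation simulators for robustness studies |
| `confusion_counts`, `metrics_from_confusion`, `auroc`, `aggregate_metrics`, `clean_fraction_correlation`, `run_trials` | per-image accuracy, precision, specificity, sensitivity, AUROC, Dice, IoU, clean-fraction Pearson agreement; repeated-trial protocol |
| `scene_config`, `generate_scene`, `generate_corpus`, `bayes_risk_mc` | synthetic WCE-like scenes with known ground truth and known class distributions |

## Worked example

Everything below runs on synthetic scenes — no downloads needed. The
generator plants spatially coherent contamination blobs inside a circular
field of view and samples pixel colors from known class Gaussians, so ground
truth is exact.

```r
library(wceseg)

corpus <- generate_corpus(100, config = scene_config(height = 96, width = 96), seed = 1)
images <- lapply(corpus$scenes, `[[`, "image")
masks  <- lapply(corpus$scenes, `[[`, "mask")
fov    <- corpus$scenes[[1]]$fov

# 5 rounds: re-cluster, pick 20 representative frames, fit, evaluate the rest
reports <- run_trials(images, masks, n_trials = 5, k = 20, seed = 42, fov = fov)
reports[[1]]
#> <trial_report> 80 images
#>   accuracy             0.9996 +/- 0.0002
#>   precision            0.9993 +/- 0.0010
#>   specificity          0.9996 +/- 0.0006
#>   sensitivity          0.9996 +/- 0.0004
#>   auroc                1.0000 +/- 0.0000
#>   dsc                  0.9995 +/- 0.0006
#>   iou                  0.9989 +/- 0.0012
#>   clean_fraction_pred  0.5262 +/- 0.2642
#>   clean_fraction_gt    0.5262 +/- 0.2644

fit_idx <- attr(reports[[1]], "fit_indices")
model <- gbc_fit(images[fit_idx], masks[fit_idx], fov = fov)
model
#> <gbc_model> two-class tri-variate Gaussian Bayes classifier
#>   clean        prior 0.4825  mean (185.0, 115.0, 110.0)  n = 69,783
#>   contaminated prior 0.5175  mean (150.0, 140.0, 70.0)  n = 74,857
#>   26 learned parameters, covariance ridge epsilon = 0.001

seg <- gbc_segment(images[[99]], model, fov = fov)
clean_fraction(seg$mask, fov)   # predicted SBVQ score: 0.2907
clean_fraction(masks[[99]], fov) # annotated:           0.2904
```

The per-trial means are near-perfect here because the default palettes are
widely separated (Mahalanobis distance ≈ 6.8); with overlapping palettes the
error converges to the mixture's Bayes risk — see the methods vignette
(`vignettes/gbc-segmentation.Rmd`).

A command-line front end covering the same pipeline (simulate,
select-frames, fit, segment, corrupt, evaluate, run-trials) is installed at
`exec/wceseg`; see its header for usage.

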