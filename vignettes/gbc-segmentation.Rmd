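---
title: "Gaussian Bayes segmentation of capsule endoscopy frames: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gaussian Bayes segmentation of capsule endoscopy frames}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wceseg)
```

## The problem and the model

Wireless capsule endoscopy frames are frequently obscured by bubbles, bile,
debris and turbid fluid. Quantifying the *clean fraction* of each frame — the
share of pixels showing visible mucosa — gives an objective small-bowel
visualization quality score, but pixel-annotated training data in this domain
is scarce and expensive.

`wceseg` treats the problem as per-pixel two-class classification on raw RGB
intensities. For each class $k \in \{\text{clean}, \text{contaminated}\}$ the
model consists of a prior $p(y=k)$, estimated as the fraction of training
pixels carrying that label, and a tri-variate Gaussian class-conditional
density

$$p(x \mid y = k) = \mathcal{N}(x;\, \mu_k, \Sigma_k), \qquad x = (r, g, b)
\in [0, 255]^3,$$

with a full $3\times3$ covariance because the color channels of tissue are
strongly correlated. Classification is by maximum posterior,
$k^* = \arg\max_k p(x \mid y=k)\, p(y=k) / p(x)$, i.e. quadratic discriminant
analysis with two classes. The model has exactly 26 learned numbers
(2 priors, two 3-vector means, two $3\times3$ covariances), which is what
makes it usable when only ~20 annotated frames exist.

Key modeling assumptions, all inherited from the pixel-wise design:

* pixels are conditionally independent given their class — no spatial prior,
  no texture or shape features;
* each class's color distribution is unimodal Gaussian on the raw 0–255
  scale (no normalization to $[0,1]$; the decision is invariant to affine
  rescaling anyway, and raw counts keep the parameters interpretable);
* the classes are defined by color alone, which is also why the model is
  expected to be — and is, see below — most sensitive to color-shifting
  degradations and least sensitive to blur.

## Frame selection on an annotation budget

To spend a budget of $K$ annotated frames well, the corpus is grouped by
color content and one frame is drawn per group:

1. each frame is converted from sRGB to CIELAB (D65 white point) and binned
   into a 3-D histogram with 8 bins per channel over the *fixed* ranges
   $L \in [0, 100]$, $a, b \in [-128, 127]$ — 512 bins flattened L-major.
   Fixed absolute bin edges (not per-image ranges) keep bins comparable
   across frames; histograms are L1-normalized so corpora with mixed
   resolutions are comparable;
2. the feature vectors are clustered by K-means with $K = 20$, k-means++
   initialization, 10 restarts, at most 300 Lloyd iterations, and
   lowest-index tie-breaking in the assignment step so results are a pure
   function of the seed. An empty final cluster raises an error advising a
   smaller $K$ rather than silently reseeding;
3. one frame per cluster is selected uniformly at random; the remainder is
   the evaluation set. On a 2000-frame corpus this produces the 20 / 1980
   fit/evaluation split used throughout.

The number of bins (8) and clusters (20) are protocol constants; the package
exposes both as arguments but the defaults are the studied configuration.

## Estimation and numerics

* **Covariance estimator.** Unbiased $1/(N-1)$ by default (`unbiased = FALSE`
  switches to $1/N$); with $10^4$–$10^6$ training pixels per class the two
  differ negligibly, but the unbiased form matches the usual sample-covariance
  convention.
* **Regularization.** $\Sigma_k \leftarrow \Sigma_k + \epsilon I$ with
  $\epsilon = 10^{-3}$ (squared intensity counts). This exists purely to keep
  $\Sigma_k$ positive definite under degenerate annotations (e.g. a constant
  color region); it is far below the $\sim 10^2$ scale of real covariance
  entries and does not influence results on non-degenerate data. Fitting
  demands at least 4 pixels per class; fewer cannot identify a covariance.
* **Likelihood evaluation.** Always in log space through the stored Cholesky
  factor — no explicit inverse or determinant. Posteriors are normalized by
  log-sum-exp, so the evidence is computed rather than dropped and the
  probability map is a genuine posterior, which is what makes pixel AUROC
  meaningful.
* **Ties.** A pixel with exactly equal posteriors is labeled clean, the
  positive class; with continuous inputs this is a measure-zero event, but
  the rule is fixed for determinism.
* **Serialization.** Models round-trip through JSON with 17 significant
  digits, which reproduces the double-precision parameters bit-exactly, so a
  reloaded model yields identical posteriors.

## Degradation simulators

Six parametric corruptions reproduce common WCE capture problems. None of
them displaces pixels — blurs are shift-invariant convolutions, not warps —
so ground-truth masks remain valid for degraded frames.

| scenario | parameters (sampled range) | notes |
|---|---|---|
| fog | intensity $\in [0.25, 1]$, per-disk transparency $0.05$ | soft white disks, Poisson count proportional to intensity and frame area; coverage grows monotonically with intensity |
| Gaussian noise | variance $\in [5, 300]$ | added per channel in real arithmetic, then rounded and clipped |
| defocus | disk radius $\in [1, 8]$ px | normalized disk point-spread function with an anti-aliased edge; reflective borders |
| motion blur | angle $\in \{0°, 15°, \dots, 345°\}$, length $\in [1, 25]$ px | normalized anti-aliased line kernel; opposite angles are canonicalized modulo 180° so they are bit-identical |
| brightness | $\gamma \in [0.75, 1.25]$ | power law $S = r^{1/\gamma}$ on normalized intensities; $\gamma > 1$ brightens. Note this pairing of exponent and direction is the package's convention and differs from classical "gamma correction" ($S = r^\gamma$) |
| color jitter | H, S, V shifts each $\in [-5, 5]$ | 8-bit HSV convention: H in half-degree units (0–179, wraps), S and V in 0–255 (clip) |

Design choices where the protocol left freedom:

* **Defocus radius range** $[1, 8]$ px spans mild to severe blur at the
  336-pixel frame scale; the radius is the knob, the anti-aliased edge is
  fixed.
* **Noise variance range.** The simulator enforces $[5, 300]$; the range is
  an argument (`check_range = FALSE` lifts it) because narrower ranges such
  as $[5, 50]$ are also plausible study conditions.
* **Hue shift units.** "±5" is interpreted on the half-degree 0–179 scale —
  the standard 8-bit HSV convention — i.e. ±10° of hue.
* **Fog geometry.** Disk count, radii and the soft edge profile are package
  choices; only the intensity range and the 0.05 transparency are protocol
  constants.

Convolution uses FFT filtering on a reflect-padded copy of the frame, so
borders neither darken nor wrap.

## Evaluation conventions

Clean is the positive class everywhere. Per image, the package computes
accuracy, precision (PPV), specificity (TNR), sensitivity (clean recall),
Dice (DSC, = pixel F1), IoU, rank-based AUROC of the clean posterior with
midrank tie handling, and the clean fractions of prediction and ground truth.

* **Per-image, then aggregate.** Metrics are computed per frame and then
  averaged (mean ± sample SD across frames). Pooling all pixels first would
  be the other defensible reading; per-image is used because frame-level
  spread is the quantity of clinical interest, and the package reports
  per-image tables so either aggregation can be recomputed. The same
  convention applies to AUROC (per-image, then averaged).
* **Undefined metrics.** A metric whose defining ratio is $0/0$ (e.g.
  specificity on an all-clean frame) is `NA`, excluded from aggregation, and
  counted — never coerced to 0 or 1.
* **Repeated trials.** `run_trials()` repeats the complete protocol
  (re-cluster with a fresh derived seed, select, fit, evaluate the rest) the
  requested number of times; the clustering is re-run each round rather than
  reusing a fixed grouping.
* **Agreement.** `clean_fraction_correlation()` reports Pearson's $r$ between
  predicted and annotated clean fractions across frames.

## The synthetic scene generator

Real annotated WCE corpora cannot ship with a package, so all testing runs on
generated scenes with exact ground truth:

* a circular field of view (FOV) emulates the dark corners of capsule
  frames; pixels outside it are black and labeled contaminated. FOV
  restriction is **off by default** in fitting and evaluation — annotated
  regions are taken at face value — and opt-in via the `fov` argument, which
  is the right setting for these synthetic scenes;
* contamination is spatially coherent: a superposition of `n_blobs` random
  anisotropic Gaussian bumps is thresholded at the in-FOV quantile matching
  the target contamination fraction, so the realized fraction equals the
  target up to pixel quantization and blob shapes resemble annotated regions
  (which makes Dice/IoU behave as they do on real masks);
* colors are sampled i.i.d. per pixel from the class Gaussians, rounded and
  clipped to 8 bits. The default palettes — clean pinkish
  $\mu = (185, 115, 110)$, contaminated yellow-green $\mu = (150, 140, 70)$,
  correlated covariances, Mahalanobis separation $\approx 6.8$ — are package
  defaults emulating the qualitative appearance of mucosa versus luminal
  content, not measurements of any real corpus. Means sit $\ge 3\sigma$ from
  0 and 255 so clipping bias is negligible.

Because pixels are i.i.d. given the class, the generator matches the GBC's
own assumptions exactly. That is deliberate: it makes error rates analytically
predictable (the observed pixel error converges to the mixture's Bayes risk,
computable by `bayes_risk_mc()`), so tests can check the implementation
against theory. The flip side is what passing tests do *not* show: real
mucosa has spatial correlation, texture, specular highlights and bubble
geometry that the generator deliberately omits, so performance numbers on
synthetic corpora say nothing quantitative about clinical images — they
validate the machinery, not the clinical claim.

## Study conditions used by the test suite and acceptance script

Problem sizes are chosen so the full suite runs in about a minute while still
exercising asymptotic claims:

* selection protocol: 2000 scenes at 48² (script) / 32² (tests), K = 20;
* parameter recovery: $10^6$ pixels per class (means recovered to ±0.5
  counts, covariances to 2% relative Frobenius error);
* Bayes-risk agreement: ~$10^6$ FOV pixels at 256², against a $10^6$-draw
  Monte-Carlo risk, on overlapping palettes (clean $\mu = (175,120,105)$ vs
  contaminated $\mu = (158,132,88)$, separation $\approx 2.4$, risk
  $\approx 6\%$);
* corruption volume: 200 frames × 6 scenarios, verifying the
  $|{\rm out}| = 6\,|{\rm in}|$ law that scales to 2000 × 6 = 12000;
* robustness ordering: on the overlapping palettes, mean Dice under color
  jitter at maximal shifts is compared against defocus at the mid-range
  radius 4.5 px. The ordering (jitter hurts at least as much as blur) is the
  expected signature of a color-only classifier: blur averages i.i.d. color
  noise within regions and only mixes classes near boundaries, while a color
  shift moves every pixel relative to the fitted densities. On widely
  separated palettes both effects are within rounding of zero, so the
  comparison is run where the classifier has a margin to lose.

## Known limitations

* No spatial regularization: the predicted masks are per-pixel and can be
  speckled near the decision boundary; real pipelines may want morphological
  cleanup, which is out of scope here.
* Two classes only, single Gaussian per class; multimodal contamination
  (e.g. dark bile *and* bright froth in one corpus) strains the unimodality
  assumption.
* The CIELAB conversion uses `grDevices::convertColor`, whose sRGB matrix
  differs from the IEC constants in the third decimal; irrelevant at the
  12.5-unit bin width used for clustering.
* Degradation operators are calibrated for plausibility, not radiometric
  fidelity; they are stress tests, not forward models of capsule optics.
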