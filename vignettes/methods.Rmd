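---
title: "Tissue-component mapping and texture-based grading: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tissue-component mapping and texture-based grading: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Whole-mount radical-prostatectomy sections stained with hematoxylin and
eosin carry the information a pathologist uses to find and grade prostate
cancer: gland architecture, nuclear density, and the balance of stroma,
nuclei and open gland lumina. `histotcm` implements a classical
(non-deep-learning) pipeline for this task. Each slide is partitioned into
480 µm × 480 µm regions of interest (ROIs, 960 × 960 px at the nominal
0.5 µm/px scan resolution); each ROI is reduced to a three-class
*tissue-component map* (TCM: nuclei / lumina / other); the TCM is
summarized by a fixed 156-element texture descriptor; and conventional
classifiers decide, per ROI, cancer vs. non-cancer (*detection*) and high-
vs. low-grade cancer (*grading*), evaluated with leave-one-patient-out
(LOPO) cross-validation.

## Tissue-component mapping

**Color deconvolution.** RGB transmittance is converted to optical density
per channel, `OD = -log10((v + eps) / (1 + eps))` with `eps = 1/256` so
saturated pixels stay finite (white maps exactly to zero), and unmixed with
the inverse of the row-normalized Ruifrok–Johnston H&E stain matrix. The
residual (third) stain vector is the unit cross product of the hematoxylin
and eosin vectors. Negative unmixed concentrations are clamped to zero.

**Slide-adaptive nucleus threshold.** Stain intensity varies between
slides, so a global hematoxylin cutoff fails. Per slide, 2000 tiles of
120 µm × 120 µm are sampled uniformly at random (tiles whose mean RGB is
≥ 0.9 are rejected as background; an optional hue/saturation band filter
rejects marking dye, off by default for synthetic data). All tile
hematoxylin values are pooled into one 256-bin histogram spanning the
observed range, and the nucleus threshold is that histogram's Otsu
threshold. Two numerical conventions matter: bins track the data range, so
the threshold is exactly scale-equivariant; and the between-class variance
is flat across an empty histogram gap, so tied maximizing cuts are
averaged, placing the threshold mid-gap rather than at the gap's edge. A
constant pooled histogram (a blank slide) is an error, not a threshold.

**Red-blood-cell suppression.** RBCs take up hematoxylin and would be
segmented as nuclei, but are far redder. Seed pixels satisfy hue ≥ 0.95,
saturation ≥ 0.72 and value ≥ 0.60; the seed mask is dilated with a disk of
radius 4 µm (an erythrocyte's approximate radius; pixels whose center
distance is at most the radius, converted to pixels with round-half-up at
the working resolution) and subtracted from the nucleus map. The color
model is hue-saturation-**value** (`grDevices::rgb2hsv`). This is a
deliberate choice: under the HSI variant with intensity = mean(R,G,B) and
saturation = 1 − min/I, the three thresholds jointly delimit an *empty*
region of RGB space — no color can satisfy them, which we verified by
exhaustive grid search — whereas under HSV a typical blood red
(0.80, 0.12, 0.20) maps to (0.98, 0.85, 0.80) and is accepted.

**Lumina and composition.** Lumina are near-white: a pixel is luminal iff
R ≥ 0.86, G ≥ 0.71 and B ≥ 0.82. Each ROI is first downsampled by the
nearest-neighbor ratio 0.25 (output pixel *i* reads source pixel
`floor((i - 0.5)/ratio) + 1`, so a 960 px ROI becomes exactly 240 px at an
effective 2 µm/px); all mapping then runs at this working resolution,
including the RBC dilation radius. The TCM assigns nuclei (code 1), lumina
(code 2) and other (code 3); nuclei take precedence over lumina on the rare
overlapping pixel, because hematoxylin evidence is more specific than
near-white color. Every pixel receives exactly one code.

## The 156-feature descriptor

The descriptor concatenates, in fixed order:

* **24 first-order statistics** — {mean, variance, skewness, kurtosis,
  energy, entropy} on four derived images: the coded 3-level map and the
  three per-class binary indicator maps. Variance is the population moment;
  skewness/kurtosis are standardized third and fourth moments, defined as 0
  on a constant image; energy and entropy are taken on the discrete value
  histogram (a constant image has energy 1, entropy 0). The source
  publication does not enumerate its 24 first-order statistics; this
  6 × 4 scheme is our declared interpretation, isolated behind the named
  feature schema so an alternative set is a drop-in.
* **22 co-occurrence statistics × 4 directions** — grey-level co-occurrence
  matrices over the three TCM codes (no requantization) at neighbor
  distance 1 for offsets (0,1), (−1,1), (−1,0), (−1,−1), accumulated
  symmetrically and normalized, kept per direction (no averaging across
  directions). The statistic set is the widely used 22-statistic collection
  (Haralick's measures plus the Soh–Tsatsoulis and Clausi additions), again
  a declared stand-in for an unenumerated original. Note two of the 22
  (the two correlation definitions) are algebraically identical; the set is
  kept intact for fidelity to the conventional collection, and downstream
  linear algebra is ridge-guarded against the resulting collinearity.
* **11 run-length statistics × 4 directions** — run-length matrices of
  maximal constant-code runs along each direction's scan lines, summarized
  by SRE, LRE, GLN, RLN, RP, LGRE, HGRE, SRLGE, SRHGE, LRLGE, LRHGE.

Entropies use the natural logarithm. Statistics undefined on a degenerate
matrix (zero marginal variance, all-zero matrix) map to 0 with a warning,
so every descriptor is finite, including on single-class maps. Tests
validate both matrices and all statistics against brute-force enumerations
on random maps to 1e-10.

## Feature selection

Backward elimination on a tuning cohort: starting from all features,
repeatedly remove the single feature whose removal maximizes the pooled
LOPO AUC of a Fisher linear discriminant, down to one feature; the chosen
subset is the AUC-maximizing point of the trace. The stopping rule is not
specified by the source, so the trace runs to exhaustion and the subset
size is data-dependent rather than hard-coded. Ties during removal drop
the feature with the larger column index (deterministic and order-stable);
ties in the final choice prefer the smaller subset. Folds whose training
half contains a single class are excluded with a warning.

## Classifiers, balancing, calibration

Features are standardized to zero mean / unit variance with training
statistics before every classifier (SVM hyperparameters are
scale-sensitive; whether the original standardized is unknown, so the
choice is made explicit here).

* **Fisher** — least-squares linear discriminant
  `w = Sw^-1 (mu1 - mu0)` on the pooled within-class covariance; a
  singular covariance falls back to a ridge (1e-6) with a warning.
* **Logistic** — linear logistic regression by weakly ridge-penalized
  likelihood (glmnet, alpha 0, lambda 1e-3). With 156 features a balanced
  training fold is often linearly separable and the maximum-likelihood
  estimate does not exist; the weak penalty keeps the fit defined and
  coincides with ML when ML exists.
* **SVM** — for detection, a nu-SVM with RBF kernel (gamma 0.50625,
  nu 0.5); the published "cost = 12.5" is stored verbatim although a nu-SVM
  is parameterized by nu, not cost — an inconsistency inherited from the
  source description. For grading, a C-SVC with linear kernel (cost 2.7;
  the published gamma 0.03375 is stored but inert for a linear kernel).

Training sets are balanced per task: detection subsamples negatives
without replacement down to the positive count (negatives dominate a
prostatectomy cohort); grading duplicates the minority class with
replacement up to the majority count. Confidence calibration is not
specified by the source; Fisher and SVM scores are passed through a
logistic link fitted on training-set decision values (logistic is natively
probabilistic), giving all three classifiers a common [0, 1] confidence
scale on which the fixed 0.5 operating point is meaningful.

## Ground truth and evaluation

ROI labels derive from integer annotation masks with a 0.5 area rule: an
ROI is cancerous iff the summed fraction of the nine cancerous codes
(G3 … G5+3 and extraprostatic extension) reaches 0.5. The source states
"more than 50%" in one place and "≥ 50%" in another; we use ≥ so an exact
half resolves deterministically. Grading experiment G4-vs-G3 takes ROIs
with ≥ 50% G4 as positive and ≥ 50% G3 as negative; G4&G5-vs-G3 pools G4,
G4+5, G5, G5+4 as the positive source. Mixed G3+4 / G4+3 regions are used
for detection but excluded from grading; G5+3 and EPE are likewise
excluded from grading by default (their membership is unstated in the
source). Tiles extending past the slide edge are discarded — partial tiles
would distort area fractions.

Evaluation is leave-one-patient-out: one fold per patient, all of a
patient's ROIs on one side, with an assertable integrity check that no
patient straddles a fold. The ROC is pooled over all folds' confidences
(not averaged per fold, per the cumulative-confidence convention) with a
threshold sweep and trapezoidal AUC, which equals pairwise concordance with
half credit for ties (validated against brute force to 1e-12 and against
pROC). Cumulative error rate, FNR and FPR are reported at the 0.5
operating point, plus a per-tissue-type table (FNR for cancerous types,
FPR for non-cancerous, with per-type counts) and white/black
(detection) or white/grey/black (grading) whole-slide label-map renderings.

## The synthetic generator

The generator exists so every stage is testable with known ground truth;
it emulates the appearance cues the pipeline exploits, not photorealism:

* dark basophilic nuclei (hematoxylin OD 0.85), pink eosin stroma
  (eosin OD 0.30), near-clear lumina, rendered through the *same* forward
  Beer–Lambert model and stain matrix the pipeline inverts, so
  deconvolution has an analytic round trip;
* class-dependent morphology: benign tissue has sparse nuclei
  (300 /mm²) and a few large open glands (8 /mm², 24 µm lumina); low-grade
  cancer has separate round glands ringed by nuclei (25 /mm², 20 µm) and
  moderate nuclear density (900 /mm²); high-grade cancer has many small,
  possibly fused glands (45 /mm², 9 µm) and crowded nuclei (2200 /mm²);
* per-patient stain brightness multipliers drawn from [0.8, 1.2], so the
  per-slide adaptive threshold has real work to do;
* red-blood-cell blobs painted blood-red (HSV 0.98/0.85/0.78) on top of
  the rendered tissue;
* additive Gaussian transmittance noise (sd 0.01), clipped to [0, 1].

Density and radius defaults were chosen once as histologically plausible
round numbers and are not calibration dials. Because compartments are
piecewise constant in concentration and the downsampler picks exact source
pixels, generator masks decimated with the same operator align with the
rendered image pixel-for-pixel; segmentation recovery (Dice) on this data
therefore probes thresholding and color logic, not boundary blur. Real
H&E — with focus blur, anti-aliased edges, chromatin texture inside
nuclei, touching nuclei and annotation noise — is harder, and passing
these tests does not certify clinical performance; they certify that the
implementation does what the method says.

Cohorts are planned lazily: `generate_cohort()` draws per-patient
brightness, per-tile classes (default mix 60% benign / 20% low-grade /
20% high-grade, a negative-majority cohort as in the clinical setting) and
per-tile sub-seeds; `build_slide()` materializes any slide bit-reproducibly
from its seeds. Annotation masks are label images (G3 ← low, G4 ← high,
Healthy/BPH ← benign); polygon contours are out of scope.

## Problem sizes and numerical choices

The default validation cohort used by the acceptance tests and the
acceptance script is 20 patients × 2 slides × 4×4 ROIs = 640 ROIs of
960 × 960 px, with segmentation-recovery studies of 50 (tests) or 25
(script) ROIs per class — sizes chosen so a complete run is a desk-scale
computation. Other fixed numerical choices, collected:

* optical-density floor `eps = 1/256`;
* µm→pixel conversion by round-half-up, always via the current working
  resolution;
* dilation disks rasterized as pixels with center distance ≤ radius;
* Otsu ties averaged (mid-gap placement), 256 bins;
* degenerate texture statistics map to 0; Fisher ridge 1e-6; logistic
  ridge lambda 1e-3;
* removal ties in backward selection drop the larger column index; final
  ties prefer the smaller subset;
* coordinates are 0-based, half-open, (row, col) order throughout.

## Known limitations

Slide-level or patient-level Gleason scoring is out of scope, as are
pyramidal/vendor slide formats, stain-vector estimation from data, nucleus
instance segmentation, wavelet/fractal features, co-occurrence distances
greater than 1, and all deep-learning arms. The 22-GLCM and 24-first-order
statistic identities are declared interpretations with matching counts, not
a verified reproduction of the original feature list.
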