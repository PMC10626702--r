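---
title: "Methods: texture-based discrimination of dental lesions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: texture-based discrimination of dental lesions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radiotex)
```

## The problem and the model

Radiolucent jaw lesions — cysts, tumors and abscesses — appear on panoramic
radiographs as darker regions whose *internal texture*, not just their mean
brightness, carries diagnostic information: cystic cavities tend to be
homogeneous, tumors show rough, high-variance internal structure, abscesses
sit in between with diffuse borders. radiotex implements a classical texture
pipeline around that observation:

1. **preprocess** — Gaussian smoothing, 3×3 median filtering, percentile
   contrast stretch;
2. **ROI** — a fixed 40×40-pixel window centered on the lesion;
3. **features** — three families computed on the window:
   13 gray-level co-occurrence (GLCM) statistics, 7 gray-level run-length
   (GLRLM) statistics, and 5 moments of the 2-D Haar wavelet detail
   coefficients;
4. **classification** — a soft-margin kernel SVM on standardized features,
   lesion vs normal;
5. **evaluation** — confusion matrix, accuracy, MCC, sensitivity,
   specificity, PPV, and ROC/AUC.

Because the clinical radiographs behind this design were never deposited,
the package ships a first-class synthetic study generator; every stage is
exercised end to end on data the test suite can rebuild from a seed.

## Preprocessing

All three operators preserve shape and the `[0, 255]` integer range.

* **Gaussian smoothing** (`gaussian_smooth`): separable convolution with a
  normalized kernel, radius `ceiling(3*sigma)`, reflect (edge-duplicating)
  boundary. The smoothing scale was not specified by the protocol this
  reproduces; the default `sigma = 1` px gives mild denoising and is
  configurable.
* **Median filter** (`median_filter3x3`): the exact 5th order statistic of
  each 3×3 neighborhood, computed by a vectorized 19-exchange median
  network and verified against a brute-force sort.
* **Contrast stretch** (`contrast_stretch`): the `imadjust` convention —
  "1% of the data at the extremes" is read as 1% *per tail* (the MATLAB
  reading); the 0.01 and 0.99 quantiles (R type-7, linear interpolation
  between order statistics — a documented constant so tests are exact) map
  to 0 and 255, values outside clip, a degenerate flat image maps to
  mid-gray 127. The map is monotone.

The stage order Gaussian → median → stretch follows the narrative order of
the source protocol; it is configurable in `pipeline_config()`.

## Region of interest

`extract_roi()` uses the even-window convention: a 1-based center `(r, c)`
with `size = 40` spans rows `r-20 … r+19`. Out-of-bounds windows are errors,
never silently clamped. Lesion centers come from the annotation table (disk
format uses 0-based coordinates; the R API is 1-based). `regional_maxima()`
(8-connected plateaus strictly above all outside neighbors) is provided as
the QA/visualization operator it was in the original workflow; it is not on
the feature path.

## Co-occurrence features

`compute_glcm()` counts quantized gray-level pairs (`quantize()`:
`floor(p*G/256)`, default `G = 8` — a 40×40 patch yields ~1521 pairs per
angle, enough to populate 64 cells) at distance `d = 1` along the four
standard angles, symmetric by default. Neither `d`, the angles, nor `G` were
published; these defaults are standard Haralick practice and configurable.
Features are computed per angle and *averaged* (the alternative —
concatenating per-angle features — would contradict the fixed count of 13).
Indices run 0…G−1 in all moments.

The four reference-formula features are energy, contrast, correlation and
homogeneity; the printed correlation numerator is garbled in the source and
is implemented as the standard `sum(ij*P) - mux*muy`. The remaining nine use
the common co-occurrence definitions. One naming collision required a
decision: the published list names both *homogeneity* and *inverse
difference*, which coincide under one convention. Here `homogeneity` is the
printed `sum P/(1+|i-j|)` and `inverse_difference` is the squared-kernel
`sum P/(1+(i-j)^2)`; the *normalized* variants divide `|i-j|` by `G` and
`(i-j)^2` by `G^2`. The information measure is information measure of
correlation 1 with natural logs (the ratio is base-invariant). A constant
patch has undefined correlation; it is returned as 0 with a warning so batch
runs never abort.

## Run-length features

`compute_glrlm()` scans maximal constant runs along rows, columns and both
diagonal families, sharing `quantize()` and `G = 8` with the GLCM module for
comparability. The seven features (SRE, LRE, GLN, RLN, RP, LGRE, HGRE) were
named but not defined in the source; the classic Galloway/Chu formulas with
1-based level and length indices are used (0-based levels would divide by
zero in LGRE). Direction averaging mirrors the GLCM module.

## Wavelet features

`dwt2()` is a separable filter-bank transform: rows filtered with the
low/high-pass pair and downsampled, then columns, giving LL/LH/HL/HH per
level, recursing on LL. The filter was never named in the source; the
orthonormal Haar pair is the default — it is exact up to √2 factors, so
energy conservation and perfect reconstruction can be asserted at 1e−8 and
1e−10 — and the pair is an argument for anyone wanting another orthonormal
filter. Boundary extension is periodic. A 40×40 window is not a power of
two; each stage only needs even dimensions, so three levels work
(40→20→10→5). Other sizes error by default with the maximum feasible level,
or zero-pad under `pad = TRUE` (what `wavelet_feature_vector()` uses).

The five features pool *all* detail coefficients across levels and
orientations — forced by the published total of five — and are mean, sample
standard deviation, Fisher skewness (bias-uncorrected), excess kurtosis, and
mean absolute deviation. The source lists "dispersion" twice; sd + MAD is
this package's reading, documented rather than inferred as the original
intent. Zero-variance samples yield flagged zeros for skewness/kurtosis.

## Classification

The published protocol's "one-three-hold-out cross-validation" with split
percentages summing to 120% cannot be implemented as printed.
`split_dataset()` is a stratified single hold-out (default 2/3 train,
consistent with evaluating ~80 of 172 images) and `evaluate_method(repeats=)`
offers seeded repeated hold-out; both are labelled reconstructions.

No SVM implementation is assumed from the environment: `fit_svm()` solves
the C-SVM dual with an in-package SMO solver using maximal-violating-pair
working-set selection. The solver is deterministic, which is what makes
"refit ⇒ identical predictions" a hard guarantee rather than a seed
convention. Features are standardized with training-set statistics only
(information-leak test included). Defaults: RBF kernel, `C = 1`,
`gamma = 1/(p · mean variance)` of the standardized features — i.e. `1/p` —
with a linear kernel available. The binary task is lesion-vs-normal
(positive = abnormal, matching the reference TP definition); any pairwise
task can be configured through `positive_classes`.

## Evaluation

Metrics default to the printed reporting precision (integer percent,
2-decimal MCC; `digits = NULL` for full precision). Several published table
cells are inconsistent with standard rounding of their own confusion
matrices (e.g. a 98.75% accuracy printed as 98%); the package always
computes at full precision and reports both, and its worked examples are
restricted to the cells that standard rounding reproduces. Degenerate
denominators give flagged `NA`s (rates) or a flagged 0 (MCC), never silent
zeros or crashes. `roc_curve()` sweeps grouped score thresholds; the
trapezoidal AUC equals the Mann–Whitney statistic with half credit for
ties, checked against an O(n²) oracle.

## The synthetic study: what it emulates and what it does not

The study distribution defaults follow the reference cohort: 73 abscesses,
52 cysts, 27 tumors, 40 normals. (Those counts sum to 192 although the
source also states N = 172 and, elsewhere, a third incompatible breakdown;
the per-class counts are taken as authoritative.) Images default to
400×800 — panoramic radiographs are wide — which comfortably admits the
40×40 ROI.

A background is a smooth vertical brightness gradient (base 110, amplitude
30) plus a gentle horizontal sinusoid (amplitude 8) and i.i.d. Gaussian
noise (sd 6). Lesion texture is a stationary Gaussian random field —
white noise smoothed to a chosen correlation length, rescaled to a chosen
mean and sd — because the three feature families are functions of exactly
those properties (local pair statistics, run structure, detail-coefficient
moments). Class presets are fixed package constants chosen once to express
the radiological reading above: cyst (mean 70, sd 6, correlation 3 px,
feather 2 px), tumor (110, 30, 0.8 px, 1 px), abscess (90, 15, 1.8 px,
4 px). Ellipse semi-axes are uniform in 10–16 px so the lesion fills most
of the ROI; one lesion per image (multi-lesion films were never discussed
in the source). Every image gets a seed derived from the study seed, so a
study is bit-reproducible.

What a green end-to-end test establishes: the pipeline is internally
consistent and the feature families do carry the class signal the generator
encodes (held-out accuracy ≥ 0.85 on the default study). What it does
*not* establish: performance on clinical radiographs. The generator has no
anatomy — no teeth, mandible, spine shadow or exposure artifacts — and its
lesions differ from background in ways that are cleaner than real
radiolucencies. The published headline accuracies (98/95/91%) and AUCs
depend on the original images and are explicitly not reproduction targets;
only the metrics arithmetically determined by the published confusion
matrices are.

## Numerical conventions, in one place

* Quantile type 7 in the contrast stretch; reflect padding in both spatial
  filters; periodic extension in the wavelet transform.
* Ties in the median are exact (integer order statistics).
* GLCM moments use 0-based indices; GLRLM emphasis weights 1-based.
* SMO stopping tolerance 1e−3 on the duality-gap surrogate; intercept from
  free support vectors, else the midpoint of the feasible interval.
* Degenerate cases (flat patches, zero denominators, single-class inputs)
  are either flagged values or informative errors — chosen per operator and
  documented on its help page.
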