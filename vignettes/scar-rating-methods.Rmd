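---
title: "Methods: automated VSS rating from texture and color features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated VSS rating from texture and color features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scarvss)
```

## The problem

The Vancouver Scar Scale (VSS) rates a burn scar on four subscales —
pigmentation (0–2), vascularity (0–3), pliability (0–5) and height
(0–3) — whose sum (0–13) is the total severity score assigned by a
clinician. Ratings are subjective and show limited inter-rater
reliability, which motivates an automated rater: learn the mapping from
a scar photograph to its VSS total from clinician-labelled examples.

`scarvss` implements that pipeline. Each manually cropped scar
photograph is divided into a 3×3 grid of equal-size sub-images (a
standard sample-multiplication device for small image datasets), every
sub-image becomes one classification sample carrying its parent's VSS
total, and a combined texture + color feature vector is classified with
one-vs-one error-correcting output codes (ECOC). Performance is
measured by leave-one-out (LOO) cross-validation, with accuracy
reported exactly and at one- and two-score tolerance. Only color and
texture enter the features; the pliability and height subscales
describe mechanical and 3-D properties that a 2-D photograph cannot
capture, so the classifier learns the total score from the appearance
correlates alone.

## Feature blocks

All texture features are computed on the grayscale conversion
`gray = round(0.2989 R + 0.5870 G + 0.1140 B)` (ITU-R BT.601 luma
weights, rounding half away from zero — the convention of the numerical
environments this pipeline descends from). Color features use the RGB
pixels directly.

### Gray-level co-occurrence matrix (19 features)

Intensities are first quantized to `L = 8` equal-width levels spanning
the image's own min–max range. The co-occurrence count
`c_h(p, q)` is the number of ordered pixel pairs separated by the
offset `h = (0, 1)` — one pixel to the right — whose quantized values
are `(p, q)`; dividing by the total pair count `n(h)` gives the
co-occurrence probability `p_h(p, q)`. The matrix is deliberately
non-symmetric (a single rightward offset, exactly as specified for the
protocol). From `p_h` the canonical 19-feature vector is computed:
entropy, energy, correlation, contrast, sum of squares (variance), sum
average, sum variance, sum entropy, difference variance, difference
entropy, the first information measure of correlation, autocorrelation,
dissimilarity, homogeneity, cluster prominence, cluster shade, maximum
probability, inverse difference normalized, and inverse difference
moment normalized.

Numerical conventions, chosen where the protocol is silent and frozen
throughout: natural logarithms with `0·log 0 ≡ 0`; degenerate
denominators (zero marginal standard deviation, zero marginal entropy)
yield 0 rather than `NaN`; sum variance is centered on the *sum
average* (the widely used correction of the original formulation);
"information measures of correlation" counts as one feature (IMC1) so
the list totals exactly 19 — IMC2 is available via
`glcm_features(extras = TRUE)` but excluded from the canonical vector;
homogeneity is `Σ p/(1+|i−j|)` while feature 18 is its `L`-normalized
variant, so the two are not duplicates.

### Semi-variogram (20 features)

The directional semi-variogram
`γ(h) = Σ (f(x) − f(x+h))² / (2 m(h))` is half the mean squared
intensity difference over all `m(h)` pixel pairs at lag `h` along one
axis, computed on the *unquantized* grayscale image. It captures the
global spatial correlation structure: `γ` rises slowly with lag for
smooth fields and jumps immediately for rough ones. The feature block
concatenates `γ(1..10)` horizontally then vertically (isotropy is
assumed; anisotropic variogram models are out of scope). Useful
identities used as test anchors: a constant image has `γ ≡ 0`; a
unit-slope horizontal ramp has `γ(h) = h²/2`; `γ` is invariant to
adding a constant and scales by `a²` under intensity scaling by `a`.

### Local binary patterns (256 features)

The LBP code of a pixel thresholds `V = 8` neighbors sampled on the
circle of radius `R = 1` (neighbor 0 due east, counter-clockwise,
bilinear interpolation at the four diagonal positions) against the
center: bit `v` is set when `f_v − f_u ≥ 0`, so a constant patch codes
to `2^V − 1 = 255`. The feature block is the 256-bin relative-frequency
histogram of codes over all interior pixels — the raw-code convention
with no rotation-invariant or uniform-pattern mapping, keeping the full
local-structure information. Note LBP is invariant to overall contrast:
only the *ratio* of structured texture to noise, and the spatial scale
of the structure, move the histogram.

### Color features (12 + 12 + 12)

Per RGB channel: population (divide-by-`N`) central moments — mean,
variance, skewness `m₃/m₂^{3/2}` and non-excess kurtosis `m₄/m₂²`
(Gaussian → 3), with skewness and kurtosis defined as 0 for a constant
channel. The HSV block holds 4-bin histograms of hue, saturation and
value over the fixed range `[0, 1]` each (hue binned linearly, a
deliberate simplification — no circular wrap); the CIELAB block holds
4-bin histograms of `L*` over `[0, 100]` and `a*`, `b*` over
`[−128, 127]`. Bin edges are fixed by these nominal ranges rather than
per-image, so histogram features are comparable across samples; values
outside a range are clipped into it and the last bin is right-closed.
sRGB primaries under a D65 white point are assumed for the CIELAB
transform since no camera calibration data exist.

## Feature assembly and standardization

Any subset of the six blocks can be combined, named with the
field's `+`-notation, e.g. `"(LBP+SV)+(RGB+HSV+Lab)"`
(256 + 20 + 12 + 12 + 12 = 312 columns). Columns always appear in the
canonical order GLCM, SV, LBP, RGB, HSV, LAB restricted to the
combination. The matrix is then standardized column-wise to zero mean
and unit sample (N−1) standard deviation over the **entire dataset
before cross-validation** — deliberately mirroring the original
protocol even though it leaks test-sample statistics into training;
`standardize(fm, stats = )` supports fold-wise transformation of
held-out data for users who prefer the stricter variant. Zero-variance
columns are zeroed and flagged rather than dropped, keeping column
counts stable across combinations.

## The classifier

`ecoc_fit()` trains the one-vs-one ECOC design: for `K` classes,
`K(K−1)/2` binary learners, one per unordered class pair (28 for the 8
observed VSS totals), each trained only on the samples of its two
classes. Prediction scores every learner and picks the class minimizing
the loss-weighted decoding
`Σ_l |m_kl| g(m_kl s_l) / Σ_l |m_kl|`, with `g` the hinge loss
`max(0, 1−z)/2` on signed margins (SVM, LDA) or the Hamming loss
`(1−sign(z))/2` on hard votes (1-NN, naive Bayes). With Hamming loss on
votes this provably reduces to pairwise majority voting — verified
exhaustively in the tests for `K ≤ 4`. All ties — decoding ties and
1-NN distance ties — resolve to the smallest class label / earliest
training sample: determinism and reproducibility are preferred over any
unstated convention of the original toolbox.

Learners: `knn1` (1-nearest-neighbor, Euclidean, implemented natively),
`linear_svm` (soft margin, cost 1 — a standard toolbox default, as the
original box constraint is unstated), `grid_svm` (RBF SVM whose cost
`{0.01, 0.1, 1, 10, 100}` and kernel width `{0.1, 1, 10}` — width
interpreted as the bandwidth σ with `gamma = 1/(2σ²)` — are chosen by
an inner 5-fold cross-validated grid search; an explicit, deterministic
stand-in for Bayesian hyperparameter optimization, which is out of
scope), plus `lda` and `gnb` for completeness. LDA and naive Bayes drop
columns that are constant within their two-class subset before fitting,
since frozen standardized columns would otherwise break the
within-group covariance estimate.

`loo_cross_validate()` refits the full model `N` times, each time
predicting the single held-out sample, and is invariant to sample order
for deterministic learners.

## Tolerance accuracy

`tolerance_accuracy(cm, tol)` accepts a prediction when it lies within
`tol` *positions* of the true class in the ascending list of observed
classes (for the study's classes `0,1,2,4,5,7,8,9`, one-score tolerance
around class 5 accepts 4 and 7). The alternative reading — absolute
VSS-score difference `|ΔVSS| ≤ tol` — is available as
`mode = "score"`. Position semantics is the default because it exactly
reproduces all five internally consistent headline accuracies of the
packaged reference matrices (92.13/98.15 and 88.43/94.91), whereas the
score reading gives 91.67 instead of 92.13 on the first; both numbers
can be verified in one line each with `reference_confusion()`.
Percentages are rounded half-up to two decimals, matching the reference
tables. One of the shipped matrices has a printed exact accuracy
inconsistent with its own trace (81.19 vs 170/216 = 78.70); only its
internally consistent tolerance accuracies are used as worked examples.

## The synthetic study emulator

The original clinical images are not redistributable, so
`generate_study_dataset()` emulates the *design*: 24 parent images with
the observed class labels `{0,1,2,4,5,7,8,9}` and parent counts
`3,9,2,1,1,5,1,2`, each subdivided 3×3 into the 216 samples with
per-class counts `27,81,18,9,9,45,9,18`. Manifest rows carry a fixed
subscore decomposition summing to each total (e.g. 9 = pigmentation 2 +
vascularity 3 + pliability 2 + height 2), all within the VSS subscale
ranges.

Each class is a stationary colored texture: base color plus
`amplitude ×` (white noise smoothed by a sum-one box kernel of radius
`texture_scale`, shared across channels) plus per-channel white noise
of standard deviation `noise_sd`, rounded and clipped to `[0, 255]`.
The default class table spreads three knobs:

* **mean color**, spaced widely across RGB space (pale skin through
  pink, violet, red, brown, dark purple);
* **texture correlation length** (`texture_scale` 0–4 pixels);
* **roughness contrast** (`noise_sd` 2–18 and `amplitude` 25–140).

Two properties shaped the table. Smoothing radii stay small because a
33×33 tile contains only about `(33/(2s+1))²` independent texture
patches — at large radii per-tile LBP histograms and semi-variograms
become unstable and class clusters smear. And since LBP is
contrast-invariant, no two classes share the same (scale,
contrast-to-noise-ratio) pair; the absolute noise and amplitude levels
still separate classes through the semi-variogram sill/nugget and the
color-variance moments. `default_class_specs(separation)` interpolates
every knob toward its across-class center, so accuracy degrades
controllably as `separation → 0`; the tests verify this monotonic
degradation at separations 1/0.2/0.05 on a color-only combination.

What passing on synthetic data does **not** show: the generator's
classes are stationary Gaussian textures with class-constant color —
real scars have spatially structured pigmentation, specular highlights,
lighting gradients and camera variation, none of which are modelled.
Synthetic recovery demonstrates that the pipeline's plumbing, features
and classifier behave correctly, not that clinical accuracy transfers.
Correspondingly, the absolute LOO accuracies of the original study are
*not* reproduced from images; its two confusion matrices ship as
fixtures and their tolerance accuracies are recomputed exactly.

## Problem sizes and runtime choices

The test suite exercises: oracle equivalence of every texture primitive
against naive double-loop reimplementations on 100 random 8×8 images
(tolerance 1e−10); the full pipeline — generation, 312-column feature
extraction, 216-fold LOO with ECOC-1-NN — on 3 seeds of the default
synthetic dataset (each run takes a few seconds), with a
label-permutation control expected near the class-frequency chance
level of ≈22%; and exhaustive decoding equivalence for `K ≤ 4`. Parent
images default to 99×99 so each 33×33 tile supports 10-lag
semi-variograms with margin.

## Known limitations

* Hue is binned linearly; a hue histogram straddling the red wrap-around
  splits across the first and last bins.
* The GLCM gray-level count (8), symmetry convention and logarithm base
  are declared defaults, not values recoverable from the reference
  protocol.
* Dataset-wide standardization before LOO leaks distributional
  information across folds; it is kept as the default for protocol
  fidelity and documented here.
* `grid_svm` is a grid search, not Bayesian optimization; reports label
  it accordingly.
* Class imbalance is left untouched (no reweighting), as in the
  reference protocol.
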