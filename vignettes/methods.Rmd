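---
title: "Handcrafted multimodal lesion classification: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Handcrafted multimodal lesion classification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the modelling stance

Clinical skin-lesion photographs taken with smartphones vary wildly in
resolution, illumination and framing, and the six diagnostic categories the
package targets (actinic keratosis, basal cell carcinoma, melanoma, nevus,
squamous cell carcinoma, seborrheic keratosis) are heavily imbalanced in
practice, with melanoma rare. Instead of learned deep features, lesioncraft
encodes the visual cues a dermatologist actually reads — colour variegation,
surface texture, border and shape irregularity — as fixed, interpretable
descriptors, fuses them with the clinical record, and classifies with
gradient-boosted trees. Every number the model consumes can be traced back
to a formula over pixels or to a named clinical field.

The descriptor is

* **colour** (96-d): 32-bin histograms of H, S and V, each L2-normalized;
* **texture** (13-d): the thirteen classic Haralick statistics of the
  gray-level co-occurrence matrix (GLCM), averaged over the four
  unit-distance directions 0°, 45°, 90°, 135°;
* **shape** (7-d): the seven Hu moment invariants of the grayscale
  intensity image, log-stabilized;
* **metadata** (12-d): z-scored age and two lesion diameters, gender coded
  Male = 1 / Female = 0, and eight 0/1 clinical flags.

Concatenation gives a 116-d visual vector and a 128-d fused vector. A
soft-voting ensemble of three gradient-boosted tree models (500 rounds,
depth 6, learning rate 0.03 each) averages class-probability distributions;
the argmax is the prediction.

## Preprocessing

Images are smoothed with a 5×5 Gaussian kernel (σ = 1 pixel) and resized to
224×224 by bilinear interpolation before any feature is computed. Three
numerical conventions are fixed here because they silently change
downstream values and are otherwise arbitrary:

* **Border handling** is edge-inclusive reflect padding. Zero padding would
  darken lesion borders, and borders matter to the shape features.
* **Resampling** uses half-pixel sample centres (`align_corners = FALSE`).
  Under this convention resizing at native resolution is the exact
  identity, constants are preserved exactly, and affine intensity ramps
  survive within 0.5 intensity units — the properties the test oracles
  assert.
* **Arithmetic stays in floating point** end to end; quantization to 8 bits
  happens only on PNG export. Smoothing and warping are convex
  combinations of in-range values, so outputs are clamped to [0, 255] only
  to remove floating-point summation dust.

Single-channel input is replicated to three channels with a warning rather
than rejected; a command-line run over a mixed folder should not die on one
grayscale file.

## Colour module

Ranges are fixed at H ∈ [0, 360), S ∈ [0, 1], V ∈ [0, 1] with 32 equal-width
bins per channel; the last bin is closed so the bins partition all 50,176
pixels, and achromatic pixels (S = 0) contribute hue 0 so hue is always
defined. Histogram counts are divided by the L2 norm plus ε = 1e-8: the
all-zero vector maps to zero instead of dividing by zero, and each non-zero
block has norm 1 within 1e-6. Different imaging stacks disagree about 8-bit
HSV conventions (some store H in [0, 180)); the package defines its own
canonical ranges and documents them rather than inheriting any library's.

## Texture module

Grayscale is the usual luminance combination 0.299 R + 0.587 G + 0.114 B.
The GLCM at displacement d = 1 is accumulated **symmetrically** — each
ordered pair is counted in both (i, j) and (j, i) — which is the original
Haralick convention and makes the matrix exactly symmetric. Gray levels are
0-based indices. The 13 statistics are computed from one shared pass of
marginals, diagonal-sum distributions and entropies, with these fixed
conventions:

* logarithms are base 2 (entropies in bits), applied consistently so the
  two information measures of correlation remain internally coherent;
* 0 · log 0 := 0;
* correlation is 0 when either marginal deviation is 0, and the first
  information measure of correlation is 0 when max(HX, HY) = 0, so constant
  images produce finite features;
* the square-root argument of the second information measure is clamped at
  0 before the root;
* the variance statistic is the weighted form Σ (i − μ_x)² P(i, j); an
  unweighted reading of the textbook row is not a probability-weighted sum
  and was rejected.

The number of gray levels G defaults to 256 in the extractor (plain 8-bit
grayscale, no quantization). The end-to-end pipeline quantizes to G = 64,
squarely within the 8–64 range common in Haralick practice: co-occurrence
statistics at 64 levels are nearly as informative, far less sparse, and the
G×G accumulations dominate per-image cost. Both choices are exposed as
`levels` / `glcm_levels` arguments.

## Shape module

Moments are computed on the grayscale **intensity** image — no binarization
or segmentation — with x = column and y = row, 0-based. Central moments
through order 3 are scale-normalized with exponent (p + q)/2 + 1 and
combined into the seven Hu polynomials. The wide dynamic range is
compressed by h̃ = −sign(h) · log10(|h| + 1e-10), with sign(0) := 0 so an
exact zero maps to 0; continuity at the origin is impossible for this
transform, so determinism is chosen. The invariants are checked in the test
suite against their defining symmetries (translation, rotation, scale, and
sign flip of the seventh under mirroring) and against the closed form
h₁ → 1/(2π) for a filled disk.

Because the moments see intensity, not a segmented contour, they respond to
internal brightness structure as well as outline; with global descriptors
this is unavoidable, and the synthetic probes size their expectations
accordingly (the uniform background carries moments too).

## Splitting and augmentation

The split is computed **before** any augmentation, on original images only,
at patient granularity: whole patients are assigned greedily per class
(rarest class first) until the class-wise test share reaches the target, so
no patient — and therefore no augmented derivative — ever spans both sides.
A class owned by a single patient cannot be split and goes wholly to train
with a warning. Patient-level assignment is the stricter of the two
plausible protocols (image-level vs patient-level) and subsumes the other;
it is the only mode implemented.

Offline augmentation then balances each training class to a fixed target
(2500 by default) by cycling uniformly over the class's parents. Each new
record draws its transform parameters from an RNG stream derived from
(seed, parent id, replica index), so a regenerated dataset is bit-identical
and independent of record order. The transform applies, in a fixed order:
horizontal flip (p = 0.5), vertical flip (p = 0.5), rotation uniform in
[−30°, 30°], multiplicative brightness in [0.8, 1.2] clamped to [0, 255],
and with p = 0.5 an affine translate (≤10% of the side) plus isotropic
scale in [0.9, 1.1]. The source parameters give a transform *set*; the
composition order is fixed here purely for reproducibility. Geometry uses
inverse-mapped bilinear sampling with reflect fill, matching the
preprocessing border policy.

The test side contains only genuine images. A published protocol that
appears to imply hundreds of test melanomas cannot be reconciled with only
52 original melanoma images and an unaugmented test set; the leakage-safe
reading is the only mode this package implements.

## Metadata encoding

Standardization statistics (mean, **population** standard deviation,
median) are fitted on the training partition only and carried to the test
side unchanged — test z-scores are deliberately not recentred. Missing
continuous values are imputed with the training median before z-scoring;
missing flags become 0; every imputation is counted and reported once per
call. Unknown gender tokens are an error listing the accepted spellings.
The 12-slot output order is fixed (age, gender, two diameters, eight
flags); any fixed order is equivalent for tree ensembles, but
reproducibility requires one.

## Ensemble

The three members share the core hyperparameters (500 iterations, depth 6,
learning rate 0.03) and differ in tree construction so their errors
decorrelate: exact depth-wise growth, histogram depth-wise growth with 0.8
row/column subsampling, and histogram leaf-wise (loss-guided) growth capped
at 63 leaves. All other booster parameters stay at library defaults and are
recorded in the fitted object. Training is single-threaded with per-member
derived seeds, so refits are bit-reproducible.

Soft voting — the unweighted mean of the three class-probability
distributions, then argmax — is the default combiner; probability averaging
is the mathematically explicit rule, and a hard majority-vote mode is
available behind `mode = "hard"` (remaining vote ties fall back to the
averaged probabilities). Exact ties break to the lowest label index and are
reported. A schema fingerprint of the training feature names is checked at
prediction time.

## Evaluation

Per-class precision, recall and specificity are one-vs-rest from the 6×6
confusion matrix; macro metrics are unweighted class means; F1 is macro-F1.
The published binary-looking formulas only cohere for six classes under
this one-vs-rest macro reading, which is the implemented one. The
multiclass Matthews correlation is the Gorodkin generalization over the
full matrix; Cohen's κ uses chance agreement from the marginals. AUC is
macro one-vs-rest and requires probabilities — it is reported as missing,
not 0, when only hard labels exist. A class that is never predicted gets
precision 0 with a warning.

Confidence intervals are percentile bootstrap (B = 1000, 95%) over
resampled prediction/label pairs — the plain reading of "empirical
bootstrapping"; BCa would add complexity without a stated justification.
Degenerate resamples fall back to the battery's own conventions.

## The synthetic generator

The generator exists to make every pipeline stage verifiable without any
download. Each class recipe paints a skin-toned 224×224 field, one
elliptical blob whose border radius is perturbed by low-order radial
harmonics, a class-conditional HSV fill, and correlated noise inside the
blob; metadata is drawn from class-conditional priors (age, diameters,
symptom probabilities). Synthetic patients own 1–3 same-class lesions so
patient-level splitting is exercised. One `separability` dial in (0, 1]
widens all class ranges as it decreases: at 1.0 the six hue ranges are
pairwise disjoint; near 0 they overlap heavily. A second
`meta_separability` dial (defaulting to the first) decouples metadata
strength from image strength, creating the scenario that matters for the
fusion claim: ambiguous images with informative clinical context.

The classes are abstract stand-ins, not simulated pathology. Passing the
end-to-end tests shows the pipeline recovers plantable colour / texture /
shape / metadata signal through the full preprocess → extract → fuse →
classify → evaluate chain; it says nothing about accuracy on real clinical
photographs, which have hair, rulers, shading gradients and correlated
class structure the generator does not model.

## Problem sizes used by the checks

The packaged checks run the full pipeline at 100 images per class
(separability 1.0) for the headline recovery figure; separability
monotonicity at 24 images per class over three seeds and three levels,
asserted on means; the metadata-gain scenario at 40 images per class with
visual separability 0.22 and metadata separability 1.0; and oracle
equivalence on ≥100 random ≤16×16 images. These sizes give stable
pass/fail behaviour for properties (accuracy thresholds, orderings,
bit-identity) rather than tight estimates of any rate.

## Known limitations

* Global descriptors, no lesion segmentation: background pixels vote in
  every histogram and moment.
* The three ensemble members are all gradient-boosted tree models from one
  library, diversified by growth strategy; they are configured per the
  shared hyperparameter table but are not three independent codebases.
* The Haralick variance row and the GLCM pairing conventions vary across
  the literature; this package's choices are documented above and enforced
  by oracle tests, but other implementations may differ numerically.
* Bootstrap intervals treat test predictions as i.i.d.; with multiple
  lesions per patient this slightly understates uncertainty.
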