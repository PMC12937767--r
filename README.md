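# lesioncraft

Interpretable six-class skin lesion classification from clinical
photographs and patient metadata, built entirely from handcrafted
descriptors and gradient-boosted trees.

Smartphone-captured lesion photographs are noisy, variably sized and
heavily class-imbalanced, and the clinical categories of interest — actinic
keratosis (ACK), basal cell carcinoma (BCC), melanoma (MEL), nevus (NEV),
squamous cell carcinoma (SCC), seborrheic keratosis (SEK) — are routinely
diagnosed by eye from colour, surface texture, shape and the patient's
history. lesioncraft digitizes exactly those cues for researchers and
tool-builders who need a lightweight, auditable alternative to deep
networks:

* **F_color ∈ R⁹⁶** — 32-bin histograms of H, S, V, each L2-normalized
  (`ĥ = h / (‖h‖₂ + ε)`, ε = 1e-8);
* **F_texture ∈ R¹³** — the 13 Haralick statistics (ASM, contrast,
  correlation, variance, IDM, sum/difference statistics, entropies, two
  information measures of correlation) of the symmetric unit-distance GLCM
  `P(i, j)`, averaged over θ ∈ {0°, 45°, 90°, 135°};
* **F_shape ∈ R⁷** — Hu moment invariants of the intensity image from
  normalized central moments `η_pq = μ_pq / μ₀₀^((p+q)/2+1)`, compressed by
  `h̃ = −sign(h)·log₁₀(|h| + 1e-10)`;
* **F_meta ∈ R¹²** — z-scored age and lesion diameters (train-fitted
  statistics), gender (Male = 1), eight 0/1 clinical flags.

The fused vector `F = [F_color | F_texture | F_shape | F_meta] ∈ R¹²⁸` is
classified by a soft-voting ensemble of three gradient-boosted tree models
(500 rounds, depth 6, learning rate 0.03; exact depth-wise, subsampled
histogram, and leaf-wise growth), averaging class probabilities:
`P(y = k) = ⅓ Σ_m P_m(y = k | F)`, `ŷ = argmax_k P(y = k)`.

Around the classifier the package provides Gaussian smoothing + bilinear
224×224 normalization, leakage-safe patient-level stratified splitting,
offline class-balancing augmentation (flips, ±30° rotation, brightness
0.8–1.2, affine translate/scale), a full metric battery (macro
precision/recall/F1/specificity, one-vs-rest AUC, Gorodkin multiclass MCC,
Cohen's κ, percentile bootstrap CIs), an ablation harness over feature
subsets, and a seeded synthetic lesion generator so everything above is
testable offline.

## Worked example

```r
library(lesioncraft)

# six synthetic lesion classes, 20 images each, fully separable signal
ds <- gen_dataset(n_per_class = 20, separability = 1.0, seed = 7)
pl <- run_pipeline(ds, seed = 7)           # split -> features -> ensemble
print(pl)
#> <lesion_pipeline> trained on 93 images, tested on 27
#> <lesion_metrics> n = 27 | acc 1.0000 | macro-F1 1.0000 | kappa 1.0000 | MCC 1.0000
#>  class support precision recall specificity f1
#>    ACK       5         1      1           1  1
#>    BCC       4         1      1           1  1
#>    MEL       4         1      1           1  1
#>    NEV       5         1      1           1  1
#>    SCC       5         1      1           1  1
#>    SEK       4         1      1           1  1

glance(pl$metrics)      # one-row metric summary (tibble)
tidy(pl$model)          # gain-ranked feature importances with block labels
autoplot(pl$metrics$confusion)   # confusion heat-map (ggplot)
```

With fully separable synthetic classes the pipeline recovers every held-out
label; the per-class table shows the one-vs-rest battery at its ceiling.
Lowering `separability` degrades accuracy monotonically, and
`meta_separability` lets you make images ambiguous while metadata stays
informative — the scenario where fusing the 12 clinical fields visibly
lifts accuracy (`run_ablation(ds, subsets = c("C+H+S", "C+H+S+M"))`).

A thin CLI wraps the same functions:

```sh
exec/lesioncraft simulate --n-per-class 20 --separability 0.8 --seed 1 --out demo
exec/lesioncraft evaluate --data demo --seed 1
```

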