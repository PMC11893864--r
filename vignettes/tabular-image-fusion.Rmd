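---
title: "Methods: hybrid tabular-to-image transfer learning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hybrid tabular-to-image transfer learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tabfuse)
```

## The problem and the model

Small clinical tables — here the standard 13-predictor heart-disease
schema with a binary disease target — are too small to train a
convolutional network, yet convolutional feature extractors trained on
large image corpora encode generic pattern detectors that can be reused as
fixed transforms. `tabfuse` operationalizes that reuse for tabular data:
each record is laid out as a tiny intensity grid whose spatial
neighborhoods reflect feature correlation, the grid is upscaled to a
standard network input size, a *frozen* convolutional backbone emits a
feature vector, and that vector is concatenated with the normalized
tabular features before a classical, tunable classifier makes the call.
The frozen backbone means transfer learning is inference-only: no gradient
ever flows, so the deep block is a deterministic function of the record
and introduces no extra estimation variance beyond the classifier's own.

The pipeline is deliberately modular: every stage (schema validation,
imputation, normalization, ordering, embedding, extraction, fusion,
tuning) is fitted once on training data and then frozen into a single
bundle that can be applied unchanged to unseen data, which is the unit of
generalization testing.

## Normalization and preprocessing

Min-max scaling `x' = (x − min(x)) / (max(x) − min(x))` maps each fitted
feature linearly onto [0, 1] — the natural intensity range for grid
cells. All 13 predictors are scaled uniformly, including nominal codes:
once features become pixel intensities the distinction between a scaled
code and a scaled measurement disappears, and keeping the treatment
uniform makes the grid interpretable as one grayscale image. This is an
interpretation choice; the nominal codes' ordinal artifacts are carried
into the image deliberately rather than one-hot expanded, which would
break the fixed 13-cell layout.

Values unseen at fit time are clipped into [0, 1] (the embedding
contract requires it), constant features map to 0 and are flagged
degenerate. Missing cells are imputed with the training median (numeric)
or mode (nominal, ties toward the smaller code) — the simplest
deterministic rule, since nothing in the problem demands model-based
imputation. Outliers are only ever *flagged* (Tukey's 1.5·IQR fence,
quartiles by linear interpolation between order statistics, `quantile`
type 7): destructive row dropping is left to the analyst. The
thalassemia code 0 is accepted as schema-valid but reported as a
missingness indicator, because the coding convention labels it NULL.

Leakage control: normalization, ordering and imputation are fitted on
training rows only by default. A paper-mode flag fits them on the full
dataset instead, reproducing the common (if optimistic) practice of
preprocessing before splitting; it exists so both procedures can be
compared explicitly rather than silently.

## Feature ordering and the grid

Pearson correlations between all scaled features give `R`; the distance
is `d = 1 − r` (signed, the most literal transform — anticorrelated
features are *far*), optionally `1 − |r|`; average-linkage agglomerative
clustering on `d` gives a dendrogram whose leaf order is the feature
permutation. Average linkage is the conventional choice for
correlation-derived distances and is configurable (single/complete).
`hclust`'s deterministic merge order makes the permutation reproducible;
no optimal-leaf-ordering rotation is applied, again for determinism.

The reordered record fills a `ceiling(sqrt(d))`-sided grid row-major from
the top-left; for 13 features that is a 4×4 grid with the last three
cells of the fourth row zero-padded. Upscaling to the network input side
(224 default) uses nearest-neighbor block replication, *not* bilinear
interpolation: block replication is the only resampling that retains the
original intensity values exactly (each source cell becomes a constant
56×56 block at 4→224), so the image carries precisely the record's 13
values plus zeros. The grayscale plane is replicated into three identical
channels to match convolutional input conventions. The whole embedding is
invertible — grid, order and mask recover the scaled record exactly —
which the tests exercise as a property.

## The frozen backbone

The default backbone is a small seeded stack: grayscale reduction,
bias-free 3×3 convolutions (8 filters), ReLU, global average pooling, and
a seeded linear projection to the output dimension (default 32). It is
frozen at creation, bit-reproducible from its seed, serialized inside the
pipeline bundle, and — being bias-free with a non-negative activation —
maps the all-zero image to the zero vector, a property the tests use as a
linearity anchor. It is a genuine (if small) convolutional feature
extractor in its own right: fixed random convolutional features are a
long-standing, well-characterized representation.

A VGG16 adapter describes the pretrained route: 224-pixel input, the
final convolutional block reduced by global average pooling to 512
features (pooling keeps the fused matrix desk-scale; a flatten mode with
25,088 features is specified for completeness), with the network's
standard input preprocessing applied inside the adapter so backbone
conventions never leak into the conversion stage. Extraction through this
adapter requires the pretrained weights; without them it raises an
explicit capability error that points at the toy backbone.

## Fusion, tuning, and evaluation

Fusion is column-wise concatenation, tabular block first, with block
labels retained. Grid search is exhaustive over compact per-family grids
(each family's commonly reported optimum is inside its grid), scored by
accuracy under stratified k-fold CV (k = 5 default) with one seeded fold
assignment shared across candidates, ties broken toward the
first-declared candidate, and the winner refit on all training rows.
Backbone features are computed once before CV: the backbone is frozen, so
this saves k redundant passes without any label leakage. The standalone
mode runs the identical machinery with the deep block removed, giving
paired hybrid-vs-standalone scores.

Family implementations use the established engines: `ranger` (random
forest), `glmnet` ridge logistic regression (lambda = 1/(C·n), matching
the C convention of regularized linear solvers), `rpart` (decision
tree), `xgboost` (gradient boosting), `e1071` (SVM). Distance-weighted
k-nearest neighbors is implemented directly (no installed engine offers
the distance-weighted vote), with deterministic distance-then-index tie
ordering.

Metrics come from the confusion counts with disease (1) positive:
accuracy, precision, recall (≡ sensitivity — the two formulas are
identical, and the package keeps both names for report compatibility),
F1, specificity. Zero-denominator ratios surface as explicit undefined
markers with reasons; silent zeros would corrupt comparison tables.
Proportions internally; percentages only at presentation.

## The synthetic-data generator

The generator is a Gaussian copula over empirical marginals, fitted per
target class and sampled proportionally to class prevalence. Numeric
marginals are the class's sorted observed values (inverse empirical CDF,
so sampling emits only observed sample points); nominal marginals are
category frequencies realized by thresholding the latent normal.
Dependence is a latent correlation matrix obtained from within-class
Spearman rank correlations via `r = 2 sin(πρ/6)` and repaired to positive
semi-definiteness by eigenvalue clipping (floor 1e-8, rescaled to unit
diagonal). The copula was chosen over a neural tabular GAN as the default
because it is deterministic under a seed, dependency-light, fits in
seconds at desk scale, and satisfies the same sampling and evaluation
contract; the generator interface accepts a backend argument so a GAN
adapter can stand behind it.

Quality evaluation follows a three-part protocol: (i) per-feature
correlation MAE against the reference — for feature *i*, the mean over
*j ≠ i* of `|cor_real(i,j) − cor_synth(i,j)|` on coded values, averaged
over features; (ii) the same quantity between two random halves of the
reference alone, which calibrates what sampling noise looks like; (iii)
per-feature two-sample KS tests (numeric, asymptotic p) and χ² tests
(nominal, categories with expected count below 5 pooled, no continuity
correction so identical tables score exactly 0) with pass = p ≥ 0.05.
Pearson correlation on integer-coded nominals is used as-is, matching the
undifferentiated correlation analysis the protocol calls for.

`heart_reference_generator()` is a directly constructed copula model — a
stated ground-truth population for calibration studies. Its numeric
marginals are smooth parametric quantile grids (normals for age, resting
blood pressure, cholesterol and maximum heart rate; gammas for ST
depression) clipped into the schema domains, its nominal frequencies and
class shifts are chosen to echo the public Kaggle heart data's summary
behavior under that dataset's target coding (higher peak heart rate,
lower ST depression, more non-typical chest pain in the class labeled 1),
and its latent correlation matrix states a dozen clinically sensible
pairwise entries (age–max-heart-rate −0.40, ST-depression–slope −0.50,
chest-pain–exercise-angina −0.40, …) with everything else zero, then
PSD-repairs. What it does *not* emulate: measurement discretization
(real ST depression comes in 0.1 steps), missingness patterns, cohort
heterogeneity, or label noise — so passing calibration tests demonstrates
the generator's fidelity to a copula-class population, not performance on
real clinical data.

Calibration study sizes (reference 2,000 split 50:50 with 1,000 synthetic
samples for the marginal check; 5,000/5,000 for the correlation check)
were chosen so that sampling noise in the checked statistics is an order
of magnitude below the decision thresholds while the full study runs in
seconds.

## Shapley explanations

The coalition value `v(S)` for a deterministic pipeline is defined by
background replacement: features in `S` keep the explained record's
values, the rest are replaced by each background row's values, and the
pipeline's class-1 scores are averaged — the interventional expectation
over a finite background set. Replacement happens on the *raw* 13
tabular features, before imaging and extraction, so the deep block reacts
to coalitions; attributions over the fused 13+512 columns would be
uninterpretable and are out of scope. The exact enumerator visits all
2^M coalitions (8,192 at M = 13; capped at 15 features) and satisfies
efficiency, dummy, symmetry and linearity to round-off; the permutation
sampler is seeded, reports Monte-Carlo standard errors, telescopes to
exact efficiency even at one permutation, and converges to the
enumerator. A default background of ~20 seeded training rows bounds
exact-mode cost. The module emits plot-ready long tables (record,
feature, value, φ) rather than rendering beeswarm plots itself.

## Numerical and design notes

- All randomness flows from explicit per-call seeds; the command layer
  derives stage seeds from one global seed, making full runs
  bit-reproducible with the toy backbone.
- Degenerate inputs are handled, never silently: constant features warn
  and get zero correlations (distance 1 to everything), degenerate
  normalization maps to 0, single-category nominal tests are skipped with
  a note, undefined metric ratios carry reasons.
- Grid-search ties, dendrogram traversal, kNN neighbor ties and mode ties
  all break deterministically (first-declared / lower index / smaller
  code).
- Images are floats in [0, 1] end to end; any backend-specific intensity
  convention belongs inside the backbone adapter.
- Test and example problem sizes (hundreds of records, 8–32 pixel toy
  images) were chosen as the smallest scales at which every checked
  property is still sharply decided; the conversion and extraction code
  paths are size-generic and run at 224 unchanged.

## Known limitations

- The copula generator cannot represent dependence structures beyond its
  latent Gaussian family (e.g. tail dependence, nonlinear interactions);
  its calibration results say nothing about neural generators.
- The toy backbone demonstrates the architecture and determinism
  contracts; its features are generic random-convolution summaries, not
  ImageNet-trained representations, so absolute classification accuracy
  with it is not comparable to a pretrained backbone.
- Nominal codes are scaled as ordinals into the image; categorical
  structure is preserved only through the generator and the χ² tests,
  not through the embedding.
- No probability calibration, no ROC/AUC, no class rebalancing: class
  imbalance is addressed only through labeled synthetic augmentation.
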