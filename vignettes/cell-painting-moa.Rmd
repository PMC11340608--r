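---
title: "Mechanism-of-action profiling from Cell Painting data: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mechanism-of-action profiling from Cell Painting data: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cvfusion)
```

## The problem

Cell Painting stains eight cellular compartments with six dyes and images
them in five fluorescence channels (DNA, ER, RNA, AGP, Mito). When cells are
treated with a bioactive compound, the morphology changes the assay captures
carry information about the compound's mechanism of action (MOA) — the
molecular target class through which it acts. `cvfusion` implements a
complete analysis stack for MOA classification from such data, built around
three information sources per treatment:

* **image-based profiles (IBP)** — well-level vectors of morphology features
  aggregated from segmented single cells,
* **raw five-channel images** — fields of view processed without
  segmentation, and
* **compound structure** — the treatment molecule itself, encoded as a
  hashed substructure fingerprint.

The hard part of this problem is not fitting a classifier; it is that
multi-site datasets confound biology with *batch effects* — systematic
differences between sources, microscopes and plates that a model can exploit
instead of the phenotype. Most of the package is therefore normalization and
evaluation machinery: control-based standardization on both the profile and
the image side, whitening, batch-effect scoring, and a cross-validation
scheme that makes leakage structurally impossible.

## The synthetic data generator

Real Cell Painting datasets are hundreds of gigabytes. To make every stage
of the pipeline testable on a desk, `synth_config()` + `make_layouts()` /
`render_field()` / `make_profiles()` generate a miniature dataset with the
same *structure*:

* 384-well plates whose outermost wells hold the eight JUMP positive-control
  compounds (including AMG900, which is excluded from positive-control
  statistics by default because its MOA coincides with a treatment class)
  and whose second ring holds DMSO solvent controls;
* several sources, each with its own multiplicative intensity gain, and
  microscopes with additive offsets (`batch_offset_scale`); per-plate radial
  illumination fall-off (`illumination_gradient_scale`), with the
  ground-truth illumination surface emitted so correction is testable
  against truth;
* 4–10 replicate wells per compound, spread over at least two sources,
  mirroring the replicate-based selection rule used for datasets of this
  kind, and several fields of view per well;
* class signal in two forms: informative profile features receive a
  class-specific mean shift of `class_effect_size` noise-SD units, and
  rendered cells change both their eccentricity and their per-organelle
  staining intensity with class. Intensity participates because the bundled
  test encoder pools patches by averaging and is therefore blind to pure
  shape changes; real morphology signal likewise mixes shape and texture.
* three quality-score columns (blur, saturation, focus) drawn as
  independent uniforms, with an optional corrupted fraction.

The `profile_class_groups` / `image_class_groups` / `chem_families` knobs
let classes *share* signatures within a modality. This is how the tri-modal
benchmark plants *partial* signal: with four classes, profiles and images
separating classes {1,2} from {3,4} and chemistry separating {1,3} from
{2,4}, no single modality can exceed pair-level performance but the
combination identifies every class.

Everything is deterministic given the config seed; each plate/well/field
gets its own derived RNG stream, keyed by the plate's index within its
source so that turning all batch knobs to zero makes the same well render
identically across sources.

**What passing tests on this generator do and do not show.** The generator
reproduces the *structure* that matters to the pipeline (controls on rings,
replicate spread, additive/multiplicative batch structure, partial class
signal) but not the content of real data: cells are smooth ellipses, not
textured cells; profile features are Gaussian, not CellProfiler's 4,762
heavy-tailed correlated features; fingerprint families are toy scaffolds. A
green suite demonstrates that the operations implement their contracts and
that the pipeline's orderings (e.g. batch-effect score before vs. after
normalization) hold under controlled conditions — not that any particular
accuracy will be reached on a real dataset.

## Profile-side pipeline

**Quality control.** Raw blur, saturation and focus quality features are
aggregated per group (mean over columns), min-max normalized, and
post-processed: saturation is quantile-mapped to a standard normal z and
scored as |tanh(z)| so that both extremes (over- and under-saturation) score
high; focus is inverted so high scores mean poor focus. A well datapoint is
excluded if any of its three scores exceeds that score's 90th percentile.
For independent continuous scores this excludes 1 − 0.9³ ≈ 27.1% of data, a
calibration the acceptance suite verifies on 10,000 datapoints. The |tanh|
form and the rank-based quantile map are this package's choices; both are
monotone on each tail, which is all the percentile rule needs.

**Standard feature filtering.** `pycyto_filter()` removes features with
missing values, blocklisted names, variance below 1.0, and one member of
each pair with |Pearson r| > 0.9. The correlation tie-break is the standard
greedy rule: within the worst pair, drop the feature with the larger mean
absolute correlation to everything else; ties drop the later column.

**Shapley-ranked selection.** `shapley_rank()` fits a multiclass XGBoost
model and attributes each prediction to features with the tree-path
(TreeSHAP) method, as `predcontrib` contributions. Global importance is the
mean absolute contribution over samples and classes — the standard global
summary; the per-class top-10 table is attached for interpretability.
`select_top_k()` keeps the leading 150 features by default, the point at
which the marginal contribution of further features is negligible on
datasets of this kind.

**Normalization.** `mad_robustize()` centres every feature on the median of
the same-plate DMSO controls and scales by their (unscaled) median absolute
deviation, with ε = 10⁻⁶ guarding constant control features — robustize must
never emit infinities. `minmax_table()` is the simple [0, 1] map (also the
default input scaling for the fusion model). `fit_spherizer()` /
`apply_spherizer()` implement ZCA-cor whitening of the control correlation
matrix: centre on the control mean, scale to unit variance, then rotate with
eigenvalue regularization λ (each eigenvalue becomes eigenvalue + λ). The
ZCA rotation is the whitening transform closest to the original coordinates,
which keeps transformed profiles interpretable. λ defaults to 10⁻²
everywhere sphering is used; with fewer controls than features the
regularization alone keeps the transform finite.

**Outlier removal.** After normalization, `drop_outliers()` removes features
in which more than 1% of values exceed 100 in absolute value, then rows with
any remaining out-of-range value. Dropping pervasively contaminated features
*first* means a broken feature costs one column, not all its rows; isolated
extreme wells are then dropped individually.

## Image-side pipeline

Processing order is: illumination correction → per-channel min-max (PCN) →
plate-wise channel-wise standardization (PCS) → per-image rescale to [0, 1]
→ crop/flip → channel-weighted augmentation (CWA, training only). PCS
produces values centred at zero while the augmentation clips to [0, 1];
since no canonical ordering reconciles these two domains, the pipeline
re-min-maxes after PCS. Each stage can be disabled, and `prep_image()`
exposes the composition.

* **Illumination correction** divides each channel by the plate's
  illumination function (strictly positive, same shape), removing
  vignetting.
* **PCN** maps each channel independently onto [0, 1]; a constant channel
  maps to zeros.
* **PCS** pools all pixels of all eligible control images per plate and
  channel and extracts mean/SD (population convention — pixel populations
  are large, but the convention must be fixed) and median/MAD (unscaled).
  Standardization uses median/MAD by default, the variant more robust to
  the extreme pixel values common in fluorescence images, with positive
  controls as the default control role. Zero spreads fall back to ε = 10⁻⁶.
* **CWA** fires per image with probability 0.8 and then touches each channel
  independently with probability 0.4; a touched channel is scaled by
  (1 + s), s ~ U(−0.6, 0.6), shifted by b ~ U(−0.1, 0.1), and clipped to
  [0, 1]. "Intensity" is multiplicative and "brightness" additive, the
  convention of the augmentation literature this design follows; draws are
  per channel. The expected modified-channel fraction is 0.8 × 0.4 = 0.32.
* **Cropping** takes 896 × 896 (divisible into transformer patch windows):
  random crop plus independent horizontal/vertical flips in training,
  deterministic centre crop in evaluation.

## Compound structure

`smiles_to_fp()` encodes a molecule's circular substructures (radius 2 ≈
ECFP4, the cited method's default) as a 2048-bit hashed binary vector.
Hashing is delegated to Open Babel's extended-connectivity implementation;
its native 4096-bit vector is folded to 2048 bits by OR-ing halves, a
standard fingerprint-folding operation. Canonicalization inside the toolkit
makes any valid SMILES spelling of a molecule produce the same bits.
Chirality flags are off by default, matching the toolkit default.

## Models and fusion

No deep-learning framework is involved: the networks are small enough that
the package implements dense layers, batch normalization, dropout and the
AdamW optimizer directly in matrix algebra, with hand-derived gradients
(verified against numerical differentiation in the test suite). This keeps
training bit-reproducible under a seed on a single CPU.

* The **profile MLP** is the six-stage fully connected architecture with
  batch normalization, dropout 0.2 in the first two stages, and the
  activation sequence ELU, ReLU, ELU, ReLU, SELU before a linear head. The
  source this design follows lists two different activations for its third
  layer; ELU/ReLU/ELU/ReLU/SELU is one consistent resolution and is
  configurable. Widths are repository choices (256/128/64/64/32 by
  default).
* The **chemistry MLP** has ReLU hidden layers (1024/256/64 by default,
  also a repository choice) with dropout 0.5.
* The **image encoder** is an injected dependency behind a one-function
  contract (image batch → embedding matrix). Production users plug in a
  pretrained hierarchical windowed transformer at 896 × 896, inflating its
  3-channel patch embedding to five channels by replicating the
  channel-mean kernel (`inflate_channel_kernel()`); the bundled
  `tiny_image_encoder()` — fixed average-pool patch embedding plus a small
  learned head — keeps the full pipeline desk-testable.
* **MOAB fusion** appends 1 to each embedding and stacks outer sum,
  difference, product and quotient as four (m+1) × (n+1) channels
  (`moab_fuse()`). The learned reduction is a 1 × 1 convolution across the
  four channels followed by ReLU and global average pooling — the
  nonlinearity before pooling is what preserves interaction information.
  Three modalities fuse hierarchically: (image ⊗ profile) first, the pooled
  result ⊗ chemistry second, preserving the two-input block exactly at each
  step. The quotient divisor is guarded with ε = 10⁻⁶; inside the trained
  model the trunk embeddings additionally pass through a sigmoid, which
  keeps the quotient channel well-conditioned during optimization (an
  unbounded divisor crossing zero makes training erratic).
* **Training** minimizes cross-entropy with AdamW and decoupled weight decay
  10⁻², end to end through both MOAB blocks and all three trunks. Learning
  rate (5 × 10⁻³), batch size (8) and epochs (10) are repository defaults
  chosen for the synthetic benchmark sizes; weight decay and the two
  dropout rates are the regularization the design this follows prescribes.
  Training is deterministic given the seed; `n_restarts` trains several
  independently initialized models and keeps the one with the best
  validation macro-F1 — small networks on small data occasionally draw a
  poor initialization, and validation-based selection is the standard
  remedy. A shared compound between training and validation rows is a hard
  error, not a warning.

**Prediction aggregation** averages class-probability vectors from fields to
wells to compounds (`aggregate_predictions()`); the compound-level argmax is
the class call. Averaging is permutation-invariant and idempotent, and both
properties are tested.

## Evaluation

* **Splits.** `make_splits()` assigns *compounds* (never wells) to five
  class-stratified test folds that partition the compound set, then divides
  the remainder 70:10 into train and validation per fold. With few
  compounds per class the per-class validation quota of those ratios rounds
  to zero, so validation compounds are allocated by stratified largest
  remainder: the global ⅛ fraction of non-test compounds is met exactly
  while staying as class-balanced as the counts allow. `check_splits()`
  re-verifies disjointness, partition and class coverage.
* **Metrics.** Accuracy, macro precision/recall/F1 from argmax calls; macro
  one-vs-rest AUC (rank-sum form) and AUPR (step-wise integration) from the
  probability vectors. The AUC implementation is cross-checked against an
  independent ROC package in the tests.
* **kBET.** For each point the batch composition of its k nearest
  neighbours (Euclidean, self excluded) is compared with the global batch
  proportions by a χ² test with n_batches − 1 degrees of freedom on counts;
  the score is the fraction of points accepted at α = 0.05, so higher
  means better mixed. k defaults to min(25, ⌊n/10⌋) — the reference method
  leaves k open; a fixed moderate neighbourhood keeps the test powered
  without saturating. On identically distributed batches the score
  calibrates to 1 − α.
* **ATE.** Per plate, a spherizer (λ = 10⁻²) is fitted on the DMSO controls
  and applied to all wells; each treated well's Euclidean distance to the
  plate's median control profile is z-scored against the mean and sample SD
  (n − 1; the convention is unstated upstream and must simply be fixed) of
  the control distances. A compound's ATE is its mean z across replicates;
  compounds are bucketed into strong/medium/weak as the top/middle/bottom
  20% of the ATE distribution, ties resolved by stable rank on compound id.
  `accuracy_by_bucket()` then reports classification accuracy per bucket —
  on effect-graded data, strong-effect compounds classify at least as well
  as weak ones.

## Numerical choices, in one place

| Quantity | Value | Why |
|---|---|---|
| Zero-spread guards (PCS, robustize, MOAB quotient) | ε = 10⁻⁶ | degenerate inputs must not poison a batch |
| Spherizer regularization λ | 10⁻² | the one value the upstream analysis prescribes; used everywhere sphering occurs |
| Pixel SD convention | population (n) | pixel populations are large; choice immaterial but fixed |
| Control-distance SD in ATE | sample (n − 1) | unstated upstream; fixed here |
| MAD scaling | unscaled (constant = 1) | matches the robustize convention of the profile tooling this mirrors |
| Outlier threshold | 100, feature dropped at > 1% contamination | see outlier section |
| Batch-norm ε, momentum | 10⁻⁵, 0.1 | standard values |
| Fingerprint radius / length | 2 / 2048 | ECFP4-equivalent default |

## Problem sizes used by the tests and the acceptance script

Unit tests run on 2-plate, 3-class configurations with 96-pixel fields. The
acceptance computations use: 10,000 datapoints for QC calibration; 500
well-datapoints × 200 features (10 informative, effect 1 SD, three seeds)
for Shapley recovery; ~300 wells × 40 features for the kBET ordering and
n = 1000 for its null calibration; and a tri-modal benchmark of 4 classes ×
6 compounds × 4 replicate wells × 3 fields at 96 pixels (three seeds, three
restarts, 10 epochs) for fusion synergy. These sizes were chosen as the
smallest at which each property is comfortably away from its noise floor.

## Known limitations

* The bundled tiny encoder sees mean-pooled patches only; shape-only class
  signal (pure eccentricity change at constant intensity) is invisible to
  it. Production-scale image modelling requires an external pretrained
  backbone behind the encoder contract.
* kBET uses a dense distance matrix — fine to a few thousand points,
  inappropriate beyond.
* Fingerprints delegate to Open Babel's ECFP; bit positions differ from
  other toolkits' implementations, so fingerprints are comparable within a
  dataset but not bit-for-bit across toolkits.
* The pure-R trainer is deliberately small-scale: it is meant for the
  bundled benchmark and method development, not for training on a full
  production dataset.
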