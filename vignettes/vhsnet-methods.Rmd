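---
title: "Methods: VHS scoring with a regressive vision transformer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: VHS scoring with a regressive vision transformer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The measurement

The vertebral heart scale (VHS) is the standard radiographic index of
cardiac size in dogs. On a lateral thoracic radiograph the clinician places
six landmarks: the long axis of the heart from the carina (tracheal
bifurcation) to the apex (points A, B), the short axis at the widest point
of the silhouette, perpendicular to the long axis (C, D), and a vertebral
reference from the cranial edge of the fourth thoracic vertebra to the
caudal end of the ninth (E, F), spanning six vertebrae. The score is

$$\mathrm{VHS} = 6 \cdot \frac{|AB| + |CD|}{|EF|},$$

i.e. the summed axis lengths expressed in single-vertebra units. Hearts
with VHS below 8.2 are graded *small*, between 8.2 and 10 (inclusive on
both ends) *normal*, and above 10 *large* (cardiomegaly). `vhsnet`
implements this measurement (`vhs_score()`, `classify_vhs()`), a deep
regressor that predicts the six landmarks from the image, and the
surrounding training, evaluation and annotation machinery.

Because the score is a ratio of lengths it is invariant under rotation,
translation and uniform scaling of all six points; the test suite checks
this to a relative tolerance of 1e-9.

## Model

`rvt_model()` builds a pyramid vision transformer encoder with
spatial-reduction attention (SRA). Each stage embeds non-overlapping
patches, adds learned absolute positional embeddings, and applies
pre-norm transformer blocks in which the attention keys and values are
computed from a spatially reduced copy of the sequence: $R \times R$
token neighbourhoods are concatenated and linearly projected back to the
stage width, then layer-normalized, so attention cost scales with
$N^2/R^2$ rather than $N^2$. Attention per head is
$\mathrm{softmax}(QK^\top/\sqrt{d} + B)\,V$ with an optional learned
relative-position bias $B$; the bias is a per-head table indexed by the
quantized query-to-key-neighbourhood offset, with a configuration switch
(`use_attention_bias`) to disable it.

Two encoder feature maps — a shallow, texture-level stage and a deeper,
shape-level stage — are each passed through a 3×3 convolutional unit, the
deep map is bilinearly upsampled to the shallow grid, and the two are
concatenated channel-wise (the feature-fusion module,
`use_feature_fusion`). Global average pooling and a small MLP produce
twelve sigmoid outputs, the normalized landmark coordinates, plus three
class logits from a parallel linear head (`head_mode = "aux_head"`). The
alternative `head_mode = "soft_vhs"` derives logits purely from geometry,
as negative squared distances of the predicted VHS to the class-interval
midpoints over a temperature, making the classifier fully consistent with
the measurement by construction.

### The orthogonal layer

Clinical convention requires $CD \perp AB$. The final layer enforces this
differentiably: with points numbered A=1, B=2, C=3, D=4, the
perpendicular slope is $s = -(x_1 - x_2)/(y_1 - y_2)$ and the layer
replaces $y_4$ by $\hat y_4 = s\,(x_4 - x_3) + y_3$, leaving every other
coordinate untouched. When the long axis is horizontal
($|y_1 - y_2| < \varepsilon$, default $10^{-6}$) the slope is undefined
and the symmetric rule is used instead — $x_4$ is replaced by $x_3$ —
which also yields exact perpendicularity. The projection is idempotent,
and gradients flow to all contributing coordinates (the slope inputs
included), which the tests verify against finite differences.

Two engineering consequences are worth recording. First, the layer is
active during training *and* inference by default
(`use_orthogonal_layer`); since the literature leaves the training-time
status open we chose joint training, and stabilize it by initializing the
output head at an anatomically plausible constellation (small output
weights, logit-space bias at a typical landmark layout). Without that
prior a randomly initialized head can emit a near-horizontal long axis,
where the slope $s$ — and with it the loss — explodes. Second, because
the layer discards the raw $y_4$ output on non-degenerate inputs, the
twelfth head unit receives its gradient only through the slope formula;
its direct column is zero. Both behaviours are asserted in the tests.

At inference the reported class label is always derived from the
predicted VHS via `classify_vhs()`, so measurement and diagnosis can
never disagree; the classifier head's probabilities are reported
alongside.

## Objective and training

Training minimizes, over mini-batches,

$$\mathcal{L} = w_{ce}\,\mathrm{CE}(f_{cls}(x), y) +
  \gamma\,\mathrm{MSE}(f_{kp}(x), p),$$

with Adam. The MSE is computed on pixel-scale coordinates (normalized
outputs multiplied by the model input size). This choice makes
$\gamma = 0.01$ a meaningful balance: on normalized coordinates the
regression term would be of order $10^{-4}$ against a cross-entropy of
order 1, effectively switching the keypoint task off — which is exactly
the failure mode we observed (predictions collapse to the dataset-mean
constellation). On pixel coordinates the two terms start at comparable
magnitude and the balance transfers across input sizes through the
$\gamma S^2$ equivalence. `gamma = 0` gives the cross-entropy-only
training mode (the classical image-classification baseline);
`ce_weight = 0, gamma = 1` trains a pure landmark regressor.

Two presets are provided by `train_config()`. The `"full"` preset is the
full-scale recipe: constant learning rate $3\times10^{-5}$, batch 16,
1000 epochs, no early stopping. The `"desk"` preset is sized for a single
CPU core: learning rate $10^{-3}$ with a 100-step linear warmup, batch
16, 2000 steps, global gradient-norm clipping at 5, and early stopping on
validation R-accuracy with a patience of 600 steps. The higher learning
rate is the standard regime for a small transformer trained from scratch
for a few thousand steps; $3\times10^{-5}$ is appropriate for the
full-scale schedule (tens of thousands of steps) but barely moves a
from-scratch desk model. Weights are initialized Glorot-scaled — at
widths of 32–64 channels a fixed small standard deviation would shrink
activations at every layer and stall optimization.

Determinism: all randomness (data generation, initialization, shuffling)
is seeded, the compiled kernels are single-threaded, and two runs with
the same seed produce bit-identical loss trajectories.

### Numerical engine

The package deliberately depends on no deep-learning framework; it
ships its own reverse-mode engine: a tape of nodes over base-R matrices for the
double-precision geometric tail (orthogonal layer, VHS, losses — keeping
the 1e-9 geometric contracts) and compiled single-precision kernels
(RcppArmadillo) for the encoder. Activation tensors live in a bump
allocator that is recycled once per step; this keeps the working set in
warm memory pages, which matters more than FLOPs on a single-core budget.
Gradient correctness is established by finite-difference tests op-by-op
and end-to-end.

## Synthetic radiographs

Real annotated radiograph collections of this kind are not publicly
accessible, so the generator (`generate_sample()`,
`generate_dataset()`) stands in with the minimum structure that makes the
six landmarks well defined and the VHS controllable:

* a bright vertebral column of 11 equal-length rounded segments along a
  gently curved arc near the top of the field, with E at the cranial edge
  of segment 4 and F at the caudal end of segment 9 (six vertebral
  units);
* an elliptical cardiac silhouette whose major-axis endpoints are A
  (carina end, near the spine) and B (apex), with C and D at the ends of
  the minor axis — perpendicular to AB at its midpoint by construction;
  the axis lengths are solved against the realized $|EF|$ chord so that
  the sample's VHS equals its target exactly, given a short/long aspect
  ratio drawn from $[0.6, 0.85]$;
* nuisance structure: additive Gaussian noise (sd 0.03 in `[0,1]`
  intensity units), a random linear illumination gradient, and a rigid
  rotation (up to ±8°) plus translation of the whole scene, applied
  identically to image and landmarks.

Class targets are drawn with probabilities 208/1400, 573/1400, 619/1400
(the published training-set composition), with VHS uniform within
$[6.5, 8.2)$, $[8.2, 10]$ and $(10, 13]$ per class — the literature
gives only the thresholds, so uniform within clinically plausible ranges
is assumed and configurable. Defaults (noise level, rotation range,
96-px desk size with the 512-px preset available) were fixed once as
generator design choices.

What passing tests on this generator do show: the full pipeline —
rendering, annotation I/O, encoder, constraint layer, joint objective,
optimization, evaluation — learns the geometry-to-score mapping end to
end, with exact ground truth to measure against. What they do not show:
performance on real radiographs, which carry breed variation, exposure
artifacts, overlapping soft-tissue structure and annotation noise that
the generator deliberately does not simulate.

## Evaluation

`vhs_confusion()` and `confusion_percentages()` reproduce the reporting
conventions for three-class confusion matrices: per-cell share of all
samples, and per-row (true-class) correct and error percentages, rounded
to one decimal. `one_vs_rest_metrics()` gives per-class AUC (rank
statistic with midrank ties — verified against an $O(n^2)$ pairwise
oracle), precision, specificity and sensitivity under the argmax rule; a
class absent from the truth yields `NA`, not 0. `icc_agreement()` is the
two-way random-effects, absolute-agreement, single-measurement ICC(2,1)
— the standard inter-rater form for continuous measurements; the form is
recorded in the report so the choice is auditable.

The two training modes are compared as *C-accuracy* (cross-entropy-only
model, class from logits) versus *R-accuracy* (jointly trained model,
class from the regressed VHS), matching how such models are read in
practice.

## Scales used by the shipped checks

The acceptance-style checks train the desk model (96-px input, two
stages of widths 32/64, strides /8 and /16, heads 1/2, reduction ratios
4/2, depths 2/2) on 500 synthetic radiographs with 150 held out, for up
to 2000 steps; the joint-vs-CE comparison uses 5 seeds at 300/150 samples
and 600 steps with batch 8 — long enough that both arms are past their
warmup noise, where the comparison is uninformative; the bootstrap check trains a pure
regressor on 150 labeled images (50 held out) and labels 200 unseen
ones. These sizes are the package's desk-scale study conditions; the
`"full"` model preset (512-px input, four stages, /4 /8 /16 /32) mirrors
the full-scale architecture for users with the compute to train it.

## Known limitations

* The generator's phantoms are deliberately schematic; no claim about
  real-radiograph accuracy follows from the synthetic results.
* The desk model's first stage uses 8-px patches (a 12×12 token grid);
  sub-patch localization relies on the linear patch embedding preserving
  pixel-level information, which suffices for high-contrast phantoms but
  would be the first thing to revisit for real images (4-px patches, as
  in the full preset, at correspondingly higher cost).
* The relative-position bias table is quantized to neighbourhood-center
  offsets; disabling it (`use_attention_bias = FALSE`) costs little on
  phantoms.
* Training runs single-threaded; there is no multi-device support.
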