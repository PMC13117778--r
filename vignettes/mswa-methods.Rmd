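---
title: "Multi-scale wavelet attention for patient-level histopathology classification: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-scale wavelet attention: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Histopathological diagnosis of breast biopsies separates benign from
malignant tissue, and malignancy expresses itself largely as *texture*:
irregular nuclear detail and disordered tissue architecture spread across
several spatial scales. Plain convolutional networks see this only through
stacks of small spatial kernels; they carry no explicit notion of spatial
frequency. `mswanet` implements a residual network whose stages are
augmented with a multi-scale wavelet attention (MSWA) block that analyses
each stage's feature maps in the frequency domain, together with the strict
patient-level evaluation protocol that such models need for a credible
claim on clinical data.

## The MSWA block

Given a stage output \(X \in \mathbb{R}^{C \times H \times W}\), a separable
2-D discrete wavelet transform splits it into four sub-bands
\(\{LL, LH, HL, HH\}\) of size \(\lceil H/2\rceil \times \lceil
W/2\rceil\), the approximation band and three orientations of detail. Each
band is scored by its energy

\[
\varepsilon_s = \frac{1}{HW}\sum_{i,j} X_s(i,j), \qquad
s \in \{LL, LH, HL, HH\},
\]

averaged over channels, and the dominant band is selected; the selection is
applied recursively \(L\) times (the dominant band of level \(\ell\) is
decomposed again at level \(\ell+1\)), so the spatial size halves per level
without any extra pooling. The final band is upsampled in one direct
bilinear step back to \(H \times W\), passed through a 1×1 channel-alignment
convolution with bias, and added to the input:

\[
Y = X + \mathrm{Conv}_{1\times1}(\mathrm{Upsample}(\mathrm{MSWA}(X))).
\]

One MSWA block follows each of the four residual stages (widths
64/128/256/512 in the 18-layer backbone).

Design choices worth spelling out, with the reasoning:

* **Energy convention.** The default `raw-mean` scores a band by the plain
  mean of its coefficients, which is the formula as printed in the
  literature this block derives from. On non-negative post-ReLU activations
  the approximation band then nearly always wins, because detail
  coefficients are zero-mean. Because "energy" usually means a magnitude,
  `abs-mean` and `squared-mean` are also implemented and selectable in
  `wavelet_spec()`; they let the detail bands compete and are used in
  several of the package's own tests. The default stays faithful to the
  printed formula.
* **Tie-breaking** is the fixed precedence `LL > LH > HL > HH`, purely for
  determinism.
* **Multi-channel selection** averages energies over channels so a single
  path is selected for the whole block; a per-channel selection would
  branch the recursion.
* **Boundary handling.** The transform uses periodic (circular) extension,
  under which even-sized inputs give exactly \(H/2 \times W/2\) sub-bands
  and orthogonal families conserve energy (the Parseval identity, asserted
  to 1e-6 in the tests). Odd-sized inputs are edge-replicated by one
  row/column at the bottom/right before decomposition, which makes the
  ceiling-size law hold for every input.
* **Alignment convolution** is a bare 1×1 convolution with bias and no
  normalization or activation, zero-initialized. Zero initialization makes
  a freshly built MSWA network *exactly* the plain backbone — training
  starts from the unmodified residual network and learns how much frequency
  refinement to add. The identity is asserted at the logit level.
* **Differentiability.** The DWT and the bilinear resize are linear, so
  their backward passes are their adjoints. The argmax selection is
  discrete: it is treated as a constant of the forward pass
  (straight-through), gradients flow only through the selected path, and
  the selection is recomputed at every forward pass. Backpropagated
  gradients match central finite differences to 1e-4 wherever an epsilon
  perturbation does not flip the selection; a flip is a genuine
  discontinuity of the forward function and is excluded from the check.
* **Upsampling** is one direct bilinear resize from the final level to
  \(H \times W\) (half-pixel centers, clamped edges), not \(L\) successive
  ×2 steps; the fused operator form keeps the adjoint trivial.

The wavelet families supported are haar, db2, db4, sym4, coif2, coif3 and
bior3.5, with the standard published analysis filter pairs frozen into the
package (and exported to JSON via `write_filter_tables()` for inspection).
The tests verify the Haar pair against its closed form, filter lengths and
orthonormality for the Daubechies/Symlet/Coiflet families, and the whole
transform against a naive convolve-then-downsample reference on random
small integer inputs.

## Backbone and training

The backbone is the standard 18-layer residual design: 7×7 stride-2 stem
convolution, batch norm, ReLU, 3×3 stride-2 max pooling, four stages of two
basic blocks (3×3 convolutions without bias, batch norm, identity
shortcuts, 1×1 strided projection where shape changes), global average
pooling and a linear head. With the canonical 1000-class head the plain
backbone has exactly 11,689,512 learnable parameters, which the tests
assert; the two-class MSWA variant adds the four alignment convolutions
(349,120 parameters) for about 11.53 M total.

Because no deep-learning runtime is available to R, the package carries its
own compact engine: convolutions are lowered to GEMM via an im2col gather
written in C++ (with the col2im adjoint for the backward pass), and batch
norm, pooling, the bilinear resize and AdamW are vectorized R on BLAS. The
full backward pass is verified against central finite differences on every
parameter group of a reduced model.

Training follows the reference recipe: cross-entropy loss, AdamW with
decoupled weight decay 0.01, initial learning rate 3e-4, batch size 32, no
learning-rate schedule (only the initial rate is specified upstream; the
decay value is the optimizer's conventional default and is recorded in
`train_config()`). Where a validation fold is supplied, the epoch with the
highest *patient-level* validation accuracy is kept; the upstream protocol
says only "highest performance on the validation set", and the patient
level is the level the study reports, so that is the selection metric used.
Transfer-learned initialization is a flag in the configuration but is not
available offline; models train from He-initialized weights.

Two knobs exist purely so that the full pipeline runs on one CPU in
minutes and are not part of the reference architecture: `width_multiplier`
scales the stage widths (desk-scale experiments use 0.25, i.e. widths
16/32/64/128), and `input_size` resizes the extracted 224-pixel patches
before training (desk-scale uses 48). The network is fully convolutional
down to the pooled head, so the input size is free.

## Patch pipeline and patient-level protocol

Whole images are tiled into 224×224 patches with 20% overlap using a
valid-region rule: `stride = round(224 × 0.8) = 179` (the rounding is
explicit — floor happens to agree here but not in general), and boundary
remainders are discarded. For the native 700×460 image this gives a 3×2
grid, i.e. 6 patches. Anchors are enumerated row-major (rows outer), which
fixes the meaning of `patch_index`.

Splits happen strictly *before* patch extraction and always at patient
granularity: a stratified 70/30 train/test split (per class,
`round(n × 0.3)` test patients, minimum 1), then a stratified 5-fold
partition of the training patients by seeded round-robin dealing. The
published patient table this protocol mirrors reports a 16/41 | 8/17 split
of 24 benign + 58 malignant patients; no single rounding rule produces 8
benign test patients out of 24 jointly with 17 of 58, so the default rule
gives 7 and `patient_split(..., test_counts = c(benign = 8, malignant =
17))` reproduces the published counts literally. A `leakage_audit()` checks
any plan (and optionally a patch manifest) for patients present in more
than one subset; `run_study()` refuses to train when the audit fails.

Class balancing operates within each training fold: the benign pool is
expanded fivefold by exact pixel permutations (horizontal/vertical flips,
90° and 180° rotations) and the malignant pool is randomly downsampled
without replacement to that size — or, when fivefold benign exceeds the
malignant count, the augmented benign pool is subsampled to it. Either way
the classes end up equal and no malignant patch is duplicated.
Augmentation is materialized once per fold rather than resampled per epoch,
trading augmentation diversity for exact reproducibility of a fold's
training set under its seed.

## Ensemble, aggregation and uncertainty

Each of the five fold models predicts softmax probabilities for every test
patch; the ensemble is their per-key arithmetic mean. Hierarchical
aggregation then averages patch vectors within an image and image vectors
within a patient. Image labels are the argmax of the image vector; patient
labels apply the 0.5 threshold to the malignant probability, with the
boundary mapped to malignant — for two classes the rules coincide except
exactly at the boundary, where the malignant choice favours sensitivity,
the clinically conservative direction. An alternative single-model mode
(`ensemble = "refit"`) retrains once on the whole training split, since the
upstream description mentions both readings; fold averaging is the default.

Patient-level accuracy carries a 95% percentile bootstrap interval: 1000
resamples drawn with replacement at patient granularity. For 24-of-25
correct patients the exact resampling distribution puts the 2.5th
percentile at 22/25, so the lower bound is 0.88, which the tests assert as
the modal value across seeds. (A published table shows 0.84 for one
magnification at the same accuracy and patient count; no percentile
bootstrap can produce both bounds from identical inputs, and the package
asserts only the reproducible one.) Per-fold metrics of two models can be
compared with a standard paired t-test; zero-variance differences are
reported as a degenerate result rather than a crash.

## Grad-CAM

Attribution maps are computed at a residual-stage output, by default the
last stage, taken *before* that stage's MSWA block (the upstream
description of "the final convolutional layer of the residual stage" does
not say whether before or after the attention refinement; the attachment
point is configurable via `layer_selector`). Channel weights are the
spatial global average of the class-score gradient, the map is the ReLU of
the weighted activation sum, and for display it is bilinearly resized to
the patch and then min-max normalized — normalizing after the resize keeps
the displayed maximum exactly 1. The overlay applies a jet-style colormap
at 0.4 opacity. The normalized map is invariant to positive rescaling of
the class score, which the tests assert.

## The synthetic cohort

The generator emulates the shape of the public breast-histopathology
archives — a patient hierarchy, several 700×460 RGB images per patient,
patient-level binary labels, a magnification tag, and the directory/file
naming convention of the public dataset so the same reader indexes both —
without emulating their content. Both classes share a smooth eosin-pink
base field (a coarse Gaussian grid bilinearly upsampled, correlation length
60 px) plus mild pixel noise; malignant images additionally carry a
zero-mean sinusoidal texture of period 8 px and amplitude 30 (0–255 scale),
modulated by a smooth mask. The classes therefore have matched mean colour
and differ in *multi-scale frequency content* — exactly the signal the MSWA
mechanism claims to exploit, which is what makes the end-to-end
learnability test meaningful rather than a test of colour thresholds. A
per-patient RGB offset (SD 8) shared across a patient's images makes
between-patient variance exceed within-patient variance, reproducing the
correlation structure that image-level splitting would leak.

Defaults are 12 benign + 12 malignant patients with 4 images each at one
magnification tag; generation is byte-deterministic per seed. The shipped
defaults satisfy, with a wide margin, the separability property the tests
assert: the mean absolute-value HH energy (Haar, one level) of malignant
images exceeds the benign mean by more than three pooled standard
deviations.

What the synthetic cohort does *not* model: stain variability, nuclei- or
gland-level morphology, magnification-dependent structure, scanner
artefacts, label noise, class imbalance at the patient level. Passing the
end-to-end tests therefore demonstrates that the implementation is correct
and that the architecture can exploit a frequency-separable signal under
the leakage-free protocol — it says nothing about accuracy on real tissue.

## Problem sizes used by the test suite

All shipped experiments run on one CPU. The unit and property tests use
feature maps up to 12×12, models at 1/16–1/8 width and 32–48-pixel inputs,
and 100–200-case property sweeps. The end-to-end learnability experiment
trains, for each of five seeds, an MSWA model and a matched plain backbone
(width 0.25, input 48, 5 epochs, ~380 training patches) on the default
24-patient cohort and compares patient-level and patch-level accuracy; the
cross-validated `run_study()` smoke test uses a smaller 16-patient cohort,
two folds and one epoch. The full-scale protocol (224-pixel inputs, full
width, 50 epochs, five folds) is exactly the same code path and is driven
from the CLI script in `inst/cli/mswa.R`.

## Known limitations

* The raw-mean energy default makes the recursion collapse toward the
  approximation path on ReLU activations; the magnitude-based modes are
  the ones under which the attention path genuinely varies. Both are
  provided; the default follows the printed formula.
* Batch-norm statistics are per-training-batch; very small batches at the
  end of an epoch add gradient noise. Running statistics are used at
  evaluation.
* The engine is CPU-only and single-threaded apart from BLAS; it is meant
  for method study and testing, not large-scale training.
* `bior3.5` is biorthogonal: the Parseval identity intentionally does not
  apply to it, and it participates only in the transform-correctness
  tests.
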