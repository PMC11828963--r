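---
title: "Few-shot crystalline-ice segmentation: models, training, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Few-shot crystalline-ice segmentation: models, training, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cryoice)
options(cryoice.quiet = TRUE)
```

## The problem

Cryo-electron tomography relies on vitrification: water frozen fast enough
stays amorphous and the specimen is preserved in a near-native state. When
vitrification fails or a vitreous sample devitrifies on warming, hexagonal,
cubic, or stacking-disordered crystalline ice forms, and its diffraction
contrast corrupts the micrographs. Screening hundreds of tilt series for this
by eye is slow; `cryoice` automates it as a binary semantic-segmentation
problem — each pixel is crystalline (non-vitrified) or not — and summarizes a
dataset by its **percent non-vitrified area**, the quantity an operator
actually acts on.

The catch is distribution shift. Every acquisition (microscope configuration,
sample content, preparation) produces its own image statistics, and nobody
annotates more than a handful of micrographs per dataset. The package
therefore treats each dataset as a *task* in the meta-learning sense: a
support set (1–10 annotated micrographs used for adaptation) and a query set
(micrographs used to evaluate the adapted model). Training optimizes for
*rapid adaptation* across a distribution of such tasks rather than for one
fixed dataset.

## Segmentation model

The segmenter is a Feature Pyramid Network. An encoder with three or more
stages (each a stride-2 3×3 convolution followed by residual blocks or dense
layers) produces feature maps at strides 2, 4, 8, …; 1×1 lateral convolutions
project each to a common channel width; a top-down pathway upsamples the
coarsest map and sums it with each lateral in turn; a small head on the finest
pyramid level emits one logit per pixel, upsampled to input resolution. FPN is
preferred here because ice patches span scales from isolated spots to sheets
covering much of the lamella.

Two encoder families are available:

* **residual** — blocks compute `y = ReLU(F(x) + x)` with
  `F = conv → norm → ReLU → conv → norm`; the identity path gives direct
  signal propagation and a unit term in the Jacobian.
* **dense** — each layer consumes the concatenation of the stage input and
  all previous layers' outputs and appends `growth_rate` channels, so a block
  maps `C` channels to `C + layers · growth` before a 1×1 transition.

Concrete recipes the architecture literature leaves open were fixed as
follows: 3×3 kernels, downsampling by strided convolution, and **group
normalization** instead of batch normalization — the inner loop of
meta-learning adapts on 1–10 images, where batch statistics are degenerate;
group norm is batch-size independent. Group counts are the largest of
{8, 4, 2, 1} dividing the channel width.

The forward pass is **functional**: all weights live in a flat named list
(`model_parameters`) passed into every call. Nothing is stored in layers, so
a task-adapted parameter set `phi` and the shared initialization `theta`
coexist, which is exactly what the MAML inner loop requires.

### Hand-written differentiation

No automatic-differentiation framework is available to this package, so
gradients are computed by a small reverse-mode tape (`R/tape.R`): each
operation records its inputs and a backward closure; convolution is im2col +
GEMM with cached gather indices and a scatter-add adjoint. Every operation —
forward and backward — is written to accept complex-valued parameters, with
all branching decisions (ReLU masks, softplus branches) taken on real parts.
That makes the gradient function itself piecewise holomorphic in the
parameters, so **Hessian-vector products are computed by the complex-step
method**: `H v = Im{∇L(θ + i·h·v)}/h` with `h = 1e-30`, exact to machine
precision with no finite-difference cancellation. Gradients are verified
against central finite differences in the test suite (relative error ~1e-6 at
the test's step size), and the meta-gradient below against finite differences
of the whole bilevel objective.

## Training algorithms

**Regular gradient descent** (`train_supervised`) is plain (mini-)batch
descent on the segmentation loss. It serves both as the pre-training path and
as the *vanilla transfer* baseline: pre-train on source data, fine-tune on
the target task.

**MAML** (`meta_step`, `meta_train`) optimizes the initialization θ so that a
few inner gradient steps on a task's support set produce good query
performance:

* inner loop: `φ_i = φ_{i-1} − α ∇L_support(φ_{i-1})`, full batch over the
  support set, `inner_steps` times;
* outer loop: `θ ← θ − β ∇_θ mean_τ L_query(φ_τ)`.

The exact outer gradient needs second derivatives: it is
`∏_i (I − α H_support(φ_{i-1}))ᵀ ∇L_query(φ_n)`, applied right-to-left as a
sequence of the complex-step Hessian-vector products above
(`second_order = TRUE`). `second_order = FALSE` drops those products
(first-order MAML); it is provided because exact second-order passes on a
full FPN are expensive, while tests pin correctness on small models where the
exact path runs in seconds. With `inner_steps = 0` or `inner_lr = 0` both
variants reduce, bitwise, to one plain gradient step on the mean query loss —
a reduction the test suite asserts.

**k-shot fine-tuning** (`finetune_kshot`) adapts a checkpoint on k ∈ [1, 10]
annotated micrographs, evaluates held-out IoU after every epoch (the
unadapted model counts as epoch 0), and returns the best snapshot, ties going
to the earlier epoch to favor less overfit models. The bound of 10 mirrors
the annotation budget the workflow is designed around; an empty held-out set
falls back to the final epoch with a warning rather than failing.

### Loss

The paper-level tooling never names its loss, so it is configurable; the
default is **BCE + soft Dice** (`bce_plus_dice`). BCE alone is dominated by
the ~95% vitreous background at the few-percent foreground fractions typical
of this problem; the Dice term keeps the foreground gradient alive. Soft Dice
uses `eps = 1` in numerator and denominator, so an all-background prediction
on an all-background mask is a fixed point with zero loss rather than a 0/0.

### Default rates and sizes

`inner_lr = 0.01`, `inner_steps = 5`, `outer_lr = 1e-3`, plain SGD, 4 tasks
per meta-batch. These are conventional starting points for MAML-style
training and are exposed in `meta_config()`; the desk-scale experiments in
the tests and acceptance script use larger rates (0.05) and smaller loops
(2 inner steps, meta-batches of 2, 120 meta-iterations) appropriate to the
~34k-parameter network and 64×64 images they train — sizes chosen so the full
study (meta-training, baseline training, and a 20-task held-out evaluation)
completes in minutes on one CPU while still separating the methods cleanly.

## Synthetic task families

The generator (`sample_dataset_config`, `render_micrograph`, `make_task`)
stands in for archive data so the whole framework is testable offline. It
emulates what a segmenter actually sees in a micrograph with crystalline ice:

* a smooth cellular background (FFT Gaussian-blurred noise, smoothness 4–16
  px, amplitude 0.1) plus i.i.d. pixel noise (sd 0.05–0.15);
* bright, high-frequency, anisotropic texture patches: elliptical supports
  filled with oriented sinusoidal carriers — **one** orientation for cubic
  ice, **three at 60° spacing** for hexagonal, a **random mixture of 2–3**
  for stacking-disordered — at contrast 1–2.5 and carrier frequency 0.12–0.35
  cycles/px (below Nyquist);
* optional dark contamination discs and bright-rimmed bubbles that are *not*
  labeled as ice (their overlap with the positive mask is capped at 10% of
  the artifact area), reproducing the classic false-positive traps;
* patch placement by rejection until the mask fraction lies in
  `[0.5, 2] × ice_fraction_target`, with targets drawn from 2–10% — the
  class imbalance regime of real vitrification screening, where ground-truth
  fractions of a few percent are typical.

A *dataset* is one draw of these rendering parameters; all images in a task
share them, and the uniform priors over the parameters define the task
distribution. Within-dataset images differ in patch placement, carrier phase
and noise realization; across datasets the intensity statistics shift — the
test suite checks that the two-sample KS statistic across configurations
exceeds the within-configuration one in ≥ 90% of trials, which is the domain
shift the meta-learner must absorb. Everything is a pure function of
(configuration, seed).

What the generator does **not** emulate: contrast-transfer-function effects,
dose and tilt geometry, 3-D consistency across a tilt series, diffraction
physics of the ice phases, and annotation noise (its labels are exact). A
model that adapts well on these tasks demonstrates that the optimization and
adaptation machinery works; it says nothing about absolute accuracy on real
micrographs, which is why the package's quantitative claims are all relative
(meta-trained vs. baseline vs. random) or internal (predicted vs. generated
ground truth).

## Evaluation and quantification

IoU and F1 over binary masks, with the convention that two empty masks score
1 — a clean lamella predicted clean is a success, not an undefined case. The
two metrics are algebraically locked (`f1 = 2·iou/(1 + iou)`), which the
suite asserts on random mask pairs. `kshot_curve` evaluates each
initialization at several k with **nested supports** (the k-shot support is a
subset of the (k+1)-shot support) so curves are comparable point to point.

Percent non-vitrified area is `100 · foreground / total` pixels. Dataset
reports aggregate per-image percentages with a normal-approximation 95%
interval (`mean ± 1.959964 · s/√n`); the unit of replication is the
micrograph, since that is how per-dataset summaries are reported in this
field, and the interval method is recorded in the report metadata.

## Workflow, I/O and determinism

`load_micrograph_stack` reads little-endian MRC 2014 stacks (modes 0/1/2/6;
files flagged as volumes via `ispg ≠ 0` are rejected) and multi-page TIFF.
Preprocessing z-scores intensities, clips at ±3σ (outliers from hot pixels
and carbon edges otherwise dominate the dynamic range), rescales to [0, 1],
and resizes so the longer side hits a target (default 1024 for real data;
the synthetic experiments use 64), bilinear, aspect preserved. Constant
images cannot be z-scored and come back all-0.5 with a warning. Annotations
are CVAT-for-images polygon XML; points are `(x = col, y = row)`, converted
to matrix indexing only at the parser boundary. Rasterization uses
pixel-center containment with boundary counting as inside (deterministic and
orientation-independent), even-odd rule, union over polygons; by default all
labels are treated as crystalline ice, matching the single-class annotation
scheme. The CLI (`simulate`, `preprocess`, `meta-train`, `finetune`,
`infer`, `analyze`) is a thin wrapper over these functions; every stage is a
pure function of its inputs and seed, and the suite asserts byte-identical
reports across repeated runs.

## Numerical and design notes

* Degenerate inputs: zero-variance images warn and return 0.5; group-norm of
  a constant channel returns its shift parameter (variance 0 is regularized
  by `eps = 1e-5`); non-finite losses abort training with a diagnostic
  instead of propagating NaN.
* Ties: `predict_mask` counts `sigmoid(logit) == threshold` as positive;
  best-epoch selection breaks ties toward the earlier epoch.
* The background amplitude (0.1) is kept below the noise and texture scales
  so that per-image intensity histograms are stable within a dataset; the
  low-frequency field contributes structure, not dominant contrast.
* Package shape: the core operates on matrices and named tensor lists rather
  than data frames — images and network weights are not naturally tabular —
  while the tabular surfaces (reports, curves, logs) return tibbles with
  `tidy()`/`glance()`/`autoplot()` methods.
* Known limitations: single output class (no per-phase breakdown), no
  CTF/dose modeling in the generator, exact second-order MAML is practical
  only for small networks (use `second_order = FALSE` for FPN-sized models),
  and checkpoint files use R serialization and are not portable to other
  ecosystems.

## A small worked example

```{r example, eval = FALSE}
bc <- backbone_config(stage_channels = c(8, 16, 32),
                      blocks_per_stage = c(1, 1, 1), fpn_channels = 16)
model <- fpn_model(bc)
cfg <- meta_config(inner_lr = 0.05, inner_steps = 2, outer_lr = 0.05,
                   meta_batch_tasks = 2, meta_iterations = 120,
                   second_order = FALSE, seed = 11)
theta <- meta_train(model, build_model(bc, 101), synthetic_task_sampler(), cfg)

task <- make_task(sample_dataset_config(seed = 5001), k_support = 5,
                  n_query = 3, seed = 901)
phi <- finetune_kshot(model, theta, task$support, task$query, cfg, epochs = 8)
preds <- model_predict(model, phi$tensors, task$query)
iou(predict_mask(log(preds[[1]] / (1 - preds[[1]])))$mask, task$query[[1]]$mask$mask)
```

Run times and the quantitative comparison (meta-trained vs. baseline vs.
random initialization, and predicted vs. ground-truth ice percentages) are
produced by `scripts/acceptance.R`; see the README for how to reproduce them.
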