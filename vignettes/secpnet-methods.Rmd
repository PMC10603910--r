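---
title: "SE-Connection pyramid segmentation: model, training recipe and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SE-Connection pyramid segmentation: model, training recipe and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Radiotherapy planning for head-and-neck cancer requires delineating
organs at risk (OAR) on CT slices: eyes, temporal lobes, mandible, brain
stem, parotid and submandibular glands, spinal cord, thyroid. These organs
span a wide size range — a temporal lobe is roughly fifteen times the volume
of an eye — and plain U-shape networks systematically underperform on the
small ones: their skip connections copy encoder features without any
learnable transformation, and little global, multi-scale context reaches the
shallow decoder stages where small structures are resolved.

`secpnet` implements a segmentation family built to address exactly this:

1. **SE-Connection (SEC) skip modules.** Instead of copying encoder features
   across, each skip connection becomes a small fusion network: the deeper
   ("level 2") feature map is passed through a 3×3 same-padding convolution
   to the shallower ("level 1") channel width, bilinearly upsampled ×2,
   concatenated channel-wise with the level-1 map, fused by a second 3×3
   convolution, and finally gated by a squeeze-and-excitation (SE) block —
   global average pooling to a channel descriptor, a two-layer bottleneck
   (linear → ReLU → linear → sigmoid), and channel-wise rescaling by the
   resulting factors in (0, 1).
2. **A bottom-up pyramid.** An SE block sits at the network bottleneck; its
   output is the deepest level-2 input. Each SEC output serves *both* as the
   decoder skip input at its stage *and* as the level-2 input of the next
   shallower SEC, so global and multi-size information flows from the bottom
   of the network to the top, stage by stage.
3. **An auto-context cascade.** The primary (pyramid) network's softmax
   probability map is concatenated with the original image and fed to a
   second, plain U-shape network that refines the segmentation.

All upsampling is bilinear interpolation rather than transposed convolution,
avoiding checkerboard artifacts.

## Architecture parameters

`secp_config()` collects the architecture hyperparameters:

| parameter | default | meaning |
|---|---|---|
| `num_classes` | — | background + organ classes (softmax head; labels are mutually exclusive) |
| `in_channels` | 1 | grayscale CT slices; multi-channel input allowed |
| `depth` | 4 | number of 2× down-samplings; inputs must be multiples of `2^depth` |
| `stage_channels` | 64–1024 | canonical U-Net widths; a small preset `secp_config_small()` (depth 3, widths 8/16/32/64) serves CPU-scale studies |
| `se_reduction` | 16 | SE bottleneck divisor; hidden width `max(1, floor(C / r))`, clamped so it never vanishes |
| `batchnorm` | TRUE | batch normalisation after each 3×3 convolution block, ReLU activations |

The published description of this model family leaves depth and widths
unstated beyond "an original U-Net"; the defaults above are the canonical
U-Net choice and are fully configurable. Two wiring details were genuinely
open and are fixed here as follows: the pyramid uses one bottom SE block plus
`depth − 1` SEC modules (the shallowest, full-resolution stage keeps a plain
skip), and the bottleneck feeds the first decoder upsampling directly while
the SE-gated path climbs the pyramid. A parameter-group audit
(`n_params()`, module-name census) pins this structure in the tests.

Convolutions followed by batch normalisation carry no bias: the
normalisation removes any constant channel offset, so such a bias would
receive an identically zero gradient.

## Training recipe

`train_plan()` encodes the optimisation settings: SGD with momentum 0.9 and
weight decay 1e-4, initial learning rate 0.01, batch size up to 16, and the
polynomial decay `lr = (1 − n/N)^0.9 · lr0` applied before each epoch. The
loss is the multi-class cross-entropy of the softmax map, written in log
base 2 (bits) as the model family's description prints it; a config switch
selects the natural log, which rescales loss and gradients by exactly ln 2
and leaves the optimisation direction unchanged. The loss is averaged over
pixels (not summed) so batch-size changes do not rescale gradients.

Training is staged (`run_staged_training()` / `fit_secpnet()`):

1. **backbone** — train the plain U-shape network to convergence;
2. **secp** — build the pyramid network, initialise every shared
   encoder/decoder/output weight from stage 1, train;
3. **secondary** — freeze the primary entirely (inference mode, no gradient,
   no statistics updates) and train the second network on auto-context
   inputs;
4. **finetune** — unfreeze everything and fine-tune end to end at `lr0/10`
   (the reduction factor is this package's choice; gradients reach the
   primary through the probability-map channels).

"Convergence" is operationalised as a fixed epoch budget per stage with an
early stop when the relative loss change over 10 epochs falls below 1e-4.
Whether a 100-epoch budget applies per stage or overall was an open
question; here it is per stage, with per-stage overrides
(`stage_epochs`, `stage_batch`).

Two further choices came out of observing stage 3 at small scale:

* **Secondary initialisation.** The staged scheme names an initialisation
  source per stage but leaves the secondary's unspecified. A cold-started
  secondary is slow and erratic on rare small-organ classes, so the
  secondary warm-starts from the stage-1 backbone: every layer matches in
  shape except the first convolution, whose image channel is copied while
  the probability-map channels are freshly initialised. Stage 3 then behaves
  as a refinement that learns to exploit the auto-context channels.
* **Batch-norm recalibration.** After each stage the batch-norm running
  statistics are recomputed over the full training set with the final
  weights (a cumulative average over batches). Mini-batch EMA statistics can
  drift from full-data statistics on channels with very sparse signal — a
  small organ's probability channel is near-zero almost everywhere — which
  otherwise makes inference-mode behaviour diverge from training precisely
  on the classes that are hardest to learn.

## Evaluation protocol

Per class: Dice `2|A∩B|/(|A|+|B|)`, precision `TP/(TP+FP)`, recall
`TP/(TP+FN)`. A class absent from both masks gets Dice 1 with an `empty`
flag (this keeps the identity Dice(A, A) = 1 universal); undefined
precision/recall (zero denominators) are excluded from averages rather than
zero-filled, in the same spirit in which background-dominated accuracy and
specificity are not reported at all. Background is excluded from all means.
Two aggregations over patient volumes are provided: *Dice per case* (each
patient's slices pooled, then averaged over patients — the default) and
*Dice global* (all volumes pooled into one pixel set). Cross-validation
splits at the patient level (`kfold_split_patients()`: disjoint, exhaustive,
sizes differing by at most one, deterministic under a seed); repeated runs
are summarised as mean ± sample standard deviation (`aggregate_runs()`), and
method comparisons use a classical two-sided paired t-test with degenerate
zero-variance cases flagged explicitly.

## The phantom generator

Real OAR datasets are private; the package therefore ships a seeded phantom
generator so every module is testable without downloads. A
`phantom_spec()` describes a population: per organ class a canonical centre,
mean elliptical radius and aspect, centre and radius jitter, mean intensity,
laterality, and a presence probability (so organs are absent from some
slices, as in real slice stacks). Organs are drawn in order of decreasing
size with first-drawn-wins occupancy, so small organs are never engulfed;
canonical positions are chosen so that footprints do not nest. The image is
the per-organ intensity over a vertical background ramp plus Gaussian noise,
clipped to [0, 1]. The default 13-class population mirrors the published
organ-volume spectrum of the head-and-neck task with pixel areas
proportional to volume^(2/3) (the areal analogue), preserving the
small-organ difficulty regime: eyes, submandibular glands and thyroid each
average under 5% of foreground pixels. A 4-organ small population
(`phantom_organs_small()`) keeps the structural challenges on a 64×64
canvas: a mirrored left/right pair sharing one intensity (separable only by
spatial context), a medium organ, a small organ, and per-slice absence.

What the phantoms do **not** emulate: anatomical shape variability, CT
acquisition physics (noise correlation, beam hardening, windowing), 3D
continuity across slices, and inter-observer contour ambiguity. Passing the
phantom study shows the implementation trains, fuses multi-size information
and generalises across patients *under these synthetic conditions*; it does
not certify clinical-grade performance on real CT.

## The scaled-down study

`phantom_study()` is the package's end-to-end check at CPU scale: 10
patients × 2 slices at 64×64 with the 4-organ population, the small preset
network (depth 3, widths 8/16/32/64, SE reduction 4), the full staged recipe
(60 epochs for the first three stages, 20 for fine-tuning, batch 4 — all
within a 200-epoch cap), 8 patients for training and a held-out fold of 2
patients for evaluation by per-case Dice. These problem sizes are the
package's chosen study conditions for a single-CPU run; the published
experiments behind this model family used 256×256 slices from hundreds of
patients on GPU hardware and are out of scope here.

## Numerical choices

* Bilinear resampling uses half-pixel centre alignment (the common deep
  learning convention); resampling to the same size is exactly the identity.
* Argmax label prediction breaks ties toward the lowest class index,
  documented and tested.
* The cross-entropy clamp is `eps = 1e-12` on the true-class probability;
  the training gradient uses the exact softmax/cross-entropy form.
* Masks resample by nearest neighbour (never inventing labels); images
  bilinearly. Aspect-preserving resizing scales the longer side to the
  target and pads symmetrically with background, recording offsets for the
  inverse mapping.
* Intensity normalisation is per-slice min–max to [0, 1] with a zero-range
  guard (constant slices map to zero); no CT-specific windowing is applied
  by default since the reference preprocessing is unreported.
* Weight initialisation is He-style Gaussian scaled by fan-in; SE gate
  biases start at zero.
* The gradient-flow audit asserts that every parameter *tensor* receives a
  nonzero gradient on a seeded batch. Individual ReLU hidden units inside an
  SE gate can be inactive for a particular batch — a property of any SE
  block, not of the pyramid wiring — so scalar-level coverage sits just
  below 1 and is reported as a fraction by the acceptance script, while a
  genuine wiring defect (a dead branch) would zero an entire tensor and fail
  the audit.

## Limitations

* Pure-CPU compute engine: fine for the package's study sizes, not for
  256×256 training runs over hundreds of patients.
* 2D slices only; no 2.5D/3D variants, and no re-implementation of
  comparison architectures beyond the plain U-Net backbone.
* No data augmentation (none is part of the recipe) and no pretrained
  weights.
* The paired t-test and cross-validation utilities implement the reporting
  protocol; they do not correct for multiple comparisons across organs.
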