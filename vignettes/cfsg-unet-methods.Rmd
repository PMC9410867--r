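---
title: "Rib-fracture detection with a dual-attention residual 3D U-Net"
author: "cfsgunet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rib-fracture detection with a dual-attention residual 3D U-Net}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(cfsgunet)
```

## The problem

Rib fractures are frequent in chest trauma and easy to miss on CT: lesions
are small, irregular, and visually close to normal rib, spread over hundreds
of thin slices. `cfsgunet` implements a segmentation-based detection
pipeline for this task: a chest CT volume in Hounsfield units (HU) is
reduced to its bone region, a 3D encoder–decoder network predicts a
voxelwise fracture probability map, connected components of the thresholded
map become detection proposals, and detection quality is summarized by FROC
analysis (lesion sensitivity against false positives per scan).

The clinical datasets such models are trained on are not redistributable,
so the package ships a synthetic thorax phantom generator that reproduces
the structural assumptions the pipeline relies on. Everything below runs
end to end on phantoms.

## Bone-region preprocessing

A chest CT contains far more than bone; the preprocessing chain isolates
the skeleton and normalizes intensities:

1. **Binarize** at 180 HU (inclusive ≥, keeping boundary voxels). This
   captures cortical and most trabecular bone plus bright debris (wires,
   calcifications).
2. **Remove small components**: components smaller than 4000 mm³ (strictly,
   physical volume from the voxel spacing) are discarded *before* dilation
   so that debris is never merged into the bone mask. Individual ribs
   exceed this size; debris does not.
3. **Dilate** with a 6-connected unit ball, 3 iterations. This covers the
   peri-cortical margin — marrow and the soft-tissue rim where fracture
   lines live — and bridges small anatomical gaps (e.g. costovertebral
   joints at coarse spacing). The published pipeline names dilation but
   not the element or radius; both are configuration fields
   (`dilation_radius_voxels`, `dilation_iterations`).
4. **Largest connected component** retains the connected skeleton and drops
   anything the size filter left elsewhere. Ties are broken toward the
   component whose first voxel comes earliest in array order, which makes
   the operation deterministic.
5. **Mask and fill**: voxels outside the bone mask are set to −300 HU.
6. **Bone-window normalization**: intensities are clipped to the bone
   display window (level 300 / width 1200, i.e. [−300, 900] HU) and mapped
   linearly to [0, 1]. The window bounds are used as fixed normalization
   bounds rather than the observed min/max: with the −300 HU background
   fill the observed minimum is −300 anyway, and fixed bounds make the
   mapping identical across scans (an observed-min/max mode is available
   via `fixed_window = FALSE`).

Connectivity for component labeling defaults to 26 and is configurable
(6/18/26). An explicit morphological closing is not part of the chain;
dilation alone is what the published pipeline names, and a closing can be
emulated by raising the dilation settings.

## The network

The backbone is a residual 3D U-Net: four encoder stages (two 3×3×3
convolution + batch-norm + ReLU layers with a 1×1×1 projected residual
connection, channels doubling per stage) with 2× max-pooling between
stages, and three decoder stages that restore resolution with kernel-2
stride-2 transpose convolutions. A final 1×1×1 convolution and sigmoid
yield the voxelwise probability. Patch spatial dimensions must be divisible
by 8 (three poolings); the full-scale input is a 1×96×96×96 patch.

Two attention modules refine the decoder:

**Channel-wise fusion attention (CFAM).** At each skip connection the
encoder features `F_e` and upsampled decoder features `F_d` (both C×L×W×H)
are reduced by global average pooling to per-channel statistics `s_e, s_d ∈
R^C`. These are concatenated into a length-2C sequence and passed through a
single 1D convolution (kernel n = 5, same padding, one channel, with bias)
and a sigmoid. The first C outputs reweight `F_e` channel-wise, the last C
reweight `F_d`. Because both published attention maps are written as the
same expression σ(f_n([s_e, s_d])), the default uses one shared
convolution; a two-convolution variant is available (`cfam_shared =
FALSE`). Modeling the *joint* statistic lets the attention close the
semantic gap between fine encoder features and abstract decoder features
before they are fused.

**Spatial-wise group attention (SGAM).** After the fusion convolution the
C channels are split into G = 4 contiguous groups. Each group is collapsed
to one channel by its own 1×1×1 convolution, mapped through its own 7×7×7
convolution plus sigmoid into a spatial attention map in (0,1), and
multiplied back over the group's channels. Groups use independent
(unshared) kernels — the grouped formulation exists precisely so each
attention map can attend to a different semantic subfeature. G must divide
every decoder-stage channel count, hence `base_channels`. G = 1 reproduces
ungrouped spatial attention.

The decoder block order is: CFAM → channel concatenation → fusion
convolution block → SGAM → convolution block with an additive residual
(taken from the SGAM output) → ReLU. `use_cfam`/`use_sgam` replace either
module by the identity, reproducing the ablation family (both off is the
plain residual U-Net backbone).

Weights use He-normal initialization (sd √(2/fan_in)), seeded through R's
RNG. The output-head bias starts at −2 so the initial probability sits near
the background rate; fracture voxels are on the order of 0.1 % of a patch,
and without this offset early training is spent uniformly deflating the
output rather than shaping it.

Channel widths (32/64/128/256 at full scale) are configuration, not
hard-coded: the published figure does not print them, and the scaled-down
runs below use `base_channels = 4`.

### A note on the implementation

No deep-learning framework is available in this R stack, and the network
*is* the method, so the forward and backward passes are implemented
natively: C++ kernels (via Rcpp) for 3D convolution, transpose convolution
and max-pooling, and a small reverse-mode tape in R for composition,
batch-norm, attention and the loss. Every kernel's gradient is verified
against central finite differences in the test suite's development history,
and the attention modules are cross-checked against independent
nested-loop evaluation in the tests themselves.

## Objective, sampling, augmentation

The loss is the sum of a soft Dice loss and a weighted binary cross-entropy
over the patch:

* Dice: `1 − 2Σ(y·p) / (Σy + Σp + ε)` with ε = 1e−5 guarding the
  empty–empty patch (the published formula carries no ε; its effect is
  bounded by ε on any non-degenerate patch).
* Weighted BCE: voxel mean of `−[α·y·log p + (1−y)·log(1−p)]` with α = 5
  upweighting the rare positive class; predictions are clamped to
  [1e−7, 1−1e−7] for log safety.

Patches are sampled 60 % positive (containing at least one fracture voxel,
centred on a uniformly chosen lesion voxel with ±(patch/4) jitter) and 40 %
negative (uniform over tissue-containing origins, containing no fracture
voxel — the class contract is exact, enforced by rejection). The 60/40 mix
is applied per draw in expectation. Augmentation applies one shared
transform to image and label: independent axis flips (p = 0.5), rotation up
to ±15° about a random axis, and isotropic scaling in [0.9, 1.1]
(magnitudes are not stated in the published protocol; they are
configuration fields). Labels are resampled nearest-neighbour and
re-binarized.

Training uses Adam (β₁ = 0.9, β₂ = 0.999, ε = 1e−8), initial learning rate
1e−3, weight decay 1e−4, batch size 16, 100 epochs at full scale. The "best"
model is the epoch with the lowest validation loss (the published protocol
tunes on a validation split but names no criterion); scans are split by
whole scan, with roughly one scan in eight of the training pool held out
for validation when no explicit split is given. The redundant published
"momentum 0.9" alongside Adam's β₁ = 0.9 is read as β₁.

## Inference and proposals

Whole scans are predicted with a sliding window (96³, stride 48 at full
scale; per axis the origins are 0, step, 2·step, …, with a final
end-aligned origin if the last window would overrun, and axes shorter than
the window are zero-padded and cropped back). Windows that contain no
tissue — all normalized intensities ≈ 0, which is exactly the −300 HU fill
under the fixed bone window — are skipped. Overlapping predictions are
fused by voxelwise averaging (max-fusion available); the fused map is
thresholded at ≥ 0.4, components smaller than 300 voxels (strict) are
dropped, and each surviving component becomes a proposal whose confidence
is the mean *fused* probability over its voxels (the post-fusion map is the
defined choice; pre-fusion window scores are not retained). Proposals are
sorted by descending confidence with deterministic ties (larger volume
first, then lower component id).

## FROC evaluation

Ground-truth lesions are the 26-connected components of the annotation
mask. Matching is greedy one-to-one in confidence order: a proposal is a
true positive if its voxel IoU with some unmatched lesion strictly exceeds
0.2 (IoU exactly 0.2 is a false positive), consuming the highest-IoU
candidate. One-to-one matching is the standard FROC convention and prevents
one detection from validating several lesions; the published protocol's
phrasing does not pin multiplicity down, so the convention is stated here.
Sweeping the confidence threshold gives (FPs/scan, sensitivity) pairs;
the sensitivity at an operating point r ∈ {0.5, 1, 2, 4, 8} FPs/scan is the
maximum sensitivity at FP load ≤ r (0 if unreachable, no interpolation),
and the summary score is the arithmetic mean over the five points.
FPs/scan divides by all scans, including scans without lesions.

## The phantom generator

The generator emulates exactly the structure the pipeline assumes, nothing
more: a soft-tissue body (≈40 HU) on air (−1000 HU); a posterior spine
column (≈600 HU); `n_rib_pairs` ribs as elliptical-arc tubes (cortical
≈700 HU shell, ≈250 HU marrow core) attached to the spine and joined
anteriorly by a sternum column (≈400 HU); a handful of small bright debris
components, each strictly below 4000 mm³ and placed away from bone; additive
Gaussian HU noise; and 2–5 fracture lesions per scan. A lesion is a
transverse cortical notch: outer-shell tube voxels within ±extent/2 of a
random position along the rib, set to ≈120 HU (a callus-like density dip)
and marked in the ground-truth mask. The notch depth stays within the
dilation reach of the preprocessing defaults, so every lesion voxel ends up
inside the bone mask with its disrupted intensity visible to the network —
mirroring the anatomical reason the real pipeline dilates before masking.
The sternum matters for a subtle reason: with a through-gap fracture an
anterior rib stump would become an isolated component smaller than
4000 mm³ and the size filter would delete it; real ribcages are connected
at both ends, and so is the phantom.

Default geometry is 160³ voxels at 1 mm spacing with 6 rib pairs;
`phantom_config_easy()` is the scaled-down setting used in tests: 96³, 4
thicker ribs, 2–3 lesions of extent 4–6 voxels, noise sd 10 HU. Rib tube
radii are sized so a single rib exceeds the 4000 mm³ filter on its own.

What the phantom does **not** emulate: lungs, vessels, cartilage,
reconstruction-kernel texture, partial-volume effects, anisotropic spacing,
displaced or comminuted fracture morphology, and the intensity overlap
between subtle fractures and normal rib that makes the clinical task hard.
Passing the end-to-end test therefore shows the pipeline's plumbing and
learning machinery work — not that clinical-grade sensitivity transfers to
real data.

## Scaled-down study sizes

The full-scale protocol (818 scans, 96³ patches, 100 epochs, batch 16 on
two V100s) is far beyond a desk run, and its headline numbers depend on a
private dataset. The package's own demonstrations therefore use a
scaled-down configuration chosen once: 8 phantoms at 96³ (6 train — of
which one validation — and 2 held out), `base_channels = 4`, G = 4, 48³
patches, batch 4, 80 patches per epoch, 5 epochs, learning rate 1e−2. The
raised learning rate compensates for the ~20× fewer optimizer steps of the
short run; at the published 1e−3 the short run decreases the loss but does
not yet localize. With these sizes the end-to-end run (generation,
preprocessing, training, sliding-window inference, FROC) completes in
roughly ten minutes on one CPU core and, on the seeded demonstration,
reaches sensitivity above 0.5 at 8 FPs/scan on the held-out phantoms in
the easy-lesion setting — a deliberately loose bound demonstrating that
the learning signal flows end to end. A 100-step run of a tiny network
retains appreciable seed-to-seed variance: on some seeds the Dice term has
not yet begun to move within the budget and detection stays near zero while
the loss still decreases; that is the expected behaviour of the short run,
not a pipeline failure, and more patches per epoch (or more epochs) resolve
it.

## Numerical choices and edge cases

* Dice ε = 1e−5; prediction clamp 1e−7; batch-norm ε = 1e−5, running-stat
  momentum 0.1 (batch statistics during training, running averages at
  inference).
* Component labeling assigns ids in order of each component's first voxel
  in column-major array order; all tie-breaks derive from that order.
* An all-air scan yields an empty bone mask, an all-zero normalized volume
  and a warning rather than an error; an empty probability map yields zero
  proposals; FROC with zero total ground truth is an error (sensitivity is
  undefined).
* Masks are written as uint8 NIfTI (bit-exact round trip), volumes as
  float32. Orientation metadata is carried but never used to resample.
* All randomness (initialization, sampling, augmentation, phantoms) flows
  through R's RNG from user-supplied seeds; per-scan phantom seeds are
  derived from the base seed by a fixed offset, so any scan can be
  regenerated independently.

## Known limitations

* The native network runs on one CPU core; full-scale training (96³
  patches, base 32) is out of reach — the implementation is built for
  method fidelity and testability at reduced scale, not throughput.
* Single-stage detection: no false-positive-reduction second stage.
* No Gaussian-weighted window blending or test-time augmentation;
  overlap fusion is plain averaging (or max).
* The phantom's simplifications listed above bound what green tests imply
  about clinical data.
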