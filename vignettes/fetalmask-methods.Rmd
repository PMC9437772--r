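---
title: "Methods: automated fetal brain masking and preprocessing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated fetal brain masking and preprocessing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Fetal resting-state fMRI delivers hundreds of 3D volumes per subject in
which the fetal brain is a small, arbitrarily oriented object embedded in
bright, high-contrast maternal tissue. Adult brain-extraction tools assume
a black background and a canonical head orientation; both assumptions fail
in utero, so fetal studies have historically traced brain masks by hand,
volume by volume. `fetalmask` automates that step - a convolutional network
predicts a per-voxel brain probability for every timepoint - and wraps the
remaining preprocessing around it: grid standardization, probability-map
post-processing, rigid realignment with framewise-displacement censoring,
linear template normalization, and Gaussian smoothing. A synthetic phantom
generator supplies ground-truthed data so the entire system can be trained
and validated without any scanner data.

## The masking model

The segmentation network is a 2D U-Net applied independently to the axial
slices of each standardized volume. The contracting path is built from
blocks of two 3x3 same-padded convolutions with ReLU activations, each
block followed by 2x2 max pooling; the expanding path mirrors it with 2x2
nearest-neighbour upsampling, and each level's contracting feature maps
are concatenated channel-wise onto the corresponding expanding maps. A
final 1x1 convolution maps to two channels - background and brain - and a
per-voxel softmax yields `p(brain)`. A 2D network was chosen over a 3D one
for computational cost; the loss of through-plane context is partly
compensated by the per-slice independence assumption, which matches how
slices are acquired in EPI.

Training minimizes mean per-pixel two-class cross-entropy with the Adam
optimizer. The learning rate follows a staircase schedule
`1e-4 * 0.9^floor(t / 10000)` in batches `t`. Because the fetal brain has
no standard orientation, each training volume is augmented with one of the
8 in-plane dihedral transforms (90-degree rotations x flips) per epoch,
the *same* transform applied to every slice so the 3D shape is preserved.
Slices are then shuffled across volumes into batches. Training stops when
mean validation Dice (threshold 0.5) has not improved for `patience`
checks, and the best-validation weights are kept.

The convolution, pooling, upsampling and backpropagation kernels are
implemented in the package itself on top of Armadillo's BLAS-backed matrix
products (`src/ops.cpp`), with an im2col layout for the 3x3 convolutions.
Gradients are verified against central finite differences in the test
suite.

Depth and width are configurable; the package default is depth 4 with 32
base filters. The desk-scale experiments use depth 3 with 8 base filters,
which is sufficient for the phantom task and trains on a single CPU in
minutes. Two initialization/bookkeeping details matter in the
short-training regime. First, the final layer's brain-class bias is
initialized to the log-odds of the expected foreground fraction (~2%), so
the untrained network already outputs the correct base rate; without
this, the first few hundred batches are spent learning that background
dominates before any boundary learning starts. Second, early-stopping
checks run every 100 batches with patience 6, and score one frame per
validation subject - Dice across frames of one subject is highly
correlated, and full-subject checks quadruple the cost without changing
the stopping decision.

## Standardization

The network consumes a fixed grid: 96 x 96 x 37 voxels at 3 mm isotropic.
`standardize_volume()` resamples trilinearly onto 3 mm spacing and
zero-pads symmetrically about the volume centre (ties toward the low
index); inputs whose physical extent exceeds the grid are centre-cropped
with a warning. Intensities are normalized to [0, 1] by a robust min-max
(1st/99th percentiles, clipped) so EPI intensity outliers cannot compress
the useful range - the choice of kernel and normalization is the package's
own, and is recorded in a `standardization_record` along with the
geometric mapping. Masks travel with nearest-neighbour interpolation in
both directions, so they stay binary; `invert_standardization()` restores
the native grid exactly. Round-trip mask transport loses only boundary
voxels (Dice >= 0.95 for masks of >= 500 voxels, asserted over a random
ellipsoid suite).

## Post-processing

Probability maps are thresholded at 0.5 (the softmax argmax point), the
26-connected components of the result are labelled, and only the largest
is kept - there is exactly one fetal brain per image, and small spurious
clusters in the maternal compartment are the typical failure mode.
Thresholding before clustering makes the component analysis well-defined;
threshold and connectivity are configurable. An input with no voxel above
threshold produces an empty mask plus a warning rather than an error. The
native-space mask is applied by voxelwise multiplication.

## Realignment and censoring

Fetal motion is large and episodic, so realignment is sequential: a
6-parameter rigid transform is estimated between each pair of neighbouring
volumes (a new reference at every step), the neighbour transforms are
composed onto a common reference (the first frame by default), and every
frame is resampled exactly once with its composed transform - one
interpolation, no compounding blur.

Registration maximizes normalized cross-correlation over the 6 rigid
parameters with Nelder-Mead, coarse-to-fine (smoothed half-resolution,
then full resolution). Several numerical details matter. Both volumes are
first cropped to the bounding box of their union foreground (plus a
motion margin): the zero background of masked volumes contributes nothing
to NCC but dominates the resampling cost. Both images are pre-smoothed by
a 1-voxel Gaussian, and the full-resolution stage samples with a Keys
tricubic kernel - hard brain/background edges otherwise bias the NCC
optimum by several tenths of a degree through interpolation aliasing.
Finally, parameters below 1e-4 mm (or the equivalent rotation) are
snapped to zero when that does not worsen the objective, so registering
identical frames returns the exact identity and a motionless series has
framewise displacement identically zero.

Even so, rotation recovery on the phantom has an intrinsic floor: the
ground-truth mask silhouette is voxelized independently at each pose, and
aligning two jagged silhouettes of a ~40 mm ellipsoid at 3.4 mm voxels
leaves an irreducible uncertainty of a few tenths of a degree on large
(5-6 degree) jumps. Quiescent-period links recover to ~0.1 degree and
~0.03 mm; composed trajectories recover to ~0.1 mm and 0.4-0.6 degrees
RMS depending on the realization. This is a property of the phantom's
sharp edges, not of scanner data, whose point-spread function smooths the
brain boundary.

Framewise displacement is the Power-style scalar
`FD = sum |dt| + r * sum |dr|` with reference radius `r = 50` mm
(configurable; the fetal head is smaller, and 25 mm is also reported in
QC contexts). The parameter deltas are taken from the *relative* rigid
transform between consecutive frames, which makes FD exactly invariant to
the choice of common reference and equal to naive parameter differencing
for pure or small motions. Frame `n + 1` is censored when `FD(n)` exceeds
the threshold; `fd_sweep()` tabulates minutes retained across a threshold
grid (default 0.5-3.8 mm in 0.3 mm steps).

## Template normalization and smoothing

`register_affine()` estimates a 12-parameter linear map (translation,
rotation, scale, shear) to a user-supplied template by NCC, initialized
from the rigid solution and refined coarse-to-fine with restarted
Nelder-Mead (12-dimensional simplices collapse easily; a restart from the
incumbent is cheap insurance). No template is bundled - age-specific fetal
templates exist in the literature, and the phantom module emits its own
template for tests. Smoothing is a separable Gaussian per frame,
`sigma = FWHM / (2 sqrt(2 ln 2))` per axis converted to voxels; boundaries
are zero-padded without renormalization, consistent with masked data
(default FWHM 4 mm, always user-overridable).

## The phantom generator

The generator reproduces the image characteristics that defeat adult
tools, not scanner physics:

* **Native grid** 80 x 80 x 32 at 3.4 mm (extent 272 x 272 x 109 mm), which
  fits inside the standard grid, so standardization involves no cropping.
* **Brain**: a textured ellipsoid with semi-axes `(40, 33, 27) mm * age/30`
  for a pseudo-gestational-age in 24-39 weeks - about 150 cm^3 at 30
  weeks, matching fetal brain volume at that age - in a uniformly random
  orientation with a random centre offset constrained to keep the brain
  inside the field of view. Texture is a seeded sum of five 3D cosines
  (wavelengths 15-40 mm) around 650 a.u., evaluated analytically in
  brain-local coordinates so it moves rigidly with the brain.
* **Maternal compartment**: no black background - a ~280 a.u. base with
  smooth cosine texture, 12 Gaussian blobs of amplitude -200 to 700 a.u.
  (high-contrast boundaries, varied intensity), and a bright abdominal
  rim near the FOV edge.
* **Motion**: quiescent runs of 6-15 frames (0.03 mm jitter) alternating
  with jumps to new poses within +/-4 mm and +/-6 degrees, mirroring how
  fetuses cycle through quiescent states. Ground-truth masks are the
  analytically moved ellipsoid - no interpolation error - and the true
  poses are returned per frame.
* **Noise and artifact**: additive Gaussian noise (sd 25 a.u.; a Rician
  model is deliberately out of scope), and an optional aliasing ghost - an
  attenuated copy of the brain wrapped half a FOV along the phase axis,
  the artifact observed to degrade masking on real data.

Everything is determined by the seed, bit-for-bit. What the phantom does
*not* emulate: k-space/EPI physics, susceptibility distortion, partial
volume at the brain edge (the silhouette is sharp), BOLD signal, or
through-plane slice timing. Tests passing on phantoms therefore establish
that the implementation is correct and the pipeline is coherent - not that
the network generalizes to scanner data; for that the training step must
be re-run on hand-masked volumes.

## Desk-scale benchmark

`run_segmentation_experiment()` generates 30 subjects (4 frames each),
splits 20/5/5 at the subject level, trains the depth-3/base-8 network for
up to 1,000 batches, and evaluates the 20 held-out test volumes through
the full deployment path, scoring masks in native space against the
ground truth. Training labels are the phantom's analytic mask rendered
directly on the standard grid: nearest-neighbour resampling of the native
mask would alias the boundary and train the network against label noise
(with hand-drawn masks on real data, that resampling noise is
unavoidable; with an analytic phantom it is not). Problem sizes were chosen so the whole
experiment runs in minutes on one CPU while leaving the brain ~25 voxels
across on the standard grid - large enough that boundary effects do not
dominate the Dice. `scripts/acceptance.R` re-runs exactly this experiment
from scratch and writes the mean per-volume Dice, sensitivity and
specificity as JSON.

## Known limitations

* The phantom's intensity model is stylized; absolute Dice values on
  phantoms say nothing quantitative about scanner data.
* NCC-based registration assumes the masked brain dominates the image;
  empty or near-empty masks degrade links to identity (flagged, not
  fatal).
* The 2D slice model ignores through-plane context; 3D convolutions are a
  known improvement direction.
* Hausdorff distance uses the maximum by default (a percentile variant is
  exposed), and surface voxels are defined by 6-connectivity to the
  background; other conventions exist.
* Multi-echo acquisitions, nonlinear warps, DVARS-style intensity outlier
  metrics and slice-timing correction are out of scope.
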