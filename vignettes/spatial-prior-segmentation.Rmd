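---
title: "Segmenting lateralized neuroanatomy with spatial priors and a 3D FCN"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting lateralized neuroanatomy with spatial priors and a 3D FCN}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(priorseg)
```

## The problem

Patch-based 3D convolutional networks segment brain structures from local
appearance alone. A patch classifier that sees a 25^3 window of a
T1-weighted image has no idea *where* in the brain that window sits, which
becomes a real failure mode for laterally symmetric anatomy: the left and
right hippocampi have essentially identical intensity statistics, and an
appearance-only network confuses them, scattering wrong-hemisphere false
positives across the image. `priorseg` implements a segmentation method
that fixes this with two cheap, linear-registration-derived spatial priors,
plus an elastic-deformation augmentation scheme that lets small cohorts
train deep networks without overfitting.

All images are assumed to already live in a common stereotaxic space
(e.g., affinely registered to an MNI template at 1 mm isotropic
resolution); registration itself is out of scope and treated as an input
precondition.

## The model

The backbone is a fully convolutional 3D network: `d` valid (unpadded,
unit-stride) 3x3x3 convolutions with ELU activations and `w` filters each,
so an input cube of side `s` shrinks to `s - 2d`. The baseline uses `d = 8`
and `w = 32`, mapping a 25^3 patch to a 9^3 patch of label posteriors; the
deep variant uses `d = 16` and a 41^3 input for the same 9^3 output. A
*dense connection* concatenates the centrally cropped feature maps of all
`d` convolutional layers (`d*w` channels), giving the classifier
simultaneous access to high-resolution early features and abstract deep
features. The concatenation is batch normalized and passed through two
1x1x1 convolutional layers (128 and 64 filters, ELU, dropout 0.1) and a
1x1x1 classifier with a voxelwise softmax over the `C` classes.

Training minimizes the categorical cross-entropy averaged over batch and
output voxels plus an l2 penalty `alpha = 1e-4` on the convolutional
filters (biases and batch-norm parameters are not penalized). Optimization
is RMSProp (decay 0.9) composed with Nesterov momentum 0.9 at a static
learning rate of 2.5e-4; weights start from Glorot uniform initialization
with zero biases.

## Spatial priors

Two complementary priors inject location awareness:

* **Coordinate channels.** Three extra input channels hold each voxel's x,
  y and z coordinates, extracted as patches exactly like the appearance
  channel. Because every image shares one common space, a coordinate patch
  tells the network where in the brain it is looking. We rescale each axis
  linearly to [-1, 1] (`coordinate_images(..., mode = "normalized")`):
  the mapping is invertible so no information is lost, and raw indices in
  the hundreds would dwarf the unit-variance appearance channel.
  Coordinate channels are *not* per-patch normalized — that would destroy
  precisely the information they carry.

* **Working and positive volumes.** For each structure `c`, the training
  labels vote: the union minus the intersection of the subject masks is
  the shell where subjects disagree, dilated once with a full 3x3x3
  element to stay conservative on unseen subjects — the working volume
  `B^c`. Voxels inside every subject's mask and outside `B^c` form the
  positive volume `P^c`: they are so consistently labelled that the
  network is never asked about them; they receive label `c` directly at
  test time. The global working volume `B` (union of the `B^c`) is the
  only region where training patches are sampled and tiles are evaluated,
  which both focuses learning on the genuinely ambiguous voxels and cuts
  inference cost substantially.

Priors are computed from all non-test subjects — the training *and*
validation subjects — because validation patches are sampled inside `B`
too; the test subjects never contribute, so there is no leakage.

## Elastic deformation augmentation

Each training sample (appearance, coordinate channels and one-hot labels
together) is warped by a fresh random field: i.i.d. U(-1, 1) displacement
components per voxel, Gaussian-smoothed per axis with SD `sigma_e`,
globally rescaled so the mean per-voxel displacement *magnitude* is
exactly 1, then multiplied by `alpha_i`. Defaults `sigma_e = 4` mm and
`alpha_i = 2` mm follow a coarse grid search over {4, 8, 16} x {1, 2, 4, 8}
mm. We read "mean per-pixel displacement" as the mean Euclidean norm of
the 3-vector — the displacement *of* a voxel is naturally a vector
magnitude — making the normalization an exact invariant that the tests
assert to 1e-9. Warping uses trilinear interpolation with edge clamping;
one-hot labels become soft labels at structure boundaries (a mild,
welcome label smoothing), and we renormalize the per-voxel class sums to
1, which only matters where edge clamping breaks exact affinity of the
interpolation. Reflections and rotations are deliberately absent: for
images already in a common space they would create implausible anatomy.

## Training procedure

One *iteration* samples ~`voxels_per_iteration` patch centres — an equal
quota per (subject, class) stratum, drawn uniformly from that class's
voxels inside `B`, with replacement when a stratum is small — extracts
patches, per-patch normalizes the appearance channel to zero mean and
unit SD, augments on the fly, and consumes everything in shuffled
minibatches of `B = 128` (32 for the deep variants). The validation set is
built once before training by *uniform* (not class-balanced) sampling
inside `B` from held-out validation subjects (20% of the cohort), so its
class mix reflects the true working-volume distribution. After each iteration
the validation cross-entropy is measured; training stops when it has not
improved for 30 iterations and the weights of the best-validation
iteration are kept.

At test time the network slides over `B` with a stride of 4 voxels,
per-voxel probabilities are arithmetic means of all overlapping tiles,
labels are the per-voxel argmax inside `B` (ties to the lower class
index), positive volumes override, everything else is background, and an
optional postprocessing step keeps only the largest connected component
per class (26-connectivity by default; the configurable choice errs
against splitting thin diagonal structures).

## The phantom cohort

Real cohorts of labelled T1-weighted MRI cannot ship with a package, so
`priorseg` generates phantoms that isolate exactly the property the method
addresses: an ellipsoidal "head" containing a mirrored left/right pair of
superellipsoid structures with *identical* intensity statistics
(background 0, head tissue 40, structures 60 on a 0-100 scale, Gaussian
noise SD 5). Only location distinguishes the hemispheres, so an
appearance-only classifier must confuse them while a location-aware one
need not. Per-subject anatomical variability comes from warping the
template with the same elastic field sampler used for augmentation
(`sigma = 8` mm, mean displacement 3 mm — enough that the cohort's
union-minus-intersection shells are a realistic few-voxel-wide band).
Scan-rescan pairs share the anatomy seed and differ only in the noise
draw. The phantoms deliberately omit MRI physics (bias fields,
multi-contrast, partial-volume tissue mixtures beyond interpolation), so
passing tests demonstrate the correctness and the qualitative behaviour
of the method, not clinical-grade accuracy.

## Scaled experiment sizes

The shipped tests and the acceptance script run a complete
train/segment/evaluate ablation (CNN-B, the appearance-only baseline,
against CNN-SP with both priors) on CPU-sized problems chosen once:
14 subjects on 48^3 grids (10 for training including the 2-subject
validation split, 4 held out), depth 8 with 8 filters per layer,
90 sampled voxels per iteration in minibatches of 30, 50 validation
patches per subject, at most 15 iterations with patience 6, inference
stride 4. The narrow width and short schedule keep a full two-variant
ablation within minutes while leaving the architecture's depth, patch
arithmetic, sampling scheme, optimizer and inference pipeline exactly as
at full scale. The experiment reproduces the qualitative result: the
baseline scatters wrong-hemisphere components that the spatial-prior
variant avoids, and CNN-SP's mean Dice exceeds CNN-B's.

## Numerical choices and edge cases

* Constant appearance patches normalize to all zeros (`SD` floored at
  1e-8): pure-background patches carry no appearance information.
* Patch regions outside the volume are zero-filled; for label patches
  the background channel is set to 1 there, keeping targets on the
  simplex.
* Probabilities are clipped to `[1e-7, 1 - 1e-7]` before logs; batch
  norm uses eps 1e-5 and running-statistics momentum 0.9 (inference uses
  running statistics, so inference is deterministic); ELU shape is 1;
  Gaussian smoothing truncates at 4 SD; RMSProp eps is 1e-6.
* Dice of two empty masks is reported as 100 with a warning; one empty
  mask gives 0; the MHD is an error on empty masks and `NA` in reports.
* The MHD averages nearest-neighbour distances over *all* mask voxels
  (not boundary voxels), following the definition's wording literally;
  overlapping voxels contribute zero, which matches the sub-voxel MHD
  magnitudes typical of good segmentations.
* The modal 3x3x3 label filter keeps the original label on ties
  (minimal-change smoothing). It is not exactly idempotent on shapes with
  sharp corners — each pass chamfers the newly exposed edge — but flat
  interfaces and uniform regions are fixed points.
* Argmax ties, component-size ties and subject splits are all resolved
  deterministically; every random stream derives from one master seed, so
  cohorts, training runs and segmentations reproduce bit-exactly.

## Known limitations

The network runtime is a single-threaded CPU implementation (GEMM-based
im2col convolutions in compiled code); it is meant for method study and
moderate problem sizes, not GPU-scale cohorts. Working volumes assume
anatomically regular structures under linear registration — highly
variable cortical structures would need wider dilation or probabilistic
atlas priors, which are out of scope. The deep 16-layer variant and
augmentation are implemented and tested functionally, but the shipped
experiments use the 8-layer baseline geometry for runtime reasons.
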