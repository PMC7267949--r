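# priorseg

Patch-based 3D fully convolutional segmentation of neuroanatomical
structures in linearly co-registered T1-weighted-like volumes, with
**registration-derived spatial priors**. For researchers studying
segmentation methodology: the package implements the full
method — network, priors, augmentation, training, inference,
evaluation — as plain R + compiled kernels, testable end to end on
generated phantom cohorts without any external data.

## The method

A fully convolutional network of `d` valid 3x3x3 convolutions (ELU, no
padding, no pooling) maps a 25^3 patch with `N` channels to a 9^3 patch of
class posteriors (`out = in - 2d`; the 16-layer deep variant takes 41^3
input). A dense connection concatenates the centrally cropped feature maps
of all convolutional layers before batch normalization, two 1x1x1 layers
(128, 64 filters; dropout 0.1) and a spatial-softmax classifier. Training
minimizes `L = J + alpha * ||W||^2`, the voxel-averaged categorical
cross-entropy plus an l2 filter penalty, with RMSProp + Nesterov momentum
at a static learning rate of 2.5e-4, class-balanced patch sampling, and
early stopping on a fixed validation set.

Spatial context comes from two priors computed in the common space:

* **coordinate channels** — three extra input channels holding each
  voxel's (x, y, z) position, rescaled to [-1, 1];
* **working volumes** — per structure `c`, `B^c = D ⊕ (U^c − I^c)`, the
  3x3x3-dilated disagreement shell between the union `U^c` and
  intersection `I^c` of the training masks, with the complementary
  **positive volume** `P^c = I^c − (I^c ∩ B^c)` labelled `c` directly at
  test time. Sampling and inference are restricted to `B = ∪ B^c`.

Random elastic deformations (U(−1,1) field, Gaussian-smoothed with
`sigma_e = 4` mm, normalized to unit mean displacement, scaled by
`alpha_i = 2` mm) augment every training sample on the fly. Evaluation
uses the Dice coefficient (percent) and the modified Hausdorff distance
`MHD = max(h(A,R), h(R,A))` in mm.

## Worked example

Generate a mirrored-structure phantom cohort, fit the spatial-prior
variant, and segment a held-out subject:

```r
library(priorseg)

cohort <- generate_cohort(phantom_config(grid_side = 48L, seed = 1L), 12)

model <- priorseg_fit(
  cohort[1:10], variant = "CNN-SP", width = 8L,
  config = train_config(voxels_per_iteration = 90L, batch_size = 30L,
                        validation_patches_per_subject = 50L,
                        max_iterations = 10L, patience = 6L),
  seed = 1L)
print(model)
#> <priorseg_model> variant CNN-SP
#> 3D FCN: 8 x conv3(8) -> dense(64) -> BN -> conv1(128) -> conv1(64) -> softmax(3)
#> input 25^3 x 4 channels -> output 9^3 x 3 classes; 29,923 parameters
#> trained 10 iterations (best validation loss 0.1972 at iteration 8)
#> priors from 10 subjects; working volume 8074 voxels

seg <- predict(model, cohort[[11]], stride = 4L)
evaluate_segmentation(seg$labels, cohort[[11]]$labels, voxel_size = 1,
                      subject_id = "sub-011")
#>  subject structure dice_pct     mhd_mm
#>  sub-011         1 94.45378 0.09257266
#>  sub-011         2 94.98102 0.05218855
#> mean Dice 94.7% (SD 0.4), mean MHD 0.07 mm
```

Structure 1 is the left and structure 2 the right mirrored structure; the
Dice values are their overlap with the phantom's true masks and the MHD
their mean boundary discrepancy in mm. The same phantom cohort makes the
failure mode of the prior-free baseline visible: `run_ablation()` trains
`CNN-B` (appearance only) and `CNN-SP` (both priors) with shared seeds and
tallies wrong-hemisphere components, which only the baseline produces.

A thin CLI wraps the same functions (`exec/priorseg`):
`priorseg make-phantoms | build-priors | train | segment | evaluate |
crossval | ablation | reliability`.

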