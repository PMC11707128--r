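---
title: "Methods: two-stage 3D U-Net segmentation of the bony pelvis and mesh-based evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-stage 3D U-Net segmentation of the bony pelvis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Harvesting a vascularized iliac crest graft for mandible reconstruction
requires patient-specific geometric models of the pelvic bone, and building
those models from CT by hand is the slow step of computer-assisted surgical
planning. `crestseg` automates it: a CT volume goes in, a triangulated
surface mesh of the bony pelvis in patient millimetre coordinates comes
out, together with evaluation machinery that scores a predicted mesh
against a reference mesh — on the whole bone and restricted to the
transplant-relevant crest region on each side.

## The segmentation model

Segmentation is a coarse-to-fine cascade of two independently trained 3D
U-Nets that both solve the same binary task (bone vs background):

1. **Stage 1** sees the whole field of view, resampled to a fixed
   160 x 160 x 224 grid. Its only job in the pipeline is localization: its
   binarized output defines a bounding box around the bone.
2. **Stage 2** sees only the crop around that box, resampled to
   256 x 144 x 144. Because the crop excludes most of the body, the
   effective voxel size inside the region of interest is much finer, and
   the second network can commit its limited capacity to the bone surface.

Both grids were chosen to match average CT aspect ratios (stage 1) and
average pelvis aspect ratios (stage 2); each dataset is scaled to the
common grid, so per-case voxel spacing varies and is tracked through every
step (`resample_to_shape()` keeps the physical extent of the grid exact).

The network (`unet_config()`, `build_network()`) is a standard 3D U-Net
with five resolution levels: ten 3 x 3 x 3 convolutions in the encoder with
four 2 x 2 x 2 max-poolings in between, feature maps doubling after every
pooling, and nine decoder convolutions with four 2 x 2 x 2
nearest-neighbour up-samplings, skip concatenation at matching levels, and
a final 1 x 1 x 1 sigmoid convolution. Activations are ReLU and no
normalization layers are used; both choices are deliberate defaults for a
small, fully convolutional network with a single input channel. The
network is fully convolutional, so its weight count depends only on the
configuration — the same weights run at any grid divisible by 16 per axis,
which is what makes transfer between the two stage resolutions possible.

**Initialization.** Weights are Glorot-uniform. The output bias starts at
`qlogis(fg_prior)` (default prior 0.1) instead of zero: with a zero bias
the initial probability map is 0.5 everywhere and the first epochs of Dice
training are spent uniformly pushing the background down before any shape
learning starts; starting at the expected foreground fraction removes that
dead phase. Stage 2 is trained from this initialization; stage 1 is then
*transfer-initialized* from the final stage-2 weights
(`transfer_init()`), the idea being that the cropped task is the easier
one and its features transfer to the harder full-field task. Freezing
layers during fine-tuning is supported but off by default — the whole
network is fine-tuned.

## Training

The loss is the soft Dice loss `L = 1 - DS` with
`DS = (2 Σ p·t + ε) / (Σ p + Σ t + ε)` and `ε = 1e-6` (the stabilizer
keeps the loss defined on empty targets). Optimization is Adam at batch
size 1 with initial learning rate 5e-4. After each epoch the mean
validation Dice loss drives a reduce-on-plateau scheduler: the rate is
divided by 10 after 10 epochs without improvement, and training stops
after 30 epochs without improvement; the weights of the best validation
epoch are kept. Two details the schedule leaves open are fixed as
follows: "improvement" means a decrease of more than 1e-5 (absolute), and
after a rate reduction the plateau counter for the *rate* criterion
restarts while the early-stop horizon keeps counting from the last real
improvement — this is the only arithmetic under which a first reduction
at +10 and a stop at +30 can coexist. The scheduler is a pure state
machine (`scheduler_new()` / `scheduler_step()`) and is tested in
isolation with scripted loss sequences. One addition to the optimizer
loop: gradients are clipped to a global norm of 1.0 before each Adam
update. Full-volume Dice training at batch size 1 occasionally produces a
single enormous gradient that kills every ReLU in one step (training loss
pinned at exactly 1 afterwards); the clip removes that failure mode and
is inert otherwise. No data augmentation is used anywhere.

**Training targets.** Reference segmentations enter as watertight surface
meshes in patient coordinates. They are rasterized at native CT
resolution with a *greedy* rule (`greedy_voxelize()`): a voxel is
foreground iff its box has positive-measure intersection with the mesh
interior or surface. This deliberately over-covers (a superset of the
centre-containment mask) so that thin cortical shells are never broken by
rasterization; the post-processing erosion compensates the dilation at
the other end of the pipeline. Greedy masks and the windowed CT are then
resampled to the stage grid; masks are interpolated trilinearly and
re-thresholded at 0.5 rather than nearest-neighbour sampled, again to
avoid aliasing holes in thin structures. Stage-2 training crops come from
the ground-truth bounding box with a 10% margin — at training time the
stage-1 predictions do not exist yet, since the stages are trained
separately and in reverse order.

**CT normalization** is a package default: clip to the full 12-bit CT range [-1024, 3071] HU and
map to [0, 1]. The wide window keeps metal unsaturated and preserves
bone/soft-tissue contrast without tuning to any particular cohort.

## Inference and post-processing

`run_pipeline()` composes: normalize, resample, stage-1 prediction,
binarize at 0.5 (`binarize_threshold`; symmetric sigmoid cut), bounding
box + 5% margin (`roi_margin`), crop, resample, stage-2 prediction,
binarize, and post-processing. An empty prediction raises a "bone not
found" error rather than returning an empty result.

Post-processing (`postprocess_mask()`) converts the binary stage-2 output
into the planning mesh: one layer of 6-connected binary erosion
(compensating the greedy dilation of the training targets), Gaussian
smoothing of the {0, 1} field with sigma = 1 voxel, and iso-surface
extraction at 0.5. The sigma/iso pair is the smallest smoothing that
removes voxel staircase artifacts while keeping the enclosed volume
approximately unbiased. Disconnected fragments (typical at the
sacrum after erosion) are *kept* — they are part of the prediction and are
scored like everything else; no largest-component selection is applied.

The iso-surfacer is marching cubes over a uniform 6-tetrahedron (Kuhn)
decomposition of each cell, with vertices welded on shared cell edges and
outward orientation. On the smooth fields it sees in this pipeline
(always post-Gaussian) its surface area and enclosed volume are within a
fraction of a percent of analytic references; like every midpoint
iso-surfacer it would inflate the area of a *raw* binary field by the
staircase factor, which is one more reason the smoothing step is not
optional.

## Evaluation metrics

All evaluation operates on meshes, not voxel masks, because the mesh is
the artifact surgical planning consumes.

* **Dice (`mesh_dice()`)**: both meshes are voxelized by centre
  containment on one shared 0.5 mm-pitch grid covering their joint
  bounds; DSC is the volumetric overlap of the two occupancy sets. The
  shared grid makes the value exactly symmetric; the pitch is
  configurable and the value converges as the pitch is refined.
* **Symmetric average surface distance (`asd_symmetric()`)**: area-weighted
  random samples on each surface (default 1e5 per surface, seed recorded),
  *exact* point-to-triangle distances against the full opposing surface
  (uniform-grid accelerated, verified against a plain-R O(N·M) brute-force
  oracle), pooled over both directions.
* **Symmetric 95% Hausdorff (`hd95_symmetric()`)**: 95th percentile of the
  pooled directed distances. Taking the max of the two one-sided
  percentiles instead is available behind `method = "max"`; pooling is the
  default reading of a "symmetric" percentile.

**Transplant ROI.** The crest region is isolated by an oblique cutting
plane stored relative to the bone's geometric centre — implemented as the
surface-area centroid, which stays defined for the non-watertight
fragments post-processing can produce (a volume centroid would not). On
top of centring, the stored anchor is divided componentwise by the mesh
bounding-box half-extents, so the plane scales with bone size when
transferred to a differently sized pelvis; a pure-translation mode
(`mode = "translate"`) is available where strict centre-relative
placement is wanted. Left and right definitions are mirror images across
the mid-sagittal (first grid) axis. For every evaluated case the absolute
plane is derived from the *ground-truth* mesh and the identical plane is
applied to the prediction, so both meshes are clipped to the same region
by construction. Clipping splits crossing triangles exactly, so kept plus
discarded area equals the original area. One subtlety: the clipped
surfaces are *open* along the cut, and the parity-based inside test that
Dice voxelization relies on is only defined for closed surfaces — ROI
Dice therefore voxelizes the two *whole* meshes and restricts the overlap
to voxel centres on the crest side of the plane (the volumetric Dice of
solid-intersect-halfspace), while the ROI distance metrics sample the
clipped surfaces directly.

Cohort summaries (`summarize_cohort()`) report mean, SD, min, 25%, median,
75% and max per metric and scope; percentiles use linear interpolation
(quantile type 7).

## The phantom generator

No patient data ships with the package; `generate_phantom()` produces the
cohort the tests and the acceptance experiment run on. Each case is the
zero level set of an analytic implicit field — two bent, thin-walled
ellipsoid-shell "iliac wings" (upper part of the shell only, giving the
curved crest) plus a rounded sacrum-like block — embedded in a
soft-tissue background. Intensities: tissue ~ N(40, 15) HU, bone ~
N(700, 100) HU, plus N(0, 20) acquisition noise; the class means are >3
pooled SD apart, which is what makes a 4-filter network learnable at desk
scale. Grid shapes (84 x 84 x 60 +/- jitter), spacings (1.3, 1.3, 1.8 mm
+/- 20%), structure sizes, pose and left/right asymmetry all vary per
case, seeded; the bone occupies roughly 1-2% of the volume so the ROI
crop covers only ~12% of the field of view and the second stage has a
genuine resolution advantage, as in clinical acquisitions. The
ground-truth mesh and the intensity rasterization come from the same
field on the same grid, so the mesh/voxel representations are consistent
by construction (and the greedy mask of the mesh provably covers the
intensity foreground). `corrupt_case()` adds the classic acquisition
problems — metal implant streaks, patient tilt, cropped caudal slices —
for robustness tests only; corrupted cases never enter default cohorts.

What the phantoms deliberately do **not** model: trabecular texture,
cortical density gradients, beam hardening or any CT reconstruction
physics, neighbouring bones (femora, spine), and anatomical shape detail
beyond "bilateral curved shells + block". A network that segments
phantoms is therefore evidence that the *pipeline* (targets, training
loop, cascade, post-processing, metrics) is correct end to end — not
evidence of clinical segmentation accuracy.

## Desk-scale problem sizes

The end-to-end experiment (`run_desk_experiment()`) mirrors the clinical-scale
configuration at roughly 1/12 scale, chosen so the whole experiment runs
in minutes on one CPU core: 45 phantoms split 30/5/10
(train/validation/test), `base_filters = 4`, stage grids 48 x 48 x 48 and
64 x 48 x 48, stage-2 trained for up to 22 epochs from its Glorot
initialization and stage-1 fine-tuned for up to 12 epochs from the
transferred weights (the transfer start is what makes the shorter stage-1
schedule sufficient). Mesh metrics on the held-out phantoms use 2e4
surface samples and a 1 mm Dice pitch. At this scale the cascade's
qualitative claims — two-stage output beats the coarse stage, median
whole-phantom mesh DSC >= 0.8, ASD within two voxels — are reproducible;
the clinical-scale accuracy numbers of a 1,000-patient corpus are not
reproducible from synthetic data and are not claimed.

## Numerical choices and degenerate inputs

* Greedy voxelization counts only positive-measure intersections: a mesh
  face lying exactly on a voxel boundary does not claim the far voxel
  (surface tests use boxes shrunk by 1e-9 of a voxel). This makes the
  axis-aligned cube counts exact.
* Inside/outside queries use parity ray casting with a fixed sub-voxel
  ray jitter, so rays never hit triangle edges exactly; the jitter is
  deterministic, keeping every voxelization reproducible.
* Surface sampling and all metric sampling take explicit seeds; the same
  seed gives bitwise-identical samples regardless of the caller's RNG
  state (`with_seed` save/restore).
* `quantile` type 7 everywhere a percentile is reported.
* Degenerate inputs fail loudly: empty meshes cannot be written or
  sampled, Dice of two empty meshes is an error (one empty mesh scores
  0), an all-background prediction raises "bone not found", and a mask
  emptied by erosion returns an empty mesh with a warning rather than an
  error (the case is real: a one-voxel-thin prediction).

## Known limitations

* Only axis-aligned NIfTI volumes are supported (gantry-tilted or
  obliquely acquired series are out of scope; DICOM series input is not
  implemented).
* Training is single-volume Adam on one CPU core in this build; it is
  deterministic per seed on a fixed machine, but bitwise reproducibility
  across different BLAS builds is not guaranteed.
* The greedy-mask / erosion pair assumes the training-target dilation and
  the post-processing erosion roughly cancel; at very coarse stage
  resolutions (voxels much thicker than the cortical shell) the
  cancellation is imperfect and shows up as a small systematic surface
  bias.
* `mesh_dice()` is a voxelized approximation; at the default 0.5 mm pitch
  its discretization error is well below the differences the cohort
  statistics report, but it is not an exact boolean-volume computation.
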