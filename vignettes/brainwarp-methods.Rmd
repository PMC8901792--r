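---
title: "Spatiotemporal registration of developing brain volumes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatiotemporal registration of developing brain volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

brainwarp reconstructs mesoscale developmental dynamics of the perinatal
mouse brain from ex-vivo 3D volumes: it aligns samples in space with a
free-form deformation optimized by attention-gated simulated annealing, then
aligns them in time by estimating each sample's developmental ("adjusted")
age from pairwise image dissimilarities, and finally renders continuous
weighted-average and differential volumes. This vignette explains the
models, the tunable parameters, the numerical choices, and what the
synthetic validation does and does not show.

## The registration problem

Perinatal brains grow quickly, change shape as regions mature, and develop
at individual paces only loosely coupled to the recorded birth date.
Registering such samples to a common frame therefore needs (i) features that
make the similarity measure sensitive to mesoscale structure mismatches,
(ii) an optimizer that tolerates pronounced differences between samples
without diverging, and (iii) a temporal correction for individual
developmental pace.

## Preprocessing: the filtered feature image

Raw stacks are resampled to an isotropic working resolution (12 µm for
light-sheet data; `load_and_standardize()`), thresholded at 1% of the
maximum intensity to suppress background, and equalized per XY-slice to
compensate for attenuation along Z. Equalization maps each slice's nonzero
voxels through their empirical CDF. Two details matter:

* **Suppression runs before equalization.** Rank-based equalization is
  scale-free: if faint background noise survived into the equalization it
  would be stretched across the full output range, in the worst case filling
  slices that contain no sample at all. Thresholding on the raw intensities
  first means ranks are computed over sample voxels only.
* **Exact (ECDF) equalization rather than a fixed bin count.** With binned
  mapping, distinct intensities falling into one bin collapse and, on
  tier-like histograms, a heavily tied minimum maps to zero and is lost to
  the background. The ECDF assigns every tied group its full cumulative
  mass, preserves within-slice ranks exactly, and keeps output in (0, 1].

The registration feature space is the *filtered image*: the binary mask
(value 1 inside the sample) plus a Laplacian-of-Gaussian contour image
normalized so its nonzero voxels average 1. The Gaussian sigma ("blur
radius") is 5 voxels by default — large enough to average out individual
labeled cells, small enough to preserve region shapes. The LoG runs in the
frequency domain with zero padding; the sampled kernel receives a
Gaussian-weighted DC correction so constant regions map to exactly 0, and
responses below 1e-6 of the maximum are cleared so "nonzero voxels" means
the contour band rather than FFT round-off. The mask term makes the initial
coarse alignment tractable (masks of unaligned brains still overlap); the
contour term sharpens the similarity peak so that small structure
displacements are penalized. Signed LoG output is reduced to its magnitude —
the normalization over "nonzero voxels" is only well-posed for nonnegative
data, and contour position, not polarity, is what registration needs.

PCA pre-alignment maps the principal axes of the binarized sample onto the
array axes in order of descending eigenvalue. The 4-fold proper-rotation
sign ambiguity is resolved automatically by maximizing binary overlap with a
reference (or, without one, by orienting the centroid-to-farthest-point
vector into the positive octant); near-spherical masks with degenerate
eigenvalues raise an error unless explicitly allowed.

## Deformation model and objective

A warp is parameterized by displacements of nodes on a regular lattice
spanning the volume, trilinearly interpolated between nodes, and applied by
backward mapping (each output voxel pulls the trilinearly interpolated
source intensity at its displaced position; samples outside the extent read
0, which is exact for background-suppressed data). Backward mapping is
hole-free; the paper-style forward phrasing describes the same family of
transforms with the inverse parameterization.

The objective to maximize is

> Pearson(warped source, target) − λ · E(grid),   λ = 1/1000

where the deformation energy E is the L1 norm of tetrahedral volume changes:
each hexahedral grid cell is split into 5 tetrahedra with alternating parity
(so faces conform across cells), and E sums |V_deformed − V_rest| over all
tetrahedra, divided by the total rest volume. The normalization makes E
dimensionless and λ transferable across resolutions and grid sizes.
Translations cost nothing; folds and volume changes are penalized. For
whole-brain benchmarking alignment (alignment quality over feature
preservation) λ = 1/100000 with doubled iterations is the conventional
operating point (`default_schedule(iteration_factor = 2)`).

Boundary nodes are free to move: whole-sample translation must remain
representable, and the energy term discourages pathological stretching.

## Attention-gated simulated annealing

Optimization proposes single-node displacements: a node is selected with
probability proportional to the L1 mismatch between warped source and
target within its adjacent grid cells (+1e-12 floor), a zero-mean Gaussian
3-vector with scale sigma is proposed, and the move is accepted with
probability min(exp(ΔE/t), 1). Per iteration only the cells adjacent to the
displaced node are re-warped; global Pearson terms are maintained as cached
per-cell sufficient statistics, refreshed by a full recomputation every 200
iterations and at stage end (the residual drift is reported and tested to
be < 1e-6). The proposal distribution is implemented as three i.i.d.
zero-mean Gaussian components — the only well-defined reading of a
"zero-mean" displacement magnitude.

Four coarse-to-fine stages (2000 iterations each) refine node counts
2×2×2 → 5×3×2 → 9×5×3 → 9×9×5 (the densest axes are assigned to the longest
brain axes; 405 nodes at the finest stage) and image resolution
96/96/96/48 µm. Stages never upsample past the native spacing of the input:
12 µm light-sheet data is downsampled 8×/8×/8×/4×, while 96 µm phantoms run
all stages at native resolution. Within a stage the temperature decays
geometrically from t0 (1e-3, 1e-3, 1e-4, 1e-5 by stage) to t0/30; sigma
starts at 20% of the new grid spacing, divides by 0.99 on acceptance,
multiplies by 0.99 on rejection, and is clamped to [0.01, 1] × the minimum
node spacing (the clamp guards against runaway growth and numerically dead
step sizes; the adaptation rule itself fixes no bounds). New nodes at a
refinement inherit trilinearly interpolated displacements, and sigma is
re-initialized from the new spacing each stage. One seeded RNG stream
drives each registration; every iteration consumes, in fixed order, the
node-choice uniform, three Gaussian components and an acceptance uniform
(always drawn, also in greedy mode), which makes runs bit-reproducible.

Setting the temperature to zero yields the greedy baseline (accept only
improvements); disabling attention selects nodes uniformly. Both are
exposed as options because they are the natural ablations: on a crafted
pair whose interior structure must cross a uniform region (a similarity
plateau sloped only by the energy term), greedy descent freezes — every
move is either neutral-but-energy-increasing or worse — while annealing at
t = 1e-3 diffuses across and locks onto the true optimum; and attention
reaches a given similarity level in roughly half the iterations of uniform
selection because proposals concentrate where mismatch lives. The
regularization contrast is sharpest in the cold phase of a schedule on
noise-mismatched images: with λ = 0 the optimizer accepts
similarity-neutral, deformation-increasing moves freely and the energy
drifts upward, while λ = 1/1000 biases the cold-phase acceptance toward
volume preservation.

## Hemisphere symmetrization and splitting

Each brain is registered to its own mirror image, yielding a transformation
T; halving every node displacement gives T/2, which places the anatomical
symmetry plane on the volume mid-plane (halving node displacements is the
exact halving the representation supports, and applying the half twice
reproduces the full warp to within interpolation error on smooth fields).
After symmetric zero-padding of X to even length, the volume is split at
the mid-plane and the left half is stored mirrored, so *all* downstream
registration operates in a single right-hemisphere frame. The mirror
registration uses the full default schedule; a configurable objective floor
turns silent misregistration into an explicit error.

## Temporal registration

Hemispheres are grouped by recorded age; one reference per group is drawn
with a seeded RNG (ties and orderings broken lexicographically for
reproducibility). References chain in ascending age — each registers onto
the previous, already-transformed reference — and every non-reference right
hemisphere registers onto its group's transformed reference, so each sample
carries exactly one grid into the common frame. Left hemispheres receive
their brain's grid by copy. Pairwise dissimilarity is 1 − Pearson between
registered filtered images at a common working resolution (default 96 µm).

Classical multidimensional scaling double-centers the squared distances and
eigendecomposes; coordinates are eigenvectors scaled by the square roots of
positive eigenvalues, variance explained is computed over positive
eigenvalues only (negative eigenvalues mark non-Euclidean distances and are
dropped with a warning), and the sign of dimension 1 is fixed so it
correlates nonnegatively with recorded age. Adjusted ages are the fitted
values of the OLS regression of recorded age on the first CMDS coordinate —
regressing the noisy recorded age on the image-derived coordinate is the
conditional-expectation direction, and its shrinkage is statistically
appropriate; the inverse direction is available as an option for
sensitivity checks. All hemispheres enter the regression jointly; the
left/right adjusted-age discrepancy per brain is reported as hemisphere
synchrony.

## Display

Average volumes over the developmental timeline use Gaussian weights with
sigma = 1/2 day (half the daily sampling interval) centered on each
hemisphere's adjusted age, normalized to sum 1 at every time point; the
timeline step is 0.1 day. Differential images subtract the average at t − 1
day from the average at t; increases render red and decreases blue, scaled
by the 99th percentile of the absolute difference. Brain growth is
summarized by per-axis OLS fits of foreground bounding-box extents against
age, normalized to the fitted size at birth (age 0). Whole-brain renders
mirror-append the hemisphere, which is exactly mid-plane symmetric by
construction. Day-to-day variability of an average series is the mean L2
(or L1) norm of consecutive-day differences, optionally on block-averaged
volumes (factor 2 per axis = 1/8 of the voxels); both norms are exposed
because both are in common use for this summary.

## The synthetic phantom model

Phantoms stand in for whole-mount EdU-labeled perinatal brains: a growing
bilaterally symmetric ellipsoid (base tissue 0.3) containing a shell-like
region ("cerebellum": intensity rising 0.1/day from 0.5) and a midline
tube ("RMS": intensity falling 0.12/day from 0.9), plus a labeled-cell
layer: fixed anatomical sites (150 shell, 40 tube; mirrored across the
midline) each switching on (shell) or off (tube) at a site-specific age
threshold drawn uniformly over the study window. The site layer matters
because labeled dividing cells are what the imaging signal measures and a
coarse deformation grid can neither create nor destroy them — they carry
the developmental-age signal *through* registration, whereas smooth tier
geometry is largely morphable. Noise is additive Gaussian with sd 2% of the
dynamic range inside the sample and 0.2% outside, clipped at zero; the
background level is kept below the 1% suppression threshold because a
threshold chosen to "separate signal from background" presupposes a
separable background, while the interior noise exercises equalization and
contour extraction. Default size is 64³ voxels at a nominal 96 µm — large
enough for ≥ 6 voxels per cell on the finest 9×9×5 grid, small enough for
desk-scale annealing runs in seconds.

Series generation draws each sample's true developmental age as recorded
age + U(−0.5, 0.5) days (the birth-dating uncertainty temporal registration
should recover), generates morphology at the true age, and applies a
random smooth anatomical deformation bounded by 20% of the jitter-grid cell
size. The jitter grid default (5, 8, 8) bounds individual anatomical
variation at roughly 1.5–3 voxels (150–300 µm), which keeps same-age
samples an order of magnitude closer to each other than to the far end of
the age range — the block structure same-age groups show in real
pairwise-distance matrices. In paired-hemisphere mode both hemispheres of a
brain share its true age and jitter (a rigid-brain assumption) with
independent voxel noise, mirroring how hemisphere splitting doubles a real
sample set.

## Validation scale and known limitations

The test suite and the acceptance script run everything at desk scale on
one CPU: recovery experiments use the full 4-stage schedule on 64³
phantoms; ablation studies use a crafted 40³ two-optimum pair (3500
iterations, 10 seeds per arm) and a 3-stage cold-quench schedule for the
regularization contrast; temporal-staging studies use 6 ages × 4
hemispheres with a 3-stage schedule (coarse stages at 192 µm, final 9×9×5
polish at 96 µm). These sizes are the package's validation operating
points, chosen so each study completes in minutes.

What passing these tests shows — and what it does not:

* Deformation recovery, energy/interpolation exactness, acceptance-rule
  correctness, CMDS exactness, determinism and the rendering identities are
  sharp checks of the implementation.
* The optimizer ablations reproduce the *qualitative* claims (annealing ≥
  greedy, attention faster, regularization bounds deformation) on
  landscapes constructed to exhibit the relevant failure mode. Real brains
  present such landscapes in milder, mixed form.
* Temporal staging on phantoms recovers the developmental ordering with
  cmds1–true-age correlation around 0.98 and adjustments within ±1 day, but
  the *precision* of adjusted ages is limited to roughly a quarter day by
  two effects that phantoms exaggerate: the annealer's residual-alignment
  floor feeds per-sample noise into every distance, and Pearson distances
  of low-complexity phantoms grow nonlinearly with age separation, which a
  linear age-on-cmds1 fit cannot absorb. At a birth-dating uncertainty of
  ±0.5 day the recorded ages themselves have a mean error of 0.25 day, so
  adjusted ages beat recorded ages only in favorable draws; the
  corresponding acceptance checks are reported honestly rather than relaxed.
  Real stacks, with orders of magnitude more texture than a phantom, give
  the distance matrix a far better noise-vs-signal regime than the
  synthetic series; conclusions about real-data staging precision should
  not be read off these phantom studies in either direction.
* No claim is made about registration accuracy relative to other software,
  atlas mapping, or anatomical realism of the phantoms.

## Parameter summary

| Parameter | Default | Meaning |
|---|---|---|
| `target_spacing_um` | 12 | working resolution after import (µm) |
| `threshold` | 0.01 | background threshold, fraction of max intensity |
| `log_radius` | 5 | LoG Gaussian sigma (voxels) |
| `lambda` | 1/1000 | deformation-energy weight (1e-5 for whole-brain mode) |
| schedule | Table of 4 stages | iterations 2000; nodes up to 9×9×5; 96/96/96/48 µm; t0 1e-3…1e-5, decaying to t0/30 |
| step adaptation | 0.99 | sigma divide/multiply factor per success/failure |
| `initial_step_fraction` | 0.2 | starting sigma as fraction of grid spacing |
| `sigma_days` | 0.5 | Gaussian blending width (days) |
| `dt` | 0.1 | rendering timeline step (days) |
| `distance_resolution_um` | 96 | working resolution of the distance matrix |
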