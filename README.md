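# brainwarp

Spatiotemporal registration of developing (perinatal) mouse brain volumes.

Comparing brain samples across early postnatal development requires putting
them into common coordinates, but perinatal brains grow fast, change shape
as regions mature, and develop at individual paces only loosely tied to the
birth date. `brainwarp` addresses all three problems for 3D light-sheet
(or comparable) volumes:

1. **Feature-enhancing preprocessing.** Volumes are resampled to an
   isotropic working resolution, background-suppressed at 1% of the
   maximum, equalized per XY-slice, and converted to a *filtered image*:
   the binary sample mask plus a Laplacian-of-Gaussian contour image
   (σ = 5 voxels) normalized to mean 1 over its nonzero voxels. The mask
   makes coarse alignment tractable; the contours sharpen the similarity
   peak at mesoscale structures.
2. **Attention-gated simulated annealing over a free-form deformation.**
   A warp is parameterized by node displacements on a regular grid
   (trilinear between nodes) and optimized to maximize

   `Pearson(warped source, target) − (1/1000) · E(grid)`

   where `E` is the L1 norm of tetrahedral volume changes of the
   triangulated grid (dimensionless, so the weight transfers across
   resolutions). Single-node Gaussian proposals are accepted with
   probability `min(exp(ΔE/t°), 1)`; nodes are chosen with probability
   proportional to the local image mismatch (attention gating); four
   coarse-to-fine stages refine the grid 2×2×2 → 9×9×5 and the resolution
   96 → 48 µm while the temperature decays to 1/30 of its stage-initial
   value and the step size adapts by factors of 0.99.
3. **Temporal registration ("adjusted ages").** Each brain is symmetrized
   against its mirror image (warp by T/2), split into hemispheres, and all
   hemispheres are chained into a common frame in order of age. Classical
   multidimensional scaling of the pairwise correlation distances
   (1 − Pearson of filtered images) yields a first coordinate that tracks
   developmental stage; regressing recorded age on it gives each sample an
   adjusted age. Gaussian-weighted averages over the adjusted-age timeline
   (σ = ½ day) and red/blue differential images render the continuous
   developmental dynamics.

A synthetic-phantom module (`phantom_spec()`, `make_phantom()`,
`make_series()`) generates growing, bilaterally symmetric volumes with a
shell-like region whose labeled-cell signal rises with age and a tube-like
region whose signal fades, plus per-sample age jitter and anatomical
jitter with known ground truth — so every stage of the pipeline is testable
without any data downloads.

## Worked example

Recover a known deformation on a phantom:

```r
library(brainwarp)

# a 64^3 developing-brain phantom at "postnatal day 2"
spec <- phantom_spec()
ph   <- make_phantom(spec, age = 2, seed = 3)

# warp it by a known random smooth deformation (the ground truth)
gt <- apply_ground_truth_deformation(ph$volume, max_disp_fraction = 0.2,
                                     node_counts = c(3, 4, 4), seed = 5)

# preprocess both into filtered feature images (mask + LoG contours)
fixed  <- preprocess_volume(ph$volume)
moving <- preprocess_volume(gt$volume)
pearson_similarity(moving, fixed)

# attention-gated simulated annealing, reduced 3-stage schedule
reg <- register_pair(moving, fixed, schedule = reduced_schedule(), seed = 7)
mask <- binarize(ph$volume, 0.01)$data
field_recovery_error(reg$grid, gt$grid, mask)
```

Output:

```
similarity before registration: 0.9355
similarity after registration:  0.9935
deformation energy:             0.3072
field recovery RMS (voxels):    1.9
```

The registration raises the filtered-image correlation from 0.94 to 0.99
and undoes the synthetic warp to a residual of 1.9 voxels RMS over the
sample foreground — well under half the final grid spacing. The full
4-stage `default_schedule()` does the same on real-scale problems in a few
minutes per brain on one CPU.

The one-command pipeline (preprocess → register → stage → render) runs from
a config object or YAML file:

```r
cfg <- run_config(
  inputs = list(synthetic = TRUE, recorded_ages = 0:5, per_age = 2),
  output_dir = "run_out", schedule = "reduced", seed = 7)
res <- run_pipeline(cfg)
res$ages$table          # recorded vs adjusted ages per hemisphere
res$variability         # day-to-day variability, adjusted vs recorded
```

A thin command-line front end with `synth`, `preprocess`, `register`,
`split` and `run` subcommands is installed at `inst/cli/brainwarp`.

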