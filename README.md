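# chainsreg

Population-based affine registration of 3-D brain image cohorts with
highly variable appearance and positioning — lesioned pre-clinical
cohorts, mixed-quality scans, images far from a canonical pose. It is
aimed at image-analysis practitioners who need to spatially normalise a
whole cohort to a reference when direct image-to-reference registration
is unreliable.

## The idea

Registering every image straight to a reference fails in two ways: a
local optimiser cannot bridge large pose differences, and lesions or
other appearance changes can capture the cost function even when the
pose is close. `chainsreg` instead:

1. **registers all ordered pairs** with a deliberately local NMI engine
   and records the inverse Normalised Mutual Information after
   alignment as a distance,
   `d(i, j) = [(H(A)+H(B)) / H(A,B)]⁻¹ ∈ [0.5, 1]`;
2. **builds a rooted tree** (the *chain graph*) over the cohort: the `r`
   images closest to the reference join Tier 1, and an image joins
   Tier t+1 when a Tier-t node is among its `r` nearest neighbours in
   the whole population. The rank `r` is chosen automatically by the
   graph-fitness measures
   `d_mean = Σⱼ d̄ⱼ` and `d_min = Σⱼ m̄ⱼ`, where `d̄ⱼ`/`m̄ⱼ` are the
   mean/minimum of the edge distances along node j's path to the root
   (smallest `d_mean` wins, ties by `d_min`, then by rank);
3. maps every image to the reference by **composing the transforms
   along its path** (*indirect*, `chains_indirect()`), optionally
   followed by a **local refinement** initialised there, under a
   reference brain mask (*direct*, `chains_direct()`).

Every step of the chain is an easy registration between two genuinely
similar images, so the method has a large effective capture range
without any global search. Accuracy with known ground truth is measured
by the Residual Displacement Error (RDE): the mean displacement in mm
that (applied ∘ recovered) induces over a reference brain mask, with
RDE > 1 voxel counted as a gross failure.

The package also ships the synthetic study populations (`build_cohort()`
— aligned lesioned copies `vA`, randomly repositioned copies `vP`, and
both combined `vAP`, on a procedural gyrified head phantom with Rician
noise and known ground-truth transforms) and the evaluation toolkit
(`rde()`, `count_misregistrations()`, `lesion_overlap()`,
`mean_std_images()`).

## Worked example

Simulate a repositioned cohort (six noisy copies of the phantom under
random 9-dof transforms, ±7 mm / ±30° / ±0.025 at 2 mm voxels), register
it, and score the recovered transforms against the known truth:

```r
library(chainsreg)

cfg    <- simulation_config(cohort_size = 6, shape = c(48, 48, 48), seed = 7)
cohort <- build_cohort("vP", cfg)
run    <- run_chains(cohort, chains_run_config(dof = 9, max_samples = 8000))
print(run$graph)

rdes <- vapply(names(cohort$volumes), function(id)
  rde(residual_transform(cohort$gt_transforms[[id]],
                         run$direct[[id]]$transform),
      cohort$brain_mask), numeric(1))
print(evaluation_report(rdes, threshold_mm = 2, method = "CHAINS-D"))
```

```
<chain_graph: 7 nodes, root 'reference', max tier 2, rank 3>
<evaluation_report 'CHAINS-D': 6 images>
  Mean 0.425  s.d. 0.181  Min 0.221  Max 0.707 (mm)
  N(misreg, RDE > 2.00 mm) = 0
```

Every image lands within a third of a voxel of its true pose on average
(0.425 mm at 2 mm voxels) with no gross failures, even though several
cohort members start far outside the local engine's capture range; the
graph routed them through intermediate images (max tier 2). The same
run on real data starts from a manifest of NIfTI paths — see the
`chains` script under `inst/scripts/` for the command-line interface
(`simulate`, `pairwise`, `graph`, `register`, `sweep-reference`,
`evaluate`) — and `run_chains(..., out = dir)` writes transforms, the
distance matrix, the graph (DOT/JSON), registered volumes and a run log.

The methods vignette (`vignettes/chain-registration.Rmd`) documents the
model, the engine's numerical choices, the generator's scaling rules and
the study sizes used by the test suite.

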