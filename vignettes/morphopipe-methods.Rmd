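---
title: "Registration pipelines and deformation-based morphometry with morphopipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Registration pipelines and deformation-based morphometry with morphopipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## What the package does

Structural imaging studies rarely end with two images: a typical cohort
holds tens of scans whose anatomical differences are the object of
study. The standard strategy is to register every scan into a common
space — rigidly, then affinely, then with a dense nonlinear deformation
— and to read anatomy off the transforms themselves: the Jacobian
determinant of the common-space-to-subject mapping measures local
volume expansion (>1) or contraction (<1), the basis of
deformation-based morphometry (DBM).

`morphopipe` provides the whole chain as composable pieces:

* a **pipeline engine** that infers stage dependencies from declared
  file footprints, eliminates duplicate stages, checkpoints after every
  completed stage, and schedules work under per-executor resource
  budgets;
* **registration atoms** (Gaussian blur, 6/12-dof linear registration,
  demons-style nonlinear registration, resampling, averaging, intensity
  normalization, majority-vote label fusion), all native and
  deterministic;
* a **transform algebra** (affines, dense displacement fields, chains;
  composition, inversion, linear-part extraction, Jacobians);
* **file handlers** that track blurred versions, per-target transform
  histories and resampled lineages per input;
* four **applications**: iterative group-wise model building (`mbm`),
  longitudinal registration chains, two-level (subject then population)
  registration, and multi-atlas label fusion (MAGeT-style);
* a **phantom generator** so every pipeline is testable from synthetic
  data with known ground truth.

## The pipeline engine

A stage declares the files it reads and writes. The pipeline is a
directed acyclic graph whose edges are inferred: the producer of an
artifact precedes each of its consumers. Stage identity is a fingerprint
— a hash of the work definition (command tokens, or callable name plus
canonicalized arguments) together with the sorted input and output
sets; resource hints are deliberately excluded so that tuning memory
hints never changes graph identity. Inserting a stage whose fingerprint
already exists is a no-op, which lets module code blur a shared target
inside a per-subject loop without bookkeeping: the duplicate stages
collapse into one.

Execution polls a runnable queue (pending stages with all predecessors
finished). A stage is claimed only when an executor's memory/thread
budget covers the stage's hints; a stage no executor could ever satisfy
is reported as unrunnable rather than looping forever. A failure
permanently blocks all transitive dependents, and the run shuts down
once nothing more can run. Stages execute one at a time inside the R
process; the claim/release accounting and the shutdown contract are the
same as a distributed pool would honour.

The checkpoint is a versioned JSON record of the graph edges, the stage
array, the stage counter, the fingerprint and output-artifact lookups,
and the status array. On restore the edges are rebuilt by iterating the
saved graph; finished stages keep their status and are never re-run,
while running/failed/blocked stages return to pending. Callable stages
reference functions by name and carry only atomic arguments, so a
restored pipeline is executable in a fresh session.

## Volumes and transforms

Volumes are 3-D arrays with a 4x4 voxel-to-world affine (0-based voxel
indices, world millimetres) read and written as NIfTI-1 via `RNifti`;
integer-typed files load as label volumes. All transforms act on world
coordinates. A displacement field stores `u(x)` so the mapping is
`x + u(x)`, with trilinear interpolation off its own grid; a chain is
applied left-to-right and the empty chain is the identity.

Numerical choices worth knowing:

* **Composition**: all-affine chains compose exactly by matrix product;
  mixed chains are sampled pointwise on a stated grid.
* **Inversion**: affines invert exactly; chains invert member-wise in
  reversed order; fields invert by *damped* fixed-point iteration on
  `v(x) = -u(x + v(x))` (factor 0.5, tolerance 0.01 mm, cap 200
  iterations). The damping matters: the undamped update oscillates
  wherever the field's local Jacobian has an eigenvalue near -1, while
  the damped map converges to the same fixed point. Convergence is
  assessed at points whose iterates stay on the grid — a voxel mapping
  beyond the field's support has nothing to invert.
* **Jacobians** are taken on the full mapping `x + u(x)` by central
  differences in world mm (one-sided at the boundary), composed with
  the inverse grid affine so oblique grids are handled; a `log_scale`
  flag returns log-determinants (off by default).
* **Linear-part extraction** is a least-squares affine fit of the
  mapping over a grid's voxel centres, restricted to the grid's mask
  when one is present. The *pure nonlinear* component of a chain is the
  displacement of `linear_part` composed with the chain's inverse — an
  affine-only chain leaves numerically nothing.
* **Smoothing** is separable Gaussian convolution with
  `sigma = fwhm / (2 sqrt(2 ln 2))` converted per axis to voxel units;
  replicate-edge boundaries.

## Registration

### Linear (LSQ6 / LSQ12)

`linear_register(source, target)` returns the affine mapping target
world coordinates into source world coordinates — the pull-back used to
resample the source onto the target grid. The parameterization is
centred on the target field of view: translations (mm), ZYX Euler
angles, log-scales and upper-triangular shears, so rigid parameters are
exactly rigid and the 12-dof matrix decomposes uniquely by QR. The
default protocol runs three coarse-to-fine levels with blur fwhm
{8, 4, 2} x voxel size and evaluation steps {4, 2, 2} x voxel size (a
2-voxel step at the finest level recovers parameters as accurately as
a dense evaluation at a third of the cost); the
evaluation grid is the target mask when present, otherwise an implicit
foreground mask (voxels above 2% of the blurred maximum) — background
voxels carry no alignment information and dominate cost.

The optimizer is layered: with an identity start the translation is
seeded by aligning intensity centroids and the coarsest level prepends
a deterministic rotation grid search (7.5-degree spacing to ±14
degrees), because the simplex refines reliably only within a few
degrees. Rigid parameters are then optimized by Nelder-Mead simplex
(two restarts, the second from a tightened simplex) and polished by
BFGS; for 12 dof the coarsest level settles the rigid parameters alone
and subsequent levels run the full 12-parameter BFGS descent — in our
experience the simplex stalls in twelve dimensions while quasi-Newton
descent does not. Everything is deterministic: fixed iteration caps, no
random starts.

The similarity metric per protocol row is squared normalized
cross-correlation (`ncc`, default) or mean squared difference (`ssd`).

### Nonlinear (demons)

`nonlinear_register` iterates, per protocol row, on images blurred with
the row's fwhm: a per-voxel force along the symmetric image gradient,
capped at the row's `step` (default 0.4 x voxel), Gaussian-regularized
with the row's `param` fwhm (fluid part), added to the field, and the
accumulated refinement smoothed with a light elastic kernel (default
2 x voxel) that keeps the field diffeomorphic. The default schedule is
two levels, blur {4, 2} x voxel, 25/15 iterations.

The default force is *local normalized cross-correlation* ascent
(the `ncc` metric): local means, variances and covariance under a
5-voxel Gaussian window drive the update. This matters specifically
for iterative model building, where the generation-1 template is a
blurred average: bright internal structures are dimmer and wider there
than in any subject, and a plain intensity-difference force responds by
spuriously shrinking them (we measured interior Jacobians of 0.2-0.4
from this effect alone). The correlation force is invariant to local
contrast scaling and removes the bias. The difference force is kept as
`metric = "ssd"` for controlled unit tests.

Forces are zeroed outside the target mask (or an implicit dilated
foreground mask): on pure-noise background the difference force
performs a random walk that folds the field and breaks inversion.

### Hierarchy and handlers

`hierarchical_register` is the single-pair convenience (optional 12-dof
linear stage, then the nonlinear refinement). The pipeline-level
equivalent, `hierarchical_stages`, emits one blur stage per level for
input and target and one registration stage per level, each consuming
the previous level's transform through the file handler's
`get_last_xfm`; because target blurs of different inputs share
fingerprints, an L-level registration of k inputs to one target costs
`k (2L + 1) + L` stages, not `k (3L + 1)`.

## Applications

**MBM (iterative group-wise model building)**: LSQ6 toward an initial
model or a bootstrap average; global multiplicative intensity
normalization (the masked mean is rescaled to a reference — the
literature's per-slice scheme is unspecified, so the global version
stands in and is flagged as such); pairwise LSQ12 with a consensus
average transform per subject; iterative NLIN toward an evolving
average; then statistics. The consensus average is the parameter-space
mean of the subject's n-1 pair transforms *plus its own identity
transform*: without the self-term the mean amplifies each subject's
deviation by n/(n-1) (we measured consensus determinants of
`(s/gm)^4` at n = 4 for prescribed scale s and cohort geometric mean
gm), leaving the nonlinear stage a volume residual it cannot absorb;
with it, the consensus space is exactly centred and determinants
recover the prescribed ratios to about 1%.

The common-to-subject chain for subject i concatenates its final NLIN
field, LSQ12 consensus affine and LSQ6 affine; the statistics stage
composes the chain, splits full and pure-nonlinear displacement, and
writes `<subject>_det_fwhm<k>`, `<subject>_log_det_fwhm<k>` and
`<subject>_rel_det_fwhm<k>` volumes per smoothing kernel (smoothing is
applied to the displacement field *before* the determinant; no
determinant-image blurring mode is provided). The default kernel is
2 x voxel size.

**Registration chain**: within each subject, timepoint i is registered
(LSQ12 then nonlinear) to timepoint i+1; the link transform maps
timepoint i+1 space back to timepoint i space. Scans at the common
timepoint (default: the earliest, overridable) are registered
group-wise; common-space-to-scan transforms concatenate the group-wise
transform with chain links (inverted links for timepoints after the
common one). `pairwise_stats` additionally writes determinants of each
adjacent link (off by default).

**Two-level**: per subject, rigid alignment plus group-wise NLIN into a
subject average — deliberately no affine scaling within subject, since
within-subject volume change is the biology under study; then pairwise
LSQ12 + NLIN across subject averages into a population average.
Population-to-scan chains concatenate the two levels.

**MAGeT-style label fusion**: every atlas is registered to every
subject and its labels propagated (nearest-neighbour); every subject is
registered to every other subject and the step-one labels
cross-propagated, giving each subject an `m x n` label library from m
atlases and n subjects; per-voxel majority voting (ties to the smallest
label) fuses each library.

## The phantom generator

All tests run on generated data: an ellipsoidal "brain" of background
intensity 0.35 containing up to six non-overlapping ellipsoidal
structures (labels 1..n, distinct intensities 0.55-0.95), edges
softened with a 1.5-voxel blur, plus seeded Gaussian noise (default
2% of the contrast range). Cohorts push the base phantom through known
per-subject affines (prescribed scales; small random rotations and
translations) composed with random smooth warps (Gaussian-smoothed
white noise rescaled to a set maximum, redrawn until the Jacobian is
positive); longitudinal series accumulate incremental warps per
timepoint. Ground-truth transforms are returned, so registration
accuracy is scored against the construction, not against plausibility.

What the phantoms do *not* emulate: MR intensity non-uniformity beyond
a smooth option, motion or ghosting artifacts, anatomical variability
beyond smooth warps, or partial-volume tissue mixtures. Passing tests
demonstrate that the algorithms recover known geometry under controlled
contrast and noise — not performance on clinical data.

## Problem sizes and defaults

The acceptance-level checks run, by design, at desk scale on one CPU:
48-cubed phantoms (1 mm isotropic) for single-registration parameter
recovery and label fusion, 40-cubed for the end-to-end group-wise and
longitudinal applications, 32-cubed and below for algebra and
degenerate-cohort checks. Default iteration counts (100 simplex
iterations per linear level; 25/15 demons iterations) were calibrated
on those phantoms: demons converges on them well before the caps, and
further iterations neither improve recovery error nor change the
determinant summaries.

Known limitations: the nonlinear optimizer is a first-order demons
scheme, not a diffeomorphic log-Euclidean method — invertibility is
maintained by step caps and elastic smoothing rather than guaranteed by
construction; the intensity normalization is a single global factor;
4-D NIfTI and MINC inputs are out of scope; and the engine's executor
pool is in-process (the polling and resource-claim contract is
implemented and tested, but stages do not run concurrently).
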