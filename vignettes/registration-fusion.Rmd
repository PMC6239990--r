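---
title: "Registration fusion: methods and design notes"
author: "regfuse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Registration fusion: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Neuroimaging results live in two kinds of template coordinate systems:
volumetric ones (a voxel grid with a voxel-to-world affine, such as the
MNI152 template) and surface ones (a triangulated cortical sheet aligned
through a common sphere, such as fsaverage). Translating data between the
two is lossy and surprisingly error-prone, because no subject-level
registration ever produced a direct correspondence between the two
*templates* — each subject was registered to each template separately.

Registration fusion builds that missing correspondence from a cohort. For
every subject we hold two registrations: a volumetric transform taking
template-volume points into the subject's anatomy (an affine plus a dense
displacement field, or any chain thereof), and a spherical surface
registration giving each vertex of the subject's cortical mesh a position
on the common sphere. Composing the two per subject yields one
template-volume-to-template-surface correspondence per subject; averaging
over the cohort yields the fused mapping. The package implements both
directions of this construction, the coverage masks and dilation the
surface-to-volume direction needs, two widely used single-registration
baselines on the same machinery, projection operators for scalar maps and
parcellations, and an evaluation suite — all exercisable on a synthetic
phantom with analytic ground truth.

## The two mapping directions

**Volume to surface.** Every template-surface vertex is located on the
subject's sphere (barycentric coordinates among the subject's sphere
positions), carried to the subject's anatomical mid-thickness surface with
the same weights, and pushed through the subject's inverse volumetric
chain into template-volume space. The fused mapping is the arithmetic,
per-vertex mean of these template-volume coordinates
(`buildVol2Surf()`). Every vertex of every subject has such a coordinate,
so the average is unproblematic; subjects whose chain cannot map a vertex
(outside the displacement-field hull, possible only on artificial grids)
are excluded per vertex with a warning.

**Surface to volume.** The reverse direction is asymmetric: not every
template voxel is cortex in every subject. Each template-grid voxel center
is mapped into each subject's anatomy; voxels landing inside that
subject's cortical ribbon are assigned the *common-sphere coordinate* of
the nearest subject mid-surface vertex. Per voxel we accumulate the
fraction of contributing subjects (coverage) and the mean sphere
coordinate, renormalized to unit length (`buildSurf2Vol()`). Sphere
positions are the only surface representation shared across subjects,
which is why averaging happens there; a zero-norm mean (antipodal
cancellation) is flagged and excluded rather than guessed.

Two masks discretize coverage: the **tight mask** keeps voxels that are
cortex in at least 50% of subjects, the **loose mask** at least 15% (both
compared with `>=`, both thresholds adjustable). The mapping is defined on
the tight mask and grown outward: every loose-but-not-tight voxel copies
the sphere coordinate of its Euclidean-nearest tight voxel, with distances
between voxel centers in world mm (so anisotropic grids behave) and ties
resolved to the lowest linear index (`dilateMapping()`). Finally each
loose voxel snaps to its nearest template-sphere vertex
(`finalizeSurf2Vol()`).

**Baselines.** The affine baseline replaces the per-subject nonlinear
chains by a single affine between the template volume and the
surface-template volume, concatenated with a supplied vertex-to-volume
coordinate table, and runs through the identical mask/dilation pipeline
with N = 1 (`buildAffineBaseline()`). The single-registration baseline is
literally the fusion pipeline on a one-subject cohort whose "subject" is
the template itself (`buildSingleRegistrationBaseline()`).

## Projection and evaluation

`projectVolToSurf()` samples a volume at each vertex's mapped coordinate
(trilinear for scalars, nearest for integer labels — labels are never
interpolated and never invented). `projectSurfToVol()` writes each
loose-mask voxel from its final vertex (nearest) or from the barycentric
blend at its averaged sphere coordinate (scalars only); voxels outside the
loose mask stay 0.

Parcellations from many subjects combine into per-structure probabilistic
maps (`makeProbMaps()`: probability = fraction of subjects) and into
winner-takes-all parcellations (`winnerTakesAll()`: maximal probability,
ties to the lowest label id, unlabeled never competes).

Two metrics quantify projection quality. The normalized absolute
difference between a projected and a reference probabilistic map is
`sum(|projected - truth|) / sum(truth)` — dissimilarity normalized by
structure size, lower is better (`nad()`). Parcellation agreement is the
Dice coefficient `2|A∩B| / (|A| + |B|)` per structure (`dice()`); a
structure absent from both parcellations is an explicit error, never a
silent 1 or 0. Approaches are compared structure-wise: values are averaged
across the two hemispheres (the phantom's two half-shells play that role),
each pair of approaches is submitted to a paired t-test across structures,
and the set of pairwise p-values is corrected with Benjamini–Hochberg FDR
at q = 0.05 (`compareApproaches()`). The FDR scope is the pairwise-test
set per metric, the reading most consistent with testing "every pair of
approaches"; the t-test and the BH step are delegated to `stats::t.test`
and `stats::p.adjust`, with the test suite checking both against
definitional implementations.

## Transform machinery and numerical choices

All coordinates are world mm, RAS, with 0-based voxel indices; readers
normalize orientation at the boundary (`readVolume()` reorients non-RAS
files) so nothing downstream reorients. Displacement fields are world-mm
vectors on their own grid, stored as a 4-D NIfTI with three volumes;
points map as `x -> x + u(x)` with `u` interpolated trilinearly.
Resampling follows the pull-back convention everywhere: to resample an
image from space A into space B, the B-to-A point mapping is evaluated at
B's voxel centers.

- *Composition* is lazy (chains applied point-wise); `bakeChain()`
  exports a chain as a single dense field on a stated grid when needed.
- *Inversion* (`invertField()`) solves `v(x) = -u(x + v(x))` by
  fixed-point iteration from `v = -u`, stopping when the largest node
  update drops below `tol` (default 0.01 mm; the phantom generator uses
  0.005 mm) or failing loudly with the achieved residual. Sample
  positions are clamped to the grid hull during iteration; without the
  clamp, nodes whose displaced position leaves the grid oscillate
  between zero and `-u` and the iteration stalls. The method assumes a
  smooth, moderate-amplitude field (displacement gradient below 1),
  which the generator guarantees.
- *Out-of-hull policy*: point mapping errors by default (surfaces may
  legitimately poke past small synthetic grids only if the caller opts
  into `"zero"` or `"na"`); image resampling fills 0.
- *Sphere location* (`barycentricLocate()`) finds the containing
  spherical triangle by ray-through-origin (gnomonic) barycentric
  coordinates on the faces incident to the nearest vertex, with an
  exhaustive fallback; weights are clipped at -1e-9, zeroed, and
  renormalized to sum 1. Anatomical sampling uses the subject's
  mid-thickness surface (the phantom ribbon's mid-shell); white vs mid
  sampling is not fixed by the underlying design, and mid-thickness is
  the symmetric choice.
- *Tie-breaks* are lowest-index everywhere (nearest vertices, dilation
  sources, winner-takes-all labels), making every operation
  deterministic.
- Voxel-level hot loops (trilinear gathers, nearest-point scans) are
  small Rcpp kernels; everything else is vectorized R.

## The shell phantom

The synthetic module replaces brain anatomy with a world in which every
quantity has a closed form: a cubic grid (default 48 voxels at 1 mm)
holding a spherical-shell "cortical ribbon" (radii 14–18 mm), an icosphere
mid-thickness surface (subdivision level 3, 642 vertices) whose
directions double as the common-sphere registration, and an angular
parcellation into L = 16 sectors grown from farthest-point-sampled seed
directions — identical by construction in the volume and on the vertices.
Hemispheres are the x < 0 and x >= 0 halves.

Each subject is the template warped by a smooth random displacement
field: Gaussian noise on a 6-node-per-axis control grid, Gaussian-smoothed
(sigma = 2 node spacings), trilinearly upsampled, and scaled so the
maximum displacement norm equals the amplitude `a` (default 1 mm). The
subject's spherical registration is the template sphere under a small
random rotation plus a smooth tangential displacement, together bounded by
the jitter budget (default 2 degrees, split evenly between the two
components). The generating field and its fixed-point inverse are recorded
as the subject's chains, so the phantom's volumetric registrations are
*exact*: the only per-subject error in the volume-to-surface direction is
the spherical jitter, a deliberate idealization discussed under
limitations.

Cohorts are prefix-stable — every draw is keyed by (master seed, subject
index, draw name) — so the first n subjects of a size-N cohort *are* the
size-n cohort, which the convergence experiment and `averagePartial()`
rely on. With recentering (default, N >= 2) the cohort-mean control-node
displacement is subtracted before a *common* scale factor sets the cohort
maximum to `a`: per-subject rescaling would destroy the zero mean, while
the common scale preserves it and keeps every subject at or below `a`.
The template is then the cohort's true center, and the fused mapping must
converge to the analytic ground truth as the cohort grows.

The affine-baseline inputs emulate what defeats the affine approach in
practice: the surface-template volume differs from the volumetric
template by a genuinely nonlinear relation. A seeded rough warp is
decomposed into its ribbon-fitted affine part plus nonlinear remainder;
the remainder is rescaled to a controlled amplitude (default 3 mm, the
scale of real template-to-template nonlinear differences) and the
supplied affine is the least-squares fit of the final relation — so the
baseline's irreducible error is exactly that remainder. The
single-registration baseline on jittered cohorts uses one extra jittered
subject as the "template reconstruction": a single imperfect registration
with no averaging benefit.

## Evaluation design

The two simulation designs mirror the intended use cases. In the
volume-to-surface design, each evaluation subject's parcellation is
carried to the template grid through that subject's true warp and
averaged into per-structure volumetric probabilistic maps; a candidate
mapping projects these to the surface, where they are scored (NAD) against
the surface probabilistic maps obtained through the spherical
registrations. In the surface-to-volume design, the per-subject surface
parcellations combine into a winner-takes-all surface parcellation, a
candidate mapping projects it into the volume, and per-structure Dice is
scored against the winner-takes-all volumetric truth.

The subjects that *evaluate* a mapping are never the subjects that
*built* it: `phantomMethodComparison()` and `convergenceExperiment()`
score against probabilistic maps from an independent evaluation cohort
(a disjoint seed stream), held fixed across replicate seeds in the
convergence experiment. This matters more than it may seem — when the
training cohort doubles as the evaluation cohort, small training cohorts
share their registration errors with the evaluation maps and score
*better*, inverting the convergence trend.

## Resolution regimes, and the problem sizes the checks use

Projection quality on the phantom has a resolution floor that is easy to
quantify. Projecting a binary structure map smears its boundary over
about one voxel, so the NAD of a perfect mapping is roughly
`0.5 * voxel / parcel-radius`; snapping voxels to nearest vertices
mislabels a band of about a quarter vertex spacing on either side of a
parcel boundary, so perfect-mapping Dice loses roughly
`0.5 * vertex-spacing / parcel-radius`. At the generator defaults (642
vertices, 16 parcels of ~8 mm radius, 1 mm voxels) these formulas put
the floors at a max-structure NAD of roughly 0.1 and Dice of roughly
0.9 — for a *perfect* mapping. The real templates sit in a much finer
regime: vertex spacing about one voxel and structure radii of
twenty-plus voxels.

The validation experiments therefore run at phantom configurations
chosen to mirror that regime, while the generator defaults stay small
for cheap unit tests:

- *Identity recovery* (zero warp, zero jitter, N = 8): 72-voxel grid,
  shell 26–33 mm, 8 parcels (radius ~21 voxels), level-5 icosphere
  (10,242 vertices, ~1 voxel spacing). Floors there are ~0.04 NAD and
  ~0.98 Dice, so the pipeline's exactness — fused coordinates within
  1e-13 voxels of truth — is observable through them.
- *Convergence and method ordering* (a = 1 mm): 64-voxel grid, shell
  22–28 mm, 8 parcels, level-4 icosphere, and a spherical jitter budget
  of 6 degrees, i.e. registration-error arcs near one voxel at the
  mid-surface radius — the error-to-voxel ratio of real surface
  registration. At the small default jitter (2 degrees, ~0.26 mm arc)
  the per-subject mapping error is only a quarter voxel, so NAD
  differences across cohort sizes would sit below the quantization
  noise of the boundary ramp; the convergence trend would then be
  measurable only in the vertex mapping error.
- Cohort sizes 4–32 with 10 replicate seeds for convergence; 16 training
  and 16 evaluation subjects for the ordering comparison.

```{r example}
library(regfuse)

spec <- phantomSpec(gridShape = 64L, rIn = 22, rOut = 28, nParcels = 8L,
                    nSubjects = 16L, amplitude = 1, jitterDeg = 6,
                    subdivisions = 4L, seed = 2L)
res <- phantomMethodComparison(spec)
res$nadComparison$means    # rf < single < affine
res$nadComparison$tests    # paired t per pair, BH-corrected flags
```

## What passing tests do and do not show

The phantom establishes that the *machinery* is correct: exact recovery
under identity conditions, convergence of the averaged mapping to the
true center under zero-mean perturbations, correct mask/dilation/
projection semantics against brute-force oracles, and the expected
ordering of fusion over single-registration approaches when errors are
realistic in voxel units. It does not establish performance on real
brains: the phantom has no MRI intensities, no segmentation errors, no
folding-pattern variability, and — most importantly — its volumetric
transforms are exact by construction, whereas real volumetric
registrations carry errors that fusion must also average away. Real-data
accuracy numbers are therefore out of scope here; the package's claim is
that the method is implemented faithfully and behaves as the theory
predicts under controlled conditions.

## Known limitations

- Dense fields are exchanged as vector NIfTI only; proprietary warp
  formats are not parsed. Meshes use a documented plain-text format.
- `invertField()` is a fixed-point solver for smooth fields, not a
  diffeomorphic log/exp machinery; wild fields fail loudly.
- Sphere-coordinate averaging excludes antipodal-degenerate voxels
  rather than guessing; they are reported.
- The NAD/Dice resolution floors above apply to any phantom use; results
  at the small default geometry measure the floor, not the mapping.
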