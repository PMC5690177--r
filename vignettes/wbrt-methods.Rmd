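---
title: "Automated whole-brain radiotherapy planning: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated whole-brain radiotherapy planning: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wbrt)
```

## The problem

Whole-brain radiation therapy (WBRT) delivers a uniform dose to the whole
brain through two opposed lateral beams while the multileaf collimator
(MLC) shields the eyes and lenses at the brain-eye interface. The
planning work is repetitive — contour the brain and ocular structures,
place the two beams, shape the MLC — yet the MLC shaping encodes
clinical judgement that is hard to express as an optimization objective.
`wbrt` implements a knowledge-based alternative: segment the new
patient's anatomy automatically, search a database of previously
approved plans for the patient with the most similar anatomy *where it
matters dosimetrically*, and reuse that plan after updating patient
identity and isocenter. Dose recomputation and plan review remain with
the treatment planning system and the clinician.

All coordinates follow one convention: x = left-right (the lateral beam
axis), y = anterior-posterior (+y anterior), z = superior-inferior
(+z superior). Every threshold below is configurable; the values given
are the defaults and the rationale for them.

## Auto-segmentation

Segmentation is a fixed chain of morphological operators on the
soft-tissue mask — no atlases, no training data, no user interaction.

**Soft tissue.** Voxels with HU in [-200, 200] (`window`). This captures
brain, scalp, muscle, eye and lens while excluding bone (> 200) and air
(< -200).

**Brain** — the *largest* soft-tissue component:

1. A 3D Sobel gradient magnitude localizes bone interfaces; voxels above
   `edgeThreshold` (300 HU/mm), dilated by `edgeDilate` (1 mm), are
   subtracted from the soft-tissue mask. This cleans the partial-volume
   rim along the skull so that thin soft-tissue connections through bone
   channels do not merge distinct structures. (The combination of the
   edge image with the mask is exposed as `edgeStrategy`; `"none"`
   disables it.)
2. Binary erosion with a spherical element of `erosionRadius` (2 mm)
   severs connections thinner than the element — extraocular muscles
   connecting brain to orbit contents are the anatomical culprit. The
   radius is a compromise: large enough to cut muscle-scale bridges
   (~3 mm diameter), small enough that the brain itself survives.
3. 26-connected components; the largest by volume is the brain.
4. The paired dilation restores the eroded margin (an opening overall),
   a closing with `closingRadius` (3 mm) smooths residual concavities,
   and a final window-constrained dilation regrows the rim removed in
   step 1 — bone still blocks it, so the mask snaps to the inner skull
   table without leaking.

**Eyes** — the two *roundest* remaining components. The soft tissue
outside the brain is eroded with the same `erosionRadius` *before*
component analysis, because in real anatomy (and in our phantom) the
globes are connected to facial soft tissue by thin bridges; the erosion
is what turns them into separate components. Candidates smaller than
`minCandidateMm3` (500 mm³) are ignored. Roundness is sphericity

$$\Psi = \frac{\pi^{1/3}\,(6V)^{2/3}}{A},$$

1 for a sphere and below 1 for everything else. The surface area $A$
comes from either face counting (exact for boxes, but a systematic 1.5×
overestimate for smooth curved surfaces, giving spheres ≈ 0.67) or an
estimator that integrates the central-difference gradient magnitude of
the voxel indicator (the coarea formula), which converges to the true
area on smooth shapes. The gradient estimator is the default precisely
because a rasterized sphere should score near 1; the face estimator is
retained for closed-form checks. A candidate must reach `roundnessMin`
(0.7); needing two such candidates is an explicit error condition —
a missing eye should stop the pipeline, not mis-segment silently.

Each selected candidate is refined inside its VOI: lens-bright voxels
(see below) are first erased to the candidate's median HU so the
internal lens edge cannot stop the evolution; a morphological geodesic
level set then grows the eroded candidate against the CT —
one-voxel dilations gated by the edge-stopping function
$g = 1/(1+|\nabla I|^2/\lambda^2)$ (λ = 60 HU/mm, growth where
$g > 0.3$) and restricted to the soft-tissue window, with
`levelsetCurvature` majority-filter passes per iteration approximating
curvature flow, for at most `levelsetIterations` (50) iterations with
early termination on convergence. A final one-voxel snap onto the
window-limited boundary layer recovers the high-gradient voxels at the
bone interface, and a closing smooths the result. Left and right are
assigned by the sign of the x centroid.

**Lenses** — the largest *bright* patch near each eye. In the eye's
bounding box plus `eyeVoiMargin` (4 mm), the H-convex transform
$f - R^\delta_f(f-h)$ (grayscale reconstruction by dilation) assigns
each regional maximum the value $\min(v, h)$ where $v$ is its height
above the surroundings; thresholding at `hconvexHeight` = 40 HU keeps
exactly the regions that out-shine their neighbourhood by at least
40 HU. The lens (80–120 HU) against vitreous (0–30 HU) clears this
easily; candidates are restricted to the soft-tissue window so cortical
bone in the VOI can never masquerade as a lens. The largest patch wins;
a closing with `lensClosingRadius` (1.5 mm) smooths it. An eye with no
supra-threshold patch yields an *empty mask plus a warning* — unlike a
missing eye this is non-fatal, since aphakic or noisy cases occur and
the plan search can proceed on brain and eyes.

All structuring elements are spheres specified in millimetres, so the
pipeline behaves identically across voxel sizes.

## Validation metrics

Dice overlap $2|A\cap B|/(|A|+|B|)$, the symmetrized mean surface
distance, and the Hausdorff distance are computed between boundary-voxel
centers in mm. "Mean Euclidian distance" is read as the symmetric mean
(all directed nearest-neighbour distances from A to B pooled with those
from B to A); Hausdorff is the maximum over both directions, making it
symmetric as implemented. Distances are between voxel centers — no
sub-voxel interpolation — which is the appropriate resolution for masks
that are themselves voxelized; the optimized implementation is tested to
1e-9 mm against an O(n²) brute-force oracle.

## Anatomy matching

The matcher never sees image data: a database case is its structure
surfaces and its plan, nothing else.

**Cropping.** Most of the brain is covered by the open field, where
anatomical mismatch is dosimetrically irrelevant; the critical region is
the brain-eye interface shaped by the MLC. Brain surface points are
therefore discarded on the superior-posterior side of a plane "from the
nape toward the forehead": by default the plane passes through the
superior pole of the eye globes and its normal is +z tilted 15° towards
-y. Both the tilt and the plane point are configuration parameters — no
canonical values exist for them, so they are documented defaults rather
than constants. Eye surfaces are always kept whole.

**Alignment.** Patients are set up at different couch positions, so a
translations-only iterative closest point (ICP) alignment removes the
bulk offset: initialize at the centroid difference, then alternate
full-3D nearest-neighbour assignment with a translation update by the
mean residual until the update is below `tolMm` (0.001 mm) or `maxIter`
(100). Rotations and scaling are deliberately excluded — couch setup
differences are translational, and a rotation would have to be undone
when reusing the plan geometry.

**Score.** After alignment, for every patient point $i$ the full-3D
nearest database point is found, and only the y and z components of the
residual — perpendicular to the lateral beams — enter the score:

$$\mathrm{score} = \sqrt{\tfrac1N \sum_{i=1}^{N}
\big[(y_i - \mathrm{closest}(y_i))^2 + (z_i - \mathrm{closest}(z_i))^2\big]}.$$

Two design points deserve emphasis. First, the x residual is discarded
because along-beam geometry differences barely perturb the dose of
parallel-opposed fields, while across-beam differences move the
high-gradient MLC edge. Second, the residuals are *squared* before
averaging: a uniform 2 mm discrepancy everywhere scores 2.0, while a
10% region at 7 mm with 1 mm elsewhere scores
$\sqrt{0.1\cdot 49 + 0.9\cdot 1} \approx 2.41$ — worse, as it should
be, since a localized large mismatch disturbs the dose where a constant
small offset merely shifts it; a plain mean distance (1.6 vs 2.0) would
rank the two the other way. The $1/N$ normalization makes scores
comparable across clouds of different sizes; the sum runs over the *new
patient's* points (one-directional), and brain and eye points are
pooled with equal weight (a per-structure weighting hook exists but
defaults to uniform).

Ranking scores every database case, sorts ascending and breaks ties by
case id. Under database growth by supersets the best score is
non-increasing by construction — the observed decrease on synthetic
70-case databases mirrors the behaviour expected of a larger library of
priors.

## Plan retargeting

The matched template plan is copied with exactly three changes: patient
name/ID, a fresh SOP instance UID, and the isocenter. Since ICP maps
patient coordinates *onto* the database case's frame, template geometry
returns to the patient frame through the inverse translation:
isocenter_new = isocenter_template − t_ICP. This inverse-translation
rule is this package's design decision — there is no canonical
prescription for it — and it is surfaced in the documentation
deliberately. Beams, MLC sequences, monitor units and all pass-through
attributes are preserved verbatim (verified attribute-by-attribute in
the tests); prescription dose is intentionally left unset, since it is
entered when dose is recomputed in the TPS.

## The synthetic phantom: what it emulates, what it does not

No clinical data ship with the package; every stage is exercised on a
parametric head phantom (`phantomSpec()`): an ellipsoidal head
(140 × 190 × 156 mm) of scalp-like soft tissue, a 6 mm ellipsoidal
skull shell around a 124 × 136 × 120 mm brain, 12 mm-radius eye globes
sealed in 3 mm bony orbit shells anterior-inferior to the brain,
9 × 5 × 9 mm lenses of 110 HU inside the globes, and 1.5 mm-radius
muscle bridges drilled from each globe through the orbit into the brain
— the thin connections whose severance the erosion step exists for. HU
values (air −1000, scalp 40, skull 700, brain 35, eye 25, lens 110,
muscle 50) respect the soft-tissue window and the lens-brighter-than-eye
assumption; optional Gaussian noise is available but off by default.
Ground-truth masks are the exact rasterized solids.

A *database* of priors is emulated by jittering the geometry per case:
independent uniform perturbations of head/brain semiaxes and centers
(±1.5–2 mm), eye centers (±1.5 mm) and eye radius (±0.75 mm), plus a
±15 mm whole-patient couch translation that the ICP must remove. Each
case is seeded by `rngSeed + case number`, so databases are exactly
reproducible, and each case carries a template plan: two lateral
opposed beams (gantry 90°/270°), isocenter at the brain centroid,
rectangular placeholder MLC apertures. Because full CT volumes of many
cases would be needlessly heavy, `generateDatabaseIndex()` builds the
database case by case, keeping only each case's cropped surface cloud
and plan — which is also how the matcher's database is meant to work.

What the phantom does *not* emulate: CT texture and beam-hardening
artifacts, partial-volume blur at interfaces, anatomical asymmetries and
pathology, contouring style variability, and realistic MLC leaf
sequences. Passing the phantom recovery tests therefore demonstrates
the operators select and delineate the intended structures under the
stated anatomical assumptions — not clinical-grade accuracy; the high
phantom Dice values (≈ 0.99 brain and eyes, ≈ 1.0 lens) reflect the
absence of those confounders, and the test thresholds (0.95 / 0.85 /
0.60) are deliberately set at the level of performance a clinical
validation of this kind of pipeline reports, not at what the clean
phantom can achieve.

## Numerical choices and problem sizes

* Erosion/dilation and components use exact offset enumeration in C++;
  26-connectivity everywhere.
* Grayscale reconstruction (H-convex) iterates 6-neighbour maxima to a
  fixed point — exact, and fast on eye-sized VOIs.
* Contours are written at the 0.5 iso-level of the mask indicator
  (vertices midway between voxel centers) and rasterized back by
  even-odd scanline with half-open crossings, so the write/read round
  trip reproduces the mask essentially exactly for structures more than
  one voxel thick.
* Nearest neighbours are exact brute force in C++; surface clouds are
  decimated (brain 1200, eyes 400 points by default) with a seeded
  sampler, keeping ranking deterministic.
* Degenerate inputs error early and descriptively: empty soft tissue,
  fewer than two round candidates, an empty database, a crop plane that
  discards everything, two empty masks in a Dice.
* Default problem sizes: unit tests run a 2 mm phantom
  (79 × 103 × 85); recovery studies use twenty 1 mm phantoms
  (156 × 206 × 170, ≈ 8 s each to segment) and a 70-case database
  (≈ 80 s to generate and index); a full autoplan on a fresh 1 mm
  phantom takes ≈ 13 s single-threaded.

## Known limitations

* Translations-only ICP cannot compensate head tilt; a rotated setup
  degrades the score for every database case symmetrically but may
  reorder close matches.
* The score treats brain and eye points uniformly; per-structure
  weighting is exposed but unvalidated.
* The crop-plane position/tilt defaults are reasoned, not fitted to
  clinical outcomes.
* Lens Dice is intrinsically fragile for small structures; the empty
  mask + warning path is the designed degradation.
* The phantom's orbit is a closed bony shell; real orbits are open
  anteriorly, where the level set relies on the soft-tissue window
  (eyelid/air) rather than bone to stop.
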