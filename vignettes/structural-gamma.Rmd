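---
title: "Structure-based gamma evaluation: model, choices, limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure-based gamma evaluation: model, choices, limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(structgamma)
```

## The model

Patient-specific QA compares a reference dose volume $D_r$ (typically the
planning system's calculation) with an evaluated volume $D_e$ (an
independent calculation or measurement) on the same grid. The gamma index
at a reference point $\mathbf{r}_r$ is

$$\gamma(\mathbf{r}_r) \;=\; \min_{\mathbf{r}_e}
\sqrt{\frac{\lVert \mathbf{r}_e-\mathbf{r}_r\rVert^2}{\delta d^2} +
      \frac{\bigl(D_e(\mathbf{r}_e)-D_r(\mathbf{r}_r)\bigr)^2}{\Delta D^2}},$$

with $\delta d$ the DTA criterion in mm and $\Delta D$ the absolute
dose-difference criterion in Gy. A voxel passes when
$|\gamma| \le 1$ (the boundary value passes), and a structure's pass rate
is the percentage of its evaluated voxels that pass.

What makes the evaluation *structural* is the restriction and the
normalisation. Each contoured structure is rasterised onto the dose grid;
both volumes are masked to the structure (dose outside set to zero); gamma
is evaluated only at reference voxels inside the mask; and
$\Delta D = \delta D\% \times D_\mathrm{norm}$ with a per-structure
normalisation dose:

* **global** — the maximum of the *unmasked* reference volume, identical
  for every structure. This reproduces conventional global gamma,
  restricted per structure.
* **local** — $D_r$ at each point. The most sensitive mode; it
  deliberately over-weights relative errors at low-dose points.
* **quantec** — the organ's QUANTEC point-dose (dmax) tolerance from the
  shipped table. Where the compendium lists several tolerance levels the
  conservative value (lowest toxicity level) is used.
* **ro** — the clinician's per-patient tolerance for the organ, read from
  a plain-text file. For PTVs the prescription dose is used when the file
  has no explicit PTV entry. Structures with no tolerance in the
  requested table are skipped for that mode and reported as such, never
  imputed.

Because a tolerance can exceed the global maximum (e.g. bladder, 65 Gy
dmax, against a 50.4 Gy prescription), tolerance-normalised gamma can be
*more* forgiving than global gamma; with a tolerance far below the
prescription it is much stricter. Both directions are exercised by the
test suite, as is the monotonicity that drives them: raising the
normalisation dose at every point can only shrink $|\gamma|$ and raise the
pass rate.

Gamma values carry a sign: the sign of
$D_e(\mathbf{r}_r) - D_r(\mathbf{r}_r)$ at the reference voxel itself
(zero difference counts as positive). The sign is taken at the voxel
rather than at the minimising point because the minimiser's sign is
unstable wherever $\gamma \approx 0$; the voxel's own difference is what a
clinician reads off a hot/cold map.

## Geometry and masking

Dose grids are held in patient coordinates with identity orientation;
the DICOM reader canonicalises axis-aligned flips and permutations on
read and rejects oblique grids as an unsupported dialect. The grid origin
is the *center* of the first voxel, which removes half-voxel ambiguity
from both masking and the DTA search. Reference and evaluated grids must
be congruent — the intended inputs are computed on one grid — though a
trilinear resampling helper is available as an explicit pre-step.

Rasterisation assigns each contour to its nearest grid slice (ties to the
lower index; a contour farther than one slice spacing from every slice is
an error naming the structure) and tests voxel *centers* against the
polygons with the even-odd rule, so multiple polygons on one slice
compose naturally into rings and disjoint parts. Points within
$10^{-6}$ mm of an edge count as inside, making boundary voxels
deterministic. There is no partial-volume weighting and no interpolation
of contours between slices; with typical 2–3 mm grids this under- or
over-counts a one-voxel shell, which is visible in the sphere-volume test
tolerance (5%).

Structure names are standardised through a lookup table (case-insensitive
matching after stripping non-alphanumerics; laterality markers map to the
unsided organ; anything starting with "PTV" is a PTV). Planning
structures whose names contain ring, couch, bolus or artifact are
excluded before evaluation and logged. The shipped table covers the 17
organs of the tolerance table plus common variants and can be extended
from a plain-text file.

## Numerical choices

**Search.** The minimisation samples the evaluated dose by trilinear
interpolation on an offset lattice of step $\delta d/10$ within a radius
of $2\,\delta d$, with offsets visited in order of increasing radius so
the search can stop as soon as the distance term alone exceeds the
current minimum. A refinement pass then samples a $\delta d/50$ lattice
within two coarse steps of the coarse minimiser. Points whose true
minimum lies beyond the radius report the best value inside it — such
points are failing anyway. The refinement step divides the coarse step
exactly, so the engine's sample set is a subset of the verification
oracle's dense $\delta d/50$ lattice; the engine can therefore only
overestimate the oracle, and the suite checks agreement within 0.02
per voxel alongside that one-sided bound.

**Search domain.** By default the DTA search runs over the
structure-masked evaluated volume, mirroring the per-structure masked
datasets of the workflow; the zeros outside the structure participate in
the search. A `search_unmasked` option searches the full evaluated grid
instead — useful for sensitivity studies and for closed-form tests, since
near the mask boundary the interpolated descent towards the outside zeros
can rescue voxels that a continuous-dose reading would fail.

**Low-dose threshold.** The threshold is a *strictly greater-than* filter
on the reference dose. With the default threshold of zero this
automatically keeps the mask-complement zeros of masked volumes out of
the statistics without a special case; voxels inside a structure with
exactly zero reference dose are consequently also excluded (and warned
about). It also means local-mode normalisation never divides by zero.

**Dose storage.** RT Dose files are written as 32-bit unsigned integers
with a content-derived dose-grid scaling, giving round-trip errors around
$10^{-9}$ of the maximum dose; instance UIDs are derived from the grid
content and no timestamps are written, so identical inputs produce
byte-identical files. Absolute dose in Gy is required; relative-dose
files are rejected because tolerances are absolute.

**Statistics.** Summary tables report the mean and *population* standard
deviation of pass rates (the spread is descriptive, not an estimate), and
count structures scoring strictly below their own global-gamma baseline.
Structures skipped in a mode are excluded from that mode's aggregate and
counted separately. Pass rates in exported CSVs are rounded to one
decimal place.

**Maps.** The signed map uses a diverging scale centred at zero — white
at agreement, red for evaluated-hotter, blue for colder — saturating at
$|\gamma| = 2$ (twice the pass cutoff keeps failing regions
distinguishable without letting outliers flatten the scale). Voxels
outside the evaluated set are transparent over the background (a CT or
phantom slice, or neutral grey). Display resampling between CT and dose
grids is left to the caller; the renderer works in dose-grid voxels.

## The phantom generator

The generator produces file-complete synthetic cases: analytic reference
fields (flat, linear wedge, Gaussian target over a background) sampled at
voxel centers; sphere and box "organs" emitted as per-slice contours
(spheres as inscribed 64-gons, whose area deficit of ~0.16% is well below
the rasterisation test tolerance); and controlled perturbations of the
evaluated dose — uniform offset, uniform scaling, a rigid shift applied
by resampling the analytic field (hence exact, with no interpolation
error), and a localised error adding a fixed dose to a seeded random
fraction of one structure's voxels. A JSON manifest records the spec and
the closed-form expectations: a flat field with offset $o$ gives
$|\gamma| = |o| / (\delta D\% \cdot D_\mathrm{norm})$ exactly at every
voxel, and a wedge of gradient $g$ shifted by $s$ gives
$\gamma = s\,g/\sqrt{\Delta D^2 + g^2\,\delta d^2}$.

Problem sizes were chosen so the whole verification cycle is comfortable
on a laptop: closed-form cases on $8^3$–$20^3$ grids, and the
engine-versus-oracle comparison on fifty $12^3$ phantoms with smooth
random Gaussian fields and mild perturbations (±3% scaling, ≤1 Gy
offsets, ≤1.5 mm shifts) — the regime of a plausibly deliverable plan
pair, where most gamma values sit below 1.

What the phantoms deliberately do not emulate: VMAT-like dose texture,
noise, anthropomorphic geometry, or grids that disagree between the two
calculations. Passing tests therefore demonstrate correctness of the
machinery (masking, normalisation, search, statistics) on known fields,
not clinical performance on real plan data.

A property worth knowing when designing phantom studies: with
$\delta d$ equal to the grid spacing, a dose spike confined to isolated
voxels can always be DTA-rescued ($\gamma = A/\sqrt{1+A^2} < 1$ along the
path to a clean neighbour), so single-voxel errors never fail. Errors
must be spatially coherent relative to $\delta d$ — as real errors are —
to drive pass rates down; the test phantoms use region-wide offsets or
`fraction = 1` localised errors for exactly this reason, and the
manifest's `expected_failing_fraction` for sparse localised errors is the
*perturbed* fraction, an upper bound on the failing fraction.

## Limitations

* Tolerances are absolute physical dose; no EQD2/BED conversion and no
  dose-volume (DVx) constraints.
* One DTA criterion for all structures; no structure-specific geometric
  tolerances.
* Axial contours on axis-aligned grids only; no oblique geometry, no 3D
  mesh structures.
* The QUANTEC table is a single conservative point-dose value per organ;
  per-patient constraints should come from the RO tolerance file.
* Interactive slice scrolling is out of scope; the renderer produces
  static slices.
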