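---
title: "Quantifying colonic content from paired T2 / T1-FS abdominal MRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying colonic content from paired T2 / T1-FS abdominal MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(colonmri)
```

## The measurement problem

Unprepared abdominal MRI — no contrast agents, no gas or liquid infusion,
no antiperistaltic drugs — preserves the physiological state of the gut and
is the only way to measure colonic content as it actually is. No single
sequence suffices, though. In T2-weighted images the colonic lumen is dark
against the bright peri-colonic fat, which makes the *colon outline*
segmentable but says nothing about what is inside. In T1-weighted
fat-saturated (T1-FS) images feces are bright while gas and fat are both
dark, which makes the *content* classifiable but leaves the colon boundary
invisible wherever the lumen holds gas. A quantitative assessment therefore
needs both acquisitions, taken minutes apart in different breath-holds, with
the abdomen deformed differently in each.

`colonmri` implements the full chain: marker-guided colon segmentation in
T2; automatic transfer of that segmentation into T1-FS space by non-rigid
registration plus shape-preserving surface adaptation; deformation-aware
point correspondence between the two spaces; and quantification of
gas/mixed/solid content volumes and colonic morphology. A digital phantom
with complete ground truth stands in for clinical scans so that every stage
is testable at desk scale.

## T2 segmentation

The specialist provides at least five anatomical marker points along the
colon, tagging the start of the cecum, the hepatic and splenic flexures, the
descending/pelvic transition and the end of the pelvic colon; intermediate
points may be added where the trajectory is convoluted.

**Medial path.** Consecutive markers are joined by minimum-cost voxel paths
on the 26-neighborhood graph, the cost of a step being its physical length
times `eps + I_n` with `I_n` the robustly normalized intensity
(1st–99th percentile rescale) of the target voxel and `eps = 0.05`. The
concatenated chain is smoothed by a moving average (window 5) with marker
vertices pinned. Because a shortest path hugs the inside of bends, each
vertex is then recentred onto the lumen medial axis: within a 15 mm ball,
voxels are weighted by the squared distance-from-boundary of a smoothed,
thresholded dark-lumen mask and the vertex moves halfway toward the weighted
centroid, three times. Without this step the path sits 5–6 mm off-center in
phantom tubes and corrupts the distance prior below; with it the residual is
about 2 mm. The path is finally resampled at 2 mm arc steps.

**Probability model.** The colon probability factorizes as
`P(v) = L(I(v)) · D(d(v))`: `L` is a kernel-density estimate (Silverman
bandwidth) of the intensities within `r0/2` of the path, rescaled so its
mode maps to 1; `D(d) = 1/(1 + exp((d − r0)/(r0/4)))` is a logistic
fall-off in the Euclidean distance `d` to the path polyline. The scale
`r0` (default 15 mm) is the distance at which the prior halves; it should
be of the order of the expected colon radius.

**Graph cut.** The binary segmentation minimizes a standard MRF energy:
unary terms `−log P` vs `−log(1−P)` (clamped to `[1e−6, 1e6]`), pairwise
6-neighborhood contrast weights
`λ · exp(−ΔI² / 2σ_c²) / ‖Δx‖` with `σ_c` the median absolute intensity
difference over edges. Path voxels are hard foreground; voxels beyond
`3·r0` are hard background. The default `λ = 8` was fixed by an energy-
balance argument verified on phantoms: the boundary surface cost must
exceed the interior pull of the distance prior under noise, and the Dice
accuracy plateaus from `λ ≈ 8` (0.94 at `λ = 4`, 0.989 at 8, 0.993 at 12)
while larger values only increase the risk of annexing adjacent dark
structures. A multigrid scheme solves the cut at 4× downsampling, upsamples
the labels, and re-solves at full resolution only in a ±3-voxel band around
the coarse boundary with the outside labels frozen (their pairwise terms
enter the band unaries as boundary conditions). The largest 26-connected
component containing the markers is kept, and voxels are labeled
1–4 by the segment of the nearest path point (ties to the lower index).

**Refinement.** Include/exclude markers re-solve the full-resolution cut in
20 mm balls around each marker with the marker voxel as a hard seed of its
polarity and everything outside the balls frozen.

## Transfer to T1-FS

**Registration.** The T2→T1-FS transform is a dense displacement field
`p ↦ p + d(p)` on the T2 grid, estimated by a three-level (4×/2×/1×)
multiresolution scheme. Because the two modalities invert tissue contrasts,
similarity is computed not on intensities but on six-channel self-similarity
descriptors (for each ±1-voxel axis offset, the Gaussian-aggregated patch
distance, exponentiated against the local mean — the MIND construction).
Each iteration applies demons-type Gauss–Newton forces per channel, damped
by a match-consistency weight `exp(−msd / 2·mean(msd))` where `msd` is the
channel-mean squared residual: structure present in only one modality (the
gas/feces pattern inside the colon has no T2 counterpart) would otherwise
drag nearby matched edges. Updates are clamped per voxel at 2 mm, forces on
the outermost voxel rows are zeroed (one-sided gradients), the update is
smoothed with σ = 2 voxels and the accumulated field with σ = 3 voxels —
strong field smoothing is appropriate because breathing and positioning
deformations are smooth at several-centimetre scale, and halving it doubles
the recovery error on phantoms. The pyramid is initialized with a
translation found by maximizing mutual information over a coordinate-wise
grid search. On default phantoms: identity recovered to 0.96 mm mean,
a 5 mm translation to 1.19 mm mean error, and smooth deformation fields of
8 mm amplitude to ~1.4 mm inside the colon.

**Inverse mapping.** The named inverse transform is never constructed
explicitly; `x` with `x + d(x) = q` is found by fixed-point iteration
`x_{k+1} = q − d(x_k)` (tolerance 0.05 mm, cap 50 iterations), which
converges because the generator bounds the displacement gradient well below
1. All label transfer into T1-FS space uses this inverse with
nearest-label sampling — labels are never interpolated.

**Surface adaptation.** The transferred mask is correct up to the
registration residual, and in feces-filled regions the T1-FS image itself
shows where the true boundary is. The adaptation represents the surface
implicitly as a signed distance function φ (negative inside) rather than as
an explicit triangle mesh: the implicit form needs no meshing library,
voxelizes exactly, and supports the same three mechanisms — normal-driven
motion, Laplacian smoothing, and a shape-preservation corridor — as clamps
and convolutions on φ. Per iteration, band voxels (|φ| < corridor + 2
voxels) probe the fecal-content probability along the outward normal at
four depths up to 2 voxels outside the surface and move outward with speed
`δ · max(0, 2·p̄ − 1)`, `δ = 0.5` mm; the probe takes the maximum over its
samples, because averaging in beyond-wall fat/tissue samples stalls the
front one voxel short of the wall. The content probability is the posterior
of the brighter component of a two-Gaussian mixture fitted to in-mask
intensities, made monotone in intensity by isotonic correction. Expansion
only: contraction is deliberately disabled, because gas-filled colon is
indistinguishable from tissue in T1-FS, so an inward force would carve away
genuine content — in non-fecal regions the transferred T2 shape is the
authority (this is the shape-preservation principle). φ is smoothed each
iteration (weight 0.5) and clamped to `[φ0 − corridor, φ0]` with corridor
6 mm, so the surface can move at most 6 mm outward and never inward of the
transfer. Convergence is judged on the mean per-iteration change over the
*moving* part of the surface (averaging over the whole band would dilute a
locally advancing front below any tolerance immediately); the front
typically settles within 15 iterations (cap 100). After voxelization
(centers inside), a corridor-limited completion step annexes mask-adjacent
voxels whose fecal posterior exceeds the same 0.5 threshold — the implicit
surface halts at the sub-voxel wall position, which otherwise strands a
one-voxel fecal skin. Segment labels are re-assigned from the nearest
transferred voxel.

## Synchronized navigation engine

Given the field, any T2 point maps forward as `p + d(p)` and any T1-FS
point maps back through the fixed-point inverse. `corresponding_slice()`
lifts a (slice, cursor) position to a world point, maps it, and projects it
onto the other grid, returning the nearest slice and in-slice position, with
an `in_view` flag instead of clamping when the mapped point leaves the
volume — the interactive windows themselves are a UI concern and out of
scope here.

## Content and morphology

Inside the T1-FS segmentation, intensities are clustered by 1-D k-means
with `k = 3` (gas / mixed / solid). The solver is the exact weighted
dynamic program over sorted unique intensities (binned to 4096 levels above
that), so the global within-cluster optimum is attained deterministically —
restart-based heuristics are unnecessary in one dimension. Clusters are
ordered by centroid; gas is the lowest, solid the highest, and each cluster
carries a solid fraction interpolated linearly in centroid intensity, which
is the stated instantiation of "percentage of solid content" — the mapping
is not uniquely determined by the science and any monotone alternative
could be substituted. Volumes are voxel counts times voxel volume;
a solid-equivalent volume weights voxels by their cluster's solid fraction.

Morphology comes from the T2 side: per segment, length is the medial-path
arc length between boundary tags; at 10 mm arc stations the mask is
resampled on a 0.5 mm-pitch, 80 mm-extent grid in the plane orthogonal to
the path tangent, the component containing the path point is contoured by
marching squares (with linear interpolation, on a σ = 1-pixel smoothed
indicator so the contour is sub-pixel accurate), and the perimeter and the
mean distance from the path point to the contour are averaged over
stations. The cross-sectional (not per-coronal-slice) definition of the
perimeter is a deliberate choice: it is the one that reduces to `2πr` on a
cylinder.

## The phantom: what it emulates, and what it does not

The generator renders a question-mark colon trajectory (ascending,
transverse, descending, pelvic) as a tube of smoothly varying radius
(12 ± 3 mm by default) filled with alternating gas/feces pockets
(lengths drawn uniform on [20, 60] mm, scaled so the expected gas share is
0.4), wrapped in a 6 mm fat shell, with small-bowel distractor tubes within
two radii of the cecum and sigmoid and a generic mid-intensity block beside
the transverse colon standing in for the liver. Intensities reproduce only
the qualitative modality contrasts (T2: lumen 30 < tissue 100 < fat 220;
T1-FS: gas 20 ≈ fat 25 < tissue 90 < feces 210; arbitrary units), with
additive Gaussian noise σ = 10 by default (Rician optional — at these
signal levels the difference is cosmetic). The inter-acquisition
deformation is a sum of three 8 mm Gaussian bumps at 48 mm scale, a
magnitude chosen as plausible for repositioning between breath-holds; the
generator validates `Σ 0.607·a/s < 0.9` so the field is provably
invertible. Everything is deterministic given the seed, and the T1-FS
volume is rendered through the *analytic inverse* of the field, so the two
spaces are exactly consistent.

What the phantom does not emulate: bias fields and coil shading, partial
volume at 2 mm resolution beyond nearest-center rasterization, haustral
folds, peristaltic motion artifacts, the full organ surroundings, and
intensity variation along the colon. Passing the suite therefore
demonstrates the pipeline's mechanics — energy minimization, transfer,
inversion, quantification — under controlled conditions, not clinical
performance; the clinical accuracies reported for this class of method are
used as conservative floors for the phantom suite, which is easier than
clinical data.

Default study conditions are ten phantoms, 96×96×64 voxels at
2×2×3 mm, seeds 0–9, scored with ground-truth markers; this runs the full
pipeline in roughly a minute per phantom on one core. Unit tests use a
64×64×44 variant of the same scene.

## Numerical choices and degenerate inputs

* Grids must be axis-aligned; oblique NIfTI orientations are rejected, not
  silently reoriented, to keep the cross-modality math unambiguous.
  Intensities are never rescaled on read; every stage normalizes robustly
  on its own.
* The k-means solver refuses inputs with fewer distinct intensities than
  clusters; the mixture model refuses masks under 50 voxels and collapses
  (component means within 1% of the range).
* Morphology stations whose path point misses the mask are skipped and
  counted; if all stations skip, that is an error, not a silent zero.
* Dice of two empty masks is 1 by convention; containment of an empty
  ground truth is undefined and errors.
* The suite's standard deviations are population (not sample) standard
  deviations; with a single phantom they are exactly 0.

## Known limitations

* Expansion-only adaptation cannot correct a transferred mask that
  overshoots into tissue; such overshoot is bounded by the T2 segmentation
  quality and the registration residual.
* The registration is tuned for smooth, breath-hold-scale deformations;
  sliding interfaces and large local distortions are outside its model.
* Segment boundaries inherit marker placement; jittered markers (σ = 3 mm
  stress test) cost little Dice but shift per-segment attribution near the
  flexures.
* The medial-path recentring assumes the lumen is darker than its
  surroundings locally; a colon segment completely embedded in dark
  structures could defeat it.
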