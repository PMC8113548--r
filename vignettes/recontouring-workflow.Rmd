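---
title: "Mirror-based planning, registration and drill guidance for craniofacial recontouring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mirror-based planning, registration and drill guidance for craniofacial recontouring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CranioGuide)
```

## The problem

Craniofacial fibrous dysplasia replaces normal bone with expanding
fibro-osseous tissue; the standard treatment of the resulting contour
deformity is *recontouring* — shaving the excess bone down to the contour the
patient would have had without the lesion. Done freehand, the surgeon has no
quantitative handle on where the target surface lies or how much bone remains
above it. Navigated workflows address this in four computational steps, all of
which this package implements on plain surface meshes, with no tracking or
display hardware in the loop:

1. **Virtual planning** — the healthy contralateral side is mirrored across
   the midsagittal plane to define the planned post-operative surface and the
   resection region.
2. **Registration** — the tracked instrument and patient reference frames are
   tied to image space through paired-point rigid registration, so the drill
   tip can be expressed in the coordinates of the plan.
3. **Guidance** — the signed distance from the drill tip to the planned
   surface drives a two-state colour cue: green while more than 1 mm of bone
   remains, red at or below 1 mm.
4. **Evaluation** — the post-operative model is superimposed onto the plan
   using the unchanged part of the skull, and hundreds of paired points along
   surface normals in the surgical area quantify the achieved accuracy.

All geometry is in millimetres.

## Mirroring and the midsagittal plane

The midsagittal plane is estimated from named anatomical landmarks in a
single least-squares problem that accepts midline landmarks, bilateral
left/right pairs, or both. Writing the plane as $(q, n)$ with unit normal
$n$, the objective is

$$\sum_{m \in \text{midline} \cup \text{midpoints}} \big(n^\top (p_m - q)\big)^2
  \;+\; \sum_{\text{pairs } i} \big\| (I - n n^\top)(r_i - l_i) \big\|^2 ,$$

i.e. midline landmarks and pair midpoints should lie on the plane and each
left-to-right axis should be parallel to the normal. The minimizing normal is
the eigenvector with the smallest eigenvalue of $S_{\mathrm{on}} -
S_{\mathrm{axis}}$ (the scatter of the on-plane points about their centroid
minus the scatter of the pair differences), and $q$ is the centroid of the
on-plane points. This closed form makes the fit exactly covariant under rigid
motions of the landmark set, which the test-suite asserts. The normal is
oriented from the anatomical left to the right, using the pair axes when
present. Configurations that leave the plane under-determined (fewer than 3
midline landmarks and fewer than 3 pairs, or collinear midline points without
pairs) are refused rather than guessed at.

Mirroring applies the Householder reflection $p \mapsto p - 2\,
((p-q)\cdot n)\, n$ to every vertex and flips the face winding, so the
mirrored surface keeps outward normals and a closed mesh keeps its positive
signed volume.

## The resection plan

`buildPlan()` measures, for every vertex on the affected side, the signed
distance to the mirrored surface, clamped at zero — the *excess map*, the
thickness of bone standing proud of the planned contour. Faces whose three
vertices all exceed a membership threshold form the resection region. The
threshold defaults to **0.5 mm**, chosen to sit below typical
mirroring-plus-segmentation noise while catching any excess a surgeon would
act on; it is a parameter, not a constant. Correspondence between the pre-op
and mirrored surfaces uses nearest-point projection rather than ray casting,
which stays well-defined for lesions that are not star-shaped around any
centre.

The excess *volume* — the quantity that is hard to judge intraoperatively —
is the prism sum over the region: each vertex contributes its excess
thickness times one third of its incident region-face area. On a uniform
2 mm slab over a 10 × 10 mm patch this integrates to 200 mm³ exactly up to
mesh discretization.

## Registration

Paired-point registration is the closed-form Kabsch/SVD solution with the
reflection case handled by flipping the smallest singular direction, and the
fiducial registration error (FRE) reported as the RMS residual, the standard
image-guidance convention.
The frame graph composes static and tracked edges over the
`TRACKER / PATIENT_DRF / DRILL_DRF / IMAGE` frames; tracked edges interpolate
translation linearly and rotation by slerp on unit quaternions, and poses are
serialized as quaternion + translation.

Surface refinement is classic iterative closest point: exact closest-point
correspondence alternating with the Kabsch fit, with per-iteration rejection
of pairs farther than 5× the median distance (robustness to partial overlap
between a post-operative model and a plan). Plain closest-point iteration
slides tangentially on smooth surfaces and converges geometrically with a
ratio close to 1, so the loop adds an Aitken-type extrapolation in twist
coordinates — in the spirit of the classic accelerated ICP — whenever
successive increments align; a jump is only accepted when it lowers the RMS,
so the RMS sequence remains monotone non-increasing, a property the tests
check on every run. With 250 surface points on the phantom this recovers a
5 mm / 5° displacement to better than 0.01° / 0.001 mm in about a hundred
iterations.

Published descriptions of this clinical workflow leave the intraoperative
patient-to-image registration procedure unspecified (landmark count,
fiducial type); here it is the same paired-point
machinery applied to anatomical landmarks or fiducials, with ICP refinement
available behind a flag. That choice, and the decision to implement
refinement at all, are design decisions of this package.

## Guidance semantics

The colour rule is taken literally: **green** iff the signed distance to the
planned surface exceeds the threshold (default 1 mm), **red** at or below it
— the boundary value itself is red. There is no hysteresis by default; a
configurable band exists but is off, because the two-rule description is
unambiguous on this point. The distance is *signed* (positive = bone still to
remove, negative = past the plan), so overshoot keeps the display red;
published descriptions do not say what is displayed past the plan, and
the signed convention is the conservative reading. State is a pure function
of distance and threshold, so replays are bit-reproducible.

Transition times between bracketing samples are linearly interpolated at the
threshold crossing, which makes the transition log independent of the
sampling rate: on an analytic linear approach the logged crossing instant
corresponds to a remaining distance of exactly 1 mm.

Distance queries run through a compiled exhaustive per-triangle scan with an
exact bounding-box lower-bound prune — a face is skipped only when it
provably cannot contain the closest point, so results are identical to brute
force (the suite checks 1000 random queries against an independent per-
triangle oracle at 1e-9). The signed distance takes its sign from the
angle-weighted pseudonormal of the closest feature, which is the standard
robust convention for points near edges and vertices.

## Evaluation

`alignPostop()` superimposes the post-operative model onto the plan using
only unchanged-region correspondences (warning if any lie on the surgical
area), optionally refined by ICP restricted to the unchanged region.
`samplePairedPoints()` then draws source points *area-uniformly* (faces
sampled proportionally to area, positions uniform in barycentric
coordinates, seeded) on the planned surface inside the surgical area, and
pairs each with the nearest intersection of its surface-normal line with the
post-operative mesh, searching both directions. Pairs with no hit within
10 mm are discarded and counted — gaps that large indicate correspondence
failure, not surgical deviation. Planned-surface normals are used; whether
commercial surface-comparison software uses the planned or post-op normals
is not documented, and this is recorded as an open choice.

Per-case statistics are min / max / mean / SD of the unsigned pair
distances (a signed under/over-cut variant exists behind a flag; reported
minima in clinical tables are near zero, not negative, which is consistent
with unsigned reporting). The cross-case aggregate uses the **population**
SD (divide by $n$): applied to the five published per-case means (1.277,
1.218, 1.525, 1.861, 1.326 mm) it gives 0.234 mm, matching the published
"±0.234", whereas the sample convention gives 0.261. The per-case SD over
points uses the same convention for consistency; the published text does not
allow that one to be verified either way. Note the arithmetic mean of those
five printed means is 1.4414, which rounds to 1.441 rather than the printed
1.442 — the published aggregate was evidently computed from unrounded
per-case values, so agreement to ±0.001 is the best any reimplementation can
achieve from the printed table.

## The synthetic phantom

Real skull meshes would make the package depend on patient data, so the
generator builds an analytically tractable stand-in: an ellipsoid
(semi-axes 70 × 90 × 65 mm, adult-cranium scale) meshed as a subdivided
icosahedron — exactly bilaterally symmetric about $x = 0$, because
reflection commutes with midpoint subdivision in floating point — with a
Gaussian bump (default height 6 mm, angular footprint σ = 0.25 rad ≈ 17 mm
of arc) displacing vertices along the outward ellipsoid normal on one side,
standing in for a zygomaticomaxillary lesion. Landmarks are exact midline
and exactly mirrored bilateral points on the smooth ellipsoid; fiducials are
seeded points on the unaffected side. Ground truth (displacement field,
lesion footprint, every frame transform, the residual field) is returned
alongside, so every quantity the pipeline estimates has an exact reference.

`simulateProcedure()` moves each resection-region vertex onto the planned
surface and offsets it along the planned normal by a smooth residual field
(random low-order spherical-harmonic-type polynomial), standardized by
area-weighted quadrature over the planned surgical area to a requested mean
and SD — defaults 1.4 ± 0.7 mm, the scale of published recontouring
accuracy. It scripts approach-and-retreat drill passes over the region,
expresses them through a random ground-truth frame chain, and perturbs poses
and fiducials with seeded zero-mean noise (defaults: 0.15 mm translation,
0.05° rotation per sample, 0.1 mm fiducial localization — optical-tracker
scale). One integer seed fixes the phantom, the procedure, the noise and
therefore every downstream report; with all noise at zero the replay
reproduces ground truth to machine precision.

What the phantom does *not* emulate: real segmentation artefacts, the
anatomy's deviation from an ellipsoid (ridges, foramina, thin walls),
lesions that distort rather than only inflate the surface, soft-tissue
occlusion of fiducials, and temporally correlated tracker noise. Passing
tests therefore demonstrate the correctness of the algorithms under the
stated error model, not clinical accuracy on patient CT data — the published
per-case clinical errors depend on patient imaging and are explicitly not
reproduced.

## Numerical choices and problem sizes

* Vertex welding at 1e-6 mm and removal of faces below 1e-12 mm² at load
  time (STL files duplicate vertices per facet).
* Rotation validity at 1e-9 ($R^\top R = I$, $\det R = +1$); plane normals
  unit to 1e-12.
* Rotation angles are computed with the atan2 form (skew norm against
  trace), which stays accurate for the sub-microdegree errors the
  registration tests measure; the naive acos form loses half the digits
  there.
* The default test-suite and the acceptance script use a subdivision-4
  phantom (5120 faces), 250-point ICP runs, 60–1000-sample pose streams,
  500 paired points per case and 10 simulated cases — sizes chosen so the
  whole suite exercises every stage in about a minute on one core while
  keeping Monte-Carlo standard errors well below the tolerances being
  asserted.

## A worked run

```{r, eval = FALSE}
ph   <- makePhantom(phantomSpec(seed = 7))
plane <- fitMidsagittalPlane(ph$landmarks)
plan <- buildPlan(ph$mesh, plane, "right")
plan
#> PlanModel (right side): 340 resection faces, max excess 5.97 mm,
#>   excess volume 12804.0 mm^3

proc <- simulateProcedure(ph, plan, residualMean = 1.4, residualSd = 0.7,
                          seed = 11)
evaluateProcedure(plan, proc, n = 500, seed = 3)
#> DeviationReport [phantom]: n = 500, min 0.0324, max 2.7209,
#>   mean 1.381 +/- 0.678 mm

aggregateCases(c(1.277, 1.218, 1.525, 1.861, 1.326))
#> AggregateReport: 5 cases, mean +/- SD = 1.441 +/- 0.234 mm
```
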