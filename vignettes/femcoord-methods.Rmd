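---
title: "femcoord: models, parameters and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{femcoord: models, parameters and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the scientific content of the package: the
pipeline and its assumptions, the tunable parameters with their defaults
and rationale, what the synthetic-data generator emulates (and what it
does not), numerical choices, and the design decisions taken where the
underlying method leaves the details open. It states no empirical result
that the test-suite does not itself compute.

## The pipeline and its assumptions

The detector assumes a closed triangular surface of one **complete**
femur in millimetres, plus the side. Units are a documented input
contract — STL carries no unit metadata and no inference is attempted.
Closedness is required because the first step is a mass-property
computation (volume, centre of mass, inertia tensor by the divergence
theorem, unit density); everything downstream tolerates open sub-meshes.

Stage 1 normalizes pose and establishes dense correspondence with an
annotated template: principal-axes alignment (the temporary femoral
coordinate system, TFCS), isotropic scaling of the subject's long-axis
extent to the template's, a coarse rotation grid (10° about the long
axis × a 180° flip about y, then a 5° refinement scored on the distal 40%
to lock the condyles), a two-bone linear-blend-skinning (LBS) fit of
femoral version / CCD angle / neck length, and a locally affine nonrigid
ICP. Principal axes only orient the bone up to axis signs and are not
anatomically labelled; the grid pre-registration resolves that, which is
what makes the whole chain invariant to the input pose.

Stage 2 refines landmarks with shape priors; each stage is an
independent function with its own diagnostics, so the per-stage contracts
can be tested in isolation.

## Tunable parameters

All tunables live in one namespace, `femcoord_config()`, with these
defaults (units in brackets):

* **Nonrigid ICP** — initial stiffness 100, 8 geometric levels, factor
  0.7, 2 closest-point/solve alternations per level, translation weight
  `gamma = 1`. The stiffness schedule trades global rigidity against
  local fit; the published variants give the shape of the schedule but
  not the constants, so these are exposed. Convergence is reported, not
  enforced (a warning flag in the diagnostics).
* **Neck axis** — coordinate descent on two tilt angles, step 1° shrunk
  to 0.1°, perimeter tolerance 1e-4 [mm], at most 200 iterations; the
  cutting-plane offset is line-searched inside the mapped neck band
  *along the current axis* (the band can sit skewed relative to the
  initial ellipse normal, and the waist must remain reachable).
* **Table-top plane** — fixed-point tolerance 1e-6 [rad] on the update
  rotation, at most 50 iterations.
* **Sagittal stack** — 15 planes per condyle placed between the 15 % and
  85 % quantiles of the mapped region extent (quantiles rather than the
  raw range make the stack robust to label-transfer outliers such as
  osteophytes); the articulating arc is the posterior-distal quadrant
  ± 20° measured about the condyle-region centre (not the contour
  centroid, which is biased by the trochlea and shaft); tilt limited to
  10° about the initial condylar axis. The tilt limit matters: a
  quadric-like condyle has a far-away spurious orientation in which its
  cuts become circles and the focus dispersion degenerates; a local
  search from the posterior-condylar initialization with a 10° box never
  sees it.
* **Notch** — 15 sector cuts, crease threshold **+0.2 [1/mm]**, rim
  candidates within 28 mm of the PFEA, 128 silhouette scanlines. The
  sign deserves a note: the boundary between the trochlear surface and
  the intercondylar fossa is a step-like edge where the fossa wall meets
  the articular surface — locally the bone is an intersection of two
  half-spaces, i.e. a **convex** crease. Its smoothed discrete curvature
  (three-point circumcircle, five-point window on a 0.9 mm-resampled
  contour) is ≥ ~0.3, while every smooth patch of the bone stays below
  ~0.13, so a single threshold separates the two regimes. Each crease is
  smeared into a short run of above-threshold samples by the
  tessellation; the most proximal run is selected and the corner is
  located as the curvature-weighted mean of the run (a sub-sample
  estimate unbiased w.r.t. which side of the crease the peak lands on),
  snapped back onto the surface. The sector band, silhouette bins and
  temporary notch point all use a mediolateral axis orthogonal to the
  posterior and distal directions — projecting onto the (tilted) cutting
  normal itself would skew mediolateral coordinates along the bone's
  length.

## The synthetic femur: what it emulates

`generate_femur()` builds a femur-like solid as a smooth union of
implicit primitives — head sphere on a neck capsule at the commanded CCD
and version angles, a bowed shaft capsule, two posterior condyles,
greater/lesser trochanter bumps, a trochanteric crest, epicondylar
prominences, a trochlear rod with a carved patellar groove and an
intercondylar fossa — and extracts the surface with naive surface nets on
a regular grid (default 2.0 mm, a typical CT-reconstruction surface
resolution). Ground truth comes from the construction, never from the
mesh: the head centre, neck and shaft axes, condylar axis and table-top
plane are closed-form; the notch is found by 1D root finding on the
exact field along the carve boundary.

Three constructions are deliberate:

* the condyles are elliptic rods with a **linear taper** toward the
  intercondylar side, so each condyle has a unique most-posterior point
  (at its untapered outer end) and the posterior tangency plane shared
  with the crest capsule is exact — this is what makes MPC/LPC/PTC and
  the TTP well-posed at a given tessellation;
* sagittal cuts of the rods are exact ellipses centred on the rod axes,
  giving the sagittal-stack stage a clean optimum (centres exactly
  collinear; foci on two mildly opposite-sloped lines that cancel in the
  combined fit);
* the patellar-groove slot opens the notch in the frontal view, as on a
  real femur — without it the frontal silhouette's distal outline would
  see the trochlea instead of the notch arch and the temporary notch
  point would be biased distally.

Unspecified generator lengths scale isotropically with `total_length`
(proportions of a canonical 450 mm femur): femoral dimensions scale
near-isotropically with bone length, so a 400 mm default subject is a
scaled canonical femur rather than a bone with an out-of-proportion
head — the latter would have an unrealistically tilted maximal diameter
and is not a shape the method claims to handle.

**What a green test does not establish.** The generator has no
interindividual shape variability beyond its parameters, no cortical
detail, no pathology other than the single para-epicondylar osteophyte
surrogate, and condyles that are analytically convenient rather than
anatomically spiral. Passing the recovery grid shows the pipeline is
correct and internally consistent on bones whose ground truth is known;
it does not quantify accuracy on real CT reconstructions, for which only
a comparison against expert annotations (out of scope here) would do.

## Numerical choices

* **Mesh cleaning** merges vertices within 1e-6 mm and drops only
  repeated-index faces. Dropping zero-area faces with three *distinct*
  vertices would break edge parity (and hence closedness) on isosurface
  meshes; repeated-index dropping is parity-safe and covers the way
  zero-area facets actually appear in STL facet soup.
* **Surface nets** rather than marching cubes/tetrahedra: one vertex per
  sign-crossing cell gives ~3× fewer vertices, no sliver faces, and a
  closed manifold on resolved fields. Grid values within 1e-9 of zero
  are nudged off the level set.
* **Ellipsoid fitting** uses the ellipsoid-specific algebraic constraint
  (4J − I² = 1 on the quadratic-form invariants). The unconstrained
  quadric fit returns hyperboloids on near-cylindrical mid-shaft data;
  the constraint is rotation-invariant and the data are centred first,
  so the fit is equivariant under rigid transforms. The ellipse fit is
  2D-in-plane (total-least-squares plane, then the numerically stable
  direct ellipse-specific conic fit); the sphere fit is algebraic with
  Gauss-Newton geometric refinement, both residuals reported.
* **Ties** in extreme-point queries are broken by vertex order; the
  pipeline contains no random number generator (the robustness harness
  is the only stochastic component and takes an explicit seed), so a
  given input always produces the identical output.
* **Left femora** are handled by mirroring the *template* (a left femur
  is the mirror image of a right one — no parameter setting of a
  right-handed template can reproduce it); the subject mesh is never
  modified. Frame conventions: the posteroanterior axis is
  anterior-positive and the distoproximal axis proximal-positive on both
  sides; the mediolateral axis completes the right-handed triad and is
  therefore lateral-positive on the right and medial-positive on the
  left (a fixed lateral-positive choice on both sides cannot coexist
  with right-handedness).
* **Euler angles** for frame comparison use the intrinsic x-y-z sequence
  on the (ML, PA, DP) axis rows, matching the
  adduction-abduction / internal-external / flexion-extension labels;
  intrinsic vs extrinsic is not derivable from the published material,
  so the choice is documented here and isolated in one function.

## Design decisions under open questions

* **Scaling direction.** The subject is scaled to the template length
  and all refinement runs in that space; results are transported back
  through the exact inverse (directions are scale-invariant, points
  unscale exactly onto the original surface).
* **Pre-registration scoring** is template→subject (the cheaper
  direction); the distal part for the 5° refinement is the distal 40 %
  of the long-axis extent.
* **Version recovery is shared between stages.** The principal axes of
  inertia twist with femoral version (about 0.6° per degree), so the
  TFCS alignment and the rotation grid absorb roughly half of a
  template-subject version offset before the LBS stage sees it. The
  fitted LBS version offset is therefore the sign-correct *remainder*,
  not the full anatomical difference; alignment and deformation jointly
  line the template neck up with the subject's. This matters when
  interpreting the deformation diagnostics, and it is why the LBS
  parameter must not be read as a torsion measurement.
* **TTP fixed point at one step.** From a pose whose posterior direction
  equals the true table-top normal, the first iterate already selects
  the fixed-point contact vertices; the second iterate only confirms a
  sub-tolerance update. Tessellation noise of the contact vertices (not
  the iteration) limits the plane's accuracy.
* **Region transfer** is by Voronoi assignment of subject vertices to
  the nearest deformed-template vertex, so mapped regions are dense at
  the subject's own resolution; sampling regions only at template
  vertices would quantize extreme-point landmarks (MPC/LPC) to the
  template resolution.

## Known limitations

Large osteophytes at the femoral *neck* can still misalign the neck axis
(the osteophyte guard covers the epicondylar selection only); partial
femora are not supported; the side must be supplied; silhouettes are
exact only for projections that are monotone along the scanline axis
(sufficient for the shapes the pipeline cuts, stated in the function
contract).
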