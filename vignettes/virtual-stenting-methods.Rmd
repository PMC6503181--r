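---
title: "Virtual coronary stenting and computed FFR: models, numerics, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual coronary stenting and computed FFR: models, numerics, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coroflow)
```

## The problem

Fractional flow reserve (FFR) is the ratio of distal to proximal coronary
pressure, Pd/Pa, under maximal hyperemia; values at or below 0.80 mark a
stenosis as flow-limiting. Measuring it requires a pressure wire and
adenosine. An image-based alternative reconstructs the artery in 3D,
solves the steady flow field, and reads off a *virtual* FFR (vFFR) — and,
because the geometry is now just data, a stent can be deployed *virtually*
and the vFFR recomputed, predicting the physiological result of an
intervention before it is performed. This package implements that
workflow end to end on a canonical vessel representation, together with a
synthetic-vessel generator so every computation in this document and in
the test suite is fully reproducible without patient data.

## Vessel model

An artery is an ordered sequence of circular cross-sections: arc length
`s` (mm, 0 at the inlet, increasing distally), center (x, y, z), unit
tangent, and lumen radius r(s). All positions in the package are arc
lengths, never station indices. The canonical sampling step is 0.25 mm,
fine enough that a 20 mm stent spans 80 stations; files store one section
per line (`s x y z r`, mm) with 12 significant digits so round trips are
lossless at text precision.

The synthetic generator produces straight or uniformly curved tubes with
smooth focal stenoses: the radius profile is
`base_radius * (1 - sum_k severity_k * bump_k(s))`, where each bump is the
C1 cosine profile `(1 + cos(2*pi*(s - s_center)/L))/2` clipped to the
lesion interval. Severity is fractional *diameter* reduction, matching
how angiographic stenosis severity is reported clinically (the generator's
default test lesion uses severity 0.58, a typical cohort mean, in a
3 mm vessel). Severities of 1 or more (total occlusions) are rejected —
occluded vessels cannot be modeled this way and are excluded clinically
too. Optional log-normal radius noise emulates irregular lumen contours;
it is off by default so the study conditions are deterministic. What the
generator does *not* emulate: non-circular lumina, branches, tapering
reference diameters, plaque eccentricity, and reconstruction error from
angiographic projection — so passing tests here validate the machinery,
not image-based reconstruction.

## The virtual stent operator

A stent is idealized as (proximal mark, distal mark, deployed diameter),
with perfect circular expansion and full apposition. Deployment has two
effects.

**Radius correction.** Inside the stent interval the radius becomes
`max(r_native, d/2)`: a stent scaffolds outward and cannot narrow a lumen,
so segments already wider than the stent are untouched. At each edge a
1 mm taper avoids the step discontinuity that would otherwise poison the
mesh and the solver: within the taper the stent's influence collapses
linearly, `r = max(r_native, w * d/2)` with `w` falling from 1 to 0. We
chose this "max with a linear ramp" over blending `w*d/2 + (1-w)*r` into
the native radius because the blend form grows the lumen again on every
re-deployment, while the ramp form is exactly idempotent — deploying the
same stent twice is a no-op, which is the behavior an operator expects.

**Trajectory smoothing.** A real stent straightens the vessel. The
centerline across the stented segment is replaced by a cubic spline fitted
through the two stations bracketing each end (the boundary station plus
one margin station beyond it) and evaluated at the interior stations, so
the stented path is straightened and joins the unstented path smoothly.
Stations keep their arc-length labels: re-labeling would shift every
distal station and break the locality guarantee that geometry farther
than a taper length from any stent is bitwise unchanged. The validator
bounds the resulting chord/arc-length discrepancy at 2%; smoothing can
only shorten the interior polyline, never lengthen it.

Multi-stent strategies deploy sequentially in proximal-to-distal order;
because each deployment is local and monotone, disjoint stents commute
and overlapping stents behave as the union interval under the max rule.

## Meshing

The lumen surface discretizes each cross-section as 64 points on its
circle, oriented by a rotation-minimizing frame (double-reflection
method) so strips do not twist; consecutive rings are joined by
2 x 64 = 128 triangles per inter-station strip — the canonical resolution
of this workflow — with planar fan caps available to close the surface.
Inward-crossing ring planes (lumen radius exceeding the local bend
radius at too coarse a step) are detected and rejected with advice to
resample.

The volume mesh is a structured sweep: each station's disk is a fan of
concentric rings — a core at roughly uniform radial spacing plus three
geometrically graded inflation layers against the wall (growth 1.2,
first layer 5% of the local radius) to resolve the viscous boundary
layer — and each inter-station slab is filled with triangular prisms
split into 3 tetrahedra each. Quad-face diagonals follow the
minimum-global-vertex rule, which guarantees compatible splits across
shared faces. The default desk-scale mesh for a 50 mm vessel is ~50k
tetrahedra; million-cell meshes are a matter of shrinking the axial step
and radial target edge. Mesh quality is enforced by construction-time
checks (positive tet volumes, labeled closed boundary) and by tests
against closed forms: total volume converges at second order to the
conical-frustum formula, wall vertices lie on the analytic surface.

Imports and exports: VRML97 IndexedFaceSet reading (the export format of
angiographic workstations) with fan triangulation; STL (ASCII and
binary); legacy VTK and XML VTU. `fit_cross_sections()` inverts surface
meshes into the canonical representation by sweeping cutting planes along
a smoothed centroid path and representing each cut by its
equivalent-area circle, `r = sqrt(A/pi)`; branched surfaces (more than
two boundary loops) are rejected, consistent with the single-lumen scope.

## Hemodynamics

Blood is Newtonian with density 1056 kg/m^3 and viscosity 3.5e-3 Pa s —
standard hemodynamic values, configurable. Flow is steady and laminar in
a rigid lumen; a Reynolds-number guard warns above 2000. The inlet is
held at the mean proximal (aortic) pressure (default 93 mmHg;
1 mmHg = 133.322 Pa); the outlet is coupled to a lumped distal
resistance of 8.721e9 Pa s m^-3 — the generic population-average
myocardial resistance used when no invasive distal measurement is
available — with a venous reference of 0 Pa, the usual FFR convention.
vFFR between two marks is the ratio of section-averaged absolute
pressures at those arc lengths.

**Reduced-order backend.** Each inter-station segment contributes a local
Poiseuille resistance `8*mu*ds/(pi*rbar^4)`; each maximal expansion run
(from a local area minimum to its downstream recovery) adds a
Borda-Carnot separation loss `0.5*rho*Q^2*(1/A_min - 1/A_down)^2`,
distributed within the run so the pressure profile stays monotone. The
flow rate solves the lumped balance
`P_in - P_v = dP_vessel(Q) + Q*R_distal` by a monotone root-find to 1e-10
relative. This backend is exact against closed forms on uniform tubes
and costs microseconds, which is what makes the exhaustive tandem
enumeration and the property-test suites affordable.

**3D finite-volume backend.** A colocated cell-centered finite-volume
discretization of the steady incompressible Navier-Stokes equations in
conservation form: first-order upwind convection, central diffusion with
deferred non-orthogonality correction, Green-Gauss gradients, SIMPLE
pressure-velocity coupling with Rhie-Chow face interpolation
(under-relaxation 0.7 momentum / 0.3 pressure), no-slip walls, and
fixed-pressure inlet/outlet with zero-gradient velocity. At an inflowing
pressure boundary the convected momentum is taken from the face-normal
velocity implied by the face mass flux; convecting the cell's own
velocity there is a positive feedback that destabilizes the inlet.

One numerical choice deserves emphasis. Splitting the thin inflation-layer
prisms into tetrahedra produces flat cells whose shared faces are nearly
parallel to the line joining the cell centroids — a geometry on which
cell-centered diffusion operators are unstable no matter how the
non-orthogonal correction is decomposed. The solver therefore
agglomerates the three tetrahedra of each swept prism back into a single
prismatic control volume (faces remain the triangulated tet faces, and
fluxes are summed per triangle, so the scheme stays strictly
conservative). This is the same spirit as element-based/vertex-centered
finite-volume codes, which assemble polyhedral control volumes from
element sectors; the tetrahedral mesh itself is unchanged and is what
gets exported.

The outlet resistance is enforced by an outer Newton/secant iteration on
the outlet pressure: `g(P_out) = P_v + Q(P_out)*R - P_out = 0`. A plain
relaxed fixed-point iteration is *divergent* in the coronary regime —
the loop gain is about `R_distal/R_vessel`, 30-100 here — while the
secant, initialized from a Poiseuille estimate built from the mesh's
slab-equivalent radii, converges in 2-4 steps, each warm-started from
the previous fields. Convergence demands all self-scaled momentum and
continuity residuals below 1e-6 (under our L1 normalization this
corresponds to conventional engineering residuals near 1e-4; looser
settings let the flow rate creep by ~0.2% per restart) and the outlet
relation satisfied to 1e-3 relative to the inlet pressure. The inner
pressure-correction system is solved by Jacobi-preconditioned conjugate
gradients to 5% per outer pass — tighter inner solves waste time SIMPLE
discards on the next re-assembly.

Verification anchors (all recomputed by the test suite and the
acceptance script): on a uniform tube the reduced backend reproduces
`vFFR = R_distal/(R_v + R_distal)` to 1e-8; on a 150 mm straight tube at
the ~50k-tetrahedron desk mesh the 3D fully developed pressure gradient
matches `8*mu*Q/(pi*r^4)` within 5% (measured over s = 60-140 mm, past
the entrance length of ~32 mm at Re ~ 180); the two backends agree
within 10% on vFFR for smooth moderate stenoses; and the computed
outlet pressure over flow equals the prescribed 8.721e9 Pa s m^-3
essentially exactly.

## Tandem lesions and statistics

With serial stenoses, wire pullback cannot apportion the aggregate
pressure loss: the downstream lesion caps hyperemic flow, so the proximal
lesion's significance is underestimated. `tandem_analysis()` virtually
removes each stenosis in turn — and every combination: the untreated
baseline plus all `2^n - 1` stented subsets (capped at n = 6, i.e. 63
solves, unless explicitly overridden), reporting the distal vFFR of each
strategy in a deterministic order. Monotonicity (adding a stent never
lowers distal vFFR) is tested exhaustively on two- and three-lesion
vessels.

The agreement statistics follow the conventions of clinical FFR
validation: Bland-Altman bias with limits of agreement at bias +/- 2
sample standard deviations (2 SD, not 1.96 SD, per the convention this
workflow reports); diagnostic accuracy against the 0.80 threshold with
the positive (ischemic) class defined as measured FFR <= 0.80 — the
boundary value is positive — and zero-denominator ratios reported as
flagged `NA`, never silently 0; Pearson correlation plus a least-squares
line through the origin. The test suite pins these to hand-computed
values, including the confusion matrix (TP 46, FN 4, TN 7, FP 0) whose
derived metrics are sensitivity 92%, specificity 100%, PPV 100%, NPV
64%, accuracy 93%.

## Worked example

```{r example}
# a 3 mm vessel with a 58% focal stenosis
vessel <- make_synthetic_vessel(50, 1.5,
  stenoses = list(stenosis_spec(s_center = 25, length = 20, severity = 0.58)))
pre <- compute_vffr(solve_reduced(vessel), 0, 50)
pre

# deploy a 3.0 x 20 mm virtual stent over the lesion
stented <- deploy_stent(vessel, stent_spec(20, 40, 3.0))
post <- compute_vffr(solve_reduced(stented), 0, 50)
post
```

```{r tandem}
two <- make_synthetic_vessel(60, 1.6, list(
  stenosis_spec(18, 10, 0.62), stenosis_spec(42, 10, 0.55)))
tandem_analysis(two, list(stent_spec(12, 24, 3.2), stent_spec(36, 48, 3.2)))
```

## Problem sizes, limitations, and scope

The package's default problem sizes are deliberate: desk-scale volume
meshes of roughly 20k-55k tetrahedra resolve the radial profile well
enough for percent-level pressure-gradient accuracy while a full solve
stays in the tens of seconds to low minutes on one core; the reduced
backend handles everything combinatorial. The canonical ~1M-tetrahedron
resolution of the clinical workflow is reachable through the meshing
parameters when higher fidelity is wanted.

Known limitations: steady flow only (no pulsatility), rigid walls (no
fluid-structure interaction), Newtonian rheology, single lumen without
side branches (which biases computed pressure drops upward), an
idealized stent (no malapposition, recoil, or strut geometry), a generic
rather than personalized distal resistance, and first-order convection
in the 3D scheme (diffusion-dominated at coronary Reynolds numbers, but
a limiter on accuracy in strongly separated flow). The clinical
validation statistics this workflow is known for are properties of a
patient cohort; nothing here recomputes them from images — the
statistics module computes the estimators themselves, verified on
constructed inputs.
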