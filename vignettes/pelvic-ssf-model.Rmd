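---
title: "A finite-element model of posterior sacrospinous fixation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A finite-element model of posterior sacrospinous fixation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Pelvic organ prolapse (POP) is excessive mobility of the bladder, vaginal
apex or rectum caused by failure of their ligamentous and fascial support.
Posterior sacrospinous ligament fixation (SSF) repairs an apical prolapse
by suturing the vaginal vault to the sacrospinous ligament, classically
unilaterally, about 2 cm medial to the ischial spine. Two surgical
questions are open: whether bilateral fixation supports the apex better
than unilateral, and whether the anchorage distance from the ischial spine
(1-3 cm) matters. `pelvifem` implements a quasi-static finite-element
pipeline to compare these configurations on a parametric synthetic pelvis:
organ mobility is quantified by the pubococcygeal-line (PCL) method, the
straining load is calibrated so the pre-operative model reproduces
imaging-derived reference-point displacements, and the surgical variants
are then solved under that identical, frozen load.

## The model

### Synthetic geometry

Patient imaging is not available, so `build_pelvic_geometry()` generates a
procedural stand-in that preserves the topology, attachment pattern and
landmark relations the mechanics depend on. Coordinates are in
millimetres: x lateral (patient-right positive), y anterior, z superior,
midsagittal plane at x = 0. The default dimensions are representative
adult female pelvimetry and are parameters, not claims about any patient:
PCL length 100 mm, inter-spine width 100 mm, sacrospinous ligament length
45 mm.

* bladder: closed ellipsoid shell (24 x 19 x 14 mm semi-axes);
* vagina: flattened tube (13 x 6 mm section) with a domed closed apex —
  the post-hysterectomy vault; the apical reference point C is the vault;
* rectum: curved circular tube (13 mm radius); the posterior reference
  point Bp sits on the anterior wall at the anorectal bend;
* pelvic floor: basin-shaped membrane spanning an elliptical bony rim,
  sagging 15 mm below it, clamped at the rim (Encastre);
* pubocervical and endopelvic fasciae: cambered membrane sheets between
  bladder/vagina and vagina/rectum respectively;
* ligaments: sacrospinous (spine to sacral insertion, both ends on bone),
  uterosacral, cardinal, round, broad and the arcus tendineus (ATFP), as
  tension-dominant truss members.

Two construction choices deserve emphasis because they shape the model's
statics. First, the fascial septa insert on the vaginal *walls*, not the
vault: the apex hangs on the uterosacral/cardinal complex alone, which is
what makes an apical support defect (and its repair) mechanically
meaningful. Second, the rectovaginal (endopelvic) tether links are given a
very low modulus (2e-4 MPa): the rectovaginal space is loose areolar
tissue, and in a stage-III apical prolapse the septal attachment is
defective. With a condensed-fascia stiffness there the rectal straining
load would drag the apex caudally almost rigidly and no positive pair of
load magnitudes could produce the observed pattern of a large posterior
displacement with a moderate apical one; with the areolar value the
pre-operative displacement pattern is statically reachable.

The *pathological* support condition disables the broad and round
ligaments (`apply_support_condition()`), the apical support defect that
produces prolapse-range mobility. The generic variant is strictly
mirror-symmetric; a seeded `asymmetry_amplitude` perturbs the right-side
landmarks and shifts the bladder laterally to emulate a patient-like
asymmetric pelvis.

### Elements and materials

All organ walls are constant-strain membrane triangles. The hollow organs
are two-term Yeoh hyperelastic solids, W(I1) = C0 (I1 - 3) + C1 (I1 - 3)^2,
under the incompressible plane-stress reduction (thickness stretch
1/(lambda1 lambda2)); the printed coefficient sets are vagina 0.111/0.27,
bladder 0.0375/0.07, rectum 0.085/0.056 MPa. The pelvic floor (E 0.1 MPa)
and fasciae (E 0.18 MPa) are St. Venant-Kirchhoff plane-stress membranes
with nu 0.45. Membrane thicknesses default to 3 mm for organs, 2 mm for
the floor and 1 mm for fasciae; all values are configuration-exposed.

A pure membrane has no bending stiffness, so in-plane compression is a
true instability: wrinkles have no length scale, the tangent is
indefinite, and the discrete equilibrium problem is ill-posed (we observed
mesh-pinned checkerboard modes that defeat both Newton and quasi-Newton
minimisation). The organs here are thin *shells*, so each interior mesh
edge carries a discrete-hinge bending energy `ce (theta - theta0)^2` with
the physical plate modulus kb = E t^3 / (12 (1 - nu^2)) (for Yeoh
materials the small-strain modulus 6 C0 and nu = 1/2). Reference dihedral
angles make the rest shape stress-free. This replaces the earlier
membrane-only design: bending is not a numerical trick but the missing
piece of shell physics, and it restores quadratic Newton convergence. A
tension-field (wrinkling-relaxed) membrane energy remains available
(`membrane_stabilization < 1` in `fe_model()`), but the full biaxial law
is the default.

Ligaments, fascia links and sutures are truss filaments. Connective-tissue
strands buckle rather than push, so ligaments and links are
tension-dominant: compression retains a factor 1e-3 of the tensile
stiffness, and the slack/taut transition is smoothed over a +-0.1% strain
band with a C1 cubic blend (the raw kink, with tensile/slack stiffness
ratios of 1000, makes Newton chatter; outside the band both branches are
exact). The *suture* is deliberately two-way: the operation note describes
a tightened tie, and the source model implements the fixation as a tie
constraint, which restrains the apex in both directions. A tension-only
suture would be mechanically inert here, because apical descent shortens
the apex-anchor distance. Suture defaults: E 1000 MPa, section 0.2 mm^2,
two filaments per side attached to distinct vault nodes 5 mm apart,
reference length equal to the tied (gap-closed) rest distance
(configurable pre-tension defaults to zero).

Inter-organ contact is not modelled; the fascia membranes plus the
distributed links carry the "no direct contact, fascia in between" load
path deterministically.

### Solver

`solve_quasi_static()` performs incremental dead loading with a quadratic
ramp of (by default) 10 increments — the unstressed structure is soft, so
early increments are small — and damped Newton iterations per increment:
analytic element internal forces (verified to be the exact gradient of the
total potential energy), element tangents by central differencing of those
forces, sparse LDL' factorisation (LDL' succeeds on indefinite matrices;
definiteness is checked on the D diagonal), a Levenberg diagonal shift
escalated whenever the tangent is not positive definite or the direction
is not a descent direction, an Armijo line search on the total potential
energy with bounded step expansion, and load-step bisection (at most 5)
on divergence. The Newton tolerance is an absolute residual norm of
1e-6 N with at most 60 iterations per increment. When a starting state is
supplied (continuation across the surgery matrix, calibration re-solves,
mesh refinement), a direct full-load Newton solve is attempted first and
the incremental schedule is the fallback; a state interpolated from
another mesh can additionally be pre-smoothed by limited-memory BFGS
iterations on the energy before Newton takes over, which removes the
mesh-scale interpolation artifacts.

Converged states satisfy global equilibrium: the reaction forces at the
fixed sets balance the applied traction resultants to well below 1e-6 N,
and fixed-set displacements are exactly zero. Tie constraints
(`apply_tie_links()`) merge displacement degrees of freedom exactly by
master-slave elimination.

### Boundary conditions and loads

The pelvic floor rim, the sacral/coccygeal ligament insertions, the
ischial spines, the pubic attachments of the pubocervical fascia and the
distal ligament ends are fully fixed (Encastre). Straining is modelled by
surface tractions (dead loads, MPa on the reference areas): on the upper
vaginal surface directed caudally, on the bladder dome at 45 degrees
anteroposteriorly, and on the rectal wall band just above the anorectal
junction directed caudally. The maximal-strain state is the final
converged load step — the only state a quasi-static model has.

### Load calibration

The straining magnitudes are unknown; `calibrate_loads()` reproduces the
empirical procedure of increasing the loads until the simulated
reference-point displacements match imaging-derived setpoints. Each driven
load is a damped secant root-find (with bracket/bisection fallback) on the
scalar map magnitude -> achieved PCL displacement; the weak coupling
between loads is handled by outer fixed-point sweeps (at most 5).
Monotonicity of the response is checked over the sampled points, not
assumed. The default setpoints are the pre-operative middle- and
posterior-compartment displacements, C = 7 mm (vaginal traction) and
Bp = 6 mm (rectal traction), matched to 0.1 mm. The anterior point Ba is
reported passively and is not driven: a large, laterally asymmetric
bladder displacement is exactly the case the PCL method cannot grade, and
`measure_descent()` flags Ba as not-evaluable whenever its out-of-plane
displacement exceeds half of its total displacement. The undriven bladder
traction is held at a small fixed default (2e-4 MPa).

### The study pipeline

`run_study()` executes the whole comparison: build geometry, mesh,
calibrate on the no-surgery pathological model, then solve the surgery
matrix — none / left / right / bilateral at the 2 cm anchor plus the 1 cm
and 3 cm variants — with the calibrated loads frozen, so that descent
differences are attributable to the repair alone. Converged states are
reused as starting guesses across the anchor grid of each side set
(continuation). Reports are written as CSV and JSON, per-configuration
VTK snapshots and STL surfaces are exported, and a manifest records the
configuration hash, seed and artifact checksums; reruns with the same
configuration are bit-identical.

```{r}
library(pelvifem)
study <- run_study(validate_config(list(output = list(dir = "out"))))
study$report
ggplot2::autoplot(study$report)
```

## Verification

The test suite checks, among others:

* constitutive patch tests: single-element uniaxial and equibiaxial Yeoh
  membrane states against the closed forms (for the uniaxial state,
  sigma = 2 (lambda^2 - 1/lambda)(C0 + 2 C1 (I1 - 3))) to 1e-4 relative,
  for all three printed coefficient sets;
* energy-gradient consistency of the residual on random small meshes
  (1e-5 relative), objectivity under random rotations (1e-6 mm), and
  global force balance (1e-6 N);
* a pressurized flat circular membrane against the classical series
  solution for the centre deflection (within 5%);
* calibration parameter recovery: magnitudes that generated synthetic
  setpoints are recovered within 1% from perturbed initial guesses;
* the qualitative surgical pattern on the default geometry: bilateral
  fixation reduces apical descent more than unilateral, left and right
  unilateral fixation agree on the symmetric pelvis, and the anchorage
  distance changes the apical descent by less than adding the second
  side;
* robustness: halving the target edge length changes the apical descent
  by less than 5%, and a tenfold suture stiffness changes the reference
  (left unilateral) repair's apical descent by less than 2%. The bilateral
  repair's own descent is much smaller, so its relative sensitivity is
  larger (about 5%, i.e. under a tenth of a millimetre in absolute terms);
  the suite bounds it in absolute terms instead.

## Numerical choices and degenerate inputs

* Newton tolerance 1e-6 N absolute; load ramp (k/10)^2; at most 60
  iterations per increment and 5 bisections per solve.
* The tangent is a central finite difference of the analytic forces
  (step 1e-6 x characteristic length); Newton directions are accepted
  only if they are descent directions for the energy.
* Flat membranes have zero transverse stiffness at zero strain; the
  generator avoids flat regions (domed caps, cambered sheets), and
  verification problems on flat patches supply a small initial
  out-of-plane state.
* Element inversion shows up as a non-finite energy; the line search
  rejects such steps and the load step is bisected rather than crashing.
* Zero-area triangles, zero-length trusses, non-positive thicknesses and
  out-of-range material constants are rejected at validation time.
* An anchor distance beyond the ligament arc length is an error
  (anatomically impossible placement).

## What the synthetic generator does and does not show

The generator emulates the *pre-operative state* the study needs: a
midsagittally symmetric pelvis with a closed vaginal vault, weakened
apical support, and calibrated compartment mobilities. It does not
reproduce any patient's organ shapes, the printed post-operative
displacement magnitudes (which depend on undeposited imaging-derived
geometry), bladder filling, levator muscle activity, frictional organ
contact, or anisotropic fibrous tissue behaviour. Passing tests therefore
demonstrate that the method — solver, calibration, surgery construction,
PCL readout — behaves correctly and that the qualitative surgical
comparisons are robust on a defensible anatomy; they are not evidence
about any individual patient.

Known limitations worth stating plainly: unilateral configurations at the
shortest (1 cm) anchor are close to a lateral snap of the vault around the
single anchor and may need the continuation path across the anchor grid to
converge; residual nearest-node tie-breaks in the link construction leave
a sub-0.1 mm left/right asymmetry in an otherwise symmetric mesh; the
rectovaginal tether is modelled as loose areolar tissue (a stage-III
apical prolapse with a defective septal attachment), which is what makes
the printed pre-operative pattern of a moderate apical and posterior
displacement statically reachable with positive loads; and the calibrated
magnitudes are effective loads for this geometry, not estimates of
intra-abdominal pressure.

## Problem sizes

The default desk-scale mesh targets a 4 mm edge length, about 5500
membrane triangles, 450 truss filaments and 8000 free degrees of freedom
(2000-12000 elements across the configurable range); the robustness check
refines to 2 mm (about 4x the elements). Distributed link families carry
fixed total cross-sections divided over the links created, and ligament
attachments are kinematic ties, so the support stiffness is independent of
the mesh resolution. A full default study (calibration plus eight surgical
configurations) runs in minutes on one CPU; the refined-mesh robustness
check is the single most expensive computation (on the order of ten
minutes).
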