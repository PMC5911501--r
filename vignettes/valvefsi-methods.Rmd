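---
title: "Unified-continuum ALE finite elements for aortic-valve FSI: model and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unified-continuum ALE finite elements for aortic-valve FSI: model and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(valvefsi)
```

## The model

`valvefsi` simulates the interaction of blood flow with native and
mechanical aortic valve leaflets as a **single incompressible continuum**.
One set of conservation laws is written over the whole moving domain
$\Omega^t$ (fluid plus solid),

$$\rho\,(\dot u + ((u - m)\cdot\nabla)u) = \nabla\cdot\tau, \qquad
  \nabla\cdot u = 0,$$

in Arbitrary Lagrangian–Eulerian (ALE) form: $u$ is the fluid velocity in
the fluid and the material velocity in the solid, and $m$ is the mesh
velocity — the material velocity inside the solid, and a smoothed extension
in the fluid.  A binary per-cell phase function $\theta$ selects the
constitutive stress,

$$\tau = \tau^D - p\,I,\qquad
  \tau^D = \theta\,\tau_f + (1-\theta)\,\tau_s,\qquad
  \tau_f = 2\mu_f\,\varepsilon(u),$$

with $\varepsilon(u) = \tfrac12(\nabla u + \nabla u^\top)$.  The solid is an
incompressible neo-Hookean material carried in **rate form**: the solid
stress evolves by the upper-convected rate driven by the strain rate,

$$D_t \tau_s = 2\mu_s\,\varepsilon(u) + \nabla u\,\tau_s + \tau_s\nabla u^\top ,$$

with incompressibility enforced by the shared continuity equation — there is
no separate strain-energy implementation.  Because velocity is continuous
across the interface, the kinematic coupling condition is satisfied by
construction; the dynamic condition is enforced weakly by dropping the
boundary stress term after integration by parts.  Monolithic coupling of
this kind has no added-mass instability: fluid and solid unknowns are solved
in one system.

Default material constants are blood density $\rho_f = 1060$ kg/m³ and
viscosity $\mu_f = 0.0027$ Pa·s, solid density $\rho_s = 1000$ kg/m³, and
leaflet shear moduli $\mu_s = 3.3\times10^9$ Pa (native valve) or
$6.5\times10^{11}$ Pa (mechanical valve leaflets).  The solid stiffnesses
are *working values* for capturing flow and valve kinematics, not measured
tissue moduli; configurations may override them (the desk-scale 2D
demonstration uses a much softer strip so that it flexes at channel scale).

### Which density enters the momentum equation?

The sources list both 1060 kg/m³ (blood) and 1000 kg/m³ (solid).  We use
the **per-phase density per cell** — $\rho_f$ on fluid cells, $\rho_s$ on
solid cells — which is the natural reading of a unified continuum with
per-cell material selection.  With a 6 % density contrast the choice is
far below every tolerance used in the tests.

## Discretization

Space: continuous piecewise-linear (P1) velocity **and** pressure on
simplices (triangles/tetrahedra).  Time: midpoint (Crank–Nicolson) over
each slab $(t^{n-1}, t^n]$ with $\bar U = \tfrac12(U^n + U^{n-1})$, the
pressure piecewise constant in time.  Equal-order P1–P1 pairs are not
inf–sup stable and the flow is convection dominated, so a simplified
Galerkin/least-squares term is added in which the time derivative and the
(elementwise zero) diffusion term are dropped from the strong residual:

$$SD_\delta = \big(\delta_1\rho\,[ (a\cdot\nabla)\bar U + \nabla P - f],\,
  \rho\,(a\cdot\nabla)v + \nabla q\big) + (\delta_2\,\nabla\cdot\bar U,\ \nabla\cdot v),$$

with $a = \bar U - M$ the frozen relative advection velocity and, per cell,

$$\delta_1 = \kappa_1\rho^{-1}\big(k^{-2} + |U^{n-1}-M^{n-1}|^2 h^{-2}\big)^{-1/2},
  \qquad \delta_2 = \kappa_2\,\rho\,h\,|U^{n-1}|.$$

$\kappa_1 = \kappa_2 = 1$ by default ("order one" constants, exposed in the
configuration).  The manufactured-solution hook $f$ exists purely for
verification and is included in the stabilization residual so that forced
test problems remain consistent; the physical model has $f = 0$.

Each step performs a **Picard iteration**: the advection velocity and the
rotational part of the solid stress rate are frozen at the previous iterate,
making the system linear in $(U^n, P^n)$; iteration continues until the
relative velocity update falls below $10^{-6}$ (at most 50 sweeps).
Failure to converge rejects the step and halves the Courant target.  The
implicit part of the solid stress, $k\,\mu_s\,\varepsilon(\bar U)$, is
assembled like a viscous term, which is what renders the solid stable at
large $\mu_s\,k$; the rotational terms and the previous stress enter the
right-hand side.  After convergence the per-cell stress is advanced
explicitly with the converged midpoint gradient (P1 velocity means one
quadrature point is exact), then symmetrized.

**Linear solver.** Bi-CGStab with diagonal (Jacobi) preconditioning is
provided and exercised in the tests; the default for production stepping is
a sparse LU factorization, which at desk scale (10³–10⁴ unknowns) is both
faster and unconditionally robust on the stabilized saddle-point system.
Any method must meet the contract $\|b - Ax\| \le \text{tol}\,\|b\|$.

**Boundary conditions.** The inlet carries a flat (uniform) velocity
profile of the waveform magnitude; walls are no-slip.  At the outlet the
homogeneous pressure condition is imposed **weakly**: dropping the boundary
stress term leaves zero traction, which pins the pressure level at the
outlet without constraining nodal values.  We found the strong nodal
$P = 0$ variant to destabilize the open boundary at blood-like Reynolds
numbers, and during the end-systolic reversal the outlet genuinely becomes
an inflow boundary — the standard remedy, included here, is **backflow
stabilization**: a penalty $\rho\,(u\cdot n)_-\,(\bar U, v)$ on outlet
facets where flow re-enters.

**Time-step control.** $dt = C\,\min_K h_K / \max(|U-M|_K)$ with target
Courant number $C = 0.5$; rejected steps (Picard failure, cell inversion,
or quality beyond the abort threshold) halve $C$ down to a floor of 0.01 —
the regime needed only during the sensitive phase of large, fast leaflet
deformation — and $C$ doubles back after ten accepted steps.  Quiescent
flow is capped at `dt_max`.

## Mesh motion

Every step, the mesh velocity is the material velocity on solid vertices
and the componentwise harmonic (Poisson) extension of the interface
velocity over the fluid region, with $M = 0$ on inlet/outlet/walls; then
$x \leftarrow x + dt\,M$.  When the worst cell quality

$$Q(K) = \frac{\|F\|_F^2}{d\,\det(F)^{2/d}} \ \ge 1$$

($F$ the deformation gradient from a measure-matched equilateral reference
simplex; $Q = 1$ exactly for equilateral cells, scale- and rotation-
invariant) exceeds a trigger (default 8), a **nonlinear quality-weighted
smoother** relaxes the interior fluid vertices by gradient descent on

$$E = \sum_K Q(F_K)\, W(F_K), \qquad
  W(F) = \tfrac12(\|F\|^2_F/d - 1) + \tfrac12(\det F - 1)^2,$$

a compressible neo-Hookean-style density weighted by the quality measure so
stiffness concentrates on the worst cells.  The reference simplices are
pinned to the cell measures at entry.  Pseudo time steps that would invert
a cell or increase $Q_{\max}$ are rejected with a halved pseudo step, so
the committed mesh never contains an inverted cell and $Q_{\max}$ is
non-increasing — these two properties, not the particular form of $W$, are
what the scheme relies on, and they are what the test suite asserts.  The
smoother runs for at most `pseudo_steps` (default 5) pseudo steps per call;
no remeshing (topology change) is ever performed.

## Valve contact

Collision is detected from the minimal distance $d_{\min}$ between leaflet
surfaces, computed either exactly (minimum point-to-facet distance; also
the test oracle) or from an **Eikonal distance field** $|\nabla\phi| = 1$
solved on the mesh by Hopf–Lax fixed-point iteration (edge and in-cell
two-point updates, iterated to stationarity).  The discrete field is an
upper bound on the true distance and agrees with it within two cell
diameters on the test fixtures; we chose this scheme over a stabilized
linear fixed-point form because the lower-bound property comes for free
and the iteration is unconditionally convergent.

A closure surface — a layer of interior facets spanning the whole orifice —
is embedded in the mesh by the geometry generators.  When
$d_{\min}$ drops below the contact threshold, **every fluid cell directly
attached under the closure surface (one upstream layer) switches phase
$1 \to 0$ in a single step**: the whole orifice closes at once, acceptable
because the closing moment of a healthy valve is very short.  Cell count
and topology never change.  The switched cells start with zero solid
stress.  At the start of the next systole the switched cells revert to
fluid and their stress is zeroed, restoring the pre-closure phase field
exactly.  The default threshold is twice the smallest cell diameter
adjacent to the leaflets, overridable in absolute units.

For the bileaflet mechanical valve, each rigid leaflet rotates about a
hinge axis fixed by two edge points.  The rotation angle $\alpha$ is the
radius-weighted circular mean of the leaflet vertices' angular positions
about the axis, relative to the closed-position direction (exact for rigid
rotations).  Locks engage at $\alpha_{\max}$ (45° by default) and
$\alpha_{\text{closed}}$; release rules are evaluated *before* lock rules
each step (no oscillation within a step): an open-locked leaflet releases
when the mean pressure above the valve exceeds the mean pressure below,
and a closed-locked leaflet releases when a new heart cycle starts.

## Cardiac cycle and pre-stress

One cycle lasts 1.124 s: a forward systolic pulse, a short reversal lobe,
then diastole with zero inflow (the closed valve holds the domain).  The
left-ventricular outflow history behind the waveform is not tabulated
anywhere, so the default is a deliberate, simple interpretation: a half
sine of peak 1.0 m/s over 0.4 s, then a negative half sine of magnitude
0.2 m/s over 0.05 s — the duration of the reversal matches the "small
amount of reversed flow" that completes closure.  All five numbers are
configuration values; this waveform is the largest numerical gap between
the published setup and what can be reproduced from it.

The native-valve simulation starts from a **pre-stressed configuration**:
a compressive radial stress $-\sigma_r\,e_r\otimes e_r$ ($\sigma_r = 4$ Pa)
is prescribed in the leaflet cells — the material behaves like a stretched,
contracting balloon, whose wall tension produces an inward body force in a
curved shell — and the leaflet vertices are relaxed pseudo-dynamically
(damped Jacobi iteration of the linear elastic balance, attachment held
fixed) until the per-step displacement stalls.  The deformed coordinates
become the initial mesh and the stress is reset to zero.  The magnitude of
the response is set by the relaxation modulus `mu_relax`, a numerical
parameter; the *direction* (free edges inward, monotone in $\sigma_r$) is
the physically meaningful, tested property.

## Geometry generators

No external mesher is required: all three generators build structured
simplicial meshes procedurally.  A triangulated disk (centre vertex plus
rings, angular count a multiple of three) is extruded level by level into
prisms; each prism splits into three tetrahedra by the minimal-vertex-index
rule, so adjacent prisms always agree on shared faces and the mesh is
conforming and watertight by construction.

* **Aortic root** (`generate_aortic_root`): annulus plane at $z=0$ with
  inner radius $R_A = 20$ mm, sinotubular junction at $z = h_l = 20$ mm
  with $R_S = 22$ mm, a fixed sinus-of-Valsalva bulge profile (scaled to
  the root, not a free parameter) between them, and an ascending-aorta
  cylinder on top.  The three leaflets are one-cell shells tagged along
  the truncated cone defined by $R_A, R_S, h_l$; the free edge dips from
  the commissures ($z = h_l$, at the sector boundaries) to a flat belly at
  the commissure height $h_c = 6$ mm spanning the opening angle $\beta$
  about each sector centre.  The exact cutting-plane construction is only
  pictorial in the source material; this piecewise-linear free-edge profile
  is our documented interpretation, chosen so the measured leaflet height
  and both rim radii equal their parameters exactly.  Membership decisions
  are made per *prism* with thresholds offset off the coordinate lattice,
  which keeps the three leaflet vertex sets bitwise symmetric under 120°
  rotation.  The closure surface is the disk of interior horizontal facets
  at $z = h_c$ inside the leaflet shells.  Leaflets are tagged cell sets,
  not CAD-fitted surfaces: at desk scale this preserves everything the
  model consumes (tags, attachment, closure surface, radii) at the cost of
  stair-stepped leaflet surfaces.

* **BMHV** (`generate_bmhv`): a straight tube with two semicircular-disc
  leaflets tagged as slabs about planes rotated from the closed
  (cross-sectional) plane about hinge axes fixed by two edge points each;
  the geometry guarantees the leaflets never touch.  Hinge points, angle
  limits (45° maximal opening) and closed-reference directions are stored
  in mesh metadata.

* **2D valve channel** (`generate_2d_valve_channel`): the desk-scale
  fixture — a rectangular channel with one or two flexible leaflet strips
  conforming to grid lines and a closure line of interior facets across
  the full cross-section at the resting tip station.  An optional resting
  tilt pre-bends the strips toward the outlet by a smooth incremental
  deformation (each increment harmonically extended into the fluid and
  relaxed by the nonlinear smoother); the tilted state is stress-free.

## The 2D demonstration and what it shows

`make_flapping_leaflet_2d()` packages the end-to-end study: a
60 × 20 mm channel (~1.1 k triangles at 1.6 mm), two 9 mm leaflet strips
resting 30° open, soft modulus (8 kPa) so the strips flex at channel
scale, peak inflow 0.32 m/s with a 0.6-fraction reversal lobe, and a
contact threshold of 4.2 mm — just below the 4.4 mm resting tip gap, which
the trace never undercuts before the closing sweep because the tilted rest
position only opens under forward flow.  Over one 1.124 s cycle the
orifice trace reproduces the four classic phases: rapid opening under the
accelerating jet, a quasi-steady open phase (GOA ≈ 1.5× its resting
value), gradual closure while the flow still moves forward, and rapid
closure completed by the reversal (contact at t ≈ 0.43 s), after which the
switched orifice cells hold GOA = 0 until the next cycle start releases
them.  No remeshing occurs and the worst cell quality stays below 6.

The resting tilt is load-bearing: with upright resting strips the elastic
recoil returns the tips to their rest gap with only a ~1 % overshoot, so
no contact threshold can separate "closing" from "at rest" robustly.  A
partially open rest position — the analogue of the pre-stressed native
starting configuration — gives the reversal a long arc to sweep through
and a closure signal two orders of magnitude above the flutter amplitude.

What the desk-scale fixture does *not* show: three-dimensional coaptation
geometry, sinus vortex dynamics, physiological Reynolds numbers at
production resolution, or clinically meaningful stresses (the moduli are
soft on purpose).  It exercises every algorithm of the production pipeline
— monolithic phase-blended assembly, ALE transport, both smoothers,
contact switching and release, CFL adaptation, post-processing — under
conditions where each behaviour can be asserted quantitatively.

## Verification

The test suite builds everything it needs programmatically:

* **Quality measure**: $Q = 1$ on equilateral simplices; $Q \ge 1$ and
  scale/rotation invariance on thousands of random simplices (AM–GM
  equality case).
* **Solid stress**: the explicit update under constant simple shear agrees
  with a high-order ODE integration (deSolve) to $10^{-6}$ relative over
  $10^3$ steps, and converges at first order.
* **Solver**: plane Couette flow is an exact discrete steady state (linear
  profile representable in P1) and is recovered from rest to $10^{-8}$;
  uniform flow with $M = U$ gives an assembled residual below $10^{-10}$
  (free-stream preservation, also checked as Galilean invariance over
  moving-mesh steps); a steady Taylor–Green manufactured solution (forcing
  included in the GLS residual) converges in L2 with error ratio
  $\ge 2$ per mesh halving over three uniform refinements.  The
  manufactured problem uses $\mu_f = 0.01$ Pa·s — the advection-dominated
  regime this stabilization is designed for; at large viscosity the known
  P1-GLS inconsistency (the dropped diffusion residual) dominates and the
  observed order decays toward one.
* **Smoothers**: harmonic extension is exact for constants and 1D linear
  profiles; the nonlinear smoother never commits an inverted cell and
  $Q_{\max}$ is non-increasing across pseudo steps on perturbed patches.
* **Contact**: Eikonal vs. geometric distances agree within $2h$ with the
  geometric value as a lower bound; close/release round-trips restore the
  phase field exactly and are cyclically reproducible; GOA is zero exactly
  when closed.
* **Post-processing**: $\lambda_2 = -|\omega|^2$ for rigid rotation (from
  the middle eigenvalue of $S^2 + \Omega^2$), Galilean invariance of
  $\lambda_2$; von Mises stress vanishes for pure pressure and equals
  $\sqrt2\,|s|$ for pure shear $s$.

Problem sizes are chosen for single-CPU verification: the unit-square
refinement study runs 8², 16², 32² meshes; the root generator is tested at
5 mm resolution and run at its 2.5 mm default only in the acceptance
script; the 2D cycle uses ~1.4 mm cells (about 1.4 k triangles).

## Known limitations

* Leaflets in the 3D generators are tagged cell shells, one cell thick at
  default resolution: stair-stepped surfaces, thickness tied to the local
  cell size when `t_l` is smaller than a cell.
* The contact model closes one upstream cell layer under the closure
  surface; the full-pocket flood-fill variant is not implemented.
* The nonlinear smoother cannot improve cells whose vertices all lie on
  the interface or boundary; during extreme deformation the driver falls
  back to Courant reduction, and a cycle can still abort if the floor is
  reached (reported with diagnostics and the partial time series).
* Pressure is piecewise constant in time, so its temporal accuracy is
  first order even though velocity is second order.
* The production-scale results (hundreds of thousands of vertices,
  MPI parallelism, patient-specific inflow) are out of scope; all claims
  here are desk-scale.
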