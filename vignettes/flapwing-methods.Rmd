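---
title: "Methods: synthetic wing kinematics, immersed-boundary flow solution and aerodynamic post-processing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic wing kinematics, immersed-boundary flow solution and aerodynamic post-processing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`flapwing` is a self-contained pipeline for studying the aerodynamics of
hummingbird fast forward flight: it generates synthetic wing-marker
kinematics with the structure measured for a calliope hummingbird
(*Selasphorus calliope*) flying at 8.3 m s⁻¹, reconstructs time-resolved
triangulated wing surfaces from those markers, computes the standard
kinematic descriptors, solves the incompressible Navier–Stokes equations
around the flapping wings and body with a sharp-interface immersed-boundary
method, and post-processes surface tractions into lift, thrust and power
coefficients and derived flight-performance numbers.  This vignette records
the models, the tunable parameters and their defaults, the numerical
choices, and the limits of what the desk-scale verification can show.

## The flight problem and reference configuration

The subject is steady fast forward flight at advance ratio near one: the
bird flies at $U = 8.3$ m s⁻¹ while its mean wingtip speed (in the
bird-fixed frame) is close to the same value, placing it between the
insect-like ($J<1$) and bird-like ($J>1$) force-production regimes.  The
reference configuration (`default_calliope_config()`) fixes

| parameter | value | meaning |
|---|---|---|
| $U$ | 8.3 m s⁻¹ | flight (freestream) speed |
| $M$ | 2.8 g | body mass |
| $f$ | 45.5 Hz | wingbeat frequency |
| $\beta$ | 67.9° | stroke-plane angle from horizontal |
| $\Phi$ | 102.5° | stroke amplitude |
| $R$ | 4.51 cm | wing length |
| $S$ | 5.18 cm² | reference single-wing area |
| $\chi_b$ | 12° | body angle from horizontal |
| $Re$ | 3000 | $U\bar c/\nu$ with mean chord $\bar c = S/R$ |
| $\Delta t$ | 5 μs | production solver time step (≈4400 steps/cycle) |

Air density is nowhere part of the dimensionless problem statement, so the
package fixes $\rho = 1.2$ kg m⁻³; with that value the published
whole-cycle power coefficient $C_P = 0.266$ converts to an aerodynamic
power of 94.5 mW through $P = \tfrac12 C_P \rho U^3 (2S)$, which is the
consistency check that pinned the choice.  $g = 9.81$ m s⁻².

All coordinates are bird-fixed: $+X$ downstream (the freestream blows in
$+X$), $+Z$ up, $+Y$ to the bird's left, origin at the shoulder midpoint.
Thrust is the $-X$ force.

## Synthetic kinematics: what the generator emulates

The original kinematics were digitised from high-speed video as nine
markers per wing (five leading edge, one wingtip, three trailing edge) at
about 22 frames per wingbeat.  No marker data are deposited anywhere, so
the package generates marker sets with the same structure and the same
summary statistics, and every downstream stage consumes only markers — the
pipeline never touches the generator's internals.

The generator (`kinematic_program()` + `generate_markers()`) prescribes:

* **Stroke**: cosine sweep of amplitude $\Phi$ in a stroke plane tilted
  $\beta$ from horizontal (phase 0 = top of downstroke).  A cosine is the
  simplest waveform consistent with the reported amplitude, frequency and
  tip-speed summaries.
* **Planform**: an ellipse in the wing plane spanning $r/R \in [0.1, 1]$,
  with area normalised to $S$.  A smooth outline is deliberate: the
  reconstruction fits a periodic cubic spline through nine markers, and an
  outline with corners (as a straight-tapered planform would have at tip
  and root) cannot be recovered faithfully from nine points.  The ellipse
  is reconstructed to well under 1% in area.
* **Twist**: the local chord pitch varies linearly in $r/R$ between a
  proximal series $\psi_p(\phi) = 25 + 7\cos(4\pi\phi)$ (always positive,
  peaking at the stroke reversals where the wing pitches over) and a distal
  series fixed by the twist $\psi_d-\psi_p = 7.5 - 32.5\sin(2\pi\phi)$,
  which peaks near $-25°$ at mid-downstroke and $+40°$ at mid-upstroke as
  reported.  These two shapes make the distal chord angle negative during
  downstroke (leading edge tilting down — the thrust-producing posture) and
  the distal effective angle of attack negative during fast upstroke, both
  reported features of the measured kinematics.
* **Area modulation**: $1 + 0.04845\sin(2\pi\phi)$, giving a
  downstroke-mean single-wing area of 5.34 cm² and an upstroke mean near
  5.03 cm² about the 5.18 cm² reference.
* **Noise**: isotropic Gaussian with 0.2 mm standard deviation by default
  (sub-pixel scale for 1000 Hz video), exercising the smoothing steps
  without shifting phase-averaged metrics.

Chords are built in the parasagittal ($X$–$Z$) plane, so the prescribed
pitch *is* the local chord angle, and the chordwise offset is rescaled by
$1/\sin\gamma$ ($\gamma$ = angle between the spanwise axis and the chord
direction) so the instantaneous surface area tracks $S$ times the area
modulation at every stroke angle.

What the generator does **not** emulate: spanwise bending (the axis is
straight at every instant), feather gaps and camber, per-marker tracking
outliers, and cycle-to-cycle variability of a real bird.  Tests that pass
on this synthetic data therefore validate the *pipeline* — reconstruction,
metrics, solver coupling, post-processing — not biological realism of any
single wingbeat.

## Surface reconstruction

`reconstruct_outline()` fits a closed periodic cubic spline (chord-length
parameterisation) through the nine markers in anatomical order; ordering
comes from the marker labels, never from geometric sorting, so a mislabelled
file fails loudly rather than silently reordering.  `triangulate_wing()`
meshes the interior with a transfinite (Coons-patch) structured grid
bounded by the leading-edge, trailing-edge and root spline arcs, with the
wingtip collapsing to a point.  A constrained Delaunay triangulation would
serve equally; the structured patch was chosen because it is fully
deterministic, reproduces the boundary exactly at the sampled resolution,
and hits a requested element count (defaults reproduce the production scale
of ≈1335 elements / 718 nodes per wing; the desk CFD profile uses ≈340
elements, which resolves the planform at the desk grid spacing).

`refine_in_time()` interpolates every node trajectory with a periodic cubic
spline over each cycle and differentiates the spline analytically for node
velocities.  `build_body()` provides a watertight fusiform body of
revolution (~8 cm long, ≈3520 elements / 1762 nodes, matching the scale of
the production body mesh), pitched nose-up at $\chi_b$; the real bird's
scanned body shape is not available, so this synthetic body is a stand-in
of the right size and orientation.

Cycle segmentation places the start of downstroke at the maximum of the
phase-averaged wingtip elevation in the stroke plane and the downstroke/
upstroke boundary at its minimum — the published analysis shades the
downstroke without defining the split, and tip-elevation extrema are the
convention that makes the halves equal for a cosine stroke.

## Kinematic descriptors

`kinematics_series()` reports, per time sample: chord angles $\psi_p,
\psi_d$ at the proximal ($r/R=0.15$) and distal ($r/R=0.9$) stations,
effective angles of attack $\alpha_p, \alpha_d$, twist $\psi_d-\psi_p$, tip
speed, and instantaneous area.  Conventions, all tested:

* $\psi$ is the signed angle between the LE→TE chord (projected to the
  parasagittal plane) and the flight direction, positive when the leading
  edge is pitched up.  The projection reading is adopted because the chord
  angle is defined against a single axis (the flight direction); the full
  3D angle would mix in stroke-position effects.
* $\alpha$ is the signed angle from the relative flow — freestream minus
  the **leading-edge** translational velocity, per the stated definition —
  to the chord, positive when the flow impinges on the ventral surface.
  With a motionless wing, $\alpha \equiv \psi$.
* `cycle_summaries()` gives $U_{tip}$ (time-mean tip speed in the
  bird-fixed frame, adopting the body-relative reading of tip velocity —
  with $U_{tip} = 8.14 < U$ and $J = U/U_{tip} = 1.02$ the global-frame
  reading would be inconsistent), $J$, and stroke-conditional areas.

## Flow solver

The solver advances the viscous incompressible Navier–Stokes equations on
a fixed, non-uniform, single-block staggered Cartesian grid (MAC layout)
with a fractional-step (projection) scheme:

1. **Convection + diffusion**, explicit second-order Adams–Bashforth with
   variable-step weights (the pipeline occasionally subdivides a step when
   a transient velocity spike near the forced membrane would exceed the
   CFL budget; the variable-step weights keep second order and — unlike a
   first-order restart — keep the scheme inside its stability region).
   Convection uses the *skew-symmetric* form (mean of the advective and
   divergence forms, each centrally differenced).  The pure advective form
   is not energy-conserving on a staggered grid and blew up at the cell
   Reynolds numbers of the desk runs; the skew form bounds the discrete
   kinetic-energy production and is stable without artificial viscosity in
   the resolved region.  Derivatives use the standard three-point
   non-uniform-grid formulas (second order on smoothly stretched meshes).
2. **Immersed boundary**: sharp-interface direct forcing.  Staggered
   velocity faces inside the closed body (ray-parity test per grid column)
   or within a support distance of a wing membrane (point–triangle
   distance against the instantaneous mesh) are set to the local surface
   velocity, interpolated barycentrically from the mesh node velocities.
   The generic default support is 0.6 fine spacings; the desk flapping
   profile uses 0.4, which halves the effective numerical thickness of the
   membrane (about one cell instead of two) and measurably reduces the
   spurious pressure drag of the wing at no stability cost.  Fresh cells
   vacated by a moving surface simply retain their last forced value,
   which is the surface velocity they must match at the instant of
   uncovering.  This is the simplest member of the direct-forcing family
   that handles zero-thickness membranes; it is first-order sharp at the
   interface, which is consistent with the desk resolution.
3. **Pressure Poisson + projection**: cell-centred geometric multigrid
   (V-cycle, red-black Gauss–Seidel smoothing, volume-weighted restriction,
   trilinear prolongation, rediscretised coarse operators) wrapped as a
   preconditioner inside conjugate gradients.  Plain V-cycles degrade on
   the anisotropic cells of the stretched outer grid; CG stabilises the
   iteration at negligible extra cost, and warm-starting from the previous
   step's pressure keeps the in-run solve at ~3–5 iterations.  For
   all-Neumann/periodic problems the right-hand side is made compatible by
   subtracting its volume mean (reported), and the solution is gauged to
   zero mean.
4. **Boundary conditions**: uniform inflow upstream, convective outflow
   (`du/dt + U du/dx = 0`, explicit upwind) with a global mass-flux
   correction downstream, free slip on the lateral faces — a conventional
   set for external-flow boxes when the original code's choices are not
   documented.  A fully periodic mode exists for verification problems.
5. **Absorbing layer**: in the geometrically stretched outer region the
   cell Reynolds number is large and central convection has no damping;
   a weak local-averaging sponge (strength ramping with the local
   coarsening ratio, identically zero in the fine block) absorbs
   grid-scale oscillations before they can reflect from the boundaries.
   Without it, desk runs at the higher desk Reynolds number destabilised
   from the far field around mid-cycle.

The production simulation behind the reference coefficients ran 333 million
points on 96 cores; that scale is documented in the
`production-emulation` profile (which refuses to run without an explicit
opt-in) but is out of scope for a single CPU.  The desk profile instead
runs the same physics at reduced scale, and the solver is verified by
properties rather than by reproducing production numbers:

* Taylor–Green decay: kinetic energy follows $e^{-4\nu t}$ within 1% over
  a convective period at $64^3$ (measured ~0.1%);
* second-order convergence of the Poisson and momentum discretisations on
  manufactured/analytic solutions (observed order ≈ 2.0);
* divergence-free to solver tolerance after every projection;
* multigrid agreement with a dense direct solve on $17^3$ to ~$10^{-10}$
  relative;
* exact invariance of a uniform stream, zero net force under uniform
  pressure, solid-volume classification of a sphere within 5%, and a
  momentum/no-penetration check on flow past a sphere at Reynolds 50.

### Desk profile and what it can and cannot show

The desk profile uses a 18×14×12 cm box (a scaled version of the
production 25×20×16 cm domain) with fine spacing $\bar c/5$ ≈ 2.3 mm around
the wings, geometric stretching (ratio ≤ 1.1) outside, ≈160k cells, ≈430
steps per wingbeat (CFL target 0.45 against the expected freestream-plus-
wingtip peak speed), ~340 triangles per wing, and Reynolds number 300: a
full-configuration run of 1.6 cycles takes a few minutes on one CPU.
Occasional transient velocity spikes next to the forced membrane are
handled by adaptive step subdivision with variable-step time weights,
rather than a smaller global step.

Two of the study's headline force properties are robustly reproduced at
this scale: vertical force is strongly downstroke-dominant, and the body's
lift is several times larger with the flapping wings present than for the
isolated body.  One is not: the *sign* of the cycle-mean wing thrust.
Thrust at advance ratio one is a small difference between the forward tilt
of the lift vector and the wing's profile drag, and the desk solver
over-counts the drag side twice over — the section Reynolds number is an
order of magnitude below the production value (the desk body-drag
coefficient runs more than twice the production one, a direct measure of
the excess), and the direct-forcing membrane carries roughly one grid cell
of numerical thickness.  Desk runs across the stably reachable Reynolds
range (300–1000) and membrane-support settings consistently give a
cycle-mean thrust coefficient near −0.2 where the production value is
+0.115, with the correct downstroke-to-upstroke structure superimposed on
that offset.  Removing the offset needs roughly half the fine spacing,
about a 4× cost, which is outside the scale this package targets; the
thrust-sign check in the acceptance suite is therefore expected to fail at
desk scale and is retained unchanged as an honest record of the
limitation.  Desk coefficient magnitudes generally exceed the production
values and are treated as directional only.

## Aerodynamic post-processing

`surface_traction()` probes pressure and velocity gradients a fixed offset
(1.4 fine spacings) along each triangle normal: both sides for membranes
(the traction is the jump), the outside only for the closed body.  Forces
are area-weighted sums; coefficients divide by $\tfrac12\rho U^2 S$ with
$S$ the *fixed* reference area (that normalisation reproduces the
published power arithmetic exactly; the instantaneous area would not).
The power coefficient integrates the wing-on-fluid stress dotted with the
surface velocity in the bird-fixed frame over the wing, divided by
$\tfrac12\rho U^3 S$.  `stroke_averages()` produces time-weighted
downstroke/upstroke/whole-cycle means (equal half-stroke duration is not
assumed), and `performance_summary()` derives aerodynamic power, body-mass-
specific power, weight support, thrust-to-body-drag ratio, and the body's
lift share.  Both readings of the body contribution are reported:
`body_share` ($C_{Z,b}/(2C_Z + C_{Z,b})$, the published 22.2% number) and
`body_weight_frac` ($\tfrac12 C_{Z,b}\rho U^2 S/(Mg)$ ≈ 20.7%), because the
two differ when total lift does not exactly balance weight.  Where the
published stroke-resolved body-lift numbers disagree between text (1.76)
and table (1.81 = 0.342/0.189), the table is taken as canonical.

`swirling_strength()` evaluates the vortex criterion — the maximum
imaginary part of the eigenvalues of the velocity-gradient tensor — from
the closed-form solution of the characteristic cubic, vectorised over
cells; an eigenvalue-decomposition oracle cross-checks it in the tests.
Iso-surface rendering is delegated to the VTK consumer; no threshold is
baked in because none is published.

## Verification scales and runtime

All sizes were chosen so the full test suite and the acceptance script
each run in well under half an hour on one CPU: Taylor–Green at $64^3$
(~140 steps), Poisson/momentum order studies at $16^3$–$32^3$, sphere
checks at ~$10^5$ cells, a 1.6-cycle full-configuration flapping run plus a
0.8-cycle isolated-body run at the desk profile, and 2-cycle synthetic
kinematics with 22 frames per cycle (refined ×4).  The isolated-body
comparison keeps the body mesh, orientation and grid identical and simply
omits the wings.

## Known limitations

* Wings are rigid-per-frame, zero-thickness membranes without camber,
  moving exactly as prescribed — there is no fluid–structure feedback, and
  the absence of camber biases lift low at a given angle of attack.
* The direct-forcing membrane treatment leaks a small amount of flow
  through the wing at coarse resolution (the pressure jump is imposed only
  through the forced velocity layer), which damps force peaks; this, with
  the reduced Reynolds number, is why desk-scale coefficients are
  directional rather than quantitative.
* The synthetic body is a generic fusiform shape, not the bird's scanned
  geometry; body-force magnitudes should be read accordingly.
* Wake-topology classification (ladder versus ring wakes) is left to
  visual inspection of the exported fields.
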