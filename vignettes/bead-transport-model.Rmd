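---
title: "Simulating microbead transport over patterned soft-magnetic films"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating microbead transport over patterned soft-magnetic films}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beadscape)
```

## The physical model

A superparamagnetic microbead (radius $r_{mb}$, typically 1.4-4 µm) sits in
water above a patterned soft-magnetic thin film (the *parent structure*,
30-50 nm of permalloy or FeCoSiB).  An external field $\mathbf{H}_{ext}$
magnetizes both the film and the bead; the bead feels the film's stray-field
landscape and is steered by rotating or switching the external field.  The
total force on the bead is

$$\mathbf{F}_a = \mathbf{F}_{hd} + \mathbf{F}_m + \mathbf{F}_f + \mathbf{F}_g,$$

hydrodynamic drag, magnetic force, dry friction and (for out-of-plane
motion) gravity.

**Bead dipole.**  The bead magnetizes along the applied field with an
effective susceptibility $\chi$, giving a point dipole
$\mathbf{m} = \chi \mathbf{H}_{ext} \tfrac{4}{3}\pi r_{mb}^3$ located at the
bead centre, one radius above the surface at rest.  $\chi$ is an effective
scaling constant fitted against looping statistics on reference disc
structures; the value 0.0256 used in the scenario presets assumes the volume
factor is part of the moment, and the same convention is used everywhere in
the package.  The bead's stray field is the standard point-dipole field
$\mathbf{H}_{mb}(\mathbf{r}) = \frac{1}{4\pi}\,[3\hat r(\mathbf{m}\cdot\hat
r) - \mathbf{m}]/r^3$.

**Reciprocity-theorem potential.**  The magnetostatic interaction energy of
bead and film can be written by integrating *either* magnetization against
the *other* body's stray field.  Integrating over the film avoids ever
computing the film's stray field:

$$U(\mathbf{s}) = -\mu_0 \int_{V_p} \mathbf{M}_p \cdot
\left[2\,\mathbf{H}_{mb}(\mathbf{r} - \mathbf{s})\right]\,dV,$$

where $\mathbf{s}$ is the bead position.  The factor 2 is the reciprocity
factor relating the mutual energy to the single-sided integral; the
$\mathbf{M}_p\cdot\mathbf{H}_{ext}$ term and the integration constant are
dropped because they cannot contribute to forces on the bead.
`compute_potential()` evaluates this sum with each film cell treated as a
point dipole of moment $\mathbf{M}_p\,\Delta V$ at the cell centre — the
controlling approximation, accurate because the bead flies at least
$r_{mb}/2 \gg$ cell size above the film.  A naive double-loop oracle in the
test suite pins the vectorized (C++) sum to 1e-12 relative.

For periodic arrays the film cells are replicated `images` times per side
before summation ("n-fold periodic boundaries"); the stripe scenario uses
300 images along the stripe axis and 1 along the transport axis, the
lattice/track scenarios 1 per side.  Dipole sums over image shells converge
as (shell distance)$^{-2}$, and the seam continuity of the resulting maps is
asserted by tests.

**Fast paths for synthetic states.**  When every field state magnetizes the
same mask uniformly along the in-plane field direction $\hat d$, the state
sum factorises: $U = -2\mu_0\, \mathbf{m}^T G(\mathbf{s})\, M_s \hat d$ with
$G$ a per-node symmetric dipole-tensor sum computed **once**.  Similarly,
when the film pattern is fixed across states (exchange-biased stripes) a
per-node vector sum is computed once and re-contracted with each state's
bead moment.  Both routes are algebraically exact and tested against the
generic per-state summation; they are what makes 72-180 angle stacks
affordable on one CPU.

## Compressing the landscape: Fourier in time, polynomials in space

The map $U$ sampled on (state × z × y × x) is made continuously evaluable in
two steps (`fit_time()`, `fit_space()`):

1. per node, a least-squares Fourier series of order $N$ over the field
   period, $U(t) \approx \mathbf{F}_1^T(t)\,a + \mathbf{F}_2^T(t)\,b$ with
   $\mathbf{F}_1 = (1, \cos\omega t, \ldots)$, $\mathbf{F}_2 = (0,
   \sin\omega t, \ldots)$.  On uniform sample grids this equals the DFT.
   Discrete switching sequences are first expanded by `concat_states()`
   (e.g. 100 copies of the 30° slab followed by 100 copies of the 150° slab)
   so that the series approximates the square wave; order $N = 100$ on 200
   samples interpolates the samples, and the sine column at the Nyquist
   harmonic (identically zero on the sample grid) is dropped rather than
   declared a rank error.
2. per node, the 2N+1 Fourier-coefficient maps are fitted over the
   3×3×3 submatrix centred on that node with the 11-term basis
   $(1, x, y, z, xy, xz, yz, xyz, x^2, y^2, z^2)$ in node-centred local
   coordinates scaled by the grid step (for conditioning; the scaling is
   recorded per axis because z-layer spacing may differ from the in-plane
   spacing).  Forces are the analytic negative gradient of the local
   polynomial.

Every node owns a submatrix; during integration the *active* submatrix is
the one centred on the nearest node along the trajectory, with hysteresis on
the tie so the fit only hops when the bead truly crosses a node boundary.
Windows wrap across periodic seams (overlapping submatrices) and shift
inwards at non-periodic borders.  Submatrices are fitted lazily on first
visit and cached with their maximum residual; a trajectory visits a few
hundred nodes, far fewer than the grid holds, and this keeps $N = 100$ maps
(201 coefficient maps per node) affordable in memory.

With fewer than 3 z layers the z-dependent basis terms are dropped and the
landscape is quasi-2D.

## Equation of motion

$$m_{e\!f\!f}\,\ddot{\mathbf{s}} = -\Gamma_{hd}\,\dot{\mathbf{s}}
\begin{pmatrix} 1 + \tfrac{9 r_{mb}}{16 (r_{mb}+z)} \\
1 + \tfrac{9 r_{mb}}{16 (r_{mb}+z)} \\
1 + \tfrac{9 r_{mb}}{8 (r_{mb}+z)}\end{pmatrix}
+ \mathbf{F}_m + \mathbf{F}_f \,(+\,\mathbf{F}_G)$$

with $\Gamma_{hd} = 6\pi\eta r_{mb}$, the added-mass inertia
$m_{e\!f\!f} = \tfrac{4\pi}{3} r_{mb}^3 (\rho_{mb} + \rho_{water}/2)$, and
the linear near-wall drag correction (1.5625 in-plane and 2.125 out-of-plane
at contact).  Water viscosity comes from a Vogel-type correlation
$\eta(T) = 2.414\times10^{-5}\,10^{247.8/(T_K - 140)}$ Pa s (within ~1% of
handbook values over 0-100 °C); scenario presets use the experimental 22 °C.

Choices worth stating explicitly:

* **Friction** is Coulomb-like and proportional to the *downward* magnetic
  force only, $\mathbf{F}_f = -F_c \max(0, -F_{m,z})\,\hat v$, active only
  at ground contact: when the net magnetic z-force points upward the bead is
  about to lift and dry friction must vanish.  There is no static-friction
  (stick-slip) model; at rest the direction $\hat v$ is undefined and the
  force is zero.  Inside the integrator the direction is mollified to
  $\mathbf{v}/(|\mathbf{v}| + \varepsilon)$ with $\varepsilon$ = 1 nm/s —
  far below any transport speed — because the discontinuous law otherwise
  forces the stiff solver to femtosecond steps when the bead stalls.
* **Gravity is buoyancy-corrected**, $F_G = -(\rho_{mb} -
  \rho_{water})\tfrac{4\pi}{3}r^3 g$: the beads move in water, and the same
  $\rho_{water}$ already enters the added mass.  Bead density defaults to
  1050 kg/m³ (polystyrene), configurable.
* **2D/3D switching**: at the start of each solver step the out-of-plane
  force from the previous evaluation decides the regime.  At ground level
  with no net upward force the 2D in-plane equation is solved with z frozen
  (forces evaluated on the ground plane); otherwise the full 3D equation
  with gravity.  A step ending below the surface is clamped to z = 0 with
  the vertical velocity zeroed.
* **Integrator**: macro-steps capped at 0.7 ms; inside each macro-step the
  frozen-regime equations are integrated by `deSolve`'s lsoda (the system is
  violently stiff: the velocity relaxation time $m_{e\!f\!f}/\Gamma_{hd}$ is
  ~100 ns against millisecond steps) at rtol 1e-8, atol 1e-12.  The active
  submatrix and regime are re-chosen between macro-steps — the submatrix hop
  is a step-end event, never a mid-step jump.
* Transient excursions up to one grid step beyond the fitted hull are
  evaluated by polynomial extrapolation of the edge submatrix; anything
  further is a domain error.  Direct calls to `eval_U()`/`eval_force()`
  are strict.

## What the synthetic states emulate — and what they do not

The upstream micromagnetic solution is out of scope; `synth_state()`
provides *uniformly saturated shape masks* as stand-ins for the relaxed
near-saturated states of the four reference systems (disc, hexagonal
triangle lattice, exchange-biased stripes, asymmetric oval track).  Under a
20 mT in-plane field soft 30-50 nm elements are close to saturation, so the
masks carry the leading pole structure: edge charges $\sigma = \mathbf{M}
\cdot \hat n$.  They deliberately omit flux-closure detail — onion-state
flank curling on discs, tip pole concentration on triangles, the "minor
inhomogeneities" of relaxed exchange-biased stripes.  Consequences observed
with the shipped presets:

* disc looping: onset, loop count and loop *radius* reproduce the published
  behaviour well (max distance to the disc edge ~11 µm vs ~10 µm reported),
  but the vertical kick during a loop is much softer — max lift ~0.7 µm vs
  ~3 µm reported.  The lift is fed by the local pole density the bead
  crosses at the zero-potential line, which an onion state concentrates far
  more than a uniform mask.  This deviation is resolution-independent
  (unchanged under z-layer refinement 9→21, in-plane 64→100, and step
  halving) and barely gravity-sensitive (+0.15 µm for neutrally buoyant
  beads): it is a property of the state substitution, not of the numerics.
* triangle lattice: the published stepwise +y ratchet does not survive the
  substitution.  The switching landscape of uniform masks is too symmetric:
  the bead executes one productive ~10 µm step from the 30° minimum to the
  150° minimum and then oscillates between two adjacent minima — with the
  Fourier-smoothed switch *and* with piecewise-instant switching, for
  point-up and point-down orientations alike.  The published mechanism
  rides on the relaxed states' tip-concentrated poles, which decide whether
  the post-switch position falls into the basin of the next-up minimum.
* exchange-biased stripes: provably cannot ratchet with uniform per-stripe
  magnetization.  In a line-charge picture the pure-z field states park the
  bead exactly on a stripe edge, and the following state's nearest minimum
  is always the *backward* one (2.5 µm gap against 10 µm stripe width); all
  phase pairings of the four-state sequence, and a self-demagnetization-
  driven reversal variant (threshold µ0 Ms t/w ≈ 2 mT), give one initial
  step followed by bounded oscillation.  The directionality in the source
  experiments comes from inhomogeneous partial reversal in the relaxed
  states.
* oval track: transport, rectification and the inter-element rest are all
  reproduced; the rest duration comes out ~48 ms against the reported
  ~120 ms, the overlap range of the synthetic two-arc wells being narrower
  than that of the relaxed states (a 34 µm track cell, the micromagnetic
  grid extent, was also examined: its 8 µm gap stops the hand-off entirely
  under the substitution, so the preset keeps the 30 µm cell chosen at
  design time).
* passing dynamics tests therefore demonstrates the *machinery* (potential,
  fits, solver) at oracle precision, while scenario-level metrics that
  hinge on internal state detail carry the substitution error.  The test
  suite asserts the published values with their stated tolerances and is
  expected to show exactly these deviations.

The stripe states are uniform $-\hat y$ per stripe, the sign chosen so the
+5 mT applied $H_y$ is antiparallel to the -5.5 mT exchange-bias field.  The
oval outline (never printed by the source experiments) is parametric: a
base arc of radius 10.5 µm (half the 21 µm box height) and a sharper tip arc
(5 µm default) joined by common external tangents in a 26 × 21 µm box, on a
30 µm track pitch; the two curvatures create the asymmetric inter-element
potential that rectifies clockwise field rotation into unidirectional
transport.

## Scenario presets and problem sizes

`build_scenario()` carries the published parameter sets (geometry, film
thickness, saturation polarization, field sequence, fit orders, 0.7 ms step
cap) and a **coarse** profile for desk-scale runs: potential grids at most
64 nodes per axis, parent grids at most 256 cells per axis, at most 9 z
layers, and 72 rotation angles for the disc (the Fourier order 30 needs at
least 61).  Physical parameters are never scaled.  Coarse runs complete in
minutes on one CPU: the disc scenario integrates 6 field periods (~9500
macro-steps), triangles 4 switching periods, ovals 3 rotations, stripes 2
periods.  The acceptance script under `scripts/` re-runs exactly these.

Numerical tolerances worth recording: Fourier design columns are dropped
when their sampled norm is below 1e-9·√n (the Nyquist sine); submatrix
fits fail loudly on rank deficiency instead of regularizing; the spatial
fit residual is stored per submatrix and adjacent-submatrix continuity is
bounded by twice the larger residual in tests.

## Known limitations

* No Brownian motion, bead-bead interactions, lubrication corrections
  beyond the linear wall factor, or surface adhesion.
* No micromagnetic relaxation: magnetization states are either imported
  (OVF) or ideal saturated masks; exchange-biased states are prescribed.
* Binary OVF segments are rejected (text OVF 1.0/2.0 only), and cached
  artifacts are text (OVF/CSV/JSON) rather than HDF5.
* The friction model is kinetic-only; a bead whose driving force stays
  below the friction bound creeps at the mollification scale instead of
  sticking exactly.

## A worked micro-example

A bead released off-centre in a static harmonic trap relaxes exponentially
at the wall-corrected overdamped rate $k/(1.5625\,\Gamma_{hd})$ — one of the
closed forms the test suite checks to 1%:

```{r trap, eval = FALSE}
spec <- potential_grid_spec(c(-30e-6, 30e-6), c(-30e-6, 30e-6), 31, 31, 0)
k <- 1e-6   # trap stiffness, J/m^2
U <- array(outer(spec$x, spec$y, function(x, y) 0.5 * k * (x^2 + y^2)),
           c(31, 31, 1, 1))
fit <- fit_space(fit_time(potential_map(U, spec), 0), 3)
bead <- bead_spec(4e-6, 0.0256)
env <- environment_spec(22)
tr <- simulate_bead(fit, bead, env, s0 = c(10e-6, 0, 0), t_span = 0.5)
rate_expected <- k / (1.5625 * drag_gamma(bead, env))
```
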