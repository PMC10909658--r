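---
title: "Methods: Casson blood flow through a catheterized, balloon-dilated stenosis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Casson blood flow through a catheterized, balloon-dilated stenosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The physical problem

stenoflow simulates blood flow through a short segment of a coronary
artery that is narrowed twice over: from the outside by a symmetric
plaque (a stenosis on the arterial wall) and from the inside by a
balloon-tipped catheter threaded along the vessel axis, as in balloon
angioplasty. The flow domain is the annular channel between the two
walls. The questions the package answers are the hemodynamic ones that
matter clinically: how fast the jet through the residual throat becomes,
where the pressure falls, how strong the wall shear stress is, and
whether the flow separates into a recirculation eddy downstream of the
constriction.

## Geometry

Both walls are analytic profiles of the axial coordinate $z \in [0, L]$.
The outer (arterial) wall is

$$\eta(z) = R\left[1 - \kappa\{b^{n-1}(z-a) - (z-a)^n\}\right],
\qquad a \le z \le a+b,$$

and $\eta = R$ elsewhere, the classic one-parameter family of smooth
symmetric stenoses: $b$ is the plaque length, $n \ge 2$ its shape
factor, and the severity coefficient

$$\kappa = \frac{\delta^*\, n^{n/(n-1)}}{R\,b^n\,(n-1)}$$

is the unique value for which the profile dips to exactly
$R - \delta^*$, attained at $z = a + b/n^{1/(n-1)}$ (mid-plaque for
$n = 2$). The inner wall is a catheter of radius $cR$ carrying a balloon
bump co-located with the plaque,

$$\epsilon(z) = R\,[c + f_1(z)],$$

with $\epsilon = cR$ outside $[a, a+b]$.

Three geometric choices are genuinely open and are fixed here as
package defaults, all configurable:

* **Balloon shape $f_1$.** No functional form is standard; we use
  $f_1(z) = (\delta_b/R)\sin^2(\pi(z-a)/b)$: $C^1$-continuous at both
  ends, symmetric, peaking mid-plaque with height $\delta_b$, which
  matches the usual sketch of a balloon parked under the plaque. A
  sharper $\sin^4$ alternative is selectable (`bump_profile`).
* **Shape factor $n = 2$**, the symmetric member of the family,
  consistent with a symmetric plaque.
* **Plaque position**: centered, $a = (L-b)/2$.

The reference case (`coronary_case()`) is an artery of radius
$R = 2$ mm and length $L = 10$ mm, a plaque of length $b = 2$ mm and
height $\delta^* = 0.82$ mm, a catheter of diameter 1 mm
($c = 0.25$) and a balloon of height $\delta_b = 0.53$ mm. The residual
throat is then $\eta - \epsilon = 0.15$ mm at $z = 5$ mm — a severe
constriction: the channel keeps only 10% of its nominal width.

Setting $c = 0$ (allowed only with $\delta_b = 0$) removes the catheter
entirely; the inner boundary becomes the symmetry axis and the channel
is an open tube. This limit exists for verification (below).

## Rheology

Blood is a Casson yield-stress fluid,
$\sqrt{\tau} = \sqrt{\tau_y} + \sqrt{\mu_p \dot\gamma}$, implemented as
a shear-rate-dependent effective viscosity

$$\mu_{\mathrm{eff}}(\dot\gamma) = \left(\sqrt{\mu_p} +
\sqrt{\tau_y / \max(\dot\gamma, \dot\gamma_{\mathrm{floor}})}\right)^2,$$

with $\dot\gamma = \sqrt{2\,\mathrm{tr}\,D^2}$ the axisymmetric
strain-rate invariant. The floor $\dot\gamma_{\mathrm{floor}}$ is a
simple bi-viscosity-style regularization: below it the material moves as
a very viscous fluid instead of a rigid plug, keeping the equations
nonsingular. We chose the floor over Papanastasiou-type exponential
regularization for transparency — one parameter, obvious meaning — and
the acceptance suite checks that halving it leaves the steady pressure
drop unchanged to well within 1%.

Defaults (`casson_params()`): $\mu_p = 3.45\times10^{-3}$ Pa s,
$\tau_y = 5\times10^{-3}$ Pa, $\rho = 1050$ kg/m³,
$\dot\gamma_{\mathrm{floor}} = 10^{-3}$ s⁻¹ — standard blood-analog
Casson constants. At the shear rates of the reference case
($\dot\gamma \gtrsim 10^3$ s⁻¹ near the throat) the yield stress is a
small correction; it matters in slow flows, which is exactly where the
tube-flow oracle below operates.

A `literal_constant` mode is retained in which the effective viscosity
is the shear-independent constant $(\sqrt\zeta - \sqrt m)^2$; it reduces
the model to a Newtonian fluid and exists for comparison runs. The
conventional full shear stress
$S_{rz} = \mu_{\mathrm{eff}}(\partial u/\partial z + \partial w/\partial r)$
and the hoop stress $S_{\theta\theta} = 2\mu_{\mathrm{eff}} u/r$ are
used throughout, the form required for the Newtonian limit to reproduce
the standard cylindrical viscous stress tensor.

## Flow solver

The unsteady axisymmetric incompressible Navier–Stokes equations (no
azimuthal velocity) are solved on a terrain-following grid: coordinates
$(z, \sigma)$ with $r = \epsilon(z) + \sigma(\eta(z) - \epsilon(z))$,
$\sigma \in [0,1]$ from inner to outer wall. Physical derivatives follow
from $\partial_r = h^{-1}\partial_\sigma$ and
$\partial_z|_r = \partial_z|_\sigma - (r_z/h)\partial_\sigma$ with
$h = \eta - \epsilon$. Fields are staggered: axial velocity $w$ on
z-faces, radial velocity $u$ on $\sigma$-faces, pressure at cell
centers — the arrangement that makes the discrete continuity equation
exact and checkerboard-free without momentum interpolation.

One time step is an incremental pressure-correction (projection) cycle:

1. **Boundary conditions.** No-slip on both walls ($u = w = 0$; on the
   axis in tube mode, symmetry instead). The inlet axial profile (the
   annular Poiseuille shape by default, or a plug) is rescaled every
   step so its *discrete* flux matches the target flow rate, ramped
   from rest by a smooth-step over 0.1 s to avoid an impulsive start.
   The outlet is zero-gradient velocity with the pressure pinned to 0
   at the outlet boundary, so all reported pressures are relative.
2. **Momentum predictor.** The full momentum right-hand side
   (advection, viscous stress divergence, old pressure gradient) is
   evaluated explicitly, then the velocity increment is passed through
   the approximately factored implicit operator
   $(I - \Delta t L_z)(I - \Delta t L_\sigma)$, tridiagonal sweeps in
   each grid direction. Both principal diffusion directions are
   therefore unconditionally stable — essential because the regularized
   plug viscosity exceeds $\mu_p$ by three orders of magnitude wherever
   the fluid is nearly at rest (including the whole domain at startup).
   The $\sigma$ sweep also carries the contravariant cross-channel
   advection implicitly (first-order upwind on the increment), so steep
   wall slopes do not throttle the step. Because the implicit operators
   act only on the *increment*, the steady state satisfies the unsplit
   discrete equations exactly; the splitting affects transients only.
3. **Advection discretization** (in the explicit right-hand side):
   three-point central differences where the cell Péclet number is
   below 2, blending to a second-order upwind-biased quadratic beyond —
   the throat jet sits at cell Péclet ~10 and pure central stencils
   would oscillate there. Both stencils are second order, which the
   grid-convergence study relies on.
4. **Pressure correction.** The discrete divergence (face fluxes of the
   mapped geometry, including the slope-induced cross-flux) must vanish.
   The projection operator — the exact composition of that divergence
   with the discrete pressure gradient — is assembled once per grid by
   probing the shared correction code path with unit vectors, stored as
   a banded matrix (bandwidth $N_\sigma + 2$), and LU-factored once with
   LAPACK's banded routines. Each step then needs a single
   back-substitution; an outer loop re-checks the divergence and mops up
   floating-point residue. The divergence tolerance is
   `poisson_rel_tol` (default $10^{-6}$) times the characteristic scale
   $U_{\mathrm{in}}/\mathrm{gap}$. We preferred the exact banded direct
   factorization over a preconditioned iterative solver: on grids of
   this shape it is faster, it is exact, and it is trivially
   deterministic.

The time step adapts to the Courant bound
$\max(|w|/\Delta z + |u|/\Delta r)\,\Delta t \le 0.5$, capped at
$\Delta t \le 10^{-3}$ s and a 10% growth rate per step. Runs start
from rest and integrate nominally to 10 s, but every acceptance
quantity is a steady-state quantity, so runs stop early once the axial
velocity field changes by less than `steady_tol` (relative $L_\infty$,
default $10^{-3}$) over one full transit time $L/U_{\mathrm{in}}$ —
comparing over a full transit makes the detector robust to the tiny
limit-cycle flutter of the downstream eddy. A blown-up state (any
non-finite velocity) aborts with the step and time reported.

## Grid

`build_grid()` refines where the physics is: with clustering enabled the
axial node density inside the stenosis interval is about four times the
outside density (at least twice is guaranteed), with smooth cosine
tapers, and the $\sigma$ spacing is mildly compressed toward both walls
(wall spacing 0.4 of the interior, a sine stretch). Aggressive
$1/N_\sigma^2$ wall clustering was deliberately rejected: it throttles
the radial Courant bound while the wall-quantity accuracy is already at
the few-per-mil level on near-uniform spacing. Grids that cannot
represent the bump (fewer than 8 axial cells across it) are rejected.

## Verification strategy

The study's published results are qualitative field renderings, so
verification is against analytic limits:

* **Newtonian annulus.** With no stenosis, no balloon and zero yield
  stress, the steady solution must match the closed-form annular
  Poiseuille profile; the acceptance run at $N_\sigma = 64$ requires
  2% $L_\infty$ agreement and 2% on the pressure gradient.
* **Casson tube (Buckingham–Reiner).** The yield-stress closure is
  verified in the open-tube limit $c = 0$ against the Buckingham–Reiner
  flow-rate law, within 3%, in a regime where the plug occupies 10% of
  the radius and the yield stress suppresses the flow rate by a factor
  of ~2.4 — a demanding, genuinely non-Newtonian target.
  An important negative result drove this design: a "nearly removed"
  catheter ($c = 0.01$) does **not** approximate a tube. A no-slip wire
  of radius $0.01R$ removes $(1-c^2)^2/\ln(1/c) \approx 22\%$ of the
  tube flux — the classical logarithmic thin-wire effect — at any yield
  stress. The package therefore supports a true symmetry-axis inner
  boundary for the tube oracle, and separately validates the $c = 0.01$
  annulus against an independent 1-D fully developed regularized-Casson
  annulus solution (quadrature of the inverted constitutive law) in the
  unit tests.
* **Operator-level checks.** The discrete momentum operator annihilates
  the exact annular Poiseuille solution at second order in the interior;
  the discrete curvilinear divergence annihilates analytic solenoidal
  fields derived from wall-conforming stream functions at second order;
  the projection reduces the divergence of arbitrary fields to
  tolerance in a bounded number of solves.
* **Conservation.** The staggered projection conserves mass by
  construction; the acceptance criterion checks the *recomputed* outlet
  flow rate against the prescribed inlet rate to 0.1% on the reference
  200 × 48 grid.
* **Grid convergence.** The throat mid-gap velocity over grids
  50 × 12, 100 × 24, 200 × 48 Richardson-extrapolates to order ≈ 2
  (the suite accepts ≥ 1.5).

## Post-processing definitions

The Stokes stream function is accumulated from the inner wall,
$\psi(z,\sigma) = \int w\,r\,dr$, by exact integration of the staggered
representation (each $w$ sample weighted by its annular cell area) —
equivalently, the trapezoidal rule on $\psi$ itself. The flow-rate
audit uses the *same* quadrature, so $\psi$ at the outer wall equals
$Q(z)/2\pi$ identically and the conservation audit is consistent with
the streamlines; a naive point-sample trapezoid over cell means was
rejected because it injects a spurious ~0.1% bias, the size of the
conservation tolerance itself.

Wall shear stress is $\mu_{\mathrm{eff}}$ times the wall-normal
derivative of the wall-tangential velocity, from a one-sided
second-order two-point quadratic through the wall; the wall viscosity is
re-evaluated from the wall shear rate. Signs are "positive =
forward-dragging" on both walls.

Recirculation zones are axial intervals where the axial velocity
reverses sign, scored by the largest excursion of $\psi$ outside its
through-flow range $[0, Q/2\pi]$ (a positive excursion is a closed
streamline loop). Excursions below $10^{-3}$ of the global $\psi$ scale
are filtered: a single-column ripple of strength $10^{-4}\psi$ at the
plaque foot is numerical texture, not an eddy. "Swirling" in this
axisymmetric setting can only mean such in-plane recirculation — the
governing equations contain no azimuthal terms — and that is how the
package operationalizes it.

## What the scenario generator does and does not emulate

`coronary_case()`, `straight_annulus_case()`, `near_tube_case()` and
`tube_case()` are complete, validated, runnable cases;
`scenario_sweep()` draws Latin-hypercube samples over stenosis height,
balloon height and flow rate (seeded, reproducible, every draw
re-validated for a positive throat gap). The generator emulates the
study conditions: steady (ramped-constant) inflow at 2.0–2.5 ml/s,
rigid walls, a single symmetric plaque with a co-located balloon.
It does not emulate pulsatile (Womersley) inflow, wall compliance or
balloon inflation dynamics, plaque irregularity, or 3-D
non-axisymmetric effects — so passing tests demonstrate correctness of
the stated model, not fidelity to any individual patient's artery.

## Findings the tests encode

Two scientific points discovered during verification are worth stating
plainly, because the test suite asserts them:

* At the reference geometry and flow range the constriction jet
  (~2.5 m/s through a 0.15 mm throat) separates on the diverging wall
  and drives a recirculation eddy that begins inside the diverging
  section (z ≈ 5.2 mm) and extends beyond the end of the 10 mm
  segment. A laminar backward-facing-step estimate of the reattachment
  length (tens of mm at this jet Reynolds number) agrees. The suite
  therefore asserts the *existence* of the downstream eddy, and the
  separate "fully relaminarized outflow within the segment" check
  fails honestly at both tested resolutions: at these parameters the
  eddy outlives the domain.
* The upstream flow is unidirectional with simple streamline topology
  at all tested flow rates, and the pressure minimum and velocity peak
  sit in the stenosis + balloon interval, as expected.

## Problem sizes and runtimes

The reference verification grid is 200 × 48 (about 63,000 adaptive
steps to steady state, a few minutes of CPU); the convergence study
uses 50 × 12 and 100 × 24 beneath it; the oracle runs use 48 × 64
(annulus and tube) and 32 × 48 (thin-wire annulus). These sizes were
chosen so the full verification suite completes comfortably on one CPU
while keeping the reference grid fine enough for sub-percent oracle
agreement and a clean second-order Richardson fit.

## Known limitations

* First-order accuracy in time (steady-state results are unaffected);
  transient snapshots are qualitatively, not formally, time-accurate.
* The zero-gradient outlet is approximate when the recirculation eddy
  crosses it, as it does in the reference case; quantities within the
  final half-millimeter should be read with that in mind.
* The regularized plug creeps ($\mu$ capped at the floor value) rather
  than moving rigidly; plug-zone boundaries are smeared over the cells
  where $\dot\gamma$ crosses the floor.
* Axisymmetry is assumed throughout; a real post-stenotic jet at these
  Reynolds numbers may break symmetry in 3-D.
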