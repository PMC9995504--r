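---
title: "Methods: coupled flow and buoyant-blade simulation of canopy shear-layer instability"
author: "monami package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coupled flow and buoyant-blade simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

`monami` simulates unidirectional open-channel flow through a submerged bed
of buoyant, deformable seagrass blades, in two dimensions (along-channel
`x`, vertical `z`), in dimensionless form. Lengths are scaled by the
undisturbed water depth `H`, velocities by the undisturbed surface speed
`U`, time by `H/U`. Five dimensionless groups govern the solution:

* `Re = U H / nu*` — Reynolds number on the constant eddy viscosity;
* `beta = (rho - rho_g) g d / (rho c_D U^2)` — blade buoyancy relative to
  drag; larger `beta` means stiffer-standing grass;
* `r = ell / H` — blade length over depth (0.5 throughout);
* `lambda = c_D N b H` — bulk canopy drag density (1 throughout);
* `Fr^2 = U^2 / (g H)` — squared Froude number (0.1 throughout).

The fluid obeys the incompressible momentum equations with a free surface
`h(x,t)`, a nonhydrostatic pressure, a constant body force `G` standing in
for the mean pressure gradient, and a volumetric canopy drag
`F = -lambda sec(theta) f` applied below the canopy top `h_g(x,t)` and zero
above it. The free surface satisfies the depth-integrated kinematic
condition, and a passive tracer `C` is advected with the flow.

## Blades

Each grid column carries one blade representative standing in for the `N`
blades per unit area. A blade is inextensible, does not resist shear
(zero flexural rigidity), and is taken to be in static equilibrium with the
flow at every instant (blade inertia, added mass and virtual buoyancy are
neglected; these are higher-order for the small-amplitude waving regime
simulated here). Three forces act on a blade element: tension (tangential),
buoyancy (`beta` upward per unit length), and quadratic drag normal to the
blade, `f = (1/2)(u . n)|u . n| n` with `n` the blade normal. The
orientation of `f` is fixed by the physical requirement that flow in `+x`
past a near-vertical blade pushes it downstream; the reaction on the fluid
is opposite. Integrating the force balance from the free tip (where tension
vanishes) gives the tension profile, `theta = atan(T^x / T^z)` gives the
angle, and integrating `(sin theta, cos theta)` from the root gives the
shape. The model assumes the blade does not overturn (`T^z > 0`,
`|theta| < pi/2`); violations raise errors.

The fixed point of sample-velocity → drag → tension → angle → shape is
found by under-relaxation starting at relax = 0.5. The plain relax-0.5 map
can cycle where the vertical drag component drives `T^z` toward zero (this
happens for uniform speeds as low as 0.3 at `beta = 0.02`, inside the swept
parameter range), so the relaxation halves whenever the fixed-point
residual grows and recovers by 5% per shrinking iteration, with the
residual measured as the un-relaxed fixed-point gap. Blades use 25 uniform
arc-length segments (matching the 24 canopy layers of the grid), tolerance
`1e-6` rad in production stepping and `1e-11` inside the steady-state
solver. The shape integral uses the segment-mean angle rather than a
trapezoid of `(sin theta, cos theta)`: both are second order, but the
segment-mean form keeps the discrete blade exactly inextensible, which the
trapezoid would violate at the `1e-4` level on 25 segments.

## Steady base state

Before onset the flow is steady and x-independent. The base state solves
the vertical momentum balance `(1/Re) u'' + G - drag = 0` with no-slip bed,
zero shear at the surface, and `G` tuned so `u = 1` at the surface, coupled
to the blade equilibrium. The solver alternates: (i) a quasi-linearized
tridiagonal solve for `u` (drag linearized about the previous iterate;
by linearity `u = G v` with `v` solved once, so the surface condition fixes
`G` exactly per iteration); (ii) blade equilibration against `u` and
canopy-height update from the blade tip; (iii) grid rebuild and re-deposit
of the blade forces. Everything — vertical stencils, velocity sampling,
force deposition — reuses the channel solver's own discrete operators, so
the converged profile is a fixed point of the 2D stepper to round-off: one
hundred coupled steps move it by less than `1e-8`. The constant `G` lumps
the mean surface slope and pressure gradient, only the sum of which is
identifiable in 1D; `Fr` enters the base state only through this constant.

At the baseline (`Re = 1000`, `beta = 0.10`) the tuned forcing gives
`u = 0.6` at `z ≈ 0.65`, just above the canopy — the height at which the
developed vortices later propagate — and the canopy-interior velocity
saturates near `sqrt(2 G / lambda)`.

## Grid

The vertical coordinate is terrain-following: each column has `N_kg` equal
layers filling `[0, h_g]` and `N_k - N_kg` equal layers filling `[h_g, h]`,
so bed, canopy top and free surface always lie on fixed computational
levels. This piecewise-uniform sigma map satisfies every property required
of the grid (the three interface conditions and uniformity in computational
space) with simple metric terms; a truly conformal (orthogonal) map is not
needed at the surface and canopy slopes that occur (at most a few percent).
Vertical derivatives use 3-point Lagrange stencils on the physical heights,
which are exact on quadratics including across the canopy-interface spacing
jump; boundary closures fold in the no-slip bed value and the zero-slope
surface condition so that the analytic drag-free profile `z(2 - z)` is a
discrete steady state to round-off. Horizontal derivatives at constant
sigma carry metric corrections where needed.

As `h_g` and `h` evolve, fields are re-mapped columnwise by monotone-cubic
(Fritsch–Carlson) interpolation in physical height — the same scheme as
`splinefun(method = "monoH.FC")`, vectorised over columns — with
nearest-value extension beyond the old range (consistent with the zero
surface shear and the smallness of per-step grid motion, about `3e-4`
depth units).

## Time stepping

The staggered (MAC) layout places `u` on x-faces, `w` on sigma-faces and
`p`, `C` at centers. One step comprises:

1. blade equilibration and drag assembly from the pre-step velocities
   (the drag lags the flow update by one `dt = 0.1`, consistent with the
   blades being in equilibrium at every instant);
2. an explicit predictor for advection (conservative flux form, centered,
   built on the contravariant volume fluxes), horizontal viscosity, canopy
   drag and forcing, advanced with third-order Adams–Bashforth (Euler and
   AB2 start-up). AB3 is used rather than AB2 because centered advection
   puts the eigenvalues on the imaginary axis, where AB2 is weakly unstable
   and AB3 is stable up to Courant ≈ 0.72;
3. implicit (backward Euler) vertical viscosity by a per-column tridiagonal
   solve. The bed-adjacent vertical diffusion number `dt/(Re dz^2)` is ≈ 1.5
   at baseline resolution, far outside any explicit multistep stability
   region; backward Euler is unconditionally stable and — unlike
   Crank–Nicolson — leaves the discrete steady balance exactly invariant;
4. a semi-implicit theta-scheme free-surface update (theta = 0.55): the
   depth-integrated continuity equation combined with the surface-slope
   force yields a tridiagonal system along x for `h`, removing the surface
   gravity-wave CFL limit (`1/sqrt(Fr^2) ≈ 3.16` exceeds the explicit
   limit at `dt = 0.1`);
5. a nonhydrostatic pressure projection: the corrections are applied to
   the contravariant fluxes themselves with face coefficients, which makes
   the operator a symmetric positive-definite 5-point Laplacian (`p = 0` at
   the surface, homogeneous Neumann at bed, inlet and outlet). The sparse
   Cholesky factorisation is cached and refreshed only when the grid has
   deformed by more than `1e-3` since the last factorisation, with
   iterative refinement against the current operator in between; the
   post-projection divergence stays below `1e-8` (in practice at round-off)
   at every step;
6. sponge restoring of `(u, w)` toward the steady profile over
   `x in [L, L_r]` with a half-cosine ramp reaching rate 10 (so
   `sigma_max dt = 1`: full restoration at the outlet);
7. monotone (van Leer flux-limited) conservative tracer advection, forward
   Euler in time, inlet held at the reference profile, zero-gradient
   outlet, no bed flux, free-surface flux with donor concentration;
8. re-mapping of `u`, `w`, `C` to the updated `(h_g, h)` grid.

The advective CFL guard aborts a step above `cfl_max = 0.9` (the vertical
Courant `|w| dt / dz` is the binding one: the developed street sits at
0.80–0.86 with rare excursions past 0.9, while `|u| dt / dx ≈ 0.65`). If a
run trips the guard, the driver applies the documented fallback — a 10%
first-order upwind blend in the momentum advection, with the guard moved to
the true Courant limit — restarts the offending step from the last stable
state, and records the switch in the run log. The blend's numerical
diffusivity (`0.05 |w| dz` vertically) is below the molecular `1/Re` at the
amplitudes where it would engage; the baseline run completes without it.

## Instability seeding and diagnostics

Runs are seeded with uniform white noise of amplitude `1e-6` on the
initial vertical velocity under a fixed integer seed, making onset
deterministic and reproducible; onset time depends logarithmically on this
amplitude (the baseline crosses `w_rms = 1e-3` near `t = 46`), while the
saturated street statistics do not. Diagnostics are sampled every 1.0 time
units (Nyquist-adequate for the 4.5 street period): the domain-wide rms of
`w` over the analysis region `x <= L`, the rms canopy-height perturbation
about the steady height, the canopy-top exchange integral, the Hovmoeller
row `w(x, z = h_bar_g)` and the per-level `w_xrms(z)`.

Street kinematics come from the developed window (`t in [300, 500]`,
`x in [20, 34]` in the full channel): the wavelength from the peak of the
time-averaged spatial periodogram and the period from the space-averaged
temporal periodogram (both Hann-tapered, with quadratic peak
interpolation — the taper keeps the interpolated peak unbiased by spectral
leakage when the window holds a non-integer number of periods), and the
propagation speed from the lag maximising the space–time cross-correlation
between samples one output interval apart, with the lag search restricted
to half a wavelength to avoid the periodic ambiguity of the correlation of
a near-sinusoidal pattern. Onset is the first `w_rms` crossing of `1e-3`
sustained for five samples; the stability mask of the parametric sweep uses
long-term `w_rms > 1e-4`. Both thresholds sit an order of magnitude above
the seeded-noise floor and an order below developed amplitudes.

# Design choices and numerical parameters

| quantity | value | note |
|---|---|---|
| grid | 216 x 48, 24 canopy layers | baseline channel 43.2 x 1 |
| `dx`, `dt` | 0.2, 0.1 | advective CFL ≈ 0.65 (u), ≈ 0.85 (w) |
| analysis length `L` | 36 | sponge over [36, 43.2] |
| blade segments | 25 | resolution-matched to the canopy layers |
| blade relax / tol | 0.5 (adaptive) / 1e-6 rad | see above |
| theta (free surface) | 0.55 | unconditionally stable, mildly damping |
| kernel width | 0.3 dx, truncated 3 sd | force-conserving, renormalized |
| sec(theta) clamp | 1.45 rad | never active in the swept regime |
| onset / stability thresholds | 1e-3 / 1e-4 | an order above the noise floor |

Further choices worth recording:

* **Force deposition in z.** The Gaussian kernel is specified in x only;
  vertically, each blade segment deposits its force onto the canopy cell
  rows it overlaps, proportionally to overlap length — conservative and
  second order. Boundary columns are padded with replicas of the edge
  blades so that a horizontally uniform canopy receives an exactly uniform
  force (otherwise the inlet columns would see a spurious drag deficit and
  the base state would not be discretely steady).
* **Canopy height.** The natural cubic spline through the blade tips
  interpolates the tips at the roots, so `h_g(x_i)` equals the tip height
  of blade `i`, clipped to `[0.05 r, 0.999 h]` as a guard never active in
  practice.
* **Tracer.** The advection scheme for `C` is monotone (van Leer) so that
  limiter over/undershoots cannot corrupt the signed flux `w C'`; the
  inlet Dirichlet condition keeps the upstream unperturbed region at the
  reference state. The exchange integral is evaluated at the fixed steady
  canopy-top level, not the instantaneous one.
* **Sign conventions.** The drag on the blade is oriented downstream for
  downstream flow (the orientation-invariant form
  `(1/2)(u.n)|u.n| n`); a literal reading of the normal-vector convention
  with a leading minus would deflect blades upstream, contradicting the
  deflected shapes the model is built to reproduce.
* **Uniform-flow oracle.** The straight-blade equilibrium satisfies
  `tan(theta) (beta - u^2 cos^2(theta) sin(theta) / 2) =
  (u^2/2) cos^3(theta)`; the vertical drag component in the denominator is
  retained (dropping it shifts the root by several degrees at moderate
  speeds, although it moves the baseline canopy height by under `1e-5`
  because canopy-interior speeds are small).

# What the tests show, and at what scale

The property suite runs the full-width channel for short windows (discrete
steadiness, divergence, budget closure) and small channels for the
conservation fixtures. The developed-street checks in the acceptance suite
use a half-length channel (108 columns, analysis length 18, measuring
window `x in [8, 17]`, full `t = 500` run) so the whole suite stays within
a desk-scale budget; the stability-corner sweep uses the half channel to
`t = 200` with averaging over `[120, 200]`, long after both corners have
reached their long-term behaviour. The acceptance script
(`scripts/acceptance.R`) runs the full 216-column baseline to `t = 500`,
about ten minutes on one core. Onset at the baseline occurs near `t = 47`
in both channel lengths.

The momentum-budget closure is verified on a rigid-canopy, drag-free
configuration where the grid stays static, because the re-mapping of a
deforming grid exchanges momentum between cells in a way that is accounted
for as its own budget term rather than a conserved flux.

# What the synthetic conditions do and do not show

All inputs are synthetic: the model's own steady state plus seeded white
noise. Passing tests therefore demonstrate internal consistency of the
discretisation and reproduction of the published baseline phenomenology
(onset near `t = 50`, a convectively propagating street with speed ≈ 0.6,
period ≈ 4.5, wavelength ≈ 2.7, grass most erect beneath the vortex
cores, exchange plateauing after `t = 300`). They do not demonstrate
fidelity to any real seagrass meadow: the eddy viscosity is constant, the
spanwise direction is absent (no secondary instabilities or vortex
braiding), blades are identical and evenly spaced, and wave forcing,
sediment, and blade-blade interaction are all outside the model.

# Known limitations

* The vertical velocity rms profile of the developed street is flat over
  `z ≈ 0.55–0.68`, so the "vortex-core height" defined as its argmax is
  ill-conditioned at the 0.1-depth level; the propagation speed matches the
  steady velocity at the upper end of that plateau (the critical layer)
  rather than at the argmax itself.
* Tracer exchange magnitudes inherit the numerical diffusion of the
  limited advection scheme; trends in `(Re, beta)` are robust, absolute
  values of `Phi` are scheme-dependent.
* The explicit drag coupling lags one step; at `dt = 0.1` this is
  invisible in the diagnostics but would matter for much stiffer blades or
  longer steps.
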