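---
title: "Methods: stage-switched radial diffusion modelling of catheter drug release"
author: "cathflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stage-switched radial diffusion modelling of catheter drug release}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The physical model and its assumptions

`cathflux` models drug transport through the wall of a silicone Foley
catheter segment as one-dimensional radial diffusion in an annulus,
C(r, t) with R1 < r < R2, governed by Fick's second law with a constant
diffusivity D.  The assumptions behind this reduction are worth keeping
explicit:

* **Strictly radial transport.**  End faces are sealed during the
  experiments being emulated and the segment (2.5 cm) is long relative to
  the 1 mm wall, so axial and azimuthal gradients are neglected.  The
  balloon-inflation orifice and the catheter tip are not modelled.
* **One diffusivity for coated and uncoated walls.**  A layer-by-layer
  polyelectrolyte coating is of micron scale, roughly a thousandth of the
  wall thickness, so its contribution to the diffusion path is negligible;
  its strong effect on loading and release is carried entirely by the
  equilibrium partition coefficients at the outer surface.
* **No reaction terms.**  The drug neither degrades nor binds irreversibly
  on the 15-day scale of interest.
* **Interface equilibrium via partition coefficients.**  At the outer
  surface the wall-side concentration is tied to the adjacent liquid by a
  dimensionless partition coefficient gamma (gammaL against the loading
  bath, gammaD against the delivery bath), optionally through a finite
  surface mass-transfer (Robin) coefficient k.  The well-mixed limit
  k >> D, selected by `k = Inf`, replaces the Robin condition by its
  Dirichlet reduction; this is the default because both baths are stirred.
* **Stage switching.**  The outer boundary condition changes at the stage
  boundaries t0 (end of loading) and t1 (end of rest): concentrated bath,
  then sealed surface, then coupling to the delivery reservoir whose
  concentration CD(t) evolves by an ODE with CD(t1) = 0.  The inner surface
  is zero-flux throughout (the lumen is closed and holds air).

## Parameters, units and defaults

Canonical units are centimetres, hours and micrograms everywhere, so
concentrations are ug/cm^3 and D is cm^2/h; this matches the scale on which
the reference constants are quoted and avoids mixed-unit float trouble.

| Parameter | Meaning | Default | Notes |
|---|---|---|---|
| D | wall diffusivity | 1.744e-5 cm^2/h | shared by both conditions |
| gammaL | wall/loading-bath partition | 1.478 (control), 3.928 (LbL) | |
| gammaD | wall/delivery-bath partition | 0.7688 (control), 1.282 (LbL) | |
| CL | loading-bath concentration | 1330 ug/cm^3 | 1.33 mg/mL |
| kL, kD | surface mass-transfer coefficients | `Inf` (well-mixed) | cm/h when finite |
| V | delivery-bath volume | 250 cm^3 | `Inf` = pure sink |
| t0, t1, t_end | stage boundaries | 12, 36, 396 h | 12 h load, 24 h rest, 15 d delivery |

Two defaults deserve justification.  The delivery-bath volume is not a
published constant of the reference experiments; 250 cm^3 is a typical
shaker-bath volume and is effectively a sink for these loadings (the
equilibrium wall retention `gammaD * Vwall / (gammaD * Vwall + V)` is below
0.1%), and both a numeric override and an exact sink mode are exposed so
the sensitivity is user-visible rather than hidden.  Second, the catheter
size codes map only to the two measured diameter pairs (14Fr: 4.7/2.7 mm,
20Fr: 6.7/4.7 mm).  These differ from the nominal 1 Fr = 1/3 mm
convention, so arbitrary French sizes are deliberately not inferred; other
geometries are supplied explicitly through `catheter_geometry()`.

## Numerical scheme

The spatial discretisation is a finite-volume scheme on a uniform node grid
with half-cells at the walls: node i owns the annular shell bounded by the
midpoints to its neighbours, and the flux across a face at radius r_f is
`2 pi r_f L D (C_{i+1} - C_i) / h`.  Two properties motivate this choice
over direct finite differences of the expanded PDE: the cell volumes
telescope to the exact annulus volume, and inter-cell fluxes cancel
pairwise, so discrete mass is conserved identically — which is what makes
a mass audit a meaningful correctness check rather than a tolerance game.
Observed spatial accuracy is second order (the test suite measures the
Richardson order on a 51/101/201-node triplet of the loading uptake).

Time stepping is an implicit theta scheme, solved by a Thomas (tridiagonal)
factorisation computed once per stage and reused every step.  Implicit
Euler (theta = 1) is the default: each stage begins with a jump in the
boundary data (the surface concentration jumps to gammaL*CL at t = 0 and to
gammaD*CD ~ 0 at t1), and implicit Euler is unconditionally
positivity-preserving for this M-matrix system.  Crank–Nicolson
(theta = 1/2) is available and second order in time, but its sign-flipping
response to modes with `dt * lambda > 2` means the startup jumps produce
small oscillations unless `dt` is below about `h^2 / (2 D)`; the solver does
not clamp negative concentrations (that would silently corrupt the mass
audit) but raises an error when any value falls below `-1e-10` times the
field maximum, advising a smaller step.

During delivery the reservoir ODE is not operator-split from the PDE:
the reservoir concentration is appended as an extra unknown coupled to the
outermost wall node, and the whole system is solved monolithically each
step, because splitting leaks mass at exactly the tolerance the audit is
meant to certify.  In the well-mixed reduction the outermost half-cell is
slaved to the reservoir (`C(R2) = gammaD * CD`), so the two are merged into
one unknown with mass `gammaD * V_n + V`; its start value at t1 is chosen
so that the merged mass equals the half-cell's rest-stage content, which
keeps the discrete conservation statement exact despite the boundary-data
jump.  The reported reservoir trajectory still starts at CD(t1) = 0.

Other numerical conventions:

* Stage-boundary discontinuities belong to the later stage: the snapshot at
  t0 is the final loading state and the rest condition applies from the
  first step after t0.
* Nominal step sizes are rounded so an integer number of steps tiles each
  stage exactly; snapshots therefore cover t = 0, t0, t1 and t_end.
* Default resolution is 201 nodes with steps of 0.01 h (load), 0.05 h
  (rest) and 0.1 h (delivery), which meets all audit and oracle tolerances
  in well under a second per simulation.
* In pure-sink mode the release is computed from the wall-mass decrement,
  and the audit compares that decrement against the time-integrated
  boundary flux using the scheme's own end-of-step quadrature — the exact
  discrete conservation identity of implicit Euler — rather than an
  extraneous trapezoidal rule.

Two closed forms serve as independent oracles: the semi-infinite loading
uptake `2 gammaL CL sqrt(D t / pi)` (valid while `sqrt(D t)` is small
against the wall thickness; `short_time_uptake()`), and the finite-bath
equilibrium `CD_inf = M(t1) / (gammaD * Vwall + V)`
(`equilibrium_reservoir()`).  The test suite holds the solver to 1% and
0.5% agreement with these, and to 0.1% agreement between the Robin solution
at k = 1e4 cm/h and the well-mixed reduction.

## Parameter estimation

`fit_release_parameters()` estimates the free parameters — by default one
shared D plus per-condition gammaL and gammaD — by bound-constrained
Levenberg–Marquardt least squares (`minpack.lm::nls.lm`) on the residuals
between simulated and observed cumulative release at the observed times.
The optimiser works in log-parameter space, which enforces positivity,
makes steps scale-free across parameters spanning five orders of magnitude,
and (the tests verify) agrees with a linear-space fit on clean data.  The
objective is unweighted by default since release values within a study span
less than one order of magnitude; a relative-weighting mode is available
for heteroscedastic data.  Jacobians are numerical: the simulator residuals
are smooth but no analytic derivatives are available.  A candidate that
crashes the solver contributes large-but-finite penalty residuals so the
search can back away rather than abort, and non-convergence is reported as
a flag with best-so-far values rather than as an exception.

Identifiability shapes the design.  A single release profile constrains the
loading phase mainly through the product `gammaL * sqrt(D)` (the
square-root uptake law), so the D–gammaL confidence region of a
single-profile fit is strongly elongated; the test suite measures a
curvature (J'J) condition number on that block more than an order of
magnitude worse than the joint fit's.  Fitting all conditions and sizes
jointly with a shared D is therefore the default, and a shared-D fit on a
single condition emits a warning.  The delivery partition coefficient
gammaD is intrinsically weakly identified when the bath is nearly a sink —
its main observable effect is a mild late-time back-pressure — which is
visible in its larger curvature-based uncertainty; with noise-free data it
is still recovered to optimizer precision.

## The synthetic-data generator

`synthetic_release_dataset()` emulates the standard study design: four
cumulative-release profiles (control and coated conditions on both
geometries), 20 sample times per profile front-loaded toward the first two
days — the burst phase carries most of the information about D and
gammaL — and additive Gaussian observation noise clamped at zero.  The
noise model's `"relative"` mode scales the standard deviation with each
point's model value (3% by default), its `"absolute"` mode uses a constant
sd in ug/cm^2; real replicate scatter for this kind of assay is only known
to triplicate-error-bar resolution, so the scale is a free parameter
everywhere.  The generator calls `simulate_protocol()` itself — one code
path for the mean curve, so a zero-noise profile equals the solver output
exactly and closed-loop fits are free of generator/fitter drift.

What the generator does *not* emulate, and hence what passing closed-loop
tests do not establish about laboratory data: systematic model error
(coating-specific diffusivity, drug binding, bath depletion or
evaporation), correlated errors across time points from shared calibration,
sampling-time uncertainty, and inter-device variability beyond the noise
model.  Recovery results on synthetic data are a check of the estimator,
not a validation of the transport model itself.

## Problem sizes used by the tests

The forward-simulation checks run at the default resolution.  Closed-loop
fitting tests use reduced, internally consistent problem sizes (61–101
nodes, steps of 0.05–1 h) shared between generator and fitter; since both
sides use one code path, parameter recovery is insensitive to the
resolution, and the package's Monte-Carlo repeatability study (20 seeded
replicates at 3% noise) characterises the estimator's statistical spread,
with the median error of D held below 10%.  The oracle comparison for the
early-time uptake uses 801 nodes and 2e-5 h steps so that discretisation
error sits well inside the 1% comparison band.

## Known limitations

* The model is 1-D radial; devices with open lumens or unsealed ends need
  a different domain.
* A single D cannot represent thick coatings; a two-layer diffusivity
  field is out of scope.
* Empirical release laws (Higuchi, Korsmeyer–Peppas) are deliberately not
  fitted; the package is about the mechanistic model.
* Crank–Nicolson is provided for smooth regimes only; with stage-boundary
  jumps at practical step sizes, implicit Euler is the right tool.
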