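---
title: "Modelling laser interstitial thermal therapy with littsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling laser interstitial thermal therapy with littsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

littsim simulates laser interstitial thermal therapy (LITT) of brain
tissue: a water-cooled catheter with a cylindrical diffusing tip is
inserted into the lesion, near-infrared laser light (1064 nm, with 980 nm
as a control parameter set) is scattered radially into the tissue, the
absorbed power heats the tissue, and the accumulated thermal dose
coagulates it. The package predicts the temperature field over time and
the final ablation boundary, and provides MR proton-resonance-frequency
(PRF) thermometry utilities for comparing simulated temperature
time-courses with phase-image measurements.

This vignette is the package's methods reference: the governing models,
the numerical choices, the tunable parameters, and what the built-in
verification does and does not establish.

## Geometry and grid

The applicator is modelled in 2D axisymmetric cylindrical coordinates
(r, z), z along the fiber axis, centred on the diffuser midpoint. The
diffuser has length `L1` (clinically 4 or 10 mm) on a catheter of outer
diameter `D1` (1.55 or 2.3 mm). `build_grid()` constructs a
vertex-centred finite-volume lattice with target node distance 0.2 mm, a
spacing at which the discretization errors of every stage are at the
percent level or below (the grid-refinement tests bound them).

Three choices here were genuinely open:

* **Domain size.** The far boundary is held at body temperature, so it
  must sit far enough away not to influence the ablation zone. The
  default 40 mm radius and +/-40 mm axial half-length keep the
  far-boundary perturbation of the centre temperature below 0.1 degC for
  clinical powers and durations (the perfusion screening length
  `delta = sqrt(k / (rho_b c_b omega_b))` is 5.2 mm, so 40 mm is nearly
  eight screening lengths).
* **Wall anchoring.** Control-volume faces are placed midway between
  nodes *except* at material interfaces, where the face coincides with
  the interface. The first tissue node sits exactly at `r = D1/2`, so
  tissue region volumes are analytically exact and boundary conditions
  apply at their physical radius. One interior node resolves the
  polycarbonate catheter wall (thickness of one grid spacing, capped at
  `D1/4` on coarse grids); the node inside it is the isothermal cooled
  boundary.
* **Coolant.** The coolant flow is not modelled; the inner catheter wall
  is an isothermal Dirichlet surface at 25 degC. This overestimates the
  cooling capability slightly (the real coolant warms by a few degrees
  along the tip) and is a known limitation shared with the model family
  this package implements.

## Radiative transfer

Two solvers compute the fluence rate `phi` (W m^-2) from the same
diffuser description; both assume index-matched, isotropic, homogeneous
tissue with absorption `mu_a`, scattering `mu_s` and Henyey-Greenstein
anisotropy `g`. The brain parameter sets are mu_a = 50 m^-1,
mu_s = 5700 m^-1, g = 0.9 at 1064 nm and mu_a = 90 m^-1,
mu_s = 7800 m^-1, g = 0.95 at 980 nm.

**Monte Carlo** (`launch_photons()`). Weighted photon packets are
launched uniformly over the diffuser cylinder with cosine-weighted
(Lambertian) outward angles -- the angular law of a diffusely emitting
surface; the emission law is not otherwise constrained by the device
description. Free paths are exponential with mean `1/(mu_a + mu_s)`;
implicit capture multiplies the weight by the single-scattering albedo at
each collision and tallies the absorbed fraction; Russian roulette
(threshold 1e-4, survival 0.1) terminates low-weight packets without
bias. Fluence uses the collision estimator `sum(w/mu_t)/V` per cell,
which is efficient here because the scattering mean free path (~0.17 mm)
is below the cell size. The per-cell standard error is estimated from ten
photon sub-batches. The kernel runs on its own counter-seeded xoshiro256++
stream, so a run is reproducible from its seed alone on any platform.

**P1 / diffusion approximation** (`solve_p1()`). The fluence solves
`-div(D grad phi) + mu_a phi = 0` with
`D = 1/(3 (mu_a + mu_s (1 - g)))`, discretized flux-conservatively on the
same grid (symmetric positive-definite sparse system, one direct solve;
the discrete residual is verified below 1e-8). Far boundaries use the
zero-incident Marshak partial-current condition.

**Source coupling and the catheter.** The governing equation has no
volumetric source, so light must enter through the diffuser surface. Two
coupled choices were open; both are set by physical argument and both
alternatives remain available as options:

* The diffuser face carries a *prescribed net influx*
  `P/(pi D1 L1)`, which injects exactly the source power regardless of
  tissue albedo. The textbook alternative -- imposing the incident
  partial current `J- = q` -- over-injects when the tissue scatters
  little light back (with the 980 nm parameters it injects 7% more than
  the nominal power, violating energy accounting), so it is not the
  default.
* The catheter is transparent: in the Monte Carlo solver a photon whose
  free path re-enters the lumen crosses it without interaction and
  continues on the far side (the crossing is resampled exactly using the
  memoryless property of the exponential path length); in P1 the
  non-diffuser wall is reflecting. A water-filled 1.55 mm lumen absorbs
  only a few percent of the light crossing it at these wavelengths.
  Terminating such photons instead (`lumen = "terminate"`,
  `catheter = "absorbing"`) discards 8% of the power at 1064 nm versus
  6% at 980 nm; that asymmetry is large enough to invert the modelled
  wavelength ordering of ablation diameters, so termination is not the
  default.

The two solvers agree closely where it matters: the Pearson correlation
of their radial fluence profiles (sampled 0.5--10 mm beyond the catheter
wall at 0.5 mm steps on the mid-plane) exceeds 0.99 for both the
4 mm / 10 W and the 10 mm / 15 W setups, with no significant paired
difference; profiles are compared raw (unnormalized) by default, with a
peak-normalized mode available. Each solver is also verified against the
infinite-medium diffusion Green's function
`phi = P exp(-mu_eff r)/(4 pi D r)` in an isotropic point-source harness
(within 10% for Monte Carlo and 5% for P1 over r = 2--10 mm; the
systematic part of the Monte Carlo deviation is the expected failure of
diffusion theory near a source). The default pipeline backend is P1; the
Monte Carlo solver is retained for validation, at roughly two orders of
magnitude more compute.

A note on the transport equation: the in-scattering term of the radiative
transfer equation is sometimes printed with a spurious `3 mu_s` factor in
this model family; the Monte Carlo kernel implements the standard
radiative transfer equation with the Henyey-Greenstein phase function.

## Bioheat transfer

`solve_pennes()` integrates the Pennes equation

    rho c dT/dt = div(k grad T) + rho_b c_b omega_b (T_b - T) + Q_r

with brain tissue rho = 1040 kg m^-3, c = 3590 J kg^-1 K^-1,
k = 0.503 W m^-1 K^-1, blood rho_b = 1050, c_b = 3640,
omega_b = 0.0048 s^-1, T_b = 37 degC, and `Q_r = mu_a phi` from the
optics stage. Metabolic heating is omitted: against a source that drives
the tissue to coagulative temperatures it is negligible. The coupling is
one-way and the properties temperature-independent -- the model family's
standard simplification; vaporization, desiccation and dynamic perfusion
are out of scope.

Discretization is finite-volume with material-resolved series
conductances at interfaces (polycarbonate wall layer: k = 0.341,
rho = 1300, c = 2300; no perfusion or source in the wall). Time stepping
is implicit backward Euler (default dt = 0.25 s; an explicit scheme would
need ~10 ms steps on a 0.2 mm grid), with Crank-Nicolson available where
second-order accuracy in time matters. The linear system is factored once
(sparse Cholesky) and reused every step. The laser switches off after the
irradiation time; a step straddling the switch uses the on-fraction.

Verified properties: uniform body temperature is an exact steady state;
pure perfusion decay matches `exp(-rho_b c_b omega_b t/(rho c))` to
better than four digits (Crank-Nicolson); the steady perfused
point-source solution matches `T - T_b = P exp(-r/delta)/(4 pi k r)` with
delta = 5.24 mm within 5%; the discrete energy balance closes per step
under adiabatic test boundaries; the solution obeys the maximum principle
without a source; and halving dt changes the 120 s peak temperature by
well under 0.5%.

## Thermal damage and the ablation boundary

`integrate_arrhenius()` accumulates the first-order injury integral

    Omega(r,z) = integral A exp(-Ea / (R T(t))) dt

with A = 3.1e98 s^-1, Ea = 6.28e5 J mol^-1, R = 8.31 J mol^-1 K^-1 and T
in kelvin; `Omega = 1` (63% denaturation) defines irreversible damage.
The activation energy is treated as J mol^-1 -- kinetics are not
dimensionally consistent otherwise -- and the perfusion rate as s^-1; the
integrand is evaluated in log space so the enormous pre-exponential
factor never overflows. No low-temperature cutoff is applied:
sub-coagulative temperatures contribute their true, negligible rate
rather than an artificial zero.

Integration uses the trapezoidal rule over stored temperature snapshots
(default every 2 s) rather than every solver step, bounding memory on
fine grids; a tenfold-finer reference integration bounds the resulting
error at the percent level for realistic heating histories, which moves
the steep `Omega = 1` isoline by far less than one grid spacing. Damage
integration continues through a 10-minute post-laser cool-down by
default, matching the timing of post-ablation imaging; the contribution
is small and a `cooldown: 0` setting disables it.

`ablation_boundary()` extracts the `Omega = 1` isoline by marching
squares with linear sub-cell interpolation, reports the maximum
cross-section diameter `D2 = 2 max(r)` over the contour -- the quantity
compared against post-ablation imaging -- and the enclosed axisymmetric
volume. Under identical power, duration and geometry the 980 nm
parameter set yields a strictly smaller ablation diameter than 1064 nm,
reproducing the qualitative wavelength ordering; in this
constant-property model the margin is small (tenths of a millimetre at
15 W / 120 s), since at equal injected power the two parameter sets
redistribute rather than change the deposited energy.

## PRF thermometry

MR thermometry converts phase changes of a spoiled gradient-echo
acquisition to temperature changes via

    dT = dphi / (2 pi a gamma B0 TE)

with sensitivity a = -0.010 ppm/degC, proton gyromagnetic ratio
gamma = 42.58 MHz/T (the ratio is occasionally misprinted as Hz/T; only
MHz/T makes the expression dimensionless), B0 = 3 T, and protocol echo
times of 7 ms (canine protocol, slope -0.0562 rad/degC) or 12 ms (human
protocol, magnitude 0.0963 rad/degC). The sign convention is kept
explicit: heating produces a negative phase shift. `series_to_temperature()`
references each pixel to the mean of five pre-laser baseline frames, so
any frame-common phase offset cancels exactly; a wrapped-phase mode
performs temporal unwrapping first.

Because no measured phase series ships with the package,
`synthesize_mrt()` generates one from a simulated temperature field: the
axisymmetric field is resampled onto a Cartesian pixel slice through the
axis (default pixel 1.46 mm = 210 mm field of view / 144 matrix),
averaged over each pixel footprint -- thermometry reports pixel-average
temperature, one of the known sim-vs-measurement differences -- inverted
to phase, prefixed with baseline frames (6 s frame spacing), and
degraded with Gaussian phase noise. The default noise level in examples
(about 0.056 rad, i.e. ~1 degC through the canine-protocol slope) is a
plausible stand-in chosen by the package, not a measured property; the
round-trip and noise-propagation tests hold for any level. What the
synthetic series cannot emulate: susceptibility and drift artifacts,
tissue heterogeneity, dehydration and shrinkage near the applicator --
so agreement on synthetic series validates the conversion chain, not the
fidelity of in-vivo thermometry.

## Problem sizes and determinism

The verification suite runs the optics validation at one million photons
per setup on the 0.2 mm grid, and the coupled two-wavelength comparison
at 0.4 mm spacing with 0.5 s steps -- resolutions at which the
grid- and step-refinement checks above bound the discretization error
well below the effects being tested. All stochastic stages take explicit
seeds: a Monte Carlo run is a pure function of its
`photon_batch(n, seed)`, and `run_ablation()` reruns bit-identically for
a fixed configuration and seed, which the manifest checksums make easy
to audit.

## Known limitations

Homogeneous, temperature-independent tissue; static perfusion; no
vaporization or charring (core temperatures above 100 degC are reported
as-is and should be read as "beyond coagulative"); isothermal coolant
wall; 2D axisymmetry (no tissue interfaces, ventricles or vessels); the
diffuser is perfectly uniform along its length. These match the
assumptions of the model family the package implements; predictions
nearest the applicator core and at tissue boundaries carry the largest
model error.
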