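# littsim

Numerical simulation of **laser interstitial thermal therapy (LITT)** in
brain tissue with a water-cooled diffusing-tip applicator, for researchers
and device engineers who need to predict temperature fields and ablation
extents at 1064 nm (with 980 nm as a control parameter set) and to compare
simulations against MR thermometry.

The package couples three physics stages on a shared 2D axisymmetric
finite-volume grid (0.2 mm default node distance):

1. **Radiative transfer** — the fluence rate φ around the cylindrical
   diffuser, either by weighted-photon Monte Carlo (implicit capture +
   Russian roulette, collision estimator) or by the P1 diffusion
   approximation
   −∇·D∇φ + μ\_a φ = 0, D = 1/(3(μ\_a + μ\_s(1−g))),
   solved as one sparse SPD system. The absorbed power density
   Q\_r = μ\_a φ feeds the thermal stage.
2. **Bioheat transfer** — the Pennes equation
   ρc ∂T/∂t = ∇·k∇T + ρ\_b c\_b ω\_b (T\_b − T) + Q\_r,
   implicit time stepping, isothermal 25 °C cooled catheter wall,
   37 °C body-temperature far field.
3. **Thermal damage** — the Arrhenius injury integral
   Ω = ∫ A exp(−E\_a/(R T)) dt; the ablation boundary is the Ω = 1
   isoline (63 % protein denaturation) and the reported diameter is
   D2 = 2·max r over that contour.

PRF thermometry utilities convert phase-image series to temperature maps
(ΔT = Δφ/(2π a γ B₀ TE)) and compute the difference statistics used to
compare simulated and measured temperature time-courses; a synthetic
MRT-series generator stands in for in-vivo acquisitions.

Brain, blood, cooling-water and polycarbonate parameter sets ship in a
material library with unit-tagged values and SI normalization.

## Worked example

Simulate a 15 W, 120 s ablation with a 10 mm diffuser tip (1.55 mm
catheter) on a 0.4 mm grid, including a 10-minute post-laser cool-down:

```r
library(littsim)

res <- run_ablation(list(
  laser  = list(wavelength = "1064nm", power = 15, duration = 120),
  grid   = list(spacing = "0.4 mm"),
  solver = list(dt = 0.5, cooldown = 600, snapshot_interval = 2)
))

res$ablation
#> Ablation result (Omega >= 1): diameter 19.92 mm, volume 4261.0 mm^3

temperature_at_probes(res$temperature, res$grid,
                      cbind(c(5.6e-3, 7.0e-3, 8.4e-3), 0))[c(31, 61), ]
#>    time  T_1  T_2  T_3
#> 31   60 77.9 63.4 53.5
#> 61  120 95.4 78.2 65.0
```

The probe table gives the temperature time-course (°C) at 5.6, 7.0 and
8.4 mm from the fiber axis on the diffuser mid-plane: the centre heats
fastest, peripheral heating decelerates, and the Ω = 1 contour reaches a
final maximum cross-section diameter of ~20 mm. Rerunning the same
configuration with `wavelength = "980nm"` gives a strictly smaller
diameter — the control wavelength deposits its energy more compactly.

Validate the fast P1 solver against Monte Carlo (radial fluence profiles
0.5–10 mm beyond the catheter wall):

```r
v <- run_p1_mc_validation(photons = 1e6, seed = 1)
v$L1_4mm_10W$stats
#> Profile comparison (n = 20): r = 0.9993 (p = 2.96e-27), paired t p = 0.599
#>   difference std = 9237, median = 609.8
v$L1_10mm_15W$stats
#> Profile comparison (n = 20): r = 0.9992 (p = 1.22e-26), paired t p = 0.0758
#>   difference std = 5414, median = 736.2
```

A thin command-line wrapper is installed at `inst/cli/littsim`
(`littsim ablate -c config.yaml -o out/`, `littsim validate-optics`,
`littsim mrt-sim`); `inst/extdata/default_config.yaml` documents every
configuration field.

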