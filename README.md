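# cortexgel

Mechanochemical simulation of the excitable actomyosin cell cortex in R.

The actin cortex couples an excitable signalling circuit — the GTPase RhoA
activating assembly of contractile actomyosin, which in turn inactivates
RhoA — to the mechanics of the gel that the circuit builds. Depending on
just two knobs, the basal RhoA activation rate *S* and the active
contractile stress, this system sits quiescent, fires isolated pulses,
oscillates, contracts, forms stationary contractile patterns, propagates
waves, or develops defect-mediated phase turbulence. `cortexgel` implements
the full model hierarchy for researchers studying cortical dynamics and
mechanochemical pattern formation:

* **Reaction circuit** — rates
  `R_r = S + a r^n/(r_a^n + r^n) - g m r/(r_g + r)` and
  `R_m = S_m + k_a r^2 - k_d m`, with nullclines, fixed points and
  stability (`chem_params()`, `find_fixed_points()`).
* **Well-mixed mechanochemical ODE model** — a viscoelastic element whose
  strain dilutes both species (`simulate_local()`), with regime
  classification and phase diagrams over any parameter pair
  (`classify_local()`, `phase_diagram_local()`).
* **1D and 2D active-gel PDE models** — Maxwell gel on a periodic domain,
  `tau v_t = -v + lambda^2 grad^2 v + sigma' grad(m/(m0+m))`, advecting
  both species (`simulate_1d()`, `simulate_2d()`), with stimulus
  protocols including transient local activation
  (`local_activation_experiment()`) and kymograph classification
  (`classify_spatial()`).
* **Linear stability analysis** — dispersion relations, fastest-growing
  modes, wavelength/frequency/wave-speed maps (`dispersion()`,
  `stability_map()`).
* **Phase-field topology** — oscillation-phase extraction, defect
  detection by plaquette winding numbers, phase velocity and vorticity,
  energy–enstrophy statistics, and power-law tail fits of phase-speed
  distributions (`extract_phase()`, `find_defects()`,
  `speed_tail_exponent()`).

## Worked example

Fixed-point structure and excitability at a weak stimulus:

```r
library(cortexgel)
p <- chem_params(S = 0.002)
find_fixed_points(p)
#>             r          m stability oscillatory          re1          re2
#> 1 0.002142468 0.09179525    stable       FALSE -0.697425997 -0.082830951
#> 2 0.024999309 0.09285018    saddle       FALSE  0.231634686 -0.079942256
#> 3 0.511106639 0.53600463    stable        TRUE -0.004616262 -0.004616262
```

Three fixed points: a stable rest state at low RhoA, an excitation
threshold (the saddle at `r ≈ 0.025`), and a high-concentration focus.
Starting from an empty cortex, the basal drive pushes the state over the
threshold once, producing a single pulse before settling back:

```r
tr <- simulate_local(p = p, t_end = 2000)
classify_local(tr)
#> local regime: excitable
```

In the continuum model the same chemistry coupled to contractile flow
destabilises the homogeneous state into travelling waves. Linear stability
analysis at `S = 0.01` s⁻¹ with the default active stress:

```r
p2 <- chem_params(S = 0.01)
fp <- find_fixed_points(p2)
dispersion(fp[1, ], p2, gel_params(sigma_prime = 49.8))
#> dispersion relation: k in (0, 1.5 ] 1/um
#>   k* = 0.2344 1/um, max growth = 0.01467 1/s, UNSTABLE
#>   wavelength = 26.8 um, frequency = 0.131 1/s, speed = 0.557 um/s
```

The fastest-growing mode has a 27 µm wavelength (about two hydrodynamic
lengths) and travels at 0.56 µm/s; running `simulate_1d()` at these
parameters and classifying the kymograph shows the corresponding
wave/pulsatile-flow states, and `local_activation_experiment()`
reproduces the three responses to a transient local RhoA burst (bistable
front at low stress, solitons at moderate stress, a pinned contractile
peak at high stress).

A command-line interface wrapping these functions ships in
`inst/cli/cortexgel` (subcommands `simulate-local`, `simulate-1d`,
`simulate-2d`, `linstab`, `phase-diagram-local`, `defects`,
`make-fixture`; all accept `--config`, `--seed`, `--out`).

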