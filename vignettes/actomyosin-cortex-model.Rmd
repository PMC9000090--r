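---
title: "Modelling the excitable actomyosin cortex: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the excitable actomyosin cortex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cortexgel)
```

## The model

`cortexgel` simulates the coupling between the RhoA signalling circuit and
the mechanics of the actomyosin cortex. Two species are tracked: active
RhoA, `r` (a fast-diffusing activator), and a combined F-actin/myosin
species, actomyosin `m` (a slow-diffusing inhibitor of RhoA and the source
of contractile stress). The reaction terms are

$$R_r = S + a\,\frac{r^n}{r_a^n + r^n} - g\,m\,\frac{r}{r_g + r},
\qquad
R_m = S_m + k_a r^2 - k_d m,$$

with basal (GEF-driven) activation $S$, autocatalytic activation saturating
at $r_a$, and F-actin-recruited GAP inhibition saturating at $r_g$. The
default constants (see `chem_params()`) are the calibrated values for the
*C. elegans* cortex; concentrations are dimensionless and rates are per
second. The Hill exponent $n$ is an explicit parameter with default 1, in
which case the autocatalytic term is the plain Michaelis form. The
inhibition term carries no separate Hill exponent: the saturating form in
$r$ with threshold $r_g$ is used exactly as written above.

Three levels of mechanical coupling are implemented:

* **Well-mixed model** (`simulate_local()`): a homogeneous cortex patch is a
  Kelvin–Voigt element with strain $u$, loaded by a saturating active
  stress, $\eta_L \dot u + E u = -\sigma_a m/(m_0+m)$. Strain changes
  dilute or concentrate both species through mass conservation,
  $\dot c_{\mathrm{dil}} = -c\,\dot u/(1+u)$, which is the entire
  mechanical feedback at this level.
* **1D active gel** (`simulate_1d()`): a periodic Maxwell gel with
  drag-scaled momentum balance
  $\tau \dot v = -v + \lambda^2 \partial_x^2 v +
  \sigma' \partial_x\!\big(m/(m_0+m)\big)$, where
  $\lambda = \sqrt{\eta/\gamma}$ is the hydrodynamic length and
  $\sigma' = \sigma_a/\gamma$. Both species are advected by $v$ and
  diffuse; only $\lambda$, $\tau$, $\sigma'$ survive as mechanical
  parameters after drag scaling, so the stress, drag, porosity and
  cytosolic-pressure variables of the underlying poroviscoelastic
  derivation are not represented individually.
* **2D active gel** (`simulate_2d()`): the compressible Stokes-like
  analogue with shear and bulk viscosities, $\eta_s = \eta/4$ and
  $\eta_b = 3\eta/4$ by default, sharing one Maxwell time $\tau$.

Linear stability of homogeneous fixed points (`jacobian_k()`,
`dispersion()`) uses the 3-variable Jacobian in $(r, m, v)$ at wavenumber
$k$; the damping entry of the mechanics row is $-(1 + \lambda^2 k^2)/\tau$,
i.e. the viscosity appearing there is the network viscosity $\eta$
(dimensionally the only consistent choice). When three fixed points exist
the analysis is evaluated at the stable point with the lowest RhoA
concentration, the branch on which a quiescent cortex sits.

### Parameters that matter

| parameter | meaning | default | unit |
|---|---|---|---|
| `S` | basal RhoA activation (stimulus) | 0 | 1/s |
| `a`, `r_a` | autocatalysis rate / threshold | 0.1609, 0.3833 | 1/s, conc |
| `g`, `r_g` | GAP feedback rate / threshold | 0.1787, 0.01 | 1/s, conc |
| `S_m`, `k_a`, `k_d` | actomyosin source / assembly / disassembly | 0.0076, 0.1408, 0.0828 | 1/s |
| `sigma_over_E` | local contractility $\sigma_a/E$ | 0.2 | — |
| `tau_local` | local viscoelastic time $\eta_L/E$ | 5 | s |
| `tau` | Maxwell relaxation time | 5 | s |
| `lam` | hydrodynamic length $\sqrt{\eta/\gamma}$ | 14.3 | µm |
| `sigma_prime` | drag-scaled active stress $\sigma_a/\gamma$ | 49.8 | µm²/s |
| `D_r`, `D_m` | diffusivities | 0.1, 0.01 | µm²/s |
| `m0` | actomyosin at half-maximal stress | 1 | conc |

`m0` is not a measured constant; it is set to 1, the order of the
steady-state actomyosin concentration, and exposed everywhere as a
parameter. The two control knobs explored by every phase diagram are `S`
and the active stress (`sigma_over_E` locally, `sigma_prime` in the
continuum).

## Initial conditions and the synthetic-data generator

The model's behaviour is strongly multistable, so initial conditions are
part of the experimental design:

* **Well-mixed runs** start from an unstressed empty cortex,
  $(r, m, u) = (0, 0, 0)$. Starting with the inhibitor absent lets basal
  activation probe excitability directly: at $S = 0$ nothing fires and
  actomyosin rises monotonically to its basal balance $S_m/k_d$
  (quiescence), at $S = 0.002\,\mathrm{s^{-1}}$ a single autocatalytic
  pulse fires before the low fixed point is reached (excitability), and at
  higher $S$ the limit cycle or the contracted state take over. A
  pre-equilibrated start $(0, S_m/k_d, 0)$ would hide the excitable regime
  entirely (the low fixed point captures the trajectory below threshold),
  while any fixed supra-threshold kick would also fire at $S = 0$, where
  the excitation threshold is $r \approx 0.033$ versus $0.025$ at
  $S = 0.002$.
* **Continuum runs** (`init_field_1d()`, `init_field_2d()`) start at the
  uniform low reaction fixed point with multiplicative noise of relative
  amplitude $10^{-2}$ from a seeded RNG. Where the base state is linearly
  unstable (the wave and pulsatile-flow regimes) this noise is amplified by
  the instability itself and no further seeding is needed. At zero
  stimulus the resting state has $r = 0$ exactly and is linearly stable,
  so pattern formation there is triggered by an additional per-cell RhoA
  seed uniform in $[0, r_\mathrm{seed}]$ (default off; 0.08 in the
  zero-stimulus pattern runs). A seed straddling the excitation threshold
  makes sub-populations of cells fire, reproducing the initial excitable
  pulse from which contractile patterns condense.
* **Local-activation experiments** start from exact rest
  ($r = 0$, $m = S_m/k_d$, no noise) and apply a boxcar stimulus
  $S_{\mathrm{in}} = 0.03\,\mathrm{s^{-1}}$ in a centred box of width
  $\lambda$ for 100 s. The response is classified from the field after the
  stimulus ends.

What the generator does *not* emulate: molecular shot noise (fields are
deterministic apart from the seeded initial perturbation), curvature of
the real cortical surface, and any coupling to cell-shape change. Passing
tests therefore demonstrate properties of the deterministic flat-torus
model, not of noisy curved cortices.

## Numerics

Time stepping is operator-split per inner step: (1) velocity, (2)
transport, (3) reaction, with the inner step bounded by `dt_max` (0.25 s)
and an advective Courant number of 0.4, and output recorded at a fixed
1 s cadence.

* **Velocity** is advanced by backward Euler solved exactly in Fourier
  space on the periodic grid; in 2D the grad–div coupling is inverted in
  closed form per mode, so the linear mechanics is unconditionally stable
  and spectrally accurate.
* **Advection** is a conservative finite-volume flux update, van Leer
  (MUSCL) limited by default. First-order upwind is available
  (`method = "upwind"`) but its numerical diffusion at the default
  resolution ($\mathit{dx} \approx 1\ \mathrm{\mu m}$, comparable to
  $D_r$) measurably blurs sharp contractile peaks: with it, the
  stable-localized response of the activation experiment slowly leaks into
  solitons and pulsatile flows freeze into static peaks.
* **Diffusion** is backward Euler with the discrete-Laplacian symbol
  evaluated by FFT — identical to solving the implicit finite-difference
  system exactly, whose inverse is an M-matrix, so positivity is
  preserved. Means are conserved to machine precision by both transport
  parts; a drift above $10^{-8}$ per step raises an error.
* **Reactions** are explicit Euler at the inner step; concentrations are
  clipped at zero (with a warning if the undershoot exceeds $-10^{-12}$),
  and any field exceeding $10^6$ aborts the run with diagnostics.
* The well-mixed ODE system uses the adaptive Runge–Kutta 4(5) method from
  `deSolve`.

Degenerate inputs: the RhoA nullcline is undefined at $r = 0$ and that
point is masked; fixed-point duplicates closer than $10^{-6}$ in $r$ are
merged; root residuals above $10^{-10}$ are flagged. Dispersion scans
report `k_star = 0` when no interior maximum exists (homogeneous
instability), and branch identities are maintained by eigenvector-overlap
matching rather than magnitude sorting to avoid branch-swap artifacts.
Both the standard spectral conventions (wavelength $2\pi/k^*$, speed
$|\mathrm{Im}\,\lambda|/k^*$) and the alternative parameterisation
$1/(2\pi k^*)$, $|\mathrm{Im}\,\lambda|/(2\pi k^*)$ are reported
(`printed_formulas = TRUE`).

## Regime classification

`classify_local()` discards a transient (first quarter of the run) and
counts prominence-filtered actomyosin maxima: at least three sustained
maxima mean pulsatile; decaying oscillations or settling onto the
high-actomyosin branch mean contractile; a single large excursion followed
by settling onto the low branch means excitable; a monotone approach means
quiescent. The high/low branch is decided against the middle (saddle)
fixed point when three exist. Ambiguous trajectories carry a
`confident = FALSE` flag rather than a silently forced label. The
pulsatile call at $(S, \sigma_a/E) = (0.025, 0.2)$ is stable under ±20%
changes of the peak-prominence threshold.

`classify_spatial()` first separates uniform from patterned states by the
spatial coefficient of variation of actomyosin (threshold 0.05), then
classifies uniform states like the local model, and patterned states by
the space–time power spectrum of the kymograph window: fluctuation power
concentrated at zero temporal frequency marks a stationary localized
pattern; power concentrated in a few travelling modes (top four cells
holding over 20% of the travelling power) marks coherent propagating
waves; broadband power marks erratic pulsatile flows. Spectral
concentration proved far more robust than frame-to-frame peak tracking,
whose per-second displacements are sub-cell for every moving state at the
default resolution.

## Phase-field analysis

The oscillation phase is $\phi = \mathrm{atan2}(r - \bar r, m - \bar m)$,
with the RhoA deviation as the first argument so that the deviation ratio
matches $(r-\bar r)/(m-\bar m)$ and the phase winds monotonically around
the limit cycle; the four-quadrant form resolves the quadrant ambiguity of
a scalar arctangent. The reference means are space–time means by default;
per-pixel temporal means (`means = "pixel"`) remove static spatial
inhomogeneity from the deviations and are used for the energy–enstrophy
statistics. Defects are detected per 2×2 plaquette as the
$2\pi$-quantised circulation of branch-wrapped phase differences; on the
torus every edge is traversed twice in opposite directions, so the total
charge is identically zero in every frame — the detector's per-frame
balance of +1 and −1 defects is a corollary, not an approximation.

Two speed observables exist and differ materially:

* the **phase velocity** $v_\phi = \nabla\phi$ (used for the effective
  kinetic energy $\bar E = \tfrac12\langle v_\phi^2\rangle$ and enstrophy
  $\bar\Omega = \tfrac12\langle\omega^2\rangle$, $\omega = \nabla\times
  v_\phi$) is bounded by the grid at defect cores ($|\nabla\phi| \le
  \pi/\mathit{dx}$), so the extreme tail of its magnitude distribution is
  resolution-limited;
* the **speed of phase-field motion** $|\partial_t\phi|/|\nabla\phi|$
  (the front speed of the pattern) diverges at the smooth zeros of the
  phase gradient and exhibits the classic cubic power-law tail of
  defect-mediated turbulence over more than two decades, robustly across
  resolutions.

`phase_turbulence_analysis()` therefore accumulates motion speeds by
default (`speed_type = "gradient"` gives the other observable). The tail
exponent is the continuous maximum-likelihood (Hill-type) estimate with
the lower cutoff chosen by Kolmogorov–Smirnov minimisation inside the top
5% of samples; the KS-based `poor_fit` flag cleanly rejects exponential
tails, though for very large turbulent samples it is conservative (a KS
distance above $1.5/\sqrt{n}$ is flagged even when the scaling window
spans decades).

For the energy–enstrophy relation, $\bar\Omega$ is a pure defect measure
(the phase flow is irrotational away from cores), while $\bar E$ also
carries the coherent wave background. The wave states coarsen slowly —
the defect count is still decaying after 800 s — so the package's
cross-stress comparison equilibrates every run uniformly to 1600 s and
averages per-frame pairs over the final 300 s on a $96^2$ grid with box
$7.5\lambda$; under that protocol the six run means for
$\sigma' = 50\ldots100\ \mathrm{\mu m^2/s}$ are collinear.

## Problem sizes used by the shipped checks

The packaged tests and the acceptance script run the well-mixed model for
2000 s trajectories; 1D experiments on the reference grid ($N = 150$, box
$10\lambda$) for up to 900 s; the turbulence tail on a reduced 2D grid
($N = 64$, box $5\lambda$, 900 s, statistics over the last 300 frames);
and the energy–enstrophy sweep at $N = 96$, box $7.5\lambda$, 1600 s per
stress value. These sizes reproduce the qualitative phase structure and
the quantitative statistics stated above; the full-resolution 2D
reference configuration ($150^2$, box $10\lambda$) is available through
the same functions.

## Known limitations

* At the default 1D resolution, sharp contractile peaks equilibrate at a
  lower amplitude than at double resolution (numerical diffusion); their
  existence, position and stability are resolution-robust, their height is
  not.
* Zero-stimulus pattern formation from noise is multistable: depending on
  the seed the transient can condense into a pinned peak, keep coarsening
  for thousands of seconds, or die back to rest. Deterministic seeded-bump
  protocols are used where a unique answer is asserted.
* The classifiers are decision trees with documented thresholds; states
  near a phase boundary are flagged low-confidence rather than refined.
* No curved geometry, no cell-shape coupling, no stochastic chemistry.
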