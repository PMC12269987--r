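---
title: "Models and numerics behind nanotherm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerics behind nanotherm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanotherm)
```

nanotherm simulates localized magnetic hyperthermia of liver tumors in
two coupled stages: (i) linear-response-theory (LRT) heating of a
superparamagnetic nanoparticle colloid in an AC magnetic field, and
(ii) the temperature field that volumetric heat source produces in
perfused liver tissue under three conduction models of increasing
physical fidelity. This vignette is the package's own account of the
models, the parameter choices, and the numerical design — including the
choices we had to make where the problem is genuinely under-determined.

## 1. Nanoparticle heating

### Relaxation

A single-domain particle suspended in a carrier fluid loses magnetic
energy through two parallel channels. Brownian relaxation — rigid
rotation of the whole particle against viscous drag — has

$$\tau_B = \frac{3\eta V_H}{k_B T},$$

where $V_H = \pi(D+2\delta)^3/6$ is the hydrodynamic volume (core
diameter $D$ plus coating $\delta$ on both sides). Néel relaxation —
internal reversal of the moment over the anisotropy barrier
$\Gamma = K V_M / k_B T$, $V_M = \pi D^3/6$ — is implemented in two
conventional forms: the Arrhenius law $\tau_N = \tau_0 e^{\Gamma}$ and
the Rosensweig-prefactor form
$\tau_N = \tfrac{\sqrt{\pi}}{2}\,\tau_0\, e^{\Gamma}/\sqrt{\Gamma}$.
The prefactor form is the default because it is the one that belongs to
the LRT dissipation chain; the plain Arrhenius form is selectable
(`neel_form = "arrhenius"`) and both are tested. The channels combine
harmonically, $1/\tau = 1/\tau_N + 1/\tau_B$, so the faster mechanism
dominates; `relaxation_curve()` exposes the classic crossover diagnostic
in which $\tau_N$ sweeps through many orders of magnitude between 7 and
15 nm radius while $\tau_B$ only grows like $(r+\delta)^3$.

$\Gamma$ grows with $D^3$ and overflows `exp()` already near
$D \approx 26$ nm at liver temperature, so $\tau_N$ is evaluated in log
space and the effective time as
$\tau = \tau_B / (1 + e^{\ln\tau_B - \ln\tau_N})$; $\tau_N$ may be
reported as `Inf` but $\tau$ is always finite and tends to $\tau_B$.

### Susceptibility and power

LRT treats the colloid as a linear magnetic system driven at angular
frequency $\omega = 2\pi f$. With the Langevin parameter
$\xi = \mu_0 M_d H_0 V_M / k_B T$, the equilibrium (chord)
susceptibility is
$\chi_0 = \chi_i\,\tfrac{3}{\xi}\left(\coth\xi - \tfrac1\xi\right)$ with
$\chi_i = \mu_0 M_d^2 \varphi V_M / 3 k_B T$, and the loss component is
$\chi'' = \chi_0\,\omega\tau/(1+(\omega\tau)^2)$, giving the volumetric
dissipation $P = \pi \mu_0 H_0^2 f \chi''$. Assumptions worth keeping in
mind: the response is linear (strictly valid for $\xi \lesssim 1$;
at the default field $\xi \approx 12$, LRT is the conventional
engineering extrapolation used throughout this literature), particles
are non-interacting, and hysteresis/Stoner–Wohlfarth physics is out of
scope. For $\xi < 10^{-4}$ the chord is evaluated by its series
$1-\xi^2/15$, so the weak-field limit $\chi_0 \to \chi_i$ is exact and
free of catastrophic cancellation; the loss factor peaks at
$\omega\tau = 1$ with value exactly $\chi_0/2$, which the tests verify
by dense grid search.

### SLP bookkeeping

Calorimetry reports specific loss power $\mathrm{SLP} = C\,\Delta
T/\Delta t$ (W/kg); LRT predicts volumetric power (W/m³). The two are
linked by the particle mass concentration: $\mathrm{SLP} = P/(\rho_{np}
\varphi)$ and $Q_{np} = \mathrm{SLP}\cdot\gamma_{np}$ with
$\gamma_{np} = \rho_{np}\varphi$ by default, making
power → SLP → $Q_{np}$ an exact round trip (tested to $10^{-12}$).
The liver scenarios use the literature source strength
$Q_{np} = 4.77978\times 10^5$ W/m³ for the best core-shell species as a
given input constant: it cannot be reconstructed from the catalogue SLP
with any plausible $\rho_{np}\varphi$ (the implied $\gamma_{np}\approx
0.124$ kg/m³ is far below $\rho_{np}\varphi \approx 6.7$ kg/m³), so we
treat it as the study's calibrated operating point rather than derive
it. A legacy SLP expression with mixed cal/g unit factors is provided
verbatim as `slp_lrt_literal()` for comparison with older papers, but
quarantined: its dimensional bookkeeping is dubious, it is never used in
the heating chain, and (contrary to folklore) its extra factor of $\nu$
makes it monotone in frequency rather than peaked at $2\pi\nu\tau=1$.

Nanoparticle density is configurable with a ferrite-class default of
5180 kg/m³; because $Q_{np}$ is an input constant, $\rho_{np}$ affects
only the optional conversions. The magnetics default temperature is body
temperature, 310 K. The default field amplitude is 37.4 kA/m; the
shipped catalogue records 37.3 kA/m with its measured SLPs, as reported
for those measurements.

## 2. Bioheat models

Tissue is a perfused continuum with a blood heat sink
$\omega_b\rho_b c_b (T - T_b)$ and metabolic source $Q_m$. The three
conduction models form a strict hierarchy. Fourier conduction gives the
Pennes equation; a single lag $\tau_q$ between heat flux and temperature
gradient gives the hyperbolic SPL (Cattaneo–Vernotte) equation; lagging
both flux ($\tau_q$) and gradient ($\tau_t$) gives the dual-phase-lag
equation

$$\rho c\,\tau_q T_{tt} + \left(\rho c + \tau_q \omega_b\rho_b c_b -
\tau_t k\nabla^2\right) T_t = k\nabla^2 T - \omega_b\rho_b c_b(T-T_b) +
Q_m + Q_{np} + \tau_q \dot Q.$$

Setting $\tau_t = 0$ recovers SPL exactly and $\tau_q = \tau_t = 0$
recovers Pennes; in the code all three are literally one discretisation
with zeroed lags, and the reduction is asserted step-for-step to
$10^{-10}$. (Note that zeroing $\tau_q$ alone does *not* reduce DPL to
Pennes — the $\tau_t k\nabla^2 T_t$ term survives — and the test suite
pins down that asymmetry.) Default lags are the liver measurements
$\tau_q = 5.66$ s, $\tau_t = 22$ s; since $\tau_t > \tau_q$ the DPL
response is over-damped (no thermal-wave overshoot) and transiently
*smoother* than Pennes, which is why DPL predicts the lowest maximum
temperature in the model comparison.

The source is switched on as a step at $t=0$ and held, making
$\dot Q_{np} \equiv 0$ afterwards; an optional linear ramp
(`source_ramp`) is provided with its exact slope feeding the
$\tau_q\dot Q$ term, because a true step renders that term a
distribution at $t=0$ that no discrete scheme evaluates meaningfully.

Temperatures are carried in °C throughout; every term is linear in $T$,
so the offset is immaterial, and the arterial temperature 37 °C doubles
as the initial condition with zero initial heating rate.

### Geometry: the one genuinely open choice

Probe families span $x = 0\ldots10$ mm on a domain quoted as $-20$ to
$20$ mm, but the heated-region shape is never stated. We calibrated it
against closed forms before building anything else. With liver
parameters the perfusion screening length is
$L=\sqrt{k/\omega_b\rho_b c_b} = 3.40$ mm and the source strength
$S = Q_{np}/\omega_b\rho_b c_b = 8.61$ K. A uniformly heated *disc* of
radius $a$ has center rise $S\,(1 - z K_1(z))$, $z = a/L$: a 5 mm disc
tops out near 42.1 °C and a 10 mm disc near 44.7 °C — the latter matches
the reported spatial contrast but its steady state never crosses 45 °C,
so a finite warm-up time to 45 °C would be impossible. A uniformly
heated *slab* $|x| \le a$ (the 1D screening solution
$S(1-e^{-a/L}\cosh(x/L))$) with $a = 10$ mm gives 45.35 °C at the
center, 41.49 °C at $x = 10$ mm and a finite 45 °C crossing — consistent
with all three reported observations at once. The slab is also the
natural idealisation of needle-track delivery, where the colloid spreads
from an injection channel rather than a point. The default geometry is
therefore a slab of half-width 10 mm spanning the domain in $y$
(`tumor_shape = "slab"`); a disc mask remains available
(`tumor_shape = "disc"`). Tissue density, absent from the standard liver
table, defaults to 1050 kg/m³ (blood-like).

Whether the reference simulations were planar 2D, axisymmetric or a 1D
slice is likewise unstated; the solver is planar 2D, with the uniform
ceiling $T_b + (Q_m+Q_{np})/\omega_b\rho_b c_b = 45.81$ °C and the slab
closed form bracketing the answer from above and below. The remark that
adjacent tissue sits "with one needle" is not interpretable as a
boundary condition and is left unmodeled.

### Discretisation

The grid is cell-centered and uniform: $[-20,20]^2$ mm at the default
$dx = 0.5$ mm is $80\times80$ cells. The diffusion operator is a
conservative five-point finite-volume stencil, exact for quadratics in
the interior; insulated faces carry zero flux and Robin faces the
convective flux $h(T_\mathrm{ext}-T)$ (default $h = 200$ W/K/m²,
$T_\mathrm{ext} = 37$ °C on all four edges — at 10 mm beyond the heated
region the choice is numerically inconsequential, and a fully insulated
variant is selectable). The operator applied to a constant field with
insulated edges is exactly zero.

Time stepping is three-level fully implicit: central second difference
for $T_{tt}$, backward first difference for $T_t$, spatial operators at
the new level, and the mixed $\tau_t k \nabla^2 T_t$ term applied to the
backward difference. Each step solves one sparse symmetric
positive-definite system $A T^{n+1} = b$ with
$A = (\rho c\,\tau_q/dt^2 + (\rho c + \tau_q w)/dt + w)\,I -
(1+\tau_t/dt)\,M$; $A$ is constant, so its Cholesky factor is computed
once and reused for the whole run (direct solve — no iterative
tolerance; the `linear_tolerance` knob of iterative variants is
unnecessary). The first step uses $T^{-1}=T^0$, encoding the zero
initial rate. The scheme is unconditionally stable, first-order in time
and second-order in space; defaults $dt = 0.5$ s, $dx = 0.5$ mm resolve
both the lag times and the screening length comfortably, and halving
either changes the 3600 s center temperature by well under 0.01 °C.
Non-finite temperatures abort the run with the offending time.

Verification is layered: exact equilibrium preservation; convergence of
insulated uniform-source runs to the closed-form steady state (within
0.01 °C by $t = 20\rho c/\omega_b\rho_b c_b \approx 1320$ s); a
manufactured solution $T^* = T_b + A\cos(\pi x/L_x)\cos(\pi y/L_y)
\,(1-e^{-t/\tau^*})^2$ whose full lagged-equation residual is injected
as a forcing, showing observed spatial order $\ge 1.8$ under $2\times$
refinement for all three models (the squared ramp matters: it has zero
initial *rate*, matching the solver's start-up assumption — a ramp with
$\dot\phi(0)\ne0$ measures the bootstrap error instead of the spatial
order); mirror symmetry to solver tolerance; and pointwise monotone
response to the source amplitude. Probing is bilinear from cell centers
(exact at centers); the running spacetime maximum ignores increases
below $10^{-9}$ °C so roundoff in an exact equilibrium cannot displace
the $t=0$ maximum.

## 3. Scenarios, catalogue and perturbations

`build_scenario()` packages the standard experiments: center-probe time
course, axial profiles at chosen minutes, the six-probe family at
$x = 0,2,\dots,10$ mm over 3600 s, the three-model comparison at the
1.5 mm probe over 600 s, and the four-species comparison. Model and
species comparisons share one grid and differ only in lags or source.
Per-species sources are scaled linearly in the catalogue SLP at fixed
mass concentration, $Q_{np,i} = Q_\mathrm{ref}\,\mathrm{SLP}_i/3866$,
which is the only scaling consistent with $Q_{np} = \mathrm{SLP}\cdot
\gamma_{np}$ when only the species changes; by linearity and positivity
of the solver the temperature ordering then equals the SLP ordering,
which is asserted rather than assumed. The catalogue's corrupt
field-frequency product column is recomputed from its amplitude and
frequency columns ($1.865\times10^{10}$ A m⁻¹ s⁻¹) rather than stored.

Scenarios serialize to YAML and round-trip byte-identically.
`perturb_scenario()` is the synthetic-data layer: seeded, reproducible
multiplicative uniform perturbations of tissue parameters and source
strength, leaving the global RNG untouched. It emulates
parameter-catalogue uncertainty (measurement spread in conductivity,
perfusion, source calibration); it deliberately does *not* emulate
spatial heterogeneity, temperature-dependent properties, or nanofluid
transport, so a passing perturbation study says nothing about those
effects in real tissue — they are listed as limitations below.

Test and verification runs use coarsened resolutions (2–4 mm cells,
1–5 s steps, minutes of simulated time) chosen so every property they
check is already resolution-converged; the headline run and the
acceptance script use the production resolution (0.5 mm / 0.5 s /
3600 s, a few seconds of wall time).

## 4. Known limitations

* Planar 2D only; no 3D or vessel-resolved (DIVA-type) geometry.
* Constant properties: no temperature dependence, no Arrhenius damage
  integral, no tumor/healthy property contrast beyond the source mask.
* The nanofluid injection and 24 h redistribution stages are abstracted
  into a static uniform source mask; no transport PDE.
* LRT is extrapolated beyond its strict small-$\xi$ validity, as is
  customary when anchoring to measured SLPs; no hysteresis modeling.
* The heated-region geometry is a calibrated idealisation (slab), not
  an imaged tumor; the disc alternative is provided for sensitivity
  checks.
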