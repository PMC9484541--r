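---
title: "Survival modelling and injury simulation for electroporation-based treatment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Survival modelling and injury simulation for electroporation-based treatment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ebtsim)
library(dplyr)
```

## The problem

Irreversible electroporation (IRE) kills cells with trains of short
high-voltage pulses: above a cell-specific field threshold the membrane is
permanently disrupted, while below it cells recover (reversible
electroporation). Treatment planning therefore needs, per cell type, a
quantitative map from pulse settings — field strength, pulse number, pulse
duration — to the probability of death, plus a check that the Joule heat
deposited by the pulses does not cause collateral thermal damage.

`ebtsim` implements that pipeline for the human digestive system: a
dose-response survival model fitted to in-vitro viability data, a bundled
database of fitted coefficients for 20 digestive-system cell lines
(esophagus, stomach, colon, bile duct, liver, pancreas) at four pulse
durations, a synthetic-data generator with the statistical structure the
fits assume, and a two-dimensional coupled electric-field / bioheat /
thermal-damage simulation that converts the model into electrical-injury
(EI) and thermal-injury (TI) area ratios around a pair of needle
electrodes.

## The survival model

Survival after $N$ pulses at field strength $E$ (V/cm) follows a
Fermi-type (logistic) curve,

$$S(E, N) = \frac{1}{1 + \exp\!\left(\frac{E - E_c(N)}{A_c(N)}\right)},$$

whose midpoint $E_c(N)$ — the field at which half the population dies —
and slope constant $A_c(N)$ both decay exponentially with pulse number:

$$E_c(N) = E_0 e^{-k_1 N}, \qquad A_c(N) = A_0 e^{-k_2 N}.$$

$(E_0, k_1, A_0, k_2)$ are the cell-specific coefficients; they depend on
pulse duration and are tabulated per cell line in `pf_coefficients()`.
$E_c(100)$ — the threshold after the clinically conventional 100-pulse
burst — doubles as the effective-field cutoff for the injury simulation:
below it, electrical injury probability is defined to be zero, which
prevents the logistic tail from accumulating spurious injury at arbitrarily
weak fields.

Two variants cover datasets the single-exponential model cannot describe:
a *modified* model in which $E_c(N)$ and $A_c(N)$ are sums of two
exponentials (8 parameters, requiring at least 5 pulse numbers), and a
*power-law* model $E = a\,(t_p/t_0)^b$ with $t_0 = 1$ ms relating a
characteristic lethal field to pulse duration $t_p$.

### The two-step fitting procedure

1. **Stage 1** (`fit_stage1()`): at each pulse number, fit the sigmoid to
   mean viability (as a fraction) versus field strength, giving
   $E_c(N)$, $A_c(N)$ and a per-fit $R^2$.
2. **Stage 2** (`fit_stage2()`): fit $E_0 e^{-k_1 N}$ to the stage-1
   $E_c$ values and, as an independent least-squares problem,
   $A_0 e^{-k_2 N}$ to the $A_c$ values — hence two separate $R^2$
   diagnostics.

Both stages use Levenberg–Marquardt least squares (`minpack.lm::nlsLM`)
with multi-start initialisation: stage 1 starts at the field whose
viability is nearest 0.5 with $A_c$ a quarter of the field range, plus a
3 × 3 quantile/scale grid; stage 2 is seeded by log-linear regression on
positive values with a fallback grid of decay rates in which the amplitude
is profiled in closed form. Bounds are $E_c, A_c, E_0, A_0 \in (0, 10^5]$
V/cm and $k \in [-0.1, 0.1]$ — deliberately two-sided, because the
published coefficient sets contain small *negative* $k_2$ values (the
slope constant can grow slowly with pulse number). $R^2$ is reported
as-is, including negative values for genuinely poor fits.

Choices where the procedure was underdetermined, made once and kept:

* Stage-1 fits consume **replicate means** (per-condition averages); an
  option fits all replicate points instead.
* Viability is stored as a percentage (the assay scale) and divided by
  100 for fitting; values above 100% — low-field stimulation of
  proliferation is real — are retained, never clipped. The logistic simply
  fits such points poorly, which surfaces as a low $R^2$ rather than as
  silent data editing.
* Duplicated field levels are averaged before stage 1.
* The modified model is invoked only on explicit request or after the
  single-exponential stage-2 fit fails; its two exponential terms are
  exchangeable, so tests and users should compare predicted curves, not
  individual coefficients.
* The power-law model is fitted, by ordinary least squares in log-log
  coordinates, to a characteristic field versus duration; by convention we
  use $E_c(100)$ since the defining publication of the model family leaves
  the choice open.

## The synthetic-data generator

The raw viability measurements behind the bundled coefficients live in an
external online repository, so the package generates datasets with the
statistical structure the analysis assumes (`generate_dataset()`): for
every design point, the true survival fraction from the model above, an
optional low-field stimulation term $b\,e^{-E/E_{cut}}$ (so mean viability
exceeds 100% well below the cutoff and vanishes at IRE-scale fields), and
additive Gaussian noise on the fraction scale, truncated at zero.
`generate_od_dataset()` emits the same data as optical-density triplets
that invert the CCK-8 normalisation
$S = 100\,(A_{exp}-A_{blank})/(A_{control}-A_{blank})$ exactly.

Defaults, chosen once as a realistic emulation of the assay design:
fields $\{250, 500, 750, 1000, 1250, 1500, 2000, 2500, 3000\}$ V/cm
(spanning the reversible threshold below 500–800 V/cm through strongly
irreversible fields), pulse numbers $10, 20, \dots, 90$, durations
$\{25, 50, 75, 100\}$ µs, 10 replicates, noise SD 0.03 on the fraction
scale (the source reports no replicate variances; 3% is typical of
plate-reader viability assays), seed 20220905. Two things the generator
deliberately does **not** emulate: plate/batch effects and
field-dependent heteroscedasticity. Parameter-recovery results on
generated data therefore show that the two-step procedure is correctly
implemented and well-conditioned on the stated design — not that real
assay noise is additive Gaussian.

## The injury simulation

A 2-D homogeneous tissue slab with two needle electrodes, discretised by
5-point finite differences on a regular grid (a deliberate replacement of
the original finite-element treatment: same PDEs, simpler, and directly
testable against closed forms). Default geometry — 40 mm × 40 mm, 1 mm
electrode diameter, 10 mm gap, 0.25 mm spacing — is the package's own
configuration; the source publication's geometry is unpublished, which is
also why its injury-ratio curves are only qualitatively, not numerically,
reproducible.

* **Potential** (`solve_potential()`): $\nabla\!\cdot\!(\sigma\nabla V)=0$
  with Dirichlet electrodes (anode at the pulse voltage, cathode at 0)
  and zero-flux outer boundaries; a sparse direct solve. With homogeneous
  $\sigma$ the potential is conductivity-invariant. The discrete solution
  obeys the maximum principle and is exact for parallel-plate electrodes;
  against the analytic two-wire potential (using the equal-area effective
  radius of the rasterized electrode disk) the error is about 3% of the
  applied voltage at 0.5 mm spacing, halving under refinement —
  first-order behaviour dominated by the staircased electrode boundary.
* **Electrical injury** (`ei_probability()`): $P_{EI} = 1 - S(|E|, N)$
  where $|E| \ge E_c(N)$, else 0; the area with $P_{EI} > 0.5$, divided
  by the tissue area (electrode interiors excluded from numerator and
  denominator), gives the relative EI area ratio. The EI endpoint is 100
  pulses; beyond it the EI map is held fixed while the thermal analysis
  continues.
* **Bioheat** (`step_bioheat()`): Pennes' equation
  $\rho c\,\partial T/\partial t = \nabla\!\cdot\!(k\nabla T) +
  \rho_b c_b \omega_b (T_b - T) + \rho q_{met} + q_J$, stepped with
  backward Euler (unconditionally stable; 0.1 s default step), outer
  boundary fixed at 37 °C, electrode interiors given electrode material
  properties with no perfusion or sources. The tabulated perfusion rate
  $w_b$ in ml/(min·kg) becomes a volumetric sink via
  $\omega_b = w_b\,\rho/(60 \times 10^6)$ s⁻¹ with blood density
  1050 kg/m³, blood heat capacity 3617 J/(kg·°C), arterial blood at
  37 °C. Joule heating is duty-cycle-averaged,
  $q_J = \sigma |E|^2 \cdot d$ with $d = 10^{-4}$ for 100 µs pulses at
  1 Hz; at that repetition rate tissue integrates the pulses thermally,
  and per-pulse microsecond transients are out of scope.
* **Thermal injury** (`arrhenius_integral()`): first-order Arrhenius
  damage $\Omega = \int \zeta e^{-E_a/(RT)}\,dt$ accumulated alongside
  the temperature march (temperatures stored in °C, converted to kelvin
  only inside the exponent), $P_{TI} = 1 - e^{-\Omega}$, threshold 0.5
  (equivalently $\Omega = \ln 2$). The source publication prints no
  kinetic constants, so the defaults $\zeta = 7.39\times10^{39}$ s⁻¹,
  $E_a = 2.577\times10^5$ J/mol are the widely used soft-tissue
  (liver protein-coagulation) pair, configurable per organ. At baseline
  37 °C these kinetics accrue $P_{TI} \approx 0.05$ over 200 s — safely
  below the 0.5 threshold, so no spurious baseline injury is reported.

The injury threshold 0.5 is fixed by convention and exposed as
configuration for sensitivity studies.

### Problem sizes

The test suite and qualitative checks run the solvers at sizes chosen to
balance discretisation error against runtime: solver-oracle comparisons on
80 mm domains at 0.5 mm and 0.25 mm spacing; the 20-cell-line sweep and
the six-organ 200-pulse thermal comparison at 0.5 mm spacing with a 1 mm
electrode radius (the coarser grid cannot resolve the default 0.5 mm
radius at the required four cells per diameter). These are package
choices; finer grids change the reported ratios by a few percent, in line
with the first-order electrode rasterization error above.

## What the qualitative checks do and do not show

With the bundled coefficients and the default protocol the simulation
reproduces, and the test suite asserts, the expected structure: the EI
area ratio is nondecreasing in pulse number for every coefficient set,
and the 200-pulse TI ordering puts the bile duct at the top (high
conductivity, 30 ml/(min·kg) perfusion — the lowest in the table) with
colon and liver at zero (conductivities of 0.012 and 0.028 S/m deposit
almost no Joule heat).

One published tendency does **not** hold pointwise: EI area monotone in
pulse duration. Several cell lines' fitted $E_c(N)$ curves cross within
$N \le 100$ (for example one esophageal line has $E_c(100) = 656.7$ V/cm
at 75 µs but 684.8 V/cm at 100 µs), so at matched pulse number the longer
duration can ablate a slightly smaller area. This is a property of the
published coefficient sets themselves — the source says "for most of the
cell lines" — and the corresponding strict assertion in the acceptance
tests is expected to flag those lines rather than paper over them.

## Known limitations

* The field is solved once with static conductivity: electroporation- and
  temperature-dependent conductivity changes (electrical-thermal
  coupling) are not modelled.
* 2-D cross-section only; no multi-electrode arrays.
* The survival model has no pulse-frequency dependence, so it should not
  be extrapolated to high-frequency burst protocols.
* Arrhenius constants are organ-independent by default; true per-organ
  kinetics are unknown.
* The in-vitro coefficients transfer cell-level dose-response to tissue
  scale unchanged; microenvironment effects are out of scope.
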