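# ebtsim

Cell-survival modelling and tissue-injury simulation for
electroporation-based treatment (EBT) of the digestive system.

Irreversible electroporation (IRE) ablates tissue with bursts of short
high-voltage pulses. Planning such a treatment needs two things: a
cell-specific dose-response model — how survival depends on electric
field strength, pulse number and pulse duration — and a thermal check
that the Joule heat of the pulses stays below damaging levels. `ebtsim`
provides both, for 20 human digestive-system cell lines (esophagus,
stomach, colon, bile duct, liver, pancreas), aimed at researchers doing
treatment-planning, device-design or dose-response work with pulsed
electric fields.

## The model

Survival follows the Peleg–Fermi curve

```
S(E, N) = 1 / (1 + exp((E − Ec(N)) / Ac(N)))
Ec(N) = E0 · exp(−k1 N),   Ac(N) = A0 · exp(−k2 N)
```

where `Ec(N)` is the half-lethality field after `N` pulses and `Ac(N)`
the sigmoid slope constant. The package implements the two-step fitting
procedure (per-pulse-number sigmoid fits, then exponential fits of
`Ec(N)` and `Ac(N)` with separate R² diagnostics), the modified
double-exponential and power-law variants, a bundled database of
published coefficients `(E0, k1, A0, k2)` per cell line and pulse
duration, a synthetic viability-data generator, and a 2-D finite
difference simulation coupling the electric field, Pennes' bioheat
equation and the Arrhenius damage integral into electrical-injury (EI)
and thermal-injury (TI) area ratios around two needle electrodes.

## Worked example

```r
library(ebtsim)
library(dplyr)

# 1. A published coefficient row and its IRE threshold after 100 pulses
truth <- pf_coefficients(complete_only = TRUE) |>
  filter(cell_line == "QBC-939", pulse_duration_us == 100)
ec_threshold(truth, n = 100) |> select(cell_line, e0, k1, ec_n)
#>   cell_line    e0    k1  ec_n
#> 1 QBC-939   1923. 0.024  174.

# 2. Generate a synthetic assay and re-fit the model
data <- generate_dataset(generator_config(truth, seed = 42))
fit  <- fit_peleg_fermi(data)
tidy(fit) |> select(cell_line, e0, k1, r2_e, a0, k2, r2_a)
#>   cell_line    e0     k1  r2_e    a0      k2  r2_a
#> 1 QBC-939   1915. 0.0239 1.000  982. 0.00858 0.998

# 3. Simulate injury around two needle electrodes in bile-duct tissue
dom <- domain_spec(spacing = 5e-4, electrode_radius = 1e-3)
res <- run_injury_analysis(truth, domain = dom)
res
#> Injury analysis: QBC-939 / 100 us in bile_duct
#>   S_EI(100) = 0.4859   S_TI(200) = 0.2351   peak T = 105.5 C
```

Reading the output: the cholangiocarcinoma line QBC-939 has a
100-pulse lethality threshold of 174 V/cm; the two-step fit recovers the
generating coefficients from noisy synthetic replicates (`e0` within
0.5%, stage-2 R² ≈ 1); and with the default 2000 V / 100 µs / 1 Hz
protocol, electroporation ablates 48.6% of the simulated cross-section
after 100 pulses while 200 pulses of Joule heating thermally injure
23.5% — the bile duct is the most heat-sensitive digestive organ (high
conductivity, very low perfusion), which is why thermal dose limits
matter most there.

`tidy(res)` returns the per-pulse series (`pulse_number`, `s_ei_ratio`,
`s_ti_ratio`, `peak_T_C`), `autoplot(res)` plots it, and
`plot_injury_map(res, "p_ei")` renders the probability maps.
`pipeline_fit()`, `pipeline_synth()` and `pipeline_simulate()` wrap the
same steps with CSV/JSON outputs and run manifests; `inst/cli/ebtsim.R`
exposes them as a command line.

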