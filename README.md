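# quetsim

Monte-Carlo virtual clinical trials of quetiapine dose non-adherence:
what happens to plasma exposure and symptom control when a patient on the
immediate-release formulation (IR, 200 mg every 12 h) or the
extended-release formulation (XR, 400 mg every 24 h) delays, skips,
doubles or stops a dose — and whether switching from IR to XR makes the
consequences of those mistakes worse.

The package is aimed at pharmacometricians and clinical-pharmacology
researchers who want a fully scripted, reproducible simulation study:
every virtual patient, dose event, profile, summary parameter and
population table is produced by seeded code.

## The model

Virtual patients are drawn from published population models with
independent between-subject variability (log-normal on all PK parameters
and on `BPRS0`, `Emax`, `EC50`; normal on the placebo slope).

Pharmacokinetics — one compartment, first-order absorption and
elimination, dose superposition:

    Cp(t) = D0 ka / (V (ka − ke)) · (e^(−ke t) − e^(−ka t))

with typical values ke = 0.12 h⁻¹, ka(IR) = 1.46 h⁻¹, ka(XR) = 0.15 h⁻¹,
V = 73.7/0.12 ≈ 614 L. Pharmacodynamics — linear placebo drift plus Emax
inhibition of the Brief Psychiatric Rating Scale:

    BPRS(t) = BPRS0 + α t − Emax·Cp(t) / (EC50 + Cp(t))

with typical BPRS0 = e^3.65 ≈ 38.5 points, α = −0.008 points/h,
Emax = e^2.2 ≈ 9.0 points, EC50 = e^4.42 ≈ 83 µg/L. A ≥14% reduction from
baseline marks genuine (non-placebo) response; 50–500 µg/L is the plasma
therapeutic window.

Each trial simulates 1000 patients to steady state (days 7–9), imposes a
single day-8 irregularity (delay by 25–100% of the interval, omission,
doubling, or discontinuation), and summarises every patient against their
own adherent profile: steady-state peaks and troughs of concentration and
%-reduction, signed % changes, time to recover the adherent steady state
after an omitted dose, therapeutic duration and "hangover" after stopping,
and odds ratios (XR vs IR) of sub-therapeutic response and supra-threshold
exposure, with Kolmogorov–Smirnov comparisons of the IR and XR
distributions.

## A worked example

```r
library(quetsim)

cfg <- study_config(n_patients = 1000, seed = 2020)
res <- run_trial(cfg)
res
#> Virtual-trial result
#>   1000 patients; formulations: IR, XR
#>   scenario arms: adherence, delay_25, delay_50, delay_75, delay_100,
#>                  omission, doubling, discontinuation
#>   proportions:
#>     IR duration_lt_24h: 53.8% (n = 818)
#>     IR recovery_lt_48h: 46.2% (n = 1000)
#>     XR duration_lt_24h: 32.8% (n = 818)
#>     XR recovery_lt_48h: 14.8% (n = 1000)

subset(res$table_delay,
       parameter == "dCmax" & formulation == "IR",
       c(scenario, mean, cv, ks_p))
#>     scenario   mean     cv ks_p
#>     delay_25  7.821 0.2028    0
#>     delay_50 19.451 0.2274    0
#>     delay_75 36.530 0.2841    0
#>    delay_100 53.290 0.3623    0
```

Reading: delaying one IR dose by 25% of the interval raises the day-9
steady-state peak by ~7.8% on average (CV 0.20) relative to adherent
dosing, growing to ~53% when the dose is taken together with the next one;
every IR-vs-XR distribution difference here is KS-significant. The
proportions say therapeutic cover after stopping lasts under 24 h for ~54%
of IR patients but only ~33% of XR patients, while the IR arm re-attains
its steady state within 48 h of a missed dose far more often (~46%) than
XR (~15%) — XR forgives a stopped schedule, IR forgives a missed dose.

Per-patient profiles and schedules are available at every intermediate
step (`sample_patients()`, `build_regimen()`, `concentration_profile()`,
`bprs_profile()`, `threshold_concentration()`, `recovery_time()`, ...);
`render_tables()` writes the population tables as CSV;
`risk_analysis()` produces the replicate-averaged odds-ratio panel. A
command-line wrapper lives at `inst/scripts/run_trial.R` and the default
study configuration at `inst/extdata/quetiapine_study.yaml`. The methods
vignette (`vignettes/quetsim-methods.Rmd`) documents the model,
conventions and their rationale.

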