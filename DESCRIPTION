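Package: quetsim
Title: Virtual-Trial Simulation of Quetiapine Dose Non-Adherence
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Monte-Carlo virtual clinical trials comparing immediate-release
    (200 mg twice daily) and extended-release (400 mg once daily) quetiapine
    under dose adherence, delay, omission, doubling and discontinuation.
    Virtual patients are sampled from published population pharmacokinetic
    (one-compartment, first-order absorption) and pharmacodynamic (linear
    placebo plus Emax inhibition of the Brief Psychiatric Rating Scale)
    models with log-normal between-subject variability. The package builds
    dose-event schedules for each non-adherence scenario, simulates dense
    concentration and BPRS response profiles by superposition, summarises
    per-patient steady-state peaks, troughs, recovery and hangover times,
    and aggregates population tables, Kolmogorov-Smirnov distribution
    comparisons and odds ratios for sub-therapeutic and supra-threshold
    exposure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
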