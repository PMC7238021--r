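# Default virtual-trial study configuration: quetiapine IR 200 mg q12h vs
# XR 400 mg q24h, five adherence scenarios, 1000 virtual patients.
n_patients: 1000
seed: 2020
formulations: [IR, XR]
scenarios: [adherence, delay, omission, doubling, discontinuation]
delay_fractions: [0.25, 0.5, 0.75, 1.0]
step: 0.05          # profile grid, h
low_threshold: 14   # % reduction in BPRS marking genuine response
high_threshold: 500 # ug/L upper therapeutic-window limit
recovery_tol: 1     # steady-state recovery band, ug/L
recovery_type: absolute
hangover_mode: threshold_conc
t_ref: 168          # placebo reference time for the borderline check, h
population:
  pk:
    mu_ke: 0.12
    mu_ka_ir: 1.46
    mu_ka_xr: 0.15
    mu_v: 73.7
    sd_ln_ke: 0.40
    sd_ln_ka_ir: 0.75
    sd_ln_ka_xr: 1.50
    sd_ln_v: 0.47
    v_mode: cl_derived
  pd:
    mu_ln_bprs0: 3.65
    mu_alpha: -0.008
    mu_ln_emax: 2.2
    mu_ln_ec50: 4.42
    # dispersions below are SDs (the square roots of the published
    # mixed-effects variances 0.27, 0.0001, 0.41, 1.77)
    sd_ln_bprs0: 0.5196152
    sd_alpha: 0.01
    sd_ln_emax: 0.6403124
    sd_ln_ec50: 1.3304135
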