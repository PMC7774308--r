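# Default beagle-study run configuration: the published typical values with
# their retained inter-individual variability and residual error models, and
# the two drug arms of the trial design.
pk:
  ka: 0.21        # 1/h, first-order absorption
  v: 447.58       # ml/kg, apparent volume
  vmax: 1252830   # ng/h/kg, maximal elimination rate
  km: 237.60      # ng/ml, Michaelis constant
pd:
  beta: 0.475     # efficacy coefficient (baseline PAR = beta x 100)
  ksyn: 88.501    # ng/h, enzyme synthesis rate
  kdeg: 0.515     # 1/h, enzyme degradation rate constant
  k: 0.002        # ml/ng/h, irreversible inactivation rate constant
omega_pk:         # variances of the log-scale random effects
  ka: 0.015
  v: 0.474
  km: 0.041
omega_pd:
  kdeg: 0.466
  k: 0.775
residual:
  pk_prop_sd: 0.10     # proportional concentration error SD
  pd_add_sd: 0.003     # additive PAR error SD (percent units)
  pd_mult_sd: 0.122    # multiplicative PAR error SD
design:
  lloq: 7.8            # ng/ml
  arms:
    - {n: 6, dose_mg_kg: 2.5, label: "2.5 mg/kg single"}
    - {n: 6, dose_mg_kg: 5, n_doses: 7, sampled_days: [1, 7],
       label: "5 mg/kg QD x 7"}
estimation:
  method: two_stage
  e0_ref: 171.8466     # ng, baseline enzyme reference for reporting ksyn
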