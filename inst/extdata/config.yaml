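binding:
  k_dbp_constant: 700000000.0
  k_alb: 600000.0
  allele_k_dbp:
    Gc1f: 1120000000.0
    Gc1s: 600000000.0
    Gc2: 360000000.0
  mw_25ohd: 400.639999999999986
  mw_vdbp: 58000.0
  mw_albumin: 66500.0
  mode: linear
thresholds:
  deficiency_ng_ml: 20.0
  bmi_overweight_pct: 85.0
  bmi_obese_pct: 95.0
  activity_min_per_day: 60.0
  activity_days_per_week: 3.0
  vif: 3.0
  isoform_groups: 6.0
seed: 1.0
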