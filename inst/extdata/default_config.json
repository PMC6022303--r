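{
  "seed": 20150301,
  "scenarios": "all",
  "programme_total_cost": 61700,
  "programme_n": 374,
  "discount_rate": 0.035,
  "bmi_cost_rate": 16,
  "psa": {"n_draws": 1000, "wtp_max": 50000, "wtp_step": 250}
}
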