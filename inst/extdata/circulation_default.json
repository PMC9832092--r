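{
  "Qvein_Lmin": 5.8,
  "Rmv_mmHg_s_per_mL": 0.005,
  "Rlvot_mmHg_s_per_mL": 0.0043,
  "Rc_mmHg_s_per_mL": 0.042,
  "Rp_mmHg_s_per_mL": 0.9046,
  "Cwk_mL_per_mmHg": 1.9504,
  "T_s": 0.8512,
  "la_shift_frac": 0.85,
  "la_shift_mode": "delay",
  "lv": {
    "Emin_mmHg_per_mL": 0.01,
    "Emax_mmHg_per_mL": 0.1191,
    "tau1_frac": 0.0725,
    "tau2_frac": 0.4503,
    "m1": 2.7463,
    "m2": 21.5683
  },
  "la": {
    "Emin_mmHg_per_mL": 0.08,
    "Emax_mmHg_per_mL": 0.17,
    "tau1_frac": 0.115,
    "tau2_frac": 0.1882,
    "m1": 1.32,
    "m2": 13.1
  }
}
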