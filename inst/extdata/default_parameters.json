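{
  "eta_water_pas": 1e-3,
  "Rm_per_m": 4e12,
  "Rpore_ref_per_m": 2e12,
  "k_pore": 1e-4,
  "k_cake_ghpl": 30,
  "Rcake_SS_ref_per_m": 1.4e13,
  "Qt_per_ref_lph": 880,
  "TMP_compress_bar": 0.7,
  "c_ref_gpl": 60,
  "nQ": 1.85,
  "nc": 0.1,
  "fine_fraction": 0.2,
  "eta_ref_pas": 1e-3,
  "k_eta_lpg": 0.04,
  "fc_floor": 0.75,
  "fc_tau_h": 2.0,
  "M_seal_nm": 50,
  "k_g_nms": 8.85,
  "k_valve_lphbar": 40,
  "sigma_f_bar": 1.0,
  "V_segment_l": 250,
  "shear_tau_h": 0.05
}
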