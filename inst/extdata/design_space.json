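{
  "q_set_lph": [400, 1200],
  "c_feed_gpl": [20, 100],
  "rcake_ss_ref_per_m": [6e12, 2.2e13],
  "n_levels": 5,
  "duration_h": 10
}
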