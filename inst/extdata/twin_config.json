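{
  "status_poll_interval_s": 60,
  "optimization_interval_min": 5,
  "tmp_mismatch_threshold_bar": 0.1,
  "adaptation_step": 0.10,
  "setpoint_min_lph": 400,
  "setpoint_max_lph": 1200
}
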