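{
  "initial_q_set_lph": 415,
  "c_feed_gpl": 60,
  "duration_h": 10,
  "schedule": [{"time_h": 5, "q_set_lph": 495}]
}
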