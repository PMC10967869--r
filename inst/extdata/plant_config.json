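{
  "total_filter_area_m2": 32.8,
  "n_segments": 4,
  "membrane_diameter_mm": 312,
  "rotation_speed_rpm": 343,
  "tmp_setpoint_bar": 0.8,
  "torque_open_setpoint_nm": 300,
  "torque_close_threshold_nm": 270,
  "min_valve_opening_pct": 5,
  "valve_step_pct": 1,
  "time_step_s": 3.6,
  "log_interval_s": 5
}
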