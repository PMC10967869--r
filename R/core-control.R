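# PLC control emulation: operating-mode latch and torque-driven retentate
# valve with hysteresis.

#' Operating-mode transition
#'
#' The plant starts flow-controlled and latches to TMP-controlled operation
#' the first time the TMP exceeds the setpoint; the mode never reverts within
#' a run.
#'
#' @param mode current mode, `"flow_controlled"` or `"tmp_controlled"`.
#' @param tmp_bar current TMP, bar.
#' @param config a [dcf_plant_config()] object.
#' @return the new mode.
#' @export
control_mode_step <- function(mode, tmp_bar, config) {
  mode <- match.arg(mode, c("flow_controlled", "tmp_controlled"))
  if (mode == "flow_controlled" && tmp_bar > config$tmp_setpoint_bar)
    "tmp_controlled"
  else
    mode
}

#' Retentate valve controller (one control cycle)
#'
#' Concentration/discharge phases switched on membrane-drive torque with 10 %
#' hysteresis: the valve stays closed until the torque reaches the opening
#' setpoint (default 300 N m), then starts discharging at the minimum opening
#' and ramps up by `valve_step_pct` per control cycle for as long as the
#' torque still rises ("until the torque does not increase any further");
#' once the torque falls below the closing threshold (default 270 N m) the
#' valve closes fully.
#'
#' @param valve_phase `"closed"` or `"discharging"`.
#' @param x_pct current valve opening, %.
#' @param torque_nm current torque, N m.
#' @param torque_prev_nm torque of the previous control cycle, N m.
#' @param config a [dcf_plant_config()] object.
#' @return list with `valve_phase` and `x_pct`.
#' @export
valve_controller_step <- function(valve_phase, x_pct, torque_nm,
                                  torque_prev_nm, config) {
  valve_phase <- match.arg(valve_phase, c("closed", "discharging"))
  if (valve_phase == "closed") {
    if (torque_nm >= config$torque_open_setpoint_nm) {
      valve_phase <- "discharging"
      x_pct <- config$min_valve_opening_pct
    }
  } else {
    if (torque_nm < config$torque_close_threshold_nm) {
      valve_phase <- "closed"
      x_pct <- 0
    } else if (torque_nm > torque_prev_nm) {
      x_pct <- min(100, x_pct + config$valve_step_pct)
    }
  }
  list(valve_phase = valve_phase, x_pct = x_pct)
}
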