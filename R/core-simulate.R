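# Time-stepped simulation of the DCF process dynamics with PLC behaviour.
#
# Explicit Euler at the plant's control cycle (3.6 s). Per step, in order:
# resistances -> flow/TMP resolution -> fouling kinetics -> mass balances ->
# viscosity/torque -> valve controller and retentate flow -> feed closure.
# Kinetics and the steady-state cake resistance use previous-step flows/TMP
# (the model's i-1 indexing); the mass balance uses the previous step's
# retentate valve flow, so the feed closure Qfeed = sum(Qper) + Qt_ret is
# exact with the fluxes actually applied.

#' Initial simulation state
#'
#' Chamber pre-filled with feed (`c(0, s) = c_feed`), clean fouling history
#' (`kp = kc = 0` unless initialised by the digital twin), flow-controlled
#' mode, valve closed.
#'
#' @param scenario a [dcf_scenario()] object.
#' @param params a [dcf_model_parameters()] object.
#' @param config a [dcf_plant_config()] object.
#' @return a `dcf_sim_state` list.
#' @export
new_sim_state <- function(scenario, params, config) {
  n <- config$n_segments
  structure(list(
    t_h = 0,
    kp = numeric(n), kc = numeric(n),
    c_gpl = rep(scenario$c_feed_gpl, n),
    rpore_per_m = numeric(n), rcake_per_m = numeric(n),
    rtot_per_m = rep(params$Rm_per_m, n),
    q_per_lph = numeric(n), q_ret_lph = numeric(n),
    q_shear_lph = scenario$initial_q_set_lph,
    tmp_bar = 0,
    torque_nm = NA_real_,
    x_pct = 0,
    mode = "flow_controlled",
    valve_phase = "closed",
    fc_value = 1,
    fc_frozen = FALSE,
    q_set_lph = scenario$initial_q_set_lph,
    q_feed_lph = scenario$initial_q_set_lph,
    qt_ret_lph = 0,
    c_eff_gpl = scenario$c_feed_gpl,
    clipped_retentate = FALSE
  ), class = "dcf_sim_state")
}

scheduled_setpoint <- function(scenario, t_h) {
  q <- scenario$initial_q_set_lph
  sch <- scenario$schedule
  if (!is.null(sch) && nrow(sch)) {
    i <- findInterval(t_h, sch$time_h)
    if (i > 0) q <- sch$q_set_lph[i]
  }
  q
}

#' Advance the simulation by one control cycle
#'
#' Executes one explicit-Euler update of length `config$time_step_s`. In
#' flow-controlled mode the total permeate setpoint is distributed over the
#' segments ([distribute_permeate_flow()]); if the resulting TMP exceeds the
#' TMP setpoint the mode latches to TMP-controlled and the step is
#' re-resolved with the TMP pinned at the setpoint (per-segment flows from the
#' Darcy relation). The empirical concentration correction decays until the
#' retentate valve first opens and is frozen from then on.
#'
#' @param state a `dcf_sim_state` (from [new_sim_state()] or a previous step).
#' @param scenario a [dcf_scenario()] object (feed concentration and setpoint
#'   schedule).
#' @param params a [dcf_model_parameters()] object.
#' @param config a [dcf_plant_config()] object.
#' @param rcake_ss_ref_per_m optional override of the reference steady-state
#'   cake resistance (DoE factor / twin estimate).
#' @return the updated `dcf_sim_state`.
#' @export
simulate_step <- function(state, scenario, params, config,
                          rcake_ss_ref_per_m = params$Rcake_SS_ref_per_m) {
  # The individual operations (pore_resistance(), cake_resistance(),
  # distribute_permeate_flow(), update_concentrations(), ...) are inlined
  # here with their argument checks hoisted: this step runs ~10^4 times per
  # simulated run and ~10^6 times per DoE. test-simulate.R pins the step
  # against the explicit composition of the exported operations.
  dt_h <- config$time_step_s / 3600
  c_feed <- scenario$c_feed_gpl
  aseg <- config$segment_area_m2

  fc <- if (state$fc_frozen) state$fc_value
        else params$fc_floor + (1 - params$fc_floor) * exp(-state$t_h / params$fc_tau_h)

  # resistances from fouling history; the shear term sees the sustained
  # (low-pass filtered) permeate flow of the previous cycles
  rpore <- params$Rpore_ref_per_m * (exp(params$k_pore * state$kp) - 1)
  rc_ratio <- state$c_gpl / params$c_ref_gpl
  rc_ratio[rc_ratio < 1e-3] <- 1e-3
  rss <- rcake_ss_ref_per_m *
    max(state$q_shear_lph / params$Qt_per_ref_lph, 1e-3)^params$nQ *
    exp(state$tmp_bar / params$TMP_compress_bar) * rc_ratio^params$nc
  rss[rss > 1e18] <- 1e18
  rcake <- rss * state$kc / (state$kc + params$k_cake_ghpl)
  rtot <- params$Rm_per_m + rpore + rcake

  # flow / TMP resolution under the current operating mode
  q_set <- scheduled_setpoint(scenario, state$t_h)
  q_at_1bar <- BAR_TO_PA * aseg / (params$eta_water_pas * rtot) / LPH_TO_M3S
  mode <- state$mode
  tmp_set <- config$tmp_setpoint_bar
  if (mode == "flow_controlled") {
    tmp <- q_set / sum(q_at_1bar)
    if (tmp > tmp_set) mode <- "tmp_controlled"   # latch, never reverts
  }
  if (mode == "tmp_controlled") {
    # the feed pump never exceeds the flow setpoint: if the resistance
    # (transiently) admits more than the setpoint at the TMP setpoint, the
    # flow constraint binds and the TMP floats below it
    tmp <- min(tmp_set, q_set / sum(q_at_1bar))
  }
  q_per <- q_at_1bar * tmp
  q_total <- tmp * sum(q_at_1bar)
  if (!is.finite(tmp) || !is.finite(q_total))
    stop(sprintf("simulate_step: non-finite state at t = %.4f h", state$t_h),
         call. = FALSE)

  # fouling kinetics (explicit Euler)
  kp <- state$kp + params$fine_fraction * c_feed * (q_per / aseg) * dt_h
  kc <- state$kc + state$c_gpl * dt_h

  # species mass balances; the feed closes against the previous cycle's
  # retentate valve flow (q_per >= 0, so clipping the cumulative balance
  # equals sequential clipping)
  q_feed <- q_total + state$qt_ret_lph
  q_ret <- q_feed - cumsum(q_per)
  clipped <- q_ret[length(q_ret)] < -1e-9 * max(q_feed, 1)
  q_ret[q_ret < 0] <- 0
  q_in <- c(q_feed, q_ret[-length(q_ret)])
  c_in <- c(c_feed, state$c_gpl[-length(state$c_gpl)])
  c_new <- state$c_gpl +
    dt_h * (q_in * c_in - q_ret * state$c_gpl) / params$V_segment_l
  c_new[c_new < 0] <- 0

  # viscosity and drive torque from the updated concentrations
  kfc <- params$k_eta_lpg * fc
  ex <- exp(kfc * c_new)
  visc_factor <- sum(ex) / length(ex)
  torque <- params$M_seal_nm +
    params$k_g_nms * config$rotation_speed_rpm * params$eta_ref_pas * visc_factor
  torque_prev <- if (is.na(state$torque_nm)) torque else state$torque_nm

  # retentate valve controller (torque hysteresis) and valve flow for the
  # next cycle's balance
  phase <- state$valve_phase
  x_pct <- state$x_pct
  if (phase == "closed") {
    if (torque >= config$torque_open_setpoint_nm) {
      phase <- "discharging"
      x_pct <- config$min_valve_opening_pct
    }
  } else if (torque < config$torque_close_threshold_nm) {
    phase <- "closed"
    x_pct <- 0
  } else if (torque > torque_prev) {
    x_pct <- min(100, x_pct + config$valve_step_pct)
  }
  fc_frozen <- state$fc_frozen || phase == "discharging"
  qt_ret <- if (x_pct > 0)
    max(0, params$k_valve_lphbar * (tmp * x_pct - params$sigma_f_bar)) else 0

  structure(list(
    t_h = state$t_h + dt_h,
    kp = kp, kc = kc,
    c_gpl = c_new,
    rpore_per_m = rpore, rcake_per_m = rcake, rtot_per_m = rtot,
    q_per_lph = q_per, q_ret_lph = q_ret,
    q_shear_lph = state$q_shear_lph +
      min(1, dt_h / params$shear_tau_h) * (q_total - state$q_shear_lph),
    tmp_bar = tmp,
    torque_nm = torque,
    x_pct = x_pct,
    mode = mode,
    valve_phase = phase,
    fc_value = fc,
    fc_frozen = fc_frozen,
    q_set_lph = q_set,
    q_feed_lph = q_total + qt_ret,
    qt_ret_lph = qt_ret,
    c_eff_gpl = log(visc_factor) / kfc,
    clipped_retentate = state$clipped_retentate || clipped
  ), class = "dcf_sim_state")
}

#' Run a full simulation
#'
#' Integrates the process dynamics over the scenario duration and returns a
#' full-resolution trace (one row per 3.6 s control cycle) plus the 5 s
#' process log mirroring the plant's sensor/actuator logging.
#'
#' @inheritParams simulate_step
#' @param state optional initial state (defaults to [new_sim_state()]); the
#'   digital twin passes its belief state here.
#' @param keep_log if `FALSE` the 5 s process log is skipped (faster for DoE
#'   batches where only the trace is needed).
#' @return an object of class `dcf_run`: list with `trace` (data.frame),
#'   `log` (process-log data.frame, see [write_process_log()]), `final_state`,
#'   `scenario`, and `c_seg` (matrix of per-segment concentrations).
#' @export
simulate_run <- function(scenario, params, config = dcf_plant_config(),
                         rcake_ss_ref_per_m = params$Rcake_SS_ref_per_m,
                         state = NULL, keep_log = TRUE) {
  dt_h <- config$time_step_s / 3600
  n_steps <- floor(scenario$duration_h / dt_h + 1e-9)
  if (is.null(state)) state <- new_sim_state(scenario, params, config)

  n <- config$n_segments
  cols <- c("time_h", "tmp_bar", "q_per_total_lph", "q_set_lph", "torque_nm",
            "valve_pct", "q_feed_lph", "qt_ret_lph", "fc", "c_eff_gpl")
  tr <- matrix(NA_real_, nrow = n_steps + 1L, ncol = length(cols),
               dimnames = list(NULL, cols))
  mode_tr <- character(n_steps + 1L)
  phase_tr <- character(n_steps + 1L)
  c_seg <- matrix(NA_real_, nrow = n_steps + 1L, ncol = n)

  fill <- function(i, s) {
    tr[i, ] <<- c(s$t_h, s$tmp_bar, sum(s$q_per_lph), s$q_set_lph,
                  if (is.na(s$torque_nm))
                    torque_from_viscosity(
                      viscosity_from_concentration(s$c_gpl, s$fc_value, params),
                      params, config)
                  else s$torque_nm,
                  s$x_pct, s$q_feed_lph, s$qt_ret_lph, s$fc_value, s$c_eff_gpl)
    mode_tr[i] <<- s$mode
    phase_tr[i] <<- s$valve_phase
    c_seg[i, ] <<- s$c_gpl
  }
  fill(1L, state)
  if (n_steps > 0) {
    for (i in seq_len(n_steps)) {
      state <- simulate_step(state, scenario, params, config,
                             rcake_ss_ref_per_m)
      fill(i + 1L, state)
    }
  }
  if (state$clipped_retentate)
    warning("simulate_run: permeate draw exceeded feed-side flow in at least ",
            "one step; retentate clipped at zero", call. = FALSE)

  trace <- as.data.frame(tr)
  trace$mode <- mode_tr
  trace$valve_phase <- phase_tr

  run <- structure(list(trace = trace, c_seg = c_seg, final_state = state,
                        scenario = scenario, config = config),
                   class = "dcf_run")
  run$log <- if (keep_log) process_log_from_trace(run) else NULL
  run
}

# Sample the full-resolution trace on the plant's 5 s logging grid
# (zero-order hold on the most recent completed control cycle).
process_log_from_trace <- function(run) {
  trace <- run$trace
  config <- run$config
  end_s <- run$scenario$duration_h * 3600
  if (end_s <= 0 || nrow(trace) < 2) {
    return(data.frame(timestamp_s = numeric(0), tmp_bar = numeric(0),
                      q_per_lph = numeric(0), q_per_setpoint_lph = numeric(0),
                      torque_nm = numeric(0), valve_pct = numeric(0),
                      mode = character(0), status = character(0)))
  }
  ticks <- seq(0, end_s, by = config$log_interval_s)
  idx <- findInterval(ticks / 3600 + 1e-12, trace$time_h)
  data.frame(
    timestamp_s = ticks,
    tmp_bar = trace$tmp_bar[idx],
    q_per_lph = trace$q_per_total_lph[idx],
    q_per_setpoint_lph = trace$q_set_lph[idx],
    torque_nm = trace$torque_nm[idx],
    valve_pct = trace$valve_pct[idx],
    mode = trace$mode[idx],
    status = "running",
    stringsAsFactors = FALSE
  )
}

#' Productivity of a run
#'
#' Time-averaged total permeate flow over the run (trapezoidal rule on the
#' simulation trace), in L/h. This is the optimisation objective of the
#' metamodel.
#'
#' @param run a `dcf_run` object (or a data.frame with columns `time_h` and
#'   `q_per_total_lph`).
#' @return productivity in L/h.
#' @export
productivity <- function(run) {
  trace <- if (inherits(run, "dcf_run")) run$trace else run
  if (is.null(trace) || nrow(trace) < 2)
    stop("productivity: empty or single-point trace", call. = FALSE)
  t <- trace$time_h
  q <- trace$q_per_total_lph
  sum(diff(t) * (head(q, -1) + tail(q, -1)) / 2) / (t[length(t)] - t[1])
}

#' First retentate-valve opening time
#'
#' @param run a `dcf_run` object.
#' @return time in hours of the first closed -> discharging transition, or
#'   `NA` if the valve never opened.
#' @export
first_valve_opening <- function(run) {
  i <- match("discharging", run$trace$valve_phase)
  if (is.na(i)) NA_real_ else run$trace$time_h[i]
}

#' Time of the latched switch to TMP-controlled mode
#'
#' @param run a `dcf_run` object.
#' @return time in hours of the switch, or `NA` if the run stayed
#'   flow-controlled.
#' @export
mode_switch_time <- function(run) {
  i <- match("tmp_controlled", run$trace$mode)
  if (is.na(i)) NA_real_ else run$trace$time_h[i]
}

#' @export
print.dcf_run <- function(x, ...) {
  tr <- x$trace
  cat(sprintf("DCF run: %.2f h, %d steps\n", tr$time_h[nrow(tr)],
              nrow(tr) - 1L))
  cat(sprintf("  productivity     %.1f L/h\n",
              if (nrow(tr) >= 2) productivity(x) else NA))
  cat(sprintf("  final TMP        %.3f bar (%s)\n", tr$tmp_bar[nrow(tr)],
              tr$mode[nrow(tr)]))
  vo <- first_valve_opening(x)
  cat(sprintf("  valve opened     %s\n",
              if (is.na(vo)) "never" else sprintf("%.2f h", vo)))
  ms <- mode_switch_time(x)
  cat(sprintf("  TMP mode since   %s\n",
              if (is.na(ms)) "never (flow-controlled throughout)"
              else sprintf("%.2f h", ms)))
  invisible(x)
}
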