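# Closed-loop digital twin: startup initialisations, torque soft sensor,
# metamodel setpoint recommendation, 5-min window simulation with
# TMP-mismatch model adaptation.
#
# The twin runs against an injected virtual clock: it polls the plant status
# every 60 s and executes an optimization cycle every 5 min (both virtual
# time), so a 10 h closed loop executes in seconds.

#' Intrinsic membrane resistance from the clean-water flux
#'
#' Inverts the Darcy relation at the post-cleaning water-flux measurement:
#' `Rm = TMP * A_total / (eta_water * Q)` (SI internally).
#'
#' @param water_flux_lph measured permeate water flux, L/h (> 0).
#' @param water_tmp_bar TMP during the water-flux measurement, bar (> 0).
#' @param params a [dcf_model_parameters()] object (water viscosity).
#' @param config a [dcf_plant_config()] object (total filter area).
#' @return membrane resistance in m^-1.
#' @export
init_membrane_resistance <- function(water_flux_lph, water_tmp_bar, params,
                                     config) {
  if (water_flux_lph <= 0 || water_tmp_bar <= 0)
    stop("init_membrane_resistance: flux and TMP must be > 0", call. = FALSE)
  (water_tmp_bar * BAR_TO_PA) * config$total_filter_area_m2 /
    (params$eta_water_pas * water_flux_lph * LPH_TO_M3S)
}

#' Initialise the cake kinetic integral from a TMP/flow measurement
#'
#' Cake formation is already detectable while the chamber fills, so at the
#' moment regular filtration starts the cake kinetic integral is initialised
#' from the measured TMP and permeate flow: the Darcy relation gives the
#' total resistance, membrane (and pore, assumed zero at start) resistances
#' are subtracted, and the Langmuir cake relation is inverted,
#' `kc = k_cake * Rcake / (Rcake_SS - Rcake)`, applied uniformly to all
#' segments. If the implied cake resistance reaches the steady-state value
#' the integral is capped at a large finite value with a warning.
#'
#' @param measured_tmp_bar measured TMP, bar.
#' @param measured_q_lph measured total permeate flow, L/h (> 0).
#' @param state a `dcf_sim_state` to initialise (typically fresh).
#' @param params a [dcf_model_parameters()] object.
#' @param config a [dcf_plant_config()] object.
#' @param rcake_ss_ref_per_m reference steady-state cake resistance used in
#'   the inversion.
#' @return the state with `kc` set and the measured TMP/flows stored as the
#'   previous-cycle values.
#' @export
init_cake_kinetic <- function(measured_tmp_bar, measured_q_lph, state, params,
                              config,
                              rcake_ss_ref_per_m = params$Rcake_SS_ref_per_m) {
  if (measured_q_lph <= 0)
    stop("init_cake_kinetic: measured flow must be > 0", call. = FALSE)
  n <- config$n_segments
  q_seg <- measured_q_lph / n
  rtot <- (measured_tmp_bar * BAR_TO_PA) * config$segment_area_m2 /
    (params$eta_water_pas * q_seg * LPH_TO_M3S)
  rcake <- pmax(rtot - params$Rm_per_m - state$rpore_per_m, 0)
  rss <- steady_state_cake_resistance(measured_q_lph, 0, state$c_gpl, params,
                                      rcake_ss_ref_per_m)
  kc <- ifelse(rcake >= rss,
               {if (any(rcake >= rss))
                 warning("init_cake_kinetic: implied cake resistance at or ",
                         "above steady state; capping kinetic integral",
                         call. = FALSE)
                 1e9},
               params$k_cake_ghpl * rcake / (rss - rcake))
  state$kc <- as.numeric(kc)
  state$rcake_per_m <- as.numeric(pmin(rcake, rss))
  state$rtot_per_m <- params$Rm_per_m + state$rpore_per_m + state$rcake_per_m
  state$tmp_bar <- measured_tmp_bar
  state$q_per_lph <- rep(q_seg, n)
  state$q_shear_lph <- measured_q_lph
  state
}

#' Torque soft sensor for the chamber solids concentration
#'
#' Inverts the viscosity-torque chain: `eta = (M - M_seal) / (k_g * omega)`,
#' then `c = ln(eta / eta_ref) / (k_eta * fc)`. The recovered value is the
#' torque-equivalent lumped chamber concentration (see
#' [effective_concentration()]). With `clip = TRUE` the estimate is clipped
#' to `bounds` (the metamodel design space) and flagged.
#'
#' @param measured_torque_nm measured membrane drive torque, N m (> M_seal).
#' @param fc_value concentration correction factor at the measurement time.
#' @param params a [dcf_model_parameters()] object.
#' @param config a [dcf_plant_config()] object.
#' @param clip clip the estimate to `bounds`.
#' @param bounds length-2 clipping interval in g/L.
#' @return list with `c_gpl` and `out_of_range` (TRUE if clipped).
#' @export
soft_sensor_concentration <- function(measured_torque_nm, fc_value, params,
                                      config, clip = TRUE,
                                      bounds = c(20, 100)) {
  if (measured_torque_nm <= params$M_seal_nm)
    stop("soft_sensor_concentration: torque at or below the seal torque ",
         "carries no concentration information", call. = FALSE)
  eta <- (measured_torque_nm - params$M_seal_nm) /
    (params$k_g_nms * config$rotation_speed_rpm)
  c_est <- log(eta / params$eta_ref_pas) / (params$k_eta_lpg * fc_value)
  out <- FALSE
  if (clip) {
    out <- c_est < bounds[1] || c_est > bounds[2]
    c_est <- min(max(c_est, bounds[1]), bounds[2])
  }
  list(c_gpl = c_est, out_of_range = out)
}

#' Setpoint recommendation from the metamodel
#'
#' Delegates to [optimal_setpoint()] at the live feed-concentration and
#' cake-resistance estimates and clips the result to the twin's admissible
#' setpoint interval.
#'
#' @param surface a fitted `dcf_surface`.
#' @param c_feed_est_gpl current feed-concentration estimate, g/L.
#' @param rcake_ss_ref_est_per_m current reference cake-resistance estimate,
#'   m^-1.
#' @param twin_config a [dcf_twin_config()] object.
#' @return list with `q_set_lph`, `predicted_productivity_lph`, `boundary`.
#' @export
recommend_setpoint <- function(surface, c_feed_est_gpl, rcake_ss_ref_est_per_m,
                               twin_config = dcf_twin_config()) {
  rec <- optimal_setpoint(surface, c_feed_est_gpl, rcake_ss_ref_est_per_m)
  rec$q_set_lph <- min(max(rec$q_set_lph, twin_config$setpoint_min_lph),
                       twin_config$setpoint_max_lph)
  rec
}

#' Simulate the past optimization window and compare TMP
#'
#' Advances the twin's belief state over the past window using the setpoint
#' that was actually active in the plant and the current feed-concentration
#' estimate, then compares the terminal simulated TMP with the measured one.
#'
#' @param belief_state `dcf_sim_state` synchronized to the window start.
#' @param q_set_lph setpoint active in the plant during the window, L/h.
#' @param c_feed_gpl current feed-concentration estimate, g/L.
#' @param measured_tmp_bar plant TMP at the window end, bar.
#' @param params belief model parameters.
#' @param config a [dcf_plant_config()] object.
#' @param n_steps number of control cycles in the window.
#' @param rcake_ss_ref_per_m current reference cake-resistance estimate.
#' @return list with `state` (belief advanced to the window end),
#'   `tmp_pred_bar` and `mismatch_bar` (= predicted - measured).
#' @export
simulate_window_and_compare <- function(belief_state, q_set_lph, c_feed_gpl,
                                        measured_tmp_bar, params, config,
                                        n_steps,
                                        rcake_ss_ref_per_m = params$Rcake_SS_ref_per_m) {
  scen <- structure(list(initial_q_set_lph = q_set_lph,
                         c_feed_gpl = c_feed_gpl,
                         duration_h = Inf, schedule = NULL),
                    class = "dcf_scenario")
  state <- belief_state
  for (i in seq_len(n_steps))
    state <- simulate_step(state, scen, params, config, rcake_ss_ref_per_m)
  list(state = state,
       tmp_pred_bar = state$tmp_bar,
       mismatch_bar = state$tmp_bar - measured_tmp_bar)
}

#' Adapt the reference steady-state cake resistance
#'
#' One-shot multiplicative adaptation per optimization cycle: if the
#' simulated TMP over-predicts the measurement by more than the threshold the
#' estimate is reduced by the adaptation step (TMP increases monotonically
#' with the cake resistance), if it under-predicts it is increased; within
#' the threshold nothing changes. The estimate is kept inside `bounds` (the
#' metamodel design space, outside which the surface is untrusted).
#'
#' @param rcake_ss_ref_est_per_m current estimate, m^-1.
#' @param mismatch_bar predicted minus measured TMP, bar.
#' @param twin_config a [dcf_twin_config()] object.
#' @param bounds length-2 admissible interval for the estimate, m^-1.
#' @return list with `rcake_ss_ref_est_per_m`, `adapted` (-1, 0 or +1 step
#'   direction) and `bounded` (TRUE if the result was clipped to `bounds`).
#' @export
adapt_model <- function(rcake_ss_ref_est_per_m, mismatch_bar,
                        twin_config = dcf_twin_config(),
                        bounds = c(6e12, 2.2e13)) {
  stopifnot(is.finite(mismatch_bar))
  est <- rcake_ss_ref_est_per_m
  adapted <- 0L
  if (mismatch_bar > twin_config$tmp_mismatch_threshold_bar) {
    est <- est * (1 - twin_config$adaptation_step)
    adapted <- -1L
  } else if (mismatch_bar < -twin_config$tmp_mismatch_threshold_bar) {
    est <- est * (1 + twin_config$adaptation_step)
    adapted <- 1L
  }
  bounded <- est < bounds[1] || est > bounds[2]
  est <- min(max(est, bounds[1]), bounds[2])
  list(rcake_ss_ref_est_per_m = est, adapted = adapted, bounded = bounded)
}

#' Run the digital twin closed loop against a plant
#'
#' Polls the plant status every 60 s of virtual time; on run detection
#' performs the startup initialisations (membrane resistance from the
#' clean-water flux where the plant provides one, cake kinetic integral from
#' the first TMP/flow sample, initial feed-concentration estimate from
#' torque) and pushes an initial setpoint recommendation. Every 5 min it
#' executes the optimization cycle: torque soft sensor -> setpoint
#' recommendation (pushed through the `accept` callback) -> simulation of the
#' past window from the belief state -> TMP-mismatch model adaptation.
#'
#' The torque soft sensor recovers the chamber concentration; the twin
#' converts it to a feed-concentration estimate with the belief model's own
#' chamber-to-feed concentration ratio before clipping to the design space
#' (see the methods vignette).
#'
#' @param plant a plant interface (see [make_virtual_plant()] /
#'   [make_replay_plant()]).
#' @param surface a fitted `dcf_surface`.
#' @param params the twin's model parameters.
#' @param config a [dcf_plant_config()] object.
#' @param twin_config a [dcf_twin_config()] object.
#' @param accept optional authorization callback `function(q_set_lph)`
#'   returning TRUE/FALSE; default auto-accepts every recommendation.
#' @param max_duration_h safety bound on the virtual-time loop.
#' @return object of class `dcf_twin_result`: `session` (one row per
#'   optimization cycle: `time_h, cfeed_est_gpl, rcake_ss_ref_est,
#'   q_set_recommended_lph, tmp_pred_bar, tmp_meas_bar, adapted`),
#'   `recommendations`, `adaptations`, final `rcake_ss_ref_est_per_m`,
#'   `params` (belief parameters incl. initialised Rm), `n_cycles`.
#' @export
run_twin <- function(plant, surface, params, config = dcf_plant_config(),
                     twin_config = dcf_twin_config(), accept = NULL,
                     max_duration_h = 100) {
  empty <- function() structure(
    list(session = data.frame(), recommendations = data.frame(),
         adaptations = data.frame(),
         rcake_ss_ref_est_per_m = params$Rcake_SS_ref_per_m,
         params = params, n_cycles = 0L), class = "dcf_twin_result")
  if (plant$read_status() != "running") return(empty())

  bounds_r <- surface$design$rcake_ss_ref_per_m
  bounds_c <- surface$design$c_feed_gpl

  # --- startup initialisations -------------------------------------------
  wf <- plant$water_flux()
  if (!is.null(wf))
    params$Rm_per_m <- init_membrane_resistance(wf$q_lph, wf$tmp_bar, params,
                                                config)
  rcake_est <- params$Rcake_SS_ref_per_m
  s0 <- plant$read_sensors()
  ss0 <- soft_sensor_concentration(s0$torque_nm, fc_correction(0, params),
                                   params, config, clip = FALSE)
  cfeed_est <- min(max(ss0$c_gpl, bounds_c[1]), bounds_c[2])
  rec <- recommend_setpoint(surface, cfeed_est, rcake_est, twin_config)
  accepted <- is.null(accept) || isTRUE(accept(rec$q_set_lph))
  if (accepted) plant$write_setpoint(rec$q_set_lph)
  active_set <- if (accepted) rec$q_set_lph else plant$current_setpoint()

  scen0 <- structure(list(initial_q_set_lph = active_set,
                          c_feed_gpl = cfeed_est, duration_h = Inf,
                          schedule = NULL), class = "dcf_scenario")
  belief <- new_sim_state(scen0, params, config)
  belief <- init_cake_kinetic(max(s0$tmp_bar, 1e-6), max(s0$q_per_lph, 1e-6),
                              belief, params, config, rcake_est)

  # --- virtual-clock loop ------------------------------------------------
  step_s <- config$time_step_s
  poll_s <- twin_config$status_poll_interval_s
  opt_s <- twin_config$optimization_interval_min * 60
  next_poll <- poll_s
  next_opt <- opt_s
  last_cycle_s <- plant$time_h() * 3600
  session <- list()
  recommendations <- list(data.frame(time_h = 0, q_set_lph = rec$q_set_lph,
                                     cfeed_est_gpl = cfeed_est,
                                     accepted = accepted))
  adaptations <- list()
  t_s <- plant$time_h() * 3600

  while (t_s / 3600 < max_duration_h) {
    t_prev <- t_s
    plant$advance_steps(1L)
    t_s <- plant$time_h() * 3600
    if (t_s <= t_prev) break  # plant cannot advance further

    if (t_s + 1e-6 >= next_opt) {
      sens <- plant$read_sensors()
      window_steps <- round((t_s - last_cycle_s) / step_s)
      # simulate the past window with the estimates that were current during
      # it, advancing the belief to the measurement time
      w <- simulate_window_and_compare(belief, active_set, scen0$c_feed_gpl,
                                       sens$tmp_bar, params, config,
                                       window_steps, rcake_est)
      # soft sensor at the measurement time; chamber -> feed conversion via
      # the belief's own concentration ratio
      ss <- tryCatch(
        soft_sensor_concentration(sens$torque_nm, w$state$fc_value, params,
                                  config, clip = FALSE),
        error = function(e) NULL)
      if (!is.null(ss)) {
        ratio <- scen0$c_feed_gpl / w$state$c_eff_gpl
        cfeed_est <- min(max(ss$c_gpl * ratio, bounds_c[1]), bounds_c[2])
      }
      rec <- recommend_setpoint(surface, cfeed_est, rcake_est, twin_config)
      accepted <- is.null(accept) || isTRUE(accept(rec$q_set_lph))
      ad <- adapt_model(rcake_est, w$mismatch_bar, twin_config, bounds_r)
      if (ad$adapted != 0L)
        adaptations[[length(adaptations) + 1L]] <-
          data.frame(time_h = t_s / 3600, mismatch_bar = w$mismatch_bar,
                     factor_applied = ad$rcake_ss_ref_est_per_m / rcake_est)
      rcake_est <- ad$rcake_ss_ref_est_per_m

      session[[length(session) + 1L]] <- data.frame(
        time_h = t_s / 3600, cfeed_est_gpl = cfeed_est,
        rcake_ss_ref_est = rcake_est, q_set_recommended_lph = rec$q_set_lph,
        tmp_pred_bar = w$tmp_pred_bar, tmp_meas_bar = sens$tmp_bar,
        adapted = ad$adapted)
      recommendations[[length(recommendations) + 1L]] <-
        data.frame(time_h = t_s / 3600, q_set_lph = rec$q_set_lph,
                   cfeed_est_gpl = cfeed_est, accepted = accepted)

      if (accepted) {
        plant$write_setpoint(rec$q_set_lph)
        active_set <- rec$q_set_lph
      }
      belief <- w$state
      scen0$c_feed_gpl <- cfeed_est
      last_cycle_s <- t_s
      next_opt <- next_opt + opt_s
    }

    if (t_s + 1e-6 >= next_poll) {
      next_poll <- next_poll + poll_s
      if (plant$read_status() != "running") break
    }
  }

  structure(list(
    session = do.call(rbind, session),
    recommendations = do.call(rbind, recommendations),
    adaptations = if (length(adaptations)) do.call(rbind, adaptations)
                  else data.frame(),
    rcake_ss_ref_est_per_m = rcake_est,
    params = params,
    n_cycles = length(session)
  ), class = "dcf_twin_result")
}

#' @export
print.dcf_twin_result <- function(x, ...) {
  cat(sprintf("DCF twin session: %d optimization cycles, %d adaptations\n",
              x$n_cycles,
              if (nrow(x$adaptations)) nrow(x$adaptations) else 0L))
  cat(sprintf("  final Rcake_SS_ref estimate: %.3e m^-1\n",
              x$rcake_ss_ref_est_per_m))
  if (x$n_cycles > 0) {
    last <- x$session[x$n_cycles, ]
    cat(sprintf("  last cycle: t = %.2f h, cfeed_est = %.1f g/L, rec = %.0f L/h\n",
                last$time_h, last$cfeed_est_gpl, last$q_set_recommended_lph))
  }
  invisible(x)
}
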