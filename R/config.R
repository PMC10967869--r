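#' Plant configuration (machine geometry and PLC setpoints)
#'
#' Describes the filtration machine and the behaviour of its programmable
#' logic controller: a four-shaft rotating-disc filter with 32.8 m2 of
#' membrane area, conceptually split into `n_segments` well-mixed chambers in
#' series. The PLC starts every run in flow-controlled mode, latches to
#' TMP-controlled mode the first time the transmembrane pressure exceeds
#' `tmp_setpoint_bar`, and drives the retentate valve from the membrane-drive
#' torque: the valve opens at `torque_open_setpoint_nm`, ramps up by
#' `valve_step_pct` per control cycle while the torque still rises, and closes
#' again below `torque_close_threshold_nm` (10 % hysteresis).
#'
#' @param total_filter_area_m2 total membrane area in m2.
#' @param n_segments number of series segments used to resolve the axial
#'   solids gradient.
#' @param membrane_diameter_mm disc diameter in mm (informational).
#' @param rotation_speed_rpm membrane drive speed in min^-1.
#' @param tmp_setpoint_bar TMP at which the plant latches to TMP control, bar.
#' @param torque_open_setpoint_nm torque opening the retentate valve, N m.
#' @param torque_close_threshold_nm torque closing the valve again, N m.
#' @param min_valve_opening_pct initial valve opening when discharge starts, %.
#' @param valve_step_pct valve-opening increment per control cycle while the
#'   torque keeps rising, percentage points.
#' @param time_step_s simulation/control cycle time in seconds.
#' @param log_interval_s cadence of the plant process log in seconds.
#' @return an object of class `dcf_plant_config`.
#' @export
dcf_plant_config <- function(total_filter_area_m2 = 32.8,
                             n_segments = 4L,
                             membrane_diameter_mm = 312,
                             rotation_speed_rpm = 343,
                             tmp_setpoint_bar = 0.8,
                             torque_open_setpoint_nm = 300,
                             torque_close_threshold_nm = 270,
                             min_valve_opening_pct = 5,
                             valve_step_pct = 1,
                             time_step_s = 3.6,
                             log_interval_s = 5) {
  cfg <- list(
    total_filter_area_m2 = total_filter_area_m2,
    n_segments = as.integer(n_segments),
    membrane_diameter_mm = membrane_diameter_mm,
    rotation_speed_rpm = rotation_speed_rpm,
    tmp_setpoint_bar = tmp_setpoint_bar,
    torque_open_setpoint_nm = torque_open_setpoint_nm,
    torque_close_threshold_nm = torque_close_threshold_nm,
    min_valve_opening_pct = min_valve_opening_pct,
    valve_step_pct = valve_step_pct,
    time_step_s = time_step_s,
    log_interval_s = log_interval_s
  )
  cfg$segment_area_m2 <- cfg$total_filter_area_m2 / cfg$n_segments
  class(cfg) <- "dcf_plant_config"
  validate_plant_config(cfg)
  cfg
}

validate_plant_config <- function(cfg) {
  problems <- character()
  num <- vapply(cfg[setdiff(names(cfg), "n_segments")], function(x)
    is.numeric(x) && length(x) == 1 && is.finite(x), logical(1))
  if (!all(num)) {
    problems <- c(problems, paste0(
      "non-scalar or non-finite fields: ",
      paste(names(num)[!num], collapse = ", ")))
  } else {
    pos <- vapply(cfg[vapply(cfg, is.numeric, logical(1))],
                  function(x) all(x > 0), logical(1))
    if (!all(pos))
      problems <- c(problems, paste0("fields must be positive: ",
                                     paste(names(pos)[!pos], collapse = ", ")))
    if (cfg$n_segments < 1L)
      problems <- c(problems, "n_segments must be >= 1")
    if (cfg$torque_close_threshold_nm >= cfg$torque_open_setpoint_nm)
      problems <- c(problems,
                    "torque_close_threshold_nm must be < torque_open_setpoint_nm")
    if (cfg$min_valve_opening_pct > 100)
      problems <- c(problems, "min_valve_opening_pct must be <= 100")
  }
  if (length(problems))
    stop("invalid plant config:\n  - ", paste(problems, collapse = "\n  - "),
         call. = FALSE)
  invisible(cfg)
}

#' Model parameters of the fouling / torque / valve correlations
#'
#' All physical and empirical constants of the process dynamics model. The
#' shipped defaults (see [dcf_default_parameters()]) are a calibrated set: the
#' magnitudes of the fouling and torque constants are not publicly documented
#' for the industrial asset, so they were tuned once so that the packaged
#' reference scenario reproduces the documented plant behaviour (retentate
#' valve opening 2.5 h into the run, TMP plateau below 0.8 bar, latched switch
#' to TMP control after the mid-run setpoint escalation).
#'
#' @param eta_water_pas permeate (water) dynamic viscosity, Pa s.
#' @param Rm_per_m intrinsic membrane resistance, m^-1.
#' @param Rpore_ref_per_m reference pore resistance scale, m^-1.
#' @param k_pore pore-blocking sensitivity, (g/m2)^-1 on the pore kinetic
#'   integral.
#' @param k_cake_ghpl cake-formation half-saturation constant, g h/L.
#' @param Rcake_SS_ref_per_m reference steady-state cake resistance, m^-1.
#'   Also a design-space factor of the metamodel and the parameter adapted by
#'   the digital twin.
#' @param Qt_per_ref_lph reference total permeate flow for the cake-shear
#'   term, L/h.
#' @param TMP_compress_bar cake compressibility pressure scale, bar.
#' @param c_ref_gpl reference solids concentration, g/L.
#' @param nQ exponent of the permeate-flow ratio in the steady-state cake
#'   resistance (dimensionless, any sign).
#' @param nc exponent of the concentration ratio (dimensionless, any sign).
#' @param fine_fraction fraction of the feed solids counted as membrane-passing
#'   fines that drive pore blocking; dimensionless in \\[0, 1\\].
#' @param eta_ref_pas retentate viscosity at zero solids, Pa s.
#' @param k_eta_lpg exponential viscosity-concentration coefficient, L/g.
#' @param fc_floor floor of the empirical concentration correction, in (0, 1].
#' @param fc_tau_h decay time of the concentration correction, h.
#' @param M_seal_nm torque consumed by the shaft seals, N m.
#' @param k_g_nms geometry factor linking rotation speed times viscosity to
#'   torque, N m min / (Pa s).
#' @param k_valve_lphbar retentate valve cross-section coefficient,
#'   L / (h bar %).
#' @param sigma_f_bar flow stress of the retentate at the valve, bar (acts on
#'   the TMP x opening product).
#' @param V_segment_l working volume of one chamber segment, L.
#' @param shear_tau_h relaxation time of the permeate flow entering the
#'   steady-state cake shear term, h: the cake responds to the sustained flow
#'   level, not to single-cycle excursions (also keeps the previous-step flow
#'   coupling numerically stable in TMP-controlled operation).
#' @return an object of class `dcf_model_parameters`.
#' @export
dcf_model_parameters <- function(eta_water_pas = 1e-3,
                                 Rm_per_m = 4e12,
                                 Rpore_ref_per_m = 2e12,
                                 k_pore = 1e-4,
                                 k_cake_ghpl = 30,
                                 Rcake_SS_ref_per_m = 1.4e13,
                                 Qt_per_ref_lph = 880,
                                 TMP_compress_bar = 0.7,
                                 c_ref_gpl = 60,
                                 nQ = 1.85,
                                 nc = 0.1,
                                 fine_fraction = 0.2,
                                 eta_ref_pas = 1e-3,
                                 k_eta_lpg = 0.04,
                                 fc_floor = 0.75,
                                 fc_tau_h = 2.0,
                                 M_seal_nm = 50,
                                 k_g_nms = 8.85,
                                 k_valve_lphbar = 40,
                                 sigma_f_bar = 1.0,
                                 V_segment_l = 250,
                                 shear_tau_h = 0.05) {
  p <- list(
    eta_water_pas = eta_water_pas, Rm_per_m = Rm_per_m,
    Rpore_ref_per_m = Rpore_ref_per_m, k_pore = k_pore,
    k_cake_ghpl = k_cake_ghpl, Rcake_SS_ref_per_m = Rcake_SS_ref_per_m,
    Qt_per_ref_lph = Qt_per_ref_lph, TMP_compress_bar = TMP_compress_bar,
    c_ref_gpl = c_ref_gpl, nQ = nQ, nc = nc, fine_fraction = fine_fraction,
    eta_ref_pas = eta_ref_pas, k_eta_lpg = k_eta_lpg, fc_floor = fc_floor,
    fc_tau_h = fc_tau_h, M_seal_nm = M_seal_nm, k_g_nms = k_g_nms,
    k_valve_lphbar = k_valve_lphbar, sigma_f_bar = sigma_f_bar,
    V_segment_l = V_segment_l, shear_tau_h = shear_tau_h
  )
  class(p) <- "dcf_model_parameters"
  validate_model_parameters(p)
  p
}

validate_model_parameters <- function(p) {
  problems <- character()
  exempt <- c("nQ", "nc")  # exponents may take any real value
  for (nm in names(p)) {
    x <- p[[nm]]
    if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
      problems <- c(problems, paste0(nm, " must be a finite scalar"))
    } else if (!(nm %in% exempt) && x <= 0 &&
               !(nm == "fine_fraction" && x == 0)) {
      problems <- c(problems, paste0(nm, " must be strictly positive"))
    }
  }
  if (is.numeric(p$fine_fraction) &&
      (p$fine_fraction < 0 || p$fine_fraction > 1))
    problems <- c(problems, "fine_fraction must lie in [0, 1]")
  if (is.numeric(p$fc_floor) && (p$fc_floor <= 0 || p$fc_floor > 1))
    problems <- c(problems, "fc_floor must lie in (0, 1]")
  if (length(problems))
    stop("invalid model parameters:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  invisible(p)
}

#' Shipped calibrated default parameter set
#'
#' Returns the packaged defaults of [dcf_model_parameters()]. These are the
#' parameters used by the reference scenario, the DoE and all examples; they
#' were calibrated once (scripts under the package sources) so that the
#' reference 10 h simulation reproduces the documented plant behaviour.
#'
#' @return a `dcf_model_parameters` object.
#' @export
dcf_default_parameters <- function() dcf_model_parameters()

#' Simulation scenario
#'
#' @param initial_q_set_lph initial permeate flow-rate setpoint, L/h.
#' @param c_feed_gpl solids concentration of the feed, g/L.
#' @param duration_h process duration, h.
#' @param schedule optional setpoint schedule: data.frame with columns
#'   `time_h` (strictly increasing, < duration) and `q_set_lph`.
#' @return an object of class `dcf_scenario`.
#' @export
dcf_scenario <- function(initial_q_set_lph, c_feed_gpl, duration_h,
                         schedule = NULL) {
  stopifnot(is.numeric(initial_q_set_lph), initial_q_set_lph > 0,
            is.numeric(c_feed_gpl), c_feed_gpl >= 0,
            is.numeric(duration_h), duration_h >= 0)
  if (!is.null(schedule)) {
    if (!is.data.frame(schedule) ||
        !all(c("time_h", "q_set_lph") %in% names(schedule)))
      stop("schedule must be a data.frame with columns time_h, q_set_lph",
           call. = FALSE)
    if (nrow(schedule) && (is.unsorted(schedule$time_h, strictly = TRUE) ||
                           any(schedule$time_h <= 0) ||
                           any(schedule$time_h >= duration_h)))
      stop("schedule times must be strictly increasing and within (0, duration)",
           call. = FALSE)
  }
  structure(list(initial_q_set_lph = initial_q_set_lph,
                 c_feed_gpl = c_feed_gpl,
                 duration_h = duration_h,
                 schedule = schedule),
            class = "dcf_scenario")
}

#' The packaged reference scenario
#'
#' 10 h run at 60 g/L feed, initial permeate setpoint 415 L/h, escalated by
#' +80 L/h at 5 h to showcase the switch from flow-controlled to
#' TMP-controlled operation. With the shipped default parameters the retentate
#' valve opens 2.5 h into the run and the TMP stays pinned at 0.8 bar after
#' the setpoint step.
#'
#' @return a `dcf_scenario`.
#' @export
dcf_reference_scenario <- function() {
  dcf_scenario(initial_q_set_lph = 415, c_feed_gpl = 60, duration_h = 10,
               schedule = data.frame(time_h = 5, q_set_lph = 415 + 80))
}

#' Digital twin configuration
#'
#' @param status_poll_interval_s plant status poll cadence, s.
#' @param optimization_interval_min optimization cycle length, min.
#' @param tmp_mismatch_threshold_bar TMP simulation/measurement mismatch above
#'   which the cake-resistance parameter is adapted, bar.
#' @param adaptation_step fractional multiplicative adaptation step of the
#'   reference steady-state cake resistance, in (0, 1).
#' @param setpoint_min_lph,setpoint_max_lph bounds of admissible setpoint
#'   recommendations (the trained design space), L/h.
#' @return an object of class `dcf_twin_config`.
#' @export
dcf_twin_config <- function(status_poll_interval_s = 60,
                            optimization_interval_min = 5,
                            tmp_mismatch_threshold_bar = 0.1,
                            adaptation_step = 0.10,
                            setpoint_min_lph = 400,
                            setpoint_max_lph = 1200) {
  tc <- list(status_poll_interval_s = status_poll_interval_s,
             optimization_interval_min = optimization_interval_min,
             tmp_mismatch_threshold_bar = tmp_mismatch_threshold_bar,
             adaptation_step = adaptation_step,
             setpoint_min_lph = setpoint_min_lph,
             setpoint_max_lph = setpoint_max_lph)
  bad <- vapply(tc, function(x)
    !is.numeric(x) || length(x) != 1 || !is.finite(x) || x <= 0, logical(1))
  problems <- character()
  if (any(bad))
    problems <- c(problems, paste0("fields must be positive scalars: ",
                                   paste(names(tc)[bad], collapse = ", ")))
  if (!any(bad)) {
    if (tc$adaptation_step >= 1)
      problems <- c(problems, "adaptation_step must lie in (0, 1)")
    if (tc$setpoint_min_lph >= tc$setpoint_max_lph)
      problems <- c(problems, "setpoint_min_lph must be < setpoint_max_lph")
  }
  if (length(problems))
    stop("invalid twin config:\n  - ", paste(problems, collapse = "\n  - "),
         call. = FALSE)
  structure(tc, class = "dcf_twin_config")
}

#' @export
print.dcf_plant_config <- function(x, ...) {
  cat("DCF plant config:",
      sprintf("%.1f m2 in %d segments, %g rpm;", x$total_filter_area_m2,
              x$n_segments, x$rotation_speed_rpm),
      sprintf("TMP setpoint %g bar; valve %g/%g N m; dt %g s\n",
              x$tmp_setpoint_bar, x$torque_open_setpoint_nm,
              x$torque_close_threshold_nm, x$time_step_s))
  invisible(x)
}

#' @export
print.dcf_model_parameters <- function(x, ...) {
  cat("DCF model parameters:\n")
  for (nm in names(x)) cat(sprintf("  %-22s %g\n", nm, x[[nm]]))
  invisible(x)
}

#' @export
print.dcf_scenario <- function(x, ...) {
  cat(sprintf("DCF scenario: %g L/h initial setpoint, %g g/L feed, %g h\n",
              x$initial_q_set_lph, x$c_feed_gpl, x$duration_h))
  if (!is.null(x$schedule) && nrow(x$schedule))
    cat("  setpoint schedule:",
        paste(sprintf("%g h -> %g L/h", x$schedule$time_h,
                      x$schedule$q_set_lph), collapse = ", "), "\n")
  invisible(x)
}
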