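# Virtual plant: stand-in for the industrial asset. Wraps the process
# dynamics simulator with hidden "true" parameters, multiplicative sensor
# noise, the PLC behaviour and 5 s logging, and implements the plant
# interface contract used by the digital twin:
#   read_status() -> "idle" | "running"
#   read_sensors() -> list(tmp_bar, q_per_lph, torque_nm, valve_pct)
#   write_setpoint(q_per_lph)
# plus advance_steps(n), time_h(), water_flux(), current_setpoint(),
# productivity(), log().

#' Virtual plant specification
#'
#' @param params hidden `true` model parameters of the plant (may differ from
#'   the twin's belief parameters).
#' @param config a [dcf_plant_config()] object.
#' @param initial_q_set_lph the plant's own initial permeate setpoint (the
#'   operator recipe), L/h.
#' @param c_feed_gpl feed concentration: a scalar, or a data.frame
#'   `(time_h, c_feed_gpl)` for a piecewise-constant drifting feed (mixing
#'   events in the storage tank).
#' @param duration_h run duration, h.
#' @param rcake_ss_ref_per_m hidden reference steady-state cake resistance.
#' @param initial_kc initial cake kinetic integral (cake formed while the
#'   chamber fills), g h/L.
#' @param noise named list of multiplicative Gaussian noise sigmas per sensor
#'   channel (`tmp`, `q_per`, `torque`, `valve`); default 1 % on tmp, q_per
#'   and torque.
#' @param seed integer seed making the plant's sensor noise bit-reproducible;
#'   `NULL` uses the global RNG stream.
#' @param water_tmp_bar TMP of the post-cleaning water-flux measurement, bar.
#' @return an object of class `dcf_virtual_plant_spec`.
#' @export
virtual_plant_spec <- function(params, config = dcf_plant_config(),
                               initial_q_set_lph = 500, c_feed_gpl = 60,
                               duration_h = 10,
                               rcake_ss_ref_per_m = params$Rcake_SS_ref_per_m,
                               initial_kc = 0,
                               noise = list(tmp = 0.01, q_per = 0.01,
                                            torque = 0.01, valve = 0),
                               seed = NULL, water_tmp_bar = 0.2) {
  stopifnot(inherits(params, "dcf_model_parameters"),
            inherits(config, "dcf_plant_config"),
            duration_h >= 0, initial_kc >= 0)
  noise <- utils::modifyList(list(tmp = 0, q_per = 0, torque = 0, valve = 0),
                             as.list(noise))
  if (any(unlist(noise) < 0))
    stop("virtual_plant_spec: noise sigmas must be >= 0", call. = FALSE)
  structure(list(params = params, config = config,
                 initial_q_set_lph = initial_q_set_lph,
                 c_feed_gpl = c_feed_gpl, duration_h = duration_h,
                 rcake_ss_ref_per_m = rcake_ss_ref_per_m,
                 initial_kc = initial_kc, noise = noise, seed = seed,
                 water_tmp_bar = water_tmp_bar),
            class = "dcf_virtual_plant_spec")
}

feed_at <- function(sched, t_h) {
  if (is.data.frame(sched)) {
    i <- max(1L, findInterval(t_h + 1e-12, sched$time_h))
    sched$c_feed_gpl[i]
  } else sched
}

#' Create a virtual plant
#'
#' Instantiates the plant interface around the process dynamics simulator
#' with the spec's hidden parameters. Sensor readings are corrupted with
#' multiplicative Gaussian noise drawn from a private RNG stream (the global
#' RNG is left untouched when a seed is given); the internal 5 s process log
#' records the same noisy readings. The initial sensor reading at t = 0 is a
#' primed flow/TMP resolution of the initial setpoint against the initial
#' resistances, so the twin's startup initialisations see consistent values.
#'
#' @param spec a [virtual_plant_spec()].
#' @return an environment of class `dcf_virtual_plant` implementing the plant
#'   interface contract.
#' @export
make_virtual_plant <- function(spec) {
  p <- new.env(parent = emptyenv())
  p$spec <- spec
  params <- spec$params
  config <- spec$config
  dt_h <- config$time_step_s / 3600

  c0 <- feed_at(spec$c_feed_gpl, 0)
  scen <- structure(list(initial_q_set_lph = spec$initial_q_set_lph,
                         c_feed_gpl = c0, duration_h = Inf, schedule = NULL),
                    class = "dcf_scenario")
  state <- new_sim_state(scen, params, config)

  # prime the initial reading: resolve flows/TMP for the initial setpoint at
  # the initial resistances (incl. cake formed during chamber filling)
  if (spec$initial_kc > 0) state$kc <- rep(spec$initial_kc, config$n_segments)
  rss0 <- steady_state_cake_resistance(spec$initial_q_set_lph, 0, state$c_gpl,
                                       params, spec$rcake_ss_ref_per_m)
  rcake0 <- cake_resistance(state$kc, rss0, params)
  rtot0 <- params$Rm_per_m + rcake0
  d0 <- distribute_permeate_flow(spec$initial_q_set_lph, rtot0,
                                 params$eta_water_pas, config$segment_area_m2)
  state$rcake_per_m <- rcake0
  state$rtot_per_m <- rtot0
  state$tmp_bar <- d0$tmp_bar
  state$q_per_lph <- d0$q_per_lph
  state$q_feed_lph <- spec$initial_q_set_lph
  state$torque_nm <- torque_from_viscosity(
    viscosity_from_concentration(state$c_gpl, 1, params), params, config)

  p$state <- state
  p$scen <- scen
  p$t_h <- 0
  p$n_steps <- 0L
  p$integral_q <- 0   # trapezoid accumulator for productivity
  p$prev_q <- sum(state$q_per_lph)

  # private RNG stream
  p$rng <- NULL
  if (!is.null(spec$seed)) {
    old <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    set.seed(spec$seed)
    p$rng <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, globalenv())
  }
  draw_noise <- function(n) {
    if (is.null(p$rng)) return(stats::rnorm(n))
    old <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", p$rng, globalenv())
    x <- stats::rnorm(n)
    p$rng <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, globalenv())
    x
  }
  noisy <- function(x, sigma) {
    if (sigma <= 0) x else x * (1 + sigma * draw_noise(length(x)))
  }

  # 5 s process log (preallocated)
  n_log <- floor(spec$duration_h * 3600 / config$log_interval_s) + 1L
  p$log_mat <- matrix(NA_real_, nrow = n_log, ncol = 6,
                      dimnames = list(NULL, c("timestamp_s", "tmp_bar",
                                              "q_per_lph", "q_per_setpoint_lph",
                                              "torque_nm", "valve_pct")))
  p$log_mode <- character(n_log)
  p$log_i <- 0L
  p$next_log_s <- 0

  log_row <- function() {
    s <- p$state
    no <- spec$noise
    p$log_i <- p$log_i + 1L
    p$log_mat[p$log_i, ] <- c(p$next_log_s,
                              noisy(s$tmp_bar, no$tmp),
                              noisy(sum(s$q_per_lph), no$q_per),
                              p$scen$initial_q_set_lph,
                              noisy(s$torque_nm, no$torque),
                              noisy(s$x_pct, no$valve))
    p$log_mode[p$log_i] <- s$mode
    p$next_log_s <- p$next_log_s + config$log_interval_s
  }
  log_row()

  p$read_status <- function() {
    if (p$t_h < spec$duration_h) "running" else "idle"
  }
  p$read_sensors <- function() {
    s <- p$state
    no <- spec$noise
    list(tmp_bar = noisy(s$tmp_bar, no$tmp),
         q_per_lph = noisy(sum(s$q_per_lph), no$q_per),
         torque_nm = noisy(s$torque_nm, no$torque),
         valve_pct = noisy(s$x_pct, no$valve))
  }
  p$write_setpoint <- function(q_per_lph) {
    p$scen$initial_q_set_lph <- q_per_lph
    invisible(q_per_lph)
  }
  p$current_setpoint <- function() p$scen$initial_q_set_lph
  p$time_h <- function() p$t_h
  p$water_flux <- function() {
    list(q_lph = darcy_flow(spec$water_tmp_bar, params$Rm_per_m,
                            params$eta_water_pas,
                            config$total_filter_area_m2),
         tmp_bar = spec$water_tmp_bar)
  }
  p$advance_steps <- function(n) {
    n_max <- floor(spec$duration_h / dt_h + 1e-9) - p$n_steps
    n <- min(n, n_max)
    if (n <= 0) return(invisible(p$t_h))
    for (i in seq_len(n)) {
      p$scen$c_feed_gpl <- feed_at(spec$c_feed_gpl, p$state$t_h)
      p$state <- simulate_step(p$state, p$scen, params, config,
                               spec$rcake_ss_ref_per_m)
      q <- sum(p$state$q_per_lph)
      p$integral_q <- p$integral_q + dt_h * (p$prev_q + q) / 2
      p$prev_q <- q
      p$n_steps <- p$n_steps + 1L
      p$t_h <- p$state$t_h
      while (p$log_i < n_log && p$t_h * 3600 + 1e-6 >= p$next_log_s)
        log_row()
    }
    invisible(p$t_h)
  }
  p$advance <- function(dt_adv_h) {
    p$advance_steps(ceiling(dt_adv_h / dt_h - 1e-9))
  }
  p$productivity <- function() {
    if (p$t_h <= 0) stop("virtual plant: no steps simulated", call. = FALSE)
    p$integral_q / p$t_h
  }
  p$log <- function() {
    i <- seq_len(p$log_i)
    df <- as.data.frame(p$log_mat[i, , drop = FALSE])
    df$mode <- p$log_mode[i]
    df$status <- "running"
    df
  }
  class(p) <- c("dcf_virtual_plant", "environment")
  p
}

#' Advance a plant and return its sensor readings
#'
#' Convenience wrapper around the plant interface: advances the hidden-
#' parameter simulation by `dt_h` (whole control cycles), applying any
#' setpoint written in the meantime, and returns the noise-corrupted sensor
#' tuple.
#'
#' @param plant a plant from [make_virtual_plant()].
#' @param dt_h time to advance, h.
#' @return list(tmp_bar, q_per_lph, torque_nm, valve_pct).
#' @export
step_plant <- function(plant, dt_h) {
  plant$advance(dt_h)
  plant$read_sensors()
}

#' Replay a recorded process log as a plant interface
#'
#' Adapter exposing the plant interface contract on top of a recorded
#' process-log data.frame (see [read_process_log()]); `write_setpoint()` is
#' recorded but has no effect on the replayed data, and `water_flux()`
#' returns `NULL`.
#'
#' @param log a process-log data.frame.
#' @return an environment of class `dcf_replay_plant`.
#' @export
make_replay_plant <- function(log) {
  p <- new.env(parent = emptyenv())
  p$log <- log
  p$i <- 1L
  p$written <- data.frame(timestamp_s = numeric(0), q_set_lph = numeric(0))
  p$read_status <- function() {
    if (p$i <= nrow(log) && log$status[p$i] == "running") "running" else "idle"
  }
  p$read_sensors <- function() {
    r <- log[min(p$i, nrow(log)), ]
    list(tmp_bar = r$tmp_bar, q_per_lph = r$q_per_lph,
         torque_nm = r$torque_nm, valve_pct = r$valve_pct)
  }
  p$write_setpoint <- function(q) {
    p$written <- rbind(p$written,
                       data.frame(timestamp_s = log$timestamp_s[min(p$i, nrow(log))],
                                  q_set_lph = q))
    invisible(q)
  }
  p$current_setpoint <- function()
    log$q_per_setpoint_lph[min(p$i, nrow(log))]
  p$time_h <- function() log$timestamp_s[min(p$i, nrow(log))] / 3600
  p$water_flux <- function() NULL
  p$advance_steps <- function(n) {
    p$i <- min(p$i + n, nrow(log) + 1L)
    invisible(p$time_h())
  }
  p$advance <- function(dt_h) {
    t_target <- p$time_h() + dt_h
    while (p$i <= nrow(log) && log$timestamp_s[p$i] / 3600 < t_target - 1e-9)
      p$i <- p$i + 1L
    invisible(p$time_h())
  }
  class(p) <- c("dcf_replay_plant", "environment")
  p
}
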