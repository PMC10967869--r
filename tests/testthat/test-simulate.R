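# Time-stepped simulation: step consistency with the exported operations,
# integration properties, control invariants, trace/log plumbing.

params <- dcf_default_parameters()
config <- dcf_plant_config()

# Explicit composition of the exported operations in the documented order;
# simulate_step() inlines exactly this sequence for speed.
compose_step <- function(state, scenario, params, config,
                         rcake_ref = params$Rcake_SS_ref_per_m) {
  dt_h <- config$time_step_s / 3600
  aseg <- config$segment_area_m2
  fc <- if (state$fc_frozen) state$fc_value else fc_correction(state$t_h, params)
  rpore <- pore_resistance(state$kp, params)
  rss <- steady_state_cake_resistance(state$q_shear_lph, state$tmp_bar,
                                      state$c_gpl, params, rcake_ref)
  rcake <- cake_resistance(state$kc, rss, params)
  rtot <- params$Rm_per_m + rpore + rcake
  q_set <- dcftwin:::scheduled_setpoint(scenario, state$t_h)
  mode <- state$mode
  if (mode == "flow_controlled") {
    d <- distribute_permeate_flow(q_set, rtot, params$eta_water_pas, aseg)
    tmp <- d$tmp_bar; q_per <- d$q_per_lph
    mode <- control_mode_step(mode, tmp, config)
    if (mode == "tmp_controlled") {
      tmp <- config$tmp_setpoint_bar
      q_per <- darcy_flow(tmp, rtot, params$eta_water_pas, aseg)
    }
  } else {
    tmp <- config$tmp_setpoint_bar
    q_per <- darcy_flow(tmp, rtot, params$eta_water_pas, aseg)
    if (sum(q_per) > q_set) {
      d <- distribute_permeate_flow(q_set, rtot, params$eta_water_pas, aseg)
      tmp <- d$tmp_bar; q_per <- d$q_per_lph
    }
  }
  kp <- update_pore_kinetic(state$kp, q_per, scenario$c_feed_gpl, dt_h, params,
                            aseg)
  kc <- update_cake_kinetic(state$kc, state$c_gpl, dt_h)
  q_feed <- sum(q_per) + state$qt_ret_lph
  bal <- update_concentrations(state$c_gpl, q_per, q_feed,
                               scenario$c_feed_gpl, dt_h, params)
  eta_seg <- viscosity_from_concentration(bal$c_gpl, fc, params)
  torque <- torque_from_viscosity(eta_seg, params, config)
  torque_prev <- if (is.na(state$torque_nm)) torque else state$torque_nm
  valve <- valve_controller_step(state$valve_phase, state$x_pct, torque,
                                 torque_prev, config)
  qt_ret <- if (valve$x_pct > 0)
    retentate_valve_flow(tmp, valve$x_pct, params) else 0
  list(tmp_bar = tmp, q_per_lph = q_per, kp = kp, kc = kc,
       c_gpl = bal$c_gpl, torque_nm = torque, x_pct = valve$x_pct,
       valve_phase = valve$valve_phase, mode = mode, qt_ret_lph = qt_ret,
       c_eff_gpl = effective_concentration(bal$c_gpl, fc, params))
}

test_that("simulate_step equals the composition of the exported operations", {
  for (scen in list(dcf_reference_scenario(),
                    dcf_scenario(900, 100, 1))) {
    state <- new_sim_state(scen, params, config)
    for (i in 1:400) {
      ref <- compose_step(state, scen, params, config)
      state <- simulate_step(state, scen, params, config)
      for (f in names(ref))
        expect_equal(state[[f]], ref[[f]], tolerance = 1e-12,
                     label = paste("field", f, "step", i))
    }
    # the fast path must have passed through both valve and torque activity
    if (scen$c_feed_gpl == 100) expect_gt(state$x_pct, 0)
  }
})

test_that("fresh state: first step gives the membrane-only Darcy TMP", {
  scen <- dcf_scenario(415, 60, 1)
  s1 <- simulate_step(new_sim_state(scen, params, config), scen, params, config)
  expect_equal(s1$tmp_bar,
               darcy_tmp(415, params$Rm_per_m, params$eta_water_pas,
                         config$total_filter_area_m2),
               tolerance = 1e-12)
  expect_equal(sum(s1$q_per_lph), 415, tolerance = 1e-9)
})

test_that("TMP-controlled mode pins the TMP at the setpoint", {
  scen <- dcf_scenario(800, 60, 1)
  state <- new_sim_state(scen, params, config)
  state$mode <- "tmp_controlled"
  state$kc <- rep(1e4, 4)      # saturated cake: resistance binds, not the cap
  state$q_shear_lph <- 800
  state$tmp_bar <- 0.8
  s1 <- simulate_step(state, scen, params, config)
  expect_identical(s1$mode, "tmp_controlled")
  expect_equal(s1$tmp_bar, config$tmp_setpoint_bar)
  expect_lt(sum(s1$q_per_lph), 800)
})

test_that("step-halving shrinks the trajectory error ~linearly (Euler order)", {
  scen <- dcf_scenario(415, 60, 0.5)
  tmp_at_end <- function(dt_s) {
    cfg <- dcf_plant_config(time_step_s = dt_s)
    run <- simulate_run(scen, params, cfg, keep_log = FALSE)
    run$final_state$tmp_bar
  }
  t36 <- tmp_at_end(3.6)
  t18 <- tmp_at_end(1.8)
  t09 <- tmp_at_end(0.9)
  e1 <- abs(t36 - t18)
  e2 <- abs(t18 - t09)
  expect_gt(e1, e2)                 # converging
  expect_gt(e1 / e2, 1.5)           # ~first order
  expect_lt(e1 / e2, 3.0)
})

test_that("full-run solids mass audit closes to 1e-6 of the cumulative flux", {
  run <- simulate_run(dcf_reference_scenario(), params, config,
                      keep_log = FALSE)
  tr <- run$trace
  n <- nrow(tr)
  dt_h <- config$time_step_s / 3600
  qfeed_bal <- tr$q_per_total_lph[-1] + tr$qt_ret_lph[-n]
  influx <- qfeed_bal * run$scenario$c_feed_gpl
  outflux <- tr$qt_ret_lph[-n] * run$c_seg[-n, config$n_segments]
  lhs <- params$V_segment_l * sum(run$c_seg[n, ] - run$c_seg[1, ])
  rhs <- dt_h * sum(influx - outflux)
  expect_equal(lhs, rhs, tolerance = 1e-6 * dt_h * sum(influx))
})

test_that("run invariants: latch prefix, TMP bound, monotone pore fouling", {
  run <- simulate_run(dcf_reference_scenario(), params, config,
                      keep_log = FALSE)
  tr <- run$trace
  # mode sequence is flow_controlled* then tmp_controlled*
  m <- tr$mode
  expect_true(all(m %in% c("flow_controlled", "tmp_controlled")))
  first_tmp <- match("tmp_controlled", m)
  expect_false(is.na(first_tmp))
  expect_true(all(m[first_tmp:length(m)] == "tmp_controlled"))
  # TMP never exceeds the setpoint while under control (crossing step aside,
  # the controller pins it the same cycle it would exceed)
  expect_lte(max(tr$tmp_bar[m == "tmp_controlled"]),
             config$tmp_setpoint_bar + 1e-9)
  # non-negative physics
  expect_true(all(tr$q_per_total_lph >= 0))
  expect_true(all(run$c_seg >= 0))
  expect_true(all(tr$qt_ret_lph >= 0))
  # pore fouling is irreversible; cake stays below its running steady state
  scen <- dcf_scenario(700, 80, 0.5)
  state <- new_sim_state(scen, params, config)
  rpore_prev <- rep(-1, 4)
  for (i in 1:400) {
    rss <- steady_state_cake_resistance(state$q_shear_lph, state$tmp_bar,
                                        state$c_gpl, params)
    state <- simulate_step(state, scen, params, config)
    expect_true(all(state$rpore_per_m >= rpore_prev))
    expect_true(all(state$rcake_per_m <= rss * (1 + 1e-12)))
    rpore_prev <- state$rpore_per_m
  }
})

test_that("productivity: time average of the total permeate flow", {
  flat <- data.frame(time_h = seq(0, 10, by = 0.1),
                     q_per_total_lph = 400)
  expect_equal(productivity(flat), 400)
  two <- data.frame(time_h = c(0, 5, 5, 10),
                    q_per_total_lph = c(400, 400, 800, 800))
  expect_equal(productivity(two), 600)
  zero <- data.frame(time_h = 0:10, q_per_total_lph = 0)
  expect_equal(productivity(zero), 0)
  expect_error(productivity(data.frame(time_h = 0, q_per_total_lph = 1)),
               "empty|single")
})

test_that("zero-duration scenario: empty log, single-row trace, no error", {
  run <- simulate_run(dcf_scenario(400, 60, 0), params, config)
  expect_equal(nrow(run$log), 0)
  expect_equal(nrow(run$trace), 1)
})

test_that("process log: 5 s cadence, schema, row count", {
  run <- simulate_run(dcf_scenario(500, 60, 1), params, config)
  # 1 h at 5 s -> 721 rows including t = 0
  expect_equal(nrow(run$log), 721)
  expect_equal(run$log$timestamp_s, seq(0, 3600, by = 5))
  expect_true(all(c("timestamp_s", "tmp_bar", "q_per_lph",
                    "q_per_setpoint_lph", "torque_nm", "valve_pct", "mode",
                    "status") %in% names(run$log)))
  expect_true(all(run$log$status == "running"))
})

test_that("setpoint schedule is applied at its step times", {
  scen <- dcf_scenario(400, 60, 1,
                       schedule = data.frame(time_h = 0.5, q_set_lph = 500))
  run <- simulate_run(scen, params, config, keep_log = FALSE)
  tr <- run$trace
  expect_equal(unique(tr$q_set_lph[tr$time_h <= 0.5 & tr$time_h > 0]), 400)
  expect_equal(unique(tr$q_set_lph[tr$time_h > 0.501]), 500)
  expect_error(dcf_scenario(400, 60, 1,
                            schedule = data.frame(time_h = 2, q_set_lph = 1)),
               "within")
})
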