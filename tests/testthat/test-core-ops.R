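# Elementary operations of the process dynamics model: Darcy relation,
# fouling resistances, kinetic integrals, flow distribution, chamber physics.

params <- dcf_default_parameters()
config <- dcf_plant_config()

test_that("Darcy relation: units, zero flow, exact inverse", {
  expect_equal(darcy_tmp(0, 1e13, 1e-3, 8.2), 0)
  # hand unit-conversion arithmetic: 500 L/h = 1.3889e-4 m3/s,
  # TMP = 1e-3 * 1.3889e-4 * 1e13 / 8.2 Pa = 1.694 bar
  expect_equal(darcy_tmp(500, 1e13, 1e-3, 8.2), 1.693767, tolerance = 1e-6)
  set.seed(42)
  for (i in 1:25) {
    q <- runif(1, 1, 5000)
    r <- 10^runif(1, 11, 14)
    eta <- 10^runif(1, -3.5, -2)
    a <- runif(1, 0.5, 50)
    expect_equal(darcy_flow(darcy_tmp(q, r, eta, a), r, eta, a), q,
                 tolerance = 1e-12)
  }
  expect_error(darcy_tmp(100, -1, 1e-3, 8.2), "must be > 0")
  expect_error(darcy_flow(0.5, 1e13, 0, 8.2), "must be > 0")
})

test_that("pore resistance: exponential law and monotonicity", {
  expect_equal(pore_resistance(0, params), 0)
  # k_pore * kp = ln 2  ->  Rpore = Rpore_ref
  expect_equal(pore_resistance(log(2) / params$k_pore, params),
               params$Rpore_ref_per_m)
  kp <- seq(0, 5000, length.out = 50)
  expect_true(all(diff(pore_resistance(kp, params)) > 0))
  expect_error(pore_resistance(-1, params), "kp")
})

test_that("pore kinetic integral: linear accumulation of the fines load", {
  aseg <- config$segment_area_m2
  expect_equal(update_pore_kinetic(3, 0, 60, 0.1, params, aseg), 3)
  # cfine is 20 % of the feed concentration
  k1 <- update_pore_kinetic(0, 415, 100, 1, params, aseg)
  expect_equal(k1, 0.2 * 100 * 415 / aseg)
  # two half-steps equal one full step at constant flow
  half <- update_pore_kinetic(update_pore_kinetic(5, 415, 60, 0.5, params, aseg),
                              415, 60, 0.5, params, aseg)
  expect_equal(half, update_pore_kinetic(5, 415, 60, 1, params, aseg))
  expect_error(update_pore_kinetic(0, 415, 60, -0.1, params, aseg), "dt")
})

test_that("steady-state cake resistance: reference collapse and guards", {
  # all ratios -> 1, TMP -> 0: result -> reference value
  expect_equal(steady_state_cake_resistance(params$Qt_per_ref_lph, 0,
                                            params$c_ref_gpl, params),
               params$Rcake_SS_ref_per_m)
  # exponent-zero collapse
  p0 <- dcf_model_parameters(nQ = 1e-300, nc = 1e-300)
  expect_equal(steady_state_cake_resistance(123, 0.5, 77, p0),
               p0$Rcake_SS_ref_per_m * exp(0.5 / p0$TMP_compress_bar),
               tolerance = 1e-9)
  # direct re-evaluation oracle, incl. halved exponent argument when the
  # compressibility scale doubles
  direct <- function(q, tmp, c, p) {
    p$Rcake_SS_ref_per_m * pmax(q / p$Qt_per_ref_lph, 1e-3)^p$nQ *
      exp(tmp / p$TMP_compress_bar) * pmax(c / p$c_ref_gpl, 1e-3)^p$nc
  }
  set.seed(7)
  for (i in 1:20) {
    q <- runif(1, 0, 1500); tmp <- runif(1, 0, 0.9); cc <- runif(1, 0, 200)
    expect_equal(steady_state_cake_resistance(q, tmp, cc, params),
                 direct(q, tmp, cc, params))
    p2 <- params; p2$TMP_compress_bar <- 2 * params$TMP_compress_bar
    expect_equal(steady_state_cake_resistance(q, tmp, cc, p2),
                 direct(q, tmp, cc, params) * exp(-tmp / (2 * params$TMP_compress_bar)))
  }
  # zero flow with negative exponent: floored, finite
  pneg <- dcf_model_parameters(nQ = -2)
  expect_true(is.finite(steady_state_cake_resistance(0, 0.5, 60, pneg)))
})

test_that("cake resistance: Langmuir saturation identities", {
  rss <- 1.4e13
  expect_equal(cake_resistance(0, rss, params), 0)
  expect_equal(cake_resistance(params$k_cake_ghpl, rss, params), rss / 2)
  # asymptote: within 1 % of the maximum at 100x the half-saturation constant
  expect_gt(cake_resistance(100 * params$k_cake_ghpl, rss, params), 0.99 * rss)
  expect_true(all(cake_resistance(10^seq(-2, 5), rss, params) <= rss))
  expect_error(cake_resistance(-1, rss, params), "kc")
})

test_that("cake kinetic integral: concentration-clock accumulation", {
  expect_equal(update_cake_kinetic(7, 0, 0.5), 7)
  expect_equal(update_cake_kinetic(0, 60, 1), 60)
  # piecewise-constant concentration: sum of increments equals the integral
  cs <- c(30, 60, 90)
  kc <- 0
  for (cc in cs) kc <- update_cake_kinetic(kc, cc, 1 / 3)
  expect_equal(kc, sum(cs) / 3)
})

test_that("flow distribution matches symmetry, Darcy linearity and bisection", {
  aseg <- config$segment_area_m2
  # equal resistances -> equal split
  d <- distribute_permeate_flow(800, rep(1e13, 4), 1e-3, aseg)
  expect_equal(d$q_per_lph, rep(200, 4))
  expect_equal(sum(d$q_per_lph), 800, tolerance = 1e-9)
  # resistance ratio 1:2 -> flow ratio 2:1
  d2 <- distribute_permeate_flow(300, c(1e13, 2e13), 1e-3, aseg)
  expect_equal(d2$q_per_lph[1] / d2$q_per_lph[2], 2)
  # invariance under the internal reference TMP
  d3a <- distribute_permeate_flow(555, c(3e12, 8e12, 1e13), 1e-3, aseg,
                                  tmp_ref_bar = 0.1)
  d3b <- distribute_permeate_flow(555, c(3e12, 8e12, 1e13), 1e-3, aseg,
                                  tmp_ref_bar = 5)
  expect_equal(d3a$tmp_bar, d3b$tmp_bar, tolerance = 1e-9)
  # bisection oracle on random resistances
  set.seed(11)
  for (i in 1:20) {
    r <- 10^runif(4, 12, 13.7)
    q <- runif(1, 50, 2000)
    d <- distribute_permeate_flow(q, r, 1e-3, aseg)
    o <- bisect_distribute(q, r, 1e-3, aseg)
    expect_equal(d$tmp_bar, o$tmp_bar, tolerance = 1e-6)
    expect_equal(d$q_per_lph, o$q_per_lph, tolerance = 1e-6)
    expect_equal(sum(d$q_per_lph), q, tolerance = 1e-9 * q)
    # each segment flow satisfies the Darcy relation at the common TMP
    expect_equal(darcy_tmp(d$q_per_lph, r, 1e-3, aseg), rep(d$tmp_bar, 4),
                 tolerance = 1e-12)
  }
  expect_error(distribute_permeate_flow(100, numeric(0), 1e-3, aseg), "empty")
})

test_that("chamber mass balances: pass-through steady state and exact audit", {
  # zero permeate draw and uniform concentration: nothing changes
  b <- update_concentrations(rep(60, 4), rep(0, 4), 500, 60, 0.01, params)
  expect_equal(b$c_gpl, rep(60, 4))
  expect_equal(b$q_ret_lph, rep(500, 4))
  # discrete mass audit: V * sum(dc) == (Qfeed*cfeed - Qret_out*c_out) * dt
  set.seed(3)
  for (i in 1:20) {
    c0 <- runif(4, 10, 150)
    qp <- runif(4, 0, 120)
    qf <- sum(qp) + runif(1, 0, 400)
    dt <- 0.001
    b <- update_concentrations(c0, qp, qf, 60, dt, params)
    lhs <- params$V_segment_l * sum(b$c_gpl - c0)
    rhs <- (qf * 60 - b$q_ret_lph[4] * c0[4]) * dt
    expect_equal(lhs, rhs, tolerance = 1e-9 * max(abs(rhs), 1))
  }
  # permeate draw exceeding the feed-side flow is clipped and flagged
  b2 <- update_concentrations(rep(60, 4), rep(200, 4), 300, 60, 0.001, params)
  expect_true(b2$clipped)
  expect_true(all(b2$q_ret_lph >= 0))
})

test_that("viscosity, torque and the concentration correction", {
  expect_equal(viscosity_from_concentration(0, 1, params), params$eta_ref_pas)
  p1 <- dcf_model_parameters(k_eta_lpg = 0.02)
  expect_equal(viscosity_from_concentration(50, 1, p1),
               p1$eta_ref_pas * exp(1))
  expect_error(viscosity_from_concentration(10, 0, params), "fc_value")

  # omega = 0: only the seal torque remains
  cfg0 <- config; cfg0$rotation_speed_rpm <- 1e-12
  expect_equal(torque_from_viscosity(0.01, params, cfg0), params$M_seal_nm,
               tolerance = 1e-6)
  # linearity in viscosity above the seal torque
  m1 <- torque_from_viscosity(0.01, params, config) - params$M_seal_nm
  m2 <- torque_from_viscosity(0.02, params, config) - params$M_seal_nm
  expect_equal(m2, 2 * m1)
  # segment aggregation reduces to the lumped law for uniform segments
  expect_equal(torque_from_viscosity(rep(0.01, 4), params, config),
               torque_from_viscosity(0.01, params, config))

  # fc decay: monotone non-increasing towards the floor
  fc <- fc_correction(seq(0, 20, by = 0.5), params)
  expect_true(all(diff(fc) < 0))
  expect_equal(fc_correction(0, params), 1)
  expect_gt(min(fc), params$fc_floor)

  # effective concentration equals the plain value for a uniform chamber
  expect_equal(effective_concentration(rep(80, 4), 0.9, params), 80)
  expect_gte(effective_concentration(c(40, 120), 0.9, params), 80)
})

test_that("retentate valve flow: closed valve, flow stress, hand value", {
  expect_equal(retentate_valve_flow(0.8, 0, params), 0)
  # TMP * X at the flow stress: exactly zero flow
  x0 <- params$sigma_f_bar / 0.5
  expect_equal(retentate_valve_flow(0.5, x0, params), 0)
  expect_equal(retentate_valve_flow(0.5, x0 - 0.5, params), 0)
  # hand evaluation: 40 * (0.8 * 50 - 1) = 1560 L/h
  expect_equal(retentate_valve_flow(0.8, 50, params), 1560)
  expect_error(retentate_valve_flow(0.8, 101, params), "opening")
  expect_error(retentate_valve_flow(-0.1, 10, params), "TMP")
})
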