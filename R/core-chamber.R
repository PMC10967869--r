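# Chamber-side physics: retentate flow cascade, species mass balances,
# viscosity/torque correlation and the retentate valve characteristic.

#' Retentate cascade and segment mass balances (one Euler step)
#'
#' The chamber segments form a series of stirred volumes. The retentate flow
#' leaving segment `s` is the inflow of segment `s+1` minus that segment's
#' permeate draw: `Qret(s) = Qret(s-1) - Qper(s)` with `Qret(0) = Qfeed`.
#' Segment concentrations advance by explicit Euler on
#' `V_segment * dc/dt = Qret(s-1) c(s-1) - Qret(s) c(s)` with boundary
#' `c(0) = c_feed`; concentrations are clipped at zero. If a segment's
#' permeate draw exceeds the available feed-side flow the retentate is clipped
#' at zero and the event flagged (degenerate regime, reported once per run).
#'
#' @param c_gpl per-segment concentrations, g/L.
#' @param q_per_lph per-segment permeate flows, L/h.
#' @param q_feed_lph feed flow entering segment 1, L/h.
#' @param c_feed_gpl feed concentration, g/L.
#' @param dt_h time step, h.
#' @param params a [dcf_model_parameters()] object (for `V_segment_l`).
#' @return list with `c_gpl` (updated concentrations), `q_ret_lph`
#'   (per-segment retentate flows) and `clipped` (TRUE if a negative retentate
#'   was clipped).
#' @export
update_concentrations <- function(c_gpl, q_per_lph, q_feed_lph, c_feed_gpl,
                                  dt_h, params) {
  n <- length(c_gpl)
  # q_per >= 0, so the running balance is non-increasing and element-wise
  # clipping equals clipping the cumulative sum
  q_raw <- q_feed_lph - cumsum(q_per_lph)
  clipped <- q_raw[n] < -1e-9 * max(q_feed_lph, 1)  # real deficit, not round-off
  q_ret <- pmax(q_raw, 0)
  q_in <- c(q_feed_lph, q_ret[-n])
  c_in <- c(c_feed_gpl, c_gpl[-n])
  c_new <- c_gpl + dt_h * (q_in * c_in - q_ret * c_gpl) / params$V_segment_l
  list(c_gpl = pmax(c_new, 0), q_ret_lph = q_ret, clipped = clipped)
}

#' Empirical concentration correction factor
#'
#' Accounts for solids bound in the cake or at the chamber walls that do not
#' contribute to retentate viscosity: `fc(t) = fc_floor +
#' (1 - fc_floor) * exp(-t / fc_tau)`. The decay runs until the retentate
#' valve opens for the first time, after which the value is frozen (handled
#' by the simulation state, not here).
#'
#' @param t_h process time, h.
#' @param params a [dcf_model_parameters()] object.
#' @return correction factor in (0, 1].
#' @export
fc_correction <- function(t_h, params) {
  params$fc_floor + (1 - params$fc_floor) * exp(-t_h / params$fc_tau_h)
}

#' Retentate viscosity from solids concentration
#'
#' `eta = eta_ref * exp(k_eta * fc * c)`.
#'
#' @param c_gpl solids concentration, g/L (>= 0, vectorised).
#' @param fc_value concentration correction factor in (0, 1].
#' @param params a [dcf_model_parameters()] object.
#' @return dynamic viscosity in Pa s.
#' @export
viscosity_from_concentration <- function(c_gpl, fc_value, params) {
  if (any(c_gpl < 0)) stop("viscosity_from_concentration: c must be >= 0",
                           call. = FALSE)
  if (fc_value <= 0 || fc_value > 1)
    stop("viscosity_from_concentration: fc_value must lie in (0, 1]",
         call. = FALSE)
  params$eta_ref_pas * exp(params$k_eta_lpg * fc_value * c_gpl)
}

#' Membrane drive torque from retentate viscosity
#'
#' First-principle drive torque: `M = M_seal + k_g * omega * eta`. Given a
#' vector of per-segment viscosities the geometry factor is shared equally
#' over the segments, `M = M_seal + sum(k_g / smax * omega * eta_s)`, which
#' reduces to the lumped relation when all segments are equal.
#'
#' @param eta_pas retentate viscosity, Pa s (scalar or per-segment vector).
#' @param params a [dcf_model_parameters()] object.
#' @param config a [dcf_plant_config()] object (rotation speed, n_segments).
#' @return torque in N m.
#' @export
torque_from_viscosity <- function(eta_pas, params, config) {
  if (any(eta_pas < 0)) stop("torque_from_viscosity: eta must be >= 0",
                             call. = FALSE)
  k <- params$k_g_nms * config$rotation_speed_rpm
  if (length(eta_pas) > 1) {
    params$M_seal_nm + sum(k / length(eta_pas) * eta_pas)
  } else {
    params$M_seal_nm + k * eta_pas
  }
}

#' Torque-equivalent lumped chamber concentration
#'
#' The concentration a perfectly mixed chamber would need to produce the same
#' drive torque as the segmented chamber: the log-mean of the per-segment
#' viscosity factors. Equals the arithmetic mean in the uniform limit; this is
#' the quantity the torque soft sensor recovers.
#'
#' @param c_gpl per-segment concentrations, g/L.
#' @param fc_value concentration correction factor.
#' @param params a [dcf_model_parameters()] object.
#' @return effective lumped concentration, g/L.
#' @export
effective_concentration <- function(c_gpl, fc_value, params) {
  k <- params$k_eta_lpg * fc_value
  log(mean(exp(k * c_gpl))) / k
}

#' Retentate flow through the valve
#'
#' `Qt_ret = max(0, k_valve * (TMP * X - sigma_f))`: the retentate yields only
#' once the pressure-opening product exceeds its flow stress; a closed valve
#' passes nothing.
#'
#' @param tmp_bar transmembrane pressure, bar (>= 0).
#' @param x_pct valve opening in \\[0, 100\\] %.
#' @param params a [dcf_model_parameters()] object.
#' @return total retentate flow, L/h.
#' @export
retentate_valve_flow <- function(tmp_bar, x_pct, params) {
  if (x_pct < 0 || x_pct > 100)
    stop("retentate_valve_flow: valve opening must lie in [0, 100] %",
         call. = FALSE)
  if (tmp_bar < 0)
    stop("retentate_valve_flow: TMP must be >= 0", call. = FALSE)
  if (x_pct == 0) return(0)
  max(0, params$k_valve_lphbar * (tmp_bar * x_pct - params$sigma_f_bar))
}
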