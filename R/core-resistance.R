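# Filtration resistances and the Darcy pressure/flow relation.
#
# Resistance-in-series: Rtot = Rm + Rpore + Rcake per chamber segment. Pore
# blocking grows exponentially with the cumulative fines load per membrane
# area; the cake layer saturates (Langmuir form) towards a steady-state
# resistance that itself depends on the previous step's total permeate flow
# (shear), TMP (compressibility) and segment concentration.

#' Darcy relation: TMP from permeate flow
#'
#' `darcy_tmp()` computes the transmembrane pressure that drives a permeate
#' flow `q_per_lph` through a total resistance `rtot_per_m` over membrane area
#' `area_m2`; `darcy_flow()` is its exact inverse. Internally SI, interfaces
#' in L/h and bar.
#'
#' @param q_per_lph permeate flow rate, L/h (vectorised).
#' @param tmp_bar transmembrane pressure, bar (vectorised).
#' @param rtot_per_m total filtration resistance, m^-1 (> 0, vectorised).
#' @param eta_pas permeate dynamic viscosity, Pa s (> 0).
#' @param area_m2 membrane area the flow passes, m2 (> 0).
#' @return TMP in bar, resp. permeate flow in L/h.
#' @export
darcy_tmp <- function(q_per_lph, rtot_per_m, eta_pas, area_m2) {
  if (any(area_m2 <= 0) || any(rtot_per_m <= 0) || any(eta_pas <= 0))
    stop("darcy_tmp: area, resistance and viscosity must be > 0", call. = FALSE)
  eta_pas * (q_per_lph * LPH_TO_M3S) * rtot_per_m / area_m2 / BAR_TO_PA
}

#' @rdname darcy_tmp
#' @export
darcy_flow <- function(tmp_bar, rtot_per_m, eta_pas, area_m2) {
  if (any(area_m2 <= 0) || any(rtot_per_m <= 0) || any(eta_pas <= 0))
    stop("darcy_flow: area, resistance and viscosity must be > 0", call. = FALSE)
  (tmp_bar * BAR_TO_PA) * area_m2 / (eta_pas * rtot_per_m) / LPH_TO_M3S
}

#' Pore resistance from the fines-load kinetic integral
#'
#' Exponential pore blocking: `Rpore = Rpore_ref * (exp(k_pore * kp) - 1)`,
#' zero at zero load and strictly increasing.
#'
#' @param kp pore kinetic integral (cumulative fines load per membrane area,
#'   g/m2), >= 0, vectorised.
#' @param params a [dcf_model_parameters()] object.
#' @return pore resistance in m^-1.
#' @export
pore_resistance <- function(kp, params) {
  if (any(kp < 0)) stop("pore_resistance: kp must be >= 0", call. = FALSE)
  params$Rpore_ref_per_m * (exp(params$k_pore * kp) - 1)
}

#' Advance the pore kinetic integral by one Euler step
#'
#' `kp' = kp + fine_fraction * c_feed * (q_per / A_segment) * dt`: the fines
#' concentration is a fixed fraction (default 20 %) of the feed concentration
#' and is convected towards the membrane with the permeate flux.
#'
#' @param kp current kinetic integral, g/m2 (vectorised over segments).
#' @param q_per_lph segment permeate flow, L/h.
#' @param c_feed_gpl feed solids concentration, g/L.
#' @param dt_h time step, h (>= 0).
#' @param params a [dcf_model_parameters()] object.
#' @param segment_area_m2 membrane area of one segment, m2.
#' @return updated kinetic integral.
#' @export
update_pore_kinetic <- function(kp, q_per_lph, c_feed_gpl, dt_h, params,
                                segment_area_m2) {
  if (dt_h < 0) stop("update_pore_kinetic: dt must be >= 0", call. = FALSE)
  if (any(kp < 0) || any(q_per_lph < 0) || any(c_feed_gpl < 0))
    stop("update_pore_kinetic: inputs must be >= 0", call. = FALSE)
  kp + params$fine_fraction * c_feed_gpl * (q_per_lph / segment_area_m2) * dt_h
}

#' Steady-state cake resistance
#'
#' `Rcake_SS = Rcake_SS_ref * (Qt_per/Qt_per_ref)^nQ * exp(TMP/TMP_compress) *
#' (c/c_ref)^nc`, evaluated with previous-time-step values of the total
#' permeate flow, TMP and segment concentration. Each power-law ratio is
#' floored at 1e-3 so that a vanishing flow or concentration combined with a
#' negative exponent cannot produce an infinite resistance; the result is
#' additionally capped at 1e18 m^-1.
#'
#' @param qt_per_prev_lph previous-step total permeate flow, L/h (>= 0).
#' @param tmp_prev_bar previous-step TMP, bar.
#' @param c_prev_gpl previous-step segment concentration, g/L (>= 0,
#'   vectorised).
#' @param params a [dcf_model_parameters()] object; `Rcake_SS_ref_per_m` may
#'   be overridden via `rcake_ss_ref_per_m` (used by the DoE and the twin).
#' @param rcake_ss_ref_per_m optional override of the reference resistance.
#' @return steady-state cake resistance in m^-1.
#' @export
steady_state_cake_resistance <- function(qt_per_prev_lph, tmp_prev_bar,
                                         c_prev_gpl, params,
                                         rcake_ss_ref_per_m = params$Rcake_SS_ref_per_m) {
  if (any(qt_per_prev_lph < 0) || any(c_prev_gpl < 0))
    stop("steady_state_cake_resistance: flow and concentration must be >= 0",
         call. = FALSE)
  rq <- pmax(qt_per_prev_lph / params$Qt_per_ref_lph, 1e-3)
  rc <- pmax(c_prev_gpl / params$c_ref_gpl, 1e-3)
  r <- rcake_ss_ref_per_m * rq^params$nQ *
    exp(tmp_prev_bar / params$TMP_compress_bar) * rc^params$nc
  pmin(r, 1e18)
}

#' Cake resistance from the cake kinetic integral
#'
#' Langmuir-type saturation towards the steady-state value:
#' `Rcake = Rcake_SS * kc / (kc + k_cake)`; bounded above by `Rcake_SS`,
#' half-saturated at `kc = k_cake`.
#'
#' @param kc cake kinetic integral, g h/L (>= 0, vectorised).
#' @param rcake_ss_per_m steady-state cake resistance, m^-1.
#' @param params a [dcf_model_parameters()] object.
#' @return cake resistance in m^-1.
#' @export
cake_resistance <- function(kc, rcake_ss_per_m, params) {
  if (any(kc < 0)) stop("cake_resistance: kc must be >= 0", call. = FALSE)
  rcake_ss_per_m * kc / (kc + params$k_cake_ghpl)
}

#' Advance the cake kinetic integral by one Euler step
#'
#' `kc' = kc + c_segment * dt`: cake builds at a rate proportional to the
#' local chamber concentration.
#'
#' @param kc current kinetic integral, g h/L (vectorised over segments).
#' @param c_segment_gpl segment concentration, g/L (>= 0).
#' @param dt_h time step, h (> 0).
#' @return updated kinetic integral.
#' @export
update_cake_kinetic <- function(kc, c_segment_gpl, dt_h) {
  if (any(c_segment_gpl < 0) || dt_h <= 0)
    stop("update_cake_kinetic: need c >= 0 and dt > 0", call. = FALSE)
  kc + c_segment_gpl * dt_h
}

#' Distribute a total permeate flow setpoint over segments
#'
#' In flow-controlled mode the PLC fixes the total permeate flow but its split
#' over the chamber segments is unknown. Following the plant model's
#' intermediate calculation, a per-segment reference flow is computed at a
#' reference TMP, the single chamber TMP is rescaled so the summed flows match
#' the setpoint, and the actual segment flows follow from the Darcy relation
#' at that TMP. Because the Darcy relation is linear in TMP the result is
#' independent of the reference TMP chosen.
#'
#' @param q_total_lph desired total permeate flow, L/h.
#' @param rtot_per_m vector of per-segment total resistances, m^-1 (> 0).
#' @param eta_pas permeate viscosity, Pa s.
#' @param segment_area_m2 membrane area per segment, m2.
#' @param tmp_ref_bar internal reference TMP, bar (result is invariant to it).
#' @return list with `tmp_bar` (scalar) and `q_per_lph` (per-segment flows
#'   summing to `q_total_lph`).
#' @export
distribute_permeate_flow <- function(q_total_lph, rtot_per_m, eta_pas,
                                     segment_area_m2, tmp_ref_bar = 0.5) {
  if (length(rtot_per_m) == 0)
    stop("distribute_permeate_flow: empty segment list", call. = FALSE)
  q_ref <- darcy_flow(tmp_ref_bar, rtot_per_m, eta_pas, segment_area_m2)
  tmp <- tmp_ref_bar * q_total_lph / sum(q_ref)
  list(tmp_bar = tmp, q_per_lph = q_ref * (tmp / tmp_ref_bar))
}
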