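# Unit conversion boundary.
#
# All physics is evaluated in SI (m3/s, Pa, Pa s, m-1, m2); every user-facing
# interface speaks the plant's units (L/h, bar, g/L, N m, %). Keeping the
# conversion in two constants avoids silent mixed-unit errors in the Darcy
# relation, which is the only place both systems meet.

#' @keywords internal
LPH_TO_M3S <- 1 / 3.6e6

#' @keywords internal
BAR_TO_PA <- 1e5
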