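---
title: "Process model, metamodel and digital twin: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Process model, metamodel and digital twin: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The process and its model

Dynamic crossflow filtration (DCF) clarifies high-solids feeds (here: pressed
grape must) through rotating ceramic membrane discs; rotation shears cake
deposits off the membrane, so the process tolerates solids loads that would
blind a static crossflow unit. The industrial asset modelled here has
32.8 m^2 of membrane on four shafts, a feed pump controlled by a PLC, and a
retentate valve. `dcftwin` simulates this plant, trains a polynomial
surrogate on simulated experiments, and closes the loop: monitor, estimate,
recommend, adapt.

## Chamber discretisation

The process chamber is split into `n_segments = 4` well-mixed volumes in
series to resolve the axial solids gradient between feed inlet and retentate
outlet. Permeate flow, fouling state and drive torque are tracked per
segment; the transmembrane pressure (TMP) is a single chamber value because
the axial pressure drop is negligible.

## Resistance-in-series fouling model

Permeate flow and TMP are linked by the Darcy relation per segment
$s$,

$$\mathrm{TMP} = \frac{\eta_w\, Q_{per}(s)\, R_{tot}(s)}{A_{segm}},
\qquad R_{tot} = R_m + R_{pore} + R_{cake},$$

evaluated in SI internally with all interfaces in plant units (L/h, bar,
g/L, N m). The three resistances are:

* **Membrane** $R_m$: constant per run; the twin re-estimates it from the
  post-cleaning water flux.
* **Pore blocking**: irreversible, driven by fine particles (a fixed 20 % of
  the feed solids) convected into the pores with the permeate flux,
  $R_{pore} = R_{pore,ref}\,(e^{k_{pore} k_p} - 1)$ with
  $\dot k_p = c_{fine} Q_{per}/A_{segm}$.
* **Cake**: saturating (Langmuir-type) towards a steady state,
  $R_{cake} = R_{cake,SS}\, k_c/(k_c + k_{cake})$ with the
  concentration-clock kinetics $\dot k_c = c(s)$, and
  $$R_{cake,SS} = R_{cake,SS,ref}
    \left(\frac{\bar Q_{t,per}}{Q_{t,per,ref}}\right)^{n_Q}
    e^{\mathrm{TMP}/\mathrm{TMP}_{compress}}
    \left(\frac{c}{c_{ref}}\right)^{n_c},$$
  combining shear thinning with sustained flux, cake compressibility with
  pressure, and a concentration dependence. Flow, TMP and concentration
  enter with previous-cycle values.

Mass balances cascade the retentate flow through the segments
($Q_{ret}(s) = Q_{ret}(s-1) - Q_{per}(s)$, $Q_{ret}(0) = Q_{feed}$) and
advance the solids concentrations by an explicit Euler step of the
per-segment species balance. Retentate viscosity follows
$\eta = \eta_{ref}\, e^{k_\eta f_c(t)\, c}$ and drive torque
$M = M_{seal} + k_g\,\omega\,\eta$, aggregated equally over segments. The
empirical correction $f_c(t) = f_{c,floor} + (1-f_{c,floor})e^{-t/\tau_f}$
accounts for solids bound in the cake or at the walls; it decays until the
retentate valve first opens and is frozen from then on. The retentate valve
passes $Q_{t,ret} = \max(0,\, k_{valve}(\mathrm{TMP}\cdot X - \sigma_f))$ at
opening $X$.

## Control emulation

The PLC is emulated faithfully: runs start **flow-controlled** (the feed
pump holds the permeate setpoint, TMP floats); the first time TMP exceeds
0.8 bar the mode latches to **TMP-controlled** (TMP pinned, flux decays) and
never reverts. The retentate valve opens when the torque reaches 300 N m,
ramps by 1 percentage point per 3.6 s cycle while the torque still rises,
and closes below 270 N m (10 % hysteresis), producing the alternating
concentration/discharge phases seen in plant logs.

# Numerical choices

* **Integration**: explicit Euler at the plant's 3.6 s control cycle. With
  segment volumes of 250 L and flows up to a few m^3/h the Courant-type
  coefficient $Q\,\Delta t/V \approx 10^{-2}$, comfortably stable;
  step-halving tests confirm first-order convergence.
* **Shear-flow relaxation** (`shear_tau_h`, default 0.05 h): the total
  permeate flow entering the cake shear term is low-pass filtered. The cake
  layer responds to the sustained flux level, not to single 3.6 s
  excursions; numerically, feeding the raw previous-cycle flow back through
  $Q^{n_Q}$ with $n_Q \approx 1.9$ makes the pinned-TMP flux iteration
  expand (per-cycle gain $n_Q \times$ cake share of the resistance exceeds
  one) and the flux would ping-pong instead of settling at its physical
  equilibrium.
* **Flow cap in TMP mode**: the feed pump never delivers more than the
  active setpoint. If a discharge-phase concentration drop transiently
  admits more than the setpoint at 0.8 bar, the flow constraint binds and
  the TMP floats below the setpoint; run productivity therefore never
  exceeds the largest setpoint applied. In the reference scenario the cap
  never binds and the TMP-controlled tail sits at 0.8 bar exactly.
* **Guards**: power-law ratios in the steady-state cake term are floored at
  $10^{-3}$ (a vanishing flow with a negative exponent must not produce an
  infinite resistance) and the result capped at $10^{18}\,\mathrm{m^{-1}}$;
  if a segment's permeate draw would exceed the available feed-side flow the
  retentate is clipped at zero and the run flagged; concentrations are
  clipped at zero.
* The flow-distribution step (single TMP such that the per-segment Darcy
  flows sum to the setpoint) follows the reference-TMP rescaling procedure;
  because the Darcy relation is linear in TMP the result is independent of
  the reference value, which tests verify against a bisection oracle.

# Calibrated default parameters

The empirical constants of the fouling, viscosity/torque and valve
correlations are not publicly documented for the industrial asset. The
shipped defaults (`dcf_default_parameters()`) were produced once by a
calibration study (`scripts/calibrate.R`) against the
documented plant behaviour and then frozen:

| target | behaviour |
|---|---|
| reference run (415 L/h, 60 g/L, +80 L/h at 5 h) | valve opens at 2.46 h; TMP < 0.8 bar before the step; latched switch at 5.16 h; pinned 0.8 bar tail with decaying flux |
| every 400 L/h design run | stays flow-controlled for 10 h, productivity 400 L/h |
| 600 L/h runs at $R_{cake,SS,ref} = 6\times10^{12}\,\mathrm{m^{-1}}$ | stay flow-controlled, productivity 600 L/h |
| 800 L/h at low cake resistance and 20 g/L | switches to TMP control before 10 h |
| surface fit | 99 % of the 125 regression residuals below 60 L/h |

Physically motivated magnitudes anchored the search: water viscosity
$10^{-3}$ Pa s; $R_m = 4\times10^{12}\,\mathrm{m^{-1}}$ gives a realistic
0.14 bar clean-membrane TMP at 415 L/h; chamber volume 1000 L (4 x 250 L)
makes the lumped concentration rise at
$Q_{feed} c_{feed}/V \approx 25$ g/L/h in the reference run, which is what
places the torque threshold crossing near 2.5 h; the torque constants
($M_{seal} = 50$ N m, $k_g = 8.85$, $k_\eta = 0.04$ L/g) put the 300 N m
threshold at a chamber concentration of ~130 g/L. The small compressibility
scale ($\mathrm{TMP}_{compress} = 0.7$ bar) is the load-bearing choice: it
penalises operation at the TMP setpoint strongly enough that overly
aggressive initial setpoints crash to a low equilibrium flux, which is what
creates an **interior productivity optimum** at high cake resistance — and
moves it to lower setpoints at high feed concentration — rather than a
monotone "more is better" response.

# Response-surface metamodel

A full factorial design (5 evenly spaced levels per factor, endpoints
included) over initial setpoint [400, 1200] L/h, feed concentration
[20, 100] g/L and reference steady-state cake resistance
$[6\times10^{12}, 2.2\times10^{13}]\,\mathrm{m^{-1}}$ yields 125 ten-hour
simulations. Factors are min-max scaled to $[0,1]$ (their magnitudes span
eleven orders); the productivity response stays in L/h. Ordinary least
squares on the full 10-term quadratic basis needs no regularisation at
125 points and interpolates exactly when the generating response is itself
quadratic (a test oracle). The optimal setpoint is the stationary point of
the surface along the setpoint axis,
$x_q^\ast = -(w_2 + w_5 c' + w_8 r')/(2 w_7)$, accepted only when the
second-derivative condition $2w_7 < 0$ holds and $x_q^\ast \in [0,1]$;
otherwise the design-space bound with the higher prediction is returned and
flagged, because the surface has no extrapolation capability. Ties at the
two bounds resolve to the upper bound. DoE results are cached in-session
under a content hash of design plus parameters, so refits are bit-identical.

# Digital twin

Every 60 s of virtual time the twin polls the plant status; on run detection
it (i) re-estimates $R_m$ from the clean-water flux, (ii) initialises the
cake kinetic integral by inverting the Langmuir relation at the first
TMP/flow sample (cake already forms while the chamber fills), and (iii)
estimates the feed concentration from the torque. Every 5 min it runs the
optimization cycle: simulate the past window from the belief state with the
setpoint that was actually active, compare the terminal simulated TMP with
the measurement, adapt if needed, estimate, recommend.

Two design choices deserve justification:

* **Chamber-to-feed conversion of the soft-sensor estimate.** Inverting
  torque through the viscosity correlation recovers the *chamber*
  concentration (exactly the torque-equivalent lumped value of the
  segmented simulator — an identity the tests pin to $10^{-9}$). During the
  concentration phase the chamber runs far above the feed value, so using
  the raw inversion as a feed estimate would drift badly. The twin instead
  multiplies it by the belief model's own feed/chamber concentration ratio
  at the measurement time. In the valve-closed linear-growth phase the
  chamber concentration is proportional to the feed concentration, so the
  correction is exact to first order; for a perfectly matched plant it is an
  exact fixed point (the matched-plant test shows 120 cycles with zero
  mismatch and zero adaptations). The window is simulated with the previous
  cycle's estimate so that the ratio can be evaluated at the measurement
  time.
* **Adaptation direction and bounds.** The TMP increases monotonically with
  the reference steady-state cake resistance, so a simulation that
  over-predicts the TMP by more than 0.1 bar multiplies the estimate by
  0.9, an under-prediction by 1.1; one step per cycle. The estimate is kept
  inside the metamodel design space, outside which the surface is
  untrusted.

**Observability.** TMP mismatch carries resistance information only while
the plant is flow-controlled (TMP floating). Once both plant and belief pin
at the 0.8 bar setpoint the mismatch is zero by construction regardless of
the parameter error. The parameter-recovery test therefore runs the twin
with an operator who rejects the (aggressive) recommendations, keeping the
plant at its moderate 500 L/h recipe long enough for the adaptation loop to
converge — three 10 % steps in the first hour. This mirrors where the
correction functionality acts in real operation (early, moderate-flow run
phases); extending the adaptation signal with the flux channel in pinned
operation would be the natural next step and is out of scope.

# The virtual plant, and what a green test establishes

The virtual plant wraps the same simulator with hidden "true" parameters
(which may differ from the twin's belief), multiplicative Gaussian sensor
noise (default 1 % per channel; the plant's own measurement scatter is
reported only qualitatively, and 1–2 % is typical of industrial flow/
pressure/torque instrumentation), an optional piecewise-constant feed
drift standing in for imperfectly mixed storage tanks, cake formed during
chamber filling (`initial_kc`), and the 5 s process log of the real
historian. A fixed seed reproduces a run bit-identically through a private
RNG stream.

It emulates the *modelled* physics only. Green closed-loop tests establish
that the twin tracks, adapts to and optimises a plant whose mismatch is a
parameter offset within the model class — they do not establish robustness
to structurally unmodelled effects (temperature, cleaning-efficiency
carry-over, the anomalous constant-TMP startups seen in some industrial
runs), nor do they validate the calibrated constants against proprietary
plant data, which are not available. The campaign comparison (twin
recommendations vs a fixed 500 L/h recipe over 20 seeded runs with uniform
feed/cake-resistance draws) demonstrates the directional benefit — the twin
tolerates the transition into TMP-controlled operation that a conservative
recipe avoids — not the magnitude of any industrial improvement.

# Known limitations

* Productivity is the sole objective; yield, energy and cleaning effort are
  not modelled.
* The metamodel is trained at a fixed 10 h duration; recommendations are
  duration-blind.
* No temperature dependence, no CFD-level disc hydrodynamics, no cleaning
  cycles beyond a per-run membrane resistance.
* Adaptation acts on a single parameter through a single (TMP) channel, with
  the pinned-mode observability gap described above.
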