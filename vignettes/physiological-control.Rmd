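---
title: "Physiological LVAD speed control on a virtual patient: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Physiological LVAD speed control on a virtual patient}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phcvad)
```

## Scope and intent

`phcvad` implements a sensorless, modular, multi-objective speed
controller for a centrifugal left ventricular assist device together with
everything needed to exercise it without hardware or clinical data: the
estimators that turn 50 Hz motor signals into physiological indices, a
closed-loop lumped-parameter circulation, scripted provocations
(orthostatic transitions, Valsalva maneuver, ramped ergometry), and the
per-phase analysis that a crossover comparison of constant-speed (CS)
versus physiologically controlled (PhC) operation requires.

This vignette explains the models and their assumptions, the parameters
that matter (with units and defaults), what the synthetic data do and do
not emulate, and the design decisions taken where the design was open.

## The circulation model

Three compartments are enough to express everything the controller can
observe through the pump: a left ventricle with time-varying elastance, a
systemic arterial Windkessel (`C_art` = 1.8 mL/mmHg, `R_art` =
0.83 mmHg·s/mL), and a venous pool (`C_ven` = 70 mL/mmHg). The right
heart and pulmonary bed are lumped into a single venous-to-LV filling
resistance (`R_fill` = 0.05 mmHg·s/mL); this sacrifices any right-heart
or pulmonary dynamics, which the controller could not see anyway, and is
the smallest structure that still exhibits preload sensitivity, suction,
a Valsalva response and an exercise response.

Ventricular pressure is `P_lv = E(t)·(V_lv − V0)` with a normalized
double-Hill activation running over a systolic interval scaled with
`sqrt(RR)`. Peak elastance carries a Frank-Starling modulation,
`Emax_eff = Emax·(1 + starling_gain·(V_ed − V_ed_ref)/V_ed_ref)` clamped
to `[0.2, 2]·Emax`, so a well-filled ventricle contracts harder; this is
what couples flow pulsatility to preload and gives the pulsatility module
something physiological to regulate. The default `Emax` of 0.41 mmHg/mL
describes a severely failing, heavily unloaded ventricle; see
"Calibration" below for why this specific value.

The pump rides its head-flow characteristic
`ΔP = b0·ω² + b1·ω·Q + b2·Q²` quasistatically (no cannula inertance), in
series with inflow/outflow cannula resistances of 1 mmHg/(L/min) each.
The flat, nonlinear centrifugal curve is what makes flow — and therefore
flow pulsatility — sensitive to the pressure environment, and it produces
higher pulsatility at lower flow rates. Omitting inertance means beat-wise
flow excursions are damped only by the curve slope and cannula losses; the
cohort-typical pulsatility is matched by calibration instead (below).

**Suction** is modeled as a smooth volume-dependent inflow obstruction,
`R_in_eff = R_in·(1 + k_occ·max(0, V_suction − V_lv)²)`. Two regimes
matter. With a moderate gain the obstruction acts as a graded choke and
produces a smooth low-flow equilibrium — physiologically a sustained
partial collapse, but invisible to an event detector because nothing
sharp happens. With a large gain (`k_occ` = 3 for the default patient, 8
for the suction-prone preset) the law becomes a relaxation oscillation:
the choke halts outflow, diastolic filling reopens the ventricle, the
next systole collapses it again — sharp, countable, per-beat flow dips,
which is what clinical suction looks like in pump-flow recordings. The
presets deliberately sit in the second regime.

**Valsalva strain** applies intrathoracic pressure `P_th` (+30 mmHg) in
full to the ventricle but only a fraction `pth_venous_frac` (0.85) to the
venous pool, which is mostly extrathoracic. The net effect is the
classic sequence: a brief flow boost (phase I, the pump inlet pressure
rises), then a progressive preload decline as venous return drops
(phase II), deep enough on the suction-prone preset to provoke repeated
suction. Applying `P_th` symmetrically to both sides — superficially
plausible — leaves the filling gradient untouched and suppresses the
entire phenomenon; this asymmetry is the single most consequential
modeling choice in the testbench.

**Posture and ergometry** are scripted parameter trajectories, not a
baroreflex: standing moves 300 mL of stressed venous volume to an
external pool over 10 s and raises intrinsic HR by 8 bpm; an ergometry
ramp raises HR by up to 30 bpm, drops systemic resistance 20 %, raises
contractility 20 % and recruits 150 mL of venous volume, with a 60 s
cooldown. The controller only sees pump signals, so scripted autonomics
are sufficient for testing it; they are *not* a model of autonomic
failure modes.

Integration is fixed-step RK4 at 400 Hz (compiled, Rcpp), decimated to
the 50 Hz logfile contract. The closed loop conserves blood volume
exactly in the continuous equations, and RK4 preserves that linear
invariant, so the 1e-6 conservation check in the test suite is a genuine
integrity check on the implementation, not a tolerance band for drift.

## Calibration

The clinically reported cohort operating point at an average set speed of 2682 rpm
— pump flow 4.9 ± 0.4 L/min, mean arterial pressure 79 ± 10 mmHg,
pulsatility 3.5 ± 0.6 L/min — fixes three free constants: the pump head
coefficient `b0` (= 1.35e-5), the systemic resistance `R_art` (= 0.83)
and `Emax` (= 0.41). They were fit once by fixed-point iteration on 80 s
rest simulations and then frozen; the acceptance script re-measures the
operating point from scratch at run time. `Emax` is low by textbook
standards because the quasistatic pump model leaves only the ventricular
pressure swing to generate pulsatility; with cannula inertance in the
model a higher `Emax` would yield the same pulsatility.

## Estimators

All estimators run causally (trailing windows only) on the sensorless
flow estimate, which inverts the strictly monotone motor map
`I = (c0 + c1·Q + c2·Q²)·ω`. Since current and flow are bijective at
fixed speed, running the detectors on estimated flow rather than raw
current is observationally equivalent and keeps every threshold in
physiological units.

* **Cycle detection**: systolic flow peaks with prominence 0.5 L/min and
  a 0.25 s refractory period; beats are the half-open sample ranges
  between consecutive peaks (0-based indices). Peak times are refined by
  parabolic interpolation before RR intervals are computed — at 50 Hz the
  raw inter-peak spacing is quantized to 20 ms, which alone is a 3 bpm
  error at 140 bpm.
* **Heart rate**: `60/median(RR)` over a trailing 10 s, with beats whose
  instantaneous rate deviates more than 25 % from the smoothed estimate
  excluded (sudden jumps are treated as pathologic and ignored), and an
  output slew of 3 bpm per update. No valid beats for 15 s flags the
  estimate invalid; the controller then freezes its command.
* **Pulsatility**: median per-beat `q_max − q_min` over the window, with
  a max-minus-min fallback when no beats are detectable.
* **Suction**: a beat is flagged when its minimum undershoots the rolling
  median of beat minima by 3 rolling IQRs *and* its steepest down-slope
  exceeds 1.1× the rolling median down-slope; flagged beats within 2 s
  merge into one event. Two refinements against the naive reading of this
  rule were necessary. First, the rolling statistics use *unflagged*
  beats only; otherwise sustained suction adapts the reference within a
  few beats and masks its own continuation. Second, the slope multiplier
  is 1.1, not a large factor: the steepest down-slope of a clean beat is
  dominated by the ordinary systolic decay (tightly distributed around
  ~70 L/min/s here), and genuine suction dips reach only ~1.2–1.9× that
  median, so a multiplier of 2 or more can never fire on this waveform
  family.
* **Aortic valve opening**: a beat counts as valve-open when more than
  15 % of its samples lie within 10 % of the beat maximum — ejection
  clamps ventricular pressure near arterial pressure and flattens the
  flow peak. This is a surrogate validated only against simulator truth
  (≥ 85 % agreement both ways in the test suite); it has not seen real
  pump data.

## Controller design choices

The clinical description of the controller fixes the module structure but not the gains,
so all of the following are config-exposed with these defaults: decision
period 1 s, `kp_ps` = 50 rpm per (L/min)·s, `su_step` = 50 rpm,
`su_clear_s` = 10 s, `max_slew` = 20 rpm/s — chosen to traverse the
±200 rpm demand-response band in about 20 s. PS is a velocity-form
proportional law acting on the current command rather than an absolute
PI: it needs no integrator state and cannot wind up against the DR cap.
The supervisor takes the minimum of PS target, DR limit and SU cap with
tie priority SU > DR > PS. RLI is attributed only when the limiter
truncates an *increase*; truncated decreases keep the requesting module's
label, and a fresh SU cap is deliberately approached at the slew rate
rather than instantaneously. Degenerate HR percentile spans (< 10 bpm,
as occurs with chronotropic incompetence) are widened symmetrically to
10 bpm with a warning rather than rejected. Activation shares are
computed per decision step, not per 50 Hz sample.

## What a green test establishes — and what it does not

The synthetic world emulates: the cohort rest operating point; phasic,
detector-visible suction under provocation; the qualitative crossover
findings (PhC rest speed 200 rpm below CS under DR governance; higher
late-ergometry speed and flow; lower Valsalva suction burden on the
suction-prone preset; more standing than supine suction under CS); and
bit-reproducible 50 Hz logs with ground truth. It does **not** emulate:
arrhythmias or ECG, cannula malposition geometry, baroreflexes,
right-heart failure, measurement artifacts other than Gaussian current
noise, or inter-patient variability beyond the three presets. Detector
thresholds validated here are calibrated to this waveform family, not to
clinical recordings; the clinically reported per-patient medians (e.g. speed
differences of −130 rpm supine) are cohort statistics of six real
patients and are *not* reproduced quantitatively, only directionally.

## Numerical details worth knowing

Valve diodes and the occlusion law are continuous but have kinks; at
400 Hz with RK4 the waveform features the estimators consume are
insensitive to the step (halving the step changes the calibrated means by
far less than the reported dispersions). The beat clock clamps RR to
[0.25, 2] s, matching the accepted-beat range of the estimators. The
H-Q root is the larger quadratic root (the descending branch); above the
maximum head the solver clamps to the vertex and flags. Ties in the
supervisor resolve to SU by `<=` comparisons, so an exactly-equal cap
wins. All randomness (RR jitter, current noise) is pre-drawn from the run
seed before the control loop starts, so PhC-mode branching cannot
desynchronize the stream and identical configurations are bit-identical.

## Known limitations

A single filling resistance stands in for the whole right heart: venous
congestion and pulmonary hypertension are out of reach. The quasistatic
pump has no inertance, so very fast flow transients (< 100 ms) are
sharper than a real cannula would show. Suction presets were tuned so the
provocations straddle the collapse threshold; a patient parameterization
far from the presets may land in the silent graded-choke regime where
suction exists but produces no discrete events — exactly the low
visibility that makes clinical suction hard to count, but worth knowing
when designing new scenarios.
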