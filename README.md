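# phcvad

Sensorless physiological speed control for a centrifugal left ventricular
assist device (LVAD), with the pump-signal estimators it depends on and a
closed-loop cardiovascular testbench to exercise it — entirely in silico.

Contemporary LVADs run at a constant speed (CS) set by clinicians, so pump
flow follows only the pressure difference across the pump and adapts
neither to exercise nor to overpumping. Excessive unloading collapses the
ventricle onto the inflow cannula (*suction*), visible as sharp dips in
the pump flow waveform. This package implements a modular physiological
controller (PhC) that modulates speed using nothing but the pump's own
motor signals, and a lumped-parameter virtual patient to validate it on
the three provocations used in clinical pilot testing: orthostatic
transitions, the Valsalva maneuver and ramped submaximal ergometry.

## The control law

Every update period (1 s) the controller composes four modules:

* **DR (demand response)** — an upper speed limit linear in the estimated
  heart rate, from `(hr_rest, speed_rest)` to `(hr_exercise,
  speed_exercise)`, clamped flat outside that range.
* **PS (pulsatility)** — a proportional speed adjustment holding a
  flow-pulsatility setpoint: `Δω = kp_ps · (pulsatility − setpoint) ·
  update_period`, capped by the DR line when increasing.
* **SU (suction reaction)** — on each detected suction event a hard speed
  cap steps down by `su_step` (never below the absolute minimum), holds
  until suction has been clear for `su_clear_s`, then relaxes.
* **Supervisor / RLI** — arbitrates by taking the minimum of the three
  commands (tie priority SU > DR > PS) and enforces the relative slew
  limit (`max_slew`, 20 rpm/s) and the absolute range 2400–3200 rpm; a
  truncated increase is attributed to RLI (rate-limited increase).

Setpoints follow the clinically used design rules: the DR speed range is
±200 rpm around the pre-test CS speed, exercise HR is the 90th percentile
of an HR history (or resting HR + 30 bpm), and the pulsatility setpoint is
the usual pulsatility minus 2 L/min, floored at 1 L/min.

Estimators run on the sensorless flow estimate recovered from motor
current at 50 Hz: cycle detection at systolic flow peaks, heart rate as
`60/median(RR)` over 10 s with pathologic-jump gating, pulsatility as the
median per-beat peak-to-peak flow, suction events from beat minima that
undershoot their rolling statistics with an abnormally steep down-slope,
and an aortic-valve-opening surrogate from the systolic plateau fraction.

## The testbench

A three-compartment closed loop — time-varying elastance left ventricle
(double-Hill activation, Frank-Starling modulation of peak elastance),
arterial Windkessel, venous pool — coupled to a centrifugal pump through
its head-flow characteristic `ΔP = b0·ω² + b1·ω·Q + b2·Q²`. Suction is a
smooth volume-dependent inflow obstruction. Scenario scripts move venous
volume (posture), apply intrathoracic pressure (Valsalva) and ramp heart
rate, resistance and contractility (ergometry); `occlusion_pulse` events
provide ground-truth positives for scoring the suction detector.
Integration runs at 400 Hz (RK4, Rcpp) and is decimated to the 50 Hz
logfile contract; identical seed and configuration give bit-identical
logs.

## Worked example

```r
library(phcvad)

run <- run_config(patient = patient_preset("default"), duration_s = 80,
                  seed = 1, mode = "CS", set_speed_rpm = 2682)
res <- simulate(run)
fr  <- res$log$frames                       # t, speed, current, power, flow
sel <- fr$t >= 20                           # discard washout
round(mean(fr$flow[sel]), 2)                # 4.88  L/min mean pump flow
round(compute_pulsatility(fr$flow[sel], 50, 60), 2)   # 3.51 L/min
round(mean(res$truth$p_art[sel]), 1)        # 79.2  mmHg mean arterial pressure

phc <- simulate(run_config(duration_s = 90, seed = 2, mode = "PhC",
                           set_speed_rpm = 2682))
tail(phc$trace$omega_cmd, 1)                # 2482  rpm (CS speed − 200)
activation_share(phc$trace$active_module[phc$trace$t > 60])
#  DR  PS  SU RLI
# 100   0   0   0
```

At rest the default virtual patient in CS mode reproduces the clinically
typical operating point (flow ≈ 4.9 L/min, pulsatility ≈ 3.5 L/min, mean
arterial pressure ≈ 79 mmHg); under PhC the controller settles on the
demand-response rest speed 200 rpm below the CS setting, governed by DR.

## Command line

```sh
Rscript inst/cli/phc.R simulate --patient P.json --controller C.json \
    --scenario S.json --mode phc --seed 1 --duration 120 --out run.csv
Rscript inst/cli/phc.R replay  --log run.csv --out beats.csv
Rscript inst/cli/phc.R analyze --log run.csv --protocol valsalva --t0 40 --t1 54
Rscript inst/cli/phc.R compare --cs a.csv --phc b.csv --protocol ergometry --t0 30 --t1 330
```

Exit codes: 0 ok, 2 validation error, 3 I/O error. Configs are JSON, one
file per concern (controller, patient, scenario).

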