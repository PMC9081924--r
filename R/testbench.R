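# Closed-loop lumped-parameter cardiovascular testbench.
#
# Three compartments (left ventricle, systemic arterial Windkessel, venous
# pool) in a closed loop with a centrifugal blood pump from LV apex to
# aorta. The right heart and pulmonary circulation are lumped into a single
# venous-to-LV filling resistance. Scenario scripts perturb the parameters
# over time (posture, Valsalva strain, ergometry ramp, inflow occlusion
# pulses) and `simulate()` produces 50 Hz pump-signal logs with a
# per-sample ground-truth sidecar.

#' Default centrifugal pump and motor model parameters
#'
#' The head-flow (H-Q) characteristic is
#' \deqn{\Delta P = b_0\omega^2 + b_1\omega Q + b_2 Q^2}
#' with \eqn{\Delta P} in mmHg, \eqn{\omega} in rpm and \eqn{Q} in L/min;
#' the flat, downward-sloping curve typical of a centrifugal pump requires
#' \eqn{b_0 > 0} and \eqn{\partial \Delta P/\partial Q < 0} over the
#' operating domain. The motor map is
#' \eqn{I = (c_0 + c_1 Q + c_2 Q^2)\,\omega} (A), strictly increasing in
#' \eqn{Q} at fixed speed, which makes the sensorless flow estimate
#' well-posed. Coefficients are calibrated so that the default virtual
#' patient at 2682 rpm rests near the clinically typical operating point
#' (about 4.9 L/min mean flow at a mean arterial pressure near 79 mmHg).
#'
#' @param b0,b1,b2 H-Q polynomial coefficients.
#' @param c0,c1,c2 motor map coefficients (A per rpm).
#' @param supply_voltage_v nominal DC supply voltage used to synthesize the
#'   power channel from current.
#' @return list of class `phc_pump_params`.
#' @export
pump_params <- function(b0 = 1.35e-5, b1 = -1.0e-3, b2 = -0.25,
                        c0 = 5e-5, c1 = 1.5e-5, c2 = 5e-7,
                        supply_voltage_v = 14) {
  p <- list(b0 = b0, b1 = b1, b2 = b2, c0 = c0, c1 = c1, c2 = c2,
            supply_voltage_v = supply_voltage_v)
  if (b0 <= 0) phc_validation_error("pump b0 must be > 0 (got %g)", b0)
  # descending H-Q over the calibrated domain (omega 1800-4000, Q 0-10)
  slope <- function(w, q) b1 * w + 2 * b2 * q
  if (slope(1800, 0) >= 0 || slope(4000, 10) >= 0)
    phc_validation_error("H-Q characteristic must slope down over the operating domain")
  if (c1 + 2 * c2 * 0 <= 0 || c1 + 2 * c2 * 10 <= 0)
    phc_validation_error("motor map must be strictly increasing in Q on [0, 10] L/min")
  class(p) <- "phc_pump_params"
  p
}

#' Virtual patient parameter presets
#'
#' @param preset one of `"default"` (stable supported heart-failure
#'   patient), `"suction_prone"` (high suction-threshold volume and low
#'   venous reserve, emulating recurring suction), or
#'   `"chronotropic_incompetent"` (no heart-rate response to activity).
#' @param ... named overrides for individual fields.
#' @return list of class `phc_patient` with ventricular elastance
#'   (`Emax`, `Emin` mmHg/mL, `V0` mL), a Frank-Starling gain acting on
#'   peak elastance around `V_ed_ref`, systemic Windkessel (`R_art`
#'   mmHg s/mL, `C_art` mL/mmHg), venous pool (`C_ven` mL/mmHg), filling
#'   and valve resistances (mmHg s/mL), cannula resistances `R_in`,
#'   `R_out` (mmHg per L/min), the suction threshold volume `V_suction`
#'   (mL) with occlusion gain `k_occ`, the fraction of intrathoracic
#'   pressure reaching the venous pool (`pth_venous_frac`), intrinsic
#'   heart rate `HR0` (bpm),
#'   chronotropic reactivity in [0, 1], intrathoracic pressure `P_th`
#'   (mmHg, 0 at rest) and initial state (`V_lv0`, `P_art0`, `P_ven0`).
#' @export
patient_preset <- function(preset = c("default", "suction_prone",
                                      "chronotropic_incompetent"), ...) {
  preset <- match.arg(preset)
  p <- list(
    Emax = 0.41, Emin = 0.06, V0 = 10, starling_gain = 0.5, V_ed_ref = 150,
    R_fill = 0.05, R_av = 0.01, R_art = 0.83, C_art = 1.8, C_ven = 70,
    R_in = 1.0, R_out = 1.0, V_suction = 25, k_occ = 3,
    pth_venous_frac = 0.85,
    HR0 = 76, hr_reactivity = 1, P_th = 0,
    V_lv0 = 150, P_art0 = 79, P_ven0 = 11)
  if (preset == "suction_prone")
    p <- modifyList(p, list(V_suction = 56, k_occ = 8, C_ven = 80,
                            P_ven0 = 9.5, V_lv0 = 120))
  if (preset == "chronotropic_incompetent")
    p <- modifyList(p, list(hr_reactivity = 0))
  p <- modifyList(p, list(...))
  validate_patient(p)
}

validate_patient <- function(p) {
  req <- c("Emax", "Emin", "V0", "starling_gain", "V_ed_ref", "R_fill",
           "R_av", "R_art", "C_art", "C_ven", "R_in", "R_out", "V_suction",
           "k_occ", "pth_venous_frac", "HR0", "hr_reactivity", "P_th",
           "V_lv0", "P_art0", "P_ven0")
  miss <- setdiff(req, names(p))
  if (length(miss))
    phc_validation_error("patient parameters missing: %s", paste(miss, collapse = ", "))
  if (!(p$Emax > p$Emin && p$Emin > 0))
    phc_validation_error("require Emax > Emin > 0 (got Emax=%g, Emin=%g)", p$Emax, p$Emin)
  for (f in c("R_fill", "R_av", "R_art", "C_art", "C_ven", "R_in", "R_out"))
    if (p[[f]] <= 0) phc_validation_error("patient field %s must be > 0 (got %g)", f, p[[f]])
  if (p$HR0 < 20 || p$HR0 > 250)
    phc_validation_error("HR0 must lie in [20, 250] bpm (got %g)", p$HR0)
  class(p) <- "phc_patient"
  p
}

#' Time-varying ventricular elastance (double-Hill activation)
#'
#' Normalized double-Hill activation scaled between `Emin` and the
#' effective peak elastance. The effective `Emax` carries a Frank-Starling
#' modulation: `Emax * (1 + starling_gain * (v_ed - V_ed_ref)/V_ed_ref)`,
#' clamped to `[0.2, 2] * Emax`, so a better-filled ventricle contracts
#' more strongly.
#'
#' @param t_in_beat time since beat onset, s, in `[0, rr)`.
#' @param rr beat period, s.
#' @param params `phc_patient` parameters.
#' @param v_ed end-diastolic volume for the Starling modulation, mL;
#'   defaults to `V_ed_ref` (no modulation).
#' @return elastance in mmHg/mL.
#' @export
elastance <- function(t_in_beat, rr, params, v_ed = params$V_ed_ref) {
  if (any(t_in_beat < 0 | t_in_beat >= rr))
    phc_validation_error("t_in_beat must lie in [0, rr)")
  act <- vapply(t_in_beat, .cpp_activation, numeric(1), rr = rr)
  params$Emin + (starling_emax(params, v_ed) - params$Emin) * act
}

starling_emax <- function(params, v_ed) {
  f <- 1 + params$starling_gain * (v_ed - params$V_ed_ref) / params$V_ed_ref
  params$Emax * clamp(f, 0.2, 2)
}

#' Pump flow from the H-Q characteristic
#'
#' Solves `b2 Q^2 + (b1 w - r_lin) Q + (b0 w^2 - dp) = 0` for the physical
#' root on the descending branch of the pump curve. `Q` may be negative
#' (regurgitant) when the pressure head exceeds the shutoff head. Outside
#' the calibrated domain (no real root) the flow is clamped to the branch
#' endpoint and flagged via the `"clamped"` attribute.
#'
#' @param dp pressure difference across the pump (outlet minus inlet), mmHg.
#' @param omega pump speed, rpm (> 0).
#' @param pump `phc_pump_params`.
#' @param r_lin additional series (cannula) resistance, mmHg per L/min.
#' @return flow in L/min with logical attribute `clamped`.
#' @export
pump_flow <- function(dp, omega, pump = pump_params(), r_lin = 0) {
  if (any(omega <= 0)) phc_validation_error("pump speed must be > 0")
  n <- max(length(dp), length(omega))
  dp <- rep_len(dp, n); omega <- rep_len(omega, n)
  q <- numeric(n); cl <- logical(n)
  for (i in seq_len(n)) {
    r <- .cpp_pump_flow(dp[i], omega[i], pump$b0, pump$b1, pump$b2, r_lin)
    q[i] <- r$q; cl[i] <- r$clamped
  }
  structure(q, clamped = cl)
}

#' Motor current from flow and speed (forward motor map)
#'
#' @param q flow, L/min. @param omega speed, rpm.
#' @param pump `phc_pump_params`.
#' @param viscosity_scale multiplicative scale on the map (hematocrit /
#'   viscosity variation), dimensionless.
#' @return current in A.
#' @export
motor_current <- function(q, omega, pump = pump_params(), viscosity_scale = 1) {
  viscosity_scale * (pump$c0 + pump$c1 * q + pump$c2 * q^2) * omega
}

#' Volume-dependent inflow-cannula resistance (suction mechanism)
#'
#' Smooth partial-occlusion law: below the suction threshold volume the
#' inflow resistance grows quadratically,
#' `R = R_in * (1 + k_occ * max(0, V_suction - V_lv)^2)`, producing the
#' sharp diastolic flow dips a suction detector must find.
#'
#' @param v_lv left-ventricular volume, mL.
#' @param params `phc_patient`.
#' @return resistance in mmHg per L/min; monotone non-increasing in `v_lv`.
#' @export
inflow_resistance <- function(v_lv, params) {
  params$R_in * (1 + params$k_occ * pmax(0, params$V_suction - v_lv)^2)
}

#' Instantaneous derivatives of the 3-compartment circulation
#'
#' State is `c(V_lv, P_art, P_ven)` (mL, mmHg, mmHg). Flows: valve-diode
#' filling and aortic ejection, quasistatic pump flow through the H-Q
#' characteristic with cannula losses (the inflow resistance depending on
#' `V_lv` via [inflow_resistance()]), and systemic runoff. Intrathoracic
#' pressure `pth` (Valsalva strain) loads the LV fully and the venous
#' pool by `pth_venous_frac`, so strain cuts the venous-to-LV filling
#' gradient. The closed loop conserves volume exactly: the three volume
#' derivatives (with `pool_rate` routed to the external pooling reservoir)
#' sum to zero at any state.
#'
#' @param state numeric `c(V_lv, P_art, P_ven)`.
#' @param t time since beat onset is taken as `t` modulo the beat period
#'   `60/HR0`, s.
#' @param patient `phc_patient`. @param pump `phc_pump_params`.
#' @param omega pump speed, rpm.
#' @param pth intrathoracic pressure, mmHg.
#' @param rart_scale,rin_mult scenario multipliers on systemic and inflow
#'   resistance. @param pool_rate venous-pooling rate, mL/s.
#' @param v_ed end-diastolic volume for the Starling term (default: current
#'   `V_lv`).
#' @return list with `d` (derivatives of the state), `q_fill`, `q_av`
#'   (mL/s) and `q_pump` (L/min).
#' @export
cv_derivatives <- function(state, t, patient, pump = pump_params(),
                           omega, pth = 0, rart_scale = 1, rin_mult = 1,
                           pool_rate = 0, v_ed = state[1]) {
  if (any(!is.finite(state)) || state[1] <= 0)
    phc_validation_error("state must be finite with V_lv > 0")
  rr <- 60 / patient$HR0
  e_act <- .cpp_activation(t %% rr, rr)
  .cpp_cv_derivs(as.numeric(state), e_act, starling_emax(patient, v_ed),
                 unclass(patient), unclass(pump), omega, pth, rart_scale,
                 rin_mult, pool_rate)
}

# ---------------------------------------------------------------------------
# Scenario scripts

KINDS <- c("posture_up", "posture_down", "valsalva_on", "valsalva_off",
           "exercise_ramp", "occlusion_pulse")

#' Build a scenario script of timed physiological perturbations
#'
#' @param events data.frame with columns `t` (s), `kind` (one of
#'   `posture_up`, `posture_down`, `valsalva_on`, `valsalva_off`,
#'   `exercise_ramp`, `occlusion_pulse`) and `magnitude` (`NA` picks the
#'   kind's default: 300 mL pooled volume for posture, +30 mmHg
#'   intrathoracic pressure for Valsalva, ramp duration in s for
#'   ergometry, inflow-resistance multiplier for occlusion pulses).
#' @return object of class `phc_scenario`.
#' @export
scenario_script <- function(events = data.frame(t = numeric(),
                                                kind = character(),
                                                magnitude = numeric())) {
  events <- as.data.frame(events)
  if (!all(c("t", "kind", "magnitude") %in% names(events)))
    phc_format_error("scenario events need columns t, kind, magnitude")
  bad <- setdiff(events$kind, KINDS)
  if (length(bad))
    phc_validation_error("unknown scenario event kind(s): %s", paste(bad, collapse = ", "))
  if (is.unsorted(events$t))
    phc_validation_error("scenario events must be time-ordered")
  on_t <- events$t[events$kind == "valsalva_on"]
  off_t <- events$t[events$kind == "valsalva_off"]
  if (length(on_t) != length(off_t) || any(off_t <= on_t))
    phc_validation_error("valsalva_on/valsalva_off events must come in ordered pairs")
  if (any(off_t - on_t > 15))
    warning("Valsalva strain longer than 15 s", call. = FALSE)
  er <- events[events$kind == "exercise_ramp", ]
  if (nrow(er) > 1) {
    dur <- ifelse(is.na(er$magnitude), 300, er$magnitude)
    if (any(er$t[-1] < (er$t + dur + 60)[-nrow(er)]))
      phc_validation_error("overlapping exercise_ramp events")
  }
  structure(list(events = events), class = "phc_scenario")
}

# defaults per event kind
event_default <- c(posture_up = 300, posture_down = 300, valsalva_on = 30,
                   valsalva_off = 0, exercise_ramp = 300, occlusion_pulse = 6)
POSTURE_RAMP_S <- 10     # venous pooling transition time
POSTURE_HR_DELTA <- 8    # bpm orthostatic heart-rate rise
VALSALVA_PTH <- 30       # mmHg default strain pressure
EXERCISE_HR_DELTA <- 30  # bpm at full ramp
EXERCISE_RART <- 0.20    # fractional systemic resistance drop at full ramp
EXERCISE_EMAX <- 0.20    # fractional contractility rise at full ramp
EXERCISE_POOL <- -150    # mL venous tone recruitment at full ramp
OCCLUSION_S <- 1.5       # occlusion pulse duration

ramp01 <- function(t, t0, t1) {
  if (t1 <= t0) return(as.numeric(t >= t0))
  clamp((t - t0) / (t1 - t0), 0, 1)
}

# Evaluate scenario parameter profiles at arbitrary times.
param_profiles <- function(patient, scenario, times) {
  n <- length(times)
  hr_delta <- numeric(n); pth <- numeric(n)
  rart <- rep(1, n); emax <- rep(1, n); rin <- rep(1, n)
  pool <- numeric(n)
  ev <- scenario$events
  react <- patient$hr_reactivity
  for (i in seq_len(nrow(ev))) {
    t0 <- ev$t[i]
    mag <- if (is.na(ev$magnitude[i])) event_default[[ev$kind[i]]] else ev$magnitude[i]
    switch(ev$kind[i],
      posture_up = {
        r <- ramp01(times, t0, t0 + POSTURE_RAMP_S)
        pool <- pool + mag * r
        hr_delta <- hr_delta + POSTURE_HR_DELTA * react * r
      },
      posture_down = {
        r <- ramp01(times, t0, t0 + POSTURE_RAMP_S)
        pool <- pool - mag * r
        hr_delta <- hr_delta - POSTURE_HR_DELTA * react * r
      },
      valsalva_on = {
        j <- which(ev$kind == "valsalva_off" & ev$t > t0)[1]
        t1 <- if (is.na(j)) Inf else ev$t[j]
        pth <- pth + mag * (times >= t0 & times < t1)
      },
      valsalva_off = {},
      exercise_ramp = {
        act <- ramp01(times, t0, t0 + mag) *
          (1 - ramp01(times, t0 + mag, t0 + mag + 60))
        hr_delta <- hr_delta + EXERCISE_HR_DELTA * react * act
        rart <- rart * (1 - EXERCISE_RART * act)
        emax <- emax * (1 + EXERCISE_EMAX * act)
        pool <- pool + EXERCISE_POOL * act
      },
      occlusion_pulse = {
        on <- times >= t0 & times < t0 + OCCLUSION_S
        rin <- pmax(rin, ifelse(on, mag, 1))
      })
  }
  list(hr0 = clamp(patient$HR0 + hr_delta, 20, 250), pth = pth,
       rart_scale = rart, emax_scale = emax, rin_mult = rin, pool_vol = pool)
}

#' Scenario-modified patient parameters at a point in time
#'
#' Applies the scripted perturbations active at time `t` to the baseline
#' patient: heart-rate shifts, systemic-resistance and contractility
#' scaling during ergometry, intrathoracic pressure during Valsalva
#' strain, venous pooled volume after posture changes and inflow-occlusion
#' multipliers.
#'
#' @param patient `phc_patient`. @param t time, s (scalar).
#' @param script `phc_scenario`.
#' @return modified `phc_patient` with extra fields `pool_volume_ml` and
#'   `rin_mult`.
#' @export
apply_scenario <- function(patient, t, script) {
  pr <- param_profiles(patient, script, t)
  out <- patient
  out$HR0 <- pr$hr0
  out$R_art <- patient$R_art * pr$rart_scale
  out$Emax <- patient$Emax * pr$emax_scale
  out$P_th <- pr$pth
  out$pool_volume_ml <- pr$pool_vol
  out$rin_mult <- pr$rin_mult
  out
}

# ---------------------------------------------------------------------------
# Run configuration and the simulator

#' Assemble a simulation run configuration
#'
#' @param patient `phc_patient`. @param pump `phc_pump_params`.
#' @param scenario `phc_scenario`.
#' @param duration_s run length, s (> 0).
#' @param seed integer RNG seed; identical `(config, seed)` gives
#'   bit-identical output.
#' @param mode `"CS"` (constant speed) or `"PhC"` (physiological control).
#' @param set_speed_rpm constant-speed setting / controller start speed.
#' @param controller `phc_controller_config`; defaults to
#'   [design_setpoints()] around `set_speed_rpm` (PhC mode only).
#' @param sigma_current motor-current measurement noise SD, A.
#' @param sigma_rr beat-to-beat lognormal RR variability SD.
#' @return `phc_run_config`.
#' @export
run_config <- function(patient = patient_preset(), pump = pump_params(),
                       scenario = scenario_script(), duration_s = 60,
                       seed = 1, mode = c("CS", "PhC"),
                       set_speed_rpm = 2682, controller = NULL,
                       sigma_current = 0.002, sigma_rr = 0.02) {
  mode <- match.arg(mode)
  if (duration_s <= 0)
    phc_validation_error("duration_s must be > 0 (got %g)", duration_s)
  if (mode == "PhC" && is.null(controller))
    controller <- design_setpoints(set_speed_rpm, rest_hr = patient$HR0,
                                   usual_pulsatility = 3.5)
  structure(list(patient = patient, pump = pump, scenario = scenario,
                 duration_s = duration_s, seed = as.integer(seed),
                 mode = mode, set_speed_rpm = set_speed_rpm,
                 controller = controller, sigma_current = sigma_current,
                 sigma_rr = sigma_rr),
            class = "phc_run_config")
}

#' Run the closed-loop simulation
#'
#' Integrates the cardiovascular model at 400 Hz (fixed-step RK4) and emits
#' 50 Hz pump signals. The motor current is synthesized from the forward
#' motor map plus seeded Gaussian measurement noise; the logged flow channel
#' is the sensorless estimate recovered from that noisy current (as a real
#' device would log it). In PhC mode the estimators and [controller_step()]
#' run in the loop once per controller update period; in CS mode the speed
#' is held constant. Identical configuration and seed give bit-identical
#' output.
#'
#' @param run `phc_run_config`.
#' @return list with `log` (a [signal_log()]), `truth` (per-sample
#'   ground-truth data.frame: `flow_true` L/min, `hr_true` bpm, `aov_open`,
#'   `occl` flags, `p_lv`, `p_art`, `p_ven` mmHg, `v_lv` mL) and `trace`
#'   (per-controller-step data.frame, PhC mode).
#' @export
simulate <- function(run) {
  if (!inherits(run, "phc_run_config"))
    phc_validation_error("simulate() expects a phc_run_config")
  set.seed(run$seed)
  fs <- 50; dt <- 1 / 400; out_every <- 8L
  dur <- run$duration_s
  n_int <- as.integer(round(dur / dt))
  n_out <- n_int %/% out_every
  t_int <- (seq_len(n_int) - 1L) * dt
  prof <- param_profiles(run$patient, run$scenario, t_int)
  pool_rate <- c(diff(prof$pool_vol), 0) / dt

  # pre-drawn randomness so the RNG stream is independent of control flow
  rr_jitter <- exp(rnorm(ceiling(dur * 4) + 8, 0, run$sigma_rr))
  i_noise <- rnorm(n_out, 0, run$sigma_current)

  pat <- run$patient
  state <- c(pat$V_lv0, pat$P_art0, pat$P_ven0, 0)
  beat <- list(phase = 60 / pat$HR0, rr = 60 / pat$HR0,
               emax_eff = pat$Emax, jitter_idx = 0L)

  upd <- if (run$mode == "PhC") run$controller$update_period else 1
  steps_per_chunk <- as.integer(round(upd / dt))
  n_chunks <- ceiling(n_int / steps_per_chunk)

  omega <- run$set_speed_rpm
  ctrl <- if (run$mode == "PhC") controller_state(run$controller, omega)
  est <- estimator_state()
  ecfg <- if (run$mode == "PhC") run$controller$estimator else est_config()

  rows <- vector("list", n_chunks)
  trace <- vector("list", n_chunks)
  speed_out <- numeric(0)
  buf_t <- numeric(0); buf_q <- numeric(0)  # trailing estimator buffer
  out_filled <- 0L

  for (ch in seq_len(n_chunks)) {
    i0 <- (ch - 1L) * steps_per_chunk + 1L
    i1 <- min(ch * steps_per_chunk, n_int)
    idx <- i0:i1
    res <- .cpp_cv_chunk(state, beat, t_int[i0], dt, length(idx), out_every,
                         unclass(pat), unclass(run$pump), omega,
                         prof$hr0[idx], prof$pth[idx], prof$rart_scale[idx],
                         prof$emax_scale[idx], prof$rin_mult[idx],
                         pool_rate[idx], rr_jitter)
    if (res$failed)
      phc_stop("phcvad_simulation_error",
               "non-physical state (ventricular collapse) at t = %.3f s", res$t_fail)
    state <- res$state; beat <- res$beat
    out <- res$out[seq_len(res$n_out), , drop = FALSE]
    k <- nrow(out)
    if (k == 0) next
    cur <- motor_current(out[, "flow_true"], omega, run$pump) +
      i_noise[out_filled + seq_len(k)]
    out_filled <- out_filled + k
    q_est <- estimate_flow(cur, omega, run$pump)
    rows[[ch]] <- cbind(out, current = cur, flow = as.numeric(q_est),
                        speed = omega)
    speed_out <- c(speed_out, rep(omega, k))
    buf_t <- c(buf_t, out[, "t"]); buf_q <- c(buf_q, as.numeric(q_est))
    keep <- buf_t > tail(buf_t, 1) - 40
    buf_t <- buf_t[keep]; buf_q <- buf_q[keep]

    if (run$mode == "PhC" && length(buf_t) >= 3 * fs) {
      t_now <- tail(buf_t, 1)
      est <- estimator_step(buf_t, buf_q, fs, est, ecfg, t_now)
      ctrl <- controller_step(est, ctrl, run$controller, t_now)
      omega <- ctrl$omega_cmd
      trace[[ch]] <- data.frame(t = t_now, omega_cmd = ctrl$omega_cmd,
                                active_module = ctrl$active_module,
                                hr = est$hr, pulsatility = est$pulsatility,
                                omega_su_cap = ctrl$omega_su_cap)
    }
  }

  m <- do.call(rbind, rows)
  frames <- data.frame(t = m[, "t"], speed = m[, "speed"],
                       current = m[, "current"],
                       power = run$pump$supply_voltage_v * m[, "current"],
                       flow = m[, "flow"])
  truth <- data.frame(t = m[, "t"], flow_true = m[, "flow_true"],
                      hr_true = m[, "hr_true"],
                      aov_open = m[, "aov_open"] > 0, occl = m[, "occl"] > 0,
                      p_lv = m[, "p_lv"], p_art = m[, "p_art"],
                      p_ven = m[, "p_ven"], v_lv = m[, "v_lv"])
  trace <- if (run$mode == "PhC") do.call(rbind, trace) else NULL

  ann <- scenario_annotations(run$scenario)
  if (!is.null(trace) && nrow(trace))
    ann <- rbind(ann, data.frame(t_start = trace$t, t_end = trace$t,
                                 kind = "module", payload = trace$active_module))
  # offline estimator pass for suction-event annotations (both modes)
  se <- detect_suction_log(frames$t, frames$flow, fs, ecfg)
  if (length(se))
    ann <- rbind(ann, data.frame(t_start = se, t_end = se,
                                 kind = "suction_event", payload = ""))
  log <- signal_log(frames, annotations = ann,
                    meta = list(mode = run$mode,
                                set_speed_rpm = run$set_speed_rpm,
                                seed = run$seed))
  list(log = log, truth = truth, trace = trace)
}

scenario_annotations <- function(scenario) {
  ev <- scenario$events
  if (!nrow(ev))
    return(data.frame(t_start = numeric(), t_end = numeric(),
                      kind = character(), payload = character()))
  mag <- ifelse(is.na(ev$magnitude), event_default[ev$kind], ev$magnitude)
  t_end <- ev$t + ifelse(ev$kind == "occlusion_pulse", OCCLUSION_S,
                  ifelse(ev$kind %in% c("posture_up", "posture_down"),
                         POSTURE_RAMP_S, 0))
  data.frame(t_start = ev$t, t_end = t_end, kind = ev$kind,
             payload = as.character(mag))
}

#' Total tracked blood volume of a simulator state
#'
#' Stressed volume in the three compartments plus the externally pooled
#' volume; conserved by the closed loop.
#' @param state numeric `c(V_lv, P_art, P_ven, V_pooled)`.
#' @param patient `phc_patient`.
#' @return volume in mL.
#' @export
total_volume <- function(state, patient) {
  state[1] + patient$C_art * state[2] + patient$C_ven * state[3] + state[4]
}
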