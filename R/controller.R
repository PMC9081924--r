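# Modular multi-objective physiological speed control.
#
# Three hemodynamically functional modules and a supervisor:
#   DR  demand response  — linear map from heart rate to an upper speed limit
#   PS  pulsatility      — proportional speed adjustment holding a flow
#                          pulsatility setpoint, capped by the DR line
#   SU  suction reaction — discrete step-downs on detected suction, held
#                          until clearance
# The supervisor arbitrates (minimum of the commands, tie priority
# SU > DR > PS) and a rate limiter (RLI) enforces relative and absolute
# speed bounds.

#' Controller configuration
#'
#' @param hr_rest,hr_exercise bpm, endpoints of the demand-response line.
#' @param speed_rest,speed_exercise rpm, speeds mapped to those endpoints.
#' @param pulsatility_setpoint L/min (>= 1).
#' @param speed_min_abs,speed_max_abs rpm, absolute safety bounds
#'   (defaults 2400 / 3200, the recommended constant-speed range).
#' @param kp_ps rpm per (L/min) s, pulsatility proportional gain.
#' @param su_step rpm, suction reaction step-down.
#' @param su_clear_s s the suction cap holds after the last event.
#' @param max_slew rpm/s relative speed limit.
#' @param update_period s between controller decisions.
#' @param estimator `phc_est_config` used by the in-loop estimators.
#' @return list of class `phc_controller_config`.
#' @export
controller_config <- function(hr_rest, hr_exercise, speed_rest,
                              speed_exercise, pulsatility_setpoint,
                              speed_min_abs = 2400, speed_max_abs = 3200,
                              kp_ps = 50, su_step = 50, su_clear_s = 10,
                              max_slew = 20, update_period = 1,
                              estimator = est_config()) {
  cfg <- structure(as.list(environment()), class = "phc_controller_config")
  validate_controller_config(cfg)
}

validate_controller_config <- function(cfg) {
  chk <- function(cond, fmt, ...) if (!cond) phc_validation_error(fmt, ...)
  chk(cfg$hr_exercise > cfg$hr_rest,
      "hr_exercise (%g) must exceed hr_rest (%g)", cfg$hr_exercise, cfg$hr_rest)
  chk(cfg$speed_exercise >= cfg$speed_rest,
      "speed_exercise (%g) must be >= speed_rest (%g)",
      cfg$speed_exercise, cfg$speed_rest)
  chk(cfg$speed_min_abs <= cfg$speed_rest,
      "speed_rest (%g) below absolute minimum %g", cfg$speed_rest, cfg$speed_min_abs)
  chk(cfg$speed_exercise <= cfg$speed_max_abs,
      "speed_exercise (%g) above absolute maximum %g",
      cfg$speed_exercise, cfg$speed_max_abs)
  chk(cfg$pulsatility_setpoint >= 1.0,
      "pulsatility_setpoint (%g) must be >= 1 L/min", cfg$pulsatility_setpoint)
  for (f in c("kp_ps", "su_step", "max_slew", "update_period", "su_clear_s"))
    chk(cfg[[f]] > 0, "%s must be > 0 (got %g)", f, cfg[[f]])
  cfg
}

#' Design controller setpoints from a patient's routine operating point
#'
#' Heart-rate endpoints come from the 10th and 90th percentile of an HR
#' history when one is available, otherwise from the resting HR with
#' 30 bpm added for exercise. The demand-response speed range spans
#' 200 rpm below to 200 rpm above the pre-test constant-speed setting
#' (clamped to the absolute limits). The pulsatility setpoint is the usual
#' pulsatility minus 2 L/min, floored at 1 L/min. Degenerate HR spans
#' below 10 bpm are widened symmetrically to 10 bpm with a warning.
#'
#' @param cs_speed rpm, pre-test constant-speed setting.
#' @param hr_history optional bpm series of routine recordings.
#' @param rest_hr bpm, resting HR (used when no history is given).
#' @param usual_pulsatility L/min, routine pulsatility (> 0).
#' @param speed_min_abs,speed_max_abs rpm absolute bounds.
#' @param ... passed through to [controller_config()].
#' @return `phc_controller_config`.
#' @export
design_setpoints <- function(cs_speed, hr_history = NULL, rest_hr = NULL,
                             usual_pulsatility, speed_min_abs = 2400,
                             speed_max_abs = 3200, ...) {
  if (cs_speed < speed_min_abs || cs_speed > speed_max_abs)
    phc_validation_error("cs_speed %g outside [%g, %g] rpm",
                         cs_speed, speed_min_abs, speed_max_abs)
  if (usual_pulsatility <= 0)
    phc_validation_error("usual_pulsatility must be > 0 (got %g)",
                         usual_pulsatility)
  if (!is.null(hr_history)) {
    qs <- quantile(hr_history, c(0.1, 0.9), names = FALSE)
    hr_rest <- qs[1]; hr_exercise <- qs[2]
  } else {
    if (is.null(rest_hr))
      phc_validation_error("either hr_history or rest_hr is required")
    hr_rest <- rest_hr; hr_exercise <- rest_hr + 30
  }
  if (hr_exercise - hr_rest < 10) {
    mid <- (hr_rest + hr_exercise) / 2
    hr_rest <- mid - 5; hr_exercise <- mid + 5
    warning("degenerate HR span widened to 10 bpm", call. = FALSE)
  }
  controller_config(
    hr_rest = hr_rest, hr_exercise = hr_exercise,
    speed_rest = clamp(cs_speed - 200, speed_min_abs, speed_max_abs),
    speed_exercise = clamp(cs_speed + 200, speed_min_abs, speed_max_abs),
    pulsatility_setpoint = max(usual_pulsatility - 2, 1.0),
    speed_min_abs = speed_min_abs, speed_max_abs = speed_max_abs, ...)
}

#' Fresh controller state
#' @param cfg `phc_controller_config`. @param omega0 rpm initial command.
#' @return list of class `phc_controller_state`.
#' @export
controller_state <- function(cfg, omega0) {
  if (omega0 < cfg$speed_min_abs || omega0 > cfg$speed_max_abs)
    phc_validation_error("initial speed %g outside absolute limits", omega0)
  structure(list(omega_cmd = omega0, active_module = "DR",
                 omega_su_cap = Inf, su_active = FALSE,
                 t_last_suction = -Inf, last_dr_limit = cfg$speed_rest,
                 hr_invalid_since = NA_real_, frozen = FALSE),
            class = "phc_controller_state")
}

#' Demand-response upper speed limit
#'
#' Linear interpolation from `(hr_rest, speed_rest)` to
#' `(hr_exercise, speed_exercise)`, clamped flat outside the HR range;
#' non-decreasing in HR. With an invalid HR the last limit is held.
#'
#' @param hr bpm (or `NA`/invalid). @param cfg `phc_controller_config`.
#' @param state optional `phc_controller_state` supplying the held limit.
#' @return upper speed limit, rpm.
#' @export
dr_limit <- function(hr, cfg, state = NULL) {
  if (is.null(hr) || !is.finite(hr)) {
    if (is.null(state)) phc_validation_error("invalid HR and no held limit")
    return(state$last_dr_limit)
  }
  frac <- clamp((hr - cfg$hr_rest) / (cfg$hr_exercise - cfg$hr_rest), 0, 1)
  cfg$speed_rest + frac * (cfg$speed_exercise - cfg$speed_rest)
}

#' Pulsatility module speed target
#'
#' Velocity-form proportional law on the pulsatility error: the proposal
#' moves the current command by `kp_ps * (pulsatility - setpoint) *
#' update_period`, capped at the demand-response limit when increasing and
#' floored at the absolute minimum when decreasing.
#'
#' @param pulsatility L/min (>= 0). @param cfg `phc_controller_config`.
#' @param omega_cmd rpm current command. @param dr_cap rpm DR upper limit.
#' @return proposed speed target, rpm.
#' @export
ps_command <- function(pulsatility, cfg, omega_cmd, dr_cap) {
  if (pulsatility < 0) phc_validation_error("pulsatility must be >= 0")
  delta <- cfg$kp_ps * (pulsatility - cfg$pulsatility_setpoint) *
    cfg$update_period
  prop <- omega_cmd + delta
  if (delta > 0) min(prop, dr_cap) else max(prop, cfg$speed_min_abs)
}

#' Suction-reaction hard cap
#'
#' On each new suction event the cap steps down by `su_step` from the
#' current command (never below the absolute minimum). The cap holds while
#' suction is more recent than the clearance time, then relaxes upward at
#' the slew rate until it disengages (returns `Inf`).
#'
#' @param new_event logical, a suction event arrived this step.
#' @param t_now s. @param state `phc_controller_state`.
#' @param cfg `phc_controller_config`.
#' @return updated `phc_controller_state` (fields `omega_su_cap`,
#'   `su_active`, `t_last_suction`).
#' @export
su_command <- function(new_event, t_now, state, cfg) {
  if (isTRUE(new_event)) {
    state$omega_su_cap <- max(state$omega_cmd - cfg$su_step, cfg$speed_min_abs)
    state$t_last_suction <- t_now
    state$su_active <- TRUE
  } else if (state$su_active &&
             t_now - state$t_last_suction >= cfg$su_clear_s) {
    state$omega_su_cap <- state$omega_su_cap +
      cfg$max_slew * cfg$update_period
    if (state$omega_su_cap >= cfg$speed_max_abs) {
      state$omega_su_cap <- Inf
      state$su_active <- FALSE
    }
  }
  state
}

#' Supervisor arbitration of module commands
#'
#' The arbitrated proposal is the minimum of the pulsatility target, the
#' demand-response upper limit and the suction hard cap. The binding
#' module is the argmin, with tie priority SU > DR > PS; the suction cap
#' always wins when it is the strict minimum.
#'
#' @param ps,dr,su proposed speeds, rpm (`su = Inf` when inactive).
#' @return list `(proposed, module)`.
#' @export
supervise <- function(ps, dr, su) {
  proposed <- min(ps, dr, su)
  module <- if (su <= proposed) "SU" else if (dr <= proposed) "DR" else "PS"
  list(proposed = proposed, module = module)
}

#' Relative and absolute speed limiting
#'
#' The command moves from `omega_prev` toward `proposed` by at most
#' `max_slew * update_period` and is clamped to the absolute speed range;
#' `limited` reports whether either bound truncated the move.
#'
#' @param omega_prev rpm within the absolute limits.
#' @param proposed rpm. @param cfg `phc_controller_config`.
#' @return list `(omega_cmd, limited)`.
#' @export
rate_limit <- function(omega_prev, proposed, cfg) {
  step <- clamp(proposed - omega_prev,
                -cfg$max_slew * cfg$update_period,
                cfg$max_slew * cfg$update_period)
  omega <- clamp(omega_prev + step, cfg$speed_min_abs, cfg$speed_max_abs)
  target <- clamp(proposed, cfg$speed_min_abs, cfg$speed_max_abs)
  list(omega_cmd = omega,
       limited = abs(omega - proposed) > 1e-12 || abs(target - proposed) > 1e-12)
}

#' One controller decision step
#'
#' Composes demand response, pulsatility and suction reaction through the
#' supervisor and the rate limiter. The active module is the supervisor's
#' binding module, relabelled RLI when the rate limiter truncated an
#' *increase* (truncated decreases keep the requesting module's label).
#' With an invalid heart rate persisting beyond the estimator timeout the
#' command freezes at its last value under the DR label.
#'
#' @param est `phc_estimator_state` with fresh outputs.
#' @param state `phc_controller_state`. @param cfg config. @param t_now s.
#' @return updated `phc_controller_state`.
#' @export
controller_step <- function(est, state, cfg, t_now) {
  if (!isTRUE(est$hr_valid)) {
    if (is.na(state$hr_invalid_since)) state$hr_invalid_since <- t_now
    if (t_now - state$hr_invalid_since >
        cfg$estimator$hr_invalid_after_s) {
      state$frozen <- TRUE
      state$active_module <- "DR"
      return(state)
    }
  } else {
    state$hr_invalid_since <- NA_real_
    state$frozen <- FALSE
  }
  dr <- dr_limit(if (isTRUE(est$hr_valid)) est$hr else NA_real_, cfg, state)
  state$last_dr_limit <- dr
  ps <- ps_command(est$pulsatility, cfg, state$omega_cmd, dr)
  state <- su_command(isTRUE(est$new_suction), t_now, state, cfg)
  arb <- supervise(ps, dr, state$omega_su_cap)
  rl <- rate_limit(state$omega_cmd, arb$proposed, cfg)
  increase <- rl$omega_cmd > state$omega_cmd
  state$active_module <- if (rl$limited && increase) "RLI" else arb$module
  state$omega_cmd <- rl$omega_cmd
  state
}

#' Module activation shares over an interval
#'
#' Fraction of controller steps spent with each module binding; shares sum
#' to 100.
#'
#' @param modules character vector of per-step active-module labels
#'   (`DR`, `PS`, `SU`, `RLI`).
#' @return named numeric vector of percentages over all four modules.
#' @export
activation_share <- function(modules) {
  if (!length(modules)) phc_validation_error("empty interval")
  lv <- c("DR", "PS", "SU", "RLI")
  100 * table(factor(modules, levels = lv)) / length(modules)
}
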