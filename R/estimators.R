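# Physiological indices derived from 50 Hz pump signals: sensorless flow
# from motor current, cardiac cycle detection on the flow waveform, heart
# rate with pathologic-jump gating, flow pulsatility, suction events and
# an aortic-valve-opening surrogate. All rolling statistics are causal
# (trailing windows) so every estimator is implementable online.

#' Estimator configuration
#'
#' Free parameters of the signal-derived indices. Defaults: peak
#' prominence 0.5 L/min and refractory period 0.25 s for cycle detection;
#' a new beat whose instantaneous rate deviates from the smoothed heart
#' rate by more than the pathologic-jump fraction 0.25 is ignored; suction
#' flags require the beat minimum to undershoot the rolling median of beat
#' minima by `k_su = 3` rolling IQRs *and* a down-slope steeper than
#' `slope_su` times the rolling median down-slope; a beat counts as
#' aortic-valve-open when more than `plateau_frac = 0.15` of its samples
#' sit within 10 % of the beat maximum.
#'
#' @param prominence L/min, peak prominence for cycle detection.
#' @param refractory_s s, minimum spacing of beat onsets.
#' @param pathologic_jump fractional HR jump treated as pathologic.
#' @param max_hr_slew bpm per update, smoothing slew of the HR output.
#' @param hr_window_s s, trailing window for the HR median.
#' @param hr_invalid_after_s s without valid beats before HR is flagged
#'   invalid.
#' @param k_su,slope_su suction rule thresholds (see above). The steepest
#'   per-beat down-slope of clean beats is dominated by the normal
#'   systolic decay and tightly distributed, while the onset beat of a
#'   suction dip runs 1.2-1.9 times the rolling median, hence the 1.1
#'   default for the multiplier.
#' @param su_window_s s, trailing window of the suction rolling statistics.
#' @param su_merge_s s, flagged beats closer than this merge to one event.
#' @param plateau_frac aortic-valve plateau fraction threshold.
#' @param puls_window_s s, default pulsatility window.
#' @return list of class `phc_est_config`.
#' @export
est_config <- function(prominence = 0.5, refractory_s = 0.25,
                       pathologic_jump = 0.25, max_hr_slew = 3,
                       hr_window_s = 10, hr_invalid_after_s = 15,
                       k_su = 3.0, slope_su = 1.1, su_window_s = 30,
                       su_merge_s = 2, plateau_frac = 0.15,
                       puls_window_s = 10) {
  structure(as.list(environment()), class = "phc_est_config")
}

#' Sensorless flow estimate from motor current
#'
#' Inverts the quadratic motor map `I = vs * (c0 + c1 Q + c2 Q^2) * omega`
#' for `Q`, taking the branch on which the map is strictly increasing, so
#' `estimate_flow(motor_current(Q, w), w) == Q` over the calibrated domain
#' (speed 1800--4000 rpm, flow 0--10 L/min). Currents below the map's
#' invertible branch clamp to the branch minimum and are flagged.
#'
#' @param current motor current, A. @param speed pump speed, rpm (> 0).
#' @param pump `phc_pump_params`.
#' @param viscosity_scale multiplicative map scale.
#' @return flow in L/min with logical attribute `clamped`.
#' @export
estimate_flow <- function(current, speed, pump = pump_params(),
                          viscosity_scale = 1) {
  if (any(speed <= 0)) phc_validation_error("speed must be > 0")
  n <- max(length(current), length(speed))
  current <- rep_len(current, n); speed <- rep_len(speed, n)
  a <- pump$c2; b <- pump$c1
  cc <- pump$c0 - current / (viscosity_scale * speed)
  disc <- b^2 - 4 * a * cc
  cl <- disc < 0
  disc[cl] <- 0
  # increasing branch: root with map derivative c1 + 2 c2 Q > 0
  q <- (-b + sqrt(disc)) / (2 * a)
  q[cl] <- -b / (2 * a)
  structure(q, clamped = cl)
}

# Local-maxima peak finder with prominence filtering and a minimum
# distance (refractory) constraint; taller peaks win ties.
find_peaks <- function(x, prominence, min_dist) {
  n <- length(x)
  if (n < 3) return(integer())
  cand <- which(diff(sign(diff(x))) < 0) + 1L
  if (!length(cand)) return(integer())
  prom <- vapply(cand, function(i) {
    lo_l <- x[i]; j <- i
    while (j > 1 && x[j - 1] <= x[i]) { j <- j - 1; lo_l <- min(lo_l, x[j]) }
    lo_r <- x[i]; j <- i
    while (j < n && x[j + 1] <= x[i]) { j <- j + 1; lo_r <- min(lo_r, x[j]) }
    x[i] - max(lo_l, lo_r)
  }, numeric(1))
  cand <- cand[prom >= prominence]
  if (length(cand) < 2) return(cand)
  keep <- logical(length(cand))
  for (o in order(x[cand], decreasing = TRUE)) {
    if (!any(keep & abs(cand - cand[o]) < min_dist)) keep[o] <- TRUE
  }
  sort(cand[keep])
}

#' Detect cardiac cycles on a flow waveform
#'
#' Beats are delimited at systolic flow peaks found with a prominence
#' threshold and a refractory period; each beat is the half-open sample
#' range between consecutive peaks (0-based indices). Beats with intervals
#' outside [0.25, 2] s are rejected. A flat signal (peak-to-peak below
#' 0.1 L/min) yields zero beats.
#'
#' @param flow flow series, L/min. @param fs sampling rate, Hz.
#' @param config `phc_est_config`.
#' @return data.frame with `i_start`, `i_end` (0-based, half-open), `rr`
#'   (s), `q_min`, `q_max` (L/min), `suction` (filled by
#'   [detect_suction()]), `aov_open`.
#' @export
detect_cycles <- function(flow, fs = 50, config = est_config()) {
  empty <- data.frame(i_start = integer(), i_end = integer(), rr = numeric(),
                      q_min = numeric(), q_max = numeric(),
                      suction = logical(), aov_open = logical())
  if (length(flow) < 3 * fs)
    phc_validation_error("detect_cycles needs at least 3 s of signal")
  if (diff(range(flow)) < 0.1) return(empty)
  pk <- find_peaks(flow, config$prominence, config$refractory_s * fs)
  if (length(pk) < 2) return(empty)
  # parabolic sub-sample interpolation of peak times: at 50 Hz the raw
  # inter-peak interval is quantized to 20 ms (about 3 bpm at 140 bpm)
  tp <- pk + vapply(pk, function(i) {
    if (i <= 1 || i >= length(flow)) return(0)
    den <- flow[i - 1] - 2 * flow[i] + flow[i + 1]
    if (den >= 0) return(0)
    clamp(0.5 * (flow[i - 1] - flow[i + 1]) / den, -0.5, 0.5)
  }, numeric(1))
  i_start <- pk[-length(pk)]; i_end <- pk[-1]
  rr <- diff(tp) / fs
  ok <- rr >= 0.25 & rr <= 2.0
  i_start <- i_start[ok]; i_end <- i_end[ok]; rr <- rr[ok]
  if (!length(i_start)) return(empty)
  q_min <- q_max <- numeric(length(i_start))
  aov <- logical(length(i_start))
  for (b in seq_along(i_start)) {
    seg <- flow[i_start[b]:(i_end[b] - 1L)]
    q_min[b] <- min(seg); q_max[b] <- max(seg)
    aov[b] <- plateau_fraction(seg) > config$plateau_frac
  }
  data.frame(i_start = i_start - 1L, i_end = i_end - 1L, rr = rr,
             q_min = q_min, q_max = q_max, suction = FALSE, aov_open = aov)
}

# Systolic plateau fraction of one beat. A 3-sample moving average runs
# first: current-noise spikes otherwise both inflate the reference
# maximum and scatter samples across the 10 % band, washing out the
# open/closed separation.
plateau_fraction <- function(seg) {
  n <- length(seg)
  if (n >= 3) seg <- c(seg[1], (seg[1:(n - 2)] + seg[2:(n - 1)] +
                                seg[3:n]) / 3, seg[n])
  hi <- max(seg); lo <- min(seg)
  if (hi - lo <= 0) return(1)
  mean(seg >= hi - 0.10 * (hi - lo))
}

#' Aortic-valve-opening surrogate for one beat
#'
#' A beat is scored as valve-open when its systolic flow plateau fraction
#' (samples within 10 % of the beat maximum) exceeds the configured
#' threshold: ejection through the aortic valve clamps ventricular
#' pressure near arterial pressure and flattens the pump-flow peak,
#' whereas a closed valve gives a sharp, narrow peak. The surrogate is
#' validated against simulator ground truth only.
#'
#' @param beat one row of [detect_cycles()] output.
#' @param flow the full flow series the beat indexes into (0-based
#'   indices), L/min.
#' @param config `phc_est_config`.
#' @return logical.
#' @export
detect_aov_opening <- function(beat, flow, config = est_config()) {
  if (beat$i_end - beat$i_start < 10)
    phc_validation_error("beat must span at least 10 samples")
  seg <- flow[(beat$i_start + 1L):beat$i_end]
  plateau_fraction(seg) > config$plateau_frac
}

#' Heart rate from detected beats with pathologic-jump gating
#'
#' The raw rate is `60 / median(rr)` over the trailing window. Beats whose
#' instantaneous rate deviates from the current smoothed rate by more than
#' the pathologic-jump fraction are excluded from the median (sudden
#' changes are treated as pathologic and ignored; gradual changes are
#' followed). The output slews at most `max_hr_slew` bpm per update. With
#' no valid beats for longer than the invalidation timeout the estimate is
#' flagged invalid.
#'
#' @param beats [detect_cycles()] output with a `t_peak` column (s) or
#'   `i_start` interpreted at `fs`. @param state `phc_estimator_state`.
#' @param config `phc_est_config`. @param t_now current time, s.
#' @param fs sampling rate used to place beats in time, Hz.
#' @return updated `phc_estimator_state` (fields `hr`, `hr_valid`).
#' @export
estimate_hr <- function(beats, state, config = est_config(), t_now = NULL,
                        fs = 50) {
  t_beat <- beat_times(beats, fs)
  if (is.null(t_now)) t_now <- if (length(t_beat)) max(t_beat) else 0
  recent <- beats[t_beat > t_now - config$hr_window_s, , drop = FALSE]
  if (nrow(recent)) {
    rate <- 60 / recent$rr
    if (is.finite(state$hr)) {
      ok <- abs(rate - state$hr) <= config$pathologic_jump * state$hr
      if (any(ok)) recent <- recent[ok, , drop = FALSE]
    }
    state$t_last_beat <- max(t_beat)
    hr_raw <- 60 / median(recent$rr)
    if (!is.finite(state$hr)) state$hr <- hr_raw
    else state$hr <- state$hr + clamp(hr_raw - state$hr,
                                      -config$max_hr_slew, config$max_hr_slew)
    state$hr_valid <- state$hr >= 20 && state$hr <= 250
  } else if (!is.finite(state$t_last_beat) ||
             t_now - state$t_last_beat > config$hr_invalid_after_s) {
    state$hr_valid <- FALSE
  }
  if (is.finite(state$t_last_beat) &&
      t_now - state$t_last_beat > config$hr_invalid_after_s)
    state$hr_valid <- FALSE
  state
}

beat_times <- function(beats, fs, t0 = 0) t0 + beats$i_start / fs

#' Fresh estimator state
#' @return list of class `phc_estimator_state` with smoothed `hr` (bpm),
#'   `hr_valid`, `pulsatility` (L/min), last-beat and last-suction
#'   bookkeeping.
#' @export
estimator_state <- function() {
  structure(list(hr = NA_real_, hr_valid = FALSE, t_last_beat = NA_real_,
                 pulsatility = 0, new_suction = FALSE,
                 t_last_suction = -Inf, suction_times = numeric()),
            class = "phc_estimator_state")
}

#' Flow pulsatility over a trailing window
#'
#' Median over the window of per-beat peak-to-peak flow (`q_max - q_min`);
#' if no beats are detected the window's overall max minus min is used as
#' a fallback, so a constant signal yields 0.
#'
#' @param flow flow series covering the window, L/min.
#' @param fs sampling rate, Hz. @param window_s window length, s (>= 2).
#' @param config `phc_est_config`.
#' @return pulsatility in L/min (>= 0).
#' @export
compute_pulsatility <- function(flow, fs = 50, window_s = 10,
                                config = est_config()) {
  if (window_s < 2) phc_validation_error("window_s must be >= 2 s")
  n <- min(length(flow), round(window_s * fs))
  w <- tail(flow, n)
  if (length(w) < 3 * fs) return(max(w) - min(w))
  beats <- detect_cycles(w, fs, config)
  if (!nrow(beats)) return(max(w) - min(w))
  median(beats$q_max - beats$q_min)
}

# Per-beat steepest down-slope magnitude, L/min per s.
beat_downslope <- function(flow, i_start, i_end, fs) {
  seg <- flow[(i_start + 1L):i_end]
  if (length(seg) < 2) return(0)
  max(0, -min(diff(seg)) * fs)
}

#' Detect suction events on a flow waveform
#'
#' A beat is flagged when (a) its flow minimum undershoots the rolling
#' median of beat minima over the trailing window by more than `k_su`
#' rolling IQRs and (b) its steepest negative flow slope exceeds
#' `slope_su` times the rolling median down-slope. Consecutive flagged
#' beats closer than the merge window collapse into a single suction
#' event. Rolling statistics are causal (trailing) only.
#'
#' @param beats [detect_cycles()] output. @param flow flow series, L/min.
#' @param fs sampling rate, Hz. @param config `phc_est_config`.
#' @param t0 absolute time of sample 0, s.
#' @return numeric vector of event times, s (empty when nothing is found).
#' @export
detect_suction <- function(beats, flow, fs = 50, config = est_config(),
                           t0 = 0) {
  if (!nrow(beats)) return(numeric())
  tb <- beat_times(beats, fs, t0)
  slope <- mapply(beat_downslope, i_start = beats$i_start,
                  i_end = beats$i_end,
                  MoreArgs = list(flow = flow, fs = fs))
  flagged <- logical(nrow(beats))
  for (b in seq_len(nrow(beats))) {
    # rolling stats over *unflagged* beats only, so sustained suction does
    # not drag the reference down and mask its own continuation
    w <- which(tb >= tb[b] - config$su_window_s & tb <= tb[b] & !flagged)
    if (length(w) < 5) next
    med <- median(beats$q_min[w])
    iqr <- diff(quantile(beats$q_min[w], c(0.25, 0.75), names = FALSE))
    med_slope <- median(slope[w])
    flagged[b] <- beats$q_min[b] < med - config$k_su * iqr &&
      slope[b] > config$slope_su * med_slope
  }
  tf <- tb[flagged]
  if (!length(tf)) return(numeric())
  ev <- tf[1]
  for (t in tf[-1]) if (t - tail(ev, 1) >= config$su_merge_s) ev <- c(ev, t)
  ev
}

# Whole-log convenience wrapper: cycles + suction in one pass.
detect_suction_log <- function(t, flow, fs = 50, config = est_config()) {
  if (length(flow) < 3 * fs) return(numeric())
  beats <- detect_cycles(flow, fs, config)
  detect_suction(beats, flow, fs, config, t0 = t[1])
}

#' One online estimator update over a trailing signal buffer
#'
#' Runs cycle detection, HR estimation, pulsatility and suction detection
#' over the trailing buffer and updates the estimator state; used in the
#' simulator's control loop once per controller update period.
#'
#' @param t,flow trailing buffer (time s, estimated flow L/min).
#' @param fs sampling rate, Hz. @param state `phc_estimator_state`.
#' @param config `phc_est_config`. @param t_now current time, s.
#' @return updated `phc_estimator_state`; `new_suction` is `TRUE` iff a
#'   suction event newer than the last processed one appeared.
#' @export
estimator_step <- function(t, flow, fs, state, config = est_config(),
                           t_now = max(t)) {
  beats <- detect_cycles(flow, fs, config)
  beats_t <- beats
  if (nrow(beats_t)) {
    state <- estimate_hr_abs(beats_t, state, config, t_now, fs, t0 = t[1])
  } else {
    state <- estimate_hr(beats, state, config, t_now, fs)
  }
  state$pulsatility <- compute_pulsatility(flow, fs, config$puls_window_s,
                                           config)
  ev <- detect_suction(beats, flow, fs, config, t0 = t[1])
  new <- ev[ev > state$t_last_suction + 1e-9]
  state$new_suction <- length(new) > 0
  if (length(new)) state$t_last_suction <- max(new)
  state$suction_times <- ev
  state
}

# estimate_hr with beats indexed relative to an absolute buffer start
estimate_hr_abs <- function(beats, state, config, t_now, fs, t0) {
  b <- beats
  b$i_start <- b$i_start + round(t0 * fs)
  estimate_hr(b, state, config, t_now, fs)
}
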