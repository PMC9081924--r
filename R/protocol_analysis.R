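# Phase segmentation of the three protocol items (orthostatic transition,
# Valsalva maneuver, ramped ergometry), per-phase outcome statistics and
# constant-speed vs physiological-control crossover comparison.
#
# All intervals are half-open [start, end); events on a boundary belong to
# the later phase. IQRs are 25th/75th percentiles with linear
# interpolation (quantile type 7).

new_segmentation <- function(protocol, label, t_start, t_end) {
  seg <- data.frame(label = label, t_start = t_start, t_end = t_end)
  structure(seg, protocol = protocol, class = c("phc_segmentation",
                                                "data.frame"))
}

check_coverage <- function(log, lo, hi) {
  if (is.null(log)) return(invisible())
  span <- range(log$frames$t)
  if (span[1] > lo + 1e-9 || span[2] < hi - 1e-9)
    phc_validation_error("log covers [%.1f, %.1f] s but [%.1f, %.1f] s is required",
                         span[1], span[2], lo, hi)
}

#' Segment an orthostatic transition
#'
#' Steady state is the window 5–10 s before transition initiation
#' (`[t-10, t-5]`), the initial phase the first 15 s after initiation and
#' the late phase 15–60 s after initiation.
#'
#' @param t_transition s, transition initiation time.
#' @param log optional `phc_signal_log`; when given, coverage of
#'   `[t-10, t+60]` is enforced.
#' @return `phc_segmentation` with labels SS, IP, LP.
#' @export
segment_orthostatic <- function(t_transition, log = NULL) {
  check_coverage(log, t_transition - 10, t_transition + 60)
  new_segmentation("orthostatic", c("SS", "IP", "LP"),
                   c(t_transition - 10, t_transition, t_transition + 15),
                   c(t_transition - 5, t_transition + 15, t_transition + 60))
}

#' Segment a Valsalva maneuver
#'
#' Steady state is the 5 s before strain onset, the straining phase runs
#' from onset to release, and the recovery phase is the first 30 s after
#' release. Strains longer than 15 s draw a warning.
#'
#' @param t_on,t_off s, strain onset and release (`t_off > t_on`).
#' @param log optional `phc_signal_log` for coverage checking.
#' @return `phc_segmentation` with labels SS, SP, RP.
#' @export
segment_valsalva <- function(t_on, t_off, log = NULL) {
  if (t_off <= t_on)
    phc_validation_error("t_off (%g) must exceed t_on (%g)", t_off, t_on)
  if (t_off - t_on > 15)
    warning("strain longer than 15 s", call. = FALSE)
  check_coverage(log, t_on - 5, t_off + 30)
  new_segmentation("valsalva", c("SS", "SP", "RP"),
                   c(t_on - 5, t_on, t_off), c(t_on, t_off, t_off + 30))
}

#' Segment a ramped ergometry bout
#'
#' Warmup is the first 10 % of the bout, the early phase 10–60 %, the late
#' phase 60–100 %, and cooldown is the fixed 60 s after the bout ends.
#'
#' @param t_start,t_end s, bout start and end (`t_end > t_start`).
#' @param log optional `phc_signal_log` for coverage checking.
#' @return `phc_segmentation` with labels WU, EP, LP, CD.
#' @export
segment_ergometry <- function(t_start, t_end, log = NULL) {
  if (t_end <= t_start)
    phc_validation_error("t_end (%g) must exceed t_start (%g)", t_end, t_start)
  check_coverage(log, t_start, t_end + 60)
  d <- t_end - t_start
  new_segmentation("ergometry", c("WU", "EP", "LP", "CD"),
                   t_start + c(0, 0.1, 0.6, 1) * d,
                   c(t_start + c(0.1, 0.6, 1) * d, t_end + 60))
}

#' Suction burden of an interval
#'
#' Events with timestamps in the half-open interval, per minute.
#'
#' @param events numeric event times, s.
#' @param interval numeric `c(start, end)`, s, `end > start`.
#' @return suction events per minute.
#' @export
suction_burden <- function(events, interval) {
  if (diff(interval) <= 0) phc_validation_error("interval length must be > 0")
  sum(events >= interval[1] & events < interval[2]) / (diff(interval) / 60)
}

#' Per-phase summary statistics of a run
#'
#' Median and IQR of speed and flow over the 50 Hz samples of each phase,
#' suction burden in events/min, and module activation shares over the
#' controller steps within the phase. An empty phase is reported as
#' missing (`NA`), not zero.
#'
#' @param log `phc_signal_log`; suction events are taken from its
#'   `suction_event` annotations unless `events` is given.
#' @param segmentation `phc_segmentation`.
#' @param modules optional data.frame (`t`, `module`) of controller-step
#'   labels; defaults to the log's `module` annotations.
#' @param events optional numeric suction-event times, s.
#' @return data.frame of class `phc_phase_summary`, one row per phase.
#' @export
summarize_phase <- function(log, segmentation, modules = NULL,
                            events = NULL) {
  ann <- log$annotations
  if (is.null(events))
    events <- ann$t_start[ann$kind == "suction_event"]
  if (is.null(modules) && nrow(ann))
    modules <- data.frame(t = ann$t_start[ann$kind == "module"],
                          module = ann$payload[ann$kind == "module"])
  fr <- log$frames
  out <- lapply(seq_len(nrow(segmentation)), function(i) {
    a <- segmentation$t_start[i]; b <- segmentation$t_end[i]
    sel <- fr$t >= a & fr$t < b
    if (!any(sel))
      return(data.frame(label = segmentation$label[i], missing = TRUE,
                        speed_med = NA_real_, speed_q1 = NA_real_,
                        speed_q3 = NA_real_, flow_med = NA_real_,
                        flow_q1 = NA_real_, flow_q3 = NA_real_,
                        se_per_min = NA_real_, share_DR = NA_real_,
                        share_PS = NA_real_, share_SU = NA_real_,
                        share_RLI = NA_real_))
    qs <- function(x) quantile(x, c(0.5, 0.25, 0.75), names = FALSE)
    sp <- qs(fr$speed[sel]); fl <- qs(fr$flow[sel])
    sh <- rep(NA_real_, 4)
    if (!is.null(modules)) {
      m <- modules$module[modules$t >= a & modules$t < b]
      if (length(m)) sh <- as.numeric(activation_share(m))
    }
    data.frame(label = segmentation$label[i], missing = FALSE,
               speed_med = sp[1], speed_q1 = sp[2], speed_q3 = sp[3],
               flow_med = fl[1], flow_q1 = fl[2], flow_q3 = fl[3],
               se_per_min = suction_burden(events, c(a, b)),
               share_DR = sh[1], share_PS = sh[2], share_SU = sh[3],
               share_RLI = sh[4])
  })
  out <- do.call(rbind, out)
  structure(out, protocol = attr(segmentation, "protocol"),
            class = c("phc_phase_summary", "data.frame"))
}

#' Crossover comparison of constant-speed vs physiological-control runs
#'
#' Per-phase PhC minus CS differences of median speed, median flow and
#' suction burden; across repetitions the median and IQR of the
#' differences are reported (protocol items are repeated and averaged).
#'
#' @param cs_summaries,phc_summaries a `phc_phase_summary` or a list of
#'   them (one per repetition), with matching phase labels.
#' @return data.frame of class `phc_mode_comparison` with fixed column
#'   order (`label`, `d_speed_med`, `d_speed_q1`, `d_speed_q3`,
#'   `d_flow_med`, ..., `d_se_min_med`, ...).
#' @export
compare_modes <- function(cs_summaries, phc_summaries) {
  as_list <- function(x) if (inherits(x, "phc_phase_summary")) list(x) else x
  cs <- as_list(cs_summaries); phc <- as_list(phc_summaries)
  if (length(cs) != length(phc))
    phc_validation_error("unequal repetition counts (%d CS vs %d PhC)",
                         length(cs), length(phc))
  labs <- cs[[1]]$label
  for (x in c(cs, phc)) {
    um <- c(setdiff(x$label, labs), setdiff(labs, x$label))
    if (length(um))
      phc_validation_error("unmatched phase label(s): %s", paste(um, collapse = ", "))
  }
  deltas <- lapply(seq_along(cs), function(r) {
    a <- cs[[r]][match(labs, cs[[r]]$label), ]
    b <- phc[[r]][match(labs, phc[[r]]$label), ]
    ok <- !a$missing & !b$missing
    data.frame(label = labs, ok = ok,
               d_speed = b$speed_med - a$speed_med,
               d_flow = b$flow_med - a$flow_med,
               d_se = b$se_per_min - a$se_per_min)
  })
  out <- lapply(labs, function(l) {
    rows <- do.call(rbind, lapply(deltas, function(d) d[d$label == l & d$ok, ]))
    if (is.null(rows) || !nrow(rows))
      return(NULL)  # phase absent in one of the modes: dropped
    qs <- function(x) quantile(x, c(0.5, 0.25, 0.75), names = FALSE)
    s <- qs(rows$d_speed); f <- qs(rows$d_flow); e <- qs(rows$d_se)
    data.frame(label = l, d_speed_med = s[1], d_speed_q1 = s[2],
               d_speed_q3 = s[3], d_flow_med = f[1], d_flow_q1 = f[2],
               d_flow_q3 = f[3], d_se_min_med = e[1], d_se_min_q1 = e[2],
               d_se_min_q3 = e[3])
  })
  structure(do.call(rbind, out),
            class = c("phc_mode_comparison", "data.frame"))
}
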