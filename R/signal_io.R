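# Pump-signal log container and file formats.
#
# Logfile dialect: plain CSV, header row, '.' decimal separator, UTF-8,
# fixed column order (t, speed, current, power, flow), with metadata in
# leading '#key=value' comment lines. Annotations (scenario events,
# suction events, controller module labels) live in a sidecar CSV
# '<path minus .csv>.events.csv' with columns t_start, t_end, kind,
# payload. Time is seconds from record start at exactly 50 Hz.

LOG_COLUMNS <- c("t", "speed", "current", "power", "flow")
FS_NOMINAL <- 50

#' Construct a pump-signal log
#'
#' @param frames data.frame with columns `t` (s from record start,
#'   strictly increasing at 50 Hz), `speed` (rpm, >= 0), `current` (A),
#'   `power` (W), `flow` (estimated flow, L/min; may be negative but must
#'   be finite).
#' @param annotations optional data.frame (`t_start`, `t_end`, `kind`,
#'   `payload`) of event markers within the log's time span.
#' @param meta list with `mode` (`"CS"` or `"PhC"`), `set_speed_rpm`,
#'   `seed`.
#' @return object of class `phc_signal_log`.
#' @export
signal_log <- function(frames, annotations = NULL,
                       meta = list(mode = "CS", set_speed_rpm = NA_real_,
                                   seed = NA_integer_)) {
  frames <- as.data.frame(frames)[LOG_COLUMNS]
  n <- nrow(frames)
  if (n == 0) phc_validation_error("a signal log must contain frames")
  for (col in LOG_COLUMNS)
    if (any(!is.finite(frames[[col]])))
      phc_format_error("non-finite value in column '%s' at row %d", col,
                       which(!is.finite(frames[[col]]))[1])
  dts <- diff(frames$t)
  if (any(dts <= 0))
    phc_format_error("time not strictly increasing at row %d",
                     which(dts <= 0)[1] + 1L)
  if (any(abs(dts - 1 / FS_NOMINAL) > 1e-9))
    phc_format_error("sampling interval deviates from 50 Hz at row %d",
                     which(abs(dts - 1 / FS_NOMINAL) > 1e-9)[1] + 1L)
  if (any(frames$speed < 0)) phc_format_error("negative pump speed")
  if (!meta$mode %in% c("CS", "PhC"))
    phc_validation_error("meta$mode must be 'CS' or 'PhC' (got '%s')", meta$mode)
  if (!is.null(annotations) && nrow(annotations)) {
    annotations <- as.data.frame(annotations)[c("t_start", "t_end", "kind",
                                                "payload")]
    lo <- frames$t[1]; hi <- frames$t[n]
    if (any(annotations$t_start < lo - 1e-9 | annotations$t_start > hi + 1e-9))
      phc_validation_error("annotation outside the log time span")
  } else {
    annotations <- data.frame(t_start = numeric(), t_end = numeric(),
                              kind = character(), payload = character())
  }
  structure(list(frames = frames, annotations = annotations, meta = meta),
            class = "phc_signal_log")
}

#' @export
print.phc_signal_log <- function(x, ...) {
  cat(sprintf("<phc_signal_log> %d frames (%.1f s at 50 Hz), mode %s, %d annotations\n",
              nrow(x$frames), nrow(x$frames) / FS_NOMINAL, x$meta$mode,
              nrow(x$annotations)))
  invisible(x)
}

sidecar_path <- function(path) paste0(sub("\\.csv$", "", path), ".events.csv")

#' Write a pump-signal log to CSV
#'
#' Fixed column order, full-precision (round-trip safe) numbers, metadata
#' as leading `#key=value` lines; annotations go to the sidecar
#' `<path>.events.csv`. Bit-stable given identical input.
#'
#' @param log `phc_signal_log` (non-empty). @param path output CSV path.
#' @return invisibly, `path`.
#' @export
write_log <- function(log, path) {
  if (!inherits(log, "phc_signal_log") || nrow(log$frames) == 0)
    phc_validation_error("write_log needs a non-empty signal log")
  dir <- dirname(path)
  if (!dir.exists(dir)) phc_io_error("directory does not exist: %s", dir)
  hdr <- c(sprintf("#mode=%s", log$meta$mode),
           sprintf("#set_speed_rpm=%s", format(log$meta$set_speed_rpm)),
           sprintf("#seed=%s", format(log$meta$seed)))
  ok <- tryCatch({
    writeLines(hdr, path)
    data.table::fwrite(log$frames, path, append = TRUE, col.names = TRUE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) phc_io_error("cannot write log to %s", path)
  if (nrow(log$annotations))
    data.table::fwrite(log$annotations, sidecar_path(path))
  invisible(path)
}

#' Read a pump-signal log from CSV
#'
#' Validates the documented column set, strictly increasing time, the
#' 50 Hz sampling interval and value finiteness; loads the annotation
#' sidecar when present.
#'
#' @param path CSV path written by [write_log()].
#' @return `phc_signal_log`.
#' @export
read_log <- function(path) {
  if (!file.exists(path)) phc_io_error("no such file: %s", path)
  lines <- readLines(path, n = 10)
  metal <- lines[startsWith(lines, "#")]
  meta <- list(mode = "CS", set_speed_rpm = NA_real_, seed = NA_integer_)
  for (l in metal) {
    kv <- strsplit(sub("^#", "", l), "=", fixed = TRUE)[[1]]
    if (length(kv) == 2)
      meta[[kv[1]]] <- if (kv[1] == "mode") kv[2] else
        suppressWarnings(as.numeric(kv[2]))
  }
  frames <- as.data.frame(data.table::fread(path, skip = length(metal)))
  miss <- setdiff(LOG_COLUMNS, names(frames))
  if (length(miss))
    phc_format_error("missing column(s): %s", paste(miss, collapse = ", "))
  ann <- NULL
  sp <- sidecar_path(path)
  if (file.exists(sp)) ann <- as.data.frame(data.table::fread(sp))
  signal_log(frames, annotations = ann, meta = meta)
}

# ---------------------------------------------------------------------------
# Configuration files (JSON, one file per concern, units in field names)

#' Read a controller configuration file
#'
#' JSON object whose fields mirror [controller_config()] (with an optional
#' `estimator` sub-object mirroring [est_config()]). Omitted optional
#' fields are filled with the defaults (absolute speed limits default to
#' 2400 / 3200 rpm) and the filled values are echoed.
#'
#' @param path JSON file. @param quiet suppress the echo.
#' @return `phc_controller_config`.
#' @export
read_controller_config <- function(path, quiet = FALSE) {
  x <- read_json_config(path)
  ecfg <- do.call(est_config, as_arglist(x$estimator, est_config))
  x$estimator <- NULL
  cfg <- do.call(controller_config,
                 c(as_arglist(x, controller_config), list(estimator = ecfg)))
  if (!quiet)
    message("controller config: ",
            paste(sprintf("%s=%g", c("speed_min_abs", "speed_max_abs"),
                          c(cfg$speed_min_abs, cfg$speed_max_abs)),
                  collapse = ", "))
  cfg
}

#' Read a virtual-patient parameter file
#' @param path JSON file; fields as in [patient_preset()], or a single
#'   `preset` name plus overrides.
#' @return `phc_patient`.
#' @export
read_patient <- function(path) {
  x <- read_json_config(path)
  preset <- x$preset %||% "default"
  x$preset <- NULL
  do.call(patient_preset, c(list(preset = preset), x))
}

#' Read a scenario script file
#' @param path JSON file with an `events` array of `(t, kind, magnitude)`
#'   objects (`magnitude` optional).
#' @return `phc_scenario`.
#' @export
read_scenario <- function(path) {
  x <- read_json_config(path)
  ev <- x$events
  if (is.null(ev) || (is.data.frame(ev) && !nrow(ev)))
    return(scenario_script())
  ev <- as.data.frame(ev)
  if (!"magnitude" %in% names(ev)) ev$magnitude <- NA_real_
  scenario_script(ev[c("t", "kind", "magnitude")])
}

read_json_config <- function(path) {
  if (!file.exists(path)) phc_io_error("no such file: %s", path)
  tryCatch(jsonlite::fromJSON(path),
           error = function(e) phc_format_error("cannot parse %s: %s", path,
                                                conditionMessage(e)))
}

as_arglist <- function(x, fn) {
  if (is.null(x)) return(list())
  x <- as.list(x)
  bad <- setdiff(names(x), names(formals(fn)))
  if (length(bad))
    phc_validation_error("unknown config field(s): %s", paste(bad, collapse = ", "))
  x
}

#' Load controller, patient and scenario configuration files together
#'
#' @param controller,patient,scenario JSON file paths; `NULL` picks the
#'   package defaults.
#' @return list `(controller, patient, scenario)`, fully validated.
#' @export
load_configs <- function(controller = NULL, patient = NULL, scenario = NULL) {
  list(
    controller = if (is.null(controller))
      design_setpoints(2682, rest_hr = 76, usual_pulsatility = 3.5)
      else read_controller_config(controller),
    patient = if (is.null(patient)) patient_preset() else read_patient(patient),
    scenario = if (is.null(scenario)) scenario_script()
      else read_scenario(scenario))
}
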