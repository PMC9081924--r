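# Shared simulation fixtures, built once per test run and cached.
.run_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .run_cache)) assign(key, expr, envir = .run_cache)
  get(key, envir = .run_cache)
}

rest_cs <- function() cached("rest_cs", simulate(
  run_config(duration_s = 80, seed = 1, mode = "CS", set_speed_rpm = 2682)))

rest_phc <- function() cached("rest_phc", simulate(
  run_config(duration_s = 90, seed = 2, mode = "PhC", set_speed_rpm = 2682)))

occlusion_scenario <- function()
  scenario_script(data.frame(t = seq(20, 110, by = 10),
                             kind = "occlusion_pulse", magnitude = NA))

occl_cs <- function() cached("occl_cs", simulate(
  run_config(scenario = occlusion_scenario(), duration_s = 120, seed = 4,
             mode = "CS")))

suction_events_of <- function(res) {
  a <- res$log$annotations
  a$t_start[a$kind == "suction_event"]
}

# a synthetic pulsatile flow wave: baseline + sinusoid, L/min
sine_flow <- function(dur_s, f_hz = 1, amp = 1.75, base = 5, fs = 50) {
  t <- seq(0, dur_s, by = 1 / fs)
  base + amp * sin(2 * pi * f_hz * t)
}
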