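test_that("design_setpoints implements the clinical setpoint rules", {
  cfg <- design_setpoints(2682, rest_hr = 76, usual_pulsatility = 3.5)
  expect_equal(cfg$hr_rest, 76)
  expect_equal(cfg$hr_exercise, 106)       # 30 bpm added for exercise
  expect_equal(cfg$speed_rest, 2482)       # 200 rpm below CS speed
  expect_equal(cfg$speed_exercise, 2882)   # 200 rpm above
  expect_equal(cfg$pulsatility_setpoint, 1.5)

  # floor at 1 L/min
  expect_equal(design_setpoints(2682, rest_hr = 76,
                                usual_pulsatility = 2.5)$pulsatility_setpoint,
               1.0)

  # HR history percentiles
  set.seed(1); hist <- rnorm(5000, 80, 10)
  cfg2 <- design_setpoints(2682, hr_history = hist, usual_pulsatility = 4)
  expect_equal(cfg2$hr_rest, quantile(hist, 0.1, names = FALSE))
  expect_equal(cfg2$hr_exercise, quantile(hist, 0.9, names = FALSE))

  # degenerate span widened to 10 bpm with a warning
  expect_warning(cfg3 <- design_setpoints(2682, hr_history = rep(80, 100),
                                          usual_pulsatility = 4),
                 "widened")
  expect_equal(cfg3$hr_exercise - cfg3$hr_rest, 10)

  # clamping against the absolute range
  cfg4 <- design_setpoints(3150, rest_hr = 76, usual_pulsatility = 3.5)
  expect_equal(cfg4$speed_exercise, 3200)

  expect_error(design_setpoints(2682, rest_hr = 76, usual_pulsatility = 0),
               "usual_pulsatility")
  expect_error(design_setpoints(2000, rest_hr = 76, usual_pulsatility = 3),
               "outside")
})

cfg <- design_setpoints(2682, rest_hr = 76, usual_pulsatility = 3.5)

test_that("dr_limit is the clamped linear demand-response line", {
  expect_equal(dr_limit(76, cfg), 2482)
  expect_equal(dr_limit(106, cfg), 2882)
  expect_equal(dr_limit(126, cfg), 2882)   # clamp above
  expect_equal(dr_limit(50, cfg), 2482)    # clamp below
  expect_equal(dr_limit(91, cfg), 2682)    # midpoint
  # monotone non-decreasing in HR (property)
  hr <- seq(40, 140, by = 0.5)
  expect_true(all(diff(vapply(hr, dr_limit, numeric(1), cfg = cfg)) >= 0))
  # invalid HR holds the last limit via state
  st <- controller_state(cfg, 2682); st$last_dr_limit <- 2600
  expect_equal(dr_limit(NA, cfg, st), 2600)
})

test_that("ps_command moves proportionally, capped by DR and the floor", {
  expect_equal(ps_command(cfg$pulsatility_setpoint, cfg, 2600, 2882), 2600)
  # 100 rpm request into 60 rpm headroom binds at the DR cap
  expect_equal(ps_command(cfg$pulsatility_setpoint + 2, cfg, 2822, 2882), 2882)
  # decrease clamps at the absolute floor
  expect_equal(ps_command(cfg$pulsatility_setpoint - 1, cfg, 2400, 2882), 2400)
  expect_error(ps_command(-1, cfg, 2600, 2882), "pulsatility")
})

test_that("su_command steps down, holds, and relaxes after clearance", {
  st <- controller_state(cfg, 2700)
  st <- su_command(TRUE, 10, st, cfg)
  expect_equal(st$omega_su_cap, 2650)      # one su_step below the command

  # at the absolute floor the cap does not go lower
  st2 <- controller_state(cfg, 2400)
  st2 <- su_command(TRUE, 10, st2, cfg)
  expect_equal(st2$omega_su_cap, 2400)

  # cap holds during the clearance window, then relaxes to inactive
  st <- su_command(FALSE, 15, st, cfg)
  expect_equal(st$omega_su_cap, 2650)
  t <- 20
  while (st$su_active && t < 100) { st <- su_command(FALSE, t, st, cfg); t <- t + 1 }
  expect_false(st$su_active)
  expect_identical(st$omega_su_cap, Inf)
})

test_that("supervise takes the minimum with SU > DR > PS tie priority", {
  expect_equal(supervise(2800, 2750, Inf), list(proposed = 2750, module = "DR"))
  expect_equal(supervise(2700, 2750, 2650), list(proposed = 2650, module = "SU"))
  expect_equal(supervise(2700, 2700, 2700), list(proposed = 2700, module = "SU"))
  expect_equal(supervise(2700, 2750, Inf), list(proposed = 2700, module = "PS"))
})

test_that("rate_limit enforces relative and absolute bounds", {
  expect_equal(rate_limit(2450, 2000, cfg)$omega_cmd, 2430)  # slew first
  expect_equal(rate_limit(2405, 2000, cfg)$omega_cmd, 2400)  # then floor
  expect_equal(rate_limit(3195, 3500, cfg)$omega_cmd, 3200)  # ceiling
  rl <- rate_limit(2600, 2700, cfg)
  expect_equal(rl$omega_cmd, 2620)
  expect_true(rl$limited)
  rl2 <- rate_limit(2600, 2610, cfg)
  expect_false(rl2$limited)
})

mk_est <- function(hr = 76, puls = 3, suction = FALSE, valid = TRUE) {
  e <- estimator_state()
  e$hr <- hr; e$hr_valid <- valid; e$pulsatility <- puls
  e$new_suction <- suction
  e
}

test_that("controller converges to the DR limit within the analytic bound", {
  st <- controller_state(cfg, 2682)
  bound <- ceiling((cfg$speed_exercise - cfg$speed_rest) /
                   (cfg$max_slew * cfg$update_period)) + 2
  est <- mk_est(hr = 76, puls = 3)   # pulsatility above setpoint, rest HR
  traj <- numeric(0)
  for (k in seq_len(bound + 10)) {
    st <- controller_step(est, st, cfg, k)
    traj <- c(traj, st$omega_cmd)
  }
  expect_equal(traj[bound], dr_limit(76, cfg))
  expect_true(all(traj[bound:length(traj)] == dr_limit(76, cfg)))
  expect_equal(st$active_module, "DR")
})

test_that("HR rise with ample pulsatility reaches exercise speed via RLI transient", {
  st <- controller_state(cfg, 2482)
  est <- mk_est(hr = 110, puls = 4)
  mods <- character(0)
  for (k in 1:30) {
    st <- controller_step(est, st, cfg, k)
    mods <- c(mods, st$active_module)
  }
  expect_equal(st$omega_cmd, cfg$speed_exercise)
  expect_true("RLI" %in% mods[1:20])   # early transient is rate limited
})

test_that("repeated suction events produce a staircase descent by su_step", {
  # keep DR and PS out of the way: exercise-level HR, pulsatility on target
  quiet <- function(suction = FALSE)
    mk_est(hr = 106, puls = cfg$pulsatility_setpoint, suction = suction)
  st <- controller_state(cfg, 2700)
  st$last_dr_limit <- cfg$speed_exercise
  omegas <- numeric(0)
  for (k in 1:4) {
    st <- controller_step(quiet(suction = TRUE), st, cfg, k * 2)
    # let the command settle onto the cap between events
    for (j in 1:3) st <- controller_step(quiet(), st, cfg, k * 2 + j * 0.25)
    omegas <- c(omegas, st$omega_cmd)
  }
  expect_equal(omegas, c(2650, 2600, 2550, 2500))
  expect_true(st$su_active)
})

test_that("invalid HR beyond the timeout freezes the command under DR", {
  # before the timeout the held (conservative) DR limit still applies, so
  # the command settles onto speed_rest and freezes there
  st <- controller_state(cfg, 2600)
  for (k in 1:20) st <- controller_step(mk_est(valid = FALSE), st, cfg, k)
  expect_true(st$frozen)
  expect_equal(st$omega_cmd, cfg$speed_rest)
  expect_equal(st$active_module, "DR")
  # and the frozen command does not move afterwards
  st2 <- controller_step(mk_est(valid = FALSE), st, cfg, 21)
  expect_equal(st2$omega_cmd, st$omega_cmd)
})

test_that("activation shares are percentages summing to 100", {
  expect_equal(as.numeric(activation_share(rep("DR", 7))["DR"]), 100)
  sh <- activation_share(c("DR", "DR", "DR", "SU"))
  expect_equal(as.numeric(sh["DR"]), 75)
  expect_equal(as.numeric(sh["SU"]), 25)
  set.seed(2)
  for (i in 1:20) {
    m <- sample(c("DR", "PS", "SU", "RLI"), sample(1:50, 1), replace = TRUE)
    expect_equal(sum(activation_share(m)), 100, tolerance = 1e-9)
  }
  expect_error(activation_share(character()), "empty")
})

test_that("safety envelope, slew bound and SU dominance hold on random inputs", {
  set.seed(42)
  for (rep in 1:50) {
    st <- controller_state(cfg, runif(1, 2400, 3200))
    prev <- st$omega_cmd
    for (k in 1:60) {
      est <- mk_est(hr = runif(1, 40, 160), puls = runif(1, 0, 8),
                    suction = runif(1) < 0.1, valid = runif(1) > 0.05)
      st <- controller_step(est, st, cfg, k)
      expect_gte(st$omega_cmd, cfg$speed_min_abs)
      expect_lte(st$omega_cmd, cfg$speed_max_abs)
      expect_lte(abs(st$omega_cmd - prev),
                 cfg$max_slew * cfg$update_period + 1e-9)
      # no upward move while the SU cap is strictly binding (the command
      # may sit above a fresh cap while the slew limit walks it down)
      if (st$su_active && st$omega_su_cap < prev)
        expect_lte(st$omega_cmd, prev)
      prev <- st$omega_cmd
    }
  }
})
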