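pat <- patient_preset()
pump <- pump_params()

test_that("elastance spans Emin to effective Emax with Starling modulation", {
  rr <- 0.8
  expect_equal(elastance(0, rr, pat), pat$Emin, tolerance = 1e-9)
  grid <- seq(0, rr - 1e-6, length.out = 2000)
  expect_equal(max(elastance(grid, rr, pat)), pat$Emax, tolerance = 1e-4)
  # Starling: larger end-diastolic volume, stronger contraction
  e_hi <- max(elastance(grid, rr, pat, v_ed = pat$V_ed_ref * 1.2))
  e_lo <- max(elastance(grid, rr, pat, v_ed = pat$V_ed_ref * 0.8))
  expect_gt(e_hi, e_lo)
  # gain switched off: independent of filling
  p0 <- patient_preset(starling_gain = 0)
  expect_equal(elastance(grid, rr, p0, v_ed = 80),
               elastance(grid, rr, p0, v_ed = 180))
  # clamping of the modulation factor
  expect_equal(max(elastance(grid, rr, pat, v_ed = 1e6)), 2 * pat$Emax,
               tolerance = 1e-4)
  expect_error(elastance(rr, rr, pat), "t_in_beat")
})

test_that("pump_flow returns the descending-branch root of the H-Q law", {
  w <- 2682
  # shutoff head gives zero flow
  expect_equal(as.numeric(pump_flow(pump$b0 * w^2, w)), 0, tolerance = 1e-12)
  # algebraic residual of the returned root (property), heads below shutoff
  set.seed(7)
  ws <- runif(50, 1800, 4000)
  dp <- runif(50, 20, 0.98 * pump$b0 * ws^2)
  q <- as.numeric(pump_flow(dp, ws))
  resid <- pump$b0 * ws^2 + pump$b1 * ws * q + pump$b2 * q^2 - dp
  expect_lt(max(abs(resid)), 1e-9)
  # descending branch over the forward-flow domain
  expect_true(all(pump$b1 * ws + 2 * pump$b2 * q < 0))
  # regurgitation above shutoff head
  expect_lt(as.numeric(pump_flow(pump$b0 * w^2 + 20, w)), 0)
  # beyond the calibrated domain the root clamps and flags
  over <- pump_flow(1e5, 2000)
  expect_true(attr(over, "clamped"))
  expect_error(pump_flow(50, 0), "speed")
})

test_that("inflow_resistance implements the smooth partial-occlusion law", {
  p <- patient_preset(k_occ = 0.04)
  expect_equal(inflow_resistance(p$V_suction + 10, p), p$R_in)
  expect_equal(inflow_resistance(p$V_suction - 5, p), 2 * p$R_in)
  v <- seq(120, 5, by = -1)
  expect_true(all(diff(inflow_resistance(v, p)) >= 0))
})

test_that("cv_derivatives conserves volume and respects equilibrium", {
  set.seed(8)
  for (i in 1:25) {
    st <- c(runif(1, 20, 250), runif(1, 40, 120), runif(1, 2, 25))
    pool <- runif(1, -20, 20)
    d <- cv_derivatives(st, runif(1, 0, 0.7), pat, pump,
                        omega = runif(1, 1800, 3600), pth = runif(1, 0, 30),
                        pool_rate = pool)
    vol_rate <- d$d[1] + pat$C_art * d$d[2] + pat$C_ven * d$d[3] + pool
    expect_lt(abs(vol_rate), 1e-9)
  }
  # omega = 0, no gradients, diastole: everything at rest
  p_eq <- 8
  v_eq <- pat$V0 + p_eq / pat$Emin
  d0 <- cv_derivatives(c(v_eq, p_eq, p_eq), 0, pat, pump, omega = 0)
  expect_equal(max(abs(d0$d)), 0, tolerance = 1e-9)
  expect_equal(d0$q_pump, 0, tolerance = 1e-12)
  expect_error(cv_derivatives(c(-5, 80, 10), 0, pat, pump, 2682), "V_lv")
})

test_that("scenario scripts validate structure and apply_scenario is windowed", {
  expect_error(scenario_script(data.frame(t = c(5, 1), kind = "posture_up",
                                          magnitude = NA)), "time-ordered")
  expect_error(scenario_script(data.frame(t = 5, kind = "valsalva_on",
                                          magnitude = NA)), "pairs")
  expect_error(scenario_script(data.frame(t = 1, kind = "warp",
                                          magnitude = NA)), "unknown")
  expect_warning(scenario_script(data.frame(
    t = c(5, 25), kind = c("valsalva_on", "valsalva_off"),
    magnitude = NA)), "15 s")
  expect_error(scenario_script(data.frame(
    t = c(0, 10), kind = "exercise_ramp", magnitude = 300)), "overlapping")

  # no events: parameters unchanged at any time
  sc0 <- scenario_script()
  p_t <- apply_scenario(pat, 37, sc0)
  expect_equal(p_t$HR0, pat$HR0)
  expect_equal(p_t$P_th, 0)

  # Valsalva pressure elevated exactly on [10, 22)
  scv <- scenario_script(data.frame(t = c(10, 22),
                                    kind = c("valsalva_on", "valsalva_off"),
                                    magnitude = c(30, NA)))
  expect_equal(apply_scenario(pat, 9.99, scv)$P_th, 0)
  expect_equal(apply_scenario(pat, 10, scv)$P_th, 30)
  expect_equal(apply_scenario(pat, 21.99, scv)$P_th, 30)
  expect_equal(apply_scenario(pat, 22, scv)$P_th, 0)

  # posture up then down restores the baseline after the transients
  scp <- scenario_script(data.frame(t = c(20, 60),
                                    kind = c("posture_up", "posture_down"),
                                    magnitude = NA))
  after <- apply_scenario(pat, 80, scp)
  expect_equal(after$HR0, pat$HR0, tolerance = 1e-9)
  expect_equal(after$pool_volume_ml, 0, tolerance = 1e-9)
  mid <- apply_scenario(pat, 40, scp)
  expect_equal(mid$pool_volume_ml, 300)
})

test_that("simulate hits the reported clinical rest operating point in CS mode", {
  res <- rest_cs()
  fr <- res$log$frames; tr <- res$truth
  sel <- fr$t >= 20
  expect_equal(mean(fr$flow[sel]), 4.9, tolerance = 0.4 / 4.9)  # reported clinical dispersion
  expect_equal(mean(tr$p_art[sel]), 79, tolerance = 10 / 79)
  expect_equal(compute_pulsatility(fr$flow[sel], 50, 60), 3.5,
               tolerance = 0.6 / 3.5)
  # logfile contract
  expect_true(all(abs(diff(fr$t) - 0.02) < 1e-9))
})

test_that("identical seed and configuration give bit-identical output", {
  run <- run_config(duration_s = 20, seed = 77, mode = "PhC")
  a <- simulate(run); b <- simulate(run)
  expect_identical(a$log$frames, b$log$frames)
  expect_identical(a$truth, b$truth)
  expect_identical(a$trace, b$trace)
  c_ <- simulate(run_config(duration_s = 20, seed = 78, mode = "PhC"))
  expect_false(identical(a$log$frames, c_$log$frames))
})

test_that("blood volume is conserved and the pump rides its H-Q curve", {
  res <- cached("long_cs", simulate(run_config(duration_s = 600, seed = 8)))
  tr <- res$truth
  tv <- tr$v_lv + pat$C_art * tr$p_art + pat$C_ven * tr$p_ven
  expect_lt(max(abs(tv - tv[1])), 1e-6 * tv[1])
  # operating point satisfies the characteristic with cannula losses
  r_in_eff <- inflow_resistance(tr$v_lv, pat)
  resid <- pump$b0 * 2682^2 + pump$b1 * 2682 * tr$flow_true +
    pump$b2 * tr$flow_true^2 -
    (r_in_eff + pat$R_out) * tr$flow_true - (tr$p_art - tr$p_lv)
  expect_lt(max(abs(resid)), 1e-6)
})

test_that("PhC rest run converges onto the reduced demand-response speed", {
  res <- rest_phc()
  tail_tr <- res$trace[res$trace$t > 60, ]
  expect_equal(median(tail_tr$omega_cmd), 2482, tolerance = 25 / 2482)
  expect_equal(names(which.max(table(tail_tr$active_module))), "DR")
})

test_that("non-physical configurations abort with a diagnostic", {
  # no venous shielding, no occlusion choke: strain collapses the ventricle
  bad <- patient_preset(pth_venous_frac = 0, k_occ = 1e-4, V_suction = 5)
  scv <- scenario_script(data.frame(t = c(10, 25),
                                    kind = c("valsalva_on", "valsalva_off"),
                                    magnitude = c(40, NA)))
  expect_error(
    suppressWarnings(simulate(run_config(patient = bad, scenario = scv,
                                         duration_s = 30, seed = 3))),
    class = "phcvad_simulation_error")
})

test_that("run_config validates inputs", {
  expect_error(run_config(duration_s = 0), "duration")
  expect_error(simulate(list()), "run_config")
})
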