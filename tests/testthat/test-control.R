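test_that("pid_step matches a hand-unrolled discrete PID recursion", {
  g <- pid_gains(kp = 0.5, ki = 0.2, kd = 0.1, anti_windup_limit = 0.5)
  # unit-step error, dt = 1: integral 0.2, 0.4, then clamped at 0.5;
  # derivative fires only at the first step (prev error undefined -> 0)
  expected <- c(0.7, 0.9, 1.0, 1.0, 1.0, 1.0, 1.0, 1.0, 1.0, 1.0)
  st <- pid_state()
  got <- numeric(10)
  for (k in 1:10) {
    r <- pid_step(1, 1, g, st)
    got[k] <- r$adjustment
    st <- r$state
  }
  expect_equal(got, expected, tolerance = 1e-12)
})

test_that("pid_step limits: zero error is a fixed point; P-only is proportional", {
  g <- pid_gains(kp = 0.3)
  expect_equal(pid_step(0, 0.1, g)$adjustment, 0)
  st <- pid_state()
  for (k in 1:5) {
    r <- pid_step(2.5, 1, g, st)
    expect_equal(r$adjustment, 0.3 * 2.5)
    st <- r$state
  }
  # integral clamp engages under sustained large error
  gi <- pid_gains(kp = 0, ki = 1, anti_windup_limit = 0.2)
  st <- pid_state()
  for (k in 1:10) { r <- pid_step(10, 1, gi, st); st <- r$state }
  expect_equal(st$integral, 0.2)
})

test_that("motion laws reproduce the prescribed closure profiles", {
  cor <- motion_law("coronary_piecewise", period = 1, systole_duration = 0.35,
                    baseline_closure = 0.1, peak_closure = 0.8)
  # apex of the systolic half-sine at t = 0.175 s
  expect_equal(motion_profile(0.175, cor), 0.8)
  # diastole: valve at minimal compression
  expect_equal(motion_profile(0.5, cor), 0.1)
  expect_equal(motion_profile(0.99, cor), 0.1)
  sin_law <- motion_law("sinusoidal", period = 1, baseline_closure = 0.2,
                        peak_closure = 0.6)
  t <- c(0.13, 0.51, 0.87)
  expect_equal(motion_profile(t, sin_law), motion_profile(t + 3, sin_law))
  expect_equal(motion_profile(0, sin_law), 0.2)    # cycle starts at minimum
  expect_equal(motion_profile(0.5, sin_law), 0.6)
  expect_error(motion_law("coronary_piecewise", period = 1,
                          systole_duration = 1.2), "systole_duration")
  expect_error(motion_profile(-1, sin_law), "t must")
})

test_that("pre-setting finds closures whose steady pressures meet the targets", {
  m <- compliance_circuit()
  reg <- pressure_regime(80, 120, tolerance = 2)
  pr <- preset_occlusions(m, reg)
  expect_true(pr$converged)
  expect_lt(pr$closure_at_pmin, pr$closure_at_pmax)
  expect_lt(abs(steady_sensor_pressure(m, pr$closure_at_pmin) - 80), 2)
  expect_lt(abs(steady_sensor_pressure(m, pr$closure_at_pmax) - 120), 2)
})

test_that("pre-setting correctness holds across randomized reachable circuits", {
  set.seed(11)
  for (rep in 1:20) {
    m <- random_circuit()
    reg <- pressure_regime(80, 120, tolerance = 2)
    pr <- preset_occlusions(m, reg)
    expect_true(pr$converged)
    expect_lt(abs(steady_sensor_pressure(m, pr$closure_at_pmin) - 80), 2)
    expect_lt(abs(steady_sensor_pressure(m, pr$closure_at_pmax) - 120), 2)
  }
})

test_that("pre-setting reports non-convergence for unreachable targets", {
  m <- compliance_circuit(pump_flow = 0.1)   # max steady pressure ~20 mmHg
  reg <- pressure_regime(5, 40, tolerance = 1)
  pr <- preset_occlusions(m, reg)
  expect_false(pr$converged)
  expect_match(pr$diagnostic, "unreachable")
  expect_error(pressure_regime(120, 80), "p_min_target")
})

test_that("closed-loop extremes meet tolerance for all ISO regimes and the coronary law", {
  for (reg in iso7198_regimes(tolerance = 2)) {
    m <- compliance_circuit()
    run <- run_regulated_stimulation(m, reg, motion_law("sinusoidal"),
                                     n_cycles = 20, seed = 4)
    post <- run$log[(run$settle_cycles + 1):nrow(run$log), ]
    expect_lt(abs(mean(post$p_min_meas) - reg$p_min_target), 2)
    expect_lt(abs(mean(post$p_max_meas) - reg$p_max_target), 2)
  }
  reg <- pressure_regime(80, 120, tolerance = 2)
  run <- run_regulated_stimulation(coronary_circuit(), reg,
                                   motion_law("coronary_piecewise"),
                                   n_cycles = 20, seed = 4)
  post <- run$log[(run$settle_cycles + 1):nrow(run$log), ]
  expect_lt(abs(mean(post$p_min_meas) - 80), 2)
  expect_lt(abs(mean(post$p_max_meas) - 120), 2)
})

test_that("commanded closures never leave [0, 1] and runs are seed-deterministic", {
  m <- coronary_circuit()
  reg <- pressure_regime(80, 120)
  r1 <- run_regulated_stimulation(m, reg, motion_law("coronary_piecewise"),
                                  n_cycles = 12, seed = 9)
  r2 <- run_regulated_stimulation(m, reg, motion_law("coronary_piecewise"),
                                  n_cycles = 12, seed = 9)
  expect_true(all(r1$log$c_lo >= 0 & r1$log$c_lo <= 1))
  expect_true(all(r1$log$c_hi >= 0 & r1$log$c_hi <= 1))
  expect_identical(r1$pressure$samples, r2$pressure$samples)
  expect_identical(r1$flow$samples, r2$flow$samples)
})

test_that("with all gains zero the extremes stay at their open-loop values", {
  m <- compliance_circuit()
  reg <- pressure_regime(80, 120)
  zg <- pid_gains(kp = 0, ki = 0, kd = 0)
  run <- run_regulated_stimulation(m, reg, motion_law("sinusoidal"),
                                   gains_min = zg, gains_max = zg,
                                   n_cycles = 10, seed = 2,
                                   noise_sd_pressure = 0)
  expect_true(all(run$log$c_lo == run$log$c_lo[1]))
  expect_true(all(run$log$c_hi == run$log$c_hi[1]))
})

test_that("zero-noise settling approaches the targets monotonically in error norm", {
  m <- compliance_circuit()
  reg <- pressure_regime(80, 120)
  run <- run_regulated_stimulation(m, reg, motion_law("sinusoidal"),
                                   n_cycles = 12, seed = 1,
                                   noise_sd_pressure = 0)
  err <- abs(run$log$p_max_meas - 120) + abs(run$log$p_min_meas - 80)
  # settled error must be far below the initial error, and small
  expect_lt(err[12], err[1] / 4)
  expect_lt(err[12], 2)
})

test_that("safety interlock decides correctly and aborts a breaching run", {
  lim <- safety_limits(0, 200)
  expect_true(safety_check(100, lim))
  expect_false(safety_check(250, lim))
  expect_error(safety_limits(200, 100), "pressure_min")

  m <- compliance_circuit()
  reg <- pressure_regime(80, 120)
  run <- run_regulated_stimulation(m, reg, motion_law("sinusoidal"),
                                   n_cycles = 10, seed = 3,
                                   limits = safety_limits(0, 110))
  expect_true(run$aborted)
  expect_false(is.na(run$abort_time))
  # trace truncated at the first breaching sample (which is retained)
  n <- length(run$pressure_raw$samples)
  expect_lt(n * 1e-3, 10)
  expect_true(all(run$pressure_raw$samples[-n] <= 110))
  expect_gt(run$pressure_raw$samples[n], 110)
})
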