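test_that("acquisition decimates to the sensor rate and preserves amplitude", {
  src <- sine_pressure(80, 120, duration = 5, rate = 1000)
  acq <- acquire(src, 40)
  expect_equal(length(acq$samples), 5 * 40)
  # 1 Hz sine at 40 Hz: amplitude within 0.5% of the closed form
  expect_equal(max(acq$samples), 120, tolerance = 0.005)
  expect_equal(min(acq$samples), 80, tolerance = 0.005)
  const <- signal_trace(rep(7, 1000), 1000, kind = "flow")
  expect_true(all(acquire(const, 200)$samples == 7))
  expect_error(acquire(acq, 1000), "exceeds")
})

test_that("3-point moving average matches hand arithmetic and the edge rule", {
  tr <- signal_trace(c(0, 3, 0), 10, kind = "pressure")
  f <- moving_average_3(tr)
  expect_equal(f$samples, c(1.5, 1, 1.5))
  const <- signal_trace(rep(5, 100), 10, kind = "pressure")
  expect_equal(moving_average_3(const)$samples, rep(5, 100))
  expect_error(moving_average_3(signal_trace(c(1, 2), 10, kind = "pressure")),
               "at least 3")
})

test_that("3-point filtering reduces white-noise SD by about sqrt(3)", {
  set.seed(42)
  x <- rnorm(20000, sd = 2)
  f <- moving_average_3(signal_trace(x, 100, kind = "pressure"))
  interior <- f$samples[2:(length(x) - 1)]
  expect_equal(stats::sd(interior), 2 / sqrt(3), tolerance = 0.03)
  # mean preserved on stationary input (absolute drift, mean is near 0)
  expect_lt(abs(mean(f$samples) - mean(x)), 1e-3)
})

test_that("cycle detection counts and times clean 1 Hz cycles", {
  tr <- sine_pressure(80, 120, duration = 30, rate = 40)
  bnd <- detect_cycles(tr, 1)
  expect_gte(length(bnd) - 1, 29)
  expect_lte(length(bnd) - 1, 30)
  # period estimate within 1% of ground truth
  expect_equal(mean(diff(bnd)), 1, tolerance = 0.01)
  expect_error(detect_cycles(signal_trace(rep(3, 200), 40, kind = "pressure"), 1),
               "constant|periodicity")
  expect_error(detect_cycles(sine_pressure(80, 120, 1.2, 40), 1), "two nominal")
})

test_that("per-cycle metrics recover exact extremes and internal consistency", {
  p <- sine_pressure(80, 120, duration = 10, rate = 200)
  q <- signal_trace(180 + 60 * sin(2 * pi * seq(0, 10 - 1/200, 1/200)), 200,
                    kind = "flow")
  bnd <- detect_cycles(p, 1)
  cm <- cycle_metrics(p, q, bnd)
  expect_equal(mean(cm$per_cycle$p_min), 80, tolerance = 1e-3)
  expect_equal(mean(cm$per_cycle$p_max), 120, tolerance = 1e-3)
  expect_equal(cm$per_cycle$dp, cm$per_cycle$p_max - cm$per_cycle$p_min)
  expect_equal(cm$per_cycle$dq, cm$per_cycle$q_max - cm$per_cycle$q_min)
  expect_error(cycle_metrics(p, q, c(-5, 1)), "outside")
})

test_that("counter-phase index distinguishes in-phase, anti-phase and diastolic flow", {
  t <- seq(0, 10 - 1/200, 1/200)
  p <- signal_trace(100 - 20 * cos(2 * pi * t), 200, kind = "pressure")
  q_same <- signal_trace(180 - 60 * cos(2 * pi * t), 200, kind = "flow")
  q_anti <- signal_trace(180 + 60 * cos(2 * pi * t), 200, kind = "flow")
  expect_equal(counterphase_index(p, q_same)$lag_s, 0)
  expect_equal(abs(counterphase_index(p, q_anti)$lag_s), 0.5,
               tolerance = 0.02)
  # square-wave flow confined to diastole -> fraction 1
  q_dia <- signal_trace(ifelse(t %% 1 >= 0.35, 300, 0), 200, kind = "flow")
  cp <- counterphase_index(p, q_dia, period = 1, systole_duration = 0.35)
  expect_equal(cp$diastolic_flow_fraction, 1, tolerance = 1e-6)
  expect_error(counterphase_index(p, signal_trace(rep(1, 100), 200, kind = "flow")),
               "mismatched")
})

test_that("Welch's ANOVA: identical groups are null, two groups equal Welch's t", {
  g <- list(a = c(1, 2, 3, 4), b = c(2, 3, 4, 1), c = c(4, 3, 2, 1))
  w <- welch_anova(g)
  expect_equal(w$F, 0)
  expect_equal(w$p, 1)
  set.seed(5)
  x <- rnorm(12, 10, 1); y <- rnorm(15, 10.8, 2.5)
  w2 <- welch_anova(list(x = x, y = y))
  tt <- stats::t.test(x, y)   # Welch two-sample t as the oracle
  expect_equal(w2$p, tt$p.value, tolerance = 1e-12)
  expect_equal(w2$F, unname(tt$statistic)^2, tolerance = 1e-12)
  expect_error(welch_anova(list(a = c(1, 1, 1), b = c(1, 2, 3))), "'a'")
  expect_error(welch_anova(list(a = 1, b = c(1, 2))), "fewer than 2")
})

test_that("trace CSV round-trips through the artifact format", {
  tr <- sine_pressure(80, 120, 2, 40)
  path <- file.path(withr::local_tempdir(), "p.csv")
  write_trace_csv(tr, path, seed = 3, config_hash = "abc")
  back <- read_trace_csv(path)
  expect_equal(back$samples, tr$samples, tolerance = 1e-12)
  expect_equal(back$sampling_rate, 40)
  expect_equal(back$kind, "pressure")
})
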