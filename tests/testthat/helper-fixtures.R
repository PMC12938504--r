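# Shared fixture builders for the suite. Everything is generated in code;
# nothing is read from disk.

# Sinusoidal pressure sweeping [p_min, p_max] at `freq`, starting at the
# minimum (the package's cycle phase convention).
sine_pressure <- function(p_min, p_max, duration, rate, freq = 1) {
  t <- seq(0, duration - 1 / rate, by = 1 / rate)
  mid <- (p_min + p_max) / 2
  amp <- (p_max - p_min) / 2
  signal_trace(mid - amp * cos(2 * pi * freq * t), rate, kind = "pressure")
}

# Compliance fixture: phantom of known compliance c_star imaged under a
# clean sinusoidal normotensive pressurization.
compliance_fixture <- function(c_star, seed, fps = 30, duration = 8,
                               mm_per_pixel = 0.001, noise_sd = 0,
                               jitter_px = 0) {
  ph <- phantom_with_compliance(c_star, p_anchor = 80)
  t <- seq(0, duration - 1 / fps, by = 1 / fps)
  p <- 100 - 20 * cos(2 * pi * t)
  d <- diameter_at_pressure(ph, p)
  stack <- render_frames(d$outer, mm_per_pixel = mm_per_pixel,
                         frame_rate = fps, noise_sd = noise_sd,
                         jitter_px = jitter_px, seed = seed)
  pressure <- sine_pressure(80, 120, duration, rate = 40)
  list(phantom = ph, stack = stack, pressure = pressure,
       regime = pressure_regime(80, 120))
}

# A small randomized but reachable circuit parameterization for property
# tests (seeded by the caller).
random_circuit <- function() {
  compliance_circuit(
    pump_flow = runif(1, 150, 300),
    sample_resistance = runif(1, 0.1, 0.3),
    tubing_compliance = runif(1, 0.003, 0.01))
}
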