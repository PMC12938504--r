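test_that("valve law hits its boundaries and the documented midpoint closed form", {
  law <- valve_law()   # exponential, 0.02 .. 200, k = 1
  expect_equal(valve_resistance(0, law), law$open_resistance)
  expect_equal(valve_resistance(1, law), law$occluded_resistance)
  # geometric interpolation: R(0.5) = sqrt(R_open * R_occ) = 2
  expect_equal(valve_resistance(0.5, law),
               sqrt(law$open_resistance * law$occluded_resistance))
  pow <- valve_law(0.02, 200, shape_exponent = 2, kind = "power")
  expect_equal(valve_resistance(0.5, pow), 0.02 + (200 - 0.02) * 0.25)
  expect_error(valve_resistance(1.2, law), "closure")
  expect_error(valve_law(0.02, 0.2), "1e4")
})

test_that("valve resistance is strictly increasing and continuous in closure", {
  for (law in list(valve_law(), valve_law(kind = "power", shape_exponent = 3),
                   valve_law(shape_exponent = 0.5))) {
    cl <- seq(0, 1, length.out = 401)
    r <- valve_resistance(cl, law)
    expect_true(all(diff(r) > 0))
    # continuity at the boundaries of the mapping
    expect_equal(valve_resistance(1e-9, law), law$open_resistance,
                 tolerance = 1e-3)
    expect_equal(valve_resistance(1 - 1e-9, law), law$occluded_resistance,
                 tolerance = 1e-3)
  }
})

test_that("node derivatives satisfy conservation and known limits", {
  m <- compliance_circuit()
  # equilibrium: all pressures at reference, pump off -> derivatives 0
  st <- list(node_pressures = rep(0, 3), valve_closure = 0.3)
  expect_equal(derivatives(m, st, pump_flow_at_t = 0), rep(0, 3))
  # at the algebraic steady state with the pump on, derivatives vanish
  p_ss <- steady_state_pressures(m, 0.3)
  expect_equal(derivatives(m, list(node_pressures = p_ss, valve_closure = 0.3)),
               rep(0, 3), tolerance = 1e-12)
})

test_that("steady-state pressures agree with an independent linear-system solve", {
  m <- coronary_circuit()
  cl <- 0.22
  r_up <- m$segment_resistances[["upstream"]]
  r_b <- m$sample_resistance / m$n_parallel_samples
  r_o <- m$segment_resistances[["downstream"]] +
    valve_resistance(cl, m$valve_law)
  # conductance-matrix formulation solved with base solve()
  G <- matrix(0, 3, 3)
  G[1, 1] <- 1 / r_up; G[1, 2] <- -1 / r_up
  G[2, 1] <- -1 / r_up; G[2, 2] <- 1 / r_up + 1 / r_b; G[2, 3] <- -1 / r_b
  G[3, 2] <- -1 / r_b; G[3, 3] <- 1 / r_b + 1 / r_o
  b <- c(m$pump_flow, 0, 0)
  p_ref <- solve(G, b)
  expect_equal(unname(steady_state_pressures(m, cl)), p_ref,
               tolerance = 1e-9)
})

test_that("simulation converges to the algebraic steady state within 1%", {
  # fast damping stage so the slowest time constant stays test-sized
  m <- compliance_circuit(reservoir_compliance = 0.05,
                          filter_compliance = 0.05)
  for (cl in c(0.1, 0.25, 0.35)) {
    sim <- simulate_circuit(m, cl, duration = 90, dt = 5e-3,
                            initial_pressures = c(50, 40, 10))
    expect_equal(unname(sim$state[2]), steady_sensor_pressure(m, cl),
                 tolerance = 0.01)
    expect_lt(sim$volume_error_fraction, 1e-3)
  }
})

test_that("with the pump off all pressures decay to the outflow reference", {
  m <- compliance_circuit(pump_flow = 100, reservoir_compliance = 0.05,
                          filter_compliance = 0.05)
  sim <- simulate_circuit(m, 0.1, duration = 120, dt = 5e-3,
                          pump_fn = function(t) rep(0, length(t)),
                          initial_pressures = c(120, 100, 40))
  expect_lt(max(abs(sim$state - m$outflow_reference_pressure)), 1)
})

test_that("steady sensor pressure is monotone in valve closure", {
  set.seed(7)
  for (rep in 1:5) {
    m <- random_circuit()
    cl <- seq(0, 1, length.out = 51)
    p <- vapply(cl, function(c) steady_sensor_pressure(m, c), numeric(1))
    expect_true(all(diff(p) >= 0))
  }
})

test_that("simulation diverges loudly rather than silently", {
  m <- compliance_circuit(tubing_compliance = 1e-7)  # stiff on purpose
  expect_error(simulate_circuit(m, 0.9, duration = 10, dt = 0.05,
                                initial_pressures = c(0, 0, 0)),
               "diverged|non-finite")
})

test_that("flow split is uniform across parallel culture units", {
  expect_identical(split_flow(540, 3), 180)
  expect_identical(split_flow(123.4, 1), 123.4)
  expect_identical(split_flow(600, 6), 100)
  expect_error(split_flow(540, 0), "n_branches")
})

test_that("pump capability limit is enforced", {
  expect_error(circuit_model(pump_flow = 700), "600")
})
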