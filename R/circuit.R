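#' Pinch-valve closure-to-resistance law
#'
#' The proportional pinch-valve raises hydraulic resistance by compressing the
#' silicone tubing externally. The closure fraction (0 = fully open, 1 = fully
#' occluded) maps to a hydraulic resistance through a strictly increasing,
#' continuous law. Two parametric families are provided:
#'
#' * `"exponential"` (default): geometric interpolation
#'   \eqn{R(c) = R_{open} (R_{occ}/R_{open})^{c^k}}. The resistance decades
#'   are spread uniformly over closure, so the controller sees a roughly
#'   constant *relative* sensitivity across the working range.
#' * `"power"`: \eqn{R(c) = R_{open} + (R_{occ}-R_{open}) c^k}.
#'
#' @param open_resistance Resistance at closure 0, mmHg min/mL.
#' @param occluded_resistance Resistance at closure 1 (effectively blocking);
#'   must be at least 1e4 times `open_resistance`.
#' @param shape_exponent Positive exponent `k` shaping the law.
#' @param kind `"exponential"` or `"power"`.
#' @return An object of class `valve_law`.
#' @export
valve_law <- function(open_resistance = 0.02, occluded_resistance = 200,
                      shape_exponent = 1, kind = c("exponential", "power")) {
  kind <- match.arg(kind)
  stopifnot(open_resistance > 0, occluded_resistance > 0, shape_exponent > 0)
  if (occluded_resistance / open_resistance < 1e4) {
    stop("occluded_resistance must be >= 1e4 x open_resistance ",
         "(the closed valve must effectively block the line)")
  }
  structure(list(open_resistance = open_resistance,
                 occluded_resistance = occluded_resistance,
                 shape_exponent = shape_exponent,
                 kind = kind),
            class = "valve_law")
}

#' Hydraulic resistance of the pinch-valve at a given closure
#'
#' @param closure Closure fraction(s) in \[0, 1\].
#' @param law A [valve_law()].
#' @return Resistance(s), mmHg min/mL; strictly increasing and continuous in
#'   `closure`.
#' @export
valve_resistance <- function(closure, law) {
  stopifnot(inherits(law, "valve_law"), is.numeric(closure))
  if (any(closure < 0 | closure > 1)) {
    stop("closure must lie in [0, 1]")
  }
  u <- closure^law$shape_exponent
  switch(law$kind,
    exponential = law$open_resistance *
      (law$occluded_resistance / law$open_resistance)^u,
    power = law$open_resistance +
      (law$occluded_resistance - law$open_resistance) * u
  )
}

#' Lumped-parameter hydraulic circuit model
#'
#' Three-node lumped network shared by both operating configurations of the
#' platform:
#'
#' ```
#' pump --> [n1: reservoir+filter C] --R_up--> [n2: sensor node "P",
#'   service C (coronary) + tubing C] --R_sample/n--> [n3: tubing C]
#'   --R_down + R_valve(c)--> vented reservoir (reference pressure)
#' ```
#'
#' The pressure sensor sits at node 2, upstream of the parallel samples; the
#' pinch valve compresses the line between the sample outlets and the
#' reservoir. In the coronary configuration a service compliance chamber at
#' node 2 stores volume during systolic valve closure and releases it in
#' diastole, producing the counter-phase pressure/flow pattern.
#'
#' Element values are calibration choices of the twin (the bench platform's
#' tubing resistances and chamber compliances are not catalogued): defaults
#' are sized so the sample branch drops a physiological ~36 mmHg at
#' 180 mL/min and all ISO regimes are reachable within the valve stroke.
#' The upstream segment resistance deliberately decouples the damping stage
#' from the sensor node: its time constant with the reservoir/filter
#' compliance is tens of seconds, so over one 1 s cycle the stage behaves as
#' a stiff constant-flow feed while still absorbing pump ripple.
#'
#' @param pump_flow Roller-pump flow, mL/min, in \[0, 600\].
#' @param reservoir_compliance,filter_compliance Damping-stage compliances
#'   (mL/mmHg), lumped at node 1.
#' @param service_compliance Service chamber compliance `C_s` (mL/mmHg) at
#'   node 2; 0 in the compliance-test configuration.
#' @param tubing_compliance Small parasitic compliance (mL/mmHg) present at
#'   every node so each node carries a state.
#' @param segment_resistances Named numeric `c(upstream=, downstream=)`,
#'   mmHg min/mL: line resistances pump-side and valve-side of the samples.
#' @param sample_resistance Hydraulic resistance of one sample branch,
#'   mmHg min/mL.
#' @param n_parallel_samples Number of samples perfused in parallel (1 for
#'   compliance testing, 3 per circuit in the coronary configuration).
#' @param valve_law A [valve_law()].
#' @param outflow_reference_pressure Reservoir (vented) pressure, mmHg.
#' @return An object of class `circuit_model`.
#' @seealso [compliance_circuit()], [coronary_circuit()] for configured
#'   defaults; [steady_state_pressures()], [simulate_circuit()].
#' @export
circuit_model <- function(pump_flow,
                          reservoir_compliance = 1.5,
                          filter_compliance = 0.5,
                          service_compliance = 0,
                          tubing_compliance = 0.005,
                          segment_resistances = c(upstream = 1.0,
                                                  downstream = 0.01),
                          sample_resistance = 0.2,
                          n_parallel_samples = 1,
                          valve_law = grafttwin::valve_law(),
                          outflow_reference_pressure = 0) {
  stopifnot(is.numeric(pump_flow), pump_flow >= 0)
  if (pump_flow > 600) {
    stop("pump_flow exceeds the 600 mL/min pump capability")
  }
  stopifnot(reservoir_compliance > 0, filter_compliance > 0,
            service_compliance >= 0, tubing_compliance > 0,
            all(segment_resistances >= 0), sample_resistance >= 0,
            n_parallel_samples >= 1,
            inherits(valve_law, "valve_law"))
  seg <- segment_resistances
  if (is.null(names(seg)) || !all(c("upstream", "downstream") %in% names(seg))) {
    seg <- c(upstream = unname(seg[1]), downstream = unname(seg[2]))
  }
  structure(list(
    pump_flow = pump_flow,
    reservoir_compliance = reservoir_compliance,
    filter_compliance = filter_compliance,
    service_compliance = service_compliance,
    tubing_compliance = tubing_compliance,
    segment_resistances = seg,
    sample_resistance = sample_resistance,
    n_parallel_samples = as.integer(n_parallel_samples),
    valve_law = valve_law,
    outflow_reference_pressure = outflow_reference_pressure
  ), class = "circuit_model")
}

#' @export
print.circuit_model <- function(x, ...) {
  cat("<circuit_model>\n")
  cat(sprintf("  pump: %.0f mL/min over %d parallel sample(s)\n",
              x$pump_flow, x$n_parallel_samples))
  cat(sprintf("  compliances (mL/mmHg): reservoir+filter %.3f, service %.3f, tubing %.3f\n",
              x$reservoir_compliance + x$filter_compliance,
              x$service_compliance, x$tubing_compliance))
  cat(sprintf("  resistances (mmHg min/mL): up %.3f, sample %.3f, down %.3f\n",
              x$segment_resistances[["upstream"]], x$sample_resistance,
              x$segment_resistances[["downstream"]]))
  cat(sprintf("  valve: %s law, %.3g .. %.3g mmHg min/mL\n",
              x$valve_law$kind, x$valve_law$open_resistance,
              x$valve_law$occluded_resistance))
  invisible(x)
}

# Node compliances as a length-3 vector (mL/mmHg); zero anywhere is a
# configuration error caught in circuit_model/derivatives.
node_compliances <- function(model) {
  c(model$reservoir_compliance + model$filter_compliance,
    model$service_compliance + model$tubing_compliance,
    model$tubing_compliance)
}

#' Compliance-test circuit configuration
#'
#' One sample, no service compliance, pump throttled to 200 mL/min so the
#' sinusoidal valve stroke sweeps the three ISO 7198 pressure regimes.
#'
#' @param pump_flow Pump flow, mL/min.
#' @param ... Overrides passed to [circuit_model()].
#' @return A `circuit_model`.
#' @export
compliance_circuit <- function(pump_flow = 200, ...) {
  circuit_model(pump_flow = pump_flow, n_parallel_samples = 1,
                service_compliance = 0,
                segment_resistances = c(upstream = 1.0, downstream = 0.01),
                ...)
}

#' Coronary-like circuit configuration
#'
#' Three samples perfused in parallel at 540 mL/min (180 mL/min each) with a
#' service compliance chamber upstream of the samples. The service compliance
#' default (0.04 mL/mmHg) is sized so that one systolic valve closure
#' (0.35 s) can store enough pump output to swing the sensor pressure by the
#' full 40 mmHg coronary excursion, with headroom; it is the single most
#' influential tuning knob for the flow waveform shape and is deliberately
#' config-exposed.
#'
#' @param pump_flow Pump flow, mL/min.
#' @param service_compliance Service chamber compliance, mL/mmHg.
#' @param ... Overrides passed to [circuit_model()].
#' @return A `circuit_model`.
#' @export
coronary_circuit <- function(pump_flow = 540, service_compliance = 0.04, ...) {
  circuit_model(pump_flow = pump_flow, n_parallel_samples = 3,
                service_compliance = service_compliance,
                segment_resistances = c(upstream = 0.25, downstream = 0.01),
                ...)
}

#' Mean flow split across parallel culture units
#'
#' The manifold geometry distributes flow uniformly across the parallel
#' branches, so each sample receives `total / n_branches`.
#'
#' @param total Total flow, mL/min.
#' @param n_branches Number of parallel branches (>= 1).
#' @return Per-branch mean flow, mL/min.
#' @examples
#' split_flow(540, 3)  # 180 mL/min per sample
#' @export
split_flow <- function(total, n_branches) {
  stopifnot(is.numeric(total), total >= 0)
  if (!is.numeric(n_branches) || n_branches < 1) {
    stop("n_branches must be >= 1")
  }
  total / n_branches
}

#' Node-pressure derivatives of the lumped network
#'
#' Conservation of volume at each compliance node:
#' \eqn{C_i \, dP_i/dt = \sum inflow - \sum outflow}. Flows are in mL/min and
#' time in seconds, so flows are divided by 60.
#'
#' @param model A [circuit_model()].
#' @param state List with `node_pressures` (length 3, mmHg) and
#'   `valve_closure` in \[0, 1\].
#' @param pump_flow_at_t Instantaneous pump flow, mL/min.
#' @return Numeric length-3 vector dP/dt, mmHg/s.
#' @export
derivatives <- function(model, state, pump_flow_at_t = model$pump_flow) {
  caps <- node_compliances(model)
  if (any(caps <= 0)) stop("zero compliance at a circuit node")
  p <- state$node_pressures
  stopifnot(length(p) == 3, all(is.finite(p)))
  r_up <- model$segment_resistances[["upstream"]]
  r_branch <- model$sample_resistance / model$n_parallel_samples
  r_out <- model$segment_resistances[["downstream"]] +
    valve_resistance(state$valve_closure, model$valve_law)
  q12 <- (p[1] - p[2]) / r_up
  q23 <- (p[2] - p[3]) / r_branch
  q3o <- (p[3] - model$outflow_reference_pressure) / r_out
  unname(c(pump_flow_at_t - q12, q12 - q23, q23 - q3o) / (60 * caps))
}

#' Steady-state node pressures at a fixed valve closure
#'
#' Solves the linear resistance network (series chain with a flow source) for
#' the equilibrium pressures; used as the algebraic oracle for the simulator
#' and as the plant map for pre-setting.
#'
#' @param model A [circuit_model()].
#' @param closure Valve closure fraction.
#' @param pump_flow Pump flow, mL/min (defaults to the model's).
#' @return Named numeric: `n1`, `n2` (sensor), `n3`, mmHg.
#' @export
steady_state_pressures <- function(model, closure,
                                   pump_flow = model$pump_flow) {
  r_up <- model$segment_resistances[["upstream"]]
  r_branch <- model$sample_resistance / model$n_parallel_samples
  r_out <- model$segment_resistances[["downstream"]] +
    valve_resistance(closure, model$valve_law)
  # At equilibrium the full pump flow traverses the chain.
  p0 <- model$outflow_reference_pressure
  p3 <- p0 + pump_flow * r_out
  p2 <- p3 + pump_flow * r_branch
  p1 <- p2 + pump_flow * r_up
  c(n1 = p1, n2 = p2, n3 = p3)
}

#' Sensor pressure at steady state (convenience)
#' @inheritParams steady_state_pressures
#' @return Steady sensor-node pressure, mmHg.
#' @export
steady_sensor_pressure <- function(model, closure,
                                   pump_flow = model$pump_flow) {
  unname(steady_state_pressures(model, closure, pump_flow)["n2"])
}

#' Simulate the hydraulic circuit
#'
#' Fixed-step explicit Euler integration of the three-node network under a
#' prescribed valve-closure command. The default step (1 ms) is at least 5x
#' smaller than the fastest node time constant under the default element
#' values, keeping the explicit scheme stable; halving the step changes
#' simulated pressures by < 0.1%.
#'
#' Volume is conserved by construction: the per-step ledger (pumped volume -
#' returned volume - change in stored volume) is tracked and reported; its
#' residual is floating-point roundoff.
#'
#' @param model A [circuit_model()].
#' @param closure_fn Function of time (s) returning closure in \[0, 1\], or a
#'   single number for a constant closure.
#' @param duration Simulated time, s.
#' @param dt Integration step, s.
#' @param pump_fn Optional function of time (s) returning pump flow (mL/min);
#'   defaults to the model's constant flow.
#' @param initial_pressures Length-3 starting pressures, mmHg.
#' @param noise_sd_pressure,noise_sd_flow Additive Gaussian sensor noise SD
#'   applied to the returned traces (0 = clean).
#' @param seed Optional integer seed for the noise.
#' @return A list of class `circuit_sim`: `pressure` and `flow`
#'   ([signal_trace()] at 1/dt Hz; flow is the per-sample branch flow),
#'   `state` (final node pressures), `times`, `node_pressures` (3 x n
#'   matrix), `volume_error_fraction`.
#' @export
simulate_circuit <- function(model, closure_fn, duration, dt = 1e-3,
                             pump_fn = NULL,
                             initial_pressures = NULL,
                             noise_sd_pressure = 0, noise_sd_flow = 0,
                             seed = NULL) {
  stopifnot(duration > 0, dt > 0, duration >= dt)
  if (is.numeric(closure_fn)) {
    cval <- closure_fn
    closure_fn <- function(t) rep(cval, length(t))
  }
  caps <- node_compliances(model)
  if (any(caps <= 0)) stop("zero compliance at a circuit node")
  n <- floor(duration / dt)
  times <- (seq_len(n) - 1) * dt
  closures <- closure_fn(times)
  if (any(closures < 0 | closures > 1)) {
    stop("closure command left [0, 1]")
  }
  pump <- if (is.null(pump_fn)) rep(model$pump_flow, n) else pump_fn(times)
  p0 <- model$outflow_reference_pressure
  p <- if (is.null(initial_pressures)) {
    steady_state_pressures(model, closures[1], pump[1])
  } else {
    stopifnot(length(initial_pressures) == 3)
    as.numeric(initial_pressures)
  }

  r_up <- model$segment_resistances[["upstream"]]
  r_branch <- model$sample_resistance / model$n_parallel_samples
  r_valve <- valve_resistance(closures, model$valve_law) +
    model$segment_resistances[["downstream"]]

  press <- numeric(n)
  flow <- numeric(n)
  pmat <- matrix(NA_real_, nrow = 3, ncol = n)
  pumped <- 0
  returned <- 0
  p_start <- p
  for (i in seq_len(n)) {
    q12 <- (p[1] - p[2]) / r_up
    q23 <- (p[2] - p[3]) / r_branch
    q3o <- (p[3] - p0) / r_valve[i]
    press[i] <- p[2]
    flow[i] <- q23 / model$n_parallel_samples
    pmat[, i] <- p
    dp <- c(pump[i] - q12, q12 - q23, q23 - q3o) / (60 * caps)
    p <- p + dt * dp
    if (any(!is.finite(p))) {
      stop(sprintf("simulation diverged (non-finite state) at t = %.4f s",
                   times[i]))
    }
    pumped <- pumped + pump[i] * dt / 60
    returned <- returned + q3o * dt / 60
  }
  stored <- sum(caps * (p - p_start))
  vol_err <- if (pumped > 0) abs(pumped - returned - stored) / pumped else 0

  if (!is.null(seed)) set.seed(seed)
  if (noise_sd_pressure > 0) press <- press + rnorm(n, sd = noise_sd_pressure)
  if (noise_sd_flow > 0) flow <- flow + rnorm(n, sd = noise_sd_flow)

  structure(list(
    pressure = signal_trace(press, 1 / dt, kind = "pressure"),
    flow = signal_trace(flow, 1 / dt, kind = "flow"),
    state = p,
    times = times,
    node_pressures = pmat,
    volume_error_fraction = vol_err
  ), class = "circuit_sim")
}
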