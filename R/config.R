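#' Default experiment configuration
#'
#' The fully expanded configuration for one of the two experimental
#' procedures, as a nested list matching the YAML schema accepted by
#' [load_config()]. All defaults reproduce the platform's documented
#' operating points: 200 mL/min pump for compliance testing, 540 mL/min over
#' three parallel samples with a service compliance for coronary
#' stimulation, the three ISO 7198 regimes at 1 Hz, 40 Hz / 200 Hz
#' acquisition with 3-point moving-average filtering, and 30 s of video at
#' 150 fps.
#'
#' @param kind `"compliance_test"` or `"coronary_run"`.
#' @return Nested configuration list of class `experiment_config`.
#' @export
default_config <- function(kind = c("compliance_test", "coronary_run")) {
  kind <- match.arg(kind)
  coronary <- kind == "coronary_run"
  cfg <- list(
    kind = kind,
    circuit = list(
      pump_flow = if (coronary) 540 else 200,
      reservoir_compliance = 1.5,
      filter_compliance = 0.5,
      service_compliance = if (coronary) 0.04 else 0,
      tubing_compliance = 0.005,
      segment_resistances = list(upstream = if (coronary) 0.25 else 1.0,
                                 downstream = 0.01),
      sample_resistance = 0.2,
      n_parallel_samples = if (coronary) 3 else 1,
      valve = list(open_resistance = 0.02, occluded_resistance = 200,
                   shape_exponent = 1, kind = "exponential")
    ),
    phantom = list(inner_diameter_ref = 3.2, wall_thickness = 0.4,
                   length = 40, distension_coeff = 7.55e-5,
                   reference_pressure = 80),
    fluid = list(glycerol_mass_fraction = 0.5, temperature_C = 37),
    regime = list(name = "normotension", p_min = 80, p_max = 120,
                  frequency = 1),
    controller = list(
      tolerance = 2,
      gains_min = as.list(unclass(
        default_controller_gains(kind)$gains_min))[c("kp", "ki", "kd")],
      gains_max = as.list(unclass(
        default_controller_gains(kind)$gains_max))[c("kp", "ki", "kd")],
      settle_cycles = 5,
      safety = list(pressure_min = -10, pressure_max = 250)
    ),
    stimulation = list(n_cycles = 36, measured_cycles = 30, seed = 1,
                       systole_duration = 0.35),
    acquisition = list(pressure_rate = 40, flow_rate = 200,
                       noise_sd_pressure = 0.5, noise_sd_flow = 1),
    imaging = list(fps = 150, duration_s = 30, mm_per_pixel = 0.0015,
                   image_width_px = 24, taper_px = 1, noise_sd = 0,
                   jitter_px = 0),
    stability = list(n_timepoints = 0, seed_stride = 101)
  )
  structure(cfg, class = c("experiment_config", "list"))
}

# Recursively overlay user values onto the defaults; unknown keys are
# collected as schema violations.
overlay_config <- function(defaults, user, path = "", bad = character(0)) {
  for (nm in names(user)) {
    key <- if (nzchar(path)) paste0(path, ".", nm) else nm
    if (!nm %in% names(defaults)) {
      bad <- c(bad, sprintf("unknown field '%s'", key))
    } else if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]]))) {
      if (!is.list(user[[nm]])) {
        bad <- c(bad, sprintf("field '%s' must be a mapping", key))
      } else {
        res <- overlay_config(defaults[[nm]], user[[nm]], key, bad)
        defaults[[nm]] <- res$value
        bad <- res$bad
      }
    } else {
      defaults[[nm]] <- user[[nm]]
    }
  }
  list(value = defaults, bad = bad)
}

validate_config <- function(cfg) {
  bad <- character(0)
  chk <- function(ok, msg) if (!isTRUE(ok)) bad <<- c(bad, msg)
  chk(cfg$kind %in% c("compliance_test", "coronary_run"),
      "kind: must be compliance_test or coronary_run")
  ci <- cfg$circuit
  chk(is.numeric(ci$pump_flow) && ci$pump_flow >= 0 && ci$pump_flow <= 600,
      "circuit.pump_flow: must be in [0, 600] mL/min")
  chk(ci$reservoir_compliance > 0, "circuit.reservoir_compliance: must be > 0")
  chk(ci$filter_compliance > 0, "circuit.filter_compliance: must be > 0")
  chk(ci$service_compliance >= 0, "circuit.service_compliance: must be >= 0")
  chk(ci$tubing_compliance > 0, "circuit.tubing_compliance: must be > 0")
  chk(ci$sample_resistance >= 0, "circuit.sample_resistance: must be >= 0")
  chk(ci$n_parallel_samples >= 1, "circuit.n_parallel_samples: must be >= 1")
  chk(ci$valve$occluded_resistance / ci$valve$open_resistance >= 1e4,
      "circuit.valve: occluded_resistance must be >= 1e4 x open_resistance")
  chk(cfg$phantom$inner_diameter_ref > 0,
      "phantom.inner_diameter_ref: must be > 0")
  chk(cfg$phantom$wall_thickness > 0, "phantom.wall_thickness: must be > 0")
  chk(cfg$phantom$distension_coeff >= 0,
      "phantom.distension_coeff: must be >= 0")
  chk(cfg$fluid$glycerol_mass_fraction >= 0 &&
        cfg$fluid$glycerol_mass_fraction <= 1,
      "fluid.glycerol_mass_fraction: must be in [0, 1]")
  chk(is.numeric(cfg$regime$p_min) && is.numeric(cfg$regime$p_max) &&
        cfg$regime$p_min < cfg$regime$p_max,
      "regime: p_min must be < p_max")
  chk(cfg$regime$frequency > 0, "regime.frequency: must be > 0")
  chk(cfg$controller$tolerance > 0, "controller.tolerance: must be > 0")
  chk(cfg$controller$safety$pressure_min < cfg$controller$safety$pressure_max,
      "controller.safety: pressure_min must be < pressure_max")
  chk(cfg$stimulation$n_cycles > cfg$controller$settle_cycles,
      "stimulation.n_cycles: must exceed controller.settle_cycles")
  chk(cfg$acquisition$pressure_rate > 0 && cfg$acquisition$flow_rate > 0,
      "acquisition: rates must be > 0")
  chk(cfg$imaging$fps > 0 && cfg$imaging$mm_per_pixel > 0,
      "imaging: fps and mm_per_pixel must be > 0")
  bad
}

#' Load and validate an experiment configuration
#'
#' Reads a YAML (or JSON) configuration, overlays it on the defaults for its
#' `kind`, validates every field, and attaches a provenance hash (MD5 of the
#' canonical YAML serialization). Schema violations are all reported at
#' once.
#'
#' @param path Path to a YAML or JSON configuration file.
#' @return A validated `experiment_config` with attribute `config_hash`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(user$kind)) stop("config error:\n  kind: field is required")
  defaults <- default_config(match.arg(user$kind,
                                       c("compliance_test", "coronary_run")))
  res <- overlay_config(defaults, user)
  cfg <- structure(res$value, class = c("experiment_config", "list"))
  bad <- c(res$bad, validate_config(cfg))
  if (length(bad) > 0) {
    stop("config error:\n", paste0("  ", bad, collapse = "\n"))
  }
  attr(cfg, "config_hash") <- config_hash(cfg)
  cfg
}

#' Save an experiment configuration as YAML
#' @param cfg An `experiment_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Provenance hash of a configuration
#'
#' MD5 of the canonical YAML serialization; embedded in every artifact a run
#' writes so outputs are traceable to their exact configuration.
#'
#' @param cfg An `experiment_config`.
#' @return Character MD5 hash.
#' @export
config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(unclass(cfg), tmp)
  unname(tools::md5sum(tmp))
}

#' Build package objects from a configuration
#'
#' @param cfg A validated `experiment_config`.
#' @return List: `model` ([circuit_model()]), `phantom` ([phantom_spec()]),
#'   `regime` ([pressure_regime()]), `law` ([motion_law()]), `gains_min`,
#'   `gains_max`, `limits`.
#' @export
config_objects <- function(cfg) {
  ci <- cfg$circuit
  model <- circuit_model(
    pump_flow = ci$pump_flow,
    reservoir_compliance = ci$reservoir_compliance,
    filter_compliance = ci$filter_compliance,
    service_compliance = ci$service_compliance,
    tubing_compliance = ci$tubing_compliance,
    segment_resistances = c(upstream = ci$segment_resistances$upstream,
                            downstream = ci$segment_resistances$downstream),
    sample_resistance = ci$sample_resistance,
    n_parallel_samples = ci$n_parallel_samples,
    valve_law = valve_law(ci$valve$open_resistance,
                          ci$valve$occluded_resistance,
                          ci$valve$shape_exponent, ci$valve$kind))
  phantom <- phantom_spec(cfg$phantom$inner_diameter_ref,
                          cfg$phantom$wall_thickness,
                          cfg$phantom$length,
                          cfg$phantom$distension_coeff,
                          cfg$phantom$reference_pressure)
  regime <- pressure_regime(cfg$regime$p_min, cfg$regime$p_max,
                            cfg$regime$frequency, cfg$controller$tolerance)
  law <- if (cfg$kind == "coronary_run") {
    motion_law("coronary_piecewise", period = 1 / cfg$regime$frequency,
               systole_duration = cfg$stimulation$systole_duration)
  } else {
    motion_law("sinusoidal", period = 1 / cfg$regime$frequency)
  }
  g <- function(x) pid_gains(x$kp, x$ki, x$kd)
  list(model = model, phantom = phantom, regime = regime, law = law,
       gains_min = g(cfg$controller$gains_min),
       gains_max = g(cfg$controller$gains_max),
       limits = safety_limits(cfg$controller$safety$pressure_min,
                              cfg$controller$safety$pressure_max))
}
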