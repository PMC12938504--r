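#' Run the ISO 7198 compliance-test procedure end to end
#'
#' Executes the full compliance protocol on the digital twin: pre-setting,
#' PID-regulated sinusoidal stimulation at the configured regime, quasi-static
#' phantom distension, synthetic video rendering over the post-settling
#' window, and the image-analysis pipeline. Returns the compliance result
#' plus a report row in the bench table layout (Pmin, Pmax, dP, DPmin,
#' DPmax, C).
#'
#' @param cfg An `experiment_config` of kind `compliance_test` (see
#'   [load_config()], [default_config()]).
#' @param output_dir Optional directory for artifacts (traces, controller
#'   log, report JSON); created if needed.
#' @param write_frames If `TRUE` and `output_dir` is set, also write the
#'   rendered frame stack as PNGs (can be large).
#' @return List of class `compliance_run`: `result`
#'   ([compliance_pipeline()] output), `metrics` ([cycle_metrics()]),
#'   `table_row` (named list in bench layout), `run`
#'   ([run_regulated_stimulation()] output), `stack`, `config_hash`, `seed`.
#' @export
run_compliance_test <- function(cfg, output_dir = NULL, write_frames = FALSE) {
  if (cfg$kind != "compliance_test") {
    stop("configuration kind must be compliance_test")
  }
  objs <- config_objects(cfg)
  seed <- cfg$stimulation$seed
  hash <- attr(cfg, "config_hash")
  if (is.null(hash)) hash <- config_hash(cfg)

  run <- run_regulated_stimulation(
    objs$model, objs$regime, objs$law,
    gains_min = objs$gains_min, gains_max = objs$gains_max,
    n_cycles = cfg$stimulation$n_cycles,
    settle_cycles = cfg$controller$settle_cycles,
    seed = seed,
    noise_sd_pressure = cfg$acquisition$noise_sd_pressure,
    noise_sd_flow = cfg$acquisition$noise_sd_flow,
    limits = objs$limits)
  if (run$aborted) {
    stop(errorCondition(
      sprintf("safety interlock aborted the run at %.3f s", run$abort_time),
      class = c("grafttwin_controller_error", "error", "condition")))
  }

  period <- 1 / objs$regime$frequency
  t0 <- cfg$controller$settle_cycles * period
  dur <- min(cfg$imaging$duration_s,
             run$pressure_raw$sampling_rate^-1 *
               length(run$pressure_raw$samples) - t0)
  fps <- cfg$imaging$fps
  t_frames <- t0 + seq(0, dur - 1 / fps, by = 1 / fps)
  raw <- run$pressure_raw
  p_at_frames <- raw$samples[pmin(length(raw$samples),
                                  round(t_frames * raw$sampling_rate) + 1)]
  d <- diameter_at_pressure(objs$phantom, p_at_frames)
  stack <- render_frames(d$outer,
                         mm_per_pixel = cfg$imaging$mm_per_pixel,
                         frame_rate = fps,
                         image_width_px = cfg$imaging$image_width_px,
                         taper_px = cfg$imaging$taper_px,
                         noise_sd = cfg$imaging$noise_sd,
                         jitter_px = cfg$imaging$jitter_px,
                         seed = seed)

  # filtered sensor pressure over the same window, rebased to t = 0
  acq <- run$pressure
  i0 <- floor((t0 - acq$start_time) * acq$sampling_rate) + 1
  i1 <- min(length(acq$samples),
            floor((t0 + dur - acq$start_time) * acq$sampling_rate))
  p_win <- signal_trace(acq$samples[i0:i1], acq$sampling_rate,
                        kind = "pressure")

  result <- compliance_pipeline(stack, p_win, objs$phantom, objs$regime)
  metrics <- run_cycle_metrics(run, cfg$stimulation$measured_cycles)

  table_row <- list(
    regime = cfg$regime$name,
    Pmin_mmHg = result$Pmin, Pmax_mmHg = result$Pmax,
    dP_mmHg = result$Pmax - result$Pmin,
    DPmin_mm = result$DPmin, DPmax_mm = result$DPmax,
    C = result$C_mean, C_sd = result$C_sd)

  out <- structure(list(result = result, metrics = metrics,
                        table_row = table_row, run = run, stack = stack,
                        config_hash = hash, seed = seed),
                   class = "compliance_run")
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    write_trace_csv(run$pressure, file.path(output_dir, "pressure_40Hz.csv"),
                    seed, hash)
    write_trace_csv(run$flow, file.path(output_dir, "flow_200Hz.csv"),
                    seed, hash)
    utils::write.csv(run$log, file.path(output_dir, "controller_log.csv"),
                     row.names = FALSE)
    report <- list(config_hash = hash, seed = seed, table = table_row,
                   per_cycle = result$per_cycle)
    jsonlite::write_json(report, file.path(output_dir, "compliance_report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    if (write_frames) write_frames_png(stack, file.path(output_dir, "frames"))
  }
  out
}

#' @export
print.compliance_run <- function(x, ...) {
  cat("<compliance_run>", x$table_row$regime, "regime, seed", x$seed, "\n")
  with(x$table_row, cat(sprintf(
    "  Pmin %.2f  Pmax %.2f  dP %.2f mmHg | DPmin %.4f  DPmax %.4f mm | C %.3f +/- %.3f\n",
    Pmin_mmHg, Pmax_mmHg, dP_mmHg, DPmin_mm, DPmax_mm, C, C_sd)))
  invisible(x)
}

#' Run the coronary-like stimulation procedure end to end
#'
#' Executes the coronary protocol: pre-setting, piecewise-law regulated
#' stimulation with the service compliance, 40 Hz / 200 Hz acquisition with
#' 3-point filtering, per-cycle metrics, counter-phase characterization, and
#' (optionally) a multi-timepoint long-term stability emulation in which the
#' configured run is repeated with independent seeds per timepoint and each
#' metric is compared across timepoints with Welch's ANOVA.
#'
#' @param cfg An `experiment_config` of kind `coronary_run`.
#' @param output_dir Optional artifact directory.
#' @return List of class `coronary_run`: `metrics` ([cycle_metrics()]),
#'   `counterphase`, `stability` (a [stability_report()] or `NULL`), `run`,
#'   `config_hash`, `seed`.
#' @export
run_coronary <- function(cfg, output_dir = NULL) {
  if (cfg$kind != "coronary_run") {
    stop("configuration kind must be coronary_run")
  }
  objs <- config_objects(cfg)
  seed <- cfg$stimulation$seed
  hash <- attr(cfg, "config_hash")
  if (is.null(hash)) hash <- config_hash(cfg)

  one_run <- function(s) {
    run_regulated_stimulation(
      objs$model, objs$regime, objs$law,
      gains_min = objs$gains_min, gains_max = objs$gains_max,
      n_cycles = cfg$stimulation$n_cycles,
      settle_cycles = cfg$controller$settle_cycles,
      seed = s,
      noise_sd_pressure = cfg$acquisition$noise_sd_pressure,
      noise_sd_flow = cfg$acquisition$noise_sd_flow,
      limits = objs$limits)
  }
  run <- one_run(seed)
  if (run$aborted) {
    stop(errorCondition(
      sprintf("safety interlock aborted the run at %.3f s", run$abort_time),
      class = c("grafttwin_controller_error", "error", "condition")))
  }
  metrics <- run_cycle_metrics(run, cfg$stimulation$measured_cycles)
  cp <- counterphase_index(run$pressure, run$flow,
                           period = 1 / objs$regime$frequency,
                           systole_duration = cfg$stimulation$systole_duration)

  stability <- NULL
  if (cfg$stability$n_timepoints >= 2) {
    seeds <- seed + cfg$stability$seed_stride * seq_len(cfg$stability$n_timepoints)
    per_tp <- lapply(seeds, function(s) {
      r <- one_run(s)
      run_cycle_metrics(r, cfg$stimulation$measured_cycles)
    })
    names(per_tp) <- paste0("timepoint_", seq_along(per_tp))
    stability <- stability_report(per_tp)
  }

  out <- structure(list(metrics = metrics, counterphase = cp,
                        stability = stability, run = run,
                        config_hash = hash, seed = seed),
                   class = "coronary_run")
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    write_trace_csv(run$pressure, file.path(output_dir, "pressure_40Hz.csv"),
                    seed, hash)
    write_trace_csv(run$flow, file.path(output_dir, "flow_200Hz.csv"),
                    seed, hash)
    utils::write.csv(run$log, file.path(output_dir, "controller_log.csv"),
                     row.names = FALSE)
    report <- list(config_hash = hash, seed = seed,
                   table = stats::setNames(
                     as.list(metrics$summary$mean), metrics$summary$metric),
                   table_sd = stats::setNames(
                     as.list(metrics$summary$sd), metrics$summary$metric),
                   counterphase = cp[c("lag_s", "diastolic_flow_fraction")])
    if (!is.null(stability)) report$stability <- stability$table
    jsonlite::write_json(report, file.path(output_dir, "coronary_report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  out
}

#' @export
print.coronary_run <- function(x, ...) {
  cat("<coronary_run> seed", x$seed, "\n")
  print(x$metrics)
  cat(sprintf("  counter-phase: lag %.3f s, diastolic flow fraction %.3f\n",
              x$counterphase$lag_s, x$counterphase$diastolic_flow_fraction))
  if (!is.null(x$stability)) print(x$stability)
  invisible(x)
}
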