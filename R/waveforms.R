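#' Uniformly sampled signal trace
#'
#' Container for a pressure (mmHg) or flow (mL/min) time series with its
#' sampling rate. All analytics in the package operate on these.
#'
#' @param samples Numeric vector of samples.
#' @param sampling_rate Sampling rate, Hz (> 0).
#' @param start_time Time of the first sample, s.
#' @param kind `"pressure"` or `"flow"`.
#' @param units Units label; defaults to mmHg for pressure, mL/min for flow.
#' @return An object of class `signal_trace`.
#' @export
signal_trace <- function(samples, sampling_rate, start_time = 0,
                         kind = c("pressure", "flow"), units = NULL) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(samples), sampling_rate > 0)
  if (is.null(units)) units <- if (kind == "pressure") "mmHg" else "mL/min"
  structure(list(samples = as.numeric(samples),
                 sampling_rate = sampling_rate,
                 start_time = start_time,
                 kind = kind,
                 units = units),
            class = "signal_trace")
}

#' @export
print.signal_trace <- function(x, ...) {
  cat(sprintf("<signal_trace> %s, %d samples at %g Hz (%.2f s), range %.2f..%.2f %s\n",
              x$kind, length(x$samples), x$sampling_rate,
              length(x$samples) / x$sampling_rate,
              min(x$samples), max(x$samples), x$units))
  invisible(x)
}

#' Sample times of a trace
#' @param trace A [signal_trace()].
#' @return Numeric vector of times, s.
#' @export
trace_times <- function(trace) {
  trace$start_time + (seq_along(trace$samples) - 1) / trace$sampling_rate
}

#' Emulate sensor acquisition of a simulated trace
#'
#' Decimates a simulator-resolution trace to the sensor sampling rate
#' (nearest-sample pick on the uniform grid) and applies additive Gaussian
#' sensor noise once. The bench sensors run at 40 Hz (pressure) and 200 Hz
#' (flow).
#'
#' @param trace A [signal_trace()] at simulator resolution.
#' @param target_rate Target sampling rate, Hz; must not exceed the source
#'   rate.
#' @param noise_sd Sensor noise SD in the trace's units (0 = off).
#' @param seed Optional integer seed.
#' @return A [signal_trace()] at `target_rate`.
#' @export
acquire <- function(trace, target_rate, noise_sd = 0, seed = NULL) {
  stopifnot(inherits(trace, "signal_trace"), target_rate > 0)
  if (target_rate > trace$sampling_rate) {
    stop("target_rate exceeds the source sampling rate; cannot resample up")
  }
  duration <- length(trace$samples) / trace$sampling_rate
  n_out <- floor(duration * target_rate)
  t_out <- (seq_len(n_out) - 1) / target_rate
  idx <- pmin(length(trace$samples), round(t_out * trace$sampling_rate) + 1)
  out <- trace$samples[idx]
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    out <- out + rnorm(n_out, sd = noise_sd)
  }
  signal_trace(out, target_rate, start_time = trace$start_time,
               kind = trace$kind, units = trace$units)
}

#' 3-point moving-average filter
#'
#' Each interior sample becomes the mean of itself and its two neighbours,
#' matching the acquisition filtering applied on the bench. Endpoints are
#' averaged over their available neighbours (2-point means), so the output
#' length equals the input length.
#'
#' @param trace A [signal_trace()] with at least 3 samples.
#' @return A filtered [signal_trace()].
#' @export
moving_average_3 <- function(trace) {
  stopifnot(inherits(trace, "signal_trace"))
  x <- trace$samples
  n <- length(x)
  if (n < 3) stop("moving_average_3 needs at least 3 samples")
  y <- x
  y[2:(n - 1)] <- (x[1:(n - 2)] + x[2:(n - 1)] + x[3:n]) / 3
  y[1] <- (x[1] + x[2]) / 2
  y[n] <- (x[n - 1] + x[n]) / 2
  out <- trace
  out$samples <- y
  out
}

#' Detect pressure-cycle boundaries
#'
#' Locates successive pressure minima spaced within +/-25% of the nominal
#' period; the pulsatile stimulation is pressure-referenced, so cycles are
#' anchored at pressure minima.
#'
#' @param trace A pressure [signal_trace()] spanning at least two nominal
#'   periods.
#' @param nominal_period Nominal cycle period, s.
#' @return Numeric vector of boundary times (s), one per detected minimum;
#'   consecutive entries delimit complete cycles.
#' @export
detect_cycles <- function(trace, nominal_period) {
  stopifnot(inherits(trace, "signal_trace"), nominal_period > 0)
  x <- trace$samples
  fs <- trace$sampling_rate
  if (length(x) / fs < 2 * nominal_period) {
    stop("trace must span at least two nominal periods")
  }
  if (max(x) - min(x) < 1e-9 * max(1, abs(mean(x)))) {
    stop("no periodicity found: trace is constant")
  }
  half <- max(1L, round(0.4 * nominal_period * fs))
  n <- length(x)
  # candidate minima: minimal within a +/-40% period window (one-sided at
  # the trace edges, so boundary minima are kept)
  is_min <- vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    x[i] <= min(x[lo:hi])
  }, logical(1))
  cand <- which(is_min)
  if (length(cand) < 2) stop("no periodicity found: fewer than two minima")
  # collapse plateaus / near-duplicates
  keep <- cand[c(TRUE, diff(cand) > 0.5 * nominal_period * fs)]
  # greedy chain: accept the next boundary only if its spacing from the last
  # accepted one falls within +/-25% of the nominal period
  lo_s <- 0.75 * nominal_period * fs
  hi_s <- 1.25 * nominal_period * fs
  acc <- keep[1]
  for (k in keep[-1]) {
    gap <- k - acc[length(acc)]
    if (gap >= lo_s && gap <= hi_s) {
      acc <- c(acc, k)
    } else if (gap > hi_s) {
      # lost track; restart the chain here
      acc <- c(acc, k)
    }
  }
  spacing <- diff(acc) / fs
  ok <- spacing > 0.75 * nominal_period & spacing < 1.25 * nominal_period
  if (!any(ok)) stop("no periodicity found near the nominal period")
  (acc - 1) / fs + trace$start_time
}

#' Per-cycle hemodynamic metrics
#'
#' For each complete cycle between consecutive boundaries, computes the
#' pressure extremes and excursion (Pmin, Pmax, dP) and, if a flow trace is
#' supplied, the flow mean, extremes and excursion (Qmean, Qmin, Qmax, dQ).
#' Aggregates are mean +/- SD across cycles, matching the bench convention of
#' reporting thirty consecutive 1 s periods.
#'
#' @param pressure A pressure [signal_trace()] (filtered).
#' @param flow Optional flow [signal_trace()] (filtered) covering the same
#'   window.
#' @param boundaries Cycle boundary times from [detect_cycles()].
#' @return An object of class `cycle_metrics`: `per_cycle` data.frame,
#'   `summary` data.frame (metric, mean, sd), `n_cycles`.
#' @export
cycle_metrics <- function(pressure, flow = NULL, boundaries) {
  stopifnot(inherits(pressure, "signal_trace"), length(boundaries) >= 2)
  t_end <- pressure$start_time + length(pressure$samples) / pressure$sampling_rate
  if (min(boundaries) < pressure$start_time - 1e-9 ||
      max(boundaries) > t_end + 1e-9) {
    stop("cycle boundary lies outside the trace")
  }
  slice <- function(trace, t0, t1) {
    i0 <- floor((t0 - trace$start_time) * trace$sampling_rate) + 1
    i1 <- ceiling((t1 - trace$start_time) * trace$sampling_rate)
    trace$samples[max(1, i0):min(length(trace$samples), i1)]
  }
  n_cyc <- length(boundaries) - 1
  rows <- lapply(seq_len(n_cyc), function(k) {
    ps <- slice(pressure, boundaries[k], boundaries[k + 1])
    row <- data.frame(cycle = k,
                      p_min = min(ps), p_max = max(ps),
                      dp = max(ps) - min(ps))
    if (!is.null(flow)) {
      qs <- slice(flow, boundaries[k], boundaries[k + 1])
      row$q_mean <- mean(qs); row$q_min <- min(qs); row$q_max <- max(qs)
      row$dq <- max(qs) - min(qs)
    }
    row
  })
  per_cycle <- do.call(rbind, rows)
  metrics <- setdiff(names(per_cycle), "cycle")
  summary <- data.frame(
    metric = metrics,
    mean = vapply(metrics, function(m) mean(per_cycle[[m]]), numeric(1)),
    sd = vapply(metrics, function(m) stats::sd(per_cycle[[m]]), numeric(1)),
    row.names = NULL
  )
  structure(list(per_cycle = per_cycle, summary = summary,
                 n_cycles = n_cyc),
            class = "cycle_metrics")
}

#' @export
print.cycle_metrics <- function(x, ...) {
  cat(sprintf("<cycle_metrics> %d cycles\n", x$n_cycles))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-7s %8.2f +/- %.2f\n", s$metric[i], s$mean[i], s$sd[i]))
  }
  invisible(x)
}

#' Counter-phase characterization of pressure and flow
#'
#' Quantifies the coronary-specific counter-phase pattern: the lag (s) at the
#' peak of the pressure-flow cross-correlation (0 for in-phase signals,
#' +/- period/2 for anti-phase), and the diastolic flow fraction -- the share
#' of per-cycle flow volume delivered outside the systolic window. Healthy
#' coronary perfusion is diastolic-dominant (fraction > 0.5).
#'
#' @param pressure,flow [signal_trace()]s covering the same window; the flow
#'   trace is resampled to the pressure rate if needed.
#' @param period Cycle period, s.
#' @param systole_duration Length of the systolic window, s, measured from
#'   each detected cycle start (pressure minimum).
#' @return List: `lag_s` in (-period/2, period/2], `diastolic_flow_fraction`
#'   in \[0, 1\], `boundaries`.
#' @export
counterphase_index <- function(pressure, flow, period = 1,
                               systole_duration = 0.35) {
  stopifnot(inherits(pressure, "signal_trace"), inherits(flow, "signal_trace"))
  dur_p <- length(pressure$samples) / pressure$sampling_rate
  dur_q <- length(flow$samples) / flow$sampling_rate
  if (abs(dur_p - dur_q) > 2 / min(pressure$sampling_rate, flow$sampling_rate)) {
    stop("pressure and flow traces have mismatched durations")
  }
  if (dur_p < 5 * period) stop("need at least 5 cycles for counter-phase analysis")
  fs <- pressure$sampling_rate
  if (abs(flow$sampling_rate - fs) > 1e-9) {
    flow <- acquire(flow, fs)
  }
  n <- min(length(pressure$samples), length(flow$samples))
  p <- pressure$samples[seq_len(n)] - mean(pressure$samples[seq_len(n)])
  q <- flow$samples[seq_len(n)] - mean(flow$samples[seq_len(n)])
  max_lag <- round(period / 2 * fs)
  cc <- stats::ccf(p, q, lag.max = max_lag, plot = FALSE)
  lag_s <- cc$lag[which.max(cc$acf)] / fs
  if (lag_s <= -period / 2) lag_s <- lag_s + period

  bnd <- detect_cycles(pressure, period)
  t_q <- trace_times(flow)[seq_len(n)]
  qs <- flow$samples[seq_len(n)]
  fracs <- vapply(seq_len(length(bnd) - 1), function(k) {
    in_cycle <- t_q >= bnd[k] & t_q < bnd[k + 1]
    if (!any(in_cycle)) return(NA_real_)
    vol <- sum(qs[in_cycle])                       # uniform dt: sums suffice
    sys <- in_cycle & t_q < bnd[k] + systole_duration
    dia_vol <- sum(qs[in_cycle & !sys])
    dia_vol / vol
  }, numeric(1))
  list(lag_s = lag_s,
       diastolic_flow_fraction = mean(fracs, na.rm = TRUE),
       boundaries = bnd)
}

#' Welch's heteroscedastic one-way ANOVA
#'
#' Compares a metric across acquisition timepoints without assuming equal
#' group variances, as used for the long-term stability assessment. Thin,
#' validated wrapper over `stats::oneway.test(var.equal = FALSE)`.
#'
#' @param groups Named list of numeric vectors, one per timepoint; each must
#'   have >= 2 values and nonzero variance.
#' @return List: `F`, `p`, `df1`, `df2`, `n_groups`.
#' @export
welch_anova <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  for (nm in names(groups)) {
    g <- groups[[nm]]
    if (length(g) < 2) stop(sprintf("group '%s' has fewer than 2 values", nm))
    if (stats::var(g) <= 0) stop(sprintf("group '%s' has zero variance", nm))
  }
  values <- unlist(groups, use.names = FALSE)
  labels <- factor(rep(names(groups), lengths(groups)))
  ft <- stats::oneway.test(values ~ labels, var.equal = FALSE)
  list(F = unname(ft$statistic), p = unname(ft$p.value),
       df1 = unname(ft$parameter[1]), df2 = unname(ft$parameter[2]),
       n_groups = length(groups))
}

#' Long-term stability report across timepoints
#'
#' Runs [welch_anova()] for each per-cycle metric across timepoints and
#' flags significance at alpha = 0.05. Groups are the per-cycle values of a
#' metric at each timepoint.
#'
#' @param metrics_by_timepoint Named list of [cycle_metrics()] objects, one
#'   per timepoint (e.g. emulated acquisition days).
#' @param alpha Significance level.
#' @return An object of class `stability_report`: data.frame with metric,
#'   F, p, significant; plus the per-timepoint summaries.
#' @export
stability_report <- function(metrics_by_timepoint, alpha = 0.05) {
  stopifnot(is.list(metrics_by_timepoint), length(metrics_by_timepoint) >= 2)
  metric_names <- setdiff(names(metrics_by_timepoint[[1]]$per_cycle), "cycle")
  tab <- do.call(rbind, lapply(metric_names, function(m) {
    groups <- lapply(metrics_by_timepoint, function(cm) cm$per_cycle[[m]])
    w <- welch_anova(groups)
    data.frame(metric = m, F = w$F, p = w$p, significant = w$p < alpha)
  }))
  structure(list(table = tab,
                 timepoints = lapply(metrics_by_timepoint, `[[`, "summary"),
                 alpha = alpha),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("<stability_report> %d timepoints, alpha = %g\n",
              length(x$timepoints), x$alpha))
  t <- x$table
  for (i in seq_len(nrow(t))) {
    cat(sprintf("  %-7s F = %6.3f  p = %.4f  %s\n", t$metric[i], t$F[i],
                t$p[i], if (t$significant[i]) "SIGNIFICANT" else "ns"))
  }
  invisible(x)
}
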