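#' Synthetic stereo-microscope frame stack
#'
#' Container for a time-ordered stack of grayscale frames of the phantom,
#' with the spatial calibration and frame rate. Frames are numeric matrices
#' in \[0, 1\] (rows = vertical/radial direction, columns = longitudinal
#' axis). Synthetic stacks carry their generator ground truth in `meta`.
#'
#' @param frames List of numeric matrices, all the same dimension.
#' @param frame_rate Frames per second.
#' @param mm_per_pixel Spatial calibration, mm per pixel.
#' @param meta Optional list of generator metadata (ground-truth diameters,
#'   jitter offsets, seed).
#' @return An object of class `frame_stack`.
#' @export
frame_stack <- function(frames, frame_rate, mm_per_pixel, meta = list()) {
  stopifnot(is.list(frames), length(frames) >= 1,
            frame_rate > 0, mm_per_pixel > 0)
  dims <- vapply(frames, dim, integer(2))
  if (length(frames) > 1 && any(dims != dims[, 1])) {
    stop("all frames must have the same dimensions")
  }
  structure(list(frames = frames, frame_rate = frame_rate,
                 mm_per_pixel = mm_per_pixel,
                 duration = length(frames) / frame_rate,
                 meta = meta),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<frame_stack> %d frames of %dx%d px at %g fps (%.2f s), %g mm/px\n",
              length(x$frames), d[1], d[2], x$frame_rate, x$duration,
              x$mm_per_pixel))
  invisible(x)
}

# Area-coverage rasterization of a horizontal bright band: pixel row r
# (1-based) covers [r-1, r); returns the covered fraction of each row for a
# band spanning [y0, y1] in pixel units.
band_coverage <- function(n_rows, y0, y1) {
  r <- seq_len(n_rows)
  pmax(0, pmin(r, y1) - pmax(r - 1, y0))
}

#' Render synthetic phantom frames
#'
#' Generates the fixture stack standing in for the stereo-microscope video:
#' the phantom appears as a bright horizontal band (outer wall to outer wall)
#' on a dark background, rendered with exact area-coverage anti-aliasing.
#' Optional per-frame rigid translation jitter (integer pixels) exercises the
#' registration step, and optional Gaussian pixel noise exercises
#' binarization. A small linear taper along the longitudinal axis emulates
#' the slight conicity of a mounted sample; because the ten measurement
#' stations then sample the pixel-rounding staircase at evenly spread
#' sub-pixel phases, the station average resolves diameter changes well below
#' one pixel, as on the bench.
#'
#' @param outer_diameters_mm Ground-truth outer diameter (mm) per frame.
#' @param mm_per_pixel Spatial calibration.
#' @param frame_rate Frames per second.
#' @param image_height_px,image_width_px Frame dimensions; the band must fit
#'   inside the frame height at all diameters.
#' @param taper_px Total linear increase of the rendered band height (in
#'   pixels) from the left to the right image edge; 0 disables the taper.
#' @param noise_sd Gaussian pixel-noise SD (in intensity units; contrast is
#'   1.0).
#' @param jitter_px Maximum absolute rigid translation per frame, integer
#'   pixels, applied in both axes (0 disables jitter).
#' @param fiducial If `TRUE`, dim a two-column marker on the band (emulating
#'   a suture or connector edge in the field of view). The phantom band is
#'   otherwise uniform along its axis, which makes a horizontal translation
#'   unobservable; the marker makes both jitter components recoverable by
#'   registration.
#' @param seed Integer seed; renders are bit-reproducible.
#' @return A [frame_stack()]; `meta` records `outer_diameters_mm`,
#'   `shifts` (n x 2 matrix, row/col), `taper_px`, `noise_sd`, `seed`.
#' @export
render_frames <- function(outer_diameters_mm, mm_per_pixel = 0.0015,
                          frame_rate = 30,
                          image_height_px = NULL, image_width_px = 24,
                          taper_px = 1, noise_sd = 0, jitter_px = 0,
                          fiducial = FALSE, seed = 1) {
  stopifnot(all(outer_diameters_mm > 0), mm_per_pixel > 0)
  d_px <- outer_diameters_mm / mm_per_pixel
  if (is.null(image_height_px)) {
    image_height_px <- ceiling(max(d_px)) + 2 * (jitter_px + 8)
  }
  if (max(d_px) + abs(taper_px) + 2 * jitter_px + 2 > image_height_px) {
    stop("diameter (plus jitter margin) exceeds the frame height")
  }
  set.seed(seed)
  n <- length(outer_diameters_mm)
  shifts <- if (jitter_px > 0) {
    cbind(row = sample(-jitter_px:jitter_px, n, replace = TRUE),
          col = sample(-jitter_px:jitter_px, n, replace = TRUE))
  } else {
    cbind(row = integer(n), col = integer(n))
  }
  shifts[1, ] <- 0L   # the stack is aligned to its first frame
  xs <- seq_len(image_width_px)
  taper <- taper_px * ((xs - 0.5) / image_width_px - 0.5)
  # Quarter-pixel vertical offset: with the band centred exactly on a pixel
  # boundary the two edges would cross pixel rows in lockstep and the column
  # counts would quantize in 2 px steps; any off-grid centre (as on a real
  # bench) decouples them.
  centre <- image_height_px / 2 + 0.25
  frames <- vector("list", n)
  for (i in seq_len(n)) {
    h <- d_px[i] + taper                     # per-column band height, px
    y0 <- centre - h / 2 + shifts[i, "row"]
    y1 <- centre + h / 2 + shifts[i, "row"]
    fr <- vapply(seq_len(image_width_px), function(j) {
      band_coverage(image_height_px, y0[j], y1[j])
    }, numeric(image_height_px))
    if (fiducial) {
      fx <- max(1, round(image_width_px * 0.3))
      fr[, fx:min(image_width_px, fx + 1)] <-
        fr[, fx:min(image_width_px, fx + 1)] * 0.6
    }
    if (shifts[i, "col"] != 0) {
      s <- shifts[i, "col"]
      shifted <- matrix(0, image_height_px, image_width_px)
      if (s > 0) {
        shifted[, (s + 1):image_width_px] <- fr[, 1:(image_width_px - s)]
        shifted[, 1:s] <- fr[, 1]            # band is x-uniform up to taper
      } else {
        shifted[, 1:(image_width_px + s)] <- fr[, (1 - s):image_width_px]
        shifted[, (image_width_px + s + 1):image_width_px] <- fr[, image_width_px]
      }
      fr <- shifted
    }
    if (noise_sd > 0) {
      fr <- fr + matrix(rnorm(length(fr), sd = noise_sd),
                        nrow = image_height_px)
    }
    frames[[i]] <- fr
  }
  frame_stack(frames, frame_rate, mm_per_pixel,
              meta = list(outer_diameters_mm = outer_diameters_mm,
                          shifts = shifts, taper_px = taper_px,
                          noise_sd = noise_sd, jitter_px = jitter_px,
                          fiducial = fiducial, seed = seed))
}

# 1-D circular cross-correlation lag of profile b relative to profile a via
# FFT; returns the shift that maps b back onto a.
profile_lag <- function(fa, b) {
  n <- length(b)
  cc <- Re(stats::fft(fa * Conj(stats::fft(b)), inverse = TRUE))
  lag <- which.max(cc) - 1
  if (lag > n / 2) lag <- lag - n
  -lag
}

# Integer-pixel rigid shift estimate via projection correlation: a rigid
# translation shifts the row-sum and column-sum profiles by the same amount,
# so two cheap 1-D correlations recover (row, col) without a 2-D FFT.
estimate_shift <- function(ref_row_fft, ref_col_fft, b) {
  c(row = profile_lag(ref_row_fft, rowSums(b)),
    col = profile_lag(ref_col_fft, colSums(b)))
}

apply_shift <- function(frame, dr, dc) {
  if (dr == 0 && dc == 0) return(frame)
  nr <- nrow(frame); nc <- ncol(frame)
  # edge-replicated sampling: avoids seams that would bias re-registration
  src_r <- pmin(nr, pmax(1, seq_len(nr) - dr))
  src_c <- pmin(nc, pmax(1, seq_len(nc) - dc))
  frame[src_r, src_c]
}

#' Register a frame stack to its first frame
#'
#' Estimates the rigid integer-pixel translation of every frame relative to
#' the first by FFT cross-correlation and shifts the frames back into
#' alignment. Constant (featureless) frames cannot be registered; the stack
#' is returned unchanged with a warning.
#'
#' @param stack A [frame_stack()].
#' @return A registered [frame_stack()]; `meta$estimated_shifts` records the
#'   per-frame (row, col) shifts that were removed.
#' @export
register_frames <- function(stack) {
  stopifnot(inherits(stack, "frame_stack"))
  n <- length(stack$frames)
  if (n == 1) {
    stack$meta$estimated_shifts <- cbind(row = 0L, col = 0L)
    return(stack)
  }
  ranges <- vapply(stack$frames, function(f) diff(range(f)), numeric(1))
  if (any(ranges < 1e-12)) {
    warning("featureless (constant) frame(s): registration skipped")
    stack$meta$estimated_shifts <- cbind(row = integer(n), col = integer(n))
    return(stack)
  }
  ref <- stack$frames[[1]]
  ref_row_fft <- stats::fft(rowSums(ref))
  ref_col_fft <- stats::fft(colSums(ref))
  est <- matrix(0L, n, 2, dimnames = list(NULL, c("row", "col")))
  for (i in 2:n) {
    s <- estimate_shift(ref_row_fft, ref_col_fft, stack$frames[[i]])
    est[i, ] <- as.integer(round(s))
    stack$frames[[i]] <- apply_shift(stack$frames[[i]],
                                     -est[i, "row"], -est[i, "col"])
  }
  stack$meta$estimated_shifts <- est
  stack
}

# Otsu's histogram threshold for values in [0, 1].
otsu_threshold <- function(x, levels = 256) {
  x <- pmin(1, pmax(0, x))
  h <- tabulate(pmin(levels, floor(x * levels) + 1L), nbins = levels)
  w <- h / sum(h)
  mids <- (seq_len(levels) - 0.5) / levels
  w0 <- cumsum(w)
  mu <- cumsum(w * mids)
  mu_t <- mu[levels]
  between <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- 0
  mids[which.max(between)]
}

#' Binarize a grayscale frame
#'
#' Automatic global thresholding by Otsu's method (maximal between-class
#' variance on a 256-bin histogram): foreground (the bright phantom band)
#' becomes 1, background 0. Set `invert = TRUE` for inverted-contrast frames
#' (dark phantom on bright background).
#'
#' @param frame Numeric matrix, values in \[0, 1\] (clipped otherwise).
#' @param invert Flip polarity before thresholding.
#' @return Integer 0/1 matrix of the same dimension.
#' @export
binarize <- function(frame, invert = FALSE) {
  stopifnot(is.matrix(frame), is.numeric(frame))
  if (diff(range(frame)) < 1e-12) {
    stop("degenerate frame: all pixels equal, no threshold exists")
  }
  x <- if (invert) 1 - frame else frame
  thr <- otsu_threshold(x)
  mask <- matrix(0L, nrow(frame), ncol(frame))
  mask[x > thr] <- 1L
  mask
}

#' Station columns for diameter measurement
#'
#' Ten (by default) evenly spaced columns along the longitudinal axis, at
#' fractions (i + 0.5)/n of the image width -- never touching the image
#' borders.
#'
#' @param width_px Image width in pixels.
#' @param n_stations Number of stations.
#' @return Integer column indices.
#' @export
station_columns <- function(width_px, n_stations = 10) {
  stopifnot(width_px >= n_stations)
  pmin(width_px, pmax(1, ceiling((seq_len(n_stations) - 0.5) / n_stations *
                                   width_px)))
}

#' Measure the outer diameter on a binary mask
#'
#' At each of the ten measurement stations the outer diameter is the count
#' of foreground pixels in that column times the calibration; the frame
#' value is the mean of the ten stations. An empty station column means the
#' band does not cross the station and the frame cannot be measured.
#'
#' @param mask 0/1 matrix from [binarize()].
#' @param mm_per_pixel Spatial calibration.
#' @param n_stations Number of stations.
#' @return List: `diameter_mm` (station mean), `station_mm` (length
#'   `n_stations`), `columns`.
#' @export
measure_outer_diameter <- function(mask, mm_per_pixel, n_stations = 10) {
  stopifnot(is.matrix(mask), mm_per_pixel > 0)
  cols <- station_columns(ncol(mask), n_stations)
  counts <- colSums(mask[, cols, drop = FALSE])
  if (any(counts == 0)) {
    stop("empty station column: no foreground band at station(s) ",
         paste(which(counts == 0), collapse = ", "))
  }
  station_mm <- counts * mm_per_pixel
  list(diameter_mm = mean(station_mm), station_mm = unname(station_mm),
       columns = cols)
}

#' ISO 7198 dynamic radial compliance
#'
#' \deqn{C = \frac{(D_{Pmax} - D_{Pmin}) / D_{Pmin}}{P_{max} - P_{min}}
#'       \times 10^4}
#' with inner diameters in mm and pressures in mmHg; the result is in
#' % per 1e-2 mmHg (so a value of 1 means a 1% diameter excursion per
#' 100 mmHg pulse pressure).
#'
#' @param DPmin,DPmax Inner diameters (mm) at the pressure extremes
#'   (`DPmin > 0`).
#' @param Pmin,Pmax Pressure extremes, mmHg (`Pmax > Pmin`).
#' @return Compliance, % 1e-2/mmHg.
#' @examples
#' compliance_eq1(3.227, 3.237, 79.67, 120.72)  # ~0.755
#' @export
compliance_eq1 <- function(DPmin, DPmax, Pmin, Pmax) {
  if (any(DPmin <= 0)) stop("DPmin must be > 0")
  if (any(Pmax <= Pmin)) stop("Pmax must be > Pmin")
  ((DPmax - DPmin) / DPmin) / (Pmax - Pmin) * 1e4
}

#' Image-based compliance measurement pipeline
#'
#' The full frame-analysis workflow: register, binarize and measure every
#' frame; segment the synchronized pressure trace into cycles; take the
#' per-cycle diameter extremes across frames, subtract twice the wall
#' thickness to obtain inner diameters; evaluate the compliance equation per
#' cycle with that cycle's measured pressure extremes; report the per-cycle
#' values and their mean +/- SD.
#'
#' Frames whose measurement fails (band not crossing a station) are flagged
#' and excluded; a cycle with no valid frames is dropped with a warning.
#'
#' @param stack A [frame_stack()] covering the same time window as
#'   `pressure`.
#' @param pressure A pressure [signal_trace()] (filtered), same window.
#' @param spec The [phantom_spec()] of the imaged sample (for the wall
#'   thickness).
#' @param regime The [pressure_regime()] applied (for the nominal period).
#' @return An object of class `compliance_result`: `DPmin`, `DPmax` (mean
#'   per-cycle inner-diameter extremes, mm), `Pmin`, `Pmax` (mean per-cycle
#'   pressure extremes, mmHg), `C_mean`, `C_sd`, `per_cycle` data.frame,
#'   `n_cycles`, `flagged_frames`.
#' @export
compliance_pipeline <- function(stack, pressure, spec, regime) {
  stopifnot(inherits(stack, "frame_stack"), inherits(pressure, "signal_trace"),
            inherits(spec, "phantom_spec"), inherits(regime, "pressure_regime"))
  period <- 1 / regime$frequency
  if (stack$duration < 5 * period) {
    stop("frame stack must cover at least 5 cycles")
  }
  reg <- register_frames(stack)
  n <- length(reg$frames)
  t_frame <- (seq_len(n) - 1) / reg$frame_rate
  dia <- rep(NA_real_, n)
  flagged <- integer(0)
  for (i in seq_len(n)) {
    m <- binarize(reg$frames[[i]])
    d <- tryCatch(measure_outer_diameter(m, reg$mm_per_pixel),
                  error = function(e) NULL)
    if (is.null(d)) flagged <- c(flagged, i) else dia[i] <- d$diameter_mm
  }

  bnd <- detect_cycles(pressure, period)
  ps <- pressure$samples
  tp <- trace_times(pressure)
  rows <- list()
  dropped <- 0
  for (k in seq_len(length(bnd) - 1)) {
    in_f <- which(t_frame >= bnd[k] & t_frame < bnd[k + 1] & !is.na(dia))
    in_p <- which(tp >= bnd[k] & tp < bnd[k + 1])
    if (length(in_f) == 0) { dropped <- dropped + 1; next }
    d_out_min <- min(dia[in_f]); d_out_max <- max(dia[in_f])
    dp_min <- d_out_min - 2 * spec$wall_thickness
    dp_max <- d_out_max - 2 * spec$wall_thickness
    p_min <- min(ps[in_p]); p_max <- max(ps[in_p])
    rows[[length(rows) + 1]] <- data.frame(
      cycle = k, DPmin = dp_min, DPmax = dp_max,
      Pmin = p_min, Pmax = p_max,
      C = compliance_eq1(dp_min, dp_max, p_min, p_max))
  }
  if (dropped > 0) {
    warning(sprintf("%d cycle(s) dropped: no valid frames", dropped))
  }
  if (length(rows) < 3) stop("fewer than 3 valid cycles; pipeline aborted")
  per_cycle <- do.call(rbind, rows)
  structure(list(
    DPmin = mean(per_cycle$DPmin), DPmax = mean(per_cycle$DPmax),
    Pmin = mean(per_cycle$Pmin), Pmax = mean(per_cycle$Pmax),
    C_mean = mean(per_cycle$C), C_sd = stats::sd(per_cycle$C),
    per_cycle = per_cycle, n_cycles = nrow(per_cycle),
    flagged_frames = flagged
  ), class = "compliance_result")
}

#' @export
print.compliance_result <- function(x, ...) {
  cat("<compliance_result>\n")
  cat(sprintf("  Pmin  %7.2f mmHg   Pmax  %7.2f mmHg\n", x$Pmin, x$Pmax))
  cat(sprintf("  DPmin %7.4f mm     DPmax %7.4f mm\n", x$DPmin, x$DPmax))
  cat(sprintf("  C = %.3f +/- %.3f %% 1e-2/mmHg over %d cycles\n",
              x$C_mean, x$C_sd, x$n_cycles))
  invisible(x)
}
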