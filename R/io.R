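#' Write a signal trace as CSV with a metadata sidecar
#'
#' The CSV dialect used throughout the package: columns `time_s`, `value`,
#' `units`. A JSON sidecar (`<path>.meta.json`) records the sampling rate,
#' kind, seed and config hash so any artifact can be traced back to the run
#' that produced it.
#'
#' @param trace A [signal_trace()].
#' @param path Output CSV path.
#' @param seed,config_hash Provenance fields for the sidecar.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path, seed = NA, config_hash = NA) {
  stopifnot(inherits(trace, "signal_trace"))
  df <- data.frame(time_s = trace_times(trace),
                   value = trace$samples,
                   units = trace$units)
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(kind = trace$kind, sampling_rate = trace$sampling_rate,
               start_time = trace$start_time, units = trace$units,
               n_samples = length(trace$samples),
               seed = seed, config_hash = config_hash)
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Read a signal trace written by [write_trace_csv()]
#'
#' @param path CSV path; the `<path>.meta.json` sidecar must be present.
#' @return A [signal_trace()].
#' @export
read_trace_csv <- function(path) {
  df <- utils::read.csv(path)
  meta_path <- paste0(path, ".meta.json")
  if (!file.exists(meta_path)) {
    stop("metadata sidecar not found: ", meta_path)
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  signal_trace(df$value, meta$sampling_rate, start_time = meta$start_time,
               kind = meta$kind, units = meta$units)
}

#' Write a frame stack as a directory of PNGs with a metadata sidecar
#'
#' Frames are written as `frame_00001.png`, ... plus `stack.meta.json`
#' holding fps, calibration and (for synthetic stacks) the generator ground
#' truth.
#'
#' @param stack A [frame_stack()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_frames_png <- function(stack, dir) {
  stopifnot(inherits(stack, "frame_stack"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(stack$frames)) {
    f <- stack$frames[[i]]
    f[f < 0] <- 0
    f[f > 1] <- 1
    png::writePNG(f, file.path(dir, sprintf("frame_%05d.png", i)))
  }
  meta <- stack$meta
  meta$frame_rate <- stack$frame_rate
  meta$mm_per_pixel <- stack$mm_per_pixel
  meta$n_frames <- length(stack$frames)
  if (!is.null(meta$shifts)) meta$shifts <- as.data.frame(meta$shifts)
  jsonlite::write_json(meta, file.path(dir, "stack.meta.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' Read a frame stack written by [write_frames_png()]
#' @param dir Directory containing the PNGs and `stack.meta.json`.
#' @return A [frame_stack()].
#' @export
read_frames_png <- function(dir) {
  meta_path <- file.path(dir, "stack.meta.json")
  if (!file.exists(meta_path)) stop("stack.meta.json not found in ", dir)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  files <- sort(list.files(dir, pattern = "^frame_\\d+\\.png$",
                           full.names = TRUE))
  if (length(files) == 0) stop("no frame PNGs found in ", dir)
  frames <- lapply(files, function(f) {
    img <- png::readPNG(f)
    if (length(dim(img)) == 3) img <- img[, , 1]
    img
  })
  frame_rate <- meta$frame_rate
  mm_per_pixel <- meta$mm_per_pixel
  meta$frame_rate <- NULL; meta$mm_per_pixel <- NULL; meta$n_frames <- NULL
  frame_stack(frames, frame_rate, mm_per_pixel, meta = meta)
}
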