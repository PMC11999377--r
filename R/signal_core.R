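# Core MSDA signal path: triaxial recording -> acceleration norm ->
# sliding-window SD -> minute-level series.

#' Construct a raw trunk-acceleration recording
#'
#' Bundles a uniformly sampled triaxial acceleration stream with its timing
#' metadata.  Axis convention: column 1 is vertical (x), column 2 lateral
#' (y), column 3 anterior/posterior (z), all in units of g.  Samples with
#' non-finite coordinates, and samples flagged in `valid`, are treated as
#' missing throughout the pipeline (device off, garment change, ...).
#'
#' @param samples numeric matrix with three columns (x, y, z) in g.
#' @param sampling_rate_hz sampling frequency in Hz (default 25).
#' @param start_time `POSIXct` wall-clock time of the first sample.
#' @param subject_id identifier string carried through to outputs.
#' @param valid optional logical vector, one flag per sample; non-finite
#'   samples are additionally marked invalid.
#' @param check_finite scan for non-finite samples (default). Callers that
#'   construct the matrix themselves and already account for gaps in
#'   `valid` may skip the scan.
#' @return an object of class `raw_recording`.
#' @export
raw_recording <- function(samples,
                          sampling_rate_hz = 25,
                          start_time = as.POSIXct("2018-01-15 00:00:00", tz = "UTC"),
                          subject_id = "subject",
                          valid = NULL,
                          check_finite = TRUE) {
  samples <- as.matrix(samples)
  if (nrow(samples) == 0L) stop("empty recording: no samples supplied")
  if (ncol(samples) != 3L) stop("samples must have three columns (x, y, z)")
  storage.mode(samples) <- "double"
  if (!is.numeric(sampling_rate_hz) || length(sampling_rate_hz) != 1L ||
      !is.finite(sampling_rate_hz) || sampling_rate_hz <= 0)
    stop("sampling_rate_hz must be a positive number")
  n <- nrow(samples)
  if (is.null(valid)) valid <- rep(TRUE, n)
  stopifnot(length(valid) == n)
  if (check_finite) {
    finite <- is.finite(.rowSums(samples, n, 3L))
    n_bad <- sum(valid & !finite)
    if (n_bad > 0L)
      message(sprintf("raw_recording: %d non-finite sample(s) marked invalid", n_bad))
    valid <- valid & finite
  }
  structure(
    list(samples = samples,
         sampling_rate_hz = as.numeric(sampling_rate_hz),
         start_time = start_time,
         subject_id = as.character(subject_id),
         valid = valid),
    class = "raw_recording")
}

#' @export
print.raw_recording <- function(x, ...) {
  dur <- nrow(x$samples) / x$sampling_rate_hz
  cat(sprintf("<raw_recording> subject %s: %d samples @ %g Hz (%.2f h), %.1f%% valid\n",
              x$subject_id, nrow(x$samples), x$sampling_rate_hz,
              dur / 3600, 100 * mean(x$valid)))
  invisible(x)
}

#' Euclidean norm of the triaxial acceleration
#'
#' Computes the per-sample magnitude `sqrt(x^2 + y^2 + z^2)` of the trunk
#' acceleration vector.  The gravity component is deliberately retained: a
#' constant offset within a window does not affect the window SD, so no
#' high-pass filtering is applied before the MSDA.  A squared variant
#' (`x^2 + y^2 + z^2`, no root) is available for sensitivity checks only.
#'
#' @param rec a [raw_recording()].
#' @param squared if `TRUE`, return the squared norm (sensitivity variant).
#' @return an object of class `norm_series`: the per-sample norm (NA where
#'   the sample is invalid) plus timing metadata.
#' @export
acceleration_norm <- function(rec, squared = FALSE) {
  stopifnot(inherits(rec, "raw_recording"))
  s <- rec$samples
  v <- s[, 1L]^2 + s[, 2L]^2 + s[, 3L]^2
  if (!squared) v <- sqrt(v)
  v[!rec$valid] <- NA_real_
  structure(
    list(values = v,
         valid = rec$valid,
         sampling_rate_hz = rec$sampling_rate_hz,
         start_time = rec$start_time,
         subject_id = rec$subject_id),
    class = "norm_series")
}

#' @export
print.norm_series <- function(x, ...) {
  cat(sprintf("<norm_series> subject %s: %d samples @ %g Hz\n",
              x$subject_id, length(x$values), x$sampling_rate_hz))
  invisible(x)
}

#' MSDA configuration
#'
#' @param window_seconds window length in seconds (default 2).
#' @param window_samples window length in samples; when `NULL` it is
#'   resolved as `round(window_seconds * sampling_rate_hz)` (2 s at 25 Hz
#'   gives 50 samples).
#' @param stride_samples distance between emitted window ends; 1 gives a
#'   fully sliding window, `window_samples` gives tumbling windows.
#' @param sd_denominator `"sample"` (n - 1) or `"population"` (n).
#' @param minute_min_valid_fraction minimum fraction of valid samples for a
#'   minute slot to count as measured (inclusive threshold, default 0.5).
#' @return an object of class `msda_config`.
#' @export
msda_config <- function(window_seconds = 2,
                        window_samples = NULL,
                        stride_samples = 1L,
                        sd_denominator = c("sample", "population"),
                        minute_min_valid_fraction = 0.5) {
  sd_denominator <- match.arg(sd_denominator)
  if (!is.null(window_samples)) {
    window_samples <- as.integer(window_samples)
    stopifnot(window_samples >= 2L)
  }
  stopifnot(window_seconds > 0, stride_samples >= 1,
            minute_min_valid_fraction >= 0, minute_min_valid_fraction <= 1)
  structure(
    list(window_seconds = window_seconds,
         window_samples = window_samples,
         stride_samples = as.integer(stride_samples),
         sd_denominator = sd_denominator,
         minute_min_valid_fraction = minute_min_valid_fraction),
    class = "msda_config")
}

#' Resolve the MSDA window length in samples
#'
#' @param cfg an [msda_config()].
#' @param sampling_rate_hz sampling frequency in Hz.
#' @return integer window length; `round(window_seconds * sampling_rate_hz)`
#'   unless `window_samples` was set explicitly.
#' @export
resolve_window <- function(cfg, sampling_rate_hz) {
  stopifnot(inherits(cfg, "msda_config"))
  k <- if (!is.null(cfg$window_samples)) cfg$window_samples
       else as.integer(round(cfg$window_seconds * sampling_rate_hz))
  if (k < 2L) stop("resolved window must span at least 2 samples")
  k
}

#' Moving standard deviation of the acceleration norm
#'
#' Slides a window of `resolve_window(cfg, fs)` samples along the norm
#' series and emits, aligned to the window end, the SD of each window that
#' is entirely made of valid samples.  Positions without a full valid
#' window (including the first `k - 1` samples and any window touching a
#' gap) are `NA`.  With `stride_samples > 1` only every stride-th window
#' end is emitted.
#'
#' @param norm a `norm_series` from [acceleration_norm()].
#' @param cfg an [msda_config()].
#' @return numeric vector of per-sample MSDA values (NA where no window is
#'   emitted), with the timing metadata of `norm` attached as attributes.
#' @export
moving_sd <- function(norm, cfg = msda_config()) {
  stopifnot(inherits(norm, "norm_series"), inherits(cfg, "msda_config"))
  v <- norm$values
  n <- length(v)
  k <- resolve_window(cfg, norm$sampling_rate_hz)
  if (k > n) {
    warning(sprintf("window (%d samples) longer than series (%d): empty output", k, n))
    return(numeric(0))
  }
  # centre on the grand mean before the rolling pass: the SD is translation
  # invariant and this keeps the running-sum variance formula well
  # conditioned around the 1 g gravity offset
  mu <- mean(v, na.rm = TRUE)
  v0 <- v - if (is.finite(mu)) mu else 0
  out <- roll_sd_c(v0, k, cfg$sd_denominator == "sample")
  if (cfg$stride_samples > 1L) {
    keep <- seq.int(k, n, by = cfg$stride_samples)
    masked <- rep(NA_real_, n)
    masked[keep] <- out[keep]
    out <- masked
  }
  attr(out, "sampling_rate_hz") <- norm$sampling_rate_hz
  attr(out, "start_time") <- norm$start_time
  attr(out, "window_samples") <- k
  out
}

#' Aggregate MSDA and step events to minute-of-day slots
#'
#' Buckets the per-sample MSDA stream and detected step events into
#' half-open minute slots `[minute, minute + 1)` counted from midnight of
#' the recording's start day (minute 0-1439, day index 0-based).  Per
#' slot, `msda` is the mean of the window SDs whose window end falls in
#' the slot and `steps` is the number of step events in the slot.  A slot
#' is valid only when the fraction of valid samples covering it is at
#' least `cfg$minute_min_valid_fraction` (inclusive) and at least one
#' window SD was emitted; invalid slots carry `NA` in both channels.
#'
#' @param msda_stream per-sample MSDA from [moving_sd()].
#' @param step_events numeric vector of step times in seconds from the
#'   recording start (e.g. from [detect_steps()]).
#' @param rec the originating [raw_recording()] (supplies validity/timing).
#' @param cfg an [msda_config()].
#' @return a `minute_series` data.frame with columns
#'   `day, minute, msda, steps, valid`, covering every day the recording
#'   touches with all 1440 slots.
#' @export
minute_aggregate <- function(msda_stream, step_events, rec, cfg = msda_config()) {
  stopifnot(inherits(rec, "raw_recording"))
  n <- nrow(rec$samples)
  fs <- rec$sampling_rate_hz
  spm <- 60 * fs  # samples per minute
  off <- as.numeric(difftime(rec$start_time, trunc(rec$start_time, "days"),
                             units = "secs"))
  if (length(msda_stream) == 0L) msda_stream <- rep(NA_real_, n)
  stopifnot(length(msda_stream) == n)
  amin <- as.integer((off + (seq_len(n) - 1) / fs) %/% 60)
  dt <- data.table::data.table(amin = amin, msda = msda_stream, valid = rec$valid)
  agg <- dt[, .(msda = mean(msda, na.rm = TRUE),
                n_valid = sum(valid),
                n_msda = sum(!is.na(msda))), by = amin]
  # step events -> absolute minute
  if (length(step_events)) {
    ev_min <- as.integer((off + step_events) %/% 60)
    ev <- data.table::data.table(amin = ev_min)[, .(steps = .N), by = amin]
  } else {
    ev <- data.table::data.table(amin = integer(0), steps = integer(0))
  }
  n_days <- (max(amin) %/% 1440L) + 1L
  grid <- data.table::data.table(amin = seq.int(0L, n_days * 1440L - 1L))
  grid <- merge(grid, agg, by = "amin", all.x = TRUE)
  grid <- merge(grid, ev, by = "amin", all.x = TRUE)
  grid[is.na(n_valid), n_valid := 0L]
  grid[is.na(n_msda), n_msda := 0L]
  grid[is.na(steps), steps := 0L]
  grid[, valid := (n_valid / spm >= cfg$minute_min_valid_fraction) & n_msda > 0L]
  grid[valid == FALSE, `:=`(msda = NA_real_, steps = NA_integer_)]
  out <- data.frame(day = grid$amin %/% 1440L,
                    minute = grid$amin %% 1440L,
                    msda = grid$msda,
                    steps = as.numeric(grid$steps),
                    valid = grid$valid)
  attr(out, "subject_id") <- rec$subject_id
  attr(out, "sampling_rate_hz") <- fs
  class(out) <- c("minute_series", "data.frame")
  out
}
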