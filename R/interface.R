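# Delimited-text file formats and the directory-level pipeline driver.
# Recordings are stored as `t_s,x,y,z` rows (seconds from the declared
# start) with `# key=value` metadata comment lines; gaps are encoded as
# absent rows.  An ISO-8601 `timestamp` column is accepted on input.

.meta_header <- function(meta) {
  paste0("# ", names(meta), "=", unlist(meta))
}

.read_meta <- function(path, n_max = 10L) {
  lines <- readLines(path, n = n_max)
  lines <- lines[startsWith(lines, "# ")]
  kv <- sub("^# ", "", lines)
  keys <- sub("=.*$", "", kv)
  vals <- sub("^[^=]*=", "", kv)
  stats::setNames(as.list(vals), keys)
}

#' Hash of a configuration object
#'
#' Stable fingerprint (md5 of the deparsed object) recorded in output file
#' headers so a run's configuration can be recognised later.
#'
#' @param x any R object.
#' @return character md5 digest.
#' @export
config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(x, control = "all"), f)
  unname(tools::md5sum(f))
}

#' Write a raw recording as delimited text
#'
#' @param rec a [raw_recording()].
#' @param path output file.
#' @param meta optional named list of extra `# key=value` header fields
#'   (e.g. seed, config hash).
#' @export
write_recording_csv <- function(rec, path, meta = list()) {
  stopifnot(inherits(rec, "raw_recording"))
  hdr <- .meta_header(c(list(subject_id = rec$subject_id,
                             start_time = format(rec$start_time, "%Y-%m-%dT%H:%M:%OS3%z"),
                             sampling_rate_hz = rec$sampling_rate_hz), meta))
  n <- nrow(rec$samples)
  dt <- data.table::data.table(t_s = round((seq_len(n) - 1) / rec$sampling_rate_hz, 6),
                               x = rec$samples[, 1L], y = rec$samples[, 2L],
                               z = rec$samples[, 3L])
  dt <- dt[rec$valid]  # gaps as absent rows
  writeLines(hdr, path)
  data.table::fwrite(dt, path, append = TRUE, col.names = TRUE)
  invisible(path)
}

#' Read a raw recording from delimited text
#'
#' Accepts the package's `t_s,x,y,z` format (with `# key=value` headers) or
#' a `timestamp,x,y,z` file with ISO-8601 timestamps.  Rows are snapped to
#' the uniform sampling grid; grid positions with no row become invalid
#' samples (gaps).  Malformed rows (non-numeric coordinates) are skipped
#' with a message; a file whose malformed fraction exceeds
#' `max_malformed_fraction` is rejected.
#'
#' @param path input file.
#' @param sampling_rate_hz sampling rate, overriding any header value.
#' @param max_malformed_fraction tolerated fraction of malformed rows
#'   (default 0.05).
#' @return a [raw_recording()].
#' @export
read_recording_csv <- function(path, sampling_rate_hz = NULL,
                               max_malformed_fraction = 0.05) {
  meta <- .read_meta(path)
  fs <- if (!is.null(sampling_rate_hz)) sampling_rate_hz
        else if (!is.null(meta$sampling_rate_hz)) as.numeric(meta$sampling_rate_hz)
        else 25
  dt <- data.table::fread(path, skip = "t_s", header = TRUE, fill = TRUE) |>
    tryCatch(error = function(e) NULL)
  if (is.null(dt))
    dt <- data.table::fread(path, header = TRUE, fill = TRUE)
  if ("timestamp" %in% names(dt) && !("t_s" %in% names(dt))) {
    ts <- as.POSIXct(dt$timestamp, format = "%Y-%m-%dT%H:%M:%OS", tz = "UTC")
    dt$t_s <- as.numeric(ts) - as.numeric(ts[1L])
    start_time <- ts[1L]
  } else {
    start_time <- if (!is.null(meta$start_time))
      as.POSIXct(meta$start_time, format = "%Y-%m-%dT%H:%M:%OS", tz = "UTC")
    else as.POSIXct("2018-01-15 00:00:00", tz = "UTC")
  }
  stopifnot(all(c("t_s", "x", "y", "z") %in% names(dt)))
  num <- function(v) suppressWarnings(as.numeric(v))
  xyz <- cbind(num(dt$x), num(dt$y), num(dt$z))
  t_s <- num(dt$t_s)
  bad <- !is.finite(t_s) | !is.finite(xyz[, 1L]) | !is.finite(xyz[, 2L]) |
    !is.finite(xyz[, 3L])
  if (any(bad)) {
    if (mean(bad) > max_malformed_fraction)
      stop(sprintf("%.1f%% of rows malformed in %s (limit %.1f%%)",
                   100 * mean(bad), path, 100 * max_malformed_fraction))
    message(sprintf("read_recording_csv: skipped %d malformed row(s)", sum(bad)))
    t_s <- t_s[!bad]; xyz <- xyz[!bad, , drop = FALSE]
  }
  idx <- as.integer(round(t_s * fs)) + 1L
  n <- max(idx)
  samples <- matrix(NA_real_, n, 3L)
  samples[idx, ] <- xyz
  valid <- logical(n)
  valid[idx] <- TRUE
  suppressMessages(raw_recording(
    samples, sampling_rate_hz = fs, start_time = start_time,
    subject_id = if (!is.null(meta$subject_id)) meta$subject_id
                 else sub("\\.[^.]*$", "", basename(path)),
    valid = valid))
}

#' Write / read a minute series
#'
#' Delimited text with columns `day,minute,msda,steps,valid`.
#'
#' @param minutes a `minute_series` data.frame.
#' @param path file path.
#' @param meta optional named list of header fields.
#' @export
write_minute_series <- function(minutes, path, meta = list()) {
  writeLines(.meta_header(meta), path)
  data.table::fwrite(as.data.frame(minutes), path, append = length(meta) > 0,
                     col.names = TRUE)
  invisible(path)
}

#' @rdname write_minute_series
#' @export
read_minute_series <- function(path) {
  dt <- data.table::fread(path, skip = "day,minute", header = TRUE)
  out <- as.data.frame(dt)
  out$valid <- as.logical(out$valid)
  class(out) <- c("minute_series", "data.frame")
  out
}

#' Write an ensemble profile (`minute,msda,steps,n_days`)
#'
#' @param profile an `ensemble_profile`.
#' @param path file path.
#' @param meta optional named list of header fields.
#' @export
write_profile_csv <- function(profile, path, meta = list()) {
  meta <- c(list(error_fraction = error_fraction(profile)), meta)
  writeLines(.meta_header(meta), path)
  data.table::fwrite(as.data.frame(profile), path, append = TRUE, col.names = TRUE)
  invisible(path)
}

#' Run the compute pipeline over a directory of recordings
#'
#' Reads every `*.csv` recording in `input_dir` (ground-truth sidecars and
#' metadata files are skipped), runs [process_recording()], writes the
#' per-subject minute series and ensemble profile, and collects the daily
#' summaries.  Excluded subjects are listed with their error fraction.
#'
#' @param input_dir directory of recording files.
#' @param output_dir directory for outputs (created if needed).
#' @param msda_cfg,step_cfg,error_threshold pipeline configuration.
#' @param metadata optional metadata data.frame with `subject_id`,
#'   `mobility_mode`, `fim_mobility` (defaults to
#'   `input_dir/metadata.csv` when present) used to attach subgroups.
#' @param seed optional seed recorded in output headers.
#' @return the summary data.frame (one row per subject), also written to
#'   `output_dir/summaries.csv`.
#' @export
run_pipeline <- function(input_dir, output_dir,
                         msda_cfg = msda_config(),
                         step_cfg = step_detector_config(),
                         error_threshold = 0.05,
                         metadata = NULL, seed = NA) {
  files <- list.files(input_dir, pattern = "\\.csv$", full.names = TRUE)
  files <- files[!grepl("(_steps|metadata|summaries)\\.csv$", files)]
  if (!length(files)) stop("no recording files found in ", input_dir)
  if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
  if (is.null(metadata) && file.exists(file.path(input_dir, "metadata.csv")))
    metadata <- as.data.frame(data.table::fread(file.path(input_dir, "metadata.csv")))
  hash <- config_hash(list(msda_cfg, step_cfg, error_threshold))
  hdr <- list(seed = seed, config_hash = hash)
  rows <- lapply(files, function(f) {
    rec <- read_recording_csv(f)
    res <- process_recording(rec, msda_cfg, step_cfg, error_threshold)
    base <- file.path(output_dir, rec$subject_id)
    write_minute_series(res$minutes, paste0(base, "_minutes.csv"),
                        meta = c(list(subject_id = rec$subject_id), hdr))
    write_profile_csv(res$profile, paste0(base, "_profile.csv"),
                      meta = c(list(subject_id = rec$subject_id), hdr))
    if (!res$retained)
      message(sprintf("excluded %s: error fraction %.3f >= %.3f",
                      rec$subject_id, res$error_fraction, error_threshold))
    data.frame(subject_id = rec$subject_id, daily_msda = res$daily_msda,
               daily_steps = res$daily_steps, retained = res$retained,
               error_fraction = res$error_fraction)
  })
  out <- do.call(rbind, rows)
  if (!is.null(metadata)) {
    out <- merge(out, metadata[, intersect(names(metadata),
                   c("subject_id", "mobility_mode", "fim_mobility"))],
                 by = "subject_id", all.x = TRUE)
    if (all(c("mobility_mode", "fim_mobility") %in% names(out)))
      out$subgroup <- assign_subgroup(out$fim_mobility, out$mobility_mode)
  }
  data.table::fwrite(out, file.path(output_dir, "summaries.csv"))
  out
}

#' Serialise a validation report
#'
#' Writes the report as structured JSON (schema version 1) and, optionally,
#' a plain-text table of the per-subgroup distribution diagnostics for both
#' channels.
#'
#' @param report a `validation_report` from [build_report()].
#' @param json_path output JSON file.
#' @param text_path optional output text file.
#' @param meta optional named list (seed, config hash) embedded in the
#'   JSON.
#' @export
write_validation_report <- function(report, json_path, text_path = NULL,
                                    meta = list()) {
  stopifnot(inherits(report, "validation_report"))
  payload <- c(list(schema_version = 1L), meta, unclass(report))
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null")
  if (!is.null(text_path)) {
    dg <- report$diagnostics
    lines <- c(
      sprintf("Validation report: %d subjects (%d excluded)", report$n,
              report$n_excluded),
      "",
      "Distribution diagnostics (MSDA | steps): kurtosis g2, skewness g1, Shapiro-Wilk p",
      sprintf("%-12s %4s  %8s %8s %8s   %8s %8s %8s",
              "group", "n", "g2", "g1", "SW p", "g2", "g1", "SW p"))
    for (g in unique(dg$group)) {
      a <- dg[dg$group == g & dg$channel == "msda", ]
      b <- dg[dg$group == g & dg$channel == "steps", ]
      lines <- c(lines, sprintf(
        "%-12s %4d  %8.2f %8.2f %8.3f   %8.2f %8.2f %8.3f",
        g, a$n, a$kurtosis_g2, a$skewness_g1, a$shapiro_p,
        b$kurtosis_g2, b$skewness_g1, b$shapiro_p))
    }
    lines <- c(lines, "",
               sprintf("Floor effect (steps): %d/%d = %.1f%%",
                       report$floor$n_zero, report$floor$n, report$floor$percent))
    writeLines(lines, text_path)
  }
  invisible(json_path)
}
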