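# Synthetic 48-hour trunk-accelerometry cohort: six FIM-mobility subgroup
# profiles, a per-subject signal generator with ground-truth step times, and
# a cohort driver that runs the full MSDA pipeline subject by subject.

#' Subgroup activity profile for the synthetic cohort generator
#'
#' Describes the daily activity pattern of one FIM-mobility subgroup.
#' Days alternate a quiet night (rest noise) and a waking period
#' (06:00-22:00, higher sedentary-movement noise) on which active bouts are
#' superposed.  A fraction `walk_fraction` of bouts are gait bouts carrying
#' a cadence-locked train of vertical impulses (the detectable step
#' signature); the remainder are non-gait activity bouts (wheelchair
#' propulsion, transfers, upper-body activity) modelled as 0.8-1.2 Hz
#' oscillation that moves the MSDA but carries no step impulses.
#'
#' @param label subgroup label, one of [subgroup_levels()].
#' @param n_subjects number of subjects in the subgroup.
#' @param mobility_mode `"walking"` or `"wheelchair"`.
#' @param fim_mobility representative FIM mobility score (1-7).
#' @param bouts_per_day mean number of active bouts per day (Poisson).
#' @param bout_duration_s,bout_duration_sd_s mean and SD of bout duration
#'   in seconds (truncated at 20 s).
#' @param walk_fraction probability that a bout is a gait bout.
#' @param gait_cadence_hz length-2 range of per-subject cadence in steps/s.
#' @param gait_impulse_g length-2 range of per-subject step-impulse
#'   amplitude in g.
#' @param weak_gait_prob probability that a subject's gait is too weak for
#'   step detection (severe hemiparesis: impulses drawn from
#'   `weak_gait_impulse_g` instead); such subjects still move the MSDA.
#' @param weak_gait_impulse_g length-2 amplitude range of weak gait.
#' @param weak_gait_sway_g amplitude in g of the additional cadence-locked
#'   vertical sway of weak gait: shuffling locomotion moves the trunk as
#'   much as regular gait but without crisp impact peaks, so the MSDA stays
#'   near its normal gait level while steps stay undetectable.
#' @param wc_osc_g amplitude in g of the non-gait activity oscillation.
#' @param rest_noise_g baseline noise SD in g during the night.
#' @param wake_noise_g baseline noise SD in g while awake (sedentary trunk
#'   movement); the main dial of overall activity intensity.
#' @param missing_segments_per_day number of missing blocks per day
#'   (bathing / garment change analogue; default 1).
#' @param missing_duration_min duration of each missing block (default 30).
#' @param subject_sd log-scale SD of the per-subject intensity factor.
#' @param day_jitter half-width of the uniform day-to-day intensity jitter
#'   (default 0.1, i.e. +/-10%).
#' @return an object of class `subgroup_profile`.
#' @export
subgroup_profile <- function(label,
                             n_subjects,
                             mobility_mode,
                             fim_mobility,
                             bouts_per_day,
                             bout_duration_s,
                             bout_duration_sd_s = bout_duration_s / 4,
                             walk_fraction,
                             gait_cadence_hz = c(1.4, 2.0),
                             gait_impulse_g = c(0.28, 0.45),
                             weak_gait_prob = 0,
                             weak_gait_impulse_g = c(0.08, 0.15),
                             weak_gait_sway_g = 0.10,
                             wc_osc_g = 0.04,
                             rest_noise_g = 0.0025,
                             wake_noise_g = 0.009,
                             missing_segments_per_day = 1L,
                             missing_duration_min = 30,
                             subject_sd = 0.2,
                             day_jitter = 0.1) {
  stopifnot(label %in% subgroup_levels(),
            n_subjects >= 1,
            mobility_mode %in% c("walking", "wheelchair"),
            fim_mobility %in% 1:7,
            bouts_per_day >= 0,
            bout_duration_s > 0,
            walk_fraction >= 0, walk_fraction <= 1,
            length(gait_cadence_hz) == 2, all(gait_cadence_hz > 0),
            length(gait_impulse_g) == 2, all(gait_impulse_g > 0),
            wc_osc_g > 0, rest_noise_g > 0, wake_noise_g > 0)
  structure(
    list(label = label, n_subjects = as.integer(n_subjects),
         mobility_mode = mobility_mode, fim_mobility = as.integer(fim_mobility),
         bouts_per_day = bouts_per_day, bout_duration_s = bout_duration_s,
         bout_duration_sd_s = bout_duration_sd_s, walk_fraction = walk_fraction,
         gait_cadence_hz = gait_cadence_hz, gait_impulse_g = gait_impulse_g,
         weak_gait_prob = weak_gait_prob, weak_gait_impulse_g = weak_gait_impulse_g,
         weak_gait_sway_g = weak_gait_sway_g,
         wc_osc_g = wc_osc_g, rest_noise_g = rest_noise_g,
         wake_noise_g = wake_noise_g,
         missing_segments_per_day = as.integer(missing_segments_per_day),
         missing_duration_min = missing_duration_min,
         subject_sd = subject_sd, day_jitter = day_jitter),
    class = "subgroup_profile")
}

#' Default subgroup profiles of the synthetic study cohort
#'
#' Six profiles in increasing order of mobility independence with subgroup
#' sizes 94/23/19/15/18/28 (197 subjects in total; 136 wheelchair users and
#' 61 walkers).  Amplitudes and bout schedules were calibrated once, by a
#' coarse grid search over the generator parameters, so that the cohort
#' median daily MSDA spans roughly 0.006-0.014 g across subgroups and daily
#' step medians range from tens (dependent wheelchair users) to thousands
#' (independent walkers); waking baseline noise increases monotonically
#' with the subgroup's independence level.
#'
#' @return named list of six [subgroup_profile()] objects in
#'   [subgroup_levels()] order.
#' @export
default_subgroup_profiles <- function() {
  list(
    `FIM1-4` = subgroup_profile(
      "FIM1-4", 94, "wheelchair", 2,
      bouts_per_day = 5, bout_duration_s = 60, bout_duration_sd_s = 15,
      walk_fraction = 0.20, gait_cadence_hz = c(1.0, 1.4),
      gait_impulse_g = c(0.28, 0.42), weak_gait_prob = 0.05,
      wc_osc_g = 0.035, rest_noise_g = 0.0022, wake_noise_g = 0.0072),
    `FIM5-WC` = subgroup_profile(
      "FIM5-WC", 23, "wheelchair", 5,
      bouts_per_day = 8, bout_duration_s = 85, bout_duration_sd_s = 20,
      walk_fraction = 0.28, gait_cadence_hz = c(1.1, 1.4),
      gait_impulse_g = c(0.28, 0.42), weak_gait_prob = 0.03,
      wc_osc_g = 0.045, rest_noise_g = 0.0024, wake_noise_g = 0.0080),
    `FIM5-walk` = subgroup_profile(
      "FIM5-walk", 15, "walking", 5,
      bouts_per_day = 8, bout_duration_s = 160, bout_duration_sd_s = 35,
      walk_fraction = 0.75, gait_cadence_hz = c(1.2, 1.6),
      gait_impulse_g = c(0.28, 0.45), weak_gait_prob = 0.08,
      wc_osc_g = 0.035, rest_noise_g = 0.0026, wake_noise_g = 0.0090),
    `FIM6-WC` = subgroup_profile(
      "FIM6-WC", 19, "wheelchair", 6,
      bouts_per_day = 12, bout_duration_s = 110, bout_duration_sd_s = 25,
      walk_fraction = 0.23, gait_cadence_hz = c(1.2, 1.5),
      gait_impulse_g = c(0.28, 0.45), weak_gait_prob = 0.02,
      wc_osc_g = 0.055, rest_noise_g = 0.0026, wake_noise_g = 0.0106),
    `FIM6-walk` = subgroup_profile(
      "FIM6-walk", 18, "walking", 6,
      bouts_per_day = 12, bout_duration_s = 195, bout_duration_sd_s = 40,
      walk_fraction = 0.75, gait_cadence_hz = c(1.4, 1.8),
      gait_impulse_g = c(0.30, 0.45), weak_gait_prob = 0.08,
      wc_osc_g = 0.040, rest_noise_g = 0.0028, wake_noise_g = 0.0112),
    `FIM7` = subgroup_profile(
      "FIM7", 28, "walking", 7,
      bouts_per_day = 15, bout_duration_s = 220, bout_duration_sd_s = 45,
      walk_fraction = 0.80, gait_cadence_hz = c(1.5, 1.9),
      gait_impulse_g = c(0.32, 0.48), weak_gait_prob = 0.05,
      wc_osc_g = 0.045, rest_noise_g = 0.0030, wake_noise_g = 0.0128)
  )
}

#' Rescale subgroup sizes of a profile list
#'
#' Utility for running the pipeline on proportionally smaller cohorts
#' (e.g. in repeated-seed simulation studies) while keeping every activity
#' parameter at its study value.
#'
#' @param profiles list of [subgroup_profile()] objects.
#' @param factor divisor applied to each `n_subjects` (rounded, minimum 2).
#' @return list of profiles with reduced `n_subjects`.
#' @export
scale_profiles <- function(profiles, factor) {
  stopifnot(factor >= 1)
  lapply(profiles, function(p) {
    p$n_subjects <- max(2L, as.integer(round(p$n_subjects / factor)))
    p
  })
}

# raised-cosine step impulse sampled at 25 Hz over 0.2 s (5 samples)
.step_shape <- function(width_samples = 5L) {
  0.5 * (1 - cos(2 * pi * (seq_len(width_samples) - 1L) / width_samples))
}

#' Generate one subject's 48-hour recording with ground truth
#'
#' Builds a triaxial recording as 1 g of gravity on the vertical axis plus
#' heteroscedastic baseline noise (night vs waking), gait bouts carrying
#' raised-cosine step impulses (width 0.2 s) on the vertical axis and a
#' cadence-frequency sway on the anterior/posterior axis, non-gait activity
#' bouts carrying 0.8-1.2 Hz oscillation (strongest on the vertical axis,
#' attenuated on the horizontal axes), and one missing block per day
#' (bathing analogue).  Deterministic for a fixed seed.
#'
#' @param profile a [subgroup_profile()].
#' @param seed integer seed for this subject.
#' @param days number of recorded 24-hour days (default 2).
#' @param sampling_rate_hz sampling frequency in Hz (default 25).
#' @param start_time recording start (defaults to midnight so the recording
#'   covers `days` whole calendar days).
#' @param subject_id identifier carried into the recording.
#' @return list with elements `recording` (a [raw_recording()]) and
#'   `truth` (list: `steps` data.frame of `time_s, observable`; `bouts`
#'   schedule data.frame; `label`; `weak_gait` flag).
#' @export
generate_subject <- function(profile, seed,
                             days = 2L,
                             sampling_rate_hz = 25,
                             start_time = as.POSIXct("2018-01-15 00:00:00", tz = "UTC"),
                             subject_id = "subject") {
  stopifnot(inherits(profile, "subgroup_profile"), days >= 1)
  p <- profile
  fs <- sampling_rate_hz
  set.seed(as.integer(seed %% 2147483647))
  n_day <- as.integer(round(24 * 3600 * fs))
  n <- n_day * as.integer(days)

  subj <- min(max(exp(rnorm(1, 0, p$subject_sd)), 0.5), 2)
  noise_f <- min(max(exp(rnorm(1, 0, p$subject_sd / 2)), 0.6), 1.7)
  cadence <- runif(1, p$gait_cadence_hz[1], p$gait_cadence_hz[2])
  weak <- runif(1) < p$weak_gait_prob
  amp_g <- if (weak) runif(1, p$weak_gait_impulse_g[1], p$weak_gait_impulse_g[2])
           else runif(1, p$gait_impulse_g[1], p$gait_impulse_g[2])

  off <- as.numeric(difftime(start_time, trunc(start_time, "days"), units = "secs"))
  tod <- (off + (seq_len(n) - 1) / fs) %% 86400
  awake <- tod >= 6 * 3600 & tod < 22 * 3600
  sig <- (p$rest_noise_g + (p$wake_noise_g - p$rest_noise_g) * awake) * noise_f
  x <- rnorm(n) * sig
  y <- rnorm(n) * (sig * 0.8)
  z <- rnorm(n) * (sig * 0.8)
  rm(tod, awake, sig)
  valid <- rep(TRUE, n)

  shape <- .step_shape()
  w <- length(shape)
  step_times <- numeric(0)
  bouts <- vector("list", 0L)

  for (d in seq_len(days)) {
    dayf <- 1 + runif(1, -p$day_jitter, p$day_jitter)
    nb <- rpois(1, p$bouts_per_day * subj)
    if (nb > 0) {
      st <- sort(runif(nb, 6.5 * 3600, 21.5 * 3600))
      du <- pmax(20, rnorm(nb, p$bout_duration_s, p$bout_duration_sd_s))
      keep <- logical(nb); last_end <- -Inf
      for (b in seq_len(nb)) {
        if (st[b] >= last_end + 60) { keep[b] <- TRUE; last_end <- st[b] + du[b] }
      }
      st <- st[keep]; du <- du[keep]
      gait <- runif(length(st)) < p$walk_fraction
      for (b in seq_along(st)) {
        t0 <- (d - 1) * 86400 + st[b]
        i0 <- as.integer(floor(t0 * fs)) + 1L
        i1 <- min(n, as.integer(floor((t0 + du[b]) * fs)))
        if (i1 <= i0) next
        tt <- (seq.int(i0, i1) - 1) / fs
        if (gait[b]) {
          ns <- floor(du[b] * cadence)
          if (ns >= 1) {
            ts <- t0 + (seq_len(ns) - 1) / cadence + rnorm(ns, 0, 0.01)
            ts <- pmin(pmax(ts, t0), t0 + du[b] - w / fs)
            si <- as.integer(floor(ts * fs)) + 1L
            ii <- rep(si, each = w) + rep(seq_len(w) - 1L, times = ns)
            ok <- ii >= 1L & ii <= n
            x[ii[ok]] <- x[ii[ok]] + (rep(shape, times = ns) * (amp_g * dayf))[ok]
            # shuffling gait: cadence-locked vertical sway, anti-phased so the
            # (sub-threshold) impact peak coincides with the sway trough
            if (weak)
              x[i0:i1] <- x[i0:i1] -
                p$weak_gait_sway_g * dayf * cos(2 * pi * cadence * (tt - t0))
            z[i0:i1] <- z[i0:i1] + 0.3 * amp_g * dayf * sin(2 * pi * cadence * tt)
            step_times <- c(step_times, ts + (w / 2) / fs)
          }
        } else {
          f <- runif(1, 0.8, 1.2)
          ph <- runif(3, 0, 2 * pi)
          amp <- p$wc_osc_g * dayf * sqrt(subj)
          x[i0:i1] <- x[i0:i1] + amp * sin(2 * pi * f * tt + ph[1])
          y[i0:i1] <- y[i0:i1] + 0.7 * amp * sin(2 * pi * f * tt + ph[2])
          z[i0:i1] <- z[i0:i1] + 0.7 * amp * sin(2 * pi * 1.3 * f * tt + ph[3])
        }
        bouts[[length(bouts) + 1L]] <-
          data.frame(day = d - 1L, start_s = t0, duration_s = du[b],
                     type = if (gait[b]) "gait" else "activity")
      }
    }
    for (m in seq_len(p$missing_segments_per_day)) {
      ms <- (d - 1) * 86400 + runif(1, 17 * 3600, 20.5 * 3600)
      i0 <- as.integer(floor(ms * fs)) + 1L
      i1 <- min(n, i0 + as.integer(round(p$missing_duration_min * 60 * fs)) - 1L)
      valid[i0:i1] <- FALSE
    }
  }

  x <- 1 + x
  rec <- raw_recording(cbind(x, y, z), sampling_rate_hz = fs,
                       start_time = start_time, subject_id = subject_id,
                       valid = valid, check_finite = FALSE)
  step_times <- sort(step_times)
  step_idx <- pmin(n, pmax(1L, as.integer(floor(step_times * fs)) + 1L))
  truth_steps <- data.frame(time_s = step_times, observable = valid[step_idx])
  truth <- list(steps = truth_steps,
                bouts = if (length(bouts)) do.call(rbind, bouts)
                        else data.frame(day = integer(0), start_s = numeric(0),
                                        duration_s = numeric(0), type = character(0)),
                label = p$label,
                weak_gait = weak)
  list(recording = rec, truth = truth)
}

#' Cohort metadata table
#'
#' Expands a profile list into one metadata row per subject with a
#' reproducibly derived per-subject seed.
#'
#' @param profiles list of [subgroup_profile()] objects.
#' @param seed master seed.
#' @return data.frame with columns `subject_id, subgroup, mobility_mode,
#'   fim_mobility, seed`.
#' @export
cohort_metadata <- function(profiles = default_subgroup_profiles(), seed = 1L) {
  stopifnot(length(profiles) >= 1)
  rows <- list()
  idx <- 0L
  for (p in profiles) {
    stopifnot(inherits(p, "subgroup_profile"))
    for (j in seq_len(p$n_subjects)) {
      idx <- idx + 1L
      rows[[idx]] <- data.frame(
        subject_id = sprintf("S%03d", idx),
        subgroup = p$label,
        mobility_mode = p$mobility_mode,
        fim_mobility = p$fim_mobility,
        seed = .subject_seed(seed, idx))
    }
  }
  out <- do.call(rbind, rows)
  out$subgroup <- factor(out$subgroup, levels = subgroup_levels())
  out
}

.subject_seed <- function(master_seed, idx) {
  as.integer((as.numeric(master_seed) * 1000003 + 7919 * idx) %% 2147483647)
}

#' Generate a full cohort of recordings
#'
#' Generates one recording plus ground truth per subject.  With `dir`
#' supplied, each recording and its ground-truth step times are written as
#' delimited text and only the metadata is returned (recordings are large:
#' prefer [simulate_cohort()] when only summaries are needed).
#'
#' @param profiles list of [subgroup_profile()] objects.
#' @param seed master seed.
#' @param days,sampling_rate_hz recording length and rate per subject.
#' @param dir optional output directory for on-disk cohorts.
#' @return with `dir = NULL`, list with `metadata` and `subjects` (list of
#'   `generate_subject()` results); otherwise the metadata data.frame
#'   (invisibly) after writing the files.
#' @export
generate_cohort <- function(profiles = default_subgroup_profiles(), seed = 1L,
                            days = 2L, sampling_rate_hz = 25, dir = NULL) {
  meta <- cohort_metadata(profiles, seed)
  prof_of <- stats::setNames(
    rep(seq_along(profiles), vapply(profiles, function(p) as.integer(p$n_subjects), integer(1))),
    NULL)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (i in seq_len(nrow(meta))) {
      s <- generate_subject(profiles[[prof_of[i]]], meta$seed[i], days,
                            sampling_rate_hz, subject_id = meta$subject_id[i])
      write_recording_csv(s$recording, file.path(dir, paste0(meta$subject_id[i], ".csv")))
      data.table::fwrite(s$truth$steps,
                         file.path(dir, paste0(meta$subject_id[i], "_steps.csv")))
    }
    data.table::fwrite(meta, file.path(dir, "metadata.csv"))
    return(invisible(meta))
  }
  subjects <- lapply(seq_len(nrow(meta)), function(i)
    generate_subject(profiles[[prof_of[i]]], meta$seed[i], days,
                     sampling_rate_hz, subject_id = meta$subject_id[i]))
  list(metadata = meta, subjects = subjects)
}

#' Run the full MSDA pipeline on one recording
#'
#' Norm, moving SD, step detection, minute aggregation, ensemble averaging,
#' error exclusion and daily summary for a single subject.
#'
#' @param rec a [raw_recording()].
#' @param msda_cfg an [msda_config()].
#' @param step_cfg a [step_detector_config()].
#' @param error_threshold exclusion threshold for
#'   [apply_error_exclusion()].
#' @return list with `minutes`, `profile`, `retained`, `error_fraction`,
#'   `daily_msda`, `daily_steps` (NA when excluded) and `step_events`.
#' @export
process_recording <- function(rec,
                              msda_cfg = msda_config(),
                              step_cfg = step_detector_config(),
                              error_threshold = 0.05) {
  nrm <- acceleration_norm(rec)
  ms <- moving_sd(nrm, msda_cfg)
  ev <- detect_steps(nrm, step_cfg)
  mins <- minute_aggregate(ms, as.numeric(ev), rec, msda_cfg)
  prof <- ensemble_average(mins)
  retained <- apply_error_exclusion(prof, error_threshold)
  if (retained) {
    dsum <- daily_summary(prof)
  } else {
    dsum <- list(daily_msda = NA_real_, daily_steps = NA_real_)
  }
  list(minutes = mins, profile = prof, retained = retained,
       error_fraction = error_fraction(prof),
       daily_msda = dsum$daily_msda, daily_steps = dsum$daily_steps,
       step_events = ev)
}

#' Simulate a cohort and summarise every subject
#'
#' Generates each subject in turn, runs the full pipeline, and collects the
#' per-subject daily summaries together with the generator's ground truth,
#' discarding the raw signals as it goes (memory stays flat in cohort
#' size).
#'
#' @inheritParams generate_cohort
#' @inheritParams process_recording
#' @param progress print one line per subject.
#' @return a `subject_summary` data.frame with columns `subject_id,
#'   subgroup, mobility_mode, fim_mobility, daily_msda, daily_steps,
#'   retained, error_fraction, truth_steps_per_day, weak_gait`.
#' @export
simulate_cohort <- function(profiles = default_subgroup_profiles(), seed = 1L,
                            days = 2L, sampling_rate_hz = 25,
                            msda_cfg = msda_config(),
                            step_cfg = step_detector_config(),
                            error_threshold = 0.05,
                            progress = FALSE) {
  meta <- cohort_metadata(profiles, seed)
  prof_of <- rep(seq_along(profiles), vapply(profiles, function(p) as.integer(p$n_subjects), integer(1)))
  rows <- vector("list", nrow(meta))
  for (i in seq_len(nrow(meta))) {
    s <- generate_subject(profiles[[prof_of[i]]], meta$seed[i], days,
                          sampling_rate_hz, subject_id = meta$subject_id[i])
    res <- process_recording(s$recording, msda_cfg, step_cfg, error_threshold)
    rows[[i]] <- data.frame(
      subject_id = meta$subject_id[i],
      subgroup = as.character(meta$subgroup[i]),
      mobility_mode = meta$mobility_mode[i],
      fim_mobility = meta$fim_mobility[i],
      daily_msda = res$daily_msda,
      daily_steps = res$daily_steps,
      retained = res$retained,
      error_fraction = res$error_fraction,
      truth_steps_per_day = sum(s$truth$steps$observable) / days,
      weak_gait = s$truth$weak_gait)
    if (progress)
      message(sprintf("%s [%s] msda=%.4f steps=%.0f", meta$subject_id[i],
                      meta$subgroup[i], res$daily_msda, res$daily_steps))
  }
  out <- do.call(rbind, rows)
  out$subgroup <- factor(out$subgroup, levels = subgroup_levels())
  attr(out, "seed") <- seed
  class(out) <- c("subject_summary", "data.frame")
  out
}
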