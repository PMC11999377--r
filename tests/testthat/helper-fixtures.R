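# Shared fixtures: norm-series construction, brute-force oracles, and small
# minute-series builders.  All synthetic inputs are generated in code.

T0 <- as.POSIXct("2018-01-15 00:00:00", tz = "UTC")

`%||%` <- function(a, b) if (is.null(a)) b else a

# wrap a numeric vector as a norm_series (the declared per-sample norm type)
as_norm <- function(v, fs = 25, valid = NULL, start_time = T0) {
  if (is.null(valid)) valid <- !is.na(v)
  structure(list(values = v, valid = valid, sampling_rate_hz = fs,
                 start_time = start_time, subject_id = "fixture"),
            class = "norm_series")
}

# recording whose norm equals abs(v): v on the vertical axis, zeros elsewhere
rec_from_values <- function(v, fs = 25, valid = NULL, start_time = T0) {
  suppressMessages(raw_recording(cbind(v, 0, 0), sampling_rate_hz = fs,
                                 start_time = start_time, subject_id = "fixture",
                                 valid = valid))
}

# independent per-window SD oracle (explicit loop, no shared code path)
brute_moving_sd <- function(v, k, denom = "sample", stride = 1L) {
  n <- length(v)
  out <- rep(NA_real_, n)
  if (k > n) return(out)
  for (e in seq.int(k, n, by = stride)) {
    w <- v[(e - k + 1L):e]
    if (!anyNA(w)) {
      out[e] <- if (denom == "sample") stats::sd(w)
                else sqrt(mean((w - mean(w))^2))
    }
  }
  out
}

# minute series builder: one row per (day, minute) over full 1440-slot days
make_minutes <- function(days, msda, steps = 0, valid = TRUE) {
  grid <- expand.grid(minute = 0:1439, day = seq_len(days) - 1L)[, c("day", "minute")]
  out <- data.frame(day = grid$day, minute = grid$minute,
                    msda = rep_len(msda, nrow(grid)),
                    steps = rep_len(as.numeric(steps), nrow(grid)),
                    valid = rep_len(valid, nrow(grid)))
  out$msda[!out$valid] <- NA_real_
  out$steps[!out$valid] <- NA_real_
  class(out) <- c("minute_series", "data.frame")
  out
}

# raised-cosine impulse train on a noisy 1 g baseline (gait-like signal)
impulse_signal <- function(n_steps, cadence_hz, amp_g, noise_sd, fs = 25,
                           pad_s = 10, seed = 1) {
  set.seed(seed)
  dur <- n_steps / cadence_hz + 2 * pad_s
  n <- ceiling(dur * fs)
  v <- 1 + rnorm(n, 0, noise_sd)
  shape <- 0.5 * (1 - cos(2 * pi * (0:4) / 5))
  t_steps <- pad_s + (seq_len(n_steps) - 1) / cadence_hz
  for (t in t_steps) {
    i <- floor(t * fs) + 1L
    idx <- i:(i + 4L)
    v[idx] <- v[idx] + amp_g * shape
  }
  list(norm = as_norm(v, fs), t_steps = t_steps + 2.5 / fs)
}

# greedy 1-1 matching of detected events to truth within a tolerance
match_events <- function(detected, truth, tol = 0.25) {
  used <- logical(length(truth))
  hits <- 0L
  for (t in detected) {
    d <- abs(truth - t)
    d[used] <- Inf
    j <- which.min(d)
    if (length(j) && d[j] <= tol) { used[j] <- TRUE; hits <- hits + 1L }
  }
  hits
}

# small profile for fast generator tests
tiny_profile <- function(...) {
  args <- list(label = "FIM6-walk", n_subjects = 2, mobility_mode = "walking",
               fim_mobility = 6, bouts_per_day = 6, bout_duration_s = 120,
               bout_duration_sd_s = 20, walk_fraction = 0.7,
               gait_cadence_hz = c(1.4, 1.8), gait_impulse_g = c(0.30, 0.45),
               wc_osc_g = 0.04, rest_noise_g = 0.0028, wake_noise_g = 0.011)
  mod <- list(...)
  args[names(mod)] <- mod
  do.call(subgroup_profile, args)
}

# subgroup sizes used for repeated-seed cohort simulations: the study's
# six-subgroup structure at reduced n so multi-seed suites stay tractable
test_cohort_profiles <- function() {
  pr <- default_subgroup_profiles()
  n <- c(8L, 2L, 3L, 2L, 3L, 3L)
  for (i in seq_along(pr)) pr[[i]]$n_subjects <- n[i]
  pr
}
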