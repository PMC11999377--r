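# Transparent step detector: peak-over-adaptive-baseline on the norm with a
# refractory period and a bout filter.  The commercial firmware behind
# chest-worn activity monitors is undisclosed; this stand-in is fully
# parameterised so it can also be degraded on purpose (raised threshold) to
# emulate missed steps in slow or irregular gait.

#' Step detector configuration
#'
#' @param smoothing_window_s moving-average smoothing applied to the norm
#'   before peak picking, in seconds (default 0.2).
#' @param peak_threshold_g required height of a peak above the local
#'   baseline, in g (default 0.1).
#' @param refractory_s minimum interval between two detected steps in
#'   seconds (default 0.25).
#' @param max_step_interval_s gap beyond which a walking bout is considered
#'   ended (default 2).
#' @param min_bout_steps minimum number of consecutive peaks for a bout to
#'   be kept; shorter runs are discarded as isolated jolts, mimicking
#'   pedometer behaviour (default 4).
#' @param baseline_window_s span of the moving-median baseline (default 2).
#' @return an object of class `step_detector_config`.
#' @export
step_detector_config <- function(smoothing_window_s = 0.2,
                                 peak_threshold_g = 0.1,
                                 refractory_s = 0.25,
                                 max_step_interval_s = 2,
                                 min_bout_steps = 4L,
                                 baseline_window_s = 2) {
  stopifnot(smoothing_window_s > 0, peak_threshold_g > 0,
            refractory_s > 0, max_step_interval_s > refractory_s,
            min_bout_steps >= 1, baseline_window_s > 0)
  structure(
    list(smoothing_window_s = smoothing_window_s,
         peak_threshold_g = peak_threshold_g,
         refractory_s = refractory_s,
         max_step_interval_s = max_step_interval_s,
         min_bout_steps = as.integer(min_bout_steps),
         baseline_window_s = baseline_window_s),
    class = "step_detector_config")
}

#' Detect step events on the acceleration norm
#'
#' Smooths the norm with a short centred moving average, estimates a local
#' baseline with a 2-second moving median, and keeps local maxima exceeding
#' baseline + `peak_threshold_g`.  Candidate peaks closer than
#' `refractory_s` are pruned greedily in time order; surviving events are
#' grouped into bouts (consecutive events at most `max_step_interval_s`
#' apart) and bouts with fewer than `min_bout_steps` events are dropped.
#' Detection uses the orientation-free norm rather than a single axis, so
#' it is robust to garment placement.  Events falling in invalid segments
#' are discarded.
#'
#' @param norm a `norm_series` from [acceleration_norm()].
#' @param cfg a [step_detector_config()].
#' @return numeric vector of event times in seconds from the recording
#'   start (class `step_events`); empty on a quiet signal.
#' @export
detect_steps <- function(norm, cfg = step_detector_config()) {
  stopifnot(inherits(norm, "norm_series"), inherits(cfg, "step_detector_config"))
  v <- norm$values
  n <- length(v)
  if (n == 0L) stop("empty norm series")
  fs <- norm$sampling_rate_hz
  # fill gaps with the series median so the rolling filters stay defined;
  # events inside gaps are removed at the end
  fill <- median(v, na.rm = TRUE)
  if (!is.finite(fill)) return(structure(numeric(0), class = "step_events"))
  vf <- v
  vf[is.na(vf)] <- fill
  ks <- max(1L, as.integer(round(cfg$smoothing_window_s * fs)))
  s <- data.table::frollmean(vf, ks, align = "center")
  s[is.na(s)] <- fill
  kb <- as.integer(round(cfg$baseline_window_s * fs))
  if (kb %% 2L == 0L) kb <- kb + 1L
  kb <- min(kb, if (n %% 2L == 1L) n else n - 1L)
  b <- if (kb >= 3L) stats::runmed(s, kb, endrule = "median") else s
  thr <- b + cfg$peak_threshold_g
  if (n < 3L) return(structure(numeric(0), class = "step_events"))
  mid <- 2:(n - 1L)
  is_peak <- s[mid] > thr[mid] & s[mid] > s[mid - 1L] & s[mid] >= s[mid + 1L]
  cand <- mid[is_peak]
  cand <- cand[norm$valid[cand]]
  if (!length(cand)) return(structure(numeric(0), class = "step_events"))
  t_cand <- (cand - 1) / fs
  # greedy refractory pruning
  keep <- logical(length(t_cand))
  last <- -Inf
  for (i in seq_along(t_cand)) {
    if (t_cand[i] - last >= cfg$refractory_s) {
      keep[i] <- TRUE
      last <- t_cand[i]
    }
  }
  tt <- t_cand[keep]
  # bout filter
  if (length(tt)) {
    bout_id <- cumsum(c(1, diff(tt) > cfg$max_step_interval_s))
    sizes <- tabulate(bout_id)
    tt <- tt[sizes[bout_id] >= cfg$min_bout_steps]
  }
  structure(tt, class = "step_events")
}
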