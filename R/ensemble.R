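# 24-hour ensemble averaging of multi-day minute series, the measurement
# error exclusion rule, and per-subject daily summaries.

#' Ensemble-average minute series over days
#'
#' Fuses the minute-level data of one subject's recorded days into a single
#' 24-hour profile: for each of the 1440 minute-of-day slots, values
#' measured at the same time of day are averaged over the days on which
#' that slot is valid (e.g. the 17:00-17:01 minutes of day 1 and day 2 are
#' averaged into one 17:00 slot).  Slots valid on no day stay missing.
#' MSDA and step channels are handled identically.  The profile's
#' `error_fraction` is the fraction of the 1440 slots left empty after
#' averaging.
#'
#' @param minutes a `minute_series` data.frame (columns
#'   `day, minute, msda, steps, valid`) covering one or more days.
#' @return an `ensemble_profile` data.frame with columns
#'   `minute, msda, steps, n_days` (1440 rows) and attribute
#'   `error_fraction`.
#' @export
ensemble_average <- function(minutes) {
  stopifnot(is.data.frame(minutes),
            all(c("day", "minute", "msda", "steps", "valid") %in% names(minutes)))
  if (nrow(minutes) == 0L) stop("no minute data supplied")
  dt <- data.table::as.data.table(minutes)
  prof <- dt[, .(msda = mean(msda[valid]),
                 steps = mean(steps[valid]),
                 n_days = sum(valid)), by = minute]
  grid <- data.table::data.table(minute = 0:1439)
  prof <- merge(grid, prof, by = "minute", all.x = TRUE)
  prof[is.na(n_days), n_days := 0L]
  prof[n_days == 0L, `:=`(msda = NA_real_, steps = NA_real_)]
  out <- as.data.frame(prof)
  attr(out, "error_fraction") <- mean(out$n_days == 0L)
  attr(out, "subject_id") <- attr(minutes, "subject_id")
  class(out) <- c("ensemble_profile", "data.frame")
  out
}

#' Measurement-error fraction of an ensemble profile
#'
#' @param profile an `ensemble_profile`.
#' @return fraction in \[0, 1\] of the 1440 slots with no contributing day.
#' @export
error_fraction <- function(profile) {
  stopifnot(inherits(profile, "ensemble_profile"))
  attr(profile, "error_fraction")
}

#' Apply the measurement-error exclusion rule
#'
#' A subject's profile is retained only when its post-ensemble measurement
#' error (fraction of empty slots) is below the threshold; profiles with an
#' error of at least the threshold (default 5%, i.e. 72 of 1440 slots) are
#' excluded.  The boundary is exclusive for retention: exactly 5% error is
#' excluded.
#'
#' @param profile an `ensemble_profile`.
#' @param threshold error fraction at and above which the profile is
#'   excluded (default 0.05).
#' @return logical: `TRUE` when the profile is retained.
#' @export
apply_error_exclusion <- function(profile, threshold = 0.05) {
  error_fraction(profile) < threshold
}

#' Daily activity summary of an ensemble profile
#'
#' Collapses the 24-hour profile to a single day's figures: `daily_msda`
#' is the mean MSDA over the contributing slots; `daily_steps` is the slot
#' sum of steps rescaled by `1440 / n_contributing` so that subjects with
#' brief gaps remain comparable on a full-day scale (a gap-free profile is
#' rescaled by exactly 1).
#'
#' @param profile an `ensemble_profile` (should have passed
#'   [apply_error_exclusion()]).
#' @return list with elements `daily_msda` and `daily_steps`.
#' @export
daily_summary <- function(profile) {
  stopifnot(inherits(profile, "ensemble_profile"))
  contrib <- profile$n_days > 0L
  if (!any(contrib)) stop("no contributing slots: cannot summarise profile")
  nc <- sum(contrib)
  list(daily_msda = mean(profile$msda[contrib]),
       daily_steps = sum(profile$steps[contrib]) * 1440 / nc)
}

#' Subgroup labels used for FIM-mobility stratification
#'
#' @return character vector of the six subgroup labels in increasing order
#'   of mobility independence.
#' @export
subgroup_levels <- function() {
  c("FIM1-4", "FIM5-WC", "FIM5-walk", "FIM6-WC", "FIM6-walk", "FIM7")
}

#' Assign a subject to a FIM-mobility subgroup
#'
#' Subjects are stratified by the FIM mobility item (1 = full assistance to
#' 7 = independent) crossed with the mobility mode: FIM1-4, FIM5 and FIM6
#' split by wheelchair vs walking, and FIM7 (always walking).
#'
#' @param fim_mobility integer FIM mobility score 1-7.
#' @param mobility_mode `"walking"` or `"wheelchair"`.
#' @return factor with levels [subgroup_levels()].
#' @export
assign_subgroup <- function(fim_mobility, mobility_mode) {
  stopifnot(length(fim_mobility) == length(mobility_mode))
  fim <- as.integer(fim_mobility)
  if (any(is.na(fim) | fim < 1L | fim > 7L))
    stop("fim_mobility must be an integer in 1..7")
  mode <- as.character(mobility_mode)
  if (!all(mode %in% c("walking", "wheelchair")))
    stop("mobility_mode must be 'walking' or 'wheelchair'")
  if (any(fim == 7L & mode == "wheelchair"))
    stop("FIM mobility 7 implies independent walking; wheelchair is inconsistent")
  lab <- ifelse(fim <= 4L, "FIM1-4",
         ifelse(fim == 7L, "FIM7",
                paste0("FIM", fim, ifelse(mode == "wheelchair", "-WC", "-walk"))))
  factor(lab, levels = subgroup_levels())
}
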