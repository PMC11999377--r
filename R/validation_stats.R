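# Nonparametric validation battery: rank correlation, distribution
# diagnostics (g1, g2, Shapiro-Wilk), subgroup comparisons and the
# floor-effect metric, assembled into a validation report.

#' Spearman rank correlation coefficient
#'
#' Rank-based correlation with average ranks for ties.  Non-finite pairs
#' are dropped.
#'
#' @param x,y numeric vectors of equal length (at least 3 complete pairs).
#' @return the coefficient in \[-1, 1\]; `NA` with a warning when either
#'   input is constant.
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant input: Spearman correlation undefined")
    return(NA_real_)
  }
  stats::cor(x, y, method = "spearman")
}

#' Spearman correlation with p-value
#'
#' @inheritParams spearman_rho
#' @return list with `rho`, `p` (asymptotic, two-sided) and `n`.
#' @export
spearman_test <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L || stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = length(x)))
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(x))
}

.central_moments <- function(x, upto = 4L) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 3L) stop("need at least 3 finite observations")
  xc <- x - mean(x)
  m <- vapply(2:upto, function(k) mean(xc^k), numeric(1))
  if (m[1] <= 0) stop("zero variance: moment coefficients undefined")
  list(n = n, m2 = m[1], m3 = m[2], m4 = m[3])
}

#' Fisher-Pearson coefficient of skewness (g1)
#'
#' `g1 = m3 / m2^(3/2)` with biased central sample moments (plain `n`
#' denominators).  Zero for a normal distribution.
#'
#' @param x numeric sample, at least 3 finite values with nonzero variance.
#' @return the skewness coefficient.
#' @export
skewness_g1 <- function(x) {
  m <- .central_moments(x)
  m$m3 / m$m2^1.5
}

#' Fisher coefficient of kurtosis (g2)
#'
#' `g2 = m4 / m2^2` with biased central sample moments.  This is the
#' non-excess form: the normal reference value is 3.
#'
#' @inheritParams skewness_g1
#' @return the kurtosis coefficient (always at least 1 for a nondegenerate
#'   sample).
#' @export
kurtosis_g2 <- function(x) {
  m <- .central_moments(x)
  m$m4 / m$m2^2
}

#' Shapiro-Wilk normality test
#'
#' @param x numeric sample with 3 to 5000 finite values.
#' @return list with `statistic` (W) and `p`.
#' @export
normality_test <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 3L || length(x) > 5000L)
    stop("Shapiro-Wilk requires between 3 and 5000 observations")
  sw <- stats::shapiro.test(x)
  list(statistic = unname(sw$statistic), p = sw$p.value)
}

#' Floor-effect metric: fraction of exact zeros
#'
#' @param x numeric sample (event counts; compared to 0 exactly, no
#'   epsilon).
#' @return list with `n_zero`, `n`, `fraction` and `percent` (the fraction
#'   as a percentage rounded to 1 decimal).
#' @export
floor_effect <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 1L) stop("empty sample")
  nz <- sum(x == 0)
  list(n_zero = nz, n = length(x), fraction = nz / length(x),
       percent = round(100 * nz / length(x), 1))
}

#' Distribution diagnostics for one sample
#'
#' @param x numeric sample.
#' @return list with `n`, `skewness_g1`, `kurtosis_g2`, `normality_p` (NA
#'   when n is outside the Shapiro-Wilk range) and `zero_fraction`.
#' @export
distribution_diagnostics <- function(x) {
  x <- x[is.finite(x)]
  sw_p <- if (length(x) >= 3L && length(x) <= 5000L && stats::sd(x) > 0)
    normality_test(x)$p else NA_real_
  list(n = length(x),
       skewness_g1 = if (length(x) >= 3L && stats::sd(x) > 0) skewness_g1(x) else NA_real_,
       kurtosis_g2 = if (length(x) >= 3L && stats::sd(x) > 0) kurtosis_g2(x) else NA_real_,
       normality_p = sw_p,
       zero_fraction = mean(x == 0))
}

#' Kruskal-Wallis omnibus test with Bonferroni-adjusted pairwise follow-up
#'
#' Compares a channel of the subject summary table across the FIM-mobility
#' subgroups: Kruskal-Wallis H across all subgroups with at least 2
#' subjects, followed by two-sample Mann-Whitney U tests for every subgroup
#' pair with p-values multiplied by the number of pairs (Bonferroni, capped
#' at 1).
#'
#' @param summaries a `subject_summary` data.frame (needs `subgroup` plus
#'   the channel column).
#' @param channel `"msda"` or `"steps"` (columns `daily_msda` /
#'   `daily_steps`).
#' @return list with `channel`, `H`, `df`, `p`, `medians` (named numeric),
#'   `n_per_group` and `pairwise` (data.frame `group1, group2, p_raw,
#'   p_adj`).
#' @export
subgroup_comparison <- function(summaries, channel = c("msda", "steps")) {
  channel <- match.arg(channel)
  col <- paste0("daily_", if (channel == "msda") "msda" else "steps")
  stopifnot(is.data.frame(summaries), col %in% names(summaries),
            "subgroup" %in% names(summaries))
  d <- summaries[is.finite(summaries[[col]]), c("subgroup", col)]
  names(d) <- c("subgroup", "value")
  d$subgroup <- droplevels(factor(d$subgroup))
  sizes <- table(d$subgroup)
  small <- names(sizes)[sizes < 2L]
  if (length(small)) {
    warning("excluding subgroup(s) with fewer than 2 subjects: ",
            paste(small, collapse = ", "))
    d <- droplevels(d[!(d$subgroup %in% small), ])
  }
  if (nlevels(d$subgroup) < 2L) stop("need at least 2 subgroups with >= 2 subjects")
  kw <- stats::kruskal.test(value ~ subgroup, data = d)
  levs <- levels(d$subgroup)
  pairs <- utils::combn(levs, 2L)
  n_pairs <- ncol(pairs)
  p_raw <- vapply(seq_len(n_pairs), function(j) {
    suppressWarnings(stats::wilcox.test(
      d$value[d$subgroup == pairs[1L, j]],
      d$value[d$subgroup == pairs[2L, j]], exact = FALSE)$p.value)
  }, numeric(1))
  list(channel = channel,
       H = unname(kw$statistic),
       df = unname(kw$parameter),
       p = kw$p.value,
       medians = vapply(levs, function(l) stats::median(d$value[d$subgroup == l]),
                        numeric(1)),
       n_per_group = as.integer(sizes[levs]),
       pairwise = data.frame(group1 = pairs[1L, ], group2 = pairs[2L, ],
                             p_raw = p_raw, p_adj = pmin(1, p_raw * n_pairs)))
}

.strata_of <- function(summaries) {
  list(all = rep(TRUE, nrow(summaries)),
       walking = summaries$mobility_mode == "walking",
       wheelchair = summaries$mobility_mode == "wheelchair")
}

#' Build the full validation report
#'
#' Assembles, from a subject summary table: Spearman correlations between
#' daily MSDA and daily steps (overall and per mobility stratum, each also
#' recomputed after excluding subjects with exactly zero steps),
#' distribution diagnostics (g1, g2, Shapiro-Wilk p, zero fraction) per
#' subgroup, per stratum and overall for both channels, subgroup medians,
#' Kruskal-Wallis omnibus tests with Bonferroni-adjusted pairwise
#' comparisons for both channels, and the step-count floor-effect metric.
#' Excluded (non-retained) subjects are dropped first.
#'
#' @param summaries a `subject_summary` data.frame as returned by
#'   [simulate_cohort()] (or read from file with the same columns).
#' @return an object of class `validation_report`.
#' @export
build_report <- function(summaries) {
  stopifnot(is.data.frame(summaries), nrow(summaries) > 0,
            all(c("subgroup", "mobility_mode", "daily_msda", "daily_steps")
                %in% names(summaries)))
  if ("retained" %in% names(summaries)) {
    n_excl <- sum(!summaries$retained)
    summaries <- summaries[summaries$retained, ]
  } else n_excl <- 0L
  summaries <- summaries[is.finite(summaries$daily_msda) &
                         is.finite(summaries$daily_steps), ]
  if (nrow(summaries) == 0L) stop("no retained subjects")

  strata <- .strata_of(summaries)
  correlations <- do.call(rbind, lapply(names(strata), function(nm) {
    s <- summaries[strata[[nm]], ]
    full <- if (nrow(s) >= 3L) spearman_test(s$daily_msda, s$daily_steps)
            else { warning("stratum '", nm, "' has fewer than 3 subjects; ",
                           "correlation omitted")
                   list(rho = NA_real_, p = NA_real_, n = nrow(s)) }
    nz <- s[s$daily_steps != 0, ]
    excl <- if (nrow(nz) >= 3L) spearman_test(nz$daily_msda, nz$daily_steps)
            else list(rho = NA_real_, p = NA_real_, n = nrow(nz))
    data.frame(stratum = nm, n = full$n, rho = full$rho, p = full$p,
               n_nonzero = excl$n, rho_excl_zero = excl$rho,
               p_excl_zero = excl$p)
  }))

  groups <- c(stats::setNames(as.list(levels(factor(summaries$subgroup))),
                              levels(factor(summaries$subgroup))))
  diag_rows <- list()
  add_diag <- function(label, rows) {
    for (ch in c("msda", "steps")) {
      col <- paste0("daily_", ch)
      dg <- distribution_diagnostics(summaries[[col]][rows])
      diag_rows[[length(diag_rows) + 1L]] <<- data.frame(
        group = label, channel = ch, n = dg$n,
        kurtosis_g2 = dg$kurtosis_g2, skewness_g1 = dg$skewness_g1,
        shapiro_p = dg$normality_p, zero_fraction = dg$zero_fraction)
    }
  }
  for (g in names(groups)) add_diag(g, summaries$subgroup == g)
  add_diag("wheelchair", summaries$mobility_mode == "wheelchair")
  add_diag("walking", summaries$mobility_mode == "walking")
  add_diag("all", rep(TRUE, nrow(summaries)))
  diagnostics <- do.call(rbind, diag_rows)

  comparisons <- list(msda = subgroup_comparison(summaries, "msda"),
                      steps = subgroup_comparison(summaries, "steps"))

  structure(
    list(n = nrow(summaries), n_excluded = n_excl,
         correlations = correlations,
         diagnostics = diagnostics,
         comparisons = comparisons,
         floor = floor_effect(summaries$daily_steps)),
    class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> %d subjects (%d excluded)\n", x$n, x$n_excluded))
  cat("\nSpearman correlation, daily MSDA vs daily steps:\n")
  co <- x$correlations
  for (i in seq_len(nrow(co)))
    cat(sprintf("  %-10s n=%3d  rho=%6.3f (p=%.3g)   excl. zeros: n=%3d rho=%6.3f\n",
                co$stratum[i], co$n[i], co$rho[i], co$p[i],
                co$n_nonzero[i], co$rho_excl_zero[i]))
  cat(sprintf("\nStep-count floor effect: %d/%d subjects at zero (%.1f%%)\n",
              x$floor$n_zero, x$floor$n, x$floor$percent))
  for (ch in c("msda", "steps")) {
    cmp <- x$comparisons[[ch]]
    cat(sprintf("\nKruskal-Wallis (%s): H=%.2f, df=%d, p=%.3g; medians:\n",
                ch, cmp$H, cmp$df, cmp$p))
    md <- cmp$medians
    cat(paste(sprintf("  %-10s %s", names(md),
                      formatC(md, digits = 4, format = "fg")), collapse = "\n"), "\n")
  }
  invisible(x)
}
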