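# msdactivity

Continuous quantification of physical activity from chest-worn
accelerometry for rehabilitation populations — including wheelchair users,
for whom step counts fail.

Step counts are the standard accelerometer-based activity measure, but
they are threshold-based: slow or irregular hemiparetic gait goes
undetected, and wheelchair locomotion yields no steps at all, so a large
share of rehabilitation inpatients pile up at exactly zero (a floor
effect). The **MSDA** (moving standard deviation of trunk acceleration)
replaces the count with a continuous measure: the standard deviation of
the Euclidean norm of the triaxial trunk acceleration,

$$\mathrm{MSDA}_i = \mathrm{SD}\left(\lVert a_j \rVert : j = i-k+1, \dots, i\right),
\qquad \lVert a_j \rVert = \sqrt{x_j^2 + y_j^2 + z_j^2},$$

computed over a 2-second sliding window ($k = 50$ samples at 25 Hz),
aggregated to minute-of-day slots, ensemble-averaged over a 48-hour
recording into one 24-hour profile (slots with ≥5% post-ensemble
measurement error excluded), and reduced to a daily mean.

The package provides:

* the MSDA signal path (`acceleration_norm()`, `moving_sd()`,
  `minute_aggregate()`) with a compiled rolling-SD kernel;
* a transparent, fully parameterised step detector (`detect_steps()`) as a
  stand-in for undisclosed pedometer firmware;
* 24-hour ensemble averaging, error exclusion and daily summaries
  (`ensemble_average()`, `apply_error_exclusion()`, `daily_summary()`);
* a synthetic 48-hour trunk-accelerometry cohort generator with
  ground-truth step times, stratified into six FIM-mobility subgroups
  (`generate_subject()`, `simulate_cohort()`);
* the nonparametric validation battery (`build_report()`): Spearman
  correlations with zero-step-excluded variants, Fisher–Pearson $g_1$ and
  Fisher $g_2$ (normal references 0 and 3), Shapiro–Wilk, Kruskal–Wallis
  with Bonferroni-adjusted pairwise Mann–Whitney tests, and the
  floor-effect metric;
* delimited-text formats for every stage and a CLI
  (`inst/cli/msda.R`: `simulate`, `compute`, `ensemble`, `report`,
  `run-all`).

See the vignette `vignettes/msda-methods.Rmd` for the model, the generator
design and the numerical conventions.

## Worked example

```r
library(msdactivity)

# one moderately active walking subject, 48 h at 25 Hz, with ground truth
pr <- default_subgroup_profiles()
s  <- generate_subject(pr[["FIM6-walk"]], seed = 42, subject_id = "demo")

res <- process_recording(s$recording)
round(res$daily_msda, 4)          # 0.0126  (daily mean MSDA, g)
round(res$daily_steps)            # 5366    (ensemble-averaged steps/day)
sum(s$truth$steps$observable) / 2 # 5093.5  (scheduled steps/day, truth)
res$retained                      # TRUE    (error fraction 0 < 5%)
```

Every one of the subject's 10,187 recorded step impulses is detected with
no false positives; the daily figure differs from the raw per-day truth
because the 24-hour ensemble fills each day's bathing gap with the other
day's data, which is precisely the deficiency-compensation the
ensemble-average protocol is for. The subject's daily MSDA (~0.013 g)
lies between the typical wheelchair-user level (~0.006) and the
independent-walker level (~0.014). A full cohort with validation
statistics:

```r
summ <- simulate_cohort(default_subgroup_profiles(), seed = 1)  # 197 subjects
rep  <- build_report(summ)
rep
```

prints, among other things, the Spearman correlation between daily MSDA
and daily steps overall and per mobility stratum (strong overall, stronger
in walkers than in wheelchair users, rising when zero-step subjects are
excluded), the step-count floor-effect percentage, and the six subgroup
medians increasing along the FIM-mobility gradient.

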