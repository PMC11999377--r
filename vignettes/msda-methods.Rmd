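---
title: "MSDA: model, pipeline and synthetic validation cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MSDA: model, pipeline and synthetic validation cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The measure

Step counts quantify physical activity well in people who walk with a
regular gait, but they fail in two clinically important ways: slow or
irregular hemiparetic gait falls under the detector's acceleration
threshold, and wheelchair locomotion produces no steps at all, piling a
large share of subjects onto an exact zero (a floor effect). The MSDA —
moving standard deviation of trunk acceleration — replaces the
threshold-based count with a continuous measure of trunk movement: the
standard deviation of the Euclidean norm of chest-worn triaxial
acceleration over a short sliding window.

For samples $a_i = (x_i, y_i, z_i)$ in g (vertical, lateral,
anterior/posterior), the per-sample norm is
$\lVert a_i \rVert = \sqrt{x_i^2 + y_i^2 + z_i^2}$, and the MSDA at
position $i$ is the SD of the $k$ norm values ending at $i$. The defaults
follow the measurement protocol the package emulates: 25 Hz sampling and a
2-second window, so $k = 50$ samples. Minute-level values are the mean of
all window SDs whose window end falls in that half-open minute-of-day
slot.

Three modelling points deserve emphasis:

* **Gravity is not removed.** The norm hovers around 1 g at rest; since
  the SD is invariant to any constant offset within a window, no high-pass
  filter is applied, and the MSDA of quiet sitting equals the sensor/body
  noise level rather than zero only in the idealised noise-free case.
* **Orientation tolerance.** The norm is invariant under sensor rotation,
  so garment placement affects the measure only through real differences
  in movement. A corollary constrains the synthetic generator (below):
  with gravity dominating the vertical axis, a small purely horizontal
  oscillation of amplitude $a$ perturbs the norm only to second order
  ($\approx a^2/2$), whereas any vertical component enters linearly.
* **Window overlap and denominator are conventions.** The source protocol
  does not state whether windows overlap or which SD denominator is used.
  The package defaults to a fully sliding window (stride 1 sample) and the
  sample ($n-1$) denominator; both are configuration options
  (`stride_samples = window` gives tumbling windows,
  `sd_denominator = "population"` the $n$ form). At $k=50$ the two
  denominators differ by ~1%.

## From recording to daily summary

`acceleration_norm()` propagates invalid samples (non-finite values,
garment-off gaps) as missing; `moving_sd()` emits a window SD only where
the full window is valid. `minute_aggregate()` marks a minute slot
measured when at least `minute_min_valid_fraction` (default 0.5,
inclusive) of its samples are valid.

`ensemble_average()` implements multi-day fusion: the 1440 minute-of-day
slots are averaged across recorded days (the 17:00 minute of day 1 with
the 17:00 minute of day 2), compensating diurnal gaps on one day with data
from the other. The protocol records 48 h, i.e. two days, but any number
of days is accepted. Measurement error is operationalised *post hoc* as
the fraction of ensemble slots with no contributing day; profiles with
error $\geq$ 5% (72 of 1440 slots, boundary inclusive on the exclusion
side) are excluded. This is the simplest reading of an error rule applied
"after ensemble averaging"; the underlying device's definition is not
public.

`daily_summary()` reduces the profile to `daily_msda` (mean over
contributing slots) and `daily_steps` (slot sum rescaled by
$1440/n_{\text{contributing}}$, so subjects with brief gaps are comparable
on a full-day scale; for a gap-free profile the factor is exactly 1).
Whether the original system sums, rescales, or reads a device register is
unknown; the rescaled sum is documented as this package's convention.

## The step-detector stand-in

Commercial step-counting firmware is undisclosed, so comparisons against
step counts use a transparent stand-in (`detect_steps()`): smooth the norm
with a 0.2 s moving average, estimate a local baseline with a 2 s moving
median, accept local maxima exceeding baseline + 0.1 g, enforce a 0.25 s
refractory interval, and drop "bouts" of fewer than 4 consecutive events
within 2 s of each other (isolated jolts, as pedometers do). All five
constants are configuration, so the detector can be degraded deliberately
(e.g. a raised threshold) to study missed slow-gait steps. Equivalence
with any particular commercial counter is *not* claimed — only the
qualitative behaviour: near-perfect counts on regular supra-threshold
gait, zero on wheelchair propulsion.

## The synthetic cohort

No recordings from the emulated system are public, so validation runs on a
synthetic cohort (`generate_subject()`, `simulate_cohort()`) built to
reproduce the *structure* the validation assumes, with known ground truth:

* 48-hour recordings at 25 Hz starting at midnight; 1 g gravity on the
  vertical axis; Gaussian baseline noise with a night level
  (`rest_noise_g`, 06:00–22:00 boundary) and a higher waking level
  (`wake_noise_g`) representing sedentary trunk movement — the main dial
  of overall activity intensity, increasing monotonically across the six
  subgroups;
* active bouts scheduled by a Poisson count per day in the waking window.
  A fraction `walk_fraction` are gait bouts: a cadence-locked train of
  raised-cosine vertical impulses (width 0.2 s — wide enough that the
  smoothed peak keeps a >5σ margin over the detection threshold at default
  amplitudes) plus a cadence-frequency anterior/posterior sway; every
  impulse time is recorded as ground truth. Non-gait bouts (wheelchair
  propulsion, transfers, upper-body activity) carry 0.8–1.2 Hz oscillation
  placed mainly on the vertical axis with attenuated horizontal components
  — the placement is forced by the second-order argument above: purely
  horizontal oscillation could not move the MSDA the way real wheelchair
  activity does;
* a `weak_gait_prob` share of walking subjects have *shuffling* gait:
  their bouts carry sub-threshold impulse amplitudes plus a cadence-locked
  vertical sway (`weak_gait_sway_g`, default 0.10 g, whose smoothed peak
  stays just below the detection threshold). They move the trunk nearly as
  much as regular walkers — so their MSDA sits mid-stratum — while the
  detector counts ~0 steps. This produces zero-step walkers that are
  rank-discordant, the configuration in which excluding zero-step subjects
  raises the walking-stratum correlation; had weak gait also meant little
  trunk movement, the excluded points would be concordant and exclusion
  would lower it;
* one 30-minute missing block per day at a random evening time (bathing
  analogue), ±10% day-to-day intensity jitter, and a log-normal
  per-subject intensity factor creating within-subgroup spread;
* six subgroup profiles sized 94/23/15/19/18/28 (in FIM1-4, FIM5-WC,
  FIM5-walk, FIM6-WC, FIM6-walk, FIM7 order; 197 subjects, 136 wheelchair
  users, 61 walkers).

Amplitudes and schedules were calibrated once by a coarse grid search so
that subgroup median daily MSDA spans roughly 0.006–0.014 g and median
daily steps run from tens (dependent wheelchair users) to thousands
(independent walkers), then frozen. The generator does **not** model
biomechanically realistic gait, orientation drift, sensor bias, tremor, or
environmental variation; passing tests therefore demonstrate that the
pipeline recovers the structure it was pointed at — ordering, floor
effect, correlation contrasts — not that it would reproduce any clinical
cohort's numbers.

## Validation battery

`build_report()` assembles, per the validation design: Spearman rank
correlations between daily MSDA and daily steps (overall, walking stratum,
wheelchair stratum, each with a zero-step-excluded variant); Fisher-Pearson
skewness $g_1 = m_3/m_2^{3/2}$ and Fisher kurtosis $g_2 = m_4/m_2^2$ with
biased (plain $n$) central moments, so the normal references are 0 and 3
($g_2$ is *not* excess kurtosis); Shapiro-Wilk normality (delegated to
`stats::shapiro.test`, valid for $3 \le n \le 5000$); Kruskal-Wallis across
the six subgroups with pairwise Mann-Whitney U tests and Bonferroni
multiplication over all 15 pairs (capped at 1); and the floor-effect
metric, the percentage of *exactly* zero step counts (counts are event
tallies; no epsilon). The pairwise statistic is this package's choice —
the design names only "Bonferroni" — selected for consistency with the
rank-based omnibus test. All tests are two-sided at $\alpha = .05$.

## Numerical choices and problem sizes

* The rolling SD runs in compiled code over right-aligned full windows,
  on a series centred at its grand mean so the running-sum variance update
  stays well conditioned around the 1 g offset; negative variances from
  rounding are clamped at 0. It is tested against a brute-force per-window
  oracle at $|\Delta| < 10^{-10}$.
* Minute slots are 0-based half-open intervals; the validity threshold is
  inclusive; the error-exclusion threshold is inclusive on the exclusion
  side (exactly 5% is excluded).
* Ties in ranks use average ranks; Mann-Whitney p-values use the normal
  approximation with continuity correction (`exact = FALSE`), adequate at
  the subgroup sizes involved.
* Repeated-seed simulation suites run the six-subgroup structure at
  reduced sizes (8/2/3/2/3/3 per seed, ten seeds pooled, every generator
  parameter at its study value); the acceptance script runs the full
  197-subject cohort once. Per-subject seeds derive deterministically from
  the master seed, so every cohort is bit-reproducible.

## Known limitations

The absolute MSDA scale of the emulated hardware is unpublished; levels
here are calibrated to the reported medians, not to raw device output.
The step detector is a stand-in, not the commercial algorithm. The
night/wake noise split is a two-level approximation of circadian activity.
The error-exclusion rule is applied jointly to both channels (the design
leaves per-channel treatment open). None of the clinical headline
statistics should be read as reproduced measurements — they are
qualitative targets for a structurally faithful simulation.
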