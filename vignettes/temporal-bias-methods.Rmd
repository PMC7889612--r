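---
title: "Simulating temporal bias: models, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating temporal bias: models, calibration and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(tempbias)
```

## The problem

A case-control study compares subjects selected by a *future* outcome,
and — crucially — observes the cases at a time defined relative to that
outcome. If a biomarker or code stream evolves along a control-to-case
trajectory, anchoring the observation to the event oversamples the late
part of that trajectory. The consequences are systematic: inflated
effect sizes relative to what a prospective observer would measure,
classifiers that collapse when deployed on calendar-anchored data, and
exposure associations that depend on the arbitrary length of a lookback
window. None of these artifacts can be repaired after the fact, because
the data needed to see them (the trajectory) were never collected.

This package builds the bias in silico: every generator knows its ground
truth, so each pipeline can compare the event-indexed answer with the
prospectively valid one.

## Trajectories and start-value imputation

A case trajectory runs from a healthy-era `start` to the event-time
`end` on normalized time t ∈ [0, 1]; calendar duration is irrelevant
because only the uniform sampling fraction matters. Four families are
supported (linear, logarithmic, logistic, Heaviside), all anchored
exactly at both endpoints and non-decreasing for `start ≤ end`. Two
families need a free parameter that a two-point fit cannot identify, so
it is exposed as a knob with a fixed default: logistic steepness
`k = 10` (a visible sigmoid that still spans both endpoints) and
logarithmic curvature `k = 99` (a strongly front-loaded rise; at
`t = 0.5` the trajectory has covered `log(50.5)/log(100) ≈ 85%` of the
gap). The Heaviside step is right-continuous: the value *at* the impulse
fraction p is already `end`, reading "impulse in the first 10% of the
trajectory" as the jump completing within that fraction.

Three imputation schemes assign the unobserved `start`:

* **weighted sampling** — a draw from the control law conditional on
  falling below the case value. Implemented by inverse CDF on
  `U(0, F_ctrl(case))`, which has the same law as rejection sampling but
  bounded runtime; the equivalence is a KS test in the suite.
* **percentile matching** — the control quantile at the case law's
  percentile of the case value. Over case draws this maps the case law
  onto the control law exactly (also a KS-tested invariant).
* **percent shift** — `start = (1 − 0.15) × case value`, mirroring the
  15% control-vs-case median gap.

## The stand-in biomarker laws

The published case/control centiles behind the original analysis are not
redistributable, so the package generates stand-in tables from two
log-normal laws sharing a log-scale SD, with the control median 15%
below the case median (default case median 60 mg/dl). The only facts
preserved from the source analysis are log-normality and the median
gap; everything else is a calibration choice that we make once:

* `sigma_log = 0.25`. This keeps the baseline association in the
  modest-effect, near-linear regime where the Heaviside/percentile
  matching cells sit on the analytic `1 − p` line, and — equally
  important — keeps the *weighted-sampling* start values sane. With a
  heavy-tailed law (log-scale SD ≳ 0.3) the truncated-below-the-case
  draw is depressed so far that the mean uniform-time case observation
  falls below the control mean and the linear/logistic ratios turn
  negative, which no longer resembles the qualitative structure being
  reproduced (all attenuation ratios in (0, 1), logarithmic > linear for
  every method). At 0.25 the full 3 × 6 table has that structure, with
  weighted sampling the most aggressive imputation (linear ratio
  ≈ 0.13) and logarithmic trajectories the most conservative (ratios
  ≈ 0.65–0.81).
* Ratios are computed on the *coefficient* (log-odds) scale of a
  logistic regression of status on the raw biomarker value. The
  percentile-matching Heaviside cells equal `1 − p` on exactly this
  scale, which is what makes them reproducible without the original
  distribution tables.
* Each of the 100 repetitions refits its own baseline on the same fresh
  case-end/control draws that the prospective fit perturbs; this
  couples numerator and denominator and matches the tight intervals of
  repeated-trial summaries. The 95% interval is the empirical
  2.5th/97.5th percentile across repetitions.
* Default draws per arm are 150,000, with 20,000 used by the tests and
  the acceptance script; at 20,000 the cell means are stable to ±0.001.

## The claims cohort and the prediction-window harness

The claims generator emits one calendar year (2015, whole months) for
`n_cases` women who deliver in a month uniform over February–December
and a pool of `control_pool_factor × n_controls` women who never
deliver (the pool emulates matched selection out of a large claims
database; exact matching on age × region then keeps one control per
case, inheriting the case's delivery month as its baseline month).
Background codes arrive homogeneously all year for everyone. Gestational
codes exist only inside the gestation span (the 9 months up to and
including delivery), with a monthly Poisson rate ramping linearly from
0.1 at conception to 3 at delivery, and — the load-bearing design
choice — each gestational code is tied to a gestation *stage* and can
only be emitted within ±1 stage of it. Stage-specific signatures are
what make the collapse real: a model trained on event-indexed windows
has only ever seen the codes of one stage (the stage reached three
months before delivery), so on January data it cannot recognize cases
whose pregnancy is at any other stage, and scores October–December
deliveries (not yet pregnant, or barely, in January) as confident
controls. A cohort-trained model sees all stages during training and
spreads its weights accordingly. Without stage structure the two models
rank January features nearly identically and no monotone classifier
could reproduce the gap.

The classifier is pluggable (`(x, y) → score function`); the reference
implementation is logistic regression on the binary occurrence matrix
plus age. Sex is not a feature — the cohort is all-female by
construction. Splits are 80/20 at the patient level, performed before
any windowing so the leakage guard (no patient in both sets) holds by
construction and is still asserted every run. Event-indexed windows that
would reach into the previous calendar year (February/March deliveries
with a 3-month offset) exclude the patient from that design, with the
exclusion logged in the window table. The confusion-matrix threshold
defaults to 0.5 and is configurable.

## The longitudinal cohort and the lookback sweep

Subjects carry yearly exposures (servings/day) from a random entry year
through 2010: subject mean + AR(1) noise, truncated at zero. The event
hazard in year t is logit-linear in *that year's* exposure only
(default coefficient −0.28 per serving: protective), so the ground
truth association is wholly concentrated in the most recent year and
any longer lookback can only dilute it. Defaults
(`exposure_mean = 3`, `subject_sd = 0.1`, `innovation_sd = 1`,
`ar1_rho = 0`, `hazard_intercept = −4.3`) were calibrated once, with
two facts in mind. First, the dilution of a current-year signal in an
L-year sum decays like 1/√L only when the years are exchangeable noise;
a large stable subject-level mean or strong autocorrelation adds a
persistent component that accumulates *coherently* with L and flattens
(or even reverses) the decay, so between-subject heterogeneity is kept
small. Second, the per-lookback mean effects of a sweep share one
cohort realization across trials — with ~1,900 cases the resulting
cohort-level noise on a mean effect is about ±0.012 and does not
average out over trials — so the decay gaps must dominate that noise,
and qualitative decay assertions in the tests carry a 0.05
normalized-units allowance plus a rank-correlation check rather than a
knife-edge inequality.

A trial matches each eligible case (first event, ≥ 2 surveys through
the event year, full coverage of the lookback span) 1:1 without
replacement to an event-free control of the same sex and age at
baseline, the control's baseline year chosen so the ages agree. The
effect is the risk difference in event proportion between the top
cumulative-exposure quintile (ties at the 80th-percentile cut all go
up) and the rest, with a two-sided Welch t-test. Effects are normalized
by the same sweep's mean 1-year effect — the signed mean, so the 1-year
normalized mean is exactly 1 even for protective (negative) effects —
and Benjamini–Hochberg FDR is applied across the full
lookback × trial grid of p-values, matching a display in which every
plotted trial is one point. Null calibration (zero effect coefficient)
is checked over 400 *independent* cohort draws: trials over a single
null cohort share its case realization and their rejection rate is
cohort-conditional, not the nominal 0.05.

## Repeated measurements and selection

Each subject has a latent true level (log-normal, default log-scale SD
0.6) and `n_tests = 4` test values: true level plus zero-mean normal
noise truncated at zero, with outcome status logit-linear in the true
level (0.02 per mg/dl, ~30% prevalence). Two published summary
statistics serve as calibration targets, not inputs: the observed grand
mean of tests (49.4 mg/dl) and the observed mean within-subject sample
SD (12.2 mg/dl). Hitting them takes two corrections: the latent noise
SD is inflated by `1/c4(n_tests)` to undo the small-sample bias of the
n−1 sample SD, and the latent log-normal location is lowered by the
analytic mean inflation of truncation at zero
(`E[σ φ(x/σ) / Φ(x/σ)]` over the true-level law). Defaults land at
≈ 49.7 / 11.8.

The selection analysis reduces each subject's tests to one exposure.
The reference is a uniformly random timepoint for everyone. The biased
schemes (largest / smallest / mean) are applied to the *case*
measurements, controls keeping their random timepoint — this is the
scenario in which case values are preferentially ascertained near
extremes. Applying a reduction to both arms instead does not produce
the min < random < max coefficient ordering at all: every order
statistic has lower conditional variance than a single random draw, so
min, max and mean all *increase* the coefficient symmetrically. The
case-side mechanism yields the documented ordering (ratios ≈ 0.38 and
≈ 1.70 at default noise), and the min–max spread grows with the noise
SD.

## What the generators do and do not emulate

The generators reproduce the statistical structure the analyses need —
log-normal biomarker arms with a median gap, gestation-locked
time-varying code signatures, a recent-year-only exposure effect,
within-subject test noise — under full seeding (every generator is
bit-reproducible given a seed). They do not emulate real-data features
such as informative missingness, care-seeking intensity correlated with
outcome, measurement batch effects, coding drift, or ascertainment
bias. Passing tests therefore demonstrate that the *designs* create or
destroy the documented artifacts under known ground truth; they do not
estimate the size of those artifacts in any particular real dataset
(the restricted-data magnitudes — e.g. a 51.9%–137% selection swing —
are reproduced as orderings, never as numbers).

## Numerical notes and limitations

* Logistic fits use `glm.fit` with a convergence/ separation guard;
  perfect separation raises a typed estimation-failure error, and grid
  cells tolerate up to 10% failed repetitions before erroring.
* All randomness flows through `set.seed` on the global stream; a
  config + seed pair reproduces every CSV byte-for-byte.
* Quantile conventions: the top-quintile cut is the type-7 80th
  percentile with ties labeled high; per-subject SDs use the n−1
  denominator.
* Calendar granularity is whole months (claims) and whole survey years
  (longitudinal); months serialize as ISO `YYYY-MM`.
* The deep sequence models sometimes used on claims streams are out of
  scope; the classifier contract accepts any scoring function, and the
  logistic reference is the model family the conclusions were robust
  under.
* Problem sizes in the tests (20,000 draws per arm, 100 repetitions;
  3,000 matched pairs and 10 model repeats; 30,000 subjects, 200 trials
  per lookback; 400 null replicates) are the package's default small
  preset — large enough that every qualitative conclusion is stable
  across seeds, as the calibration notes above quantify.
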