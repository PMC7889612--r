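# tempbias

Simulation machinery for **temporal bias** in case-control study designs:
the distortion that arises when case observations are indexed to a future
event. Because the observation window tracks the event, the underlying
control-to-case trajectory is sampled unevenly — late-trajectory features
are over-weighted — so reported effect sizes are inflated, trained
classifiers collapse when deployed prospectively, and lookback-window
associations fail to replicate across window lengths. The package is
aimed at epidemiologists and ML-for-health researchers who want to
quantify, on synthetic cohorts with known ground truth, how much of an
observed association a given study design could have manufactured.

## The model

An individual progresses from a healthy (control-like) biomarker value
`start` to the value `end` observed at its event, along a trajectory on
normalized time t ∈ [0, 1]:

- linear: `f(t) = start + (end − start) t`
- logarithmic (curvature k): `f(t) = start + (end − start) log(1 + kt) / log(1 + k)`
- logistic (steepness k): a standard logistic in t, rescaled to hit both endpoints
- Heaviside step (impulse fraction p): `start` for `t < p`, `end` for `t ≥ p`

A temporally biased case-control study observes every case at t = 1; a
prospective observer samples t ~ Uniform(0, 1). For case/control biomarker
laws we use log-normal distributions with a shared log-scale SD and the
control median 15% below the case median. Each case's unobserved `start`
is imputed by one of three schemes: *weighted sampling* (a draw from the
control law truncated below the case value), *percentile matching* (the
control quantile at the case value's own percentile), or a *15% percent
shift*. The headline quantity is the **relative effect size**

    ratio = coefficient(prospective logistic fit) / coefficient(event-time logistic fit),

averaged over 100 simulated trials; 1 means no attenuation. For
percentile matching with a Heaviside trajectory the prospective case arm
is a (1−p):p mixture of the case and control laws, so in the
modest-effect regime the ratio is analytically 1 − p — a useful built-in
oracle.

Three further pipelines exercise the same bias in other guises: a claims
style delivery-prediction harness contrasting event-indexed windows
("three months before delivery") with calendar-fixed windows (January); a
lookback sweep over a longitudinal yearly-exposure cohort with
top-quintile contrasts and Benjamini–Hochberg FDR flags; and a
repeated-measurement selection analysis (largest / smallest / mean /
random test value per subject). All inputs are produced by seeded
synthetic-data generators — no external data are required.

## Worked example

```r
library(tempbias)

params <- generator_params()          # default study conditions
laws <- standin_laws(params)          # case/control log-normal pair

relative_effect_summary(
  laws$case, laws$control,
  grid = tibble::tibble(method = "percentile_matching",
                        shape = c("linear", "heaviside"),
                        shape_param = c(NA, 0.1)),
  n_reps = 20, n_per_arm = 20000, seed = 1)
#> # A tibble: 2 × 8
#>   method              shape     shape_param ratio_mean ci_lo ci_hi n_reps n_failed
#> 1 percentile_matching linear          NA         0.524 0.511 0.536     20        0
#> 2 percentile_matching heaviside        0.1       0.894 0.890 0.897     20        0
```

Under a linear trajectory, a prospectively run study would have seen only
52% of the effect size the event-indexed design reports; even an almost
instantaneous jump confined to the first 10% of the trajectory shaves off
10.6% (the analytic mixture value is 1 − 0.1 = 0.9).

```r
lc <- gen_longitudinal_cohort(generator_params(n_subjects = 10000), seed = 2)
lookback_sweep(lc, n_trials = 50, seed = 3)$summary
#> # A tibble: 4 × 5
#>   lookback_years mean_normalized_effect mean_abs_normalized_effect frac_significant
#> 1              1                  1                          1                 1
#> 2              2                  0.787                      0.787             0.98
#> 3              3                  0.717                      0.717             0.84
#> 4              4                  0.665                      0.665             0.74
```

The protective top-quintile exposure effect is strongest with a 1-year
lookback (effects normalized to that mean) and decays in both magnitude
and FDR-corrected significance as the lookback grows — two studies using
different windows would disagree about the same ground truth.

Each result object has `tidy()`/`glance()` methods and an `autoplot()`;
`run_pipeline()` (or `inst/cli/tempbias-cli.R`) drives the same stages
from a YAML/JSON config and writes CSV tables plus a JSON run summary.

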