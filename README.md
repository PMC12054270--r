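# twostagemi

Two-stage (nested) multiple imputation for a longitudinal composite health
score built from mixed continuous and binary components, when missing data
arise from **two mechanisms at once**: ignorable intermittent missingness
(MAR) and non-ignorable non-attendance (MNAR), with optional truncation by
death. The package is aimed at biostatisticians and epidemiologists analysing
repeated-exam cohort data — the motivating setting is a five-component
cardiovascular health score (smoking, BMI, blood pressure, cholesterol,
glucose; score 0–5, higher = healthier) measured every five years.

## The method

The composite at each exam is `C_it = Σ_p D_it^p`, where `D_it^p` indicates
that component `p` is at its ideal level. Components (never the score) are
imputed in two nested stages:

1. **Stage 1** imputes the MNAR cells `m` times by chained equations (FCS)
   under a working MAR assumption, then converts each draw to its
   non-ignorable counterpart with a sensitivity parameter `k`:
   continuous components are scaled, `y_nonignr = k_cont · y_ignr`;
   the binary component's imputation probability is shifted on the odds
   scale, `logit(π_nonignr) = log(k_bin) + logit(π_ignr)`.
2. **Stage 2** imputes the MAR cells `n` times within each Stage-1 dataset,
   treating the Stage-1 values as fixed — giving `m × n` completed datasets
   with block structure.

Estimates `Q̂^(j,k)` with complete-data variances `U^(j,k)` are pooled with
the two-stage combining rules:

    Q̄ = mean(Q̂),   T = Ū + (1 + 1/m)·B + (1 − 1/n)·W
    1/ν* = [(1+1/m)B/T]²/(m−1) + [(1−1/n)W/T]²/(m(n−1))

where `B` is the between-block variance of the Stage-1 block means and `W`
the average within-block variance; inference uses `(Q − Q̄)/√T ~ t_ν*`.

Three FCS predictor structures are provided (longitudinal `LFCS`,
cross-sectional `XFCS`, combined `AFCS`), three analysis models (per-exam
means, random-intercept mixed-model slope, time-varying Cox hazard ratio for
mortality), complete-case and LOCF comparators, and a full synthetic-cohort
generator (multivariate-normal components, calibrated logistic MAR
missingness, percentile-rule MNAR non-attendance, piecewise-exponential death
times) driving a reproducible simulation study.

## Worked example

```r
library(twostagemi)

spec  <- default_cohort_spec(1000, seed = 42)   # 6 variables x 5 exams
panel <- generate_full_panel(spec)

# missingness: MAR items/waves in one half, MNAR lower-tail dropout in the other
mask <- merge_masks(
  generate_mnar_nonattendance(panel, mnar_scenario(1), seed = 43),
  generate_mar_missingness(panel, seed = 44))

# nested two-stage MI under "non-attendees were 10% less healthy" (k = 1.1)
stack <- run_two_stage(panel, mask, fcs_config("LFCS"),
                       ignorability(1.1), m = 5, n = 5, seed = 45)

pool_replicate(est_mean_by_time(times = 2:5), stack)
```

```
#> # A tibble: 4 × 11
#>   parameter q_bar   u_bar  b_between  w_within t_total     df ci_low ci_high     m     n
#> 1 mean_t2    2.25 0.00134 0.00000954 0.0000129 0.00136 48666.   2.18    2.33     5     5
#> 2 mean_t3    2.09 0.00117 0.00000439 0.0000153 0.00118 97097.   2.03    2.16     5     5
#> 3 mean_t4    1.94 0.00115 0.00000889 0.0000169 0.00118 36701.   1.87    2.01     5     5
#> 4 mean_t5    1.84 0.00112 0.0000806  0.0000459 0.00125   651.   1.77    1.91     5     5
```

Each row pools one per-exam mean of the composite over the 25 completed
datasets: `q_bar` is the pooled mean score at that exam, `u_bar` the average
complete-data variance, `b_between`/`w_within` the two imputation-variance
components, and the interval uses the `t` reference on `df` degrees of
freedom. The score declines from about 2.25 to 1.84 over follow-up; on this
cohort the complete-data means are 2.23–1.80, so the MNAR adjustment
(`k_cont = 1.1`, paired odds ratio `k_bin = 2` for smoking) tracks the truth
even though the least healthy subjects are the ones missing exams.

For mortality, generate event times, truncate after death, impute in Cox
mode, and pool the time-varying Cox log hazard ratio:

```r
events <- generate_event_times(panel, survival_spec(), seed = 46)
mask_d <- truncate_after_event(mask, events, panel$time_grid)
stack  <- run_two_stage(panel, mask_d, fcs_config("LFCS", cox_mode = TRUE),
                        ignorability(1.1), m = 5, n = 5, seed = 47,
                        events = events)
pool_replicate(est_cox(events), stack)
#> # A tibble: 1 × 11
#>   parameter  q_bar   u_bar b_between  w_within t_total     df ci_low ci_high     m     n
#> 1 log_hr    -0.244 0.00233 0.0000350 0.0000629 0.00242 10345. -0.340  -0.147     5     5
```

`exp(-0.244) ≈ 0.78`: on this single simulated cohort each additional ideal
component is associated with a roughly 22% lower mortality hazard, and the
pooled interval comfortably covers the generating truth
`log(0.85) ≈ -0.163`. (Single-cohort estimates scatter around the truth; the
simulation study below averages over many replicates.)

A full simulation study over the sensitivity grid
(`k ∈ {0.8, 0.9, 1, 1.1, 1.2}`), the three FCS structures and the
comparators is one call:

```r
res <- run_simulation_study(desk_study_config(analyses = "mean"))
autoplot(res, metric = "bias")
```

A thin command-line front end over the same functions ships in
`inst/cli/twostagemi-cli.R` (subcommands `simulate`, `impute`, `pool`,
`analyze`, `truth`, `study`).

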