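---
title: "Two-stage multiple imputation for a longitudinal composite score: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage multiple imputation for a longitudinal composite score: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twostagemi)
```

## The problem

Longitudinal cohort studies often summarize several measured variables into a
single composite health score. In the cardiovascular setting the score used
throughout this package counts, at each exam, how many of five components sit
at their ideal level: non-smoking, BMI below 25 kg/m², blood pressure below
120/80 mmHg (systolic **and** diastolic), total cholesterol below 200 mg/dL and
fasting glucose below 100 mg/dL. The score `C` ranges over 0–5; higher is
better cardiovascular health.

Missing data in such cohorts arise from more than one mechanism at once.
Intermittent item- or wave-level missingness is plausibly *missing at random*
(MAR): it can be predicted from observed data. Dropout, in contrast, is often
*missing not at random* (MNAR) — people in declining health stop attending
exams, so the missingness depends on the very values that are missing. After
death, all later exams are structurally missing. Treating everything as MAR,
or analysing complete cases, biases the three quantities an epidemiologist
typically wants from such a score: its mean at each exam, its slope over time,
and its hazard ratio for mortality.

## The two-stage (nested) imputation procedure

The package imputes the *components* (never the score directly) in two nested
stages:

1. **Stage 1 — non-ignorable cells.** The MNAR cells are imputed `m` times by
   chained equations under a working MAR assumption, then each imputed value is
   transformed to its non-ignorable counterpart through a sensitivity
   parameter `k`:
   * continuous components: `y_nonignr = k_cont * y_ignr` (so `k_cont = 1.2`
     makes the imputed values 20% larger, pushing the composite down);
   * the binary component: `logit(pi_nonignr) = log(k_bin) + logit(pi_ignr)`,
     an odds-ratio shift followed by a fresh Bernoulli draw.
2. **Stage 2 — ignorable cells.** Within each Stage-1 dataset, the MAR cells
   are imputed `n` times treating the Stage-1 values as fixed and known,
   giving `m × n` completed datasets with a block (nested) dependence
   structure.

Each completed dataset is scored and analysed; the estimates are pooled with
the two-stage combining rules. Writing `Q^(j,k)` and `U^(j,k)` for the
estimate and its complete-data variance on dataset `(j, k)`:

* point estimate `Qbar = mean(Q)`,
* `T = Ubar + (1 + 1/m) B + (1 - 1/n) W`, with `B` the variance of the
  Stage-1 block means and `W` the average within-block variance,
* reference distribution `t` with
  `1/df = ((1+1/m)B/T)^2/(m-1) + ((1-1/n)W/T)^2/(m(n-1))`.

When both squared terms vanish (`B = W = 0`) the formula is undefined; the
package uses the normal reference there, and flags a fully degenerate
`T = 0` with a zero-width interval. These limits are deliberate design
choices, as is the absence of any small-sample adjustment on top of the `t`
reference.

The default sensitivity grid pairs `k_cont` ∈ {0.8, 0.9, 1, 1.1, 1.2} with
`k_bin` ∈ {0.5, 0.5, 1, 2, 2}: values above 1 encode "non-attendees were in
worse health than their history suggests", below 1 the reverse, and 1 is the
MAR assumption. With lower-tail dropout the appropriate direction is
`k_cont > 1`; the misspecified direction overshoots the composite upward.

### Why the MNAR cells are imputed first, over the full pattern

Chained equations need complete predictors, so Stage 1 runs the cycler over
the *full* missingness pattern and retains only the MNAR-cell draws (the MAR
draws from that pass are discarded and re-imputed in Stage 2). The
alternative — pattern-specific models using only observed predictors — is
fragile when many missingness patterns coexist, which is exactly the
longitudinal situation this package targets.

Post-death cells are imputed in Stage 1 and then held fixed: every cell must
be "known" before Stage 2, and the framework generalizes to non-terminal
events where post-event values are meaningful. They are *not* k-transformed
by default (the sensitivity transform is specified for dropout, not death;
a switch exists) and they never enter the Cox risk set.

## The chained-equations engine

Every component at every time point is a distinct variable, visited in column
order (times within variable). Three predictor structures are supported for
the imputation model of component `p` at time `t`:

* **LFCS** (longitudinal): the same component at all other times;
* **XFCS** (cross-sectional): the other components at time `t`;
* **AFCS** (all): both sets.

Every model additionally includes baseline age and sex, and — when the target
analysis is the Cox model — the death indicator and the Nelson–Aalen
cumulative null hazard at each subject's follow-up end, the standard survival
auxiliaries that keep imputations compatible with the event process. A
variable never predicts itself at the same time point (zero diagonal).

Elementary draws:

* continuous — bootstrap linear regression by default (resample, refit,
  impute with the resampled coefficients plus residual-SD noise); the
  conjugate Bayesian draw (`sigma*² ~` scaled inverse-χ²,
  `beta* ~ N(betahat, sigma*²(X'X)^-1)`) is available and distributionally
  equivalent at realistic sizes, which the test suite checks by a
  Kolmogorov–Smirnov comparison. The bootstrap is the default for its lower
  cost at scale.
* binary — approximate-Bayesian logistic regression: maximum-likelihood fit,
  coefficient perturbation from the asymptotic normal, Bernoulli draw.

Numerical safeguards: singular bootstrap designs are redrawn up to 10 times
and then fitted with an escalating diagonal ridge; logistic separation falls
back to a weak ridge penalty; a single observed class imputes the constant
class (with a warning at the user surface, an error in the binary
k-transform where the logit shift would be undefined). IRLS iterates to a
step tolerance of 1e-6 (warm-started across cycles), and the missing cells
are initialized by sampling observed values of the same variable. Five
chained cycles are the default burn-in — the conventional choice for chained
equations; with zero cycles the documented output is the initial random
fill. The engine's hot loop is compiled (RcppArmadillo) and consumes R's RNG
stream, so a single seed fixes the whole nested run.

The regressor set for the binary k-transform's logistic fit is not dictated
by the method itself; the package uses the same predictor row the FCS engine
uses for that variable, which keeps the shift model and the imputation model
aligned. This is a documented default, not the only defensible choice.

## The analysis models

* **Means**: per-exam mean of the composite with complete-data variance
  `s²/N`.
* **Slope**: random-intercept linear mixed model
  `C_it = b0 + b1·time + b2'X_i + u_i + e_it`, fitted by maximum likelihood
  (ML rather than REML so fits on different imputed datasets are directly
  comparable), time in years.
* **Hazard ratio**: Cox model with the composite as a time-varying covariate
  in counting-process form — each exam value is carried forward across the
  following interval, episodes end at death or administrative censoring, and
  post-death episodes never enter the risk set even though their cells were
  imputed.

## What the synthetic cohort emulates

`default_cohort_spec()` fixes the study conditions: six variables (smoking
status plus five continuous measurements) at five exams spaced five years
apart, drawn jointly multivariate normal with

* non-decreasing means per variable (ageing cohort; e.g. SBP 125 → 141 mmHg,
  glucose 98 → 110 mg/dL over 20 years),
* exchangeable within-variable correlation 0.7 across exams (moderate-to-high
  tracking of risk factors),
* correlation 0.15 between different variables and with the covariates (low
  cross-sectional dependence),
* smoking prevalence drifting from 15% to 19% on a latent-threshold scale,
* baseline age ~ N(55, 9²) years and 45% male, included in the joint draw.

These values were chosen once as realistic mid-life cohort values consistent
with the structure just described; with the default ideal-level cut-offs they
give a population composite mean declining from about 2.45 to about 1.80
across the five exams. The missingness machinery then emulates a cohort
where:

* half the subjects are exposed to MAR missingness — logistic models on
  baseline values, baseline composite, age and sex generate item-level
  missingness in two components (BMI and cholesterol by default; the choice
  of components is configurable) and whole-wave non-attendance, with
  intercepts calibrated per wave so the expected rates hit 5/3/8/9% (items)
  and 5/4/8/11% (waves) at exams 2–5;
* the other half is exposed to MNAR non-attendance: at each exam, subjects
  whose current composite falls in a scheduled tail (10/15/20/25% at exams
  2–5; lower tail, upper tail, or both, for scenarios 1–3) miss the whole
  exam with probability 0.8. Because the composite is integer-valued, tail
  membership is decided by exact-fraction ranking with uniform tie-breaking
  rather than a naive quantile threshold, which would overshoot on ties.
  A rate-calibrated mode is also provided in which the selected fraction is
  scaled so the realized non-attendance rate matches a user-supplied
  schedule; the rule-based mode is the default.
* death times are piecewise exponential over the five 5-year intervals with
  the true composite at each interval start entering at log hazard ratio
  log(0.85) per unit, age at log(1.06)/year, male sex at log(1.4), and
  baseline interval hazards (0.012, 0.017, 0.022, 0.028, 0.035) per year,
  calibrated once so that roughly 40% of subjects die within 25 years of
  follow-up. Exams after death are relabelled as post-death missingness.

Scenario 3 applies the full percentile schedule to each tail independently;
whether the schedule should be split between tails is genuinely open, and
the chosen reading is the more aggressive one. Tail ranks are computed
within the MNAR half (not the whole cohort), another documented choice.

What the generator does **not** emulate: irregular visit spacing, more than
one binary component, competing risks, monotone dropout *patterns* (each
exam's non-attendance is drawn separately, so intermittent return is
possible), and real-cohort features such as measurement error drift or
treatment effects on thresholds. Passing tests on these synthetic cohorts
therefore demonstrate correctness of the machinery and behaviour of the
estimators under the stated mechanisms — not performance on any particular
real cohort, where richer dropout patterns reduce the longitudinal
information the LFCS/AFCS structures rely on.

## Reproducibility and problem sizes

One master seed expands into per-replicate, per-stage, per-imputation
sub-streams through a counter-based derivation, so any replicate can be
re-run in isolation and sensitivity settings share their Stage-1 ignorable
draws: under a shared seed, the continuous MNAR cells at `k` and at 1 differ
by exactly the factor `k` — an identity the test suite asserts — and the
whole study is bitwise reproducible from its seed.

Two presets ship with the package. The full-scale preset mirrors the design
the methodology was developed at (3700 subjects, 500 replicates,
`m = n = 5`, truth from a 10⁶ population). The desk-scale preset — 1000
subjects, 100 replicates, `m = n = 3`, truth from a 10⁵ population — is the
package's choice for interactive work, the bundled acceptance script and the
heavier tests; it keeps a full Scenario-1 study (all three FCS structures,
the five-point sensitivity grid, comparators, means and Cox analyses) within
tens of minutes on a single core. Monte-Carlo standard errors accompany every
bias and coverage figure so that checks against reference values can be made
at a principled tolerance; at desk scale the standard error of a coverage
estimate near 95% is about 2.2 points, and estimator contrasts that depend on
the cohort size (for instance coverage collapse under a misspecified
assumption, which requires bias to be large relative to a standard error
that shrinks with √N) are systematically milder than at full scale.

## Known limitations

* The sensitivity parameter is a constant multiplier; a stochastic `k`
  (three-stage imputation) and selection- or pattern-mixture-model Stage-1
  alternatives are out of scope.
* Rates of missing information are not computed.
* The composite is scored only when every component is determinable; no
  partial scoring is offered (deliberately — passive imputation of the score
  conflates distinct component values).
* The mixed model uses a random intercept only; random slopes are not
  fitted.
* With `m = n` small (2–3) the degrees-of-freedom formula can be very small
  when between-block variance dominates; intervals are then wide rather than
  anti-conservative, which is the intended behaviour of the combining rules.
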