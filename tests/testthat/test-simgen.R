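test_that("dichotomization matches rank arithmetic and the normal quantile", {
  out <- dichotomize_at_quantile(1:10, 0.2)
  expect_equal(sum(out), 2)
  expect_equal(which(out == 1L), c(9L, 10L))

  sym <- c(-(5:1), 1:5)
  expect_equal(mean(dichotomize_at_quantile(sym, 0.5)), 0.5)

  set.seed(11)
  z <- rnorm(10000)
  out <- dichotomize_at_quantile(z, 0.3)
  thr <- min(z[out == 1L])
  expect_lt(abs(thr - qnorm(0.7)), 0.05)

  expect_error(dichotomize_at_quantile(rep(1, 5), 0.3), "constant")
  expect_error(dichotomize_at_quantile(1:5, 1.2), "target_rate")
})

test_that("the joint draw honours means, prevalences and independence", {
  n <- 10000
  spec <- default_cohort_spec(n, seed = 1)
  # independence case: within/between correlations zero
  spec0 <- cohort_spec(n, means = spec$means, sds = spec$sds,
                       within_corr = setNames(rep(0, 6), spec$component_names),
                       between_corr = 0,
                       binary_targets = rbind(SMK = rep(0.2, 5)), seed = 3)
  p0 <- generate_full_panel(spec0)
  vals <- twostagemi:::panel_values(p0)
  cont <- vals[, c("BMI_1", "SBP_1", "TC_3", "BG_5", "DBP_2")]
  cc <- cor(cont)
  mc_se <- 1 / sqrt(n)
  expect_true(all(abs(cc[upper.tri(cc)]) < 3 * mc_se))

  # per-variable per-time means recover the generating parameters
  p1 <- generate_full_panel(spec)
  v1 <- twostagemi:::panel_values(p1)
  for (v in c("BMI", "SBP", "TC")) {
    for (t in c(1, 3, 5)) {
      mu <- spec$means[v, t]; sdv <- spec$sds[v, t]
      expect_lt(abs(mean(v1[, paste(v, t, sep = "_")]) - mu),
                3 * sdv / sqrt(n))
    }
  }

  # binomial sampling bound on smoking prevalence at target 0.2
  smk <- v1 <- twostagemi:::panel_values(p0)[, paste0("SMK_", 1:5)]
  expect_true(all(abs(colMeans(smk) - 0.2) < 3 * sqrt(0.2 * 0.8 / n) + 1 / n))
})

test_that("a non-positive-definite correlation request fails loudly", {
  spec <- default_cohort_spec(100)
  # between-variable correlation far above the within-variable one is
  # internally inconsistent and cannot form a correlation matrix
  expect_error(
    cohort_spec(100, means = spec$means, sds = spec$sds,
                within_corr = setNames(rep(0, 6), spec$component_names),
                between_corr = 0.9,
                binary_targets = spec$binary_targets),
    "positive definite")
})

test_that("MAR missingness rates follow the logistic models", {
  n <- 20000
  panel <- generate_full_panel(default_cohort_spec(n, seed = 4))
  g <- panel$data$miss_group == "MAR"

  # degenerate intercepts produce no missingness at all
  coefs_none <- default_mar_coefs(
    item = list(slopes = c(value = 0, composite = 0, age = 0, sex = 0),
                intercepts = rep(-50, 4)),
    wave = list(slopes = c(value = 0, composite = 0, age = 0, sex = 0),
                intercepts = rep(-50, 4)))
  m0 <- generate_mar_missingness(panel, coefs_none, seed = 5)
  expect_equal(sum(m0$mech), 0L)

  # intercept-only model at 5%: per-time item rate within 3 binomial SEs
  coefs_flat <- default_mar_coefs(
    item = list(slopes = c(value = 0, composite = 0, age = 0, sex = 0),
                intercepts = rep(qlogis(0.05), 4)),
    wave = list(slopes = c(value = 0, composite = 0, age = 0, sex = 0),
                intercepts = rep(-50, 4)))
  m1 <- generate_mar_missingness(panel, coefs_flat, seed = 6)
  se <- sqrt(0.05 * 0.95 / sum(g))
  for (t in 2:5) {
    rate <- mean(m1$mech[g, paste0("BMI_", t)] == 2L)
    expect_lt(abs(rate - 0.05), 3 * se)
  }

  # calibrated defaults approximate the target item / non-attendance rates
  m2 <- generate_mar_missingness(panel, seed = 7)
  items <- c(0.05, 0.03, 0.08, 0.09); waves <- c(0.05, 0.04, 0.08, 0.11)
  for (t in 2:5) {
    cols <- paste(panel$vars, t, sep = "_")
    wave_rate <- mean(rowSums(m2$mech[g, cols] == 2L) == 6L)
    expect_lt(abs(wave_rate - waves[t - 1]),
              3 * sqrt(waves[t - 1] * (1 - waves[t - 1]) / sum(g)))
  }
  expect_error(
    generate_mar_missingness(panel, default_mar_coefs(item_components = "XX")),
    "unknown components")
  # MAR cells only in the MAR half, never at time 1
  expect_true(all(m2$mech[!g, ] == 0L))
  expect_true(all(m2$mech[, paste(panel$vars, 1, sep = "_")] == 0L))
})

test_that("MNAR non-attendance hits the scheduled tail fractions", {
  n <- 20000
  panel <- generate_full_panel(default_cohort_spec(n, seed = 8))
  g <- panel$data$miss_group == "MNAR"

  expect_equal(sum(generate_mnar_nonattendance(
    panel, mnar_scenario(1, nonattend_prob = 0), seed = 9)$mech), 0L)

  mk <- generate_mnar_nonattendance(panel, mnar_scenario(1), seed = 10)
  targets <- c(0.10, 0.15, 0.20, 0.25) * 0.8
  for (t in 2:5) {
    cols <- paste(panel$vars, t, sep = "_")
    rate <- mean(rowSums(mk$mech[g, cols] == 1L) == 6L)
    expect_lt(abs(rate - targets[t - 1]),
              3 * sqrt(targets[t - 1] * (1 - targets[t - 1]) / sum(g)))
  }
  expect_true(all(mk$mech[!g, ] == 0L))

  # scenario 3: every flagged subject sits in one of the scheduled tails
  mk3 <- generate_mnar_nonattendance(panel, mnar_scenario(3), seed = 11)
  comp <- build_composite(panel)$scores
  gi <- which(g)
  for (t in 2:5) {
    flagged <- which(mk3$mech[, paste0("BMI_", t)] == 1L)
    frac <- mnar_scenario(3)$percentile_schedule[t - 1]
    lo <- quantile(comp[gi, t], frac + 0.03)
    hi <- quantile(comp[gi, t], 1 - frac - 0.03)
    expect_true(all(comp[flagged, t] <= lo | comp[flagged, t] >= hi))
  }

  expect_error(
    generate_mnar_nonattendance(panel,
                                mnar_scenario(1, percentile_schedule = c(0.1))),
    "n_times - 1")
})

test_that("event times follow the piecewise-exponential model", {
  n <- 20000
  spec <- default_cohort_spec(n, seed = 12)
  panel <- generate_full_panel(spec)

  # null composite/covariate effects, single 5-year interval: closed-form CDF
  surv0 <- survival_spec(interval_hazards = rep(0.03, 5), log_hr_truth = 0,
                         covariate_log_hrs = c(age = 0, sex = 0))
  ev0 <- generate_event_times(panel, surv0, seed = 999)
  frac5 <- mean(ev0$event_time < 5)
  expected <- 1 - exp(-0.03 * 5)
  expect_lt(abs(frac5 - expected), 3 * sqrt(expected * (1 - expected) / n))

  # Kaplan-Meier at interval boundaries matches the survivor function
  # (no censoring before administrative end, so the binomial bound applies)
  km <- survival::survfit(survival::Surv(ev0$event_time,
                                         ev0$event_indicator) ~ 1)
  for (tt in c(5, 10, 20)) {
    i <- max(which(km$time <= tt))
    s_true <- exp(-0.03 * tt)
    expect_lt(abs(km$surv[i] - s_true),
              3 * sqrt(s_true * (1 - s_true) / n))
  }

  # calibrated defaults give roughly 40% cumulative mortality
  ev <- generate_event_times(panel, survival_spec(), seed = 14)
  expect_gt(mean(ev$event_indicator), 0.34)
  expect_lt(mean(ev$event_indicator), 0.46)
  expect_true(all(ev$event_time <= 25))
  expect_true(all(ev$event_time[ev$event_indicator == 0] == 25))

  expect_error(survival_spec(interval_hazards = c(-1, 1, 1, 1, 1)), "positive")
})

test_that("post-death truncation marks exactly the later exams", {
  cohort <- small_cohort(50, seed = 15)
  ev <- tibble::tibble(subject_id = 1:50, event_time = rep(25, 50),
                       event_indicator = 0L)
  attr(ev, "admin_censor_time") <- 25
  m <- truncate_after_event(cohort$mask, ev, cohort$panel$time_grid)
  expect_equal(sum(m$mech == 3L), 0L)

  ev$event_time[1] <- 7.2; ev$event_indicator[1] <- 1L # dies in interval 2
  m <- truncate_after_event(cohort$mask, ev, cohort$panel$time_grid)
  dead_cols <- paste(cohort$panel$vars, rep(3:5, each = 6), sep = "_")
  expect_true(all(m$mech[1, dead_cols] == 3L))
  alive_cols <- paste(cohort$panel$vars, rep(1:2, each = 6), sep = "_")
  expect_true(all(m$mech[1, alive_cols] != 3L))

  m2 <- truncate_after_event(m, ev, cohort$panel$time_grid)
  expect_identical(m$mech, m2$mech)
})
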