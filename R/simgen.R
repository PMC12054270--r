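#' Generate a complete synthetic cohort panel
#'
#' Draws all variable-by-time values jointly from a multivariate normal with
#' the block correlation structure assembled from the spec (exchangeable
#' within-variable correlation across time points, a common between-variable
#' correlation, baseline covariates included in the joint draw). Binary
#' variables and the binary covariate are produced by dichotomizing their
#' latent normal draws at the empirical quantile matching the target
#' prevalence ([dichotomize_at_quantile()]).
#'
#' Each subject is also assigned to one of two equal halves of the cohort
#' (`miss_group` of `"MAR"` or `"MNAR"`): the missingness generators each act
#' on one half only.
#'
#' @param spec A [cohort_spec()].
#' @param seed RNG seed; defaults to the seed stored in the spec.
#' @return A `component_panel`.
#' @export
generate_full_panel <- function(spec, seed = spec$seed) {
  with_seed(seed, {
    lat <- assemble_latent_corr(spec)
    n <- spec$n_subjects
    Z <- matrix(rnorm(n * length(lat$cols)), nrow = n) %*% lat$chol
    colnames(Z) <- lat$cols

    out <- matrix(NA_real_, n, length(lat$cols) - 2,
                  dimnames = list(NULL, head(lat$cols, -2)))
    for (v in spec$component_names) {
      for (t in seq_len(spec$n_times)) {
        cn <- paste(v, t, sep = "_")
        if (v %in% spec$binary_components) {
          out[, cn] <- dichotomize_at_quantile(Z[, cn],
                                               spec$binary_targets[v, t])
        } else {
          out[, cn] <- spec$means[v, t] + spec$sds[v, t] * Z[, cn]
        }
      }
    }
    age <- spec$covariate_spec$age_mean + spec$covariate_spec$age_sd * Z[, "age"]
    sex <- dichotomize_at_quantile(Z[, "sex"], spec$covariate_spec$sex_prevalence)
    grp <- rep("MNAR", n)
    grp[sample.int(n, floor(n / 2))] <- "MAR"

    data <- tibble(subject_id = seq_len(n), miss_group = grp,
                   age = age, sex = sex) %>%
      dplyr::bind_cols(as_tibble(out))
    new_component_panel(data, spec)
  })
}

#' Dichotomize a latent vector at a target rate
#'
#' Returns 1 for the `round(target_rate * n)` largest values, so the observed
#' proportion of ones equals the target up to rank granularity. The implied
#' threshold is the empirical `1 - target_rate` quantile.
#'
#' @param latent Numeric vector (must not be constant).
#' @param target_rate Target proportion of ones, strictly in (0, 1).
#' @return An integer 0/1 vector.
#' @export
dichotomize_at_quantile <- function(latent, target_rate) {
  assert_that(target_rate > 0 && target_rate < 1,
              "`target_rate` must lie strictly in (0, 1)")
  if (max(latent) == min(latent)) {
    abort("cannot dichotomize a constant vector: the quantile threshold is undefined")
  }
  n <- length(latent)
  k <- max(1L, round(target_rate * n))
  out <- integer(n)
  out[order(latent, decreasing = TRUE)[seq_len(k)]] <- 1L
  out
}

# ---------------------------------------------------------------------------
# Missingness masks

MECH_OBS <- 0L; MECH_A <- 1L; MECH_B <- 2L; MECH_D <- 3L
mech_labels <- c("OBS", "A_MNAR", "B_MAR", "D_DEATH")

new_missing_mask <- function(mech, subject_id) {
  structure(list(mech = mech, subject_id = subject_id), class = "missing_mask")
}

empty_mask <- function(panel) {
  mech <- matrix(MECH_OBS, nrow(panel$data), length(vt_cols(panel)),
                 dimnames = list(NULL, vt_cols(panel)))
  new_missing_mask(mech, panel$data$subject_id)
}

#' @export
print.missing_mask <- function(x, ...) {
  tab <- table(factor(mech_labels[x$mech + 1L], levels = mech_labels))
  cat("<missing_mask> ", nrow(x$mech), " subjects x ", ncol(x$mech),
      " variable-time cells\n  ", sep = "")
  cat(paste(names(tab), tab, sep = ": ", collapse = ", "), "\n")
  invisible(x)
}

#' Convert a missingness mask to a long tibble
#'
#' @param x A `missing_mask`.
#' @param ... Unused.
#' @return A tibble with `subject_id`, `time`, `variable`, `mechanism`.
#' @export
as_tibble.missing_mask <- function(x, ...) {
  cn <- colnames(x$mech)
  tibble(subject_id = rep(x$subject_id, times = length(cn)),
         variable = rep(sub("_[0-9]+$", "", cn), each = length(x$subject_id)),
         time = rep(as.integer(sub("^.*_", "", cn)),
                    each = length(x$subject_id)),
         mechanism = mech_labels[as.vector(x$mech) + 1L]) %>%
    arrange(.data$subject_id, .data$time, .data$variable)
}

#' Merge two masks with disjoint assignments
#'
#' Combines mechanism labels cell-wise; a cell may carry at most one of the
#' MNAR and MAR labels (they act on disjoint halves of the cohort).
#'
#' @param a,b `missing_mask` objects over the same layout.
#' @return A `missing_mask`.
#' @export
merge_masks <- function(a, b) {
  assert_that(identical(dim(a$mech), dim(b$mech)),
              "masks must share the same layout")
  if (any(a$mech > 0L & b$mech > 0L)) {
    abort("masks overlap: a cell carries two mechanism labels")
  }
  new_missing_mask(a$mech + b$mech, a$subject_id)
}

#' Default MAR missingness model
#'
#' Logistic models generating missing-at-random cells in the MAR half of the
#' cohort from the second exam on: item-level missingness of two designated
#' components (predicted by the standardized baseline value of the component,
#' the standardized baseline composite, standardized age and sex) and
#' whole-wave non-attendance (predicted by baseline composite, age and sex).
#' Intercepts are calibrated per wave so the mean predicted probability in the
#' MAR half hits `target_rates` (items 5/3/8/9%, non-attendance 5/4/8/11% at
#' exams 2-5); supply `intercepts` instead to fix them directly.
#'
#' @param item_components Two components with item-level missingness.
#' @param item,wave Lists with numeric `slopes`
#'   (`c(value=, composite=, age=, sex=)` on standardized scales) and either
#'   `target_rates` (length `n_times - 1`) or fixed `intercepts`.
#' @return A list of class `mar_coefs`.
#' @export
default_mar_coefs <- function(item_components = c("BMI", "TC"),
                              item = list(slopes = c(value = 0.3, composite = -0.2,
                                                     age = 0.2, sex = 0.1),
                                          target_rates = c(0.05, 0.03, 0.08, 0.09),
                                          intercepts = NULL),
                              wave = list(slopes = c(value = 0, composite = -0.35,
                                                     age = 0.25, sex = 0.1),
                                          target_rates = c(0.05, 0.04, 0.08, 0.11),
                                          intercepts = NULL)) {
  structure(list(item_components = item_components, item = item, wave = wave),
            class = "mar_coefs")
}

calibrate_intercept <- function(lp, target) {
  if (target <= 0) return(-50)
  f <- function(a) mean(plogis(a + lp)) - target
  uniroot(f, c(-30, 30), tol = 1e-10)$root
}

#' Impose MAR missingness on the MAR half of the cohort
#'
#' At each exam from the second on, whole-wave non-attendance and item-level
#' missingness in two components are drawn Bernoulli from logistic predicted
#' probabilities depending only on fully observed baseline data (so the
#' mechanism is missing at random). Only subjects in the `"MAR"` half of the
#' cohort are affected; the first exam is always complete. Item missingness is
#' drawn among that wave's attendees.
#'
#' @param panel A complete `component_panel`.
#' @param mar_coefs A [default_mar_coefs()]-style object.
#' @param seed RNG seed.
#' @param criteria Composite criteria used for the baseline composite predictor.
#' @return A `missing_mask` with `B_MAR` cells.
#' @export
generate_mar_missingness <- function(panel, mar_coefs = default_mar_coefs(),
                                     seed = NULL,
                                     criteria = ideal_criteria()) {
  bad <- setdiff(mar_coefs$item_components, panel$vars)
  if (length(bad)) {
    abort(paste0("MAR coefficients reference unknown components: ",
                 paste(bad, collapse = ", ")))
  }
  with_seed(seed, {
    mask <- empty_mask(panel)
    g <- which(panel$data$miss_group == "MAR")
    if (!length(g)) return(mask)
    comp1 <- build_composite(panel, criteria)$scores[, 1]
    zC <- as.vector(scale(comp1))
    zage <- as.vector(scale(panel$data$age))
    sex <- panel$data$sex

    lp_terms <- function(slopes, zval) {
      slopes[["value"]] * zval + slopes[["composite"]] * zC +
        slopes[["age"]] * zage + slopes[["sex"]] * sex
    }

    for (t in 2:panel$n_times) {
      # whole-wave non-attendance
      lp <- lp_terms(mar_coefs$wave$slopes, 0)
      a <- if (!is.null(mar_coefs$wave$intercepts)) {
        mar_coefs$wave$intercepts[t - 1]
      } else {
        calibrate_intercept(lp[g], mar_coefs$wave$target_rates[t - 1])
      }
      wave_miss <- g[runif(length(g)) < plogis(a + lp[g])]
      if (length(wave_miss)) {
        mask$mech[wave_miss, paste(panel$vars, t, sep = "_")] <- MECH_B
      }
      # item-level missingness among attendees
      attend <- setdiff(g, wave_miss)
      for (v in mar_coefs$item_components) {
        zval <- as.vector(scale(panel$data[[paste(v, 1, sep = "_")]]))
        lp <- lp_terms(mar_coefs$item$slopes, zval)
        a <- if (!is.null(mar_coefs$item$intercepts)) {
          mar_coefs$item$intercepts[t - 1]
        } else if (length(attend)) {
          calibrate_intercept(lp[attend], mar_coefs$item$target_rates[t - 1])
        } else {
          -50
        }
        item_miss <- attend[runif(length(attend)) < plogis(a + lp[attend])]
        if (length(item_miss)) {
          mask$mech[item_miss, paste(v, t, sep = "_")] <- MECH_B
        }
      }
    }
    mask
  })
}

#' Describe an MNAR non-attendance scenario
#'
#' Scenario 1 removes whole exams for subjects whose composite score falls in
#' the scheduled lower tail (declining health drives non-attendance); Scenario
#' 2 uses the upper tail (healthy subjects skip exams); Scenario 3 applies the
#' full schedule to both tails independently. In `"rule"` mode the scheduled
#' tail fractions are used directly; in `"rate"` mode the selected fraction is
#' scaled so the expected non-attendance rate within the MNAR half equals
#' `rates`.
#'
#' @param scenario_id 1 (lower tail), 2 (upper), or 3 (both).
#' @param percentile_schedule Tail fractions at exams `2..n_times`.
#' @param nonattend_prob Probability a tail-flagged subject actually misses
#'   the exam.
#' @param mode `"rule"` (default) or `"rate"`.
#' @param rates Target per-wave non-attendance rates (rate mode only).
#' @return A list of class `mnar_scenario`.
#' @export
mnar_scenario <- function(scenario_id = 1,
                          percentile_schedule = c(0.10, 0.15, 0.20, 0.25),
                          nonattend_prob = 0.8,
                          mode = c("rule", "rate"),
                          rates = c(0.10, 0.125, 0.15, 0.175)) {
  mode <- match.arg(mode)
  assert_that(scenario_id %in% 1:3, "scenario_id must be 1, 2 or 3")
  assert_that(nonattend_prob >= 0 && nonattend_prob <= 1,
              "nonattend_prob must lie in [0, 1]")
  structure(list(scenario_id = scenario_id,
                 percentile_schedule = percentile_schedule,
                 nonattend_prob = nonattend_prob,
                 tail = c("lower", "upper", "both")[scenario_id],
                 mode = mode, rates = rates),
            class = "mnar_scenario")
}

#' Impose MNAR non-attendance on the MNAR half of the cohort
#'
#' At each exam from the second on, subjects in the `"MNAR"` half whose
#' composite score at that exam ranks in the scheduled tail (computed within
#' the MNAR half; ties broken by uniform jitter so the selected fraction is
#' exact) have all components set missing with probability
#' `scenario$nonattend_prob`. Because selection depends on the very values
#' that go missing, the mechanism is missing not at random.
#'
#' @param panel A complete `component_panel`.
#' @param scenario An [mnar_scenario()].
#' @param seed RNG seed.
#' @param criteria Composite criteria used to rank subjects.
#' @return A `missing_mask` with `A_MNAR` cells.
#' @export
generate_mnar_nonattendance <- function(panel, scenario = mnar_scenario(1),
                                        seed = NULL,
                                        criteria = ideal_criteria()) {
  assert_that(length(scenario$percentile_schedule) == panel$n_times - 1,
              "percentile_schedule must have n_times - 1 entries")
  with_seed(seed, {
    mask <- empty_mask(panel)
    g <- which(panel$data$miss_group == "MNAR")
    if (!length(g) || scenario$nonattend_prob == 0) return(mask)
    comp <- build_composite(panel, criteria)$scores

    for (t in 2:panel$n_times) {
      frac <- if (scenario$mode == "rate") {
        scenario$rates[t - 1] / scenario$nonattend_prob
      } else {
        scenario$percentile_schedule[t - 1]
      }
      k <- round(frac * length(g))
      if (k == 0) next
      jittered <- comp[g, t] + runif(length(g), 0, 0.5) # integer scores: break ties
      flagged <- integer(0)
      if (scenario$tail %in% c("lower", "both")) {
        flagged <- c(flagged, g[order(jittered)[seq_len(k)]])
      }
      if (scenario$tail %in% c("upper", "both")) {
        flagged <- c(flagged, g[order(jittered, decreasing = TRUE)[seq_len(k)]])
      }
      flagged <- unique(flagged)
      miss <- flagged[runif(length(flagged)) < scenario$nonattend_prob]
      if (length(miss)) {
        mask$mech[miss, paste(panel$vars, t, sep = "_")] <- MECH_A
      }
    }
    mask
  })
}

# ---------------------------------------------------------------------------
# Event times

#' Specify the piecewise-exponential survival model
#'
#' Death times are generated interval by interval: within interval `t` the
#' hazard is `interval_hazards[t] * exp(log_hr_truth * C_it +
#' covariate_log_hrs . (age - age_center, sex))`, with the true (complete-data)
#' composite at the interval start. Defaults use a protective composite effect
#' of log(0.85) per unit, age and male-sex hazard ratios of 1.06/year and 1.4,
#' and rising baseline hazards calibrated so roughly 40% of the default cohort
#' dies over 25 years of follow-up.
#'
#' @param interval_hazards Positive baseline hazard rates (per year), one per
#'   interval between consecutive exams (the last interval runs to
#'   `admin_censor_time`).
#' @param log_hr_truth True log hazard ratio per composite unit.
#' @param covariate_log_hrs Named vector `c(age=, sex=)` of log hazard ratios.
#' @param admin_censor_time Administrative censoring time in years.
#' @param age_center Age (years) at which the age effect is anchored.
#' @return A list of class `survival_spec`.
#' @export
survival_spec <- function(interval_hazards = c(0.012, 0.017, 0.022, 0.028, 0.035),
                          log_hr_truth = log(0.85),
                          covariate_log_hrs = c(age = log(1.06), sex = log(1.4)),
                          admin_censor_time = 25,
                          age_center = 55) {
  assert_that(all(interval_hazards > 0), "interval hazards must be positive")
  structure(list(interval_hazards = interval_hazards,
                 log_hr_truth = log_hr_truth,
                 covariate_log_hrs = covariate_log_hrs,
                 admin_censor_time = admin_censor_time,
                 age_center = age_center),
            class = "survival_spec")
}

#' Simulate piecewise-exponential death times
#'
#' Uses the complete (pre-missingness) composite at the start of each interval.
#' A subject dies in the first interval whose exponential draw falls inside it,
#' and is otherwise administratively censored at `surv$admin_censor_time`.
#'
#' @param panel A complete `component_panel`.
#' @param surv A [survival_spec()].
#' @param seed RNG seed.
#' @param criteria Composite criteria.
#' @return A tibble (class `event_table`) with `subject_id`, `event_time`,
#'   `event_indicator`; the censoring time is carried as an attribute.
#' @export
generate_event_times <- function(panel, surv = survival_spec(), seed = NULL,
                                 criteria = ideal_criteria()) {
  with_seed(seed, {
    comp <- build_composite(panel, criteria)$scores
    n <- nrow(comp)
    bounds <- c(panel$time_grid, surv$admin_censor_time)
    n_int <- length(bounds) - 1
    assert_that(length(surv$interval_hazards) == n_int,
                "need one interval hazard per inter-exam interval")
    lp_cov <- surv$covariate_log_hrs[["age"]] *
      (panel$data$age - surv$age_center) +
      surv$covariate_log_hrs[["sex"]] * panel$data$sex

    event_time <- rep(surv$admin_censor_time, n)
    event <- integer(n)
    alive <- rep(TRUE, n)
    for (t in seq_len(n_int)) {
      len <- bounds[t + 1] - bounds[t]
      rate <- surv$interval_hazards[t] *
        exp(surv$log_hr_truth * comp[, min(t, ncol(comp))] + lp_cov)
      draw <- rexp(n, rate)
      dies <- alive & draw < len
      event_time[dies] <- bounds[t] + draw[dies]
      event[dies] <- 1L
      alive <- alive & !dies
    }
    out <- tibble(subject_id = panel$data$subject_id,
                  event_time = event_time, event_indicator = event)
    attr(out, "admin_censor_time") <- surv$admin_censor_time
    class(out) <- c("event_table", class(out))
    out
  })
}

#' Mark post-death cells in a mask
#'
#' All cells at exam times strictly after a subject's death time are relabelled
#' `D_DEATH`, overriding any previous label. Idempotent.
#'
#' @param mask A `missing_mask`.
#' @param events An event table from [generate_event_times()].
#' @param time_grid Exam times in years (taken from the panel that produced
#'   the mask).
#' @return A `missing_mask`.
#' @export
truncate_after_event <- function(mask, events, time_grid) {
  assert_that(nrow(mask$mech) == nrow(events),
              "mask and events must cover the same subjects")
  times <- as.integer(sub("^.*_", "", colnames(mask$mech)))
  for (i in which(events$event_indicator == 1L)) {
    dead_cols <- time_grid[times] > events$event_time[i]
    mask$mech[i, dead_cols] <- MECH_D
  }
  mask
}
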