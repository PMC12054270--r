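#' Per-time means of the composite score
#'
#' The mean of the composite over the subjects with a defined score at each
#' time point, with the complete-data variance `s^2 / n`.
#'
#' @param composite A `composite_matrix`.
#' @return A tibble with columns `parameter` (`mean_t1`, ...), `estimate`,
#'   `variance`, `n_used`.
#' @export
mean_by_time <- function(composite) {
  sc <- composite$scores
  purrr::map_dfr(seq_len(ncol(sc)), function(t) {
    x <- sc[!is.na(sc[, t]), t]
    if (length(x) < 2) {
      abort(sprintf("fewer than 2 defined composite scores at time %d", t))
    }
    tibble(parameter = paste0("mean_t", t), estimate = mean(x),
           variance = var(x) / length(x), n_used = length(x))
  })
}

#' Random-intercept mixed-model slope of the composite over time
#'
#' Fits `C_it = b0 + b1 * time_it + b2' X_i + u_i + e_it` by maximum
#' likelihood, with a normal random intercept per subject, time in years and
#' baseline age and sex as covariates. Rows with an undefined composite are
#' dropped.
#'
#' @param composite A `composite_matrix`.
#' @param covariates A data frame with `subject_id`, `age`, `sex`.
#' @return An object of class `lmm_slope_fit` with the fixed effects, the
#'   variance components, the slope standard error and a convergence flag.
#' @export
fit_slope_lmm <- function(composite, covariates) {
  long <- as_tibble(composite) %>%
    filter(!is.na(.data$score)) %>%
    left_join(covariates[, c("subject_id", "age", "sex")], by = "subject_id")
  assert_that(length(unique(long$time)) >= 2 &&
                length(unique(long$subject_id)) >= 2,
              "mixed-model slope needs >= 2 time points and >= 2 subjects")
  converged <- TRUE
  fit <- withCallingHandlers(
    lme4::lmer(score ~ years + age + sex + (1 | subject_id), data = long,
               REML = FALSE,
               control = lme4::lmerControl(calc.derivs = FALSE)),
    warning = function(w) {
      converged <<- FALSE
      invokeRestart("muffleWarning")
    })
  fe <- lme4::fixef(fit)
  vc <- lme4::VarCorr(fit)
  structure(list(beta0 = unname(fe["(Intercept)"]),
                 beta1 = unname(fe["years"]),
                 beta2 = fe[c("age", "sex")],
                 sigma_b2 = as.numeric(vc$subject_id[1, 1]),
                 sigma2 = attr(vc, "sc")^2,
                 se_beta1 = sqrt(vcov(fit)["years", "years"]),
                 converged = converged,
                 n_obs = nrow(long)),
            class = "lmm_slope_fit")
}

#' @export
print.lmm_slope_fit <- function(x, ...) {
  cat(sprintf("<lmm_slope_fit> slope = %.4f (se %.4f)/year; sigma_b2 = %.3f, sigma2 = %.3f%s\n",
              x$beta1, x$se_beta1, x$sigma_b2, x$sigma2,
              if (x$converged) "" else " [convergence flagged]"))
  invisible(x)
}

#' @rdname fit_slope_lmm
#' @param x An `lmm_slope_fit`.
#' @param ... Unused.
#' @export
tidy.lmm_slope_fit <- function(x, ...) {
  tibble(term = c("(Intercept)", "years", "age", "sex"),
         estimate = c(x$beta0, x$beta1, unname(x$beta2)))
}

#' @rdname fit_slope_lmm
#' @export
glance.lmm_slope_fit <- function(x, ...) {
  tibble(sigma_b2 = x$sigma_b2, sigma2 = x$sigma2, n_obs = x$n_obs,
         converged = x$converged)
}

# Counting-process episodes: [exam_t, exam_{t+1}) with the composite constant
# within the episode; follow-up ends at the event/censor time, so post-death
# exams never enter the risk set. Episodes with an undefined composite are
# dropped (complete-case behaviour for unimputed data). Plain vectors for
# speed: this sits in the simulation study's innermost loop.
cox_episodes <- function(composite, events, covariates) {
  grid <- composite$time_grid
  admin <- attr(events, "admin_censor_time") %||% max(events$event_time)
  bounds <- c(grid, admin)
  n <- nrow(composite$scores)
  idx_cov <- match(composite$subject_id, covariates$subject_id)
  rows <- vector("list", length(grid))
  for (t in seq_along(grid)) {
    start <- bounds[t]; stop_t <- bounds[t + 1]
    keep <- which(events$event_time > start & !is.na(composite$scores[, t]))
    if (!length(keep)) next
    rows[[t]] <- list(
      subject_id = composite$subject_id[keep],
      tstart = rep(start, length(keep)),
      tstop = pmin(stop_t, events$event_time[keep]),
      event = as.integer(events$event_indicator[keep] == 1L &
                           events$event_time[keep] <= stop_t),
      score = composite$scores[keep, t],
      age = covariates$age[idx_cov[keep]],
      sex = covariates$sex[idx_cov[keep]])
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  lapply(setNames(nm = names(rows[[1]])), function(f)
    unlist(lapply(rows, `[[`, f), use.names = FALSE))
}

# Efron partial-likelihood fit on prebuilt episode vectors via the
# counting-process fitter (equivalent to coxph on the same episodes but
# without the formula/model-frame overhead of the simulation loop).
cox_tv_engine <- function(dat) {
  x <- cbind(score = dat$score, age = dat$age, sex = dat$sex)
  y <- survival::Surv(dat$tstart, dat$tstop, dat$event)
  flagged <- FALSE
  fit <- withCallingHandlers(
    survival::agreg.fit(x, y, strata = NULL, offset = NULL, init = NULL,
                        control = survival::coxph.control(),
                        weights = NULL, method = "efron", rownames = NULL,
                        resid = FALSE),
    warning = function(w) {
      flagged <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (is.character(fit) || any(!is.finite(fit$coefficients))) {
    abort("Cox partial likelihood is monotone or degenerate: fit failed")
  }
  list(log_hr = unname(fit$coefficients[1]),
       variance = unname(fit$var[1, 1]),
       covariate_log_hrs = setNames(fit$coefficients[2:3], c("age", "sex")),
       flagged = flagged)
}

#' Time-varying Cox model for the composite score
#'
#' Fits `lambda_i(t) = lambda_0(t) exp(g1 * C_it + g2' X_i)` with the composite
#' as a time-varying covariate in counting-process form (the exam value is
#' carried across the following interval) and baseline age and sex. Post-death
#' exams never enter the risk set; cells with an undefined composite are
#' dropped from the episodes.
#'
#' @param composite A `composite_matrix`.
#' @param events An event table.
#' @param covariates Data frame with `subject_id`, `age`, `sex`.
#' @return An object of class `cox_tv_fit` with the log hazard ratio per
#'   composite unit (`log_hr`), its variance, covariate effects and the
#'   number of events used.
#' @export
fit_cox_tv <- function(composite, events, covariates) {
  if (sum(events$event_indicator) == 0) {
    abort("no events: the Cox model is not estimable")
  }
  dat <- cox_episodes(composite, events, covariates)
  fit <- cox_tv_engine(dat)
  structure(c(fit, list(n_events = sum(dat$event))), class = "cox_tv_fit")
}

#' @export
print.cox_tv_fit <- function(x, ...) {
  cat(sprintf("<cox_tv_fit> log HR per composite unit = %.4f (se %.4f), HR = %.3f; %d events%s\n",
              x$log_hr, sqrt(x$variance), exp(x$log_hr), x$n_events,
              if (x$flagged) " [fit flagged]" else ""))
  invisible(x)
}

#' @rdname fit_cox_tv
#' @param x A `cox_tv_fit`.
#' @param ... Unused.
#' @export
tidy.cox_tv_fit <- function(x, ...) {
  tibble(term = c("score", "age", "sex"),
         estimate = c(x$log_hr, unname(x$covariate_log_hrs)),
         std.error = c(sqrt(x$variance), NA, NA))
}

# ---------------------------------------------------------------------------
# Estimator adapters for pool_replicate()

#' Estimator adapters for pooling
#'
#' Each returns a function mapping a completed `component_panel` to a tibble
#' of `(parameter, estimate, variance)` rows, the shape [pool_replicate()]
#' expects: per-time composite means, the mixed-model slope, or the
#' time-varying Cox log hazard ratio.
#'
#' @param criteria Composite criteria.
#' @param times Which time points to report means for.
#' @param events Event table (Cox estimator only).
#' @return A function of a `component_panel`.
#' @export
est_mean_by_time <- function(criteria = ideal_criteria(), times = NULL) {
  function(panel) {
    out <- mean_by_time(build_composite(panel, criteria))
    if (!is.null(times)) {
      out <- filter(out, .data$parameter %in% paste0("mean_t", times))
    }
    out[, c("parameter", "estimate", "variance")]
  }
}

#' @rdname est_mean_by_time
#' @export
est_slope <- function(criteria = ideal_criteria()) {
  function(panel) {
    fit <- fit_slope_lmm(build_composite(panel, criteria), panel$data)
    tibble(parameter = "slope", estimate = fit$beta1,
           variance = fit$se_beta1^2)
  }
}

#' @rdname est_mean_by_time
#' @export
est_cox <- function(events, criteria = ideal_criteria()) {
  function(panel) {
    fit <- fit_cox_tv(build_composite(panel, criteria), events, panel$data)
    tibble(parameter = "log_hr", estimate = fit$log_hr,
           variance = fit$variance)
  }
}
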