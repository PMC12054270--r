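#' Configure the chained-equations imputation engine
#'
#' The engine treats each component at each time point as a distinct variable
#' and imputes them sequentially in column order (time-major within variable).
#' Three predictor structures are available: `"AFCS"` uses the same variable at
#' all other times plus all other variables at all times (longitudinal and
#' cross-sectional information), `"LFCS"` only the same variable at other times
#' (longitudinal only), `"XFCS"` only the other variables at the same time
#' (cross-sectional only). Every imputation model additionally includes
#' baseline age and sex, and - in Cox mode - the death indicator and the
#' cumulative null hazard at the subject's event or censoring time.
#'
#' Continuous variables are imputed by bootstrap linear regression by default
#' (`"linear_boot"`; `"linear_bayes"` draws from the conjugate posterior
#' instead); binary variables always use approximate-Bayesian logistic
#' regression.
#'
#' @param structure `"AFCS"`, `"LFCS"` or `"XFCS"`.
#' @param n_iterations Chained-equation cycles after the initial random fill
#'   (with 0 cycles the output is the initial fill).
#' @param continuous_method `"linear_boot"` or `"linear_bayes"`.
#' @param cox_mode Include the survival predictors in every imputation model.
#' @return A list of class `fcs_config`.
#' @export
fcs_config <- function(structure = c("LFCS", "AFCS", "XFCS"),
                       n_iterations = 5,
                       continuous_method = c("linear_boot", "linear_bayes"),
                       cox_mode = FALSE) {
  structure_ <- match.arg(structure)
  continuous_method <- match.arg(continuous_method)
  assert_that(n_iterations >= 0, "n_iterations must be non-negative")
  structure(list(structure = structure_,
                 n_iterations = as.integer(n_iterations),
                 continuous_method = continuous_method,
                 cox_mode = cox_mode),
            class = "fcs_config")
}

#' Build the 0/1 predictor matrix for a chained-equations structure
#'
#' Rows index the variable-time targets, columns the variable-time predictors
#' plus the always-included covariates (and survival terms in Cox mode). The
#' diagonal is zero for every structure: a variable never predicts itself at
#' the same time point.
#'
#' @param structure `"AFCS"`, `"LFCS"` or `"XFCS"`.
#' @param vars Ordered variable names.
#' @param n_times Number of time points.
#' @param cox_mode Append `death` and `H0` predictor columns.
#' @return An integer 0/1 matrix with dimnames.
#' @export
build_predictor_matrix <- function(structure, vars, n_times, cox_mode = FALSE) {
  assert_that(structure %in% c("AFCS", "LFCS", "XFCS"),
              paste0("unknown FCS structure: ", structure))
  vt <- vt_names(vars, n_times)
  extras <- c("age", "sex", if (cox_mode) c("death", "H0"))
  pm <- matrix(0L, length(vt), length(vt) + length(extras),
               dimnames = list(vt, c(vt, extras)))
  split <- vt_split(vt)
  for (i in seq_along(vt)) {
    v <- split$var[i]; t <- split$time[i]
    same_var_other_t <- split$var == v & split$time != t
    other_var_same_t <- split$var != v & split$time == t
    other_var_any_t <- split$var != v
    use <- switch(structure,
                  AFCS = same_var_other_t | other_var_any_t,
                  LFCS = same_var_other_t,
                  XFCS = other_var_same_t)
    pm[i, seq_along(vt)] <- as.integer(use)
    pm[i, extras] <- 1L
  }
  pm
}

# ---------------------------------------------------------------------------
# Elementary draws (thin wrappers over the compiled routines)

check_design <- function(y_obs, X_obs, X_miss) {
  X_obs <- as.matrix(X_obs); X_miss <- as.matrix(X_miss)
  assert_that(nrow(X_obs) == length(y_obs),
              "y_obs and X_obs must have matching rows")
  assert_that(ncol(X_obs) == ncol(X_miss),
              "X_obs and X_miss must have the same columns")
  assert_that(nrow(X_obs) >= ncol(X_obs) + 2,
              "need at least rank(X) + 2 observed cases")
  list(X = X_obs, Xm = X_miss)
}

#' Bootstrap linear imputation draw
#'
#' Resamples the observed cases with replacement, fits least squares on the
#' resample, and imputes `X_miss %*% beta* + N(0, sigma*^2)` with `sigma*^2`
#' the resample residual variance. The design is used as supplied (include an
#' intercept column if one is wanted). Singular resamples are redrawn a bounded
#' number of times, then fitted with a ridge.
#'
#' @param y_obs Observed outcomes.
#' @param X_obs,X_miss Design matrices for observed and missing cases.
#' @param seed RNG seed.
#' @return Imputed values for the missing cases.
#' @export
draw_linear_boot <- function(y_obs, X_obs, X_miss, seed = NULL) {
  d <- check_design(y_obs, X_obs, X_miss)
  with_seed(seed, as.vector(cpp_draw_linear_boot(d$X, y_obs, d$Xm)))
}

#' Bayesian linear imputation draw
#'
#' Draws `sigma*^2` from the scaled inverse chi-squared posterior
#' (`nu = n - q`, scale = residual SS / nu), then
#' `beta* ~ N(betahat, sigma*^2 (X'X)^-1)`, and imputes with predictive noise.
#'
#' @inheritParams draw_linear_boot
#' @return Imputed values for the missing cases.
#' @export
draw_linear_bayes <- function(y_obs, X_obs, X_miss, seed = NULL) {
  d <- check_design(y_obs, X_obs, X_miss)
  with_seed(seed, as.vector(cpp_draw_linear_bayes(d$X, y_obs, d$Xm)))
}

#' Approximate-Bayesian logistic imputation draw
#'
#' Fits maximum-likelihood logistic regression, perturbs the coefficients with
#' a draw from their asymptotic normal distribution, and imputes Bernoulli at
#' the perturbed probabilities. Separated data fall back to a weakly penalized
#' fit; single-class input imputes the constant class with a warning.
#'
#' @inheritParams draw_linear_boot
#' @param y_obs Observed 0/1 outcomes.
#' @return Imputed 0/1 values.
#' @export
draw_logistic_abayes <- function(y_obs, X_obs, X_miss, seed = NULL) {
  d <- check_design(y_obs, X_obs, X_miss)
  if (all(y_obs == y_obs[1])) {
    warn("single observed class: imputing the constant class")
  }
  with_seed(seed, as.vector(cpp_draw_logistic_abayes(d$X, y_obs, d$Xm)))
}

# ---------------------------------------------------------------------------
# Chained imputation

# Assemble the numeric working matrix: variable-time columns, covariates, and
# (cox mode) death indicator + Nelson-Aalen cumulative hazard at follow-up end.
fcs_matrix <- function(panel, config, events = NULL) {
  dat <- panel_values(panel, covariates = TRUE)
  if (config$cox_mode) {
    if (is.null(events)) abort("cox_mode imputation needs an event table")
    h0 <- nelson_aalen_cumhaz(events)
    dat <- cbind(dat, death = events$event_indicator, H0 = h0$H0)
  }
  dat
}

# Per-target engine inputs given a mechanism matrix and the codes to impute.
fcs_plan <- function(panel, mask, config, impute_codes) {
  vt <- vt_cols(panel)
  pm <- build_predictor_matrix(config$structure, panel$vars, panel$n_times,
                               config$cox_mode)
  all_cols <- colnames(pm)
  targets <- vt[colSums(matrix(mask$mech[, vt] %in% impute_codes,
                               nrow = nrow(mask$mech))) > 0]
  if (!length(targets)) return(NULL)
  split <- vt_split(targets)
  method <- ifelse(split$var %in% panel$binary_vars, 2L,
                   ifelse(config$continuous_method == "linear_boot", 0L, 1L))
  list(
    target_col = match(targets, all_cols) - 1L,
    miss_rows = lapply(targets, function(cn)
      which(mask$mech[, cn] %in% impute_codes) - 1L),
    pred_cols = lapply(targets, function(cn)
      which(pm[cn, ] == 1L) - 1L),
    method = method,
    targets = targets)
}

#' Impute one completed panel by chained equations
#'
#' Missing cells are initialized by sampling observed values of the same
#' variable, then the engine cycles `config$n_iterations` times over the
#' incomplete variables in column order, re-imputing each from its predictor
#' row using the current values of all others. Observed cells are never
#' modified; repeated calls with distinct seeds give independent imputations.
#'
#' @param panel A `component_panel` (values at masked cells are ignored).
#' @param mask A `missing_mask` saying which cells to treat as missing.
#' @param config An [fcs_config()].
#' @param events Event table, required when `config$cox_mode` is `TRUE`.
#' @param seed RNG seed.
#' @param impute_codes Mechanism codes to impute (default: all missing cells).
#' @return A completed `component_panel`.
#' @export
impute_chained <- function(panel, mask, config = fcs_config(), events = NULL,
                           seed = NULL, impute_codes = c(1L, 2L, 3L)) {
  plan <- fcs_plan(panel, mask, config, impute_codes)
  if (is.null(plan)) return(panel)
  dat <- fcs_matrix(panel, config, events)
  # blank the cells to impute so the engine can only see observed information
  for (i in seq_along(plan$targets)) {
    dat[plan$miss_rows[[i]] + 1L, plan$target_col[i] + 1L] <- NA_real_
  }
  done <- with_seed(seed,
    cpp_impute_chained(dat, plan$target_col, plan$miss_rows, plan$pred_cols,
                       plan$method, config$n_iterations))
  set_panel_values(panel, done[, seq_along(vt_cols(panel)), drop = FALSE])
}

#' Per-iteration convergence trace of the chained-equations engine
#'
#' Runs the chained cycler one iteration at a time and records, for every
#' imputed variable, the mean and SD of its imputed cells after each cycle —
#' the standard convergence diagnostic for chained equations. Several chains
#' (independent initial fills) can be overlaid to judge mixing.
#'
#' @inheritParams impute_chained
#' @param n_chains Number of independent chains.
#' @param n_iterations Cycles to trace (defaults to the config's count).
#' @return A tibble with `chain`, `iteration`, `variable`, `imp_mean`,
#'   `imp_sd`; write it to CSV for audit with [utils::write.csv()].
#' @export
fcs_convergence_trace <- function(panel, mask, config = fcs_config(),
                                  events = NULL, seed = NULL, n_chains = 3,
                                  n_iterations = config$n_iterations,
                                  impute_codes = c(1L, 2L, 3L)) {
  plan <- fcs_plan(panel, mask, config, impute_codes)
  if (is.null(plan)) return(tibble())
  dat0 <- fcs_matrix(panel, config, events)
  for (i in seq_along(plan$targets)) {
    dat0[plan$miss_rows[[i]] + 1L, plan$target_col[i] + 1L] <- NA_real_
  }
  with_seed(seed, purrr::map_dfr(seq_len(n_chains), function(ch) {
    dat <- cpp_impute_chained(dat0, plan$target_col, plan$miss_rows,
                              plan$pred_cols, plan$method, 0L) # initial fill
    purrr::map_dfr(seq_len(n_iterations), function(it) {
      dat <<- cpp_impute_chained(dat, plan$target_col, plan$miss_rows,
                                 plan$pred_cols, plan$method, 1L,
                                 do_init = FALSE)
      purrr::map_dfr(seq_along(plan$targets), function(i) {
        vals <- dat[plan$miss_rows[[i]] + 1L, plan$target_col[i] + 1L]
        tibble(chain = ch, iteration = it, variable = plan$targets[i],
               imp_mean = mean(vals), imp_sd = sd(vals))
      })
    })
  }))
}

#' Nelson-Aalen cumulative hazard at each subject's follow-up end
#'
#' The standard increment-sum estimator `H0(t) = sum_{t_i <= t} d_i / n_i`
#' evaluated at every subject's event or censoring time; used as an auxiliary
#' predictor in Cox-mode imputation models.
#'
#' @param events An event table (`subject_id`, `event_time`,
#'   `event_indicator`).
#' @return A tibble with `subject_id`, `time`, `H0`.
#' @export
nelson_aalen_cumhaz <- function(events) {
  assert_that(nrow(events) >= 1, "need at least one subject")
  assert_that(all(events$event_time >= 0), "event times must be non-negative")
  death_times <- events$event_time[events$event_indicator == 1L]
  dt <- sort(unique(death_times))
  if (!length(dt)) {
    return(tibble(subject_id = events$subject_id, time = events$event_time,
                  H0 = rep(0, nrow(events))))
  }
  d <- tabulate(match(death_times, dt), nbins = length(dt))
  st <- sort(events$event_time)
  at_risk <- length(st) - findInterval(dt, st, left.open = TRUE)
  cum <- cumsum(d / at_risk)
  idx <- findInterval(events$event_time, dt) # right-continuous step
  tibble(subject_id = events$subject_id, time = events$event_time,
         H0 = c(0, cum)[idx + 1L])
}
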