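#' Configure a simulation study
#'
#' Bundles every knob of the replicate loop: the cohort and survival
#' generating conditions, the MNAR scenario, the sensitivity grid, the FCS
#' structures and comparators, the nested imputation counts, the analyses to
#' run and the master seed. The mean and slope analyses run on the
#' MAR + MNAR missingness pattern; the Cox analysis additionally simulates
#' death times, truncates data after death and imputes in Cox mode.
#'
#' @param n_replicates Number of simulation replicates (>= 2).
#' @param cohort_spec A [cohort_spec()].
#' @param scenario An [mnar_scenario()].
#' @param survival_spec A [survival_spec()] (needed for the Cox analysis).
#' @param k_grid Named list of [ignorability()] assumptions.
#' @param fcs_structures Subset of `c("AFCS", "LFCS", "XFCS")`.
#' @param comparators Subset of `c("CC", "LOCF")`.
#' @param m,n Stage-1 / Stage-2 imputation counts.
#' @param analyses Subset of `c("mean", "slope", "cox")`.
#' @param mar_coefs A [default_mar_coefs()] object.
#' @param criteria Composite criteria.
#' @param truth_population_size Population size for the truth computation.
#' @param n_iterations Chained-equation cycles per imputation.
#' @param continuous_method Elementary draw for continuous variables.
#' @param master_seed Master seed; expands to per-replicate, per-stage and
#'   per-imputation sub-streams.
#' @return A list of class `study_config`.
#' @export
study_config <- function(n_replicates = 500,
                         cohort_spec = default_cohort_spec(3700),
                         scenario = mnar_scenario(1),
                         survival_spec = twostagemi::survival_spec(),
                         k_grid = default_k_grid(),
                         fcs_structures = c("AFCS", "LFCS", "XFCS"),
                         comparators = c("CC", "LOCF"),
                         m = 5, n = 5,
                         analyses = c("mean", "slope", "cox"),
                         mar_coefs = default_mar_coefs(),
                         criteria = ideal_criteria(),
                         truth_population_size = 1e6,
                         n_iterations = 5,
                         continuous_method = "linear_boot",
                         master_seed = 20260920) {
  assert_that(n_replicates >= 2, "need at least 2 replicates")
  assert_that(length(analyses) >= 1 &&
                all(analyses %in% c("mean", "slope", "cox")),
              "analyses must be a non-empty subset of mean/slope/cox")
  assert_that(all(fcs_structures %in% c("AFCS", "LFCS", "XFCS")),
              "unknown FCS structure")
  structure(list(n_replicates = as.integer(n_replicates),
                 cohort_spec = cohort_spec, scenario = scenario,
                 survival_spec = survival_spec, k_grid = k_grid,
                 fcs_structures = fcs_structures, comparators = comparators,
                 m = m, n = n, analyses = analyses, mar_coefs = mar_coefs,
                 criteria = criteria,
                 truth_population_size = truth_population_size,
                 n_iterations = n_iterations,
                 continuous_method = continuous_method,
                 master_seed = master_seed),
            class = "study_config")
}

#' Desk-scale study preset
#'
#' A reduced-scale preset for interactive work and reproducibility checks:
#' 1000 subjects, 100 replicates, `m = n = 3`, truth from a 100,000-subject
#' population. All other conditions equal the full-scale defaults.
#'
#' @param ... Overrides passed to [study_config()].
#' @return A `study_config`.
#' @export
desk_study_config <- function(...) {
  args <- list(...)
  defaults <- list(n_replicates = 100, cohort_spec = default_cohort_spec(1000),
                   m = 3, n = 3, truth_population_size = 1e5)
  do.call(study_config, utils::modifyList(defaults, args))
}

#' Compute the true parameter values from a large population
#'
#' Simulates one complete population from the generating conditions: the true
#' per-time means are the population composite means, the true slope is the
#' mixed-model slope fitted to the population, and the true log hazard ratio
#' is the pre-specified generating value (passed through, not re-estimated).
#'
#' @param cohort_spec A [cohort_spec()].
#' @param survival_spec A [survival_spec()] or `NULL`.
#' @param population_size Population size (much larger than the cohort).
#' @param seed RNG seed.
#' @param analyses Which truths to compute.
#' @param criteria Composite criteria.
#' @return A list of class `truth_set` with `mean_truth` (named per
#'   parameter), `slope_truth`, `log_hr_truth`.
#' @export
compute_truth <- function(cohort_spec, survival_spec = NULL,
                          population_size = 1e5, seed = 1,
                          analyses = c("mean", "slope", "cox"),
                          criteria = ideal_criteria()) {
  spec <- cohort_spec
  spec$n_subjects <- as.integer(population_size)
  panel <- generate_full_panel(spec, seed = seed)
  comp <- build_composite(panel, criteria)
  means <- colMeans(comp$scores)
  names(means) <- paste0("mean_t", seq_along(means))
  slope <- NULL
  if ("slope" %in% analyses) {
    slope <- fit_slope_lmm(comp, panel$data)$beta1
  }
  structure(list(mean_truth = means,
                 slope_truth = slope,
                 log_hr_truth = if (!is.null(survival_spec))
                   survival_spec$log_hr_truth else NULL,
                 population_size = population_size),
            class = "truth_set")
}

#' Percent bias of an estimator over replicates
#'
#' `100 * |mean(estimates) - truth| / |truth|` by default; `signed = TRUE`
#' keeps the sign of the deviation.
#'
#' @param estimates Replicate estimates.
#' @param truth True value (non-zero).
#' @param signed Keep the sign of the bias.
#' @return Percent bias.
#' @export
percent_bias <- function(estimates, truth, signed = FALSE) {
  if (truth == 0) {
    abort("truth is zero: percent bias undefined, use absolute bias instead")
  }
  assert_that(length(estimates) >= 2, "need at least 2 replicate estimates")
  pb <- 100 * (mean(estimates) - truth) / abs(truth)
  if (signed) pb else abs(pb)
}

#' Coverage probability of replicate confidence intervals
#'
#' @param ci_low,ci_high Paired interval bounds over replicates.
#' @param truth True value.
#' @return Percent of intervals containing the truth.
#' @export
coverage <- function(ci_low, ci_high, truth) {
  assert_that(length(ci_low) == length(ci_high),
              "interval bounds must be paired")
  100 * mean(ci_low <= truth & truth <= ci_high)
}

# one comparator's per-time means with complete-data t intervals
comparator_means <- function(panel_na, criteria, times, level = 0.95) {
  comp <- build_composite(panel_na, criteria)
  purrr::map_dfr(times, function(t) {
    x <- comp$scores[!is.na(comp$scores[, t]), t]
    se <- sd(x) / sqrt(length(x))
    half <- qt((1 + level) / 2, df = length(x) - 1) * se
    tibble(parameter = paste0("mean_t", t), estimate = mean(x),
           ci_low = mean(x) - half, ci_high = mean(x) + half)
  })
}

comparator_slope <- function(panel_na, criteria, level = 0.95) {
  fit <- fit_slope_lmm(build_composite(panel_na, criteria), panel_na$data)
  half <- qnorm((1 + level) / 2) * fit$se_beta1
  tibble(parameter = "slope", estimate = fit$beta1,
         ci_low = fit$beta1 - half, ci_high = fit$beta1 + half)
}

comparator_cox <- function(panel_na, events, criteria, level = 0.95) {
  fit <- fit_cox_tv(build_composite(panel_na, criteria), events, panel_na$data)
  half <- qnorm((1 + level) / 2) * sqrt(fit$variance)
  tibble(parameter = "log_hr", estimate = fit$log_hr,
         ci_low = fit$log_hr - half, ci_high = fit$log_hr + half)
}

# Pool one stack with matrix-level estimators (the study's hot loop avoids
# rebuilding tibble panels for every completed dataset). Each estimator maps
# a value matrix to a list of (parameter, estimate, variance) vectors.
pooled_rows <- function(stack, fast_ests, level = 0.95) {
  m <- stack$m; n <- stack$n
  acc <- NULL
  idx <- 0L
  for (j in seq_len(m)) {
    for (k in seq_len(n)) {
      idx <- idx + 1L
      res <- lapply(fast_ests, function(f) f(stack$panels[[j]][[k]]))
      est <- unlist(lapply(res, `[[`, "estimate"), use.names = FALSE)
      u <- unlist(lapply(res, `[[`, "variance"), use.names = FALSE)
      if (is.null(acc)) {
        pars <- unlist(lapply(res, `[[`, "parameter"), use.names = FALSE)
        acc <- list(q = matrix(NA_real_, m * n, length(pars)),
                    u = matrix(NA_real_, m * n, length(pars)), pars = pars)
      }
      acc$q[idx, ] <- est
      acc$u[idx, ] <- u
    }
  }
  purrr::map_dfr(seq_along(acc$pars), function(p) {
    pe <- pool_two_stage(list(qhat = matrix(acc$q[, p], m, n, byrow = TRUE),
                              uhat = matrix(acc$u[, p], m, n, byrow = TRUE)),
                         level = level)
    tibble(parameter = acc$pars[p], estimate = pe$q_bar,
           ci_low = pe$ci_low, ci_high = pe$ci_high)
  })
}

# matrix-level estimators used by the study loop
fast_estimators <- function(analysis_set, panel, criteria, events = NULL) {
  n_times <- panel$n_times
  skel <- list(subject_id = panel$data$subject_id,
               time_grid = panel$time_grid)
  cov <- panel$data[, c("subject_id", "age", "sex")]
  ests <- list()
  if ("mean" %in% analysis_set) {
    ests$mean <- function(vals) {
      sc <- composite_scores(vals, n_times, criteria)
      times <- 2:n_times
      est <- colMeans(sc[, times, drop = FALSE])
      v <- apply(sc[, times, drop = FALSE], 2, var) / nrow(sc)
      list(parameter = paste0("mean_t", times), estimate = est, variance = v)
    }
  }
  if ("slope" %in% analysis_set) {
    ests$slope <- function(vals) {
      sc <- composite_scores(vals, n_times, criteria)
      comp <- structure(c(skel, list(scores = sc)), class = "composite_matrix")
      fit <- fit_slope_lmm(comp, cov)
      list(parameter = "slope", estimate = fit$beta1,
           variance = fit$se_beta1^2)
    }
  }
  if ("cox" %in% analysis_set) {
    ests$cox <- function(vals) {
      sc <- composite_scores(vals, n_times, criteria)
      dat <- cox_episodes(c(skel, list(scores = sc)), events, cov)
      fit <- cox_tv_engine(dat)
      list(parameter = "log_hr", estimate = fit$log_hr,
           variance = fit$variance)
    }
  }
  ests
}

run_one_replicate <- function(config, r) {
  sr <- derive_seed(config$master_seed, r)
  spec <- config$cohort_spec
  crit <- config$criteria
  panel <- generate_full_panel(spec, seed = derive_seed(sr, 1L))
  mask_b <- generate_mar_missingness(panel, config$mar_coefs,
                                     seed = derive_seed(sr, 2L),
                                     criteria = crit)
  mask_a <- generate_mnar_nonattendance(panel, config$scenario,
                                        seed = derive_seed(sr, 3L),
                                        criteria = crit)
  mask <- merge_masks(mask_a, mask_b)

  rows <- list()
  level <- 0.95

  run_family <- function(analysis_set, mask_use, cox_mode, events) {
    estimators <- fast_estimators(analysis_set, panel, crit, events)
    fam_rows <- list()
    for (s in config$fcs_structures) {
      cfg <- fcs_config(structure = s, n_iterations = config$n_iterations,
                        continuous_method = config$continuous_method,
                        cox_mode = cox_mode)
      stacks <- two_stage_grid(panel, mask_use, cfg, config$k_grid,
                               m = config$m, n = config$n,
                               seed = derive_seed(sr, 4L, match(s, c("AFCS", "LFCS", "XFCS")), cox_mode),
                               events = events)
      for (nm in names(stacks)) {
        a <- stacks[[nm]]$assumption
        fam_rows[[length(fam_rows) + 1L]] <-
          pooled_rows(stacks[[nm]], estimators, level) %>%
          mutate(method = paste0("2Stage_", s, "_", nm),
                 structure = s, k_cont = a$k_cont)
      }
    }
    # comparators on the same replicate data
    if ("CC" %in% config$comparators) {
      cc <- cc_restrict(panel, mask_use)
      cmp <- list()
      if ("mean" %in% analysis_set) {
        cmp$mean <- comparator_means(cc, crit, 2:spec$n_times, level)
      }
      if ("slope" %in% analysis_set) cmp$slope <- comparator_slope(cc, crit, level)
      if ("cox" %in% analysis_set) cmp$cox <- comparator_cox(cc, events, crit, level)
      fam_rows[[length(fam_rows) + 1L]] <-
        bind_rows(cmp) %>% mutate(method = "CC", structure = NA_character_,
                                  k_cont = NA_real_)
    }
    if ("LOCF" %in% config$comparators) {
      lf <- locf_fill(panel, mask_use)
      cmp <- list()
      if ("mean" %in% analysis_set) {
        cmp$mean <- comparator_means(lf, crit, 2:spec$n_times, level)
      }
      if ("slope" %in% analysis_set) cmp$slope <- comparator_slope(lf, crit, level)
      if ("cox" %in% analysis_set) cmp$cox <- comparator_cox(lf, events, crit, level)
      fam_rows[[length(fam_rows) + 1L]] <-
        bind_rows(cmp) %>% mutate(method = "LOCF", structure = NA_character_,
                                  k_cont = NA_real_)
    }
    bind_rows(fam_rows)
  }

  fam_a <- intersect(config$analyses, c("mean", "slope"))
  if (length(fam_a)) {
    rows$a <- run_family(fam_a, mask, cox_mode = FALSE, events = NULL) %>%
      mutate(with_death = FALSE)
  }
  if ("cox" %in% config$analyses) {
    events <- generate_event_times(panel, config$survival_spec,
                                   seed = derive_seed(sr, 5L), criteria = crit)
    mask_d <- truncate_after_event(mask, events, panel$time_grid)
    rows$b <- run_family("cox", mask_d, cox_mode = TRUE, events = events) %>%
      mutate(with_death = TRUE)
  }
  bind_rows(rows) %>% mutate(replicate = r)
}

#' Run the full simulation study
#'
#' For each replicate: generate a cohort, impose MAR and MNAR-scenario
#' missingness, run two-stage MI for every (ignorability, FCS structure)
#' combination sharing the Stage-1 ignorable draws across the sensitivity
#' grid, pool each configured estimator with the two-stage combining rules,
#' and evaluate the comparators on the same data. For the Cox analysis,
#' death times are simulated, post-death data truncated, and imputation runs
#' in Cox mode. Results are aggregated into percent bias and coverage against
#' the large-population truth, with Monte-Carlo standard errors.
#'
#' Per-replicate failures are logged and counted; the study aborts if more
#' than 5% of replicates fail. The whole run is reproducible from
#' `master_seed`.
#'
#' @param config A [study_config()].
#' @param verbose Print progress every 10 replicates.
#' @return A tibble of class `mi_results` keyed by (analysis parameter,
#'   method) with `percent_bias`, `coverage` and their Monte-Carlo standard
#'   errors; the per-replicate estimates, the truth set and the config ride
#'   along as attributes.
#' @export
run_simulation_study <- function(config, verbose = interactive()) {
  truth <- compute_truth(config$cohort_spec, config$survival_spec,
                         population_size = config$truth_population_size,
                         seed = derive_seed(config$master_seed, 999L),
                         analyses = config$analyses,
                         criteria = config$criteria)
  reps <- vector("list", config$n_replicates)
  failures <- character(0)
  for (r in seq_len(config$n_replicates)) {
    reps[[r]] <- tryCatch(run_one_replicate(config, r), error = function(e) {
      failures <<- c(failures, sprintf("replicate %d: %s", r,
                                       conditionMessage(e)))
      NULL
    })
    if (verbose && r %% 10 == 0) {
      message(sprintf("replicate %d / %d", r, config$n_replicates))
    }
  }
  if (length(failures) > 0.05 * config$n_replicates) {
    abort(paste0("more than 5% of replicates failed:\n",
                 paste(head(failures, 5), collapse = "\n")))
  }
  if (length(failures)) {
    warn(paste0(length(failures), " replicate(s) failed and were excluded"))
  }
  raw <- bind_rows(reps)

  truth_lookup <- c(truth$mean_truth,
                    if (!is.null(truth$slope_truth)) c(slope = truth$slope_truth),
                    if (!is.null(truth$log_hr_truth)) c(log_hr = truth$log_hr_truth))
  agg <- raw %>%
    mutate(truth = unname(truth_lookup[.data$parameter])) %>%
    group_by(.data$parameter, .data$method, .data$structure, .data$k_cont,
             .data$with_death) %>%
    summarise(
      n_replicates = dplyr::n(),
      percent_bias = percent_bias(.data$estimate, .data$truth[1]),
      signed_percent_bias = percent_bias(.data$estimate, .data$truth[1],
                                         signed = TRUE),
      coverage = coverage(.data$ci_low, .data$ci_high, .data$truth[1]),
      mc_se_bias = 100 * sd(.data$estimate) / sqrt(dplyr::n()) /
        abs(.data$truth[1]),
      mc_se_coverage = 100 * sqrt(pmax(.data$coverage / 100 *
                                         (1 - .data$coverage / 100), 1e-12) /
                                    dplyr::n()),
      truth = .data$truth[1],
      .groups = "drop") %>%
    mutate(scenario = config$scenario$scenario_id)

  structure(agg, class = c("mi_results", class(agg)),
            raw = raw, truth = truth, config = config)
}
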