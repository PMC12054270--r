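vars6 <- c("SMK", "BMI", "SBP", "DBP", "TC", "BG")

test_that("predictor matrices encode the three structures", {
  pm <- build_predictor_matrix("LFCS", vars6, 5, cox_mode = TRUE)
  on <- colnames(pm)[pm["BMI_3", ] == 1L]
  expect_setequal(on, c("BMI_1", "BMI_2", "BMI_4", "BMI_5",
                        "age", "sex", "death", "H0"))

  pm <- build_predictor_matrix("XFCS", vars6, 5)
  on <- colnames(pm)[pm["BMI_3", ] == 1L]
  expect_setequal(on, c("SMK_3", "SBP_3", "DBP_3", "TC_3", "BG_3",
                        "age", "sex"))

  pm <- build_predictor_matrix("AFCS", vars6, 5)
  on <- colnames(pm)[pm["BMI_3", ] == 1L]
  expect_length(on, 4 + 5 * 5 + 2) # own other times + 5 others all times + covs
  expect_false("BMI_3" %in% on)

  for (s in c("AFCS", "LFCS", "XFCS")) {
    pm <- build_predictor_matrix(s, vars6, 5, cox_mode = FALSE)
    expect_true(all(diag(pm[, rownames(pm)]) == 0L))
  }
  expect_error(build_predictor_matrix("ZFCS", vars6, 5), "unknown")
})

test_that("bootstrap linear draws have the bootstrap-predictive moments", {
  # noiseless limit: imputations reproduce the linear fit exactly
  X <- cbind(1, seq_len(30))
  y <- 2 + 3 * seq_len(30)
  imp <- draw_linear_boot(y, X, cbind(1, c(31, 40)), seed = 1)
  expect_equal(imp, 2 + 3 * c(31, 40), tolerance = 1e-10)

  # intercept-only: draw mean ~ ybar, draw variance ~ sigma2 (1 + 1/n)
  set.seed(5)
  n <- 400
  y <- rnorm(n, 10, 2)
  ones <- matrix(1, n, 1)
  draws <- vapply(seq_len(1200),
                  function(i) draw_linear_boot(y, ones, matrix(1, 1, 1),
                                               seed = i), 0)
  expect_lt(abs(mean(draws) - mean(y)), 4 * sd(draws) / sqrt(length(draws)))
  target_var <- var(y) * (1 + 1 / n)
  expect_lt(abs(var(draws) - target_var), 0.25 * target_var)

  # RNG contract
  a <- draw_linear_boot(y, ones, matrix(1, 5, 1), seed = 7)
  b <- draw_linear_boot(y, ones, matrix(1, 5, 1), seed = 7)
  d <- draw_linear_boot(y, ones, matrix(1, 5, 1), seed = 8)
  expect_identical(a, b)
  expect_false(identical(a, d))
})

test_that("Bayesian linear draws match bootstrap draws in distribution", {
  set.seed(6)
  n <- 500
  y <- rnorm(n, 5, 1.5)
  ones <- matrix(1, n, 1)
  boot <- vapply(seq_len(1200),
                 function(i) draw_linear_boot(y, ones, matrix(1, 1, 1),
                                              seed = i), 0)
  bayes <- vapply(seq_len(1200),
                  function(i) draw_linear_bayes(y, ones, matrix(1, 1, 1),
                                                seed = 5000 + i), 0)
  expect_gt(suppressWarnings(stats::ks.test(boot, bayes)$p.value), 0.01)

  # large-n limit: imputation distribution approaches N(Xb, sigma2)
  expect_lt(abs(mean(bayes) - mean(y)), 4 * sd(bayes) / sqrt(length(bayes)))
  expect_lt(abs(var(bayes) / var(y) - 1), 0.25)

  a <- draw_linear_bayes(y, ones, matrix(1, 3, 1), seed = 9)
  expect_identical(a, draw_linear_bayes(y, ones, matrix(1, 3, 1), seed = 9))
})

test_that("logistic draws match the observed prevalence with null predictors", {
  set.seed(7)
  n <- 600
  y <- rbinom(n, 1, 0.3)
  X <- cbind(1, rnorm(n)) # predictor with no effect
  imp <- draw_logistic_abayes(y, X, cbind(1, rnorm(20000)), seed = 2)
  expect_true(all(imp %in% 0:1))
  p <- mean(y)
  expect_lt(abs(mean(imp) - p), 4 * sqrt(p * (1 - p) / length(imp)) + 0.03)

  # perfectly separated toy data: penalized fallback stays finite
  ys <- rep(c(0, 1), each = 10)
  Xs <- cbind(1, c(seq(-2, -0.1, length.out = 10),
                   seq(0.1, 2, length.out = 10)))
  imp_s <- draw_logistic_abayes(ys, Xs, Xs, seed = 3)
  expect_true(all(imp_s %in% 0:1))

  # degenerate single class imputes that class
  expect_warning(
    imp1 <- draw_logistic_abayes(rep(1, 30), matrix(1, 30, 1),
                                 matrix(1, 10, 1), seed = 4),
    "single observed class")
  expect_true(all(imp1 == 1))
})

test_that("chained imputation preserves observed cells and recovers MCAR holes", {
  cohort <- small_cohort(400, seed = 31)
  panel <- cohort$panel

  # zero missing cells: input returned unchanged
  same <- impute_chained(panel, twostagemi:::empty_mask(panel),
                         fcs_config("LFCS"), seed = 1)
  expect_equal(twostagemi:::panel_values(same),
               twostagemi:::panel_values(panel))

  # observed cells never modified; imputed cells finite; binary stays 0/1
  done <- impute_chained(panel, cohort$mask, fcs_config("LFCS"), seed = 2)
  v0 <- twostagemi:::panel_values(panel)
  v1 <- twostagemi:::panel_values(done)
  obs <- cohort$mask$mech == 0L
  expect_equal(v1[obs], v0[obs])
  expect_true(all(is.finite(v1)))
  expect_true(all(v1[, paste0("SMK_", 1:5)] %in% 0:1))

  # MCAR deletion of 20% of BMI_3: imputed-value mean tracks the deleted mean
  set.seed(33)
  diffs <- replicate(50, {
    holes <- sample.int(400, 80)
    mask <- mask_with(panel, lapply(holes, function(r)
      list(row = r, col = "BMI_3")))
    imp <- impute_chained(panel, mask, fcs_config("LFCS"),
                          seed = sample.int(1e6, 1))
    mean(twostagemi:::panel_values(imp)[holes, "BMI_3"]) -
      mean(v0[holes, "BMI_3"])
  })
  expect_lt(abs(mean(diffs)), 3 * sd(diffs) / sqrt(length(diffs)) + 0.05)

  # a single missing cell changes that cell only
  mask1 <- mask_with(panel, list(list(row = 5, col = "TC_4")))
  one <- twostagemi:::panel_values(
    impute_chained(panel, mask1, fcs_config("AFCS"), seed = 9))
  expect_equal(sum(one != v0), 1)
  expect_true(one[5, "TC_4"] != v0[5, "TC_4"])
})

test_that("longitudinal structures beat the cross-sectional one under MCAR", {
  # strong within-variable correlation: LFCS/AFCS should out-impute XFCS
  spec <- default_cohort_spec(300, seed = 41)
  set.seed(42)
  rmse <- sapply(c("LFCS", "AFCS", "XFCS"), function(s) {
    errs <- replicate(50, {
      panel <- generate_full_panel(spec, seed = sample.int(1e6, 1))
      truth <- twostagemi:::panel_values(panel)
      holes <- sample.int(300, 60)
      mask <- mask_with(panel, lapply(holes, function(r)
        list(row = r, col = "BMI_3")))
      imp <- impute_chained(panel, mask, fcs_config(s),
                            seed = sample.int(1e6, 1))
      sqrt(mean((twostagemi:::panel_values(imp)[holes, "BMI_3"] -
                   truth[holes, "BMI_3"])^2))
    })
    mean(errs)
  })
  expect_lt(rmse[["LFCS"]], rmse[["XFCS"]])
  expect_lt(rmse[["AFCS"]], rmse[["XFCS"]])
})

test_that("the cumulative null hazard is the increment-sum estimator", {
  ev0 <- tibble::tibble(subject_id = 1:4, event_time = c(1, 2, 3, 4),
                        event_indicator = 0L)
  expect_true(all(nelson_aalen_cumhaz(ev0)$H0 == 0))

  ev <- tibble::tibble(subject_id = 1:3, event_time = c(1, 2, 3),
                       event_indicator = c(1L, 1L, 0L))
  expect_equal(nelson_aalen_cumhaz(ev)$H0, c(1 / 3, 1 / 3 + 1 / 2, 5 / 6))

  # replicating every subject leaves the estimator pointwise unchanged
  ev2 <- dplyr::bind_rows(ev, dplyr::mutate(ev, subject_id = subject_id + 3L))
  expect_equal(nelson_aalen_cumhaz(ev2)$H0[1:3], nelson_aalen_cumhaz(ev)$H0)

  expect_error(nelson_aalen_cumhaz(
    tibble::tibble(subject_id = 1, event_time = -1, event_indicator = 1L)),
    "non-negative")
})

test_that("the convergence trace records every chain, cycle and variable", {
  cohort <- small_cohort(150, seed = 44)
  tr <- fcs_convergence_trace(cohort$panel, cohort$mask, fcs_config("LFCS"),
                              seed = 9, n_chains = 2, n_iterations = 3)
  expect_setequal(unique(tr$chain), 1:2)
  expect_setequal(unique(tr$iteration), 1:3)
  expect_true(all(is.finite(tr$imp_mean)))
  # traced variables are exactly the incomplete ones
  incomplete <- colnames(cohort$mask$mech)[colSums(cohort$mask$mech > 0) > 0]
  expect_setequal(unique(tr$variable), incomplete)
  # same seed reproduces the trace
  tr2 <- fcs_convergence_trace(cohort$panel, cohort$mask, fcs_config("LFCS"),
                               seed = 9, n_chains = 2, n_iterations = 3)
  expect_identical(tr, tr2)
})
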