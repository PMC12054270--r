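#' Specify a synthetic longitudinal cohort
#'
#' A cohort specification fixes everything the generator needs: the measured
#' variables and their per-time means and standard deviations, the latent
#' correlation structure (exchangeable within-variable correlation across time
#' points, a common low correlation between different variables and the
#' baseline covariates), target prevalences for binary variables, and the
#' baseline covariate distribution (continuous "age", binary "sex"). Time
#' points are evenly spaced (`time_step` years apart).
#'
#' Six measured variables (smoking status, BMI, systolic and diastolic blood
#' pressure, total cholesterol, fasting glucose) form five health components:
#' the two pressures are pooled into a single blood-pressure component when the
#' composite score is built (see [ideal_criteria()]).
#'
#' @param n_subjects Number of subjects.
#' @param n_times Number of time points (exams).
#' @param component_names Ordered variable names; binary variables must be
#'   listed in `binary_components`.
#' @param binary_components Which variables are binary (0/1).
#' @param means,sds Numeric matrices (continuous variables x time points):
#'   per-variable per-time means and SDs. Means must be non-decreasing over
#'   time for each variable (health declines with ageing).
#' @param within_corr Named vector, one entry per variable, in `[0, 1)`:
#'   exchangeable correlation of the same variable across time points.
#' @param between_corr Single correlation in `[0, 1)` between any two distinct
#'   variables (and between variables and covariates).
#' @param binary_targets Matrix (binary variables x time points) of target
#'   prevalences in (0, 1), non-decreasing over time.
#' @param covariate_spec List with `age_mean`, `age_sd`, `sex_prevalence`.
#' @param time_step Years between consecutive exams.
#' @param seed Optional RNG seed stored with the spec.
#'
#' @return An object of class `cohort_spec`.
#' @seealso [default_cohort_spec()], [generate_full_panel()]
#' @export
cohort_spec <- function(n_subjects,
                        n_times = 5,
                        component_names = c("SMK", "BMI", "SBP", "DBP", "TC", "BG"),
                        binary_components = "SMK",
                        means,
                        sds,
                        within_corr = setNames(rep(0.7, length(component_names)),
                                               component_names),
                        between_corr = 0.15,
                        binary_targets,
                        covariate_spec = list(age_mean = 55, age_sd = 9,
                                              sex_prevalence = 0.45),
                        time_step = 5,
                        seed = NULL) {
  cont <- setdiff(component_names, binary_components)
  means <- as.matrix(means); sds <- as.matrix(sds)
  binary_targets <- as.matrix(binary_targets)
  assert_that(n_subjects >= 2, "n_subjects must be at least 2")
  assert_that(n_times >= 2, "n_times must be at least 2")
  assert_that(all(rownames(means) == cont) && ncol(means) == n_times,
              "`means` must be a (continuous variables x time points) matrix")
  assert_that(all(dim(sds) == dim(means)) && all(sds > 0),
              "`sds` must match `means` and be positive")
  assert_that(all(apply(means, 1, function(x) all(diff(x) >= 0))),
              "per-variable means must be non-decreasing over time")
  assert_that(all(rownames(binary_targets) == binary_components) &&
                ncol(binary_targets) == n_times,
              "`binary_targets` must be a (binary variables x time points) matrix")
  assert_that(all(binary_targets > 0 & binary_targets < 1),
              "binary target prevalences must lie strictly in (0, 1)")
  assert_that(all(apply(binary_targets, 1, function(x) all(diff(x) >= 0))),
              "binary target prevalences must be non-decreasing over time")
  assert_that(all(within_corr >= 0 & within_corr < 1) &&
                setequal(names(within_corr), component_names),
              "`within_corr` needs one value in [0,1) per variable")
  assert_that(between_corr >= 0 && between_corr < 1,
              "`between_corr` must lie in [0,1)")

  spec <- structure(
    list(n_subjects = as.integer(n_subjects),
         n_times = as.integer(n_times),
         component_names = component_names,
         binary_components = binary_components,
         means = means, sds = sds,
         within_corr = within_corr[component_names],
         between_corr = between_corr,
         binary_targets = binary_targets,
         covariate_spec = covariate_spec,
         time_step = time_step,
         seed = seed),
    class = "cohort_spec")
  # fail early if the assembled correlation matrix is not positive definite
  assemble_latent_corr(spec)
  spec
}

#' Default cohort specification
#'
#' Ships the study's default generating conditions: six variables over five
#' exams spaced five years apart, realistic mid-life cardiovascular values with
#' non-decreasing means (BMI, blood pressures, cholesterol and glucose drifting
#' upward as the cohort ages), exchangeable within-variable correlation 0.7,
#' between-variable correlation 0.15, smoking prevalence rising slowly from
#' 15%, and baseline covariates age ~ N(55, 9^2), 45% male.
#'
#' @param n_subjects Cohort size (3700 for the full-scale study preset).
#' @param n_times Number of exams.
#' @param seed Optional seed stored with the spec.
#' @return A `cohort_spec`.
#' @export
default_cohort_spec <- function(n_subjects = 3700, n_times = 5, seed = NULL) {
  cont <- c("BMI", "SBP", "DBP", "TC", "BG")
  means <- rbind(
    BMI = c(27.2, 27.7, 28.1, 28.4, 28.6),
    SBP = c(125, 129, 133, 137, 141),
    DBP = c(75, 76, 76.5, 77, 77),
    TC  = c(205, 209, 212, 214, 215),
    BG  = c(98, 101, 104, 107, 110))[, seq_len(n_times), drop = FALSE]
  sds <- matrix(rep(c(4.8, 18, 10, 38, 22), n_times), nrow = 5,
                dimnames = list(cont, NULL))
  smk <- rbind(SMK = c(0.15, 0.16, 0.17, 0.18, 0.19))[, seq_len(n_times),
                                                      drop = FALSE]
  cohort_spec(n_subjects = n_subjects, n_times = n_times,
              means = means, sds = sds, binary_targets = smk, seed = seed)
}

# Joint latent correlation matrix over (variable x time) latents plus the two
# baseline covariates, variable-major column order, covariates last.
assemble_latent_corr <- function(spec) {
  vars <- spec$component_names
  Tn <- spec$n_times
  cols <- c(vt_names(vars, Tn), "age", "sex")
  K <- length(cols)
  R <- matrix(spec$between_corr, K, K, dimnames = list(cols, cols))
  for (v in vars) {
    idx <- match(paste(v, seq_len(Tn), sep = "_"), cols)
    R[idx, idx] <- spec$within_corr[[v]]
  }
  diag(R) <- 1
  ch <- tryCatch(chol(R), error = function(e) NULL)
  if (is.null(ch)) {
    abort(paste0(
      "assembled latent correlation matrix is not positive definite; ",
      "check within_corr (", paste(spec$within_corr, collapse = ", "),
      ") and between_corr (", spec$between_corr, ") blocks"))
  }
  list(corr = R, chol = ch, cols = cols)
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("<cohort_spec> ", x$n_subjects, " subjects x ", x$n_times,
      " time points (every ", x$time_step, " years)\n", sep = "")
  cat("  variables: ", paste(x$component_names, collapse = ", "),
      " (binary: ", paste(x$binary_components, collapse = ", "), ")\n", sep = "")
  cat("  within-variable corr: ", paste(unique(x$within_corr), collapse = "/"),
      "; between-variable corr: ", x$between_corr, "\n", sep = "")
  invisible(x)
}
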