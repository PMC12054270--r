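#' Ignorability assumption linking ignorable and non-ignorable imputations
#'
#' The sensitivity parameter `k` converts imputations drawn under the
#' missing-at-random assumption into their non-ignorable counterparts: for
#' continuous components the imputed value is multiplied by `k_cont`; for the
#' binary component `k_bin` acts as an odds ratio on the imputation
#' probability, `logit(pi_nonignr) = log(k_bin) + logit(pi_ignr)`. The default
#' pairing follows the study's sensitivity grid: `k_cont = 1` pairs with
#' `k_bin = 1` (missing at random), `k_cont` of 1.1 or 1.2 with `k_bin = 2`
#' (non-attendees in worse health), and 0.8 or 0.9 with `k_bin = 0.5` (better
#' health).
#'
#' @param k_cont Positive multiplier for continuous components.
#' @param k_bin Positive odds ratio for the binary component; defaults to the
#'   grid pairing for `k_cont`.
#' @return A list of class `ignorability`.
#' @export
ignorability <- function(k_cont = 1, k_bin = NULL) {
  assert_that(k_cont > 0, "k_cont must be positive")
  if (is.null(k_bin)) {
    k_bin <- if (k_cont > 1) 2 else if (k_cont < 1) 0.5 else 1
  }
  assert_that(k_bin > 0, "k_bin must be positive")
  structure(list(k_cont = k_cont, k_bin = k_bin), class = "ignorability")
}

#' The default sensitivity grid of ignorability assumptions
#'
#' @return A named list of [ignorability()] objects for
#'   `k_cont = 0.8, 0.9, 1, 1.1, 1.2` with their paired binary odds ratios.
#' @export
default_k_grid <- function() {
  ks <- c(0.8, 0.9, 1, 1.1, 1.2)
  setNames(lapply(ks, ignorability), paste0("k", format(ks)))
}

#' Scale ignorable continuous imputations to non-ignorable values
#'
#' Element-wise multiplication by `k_cont` (`k = 1.2` makes the non-ignorable
#' values 20% larger than their ignorable counterparts). Applied only to cells
#' missing through the MNAR mechanism.
#'
#' @param ignorable Numeric vector of ignorable imputed values.
#' @param k_cont Positive multiplier.
#' @return The transformed vector.
#' @export
transform_continuous <- function(ignorable, k_cont) {
  assert_that(all(is.finite(ignorable)), "values must be finite")
  ignorable * k_cont
}

#' Shift ignorable binary imputations by an odds ratio
#'
#' Fits a logistic regression of the ignorable imputed 0/1 values on the
#' supplied predictors to obtain per-cell `logit(pi_ignr)`, shifts every logit
#' by `log(k_bin)`, and redraws each cell from Bernoulli at the shifted
#' probability. With `k_bin = 1` the probabilities are unchanged and the input
#' is returned as is.
#'
#' @param ignorable_bin 0/1 vector of ignorable imputed values.
#' @param predictors Numeric matrix of predictors for these cells (an
#'   intercept is added internally).
#' @param k_bin Positive odds ratio.
#' @param seed RNG seed.
#' @return A 0/1 vector of non-ignorable imputed values.
#' @export
transform_binary <- function(ignorable_bin, predictors, k_bin, seed = NULL) {
  if (k_bin == 1) return(ignorable_bin)
  if (all(ignorable_bin == ignorable_bin[1])) {
    abort("single-class ignorable imputations: logit undefined for k_bin != 1")
  }
  X <- cbind(1, as.matrix(predictors))
  beta <- cpp_logistic_fit(X, as.numeric(ignorable_bin), 1e-6)
  eta <- as.vector(X %*% beta) + log(k_bin)
  with_seed(seed, as.integer(runif(length(eta)) < plogis(eta)))
}

# ---------------------------------------------------------------------------
# Stage 1

# m chained runs over the full missingness pattern; returns the completed
# working matrices (needed to evaluate the binary transform's predictors).
# The engine plan and working matrix are built once and reused across runs.
stage1_raw <- function(panel, mask, config, m, seed, events = NULL) {
  vt <- vt_cols(panel)
  plan <- fcs_plan(panel, mask, config, c(MECH_A, MECH_B, MECH_D))
  dat0 <- fcs_matrix(panel, config, events)
  if (is.null(plan)) {
    vals <- dat0[, seq_along(vt), drop = FALSE]
    return(replicate(m, vals, simplify = FALSE))
  }
  for (i in seq_along(plan$targets)) {
    dat0[plan$miss_rows[[i]] + 1L, plan$target_col[i] + 1L] <- NA_real_
  }
  lapply(seq_len(m), function(j) {
    done <- with_seed(derive_seed(seed, 1L, j),
      cpp_impute_chained(dat0, plan$target_col, plan$miss_rows,
                         plan$pred_cols, plan$method, config$n_iterations))
    out <- done[, seq_along(vt), drop = FALSE]
    colnames(out) <- vt
    out
  })
}

# Apply the k-transform to one stage-1 completed matrix and keep only the
# MNAR (and post-death) cell values. Post-death cells are fixed but not
# k-transformed unless `transform_death` is set.
apply_ignorability <- function(raw_vals, panel, mask, config, assumption,
                               seed, events = NULL, transform_death = FALSE) {
  vt <- vt_cols(panel)
  keep <- matrix(NA_real_, nrow(raw_vals), length(vt),
                 dimnames = list(NULL, vt))
  a_codes <- if (transform_death) c(MECH_A, MECH_D) else MECH_A
  fixed_codes <- c(MECH_A, MECH_D)
  pm <- build_predictor_matrix(config$structure, panel$vars, panel$n_times,
                               config$cox_mode)
  full <- raw_vals
  if (config$cox_mode) {
    h0 <- nelson_aalen_cumhaz(events)
    full <- cbind(raw_vals, age = panel$data$age, sex = panel$data$sex,
                  death = events$event_indicator, H0 = h0$H0)
  } else {
    full <- cbind(raw_vals, age = panel$data$age, sex = panel$data$sex)
  }
  si <- 0L
  for (cn in vt) {
    cells <- mask$mech[, cn] %in% fixed_codes
    if (!any(cells)) next
    v <- sub("_[0-9]+$", "", cn)
    adj <- mask$mech[, cn] %in% a_codes
    vals <- raw_vals[, cn]
    if (any(adj)) {
      si <- si + 1L
      if (v %in% panel$binary_vars) {
        if (assumption$k_bin != 1 &&
            length(unique(vals[adj])) > 1) {
          preds <- full[adj, colnames(pm)[pm[cn, ] == 1L], drop = FALSE]
          vals[adj] <- transform_binary(vals[adj], preds, assumption$k_bin,
                                        seed = derive_seed(seed, 3L, si))
        }
      } else {
        vals[adj] <- transform_continuous(vals[adj], assumption$k_cont)
      }
    }
    keep[cells, cn] <- vals[cells]
  }
  keep
}

#' Stage 1: impute and adjust the non-ignorable missingness
#'
#' Runs chained-equations imputation `m` times over the full missingness
#' pattern (independent sub-seeds), retains only the MNAR-cell values (plus
#' post-death cells in Cox mode, which are fixed but not adjusted), and
#' transforms the MNAR cells to their non-ignorable counterparts under the
#' given ignorability assumption. MAR-cell draws from this stage are
#' discarded; they are re-imputed in Stage 2.
#'
#' @param panel A `component_panel`.
#' @param mask A `missing_mask` with mechanism labels.
#' @param config An [fcs_config()].
#' @param assumption An [ignorability()].
#' @param m Number of Stage-1 imputations (at least 2 for pooling).
#' @param seed RNG seed (Stage-1 sub-seeds do not depend on the assumption, so
#'   runs at different `k` share their underlying ignorable draws).
#' @param events Event table (Cox mode).
#' @return An object of class `stage1_values`: `m` matrices holding values at
#'   the fixed cells and `NA` elsewhere.
#' @export
run_stage1 <- function(panel, mask, config, assumption = ignorability(1),
                       m = 5, seed = NULL, events = NULL) {
  seed <- seed %||% sample.int(.Machine$integer.max, 1)
  raw <- stage1_raw(panel, mask, config, m, seed, events)
  values <- lapply(seq_len(m), function(j) {
    apply_ignorability(raw[[j]], panel, mask, config, assumption,
                       seed = derive_seed(seed, 2L, j), events = events)
  })
  structure(list(values = values, m = m, assumption = assumption),
            class = "stage1_values")
}

# ---------------------------------------------------------------------------
# Stage 2 and the nested stack

new_imputed_stack <- function(panels, skeleton, mask, m, n, assumption,
                              config) {
  stack <- structure(
    list(panels = panels, skeleton = skeleton, mask = mask, m = m, n = n,
         assumption = assumption, config = config),
    class = "imputed_stack")
  validate_stack(stack)
  stack
}

# Invariants of the nested structure: within a block all panels agree on the
# fixed (MNAR and post-death) cells; across the whole stack all panels agree
# on the observed cells.
validate_stack <- function(stack) {
  fixed <- stack$mask$mech == MECH_A | stack$mask$mech == MECH_D
  obs <- stack$mask$mech == MECH_OBS
  ref_obs <- stack$panels[[1]][[1]][obs]
  for (j in seq_len(stack$m)) {
    ref_fixed <- stack$panels[[j]][[1]][fixed]
    for (k in seq_len(stack$n)) {
      p <- stack$panels[[j]][[k]]
      if (any(p[fixed] != ref_fixed)) {
        abort("stack invariant violated: MNAR cells differ within a block")
      }
      if (any(p[obs] != ref_obs)) {
        abort("stack invariant violated: observed cells differ across panels")
      }
    }
  }
  invisible(stack)
}

#' @export
print.imputed_stack <- function(x, ...) {
  cat("<imputed_stack> m = ", x$m, " blocks x n = ", x$n,
      " imputations (k_cont = ", x$assumption$k_cont,
      ", k_bin = ", x$assumption$k_bin, ", ", x$config$structure, ")\n",
      sep = "")
  invisible(x)
}

#' Extract one completed panel from a stack
#'
#' @param stack An `imputed_stack`.
#' @param j Stage-1 block index.
#' @param k Stage-2 index within the block.
#' @return A completed `component_panel`.
#' @export
stack_panel <- function(stack, j, k) {
  set_panel_values(stack$skeleton, stack$panels[[j]][[k]])
}

#' Stage 2: impute the ignorable missingness within each block
#'
#' For each Stage-1 block the MNAR (and post-death) values are fixed and
#' known; the MAR cells are then imputed `n` times independently by chained
#' equations restricted to those cells. The result is the full nested stack of
#' `m x n` completed panels.
#'
#' @param panel,mask,config,events As in [run_stage1()].
#' @param stage1_values A `stage1_values` object.
#' @param n Number of Stage-2 imputations per block (at least 2).
#' @param seed RNG seed.
#' @return An `imputed_stack`.
#' @export
run_stage2 <- function(panel, mask, stage1_values, config, n = 5, seed = NULL,
                       events = NULL) {
  seed <- seed %||% sample.int(.Machine$integer.max, 1)
  m <- stage1_values$m
  vt <- vt_cols(panel)
  fixed <- which(mask$mech == MECH_A | mask$mech == MECH_D)
  plan <- fcs_plan(panel, mask, config, MECH_B)
  dat_base <- fcs_matrix(panel, config, events)
  if (!is.null(plan)) {
    for (i in seq_along(plan$targets)) {
      dat_base[plan$miss_rows[[i]] + 1L, plan$target_col[i] + 1L] <- NA_real_
    }
  }
  nvt <- length(vt)
  panels <- lapply(seq_len(m), function(j) {
    datj <- dat_base
    # fixed cells are linear indices into the leading vt block of the matrix
    datj[fixed] <- stage1_values$values[[j]][fixed]
    lapply(seq_len(n), function(kk) {
      if (is.null(plan)) {
        out <- datj[, seq_len(nvt), drop = FALSE]
      } else {
        done <- with_seed(derive_seed(seed, 4L, j, kk),
          cpp_impute_chained(datj, plan$target_col, plan$miss_rows,
                             plan$pred_cols, plan$method,
                             config$n_iterations))
        out <- done[, seq_len(nvt), drop = FALSE]
      }
      colnames(out) <- vt
      out
    })
  })
  new_imputed_stack(panels, panel, mask, m, n, stage1_values$assumption,
                    config)
}

#' Run the full two-stage multiple imputation
#'
#' Composition of [run_stage1()] (non-ignorable missingness, `m` imputations,
#' k-adjustment) and [run_stage2()] (ignorable missingness, `n` imputations
#' per block), yielding the nested `m x n` stack. With a fully observed panel
#' the stack holds identical copies of the input.
#'
#' @inheritParams run_stage1
#' @param n Number of Stage-2 imputations per block.
#' @return An `imputed_stack`.
#' @export
run_two_stage <- function(panel, mask, config = fcs_config(),
                          assumption = ignorability(1), m = 5, n = 5,
                          seed = NULL, events = NULL) {
  seed <- seed %||% sample.int(.Machine$integer.max, 1)
  s1 <- run_stage1(panel, mask, config, assumption, m = m,
                   seed = derive_seed(seed, 10L), events = events)
  run_stage2(panel, mask, s1, config, n = n, seed = derive_seed(seed, 20L),
             events = events)
}

# Shared-stage-1 grid: one set of raw Stage-1 draws serves every ignorability
# assumption, so sensitivity runs differ only through the k-transform (and the
# Stage-2 imputations that condition on it).
two_stage_grid <- function(panel, mask, config, assumptions, m, n, seed,
                           events = NULL) {
  s1seed <- derive_seed(seed, 10L)
  raw <- stage1_raw(panel, mask, config, m, s1seed, events)
  out <- lapply(assumptions, function(a) {
    values <- lapply(seq_len(m), function(j) {
      apply_ignorability(raw[[j]], panel, mask, config, a,
                         seed = derive_seed(s1seed, 2L, j), events = events)
    })
    s1 <- structure(list(values = values, m = m, assumption = a),
                    class = "stage1_values")
    run_stage2(panel, mask, s1, config, n = n, seed = derive_seed(seed, 20L),
               events = events)
  })
  names(out) <- names(assumptions)
  out
}
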