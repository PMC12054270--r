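#' Pool estimates from a nested two-stage imputation grid
#'
#' Combines per-dataset estimates `Q^(j,k)` and their within-dataset variances
#' `U^(j,k)` from an `m x n` nested stack with the two-stage combining rules:
#' the pooled point estimate is the grand mean; the total variance
#' `T = Ubar + (1 + 1/m) B + (1 - 1/n) W` adds the average within-dataset
#' variance, the between-block variance of the Stage-1 block means, and the
#' average within-block variance; and the reference distribution is Student t
#' with degrees of freedom
#' `nu*^-1 = ((1+1/m)B/T)^2/(m-1) + ((1-1/n)W/T)^2/(m(n-1))`. When both
#' squared terms vanish the normal reference is used (`df = Inf`), and a zero
#' total variance yields a degenerate zero-width interval.
#'
#' @param grid Either a data frame with columns `j`, `k`, `qhat`, `uhat`
#'   (block index, within-block index, estimate, within-dataset variance) or a
#'   list with `qhat` and `uhat` matrices of dimension `m x n`.
#' @param level Confidence level (default 0.95).
#' @return An object of class `pooled_estimate` with fields `q_bar`, `u_bar`,
#'   `b_between`, `w_within`, `t_total`, `df`, `ci_low`, `ci_high`, `level`,
#'   `m`, `n`.
#' @export
pool_two_stage <- function(grid, level = 0.95) {
  if (is.data.frame(grid)) {
    assert_that(all(c("j", "k", "qhat", "uhat") %in% names(grid)),
                "grid needs columns j, k, qhat, uhat")
    m <- length(unique(grid$j)); n <- length(unique(grid$k))
    assert_that(nrow(grid) == m * n && !anyNA(grid$qhat) && !anyNA(grid$uhat),
                "grid must be complete (m x n rows, no missing cells)")
    qhat <- matrix(grid$qhat[order(grid$j, grid$k)], m, n, byrow = TRUE)
    uhat <- matrix(grid$uhat[order(grid$j, grid$k)], m, n, byrow = TRUE)
  } else {
    qhat <- as.matrix(grid$qhat); uhat <- as.matrix(grid$uhat)
    m <- nrow(qhat); n <- ncol(qhat)
  }
  assert_that(m >= 2 && n >= 2,
              "two-stage pooling needs m >= 2 blocks and n >= 2 per block")
  assert_that(all(uhat >= 0), "within-dataset variances must be non-negative")

  q_bar <- mean(qhat)
  u_bar <- mean(uhat)
  q_j <- rowMeans(qhat)
  b <- sum((q_j - q_bar)^2) / (m - 1)
  w <- sum((qhat - q_j)^2 / (n - 1)) / m
  t_total <- u_bar + (1 + 1 / m) * b + (1 - 1 / n) * w

  if (t_total <= 0) {
    df <- Inf
    ci <- c(q_bar, q_bar)
    degenerate <- TRUE
  } else {
    nu_inv <- ((1 + 1 / m) * b / t_total)^2 / (m - 1) +
      ((1 - 1 / n) * w / t_total)^2 / (m * (n - 1))
    df <- if (nu_inv > 0) 1 / nu_inv else Inf
    half <- qt((1 + level) / 2, df = df) * sqrt(t_total)
    ci <- q_bar + c(-half, half)
    degenerate <- FALSE
  }
  structure(list(q_bar = q_bar, u_bar = u_bar, b_between = b, w_within = w,
                 t_total = t_total, df = df, ci_low = ci[1], ci_high = ci[2],
                 level = level, m = m, n = n, degenerate = degenerate),
            class = "pooled_estimate")
}

#' @export
print.pooled_estimate <- function(x, ...) {
  cat(sprintf(
    "<pooled_estimate> Q = %.4g, T = %.4g (U = %.3g, B = %.3g, W = %.3g), df = %.3g\n",
    x$q_bar, x$t_total, x$u_bar, x$b_between, x$w_within, x$df))
  cat(sprintf("  %.0f%% CI [%.4g, %.4g]  (m = %d, n = %d)\n",
              100 * x$level, x$ci_low, x$ci_high, x$m, x$n))
  invisible(x)
}

#' @rdname pool_two_stage
#' @param x A `pooled_estimate`.
#' @param ... Unused.
#' @export
tidy.pooled_estimate <- function(x, ...) {
  tibble(estimate = x$q_bar, std.error = sqrt(x$t_total), df = x$df,
         conf.low = x$ci_low, conf.high = x$ci_high)
}

#' @rdname pool_two_stage
#' @export
glance.pooled_estimate <- function(x, ...) {
  tibble(u_bar = x$u_bar, b_between = x$b_between, w_within = x$w_within,
         t_total = x$t_total, df = x$df, m = x$m, n = x$n, level = x$level)
}

#' Apply an estimator to every panel of a stack and pool
#'
#' Runs `estimator_fn` on each of the `m x n` completed panels and pools each
#' returned parameter with [pool_two_stage()]. An estimator failure on any
#' panel aborts with the offending block and index flagged, never silently
#' dropped.
#'
#' @param estimator_fn Function taking a completed `component_panel` and
#'   returning a data frame with columns `parameter`, `estimate`, `variance`.
#' @param stack An `imputed_stack`.
#' @param level Confidence level.
#' @return A tibble with one row per parameter: pooled estimate, the variance
#'   components, degrees of freedom and confidence bounds.
#' @export
pool_replicate <- function(estimator_fn, stack, level = 0.95) {
  ests <- vector("list", stack$m * stack$n)
  idx <- 0L
  for (j in seq_len(stack$m)) {
    for (k in seq_len(stack$n)) {
      idx <- idx + 1L
      res <- tryCatch(estimator_fn(stack_panel(stack, j, k)),
                      error = function(e) {
                        abort(sprintf(
                          "estimator failed on imputed panel (j = %d, k = %d): %s",
                          j, k, conditionMessage(e)))
                      })
      ests[[idx]] <- mutate(as_tibble(res), j = j, k = k)
    }
  }
  all <- bind_rows(ests)
  all %>%
    group_by(.data$parameter) %>%
    dplyr::group_modify(function(d, g) {
      p <- pool_two_stage(list(
        qhat = matrix(d$estimate[order(d$j, d$k)], stack$m, stack$n,
                      byrow = TRUE),
        uhat = matrix(d$variance[order(d$j, d$k)], stack$m, stack$n,
                      byrow = TRUE)), level = level)
      tibble(q_bar = p$q_bar, u_bar = p$u_bar, b_between = p$b_between,
             w_within = p$w_within, t_total = p$t_total, df = p$df,
             ci_low = p$ci_low, ci_high = p$ci_high, m = p$m, n = p$n)
    }) %>%
    ungroup()
}
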