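# brute-force oracle: direct loop-based two-stage combining rules
pool_oracle <- function(qhat, uhat, level = 0.95) {
  m <- nrow(qhat); n <- ncol(qhat)
  qbar <- mean(qhat)
  ubar <- mean(uhat)
  qj <- numeric(m)
  for (j in 1:m) qj[j] <- mean(qhat[j, ])
  b <- 0
  for (j in 1:m) b <- b + (qj[j] - qbar)^2
  b <- b / (m - 1)
  w <- 0
  for (j in 1:m) {
    wj <- 0
    for (k in 1:n) wj <- wj + (qhat[j, k] - qj[j])^2
    w <- w + wj / (n - 1)
  }
  w <- w / m
  tt <- ubar + (1 + 1 / m) * b + (1 - 1 / n) * w
  nu_inv <- (((1 + 1 / m) * b / tt)^2) / (m - 1) +
    (((1 - 1 / n) * w / tt)^2) / (m * (n - 1))
  list(q = qbar, u = ubar, b = b, w = w, t = tt,
       df = if (nu_inv > 0) 1 / nu_inv else Inf)
}

test_that("the worked 2x2 grid reproduces the combining-rule arithmetic", {
  p <- pool_two_stage(list(qhat = rbind(c(1, 2), c(3, 4)),
                           uhat = matrix(0, 2, 2)))
  expect_equal(p$q_bar, 2.5)
  expect_equal(p$b_between, 2)
  expect_equal(p$w_within, 0.5)
  expect_equal(p$t_total, 3.25)
  # nu*^-1 = (3/3.25)^2 / 1 + (0.25/3.25)^2 / 2
  expect_equal(p$df, 1 / ((3 / 3.25)^2 + 0.5 * (0.25 / 3.25)^2),
               tolerance = 1e-10)
  expect_equal(p$df, 1.169551, tolerance = 1e-6)
})

test_that("degenerate grids take their limiting forms", {
  # no spread at all: T = u, normal reference
  p <- pool_two_stage(list(qhat = matrix(2, 3, 3), uhat = matrix(0.5, 3, 3)))
  expect_equal(p$q_bar, 2)
  expect_equal(p$b_between, 0)
  expect_equal(p$w_within, 0)
  expect_equal(p$t_total, 0.5)
  expect_equal(p$df, Inf)
  expect_equal(p$ci_high - p$q_bar, qnorm(0.975) * sqrt(0.5), tolerance = 1e-10)

  # U = W = 0, B > 0: df = m - 1 exactly
  q <- matrix(c(1, 1, 2, 2, 5, 5), 3, 2, byrow = TRUE)
  p2 <- pool_two_stage(list(qhat = q, uhat = matrix(0, 3, 2)))
  expect_equal(p2$df, 3 - 1)

  # fully degenerate: zero-width interval flagged
  p3 <- pool_two_stage(list(qhat = matrix(1, 2, 2), uhat = matrix(0, 2, 2)))
  expect_true(p3$degenerate)
  expect_equal(p3$ci_low, p3$ci_high)

  expect_error(pool_two_stage(list(qhat = matrix(1, 1, 3),
                                   uhat = matrix(1, 1, 3))), "m >= 2")
})

test_that("formula outputs match the brute-force oracle on random grids", {
  set.seed(61)
  for (rep in 1:25) {
    m <- sample(2:6, 1); n <- sample(2:6, 1)
    qhat <- matrix(rnorm(m * n, 3, 2), m, n)
    uhat <- matrix(rexp(m * n), m, n)
    p <- pool_two_stage(list(qhat = qhat, uhat = uhat))
    o <- pool_oracle(qhat, uhat)
    expect_equal(p$q_bar, o$q, tolerance = 1e-12)
    expect_equal(p$b_between, o$b, tolerance = 1e-12)
    expect_equal(p$w_within, o$w, tolerance = 1e-12)
    expect_equal(p$t_total, o$t, tolerance = 1e-12)
    expect_equal(p$df, o$df, tolerance = 1e-9)
    # exact identity re-asserted from components
    expect_equal(p$t_total,
                 p$u_bar + (1 + 1 / m) * p$b_between +
                   (1 - 1 / n) * p$w_within, tolerance = 1e-12)
    expect_true(p$ci_low <= p$q_bar && p$q_bar <= p$ci_high)
  }
})

test_that("B and W are translation invariant; the mean shifts", {
  set.seed(62)
  qhat <- matrix(rnorm(12), 3, 4)
  uhat <- matrix(rexp(12), 3, 4)
  p1 <- pool_two_stage(list(qhat = qhat, uhat = uhat))
  p2 <- pool_two_stage(list(qhat = qhat + 7, uhat = uhat))
  expect_equal(p2$q_bar, p1$q_bar + 7)
  expect_equal(p2$b_between, p1$b_between)
  expect_equal(p2$w_within, p1$w_within)

  # df decreases as the between-block share of T grows (fixed m, n, W, U = 0):
  # grids constructed with exact B and W so only the B-share moves
  m <- 3; n <- 4
  w_dev <- sqrt(3 / 5) * c(-1.5, -0.5, 0.5, 1.5) # W = 1 per block
  dfs <- sapply(c(1, 2, 4, 8), function(B) {
    b_dev <- sqrt(B) * c(-1, 0, 1) # sum of squares = B (m - 1)
    q <- outer(b_dev, rep(1, n)) + matrix(w_dev, m, n, byrow = TRUE)
    p <- pool_two_stage(list(qhat = q, uhat = matrix(0, m, n)))
    stopifnot(abs(p$b_between - B) < 1e-12, abs(p$w_within - 1) < 1e-12)
    p$df
  })
  expect_true(all(diff(dfs) < 0))
})

test_that("grid data frames and matrix input agree", {
  set.seed(63)
  df <- expand.grid(j = 1:3, k = 1:2)
  df$qhat <- rnorm(6); df$uhat <- rexp(6)
  p_df <- pool_two_stage(df)
  p_mat <- pool_two_stage(list(
    qhat = matrix(df$qhat[order(df$j, df$k)], 3, 2, byrow = TRUE),
    uhat = matrix(df$uhat[order(df$j, df$k)], 3, 2, byrow = TRUE)))
  expect_equal(p_df$t_total, p_mat$t_total)
  expect_equal(tidy(p_df)$estimate, p_mat$q_bar)
  expect_equal(glance(p_df)$m, 3)
})

test_that("pool_replicate pools estimators over a stack", {
  cohort <- small_cohort(250, seed = 64)
  stack <- run_two_stage(cohort$panel, cohort$mask, fcs_config("LFCS"),
                         ignorability(1), m = 2, n = 2, seed = 11)

  # constant estimator: no between or within spread
  const <- function(panel) tibble::tibble(parameter = "c", estimate = 1,
                                          variance = 0.2)
  p <- pool_replicate(const, stack)
  expect_equal(p$b_between, 0)
  expect_equal(p$w_within, 0)
  expect_equal(p$q_bar, 1)

  # no missing data: pooled mean equals the complete-data estimate exactly
  stack0 <- run_two_stage(cohort$panel, twostagemi:::empty_mask(cohort$panel),
                          fcs_config("LFCS"), ignorability(1), m = 2, n = 2,
                          seed = 12)
  p0 <- pool_replicate(est_mean_by_time(), stack0)
  full <- mean_by_time(build_composite(cohort$panel))
  expect_equal(p0$q_bar, full$estimate)
  expect_equal(p0$b_between, rep(0, 5))

  # imputation inflates variance: T >= Ubar
  p1 <- pool_replicate(est_mean_by_time(), stack)
  expect_true(all(p1$t_total >= p1$u_bar))

  # estimator failures are flagged with their block coordinates
  boom <- function(panel) stop("nope")
  expect_error(pool_replicate(boom, stack), "j = 1, k = 1")
})
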