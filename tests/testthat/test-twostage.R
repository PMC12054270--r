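test_that("the continuous k-transform is exact multiplication", {
  expect_equal(transform_continuous(c(1, 2, 3), 1), c(1, 2, 3))
  expect_equal(transform_continuous(100, 1.2), 120)
  expect_equal(transform_continuous(250, 0.8), 200)
  expect_error(transform_continuous(c(1, Inf), 1.1), "finite")
})

test_that("the binary k-transform shifts the odds as specified", {
  # odds 1 -> odds 2 under k_bin = 2
  set.seed(51)
  ig <- rbinom(20000, 1, 0.5)
  nb <- transform_binary(ig, matrix(0, length(ig), 0), k_bin = 2, seed = 1)
  p_obs <- mean(ig); odds <- p_obs / (1 - p_obs) * 2
  target <- odds / (1 + odds)
  expect_lt(abs(mean(nb) - target), 3 * sqrt(target * (1 - target) / 20000))

  # identity at k_bin = 1
  expect_identical(transform_binary(ig, matrix(0, length(ig), 0), 1), ig)

  # prevalence 0.3 with k_bin = 0.5: odds 3/7 halves
  ig3 <- rbinom(20000, 1, 0.3)
  nb3 <- transform_binary(ig3, matrix(0, length(ig3), 0), 0.5, seed = 2)
  odds3 <- mean(ig3) / (1 - mean(ig3)) * 0.5
  t3 <- odds3 / (1 + odds3)
  expect_lt(abs(mean(nb3) - t3), 3 * sqrt(t3 * (1 - t3) / 20000))

  expect_error(transform_binary(rep(1L, 10), matrix(0, 10, 0), 2),
               "single-class")
})

test_that("stage 1 retains adjusted MNAR draws and fixes post-death cells", {
  cohort <- small_cohort(300, seed = 52)
  cfg <- fcs_config("LFCS")

  # no MNAR cells: stage 1 retains nothing
  mask_b_only <- cohort$mask
  mask_b_only$mech[mask_b_only$mech == 1L] <- 0L
  s1 <- run_stage1(cohort$panel, mask_b_only, cfg, ignorability(1.2),
                   m = 2, seed = 3)
  expect_true(all(is.na(s1$values[[1]])))

  # identity transform: retained values equal the raw chained draws
  s_id <- run_stage1(cohort$panel, cohort$mask, cfg, ignorability(1, 1),
                     m = 2, seed = 4)
  raw <- twostagemi:::stage1_raw(cohort$panel, cohort$mask, cfg, 2, 4)
  acell <- cohort$mask$mech == 1L
  expect_equal(s_id$values[[1]][acell], raw[[1]][acell])

  # k_cont = 1.2: every continuous MNAR value is exactly 1.2 x its raw draw
  s_k <- run_stage1(cohort$panel, cohort$mask, cfg, ignorability(1.2),
                    m = 2, seed = 4)
  cont_cols <- !grepl("^SMK", colnames(cohort$mask$mech))
  sel <- acell & matrix(rep(cont_cols, each = nrow(acell)), nrow(acell))
  expect_equal(s_k$values[[1]][sel], 1.2 * raw[[1]][sel])
})

test_that("stage 2 produces the nested block structure", {
  cohort <- small_cohort(300, seed = 53)
  cfg <- fcs_config("LFCS")
  stack <- run_two_stage(cohort$panel, cohort$mask, cfg, ignorability(1.1),
                         m = 2, n = 2, seed = 5)
  expect_equal(length(stack$panels), 2)
  expect_equal(length(stack$panels[[1]]), 2)

  acell <- cohort$mask$mech == 1L
  obs <- cohort$mask$mech == 0L
  # MNAR cells: identical within block, generally differing between blocks
  expect_equal(stack$panels[[1]][[1]][acell], stack$panels[[1]][[2]][acell])
  expect_false(all(stack$panels[[1]][[1]][acell] ==
                     stack$panels[[2]][[1]][acell]))
  # observed cells identical everywhere
  expect_equal(stack$panels[[1]][[1]][obs], stack$panels[[2]][[2]][obs])
  # MAR cells differ within a block (independent stage-2 draws)
  bcell <- cohort$mask$mech == 2L
  expect_false(all(stack$panels[[1]][[1]][bcell] ==
                     stack$panels[[1]][[2]][bcell]))

  # no MAR cells: all panels within a block identical
  mask_a_only <- cohort$mask
  mask_a_only$mech[mask_a_only$mech == 2L] <- 0L
  s1 <- run_stage1(cohort$panel, mask_a_only, cfg, ignorability(1.1),
                   m = 2, seed = 6)
  st2 <- run_stage2(cohort$panel, mask_a_only, s1, cfg, n = 2, seed = 7)
  expect_identical(st2$panels[[1]][[1]], st2$panels[[1]][[2]])
})

test_that("the full two-stage run is reproducible and degenerates cleanly", {
  cohort <- small_cohort(250, seed = 54)
  cfg <- fcs_config("LFCS")

  # fully observed panel: identical copies of the input
  stack0 <- run_two_stage(cohort$panel, twostagemi:::empty_mask(cohort$panel),
                          cfg, ignorability(1.1), m = 2, n = 2, seed = 8)
  v0 <- twostagemi:::panel_values(cohort$panel)
  dimnames(v0) <- list(NULL, colnames(v0))
  expect_equal(stack0$panels[[2]][[2]], v0)

  a <- run_two_stage(cohort$panel, cohort$mask, cfg, ignorability(1.1),
                     m = 2, n = 2, seed = 9)
  b <- run_two_stage(cohort$panel, cohort$mask, cfg, ignorability(1.1),
                     m = 2, n = 2, seed = 9)
  expect_identical(a$panels, b$panels)
})

test_that("shared stage-1 seeds make the k-adjustment exact and monotone", {
  cohort <- small_cohort(400, seed = 55)
  cfg <- fcs_config("LFCS")
  grid <- twostagemi:::two_stage_grid(
    cohort$panel, cohort$mask, cfg,
    list(k1 = ignorability(1), k11 = ignorability(1.1),
         k12 = ignorability(1.2)),
    m = 2, n = 2, seed = 10)

  acell <- cohort$mask$mech == 1L
  cont <- !grepl("^SMK", colnames(cohort$mask$mech))
  sel <- acell & matrix(rep(cont, each = nrow(acell)), nrow(acell))
  ratio <- grid$k11$panels[[1]][[1]][sel] / grid$k1$panels[[1]][[1]][sel]
  expect_equal(ratio, rep(1.1, sum(sel)), tolerance = 1e-12)

  # mean imputed SBP at MNAR cells rises with k (paired construction)
  sbp_sel <- acell & matrix(rep(grepl("^SBP", colnames(cohort$mask$mech)),
                                each = nrow(acell)), nrow(acell))
  expect_gt(mean(grid$k11$panels[[1]][[1]][sbp_sel]),
            mean(grid$k1$panels[[1]][[1]][sbp_sel]))

  # composite dose-response: larger k_cont lowers the composite at MNAR waves
  crit <- ideal_criteria()
  any_a <- sapply(1:5, function(t)
    rowSums(cohort$mask$mech[, paste(cohort$panel$vars, t, sep = "_")] == 1L) > 0)
  cmean <- sapply(grid, function(s)
    mean(twostagemi:::composite_scores(s$panels[[1]][[1]], 5, crit)[any_a]))
  expect_true(cmean[["k1"]] >= cmean[["k11"]])
  expect_true(cmean[["k11"]] >= cmean[["k12"]])
})
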