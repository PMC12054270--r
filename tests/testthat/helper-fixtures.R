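# Shared fixtures, built in code at test time.

# a small default cohort with both missingness mechanisms imposed
small_cohort <- function(n = 400, seed = 2) {
  spec <- default_cohort_spec(n, seed = seed)
  panel <- generate_full_panel(spec)
  mask <- merge_masks(
    generate_mnar_nonattendance(panel, mnar_scenario(1), seed = seed + 1),
    generate_mar_missingness(panel, seed = seed + 2))
  list(spec = spec, panel = panel, mask = mask)
}

# a tiny fully specified panel for hand-checkable composite arithmetic
toy_panel <- function(values, n_times = 2) {
  vars <- c("SMK", "BMI", "SBP", "DBP", "TC", "BG")
  n <- nrow(values)
  data <- tibble::tibble(subject_id = seq_len(n), miss_group = "MAR",
                         age = 55, sex = 0L)
  data <- dplyr::bind_cols(data, tibble::as_tibble(values))
  spec <- list(n_subjects = n, n_times = n_times, component_names = vars,
               binary_components = "SMK", time_step = 5)
  twostagemi:::new_component_panel(data, spec)
}

# wide value matrix helper: one row per subject, all six variables ideal
ideal_values <- function(n, n_times = 2) {
  vars <- c("SMK", "BMI", "SBP", "DBP", "TC", "BG")
  base <- c(SMK = 0, BMI = 22, SBP = 110, DBP = 70, TC = 180, BG = 90)
  m <- matrix(rep(base[vars], each = n * n_times), nrow = n)
  colnames(m) <- twostagemi:::vt_names(vars, n_times)
  m[, order(rep(seq_along(vars), n_times))] # keep variable-major order
  out <- matrix(NA_real_, n, length(vars) * n_times,
                dimnames = list(NULL, twostagemi:::vt_names(vars, n_times)))
  for (v in vars) for (t in seq_len(n_times)) {
    out[, paste(v, t, sep = "_")] <- base[[v]]
  }
  out
}

# mask with chosen cells set to a mechanism
mask_with <- function(panel, cells = list(), code = 2L) {
  mask <- twostagemi:::empty_mask(panel)
  for (cell in cells) mask$mech[cell$row, cell$col] <- code
  mask
}
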