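# Internal helpers shared across modules.

# Deterministic sub-seed derivation: one master seed expands to per-replicate,
# per-stage, per-imputation streams so any single replicate can be re-run in
# isolation. Linear-congruential mixing mod 2^31 - 1 (kept in exact double
# arithmetic; 69069 * 2^31 < 2^53).
derive_seed <- function(seed, ...) {
  idx <- c(...)
  x <- as.double(seed %% 2147483647)
  for (a in idx) {
    x <- (x * 69069 + as.double(a) + 1) %% 2147483647
  }
  as.integer(x) + 1L
}

with_seed <- function(seed, expr) {
  if (!is.null(seed)) set.seed(seed)
  expr
}

# variable-by-time column labels, variable-major ("BMI_3" = BMI at time 3)
vt_names <- function(vars, n_times) {
  as.vector(t(outer(vars, seq_len(n_times), paste, sep = "_")))
}

vt_split <- function(x) {
  m <- regmatches(x, regexpr("_[0-9]+$", x))
  list(var = sub("_[0-9]+$", "", x), time = as.integer(sub("_", "", m)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) abort(msg)
  invisible(TRUE)
}
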