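#' Ideal-level criteria for the five-component composite
#'
#' Each of the five health components is dichotomized into an ideal / not-ideal
#' indicator; the composite score is the number of components at ideal level
#' (0-5, higher is better cardiovascular health). Default cut-offs follow the
#' ideal levels of the Life's Simple 7 conventions: non-smoking, BMI below
#' 25 kg/m^2, blood pressure below 120/80 mmHg (both pressures, conjunctively),
#' total cholesterol below 200 mg/dL, and fasting glucose below 100 mg/dL.
#' All thresholds are configurable; the defaults are labelled as such in
#' exported metadata.
#'
#' A rule is a list with `vars` (one or more measured variables), `direction`
#' (`"below"`, `"above"` or `"equal"`) and `threshold` (one per variable; all
#' must satisfy the rule for the component to count as ideal).
#'
#' @param rules Named list of component rules; names are component names.
#' @return A list of class `ideal_criteria` (exactly five components).
#' @export
ideal_criteria <- function(rules = list(
    SMK = list(vars = "SMK", direction = "equal", threshold = 0),
    BMI = list(vars = "BMI", direction = "below", threshold = 25),
    BP  = list(vars = c("SBP", "DBP"), direction = "below",
               threshold = c(120, 80)),
    TC  = list(vars = "TC", direction = "below", threshold = 200),
    BG  = list(vars = "BG", direction = "below", threshold = 100))) {
  assert_that(length(rules) == 5, "composite criteria need exactly 5 components")
  for (r in rules) {
    assert_that(all(is.finite(r$threshold)) &&
                  length(r$threshold) == length(r$vars),
                "each rule needs one finite threshold per variable")
    assert_that(r$direction %in% c("below", "above", "equal"),
                "rule direction must be below/above/equal")
  }
  structure(rules, class = "ideal_criteria", source = "package default")
}

#' Build the composite score matrix
#'
#' Computes, for every subject and time point, the number of components at
#' ideal level. The score is defined only where every component indicator is
#' determinable; a single missing variable at a cell makes that cell's score
#' missing.
#'
#' @param panel A `component_panel` (may contain `NA` cells).
#' @param criteria An [ideal_criteria()] set.
#' @return An object of class `composite_matrix`: subject x time integer
#'   scores, with the subject ids and time grid attached.
#' @export
build_composite <- function(panel, criteria = ideal_criteria()) {
  bad <- setdiff(unlist(lapply(criteria, `[[`, "vars")), panel$vars)
  if (length(bad)) {
    abort(paste0("criteria reference unknown variables: ",
                 paste(bad, collapse = ", ")))
  }
  structure(list(scores = composite_scores(panel_values(panel), panel$n_times,
                                           criteria),
                 subject_id = panel$data$subject_id,
                 time_grid = panel$time_grid),
            class = "composite_matrix")
}

# matrix-level scorer: `vals` is the subject x variable-time value matrix
composite_scores <- function(vals, n_times, criteria) {
  scores <- matrix(0, nrow(vals), n_times)
  for (rule in criteria) {
    ind <- matrix(TRUE, nrow(vals), n_times)
    for (i in seq_along(rule$vars)) {
      v <- vals[, paste(rule$vars[i], seq_len(n_times), sep = "_"),
                drop = FALSE]
      ind <- ind & switch(rule$direction,
                          below = v < rule$threshold[i],
                          above = v > rule$threshold[i],
                          equal = v == rule$threshold[i])
    }
    scores <- scores + ind # NA propagates: missing component => missing score
  }
  dimnames(scores) <- NULL
  scores
}

#' @export
print.composite_matrix <- function(x, ...) {
  cat("<composite_matrix> ", nrow(x$scores), " subjects x ", ncol(x$scores),
      " time points; ", sum(is.na(x$scores)), " undefined cells\n", sep = "")
  invisible(x)
}

#' @export
as_tibble.composite_matrix <- function(x, ...) {
  tibble(subject_id = rep(x$subject_id, times = ncol(x$scores)),
         time = rep(seq_len(ncol(x$scores)), each = nrow(x$scores)),
         years = rep(x$time_grid, each = nrow(x$scores)),
         score = as.vector(x$scores))
}

#' Last observation carried forward
#'
#' Fills every masked cell with the most recent earlier value of the same
#' variable for that subject; monotone missing chains propagate the last
#' observed value. The first exam must be complete, so every chain has an
#' anchor.
#'
#' @param panel A `component_panel`.
#' @param mask A `missing_mask`.
#' @return A complete `component_panel`.
#' @export
locf_fill <- function(panel, mask) {
  vals <- panel_values(panel)
  for (v in panel$vars) {
    for (t in 2:panel$n_times) {
      cn <- paste(v, t, sep = "_")
      miss <- mask$mech[, cn] > 0L
      vals[miss, cn] <- vals[miss, paste(v, t - 1, sep = "_")]
    }
  }
  set_panel_values(panel, vals)
}

#' Complete-case restriction
#'
#' Any subject-time with at least one masked component contributes no data at
#' that time (all variables set `NA` there); the subject's other exams are
#' retained.
#'
#' @param panel A `component_panel`.
#' @param mask A `missing_mask`.
#' @return A `component_panel` with wave-level `NA`s.
#' @export
cc_restrict <- function(panel, mask) {
  vals <- panel_values(panel)
  times <- as.integer(sub("^.*_", "", colnames(mask$mech)))
  for (t in unique(times)) {
    cols <- colnames(mask$mech)[times == t]
    any_miss <- rowSums(mask$mech[, cols, drop = FALSE] > 0L) > 0L
    vals[any_miss, cols] <- NA_real_
  }
  set_panel_values(panel, vals)
}
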