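# The component panel container and conversions.

new_component_panel <- function(data, spec) {
  structure(
    list(data = data,
         vars = spec$component_names,
         binary_vars = spec$binary_components,
         n_times = spec$n_times,
         time_grid = (seq_len(spec$n_times) - 1) * spec$time_step,
         spec = spec),
    class = "component_panel")
}

#' @export
print.component_panel <- function(x, ...) {
  cat("<component_panel> ", nrow(x$data), " subjects x ", x$n_times,
      " time points x ", length(x$vars), " variables\n", sep = "")
  miss <- sum(is.na(as.matrix(x$data[, vt_cols(x)])))
  cat("  missing cells: ", miss, "\n", sep = "")
  invisible(x)
}

vt_cols <- function(panel) vt_names(panel$vars, panel$n_times)

# subject x (variable-time) value matrix, optionally with covariates appended
panel_values <- function(panel, covariates = FALSE) {
  cols <- vt_cols(panel)
  if (covariates) cols <- c(cols, "age", "sex")
  m <- as.matrix(panel$data[, cols])
  rownames(m) <- NULL
  m
}

# replace the variable-time block of a panel with new values
set_panel_values <- function(panel, values) {
  cols <- vt_cols(panel)
  panel$data[, cols] <- as.data.frame(values)[, seq_along(cols)]
  panel
}

#' Convert a panel to a long tibble
#'
#' One row per subject, time point and variable, with baseline covariates
#' repeated on each row.
#'
#' @param x A `component_panel`.
#' @param ... Unused.
#' @return A tibble with columns `subject_id`, `time`, `variable`, `value`,
#'   `age`, `sex`, `miss_group`.
#' @export
as_tibble.component_panel <- function(x, ...) {
  x$data %>%
    tidyr::pivot_longer(cols = all_of(vt_cols(x)),
                        names_to = "var_time", values_to = "value") %>%
    mutate(variable = sub("_[0-9]+$", "", .data$var_time),
           time = as.integer(sub("^.*_", "", .data$var_time))) %>%
    select("subject_id", "time", "variable", "value", "age", "sex",
           "miss_group") %>%
    arrange(.data$subject_id, .data$time, .data$variable)
}

#' Mask a panel's missing cells as NA
#'
#' Replaces every cell flagged by the mask (any mechanism) with `NA`, the
#' representation the comparator transforms and complete-data checks work from.
#'
#' @param panel A `component_panel`.
#' @param mask A `missing_mask` over the same layout.
#' @return A `component_panel` with `NA` at masked cells.
#' @export
apply_mask <- function(panel, mask) {
  vals <- panel_values(panel)
  vals[mask$mech > 0L] <- NA_real_
  set_panel_values(panel, vals)
}
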