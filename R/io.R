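#' Read and write panels, masks and events as CSV
#'
#' Panels serialize to long format (`subject_id`, `time`, `variable`, `value`)
#' with the baseline covariates and missingness-group column carried on every
#' row; masks to the same layout with a `mechanism` column; events to one row
#' per subject. `read_panel_csv()` reconstructs a `component_panel` from a
#' long CSV with that schema (user-supplied cohorts included), inferring the
#' variable set and time points from the data.
#'
#' @param panel A `component_panel`.
#' @param path File path.
#' @name panel_io
#' @return The written path (writers, invisibly) or the reconstructed object
#'   (readers).
#' @export
write_panel_csv <- function(panel, path) {
  write.csv(as_tibble(panel), path, row.names = FALSE)
  invisible(path)
}

#' @rdname panel_io
#' @param binary_components Names of binary variables in the file.
#' @param time_step Years between consecutive time points.
#' @export
read_panel_csv <- function(path, binary_components = "SMK", time_step = 5) {
  long <- as_tibble(read.csv(path))
  need <- c("subject_id", "time", "variable", "value")
  assert_that(all(need %in% names(long)),
              "panel CSV needs columns subject_id, time, variable, value")
  if (!"miss_group" %in% names(long)) long$miss_group <- "MAR"
  if (!"age" %in% names(long)) long$age <- NA_real_
  if (!"sex" %in% names(long)) long$sex <- NA_real_
  vars <- unique(long$variable)
  n_times <- max(long$time)
  wide <- long %>%
    mutate(var_time = paste(.data$variable, .data$time, sep = "_")) %>%
    select("subject_id", "miss_group", "age", "sex", "var_time", "value") %>%
    tidyr::pivot_wider(names_from = "var_time", values_from = "value")
  wide <- wide[, c("subject_id", "miss_group", "age", "sex",
                   vt_names(vars, n_times))]
  spec <- list(n_subjects = nrow(wide), n_times = as.integer(n_times),
               component_names = vars,
               binary_components = intersect(binary_components, vars),
               time_step = time_step)
  new_component_panel(wide, spec)
}

#' @rdname panel_io
#' @param mask A `missing_mask`.
#' @export
write_mask_csv <- function(mask, path) {
  write.csv(as_tibble(mask), path, row.names = FALSE)
  invisible(path)
}

#' @rdname panel_io
#' @export
read_mask_csv <- function(path) {
  long <- as_tibble(read.csv(path))
  vars <- unique(long$variable)
  n_times <- max(long$time)
  ids <- sort(unique(long$subject_id))
  mech <- matrix(MECH_OBS, length(ids), length(vars) * n_times,
                 dimnames = list(NULL, vt_names(vars, n_times)))
  code <- match(long$mechanism, mech_labels) - 1L
  mech[cbind(match(long$subject_id, ids),
             match(paste(long$variable, long$time, sep = "_"),
                   colnames(mech)))] <- code
  new_missing_mask(mech, ids)
}

#' @rdname panel_io
#' @param events An event table.
#' @export
write_events_csv <- function(events, path) {
  write.csv(events[, c("subject_id", "event_time", "event_indicator")], path,
            row.names = FALSE)
  invisible(path)
}

#' @rdname panel_io
#' @param admin_censor_time Administrative censoring time attached to the
#'   reconstructed table.
#' @export
read_events_csv <- function(path, admin_censor_time = NULL) {
  out <- as_tibble(read.csv(path))
  attr(out, "admin_censor_time") <- admin_censor_time %||% max(out$event_time)
  class(out) <- c("event_table", class(out))
  out
}

#' Serialize a cohort specification to YAML
#'
#' Versioned schema; matrices are stored with their dimnames so the spec
#' round-trips exactly.
#'
#' @param spec A `cohort_spec`.
#' @param path File path.
#' @return The path, invisibly.
#' @export
write_cohort_spec_yaml <- function(spec, path) {
  ser <- list(
    schema = "twostagemi/cohort_spec/1",
    n_subjects = spec$n_subjects, n_times = spec$n_times,
    component_names = spec$component_names,
    binary_components = spec$binary_components,
    means = apply(spec$means, 1, identity, simplify = FALSE),
    sds = apply(spec$sds, 1, identity, simplify = FALSE),
    within_corr = as.list(spec$within_corr),
    between_corr = spec$between_corr,
    binary_targets = apply(spec$binary_targets, 1, identity, simplify = FALSE),
    covariate_spec = spec$covariate_spec,
    time_step = spec$time_step,
    seed = spec$seed)
  yaml::write_yaml(ser, path)
  invisible(path)
}

#' @rdname write_cohort_spec_yaml
#' @export
read_cohort_spec_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  assert_that(identical(y$schema, "twostagemi/cohort_spec/1"),
              "unrecognized cohort spec schema")
  listmat <- function(x) do.call(rbind, x)
  cohort_spec(n_subjects = y$n_subjects, n_times = y$n_times,
              component_names = y$component_names,
              binary_components = y$binary_components,
              means = listmat(y$means), sds = listmat(y$sds),
              within_corr = unlist(y$within_corr),
              between_corr = y$between_corr,
              binary_targets = listmat(y$binary_targets),
              covariate_spec = y$covariate_spec,
              time_step = y$time_step, seed = y$seed)
}

#' Write an imputed stack as a directory of CSVs with a manifest
#'
#' One wide CSV per completed panel, named `imp_j{j}_k{k}.csv`, plus a
#' `manifest.json` recording the nesting dimensions, the ignorability
#' assumption and the engine configuration.
#'
#' @param stack An `imputed_stack`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_stack_csvs <- function(stack, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (j in seq_len(stack$m)) {
    for (k in seq_len(stack$n)) {
      p <- stack_panel(stack, j, k)
      write.csv(p$data, file.path(dir, sprintf("imp_j%d_k%d.csv", j, k)),
                row.names = FALSE)
    }
  }
  manifest <- list(m = stack$m, n = stack$n,
                   k_cont = stack$assumption$k_cont,
                   k_bin = stack$assumption$k_bin,
                   structure = stack$config$structure,
                   n_iterations = stack$config$n_iterations,
                   cox_mode = stack$config$cox_mode)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Export pooled estimates with their run metadata to CSV
#'
#' Writes the tibble from [pool_replicate()] with the stack's nesting
#' dimensions, ignorability assumption and FCS structure attached as columns.
#'
#' @param pooled Output of [pool_replicate()].
#' @param stack The `imputed_stack` the estimates were pooled from.
#' @param path File path.
#' @return The path, invisibly.
#' @export
write_pooled_csv <- function(pooled, stack, path) {
  out <- mutate(pooled, m = stack$m, n = stack$n,
                k_cont = stack$assumption$k_cont,
                k_bin = stack$assumption$k_bin,
                fcs_structure = stack$config$structure)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Export aggregated study results to CSV
#'
#' @param results An `mi_results` tibble.
#' @param path File path.
#' @return The path, invisibly.
#' @export
write_results_csv <- function(results, path) {
  write.csv(as.data.frame(results), path, row.names = FALSE)
  invisible(path)
}
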