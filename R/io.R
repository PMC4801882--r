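#' @name cli_io
#' @title Tabular I/O and configuration
#'
#' @description
#' Readers and writers for the pipeline's plain-text formats: measurement
#' tables and totals ranges as CSV, parameter sets and experiment designs as
#' flat YAML/JSON configs, fit results as JSON, trajectories and sensitivity
#' reports as CSV. Every writer's output is readable by its paired reader.
NULL

measurement_cols <- c("mouse_id", "group", "day", "subset",
                      "labeled_fraction")

#' Read or write a measurement table CSV
#'
#' Columns `mouse_id, group, day, subset, labeled_fraction`; subset
#' vocabulary as in [measured_subsets()].
#'
#' @param path CSV file path.
#' @return `read_measurements()`: the measurement data frame.
#' @export
read_measurements <- function(path) {
  if (!file.exists(path))
    bcd_error(paste0("file not found: ", path), "bcd_io_error")
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(measurement_cols, names(df))
  if (length(missing))
    bcd_error(paste0("measurement CSV missing column(s): ",
                     paste(missing, collapse = ", ")), "bcd_io_error")
  bad <- setdiff(unique(df$subset), subset_names())
  if (length(bad))
    bcd_error(paste0("unknown subset(s) in CSV: ",
                     paste(bad, collapse = ", ")), "bcd_io_error")
  if (any(df$labeled_fraction < 0 | df$labeled_fraction > 1, na.rm = TRUE))
    bcd_error("labeled fractions must lie in [0, 1]", "bcd_io_error")
  df[measurement_cols]
}

#' @rdname read_measurements
#' @param data Measurement data frame.
#' @export
write_measurements <- function(data, path) {
  missing <- setdiff(measurement_cols, names(data))
  if (length(missing))
    bcd_error(paste0("missing column(s): ", paste(missing, collapse = ", ")),
              "bcd_invalid_input")
  write.csv(data[measurement_cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read or write a totals-range CSV
#'
#' Columns `subset, lower, upper` (see [generate_totals_ranges()]).
#'
#' @param path CSV file path.
#' @export
read_totals_ranges <- function(path) {
  if (!file.exists(path))
    bcd_error(paste0("file not found: ", path), "bcd_io_error")
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("subset", "lower", "upper") %in% names(df)))
    bcd_error("totals-range CSV needs columns subset, lower, upper",
              "bcd_io_error")
  df
}

#' @rdname read_totals_ranges
#' @param ranges Totals-range data frame.
#' @export
write_totals_ranges <- function(ranges, path) {
  write.csv(ranges[c("subset", "lower", "upper")], path, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}

#' Export a labeling trajectory as CSV
#'
#' Long format with columns `time_units, day, compartment, unlabeled,
#' labeled, total, labeled_fraction`.
#'
#' @param traj A `labeling_trajectory` from [simulate_experiment()].
#' @param path CSV file path.
#' @export
write_trajectory_csv <- function(traj, path) {
  if (!inherits(traj, "labeling_trajectory"))
    bcd_error("`traj` must be a labeling_trajectory", "bcd_invalid_input")
  long <- do.call(rbind, lapply(seq_along(state_names()), function(j) {
    data.frame(time_units = traj$time, day = traj$time / 4,
               compartment = subset_names()[j],
               unlabeled = traj$unlabeled[, j], labeled = traj$labeled[, j],
               total = traj$total[, j],
               labeled_fraction = traj$fraction[, j])
  }))
  long <- long[order(long$time_units, match(long$compartment,
                                            subset_names())), ]
  write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read or write an experiment design config (YAML/JSON)
#'
#' Keys: `group`, `recovery`, `labeling_duration`, `measurement_days`,
#' `subsets`, and `depletion` (named survival fractions).
#'
#' @param path Config path (`.yaml`, `.yml` or `.json`).
#' @export
read_design_config <- function(path) {
  x <- read_config(path)
  known <- c("group", "depletion", "recovery", "labeling_duration",
             "measurement_days", "subsets")
  extra <- setdiff(names(x), known)
  if (length(extra))
    bcd_error(paste0("unknown design key(s): ",
                     paste(extra, collapse = ", ")), "bcd_invalid_input")
  if (!is.null(x$depletion)) x$depletion <- depletion_spec(unlist(x$depletion))
  do.call(experiment_design, x)
}

#' @rdname read_design_config
#' @param design An [experiment_design()].
#' @export
write_design_config <- function(design, path) {
  x <- unclass(design)
  x$depletion <- as.list(unclass(x$depletion))
  names(x$depletion) <- subset_names()
  write_config(x, path)
  invisible(path)
}

#' Write or read a fit result as JSON
#'
#' Stores the best-fit parameters, log-likelihood, candidate counts, seed,
#' sampling ranges and any attached confidence intervals.
#'
#' @param fit A `bcell_fit` from [fit_mle()], optionally with a `ci`
#'   element (named list of `lower`/`upper` pairs).
#' @param path JSON file path.
#' @export
write_fit_json <- function(fit, path) {
  if (!inherits(fit, "bcell_fit"))
    bcd_error("`fit` must come from fit_mle()", "bcd_invalid_input")
  x <- list(group = fit$design$group,
            parameters = as.list(unclass(fit$params)),
            lnL = fit$lnL, n_evaluated = fit$n_evaluated,
            n_passed = fit$n_passed, n_failed = fit$n_failed,
            seed = fit$seed,
            sampled = fit$ranges$sampled,
            fixed = as.list(fit$ranges$fixed))
  if (!is.null(fit$ci)) x$ci <- fit$ci
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_fit_json
#' @export
read_fit_json <- function(path) {
  if (!file.exists(path))
    bcd_error(paste0("file not found: ", path), "bcd_io_error")
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Export sensitivity results as CSV
#'
#' `write_sensitivity_csv()` writes one or more stepwise reports in a long
#' layout (`outcome, R, R2, parameter, partial_R`); `write_prcc_csv()`
#' writes a PRCC matrix (outcomes in rows, inputs in columns).
#'
#' @param reports A `sensitivity_report` or list of them.
#' @param path CSV file path.
#' @export
write_sensitivity_csv <- function(reports, path) {
  if (inherits(reports, "sensitivity_report")) reports <- list(reports)
  long <- do.call(rbind, lapply(reports, function(r) {
    if (!nrow(r$table)) return(NULL)
    data.frame(outcome = r$outcome, R = r$R, R2 = r$R2,
               parameter = r$table$parameter,
               partial_R = r$table$partial_R)
  }))
  write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_sensitivity_csv
#' @param prcc_matrix Matrix of PRCCs (rows = outcomes, columns = inputs).
#' @export
write_prcc_csv <- function(prcc_matrix, path) {
  df <- data.frame(outcome = rownames(prcc_matrix), prcc_matrix,
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
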