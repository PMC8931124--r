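#' Read and write pipeline tables as CSV
#'
#' Thin, column-typed CSV readers and writers for the tables that flow
#' between the simulation, estimation and statistical layers: trial-level
#' binary choices, token allocations, agent populations and per-subject
#' structural estimates. Headers are fixed; files are UTF-8 with one
#' record per row, so every statistic in a report can be recomputed from
#' the emitted CSVs alone.
#'
#' @param x The tibble to write.
#' @param path File path.
#' @return Writers return `x` invisibly; readers return a tibble.
#' @name pipeline_io
NULL

#' @rdname pipeline_io
#' @export
write_trials <- function(x, path) {
  readr::write_csv(x[, c("subject_id", "condition", "trial_id",
                         "earlier_amount", "later_amount",
                         "earlier_delay_days", "later_delay_days",
                         "common_amount", "domain", "endowment", "t0",
                         "choice_later")], path)
  invisible(x)
}

#' @rdname pipeline_io
#' @export
read_trials <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    subject_id = readr::col_integer(),
    condition = readr::col_character(),
    trial_id = readr::col_integer(),
    earlier_amount = readr::col_double(),
    later_amount = readr::col_double(),
    earlier_delay_days = readr::col_integer(),
    later_delay_days = readr::col_integer(),
    common_amount = readr::col_double(),
    domain = readr::col_character(),
    endowment = readr::col_double(),
    t0 = readr::col_integer(),
    choice_later = readr::col_double()
  ))
}

#' @rdname pipeline_io
#' @export
write_allocations <- function(x, path) {
  readr::write_csv(x[, c("subject_id", "task_id", "a_t", "a_tk", "t_days",
                         "k_days", "budget_tokens", "tokens_early")], path)
  invisible(x)
}

#' @rdname pipeline_io
#' @export
read_allocations <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    subject_id = readr::col_integer(),
    task_id = readr::col_integer(),
    a_t = readr::col_double(),
    a_tk = readr::col_double(),
    t_days = readr::col_integer(),
    k_days = readr::col_integer(),
    budget_tokens = readr::col_double(),
    tokens_early = readr::col_double()
  ))
}

#' @rdname pipeline_io
#' @export
write_population <- function(x, path) {
  readr::write_csv(x[, c("subject_id", "alpha", "beta", "delta")], path)
  invisible(x)
}

#' @rdname pipeline_io
#' @export
read_population <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    subject_id = readr::col_integer(),
    alpha = readr::col_double(),
    beta = readr::col_double(),
    delta = readr::col_double()
  ))
}

#' @rdname pipeline_io
#' @export
write_estimates <- function(x, path) {
  readr::write_csv(x[, c("subject_id", "alpha_hat", "beta_hat",
                         "delta_hat", "n_interior", "n_corner",
                         "negative_alpha_flag")], path)
  invisible(x)
}

#' @rdname pipeline_io
#' @export
read_estimates <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    subject_id = readr::col_integer(),
    alpha_hat = readr::col_double(),
    beta_hat = readr::col_double(),
    delta_hat = readr::col_double(),
    n_interior = readr::col_integer(),
    n_corner = readr::col_integer(),
    negative_alpha_flag = readr::col_logical()
  ))
}

#' Write the statistics of a replication report as JSON
#'
#' Serialises the statistical content of a [run_experiment()] report
#' (proportions, test statistics, effect sizes, estimates summary) to a
#' JSON file keyed by section. Requires the `jsonlite` package.
#'
#' @param report A `cancel_report`.
#' @param path Output path.
#' @return The report, invisibly.
#' @export
write_report_json <- function(report, path) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop("`jsonlite` is required to write JSON reports.", call. = FALSE)
  }
  keep <- intersect(
    c("experiment", "config", "provenance", "proportions", "rank_tests",
      "chi2", "fisher_p", "n_excluded", "distribution",
      "mean_age_baseline", "mean_age_cancellation", "cohen_d"),
    names(report)
  )
  jsonlite::write_json(report[keep], path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(report)
}
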