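#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a sequence-confrontation report
#'
#' @param x A `cohort_report` from [pairwise_eval()].
#' @param ... Unused.
#' @return For `tidy()`, the per-pair table (one row per patient);
#'   for `glance()`, the per-tolerance summary.
#' @export
tidy.cohort_report <- function(x, ...) x$pairs

#' @rdname tidy.cohort_report
#' @export
glance.cohort_report <- function(x, ...) x$summary

#' Tidy a sequence inventory
#'
#' @param x A `sequence_inventory` from [tabulate_sequences()].
#' @param ... Unused.
#' @return For `tidy()`, one row per distinct simple sequence; for
#'   `glance()`, a one-row tibble with the cohort size and per-category
#'   totals (`n_a_good_prognosis`, ... as named by the rules).
#' @export
tidy.sequence_inventory <- function(x, ...) x$sequences

#' @rdname tidy.sequence_inventory
#' @export
glance.sequence_inventory <- function(x, ...) {
  wide <- setNames(as.list(x$categories$n),
                   paste0("n_", x$categories$category))
  dplyr::bind_cols(tibble(n = x$n_total), as_tibble(wide))
}

#' Tidy a validation experiment result
#'
#' @param x A `validation_result` from [run_validation_experiment()].
#' @param ... Unused.
#' @return For `tidy()`, the stacked per-pair tables of both forms; for
#'   `glance()`, the stacked per-tolerance summaries.
#' @export
tidy.validation_result <- function(x, ...) {
  bind_rows(x$simple$pairs, x$extended$pairs)
}

#' @rdname tidy.validation_result
#' @export
glance.validation_result <- function(x, ...) {
  bind_rows(x$simple$summary, x$extended$summary)
}
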