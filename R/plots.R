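.STATE_PALETTE <- c(
  A = "#66c2a5", C = "#fc8d62", D = "#e31a1c", N = "#a6d854",
  K = "#8da0cb", R = "#ffd92f", O = "#e78ac3", I = "grey85"
)

#' Sequence index plot
#'
#' Draws each patient's extended sequence as a horizontal band of
#' day-coloured tiles (one tile per calendar day, coloured by state, gap
#' days in grey), the standard rendering of state-sequence data.
#' Sequences are aligned on each patient's own first state (day 1).
#'
#' @param sequences A sequence tibble from [care_sequences()] (columns
#'   `patient_id`, `extended`).
#' @param max_patients Cap on the number of patients drawn (default 50).
#' @return A ggplot object.
#' @export
plot_sequence_index <- function(sequences, max_patients = 50) {
  seqs <- sequences |>
    filter(nchar(.data$extended) > 0) |>
    utils::head(max_patients)
  if (nrow(seqs) == 0) abort("No non-empty sequences to plot.")
  long <- seqs |>
    mutate(chars = strsplit(.data$extended, "")) |>
    select("patient_id", "chars") |>
    tidyr::unnest_longer("chars", values_to = "state") |>
    group_by(.data$patient_id) |>
    mutate(day = dplyr::row_number()) |>
    ungroup()
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$day, y = .data$patient_id, fill = .data$state
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = .STATE_PALETTE, name = "State") +
    ggplot2::labs(x = "Day since first state", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a sequence-confrontation report
#'
#' Bar chart of the match rate at each tolerance.
#'
#' @param object A `cohort_report` from [pairwise_eval()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cohort_report <- function(object, ...) {
  df <- object$summary |>
    mutate(tolerance = factor(.data$tolerance))
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$tolerance, y = .data$match_rate
  )) +
    ggplot2::geom_col(fill = "#4477aa") +
    ggplot2::coord_cartesian(ylim = c(0, 100)) +
    ggplot2::labs(
      x = paste0("Tolerance (LED, ", object$form, " form)"),
      y = "Match rate (%)"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a sequence inventory
#'
#' Horizontal bars of the distinct simple sequences, coloured by
#' standard-category assignment.
#'
#' @param object A `sequence_inventory` from [tabulate_sequences()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sequence_inventory <- function(object, ...) {
  df <- object$sequences |>
    mutate(simple = stats::reorder(.data$simple, .data$n))
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$n, y = .data$simple, fill = .data$category
  )) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Patients", y = "Simple sequence", fill = "Category") +
    ggplot2::theme_minimal()
}
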