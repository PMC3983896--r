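#' Standard-sequence category rules
#'
#' The three standard care pathways for non-metastatic breast cancer,
#' encoded as anchored regular expressions over the simple-form alphabet
#' and evaluated in order (first match wins; anything else falls back to
#' `other`):
#'
#' * `a_good_prognosis` — optional pathology, surgery with pathology,
#'   optional radiotherapy (`ADR`, `AD`, `DR`, `D`);
#' * `b_poor_prognosis` — optional pathology, surgery with pathology,
#'   adjuvant chemotherapy, then radiotherapy or a concomitant
#'   chemo-radiotherapy period followed by chemotherapy (`ADKR`,
#'   `ADKOK`, `DKR`, `DKOK`);
#' * `c_neoadjuvant` — optional pathology, neoadjuvant chemotherapy,
#'   surgery with pathology, radiotherapy (`ANDR`).
#'
#' The patterns are configurable so that the taxonomy can be adapted to
#' other cancer sites.
#'
#' @param patterns Named character vector of anchored regular expressions
#'   (category id -> pattern), evaluated in order.
#' @return A `category_rules` object (tibble with columns `category`,
#'   `pattern`).
#' @export
category_rules <- function(patterns = c(
                             a_good_prognosis = "^A?DR?$",
                             b_poor_prognosis = "^A?DK(R|OK)$",
                             c_neoadjuvant = "^A?NDR$"
                           )) {
  if (is.null(names(patterns)) || any(names(patterns) == "")) {
    abort("`patterns` must be a named character vector.")
  }
  structure(
    tibble(category = names(patterns), pattern = unname(patterns)),
    class = c("category_rules", class(tibble()))
  )
}

#' Assign simple sequences to standard care categories
#'
#' @param simple Character vector of simple-form sequences (alphabet
#'   `A C D N K R O`).
#' @param rules A [category_rules()] object.
#' @return A character vector of category ids (`other` where no pattern
#'   matches).
#' @export
#' @examples
#' classify_standard(c("ADR", "DKOK", "ANDRK"))
classify_standard <- function(simple, rules = category_rules()) {
  bad <- grepl(paste0("[^", paste(.STATE_CODES, collapse = ""), "]"), simple)
  if (any(bad)) {
    abort(paste("Invalid characters in sequence(s):",
                paste(utils::head(unique(simple[bad]), 5), collapse = ", ")))
  }
  out <- rep("other", length(simple))
  for (i in rev(seq_len(nrow(rules)))) {
    out[grepl(rules$pattern[i], simple)] <- rules$category[i]
  }
  out
}

#' Tabulate a cohort of simple sequences into a category inventory
#'
#' Counts each distinct simple sequence, assigns it a standard category,
#' and aggregates per-category totals; percentages are computed on the
#' cohort size and rounded to whole percent for display.
#'
#' @param cohort Either a character vector of simple-form sequences (one
#'   per patient) or a data frame with columns `simple` and `n`
#'   (pre-counted distinct sequences).
#' @param rules A [category_rules()] object.
#' @return A `sequence_inventory` object: a list with `sequences`
#'   (per distinct string: `simple`, `n`, `pct`, `category`),
#'   `categories` (per category: `n`, `pct`) and `n_total`.  Has
#'   [tidy()][generics::tidy] and [glance()][generics::glance] methods.
#' @export
tabulate_sequences <- function(cohort, rules = category_rules()) {
  if (is.data.frame(cohort)) {
    if (!all(c("simple", "n") %in% names(cohort))) {
      abort("A data-frame cohort needs columns `simple` and `n`.")
    }
    counts <- cohort |>
      group_by(.data$simple) |>
      summarise(n = sum(.data$n), .groups = "drop")
  } else {
    counts <- tibble(simple = as.character(cohort)) |>
      dplyr::count(.data$simple)
  }
  if (nrow(counts) == 0) abort("The cohort is empty.")
  n_total <- sum(counts$n)
  seqs <- counts |>
    mutate(
      category = classify_standard(.data$simple, rules),
      pct = round(.data$n / n_total * 100)
    ) |>
    arrange(.data$category, dplyr::desc(.data$n), .data$simple) |>
    select("simple", "n", "pct", "category")
  cats <- seqs |>
    group_by(.data$category) |>
    summarise(n = sum(.data$n), .groups = "drop") |>
    mutate(pct = round(.data$n / n_total * 100))
  # report all categories, including empty ones
  all_cats <- c(rules$category, "other")
  cats <- tibble(category = all_cats) |>
    left_join(cats, by = "category") |>
    mutate(n = dplyr::coalesce(.data$n, 0L),
           pct = dplyr::coalesce(.data$pct, 0))
  structure(
    list(sequences = seqs, categories = cats, n_total = n_total),
    class = "sequence_inventory"
  )
}

#' @export
print.sequence_inventory <- function(x, ...) {
  cat("Sequence inventory,", x$n_total, "patients\n")
  for (i in seq_len(nrow(x$categories))) {
    cat(sprintf("  %-18s %4d (%d%%)\n", x$categories$category[i],
                x$categories$n[i], x$categories$pct[i]))
  }
  invisible(x)
}

#' Observed simple-form sequence frequencies of a published breast-cancer
#' evaluation cohort
#'
#' Distinct simple-form care sequences and their frequencies as observed
#' (manually reconstructed from medical records) in a published regional
#' cancer-registry evaluation sample of 159 women with unilateral
#' non-metastatic breast cancer diagnosed in 2008.  Useful as a reference
#' input for the standard-category classifier.
#'
#' @return A tibble with columns `simple` and `n` (17 rows, counts
#'   summing to 159).
#' @export
#' @examples
#' glance(tabulate_sequences(observed_breast_cohort()))
observed_breast_cohort <- function() {
  tibble(
    simple = c(
      "ADR", "AD", "DR", "D",
      "ADKR", "ADKOK", "DKR", "DKOK",
      "ANDR",
      "A", "ADK", "AK", "AR", "ADKDR", "ANDRK", "DK", "DKDKOK"
    ),
    n = c(
      47L, 16L, 13L, 5L,
      42L, 8L, 2L, 2L,
      8L,
      6L, 2L, 2L, 2L, 1L, 1L, 1L, 1L
    )
  )
}
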