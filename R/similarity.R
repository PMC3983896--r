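#' Generalised Levenshtein edit distance
#'
#' Minimum total cost of single-character insertions, deletions and
#' substitutions turning one string into the other, computed by dynamic
#' programming.  With the default unit costs this is the classical edit
#' distance: symmetric, zero exactly for equal strings, bounded below by
#' the length difference and above by the longer length.  The cost hook
#' allows non-unit operation costs; costs must be strictly positive.
#'
#' @param a,b Character vectors, recycled to a common length.
#' @param insert,delete,substitute Operation costs (defaults 1).
#' @return A numeric vector of distances (integer-valued under unit
#'   costs).
#' @export
#' @examples
#' levenshtein("AC", "AD")   # 1
#' levenshtein("K", "AK")    # 1
levenshtein <- function(a, b, insert = 1, delete = 1, substitute = 1) {
  if (any(c(insert, delete, substitute) <= 0)) {
    abort("Operation costs must be strictly positive.")
  }
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n)
  b <- rep_len(as.character(b), n)
  led_pairs_cpp(a, b, insert, delete, substitute)
}

#' Pairwise distance matrix between two string sets
#'
#' @param x,y Character vectors (`y` defaults to `x`).
#' @inheritParams levenshtein
#' @return A numeric matrix with `length(x)` rows and `length(y)` columns.
#' @export
levenshtein_matrix <- function(x, y = x, insert = 1, delete = 1,
                               substitute = 1) {
  if (any(c(insert, delete, substitute) <= 0)) {
    abort("Operation costs must be strictly positive.")
  }
  m <- led_matrix_cpp(as.character(x), as.character(y), insert, delete,
                      substitute)
  dimnames(m) <- list(x, y)
  m
}

#' Confront algorithm-produced sequences with reference sequences
#'
#' Pairs each patient's algorithm sequence with the reference sequence of
#' the same patient, computes the unit-cost Levenshtein edit distance per
#' pair, and aggregates match counts and rates at the requested
#' tolerances: a pair matches at tolerance *t* when its distance is at
#' most *t*.  Simple-form comparison conventionally uses tolerance 0
#' (identical presence and order of states); extended-form comparison
#' uses day tolerances (1 and 3 by default), since one character is one
#' calendar day.
#'
#' @param algorithm,reference Data frames with columns `patient_id` and
#'   the compared form (`simple` or `extended`), e.g. outputs of
#'   [care_sequences()].  Patient sets must be identical.
#' @param form `"simple"` or `"extended"`.
#' @param tolerances Integer vector of match tolerances; defaults to 0
#'   for the simple form and `c(1, 3)` for the extended form.
#' @return A `cohort_report` object: a list with `pairs` (one row per
#'   patient: `patient_id`, `form`, `led`, one `match_at_*` column per
#'   tolerance) and `summary` (per tolerance: `n_pairs`, `n_dissimilar`,
#'   `match_rate` in percent, and the median and range of the distances
#'   of the dissimilar pairs).  Has [tidy()][generics::tidy],
#'   [glance()][generics::glance] and [autoplot()][ggplot2::autoplot]
#'   methods.
#' @export
pairwise_eval <- function(algorithm, reference,
                          form = c("simple", "extended"),
                          tolerances = NULL) {
  form <- match.arg(form)
  if (is.null(tolerances)) {
    tolerances <- if (form == "simple") 0L else c(1L, 3L)
  }
  tolerances <- sort(unique(as.integer(tolerances)))
  for (nm in c("patient_id", form)) {
    if (!nm %in% names(algorithm) || !nm %in% names(reference)) {
      abort(paste0("Both inputs need columns `patient_id` and `", form, "`."))
    }
  }
  only_a <- setdiff(algorithm$patient_id, reference$patient_id)
  only_r <- setdiff(reference$patient_id, algorithm$patient_id)
  if (length(only_a) > 0 || length(only_r) > 0) {
    abort(c(
      "Patient sets differ between the two inputs.",
      x = paste("Only in `algorithm`:",
                paste(utils::head(only_a, 5), collapse = ", ")),
      x = paste("Only in `reference`:",
                paste(utils::head(only_r, 5), collapse = ", "))
    ))
  }
  if (anyDuplicated(algorithm$patient_id) || anyDuplicated(reference$patient_id)) {
    abort("Inputs must have one row per patient.")
  }

  a <- algorithm[[form]]
  b <- reference[[form]][match(algorithm$patient_id, reference$patient_id)]
  pairs <- tibble(
    patient_id = algorithm$patient_id,
    form = form,
    led = as.integer(levenshtein(a, b))
  )
  for (t in tolerances) {
    pairs[[paste0("match_at_", t)]] <- pairs$led <= t
  }

  summary <- purrr::map_dfr(tolerances, function(t) {
    dis <- pairs$led[pairs$led > t]
    tibble(
      form = form,
      tolerance = t,
      n_pairs = nrow(pairs),
      n_dissimilar = length(dis),
      match_rate = (nrow(pairs) - length(dis)) / nrow(pairs) * 100,
      led_median = if (length(dis)) median(dis) else NA_real_,
      led_min = if (length(dis)) min(dis) else NA_integer_,
      led_max = if (length(dis)) max(dis) else NA_integer_
    )
  })

  structure(
    list(pairs = pairs, summary = summary, form = form,
         tolerances = tolerances),
    class = "cohort_report"
  )
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("Sequence confrontation (", x$form, " form), ",
      nrow(x$pairs), " pairs\n", sep = "")
  df <- as.data.frame(x$summary)
  df$match_rate <- sprintf("%.1f%%", df$match_rate)
  print(df[, c("tolerance", "n_dissimilar", "match_rate", "led_median",
               "led_min", "led_max")], row.names = FALSE)
  invisible(x)
}
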