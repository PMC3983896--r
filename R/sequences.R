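check_single_patient <- function(states, what) {
  if ("patient_id" %in% names(states) &&
      length(unique(states$patient_id)) > 1) {
    abort(paste0("`", what, "()` expects the states of a single patient; ",
                 "use care_sequences() for a cohort."))
  }
  invisible(states)
}

#' Simple form of a state sequence
#'
#' One character per state, in chronological order: the presence and
#' order of the states, without their durations.
#'
#' @param states A care-state tibble for one patient (columns `code`,
#'   `start`, `end`), as produced by [aggregate_states()].
#' @return A single string over the alphabet `A C D N K R O` (empty for
#'   an empty state list).
#' @export
#' @examples
#' s <- tibble::tibble(
#'   code = c("A", "D", "R"),
#'   start = as.Date(c("2008-01-01", "2008-01-10", "2008-02-01")),
#'   end = as.Date(c("2008-01-01", "2008-01-10", "2008-02-05"))
#' )
#' simple_form(s)
simple_form <- function(states) {
  check_single_patient(states, "simple_form")
  states <- arrange(states, .data$start)
  paste(states$code, collapse = "")
}

#' Duration-extended form of a state sequence
#'
#' Each state contributes its code repeated once per calendar day of its
#' (inclusive) duration; each period between two states without any event
#' contributes the gap code `I` once per day, starting the day after the
#' previous state ends and ending the day before the next state starts.
#' The string length therefore equals the trajectory span in days (end of
#' last state - start of first state + 1).
#'
#' @inheritParams simple_form
#' @return A single string over the alphabet `A C D N K R O I`.
#' @export
#' @examples
#' s <- tibble::tibble(
#'   code = c("A", "D", "R"),
#'   start = as.Date(c("2008-01-01", "2008-01-10", "2008-02-01")),
#'   end = as.Date(c("2008-01-01", "2008-01-10", "2008-02-05"))
#' )
#' nchar(extended_form(s))  # 36-day span
extended_form <- function(states) {
  check_single_patient(states, "extended_form")
  if (nrow(states) == 0) return("")
  states <- arrange(states, .data$start)
  if (nrow(states) > 1) {
    overlap <- states$start[-1] <= states$end[-nrow(states)]
    if (any(overlap)) {
      abort("States overlap: extended form is undefined.")
    }
  }
  dur <- as.integer(states$end - states$start) + 1L
  gap <- c(0L, as.integer(states$start[-1] - states$end[-nrow(states)]) - 1L)
  pieces <- character(2L * nrow(states))
  pieces[seq(1, length(pieces), by = 2)] <- strrep(.GAP_CODE, gap)
  pieces[seq(2, length(pieces), by = 2)] <- strrep(states$code, dur)
  paste(pieces, collapse = "")
}

#' Per-patient care sequences
#'
#' Renders the state list of every patient as its simple and extended
#' character forms, anchored at the patient's own first state.
#'
#' @param states A multi-patient care-state tibble from
#'   [aggregate_states()].
#' @param patients Optional character vector of patient identifiers the
#'   output must cover; patients without any state get an empty sequence
#'   (useful when comparing against a reference cohort).
#' @return A tibble with one row per patient: `patient_id`, `simple`,
#'   `extended`, `origin` (start of the first state), `end` (end of the
#'   last state, the trajectory endpoint).
#' @export
care_sequences <- function(states, patients = NULL) {
  out <- states |>
    group_by(.data$patient_id) |>
    dplyr::group_modify(function(s, key) {
      tibble(
        simple = simple_form(s),
        extended = extended_form(s),
        origin = min(s$start),
        end = max(s$end)
      )
    }) |>
    ungroup()
  if (!is.null(patients)) {
    missing <- setdiff(as.character(patients), out$patient_id)
    if (length(missing) > 0) {
      out <- bind_rows(out, tibble(
        patient_id = missing, simple = "", extended = "",
        origin = as.Date(NA), end = as.Date(NA)
      ))
    }
    out <- out[match(as.character(patients), out$patient_id), ]
  }
  arrange(out, .data$patient_id)
}

#' Vertical SPELL storage of state sequences
#'
#' `to_spell()` writes states vertically, one row per state (`patient_id`,
#' `state`, `start`, `end`); `from_spell()` reads them back into a
#' care-state tibble, reordering rows by patient and start date.  The
#' round trip is the identity on the state codes and dates (constituent
#' event counts are not stored in SPELL rows).
#'
#' @param states A care-state tibble.
#' @return For `to_spell()`, a SPELL tibble; for `from_spell()`, a
#'   care-state tibble with `n_events` set to `NA`.
#' @export
to_spell <- function(states) {
  states |>
    arrange(.data$patient_id, .data$start) |>
    select("patient_id", state = "code", "start", "end")
}

#' @rdname to_spell
#' @param rows A SPELL tibble (`patient_id`, `state`, `start`, `end`).
#' @export
from_spell <- function(rows) {
  bad <- !rows$state %in% .STATE_CODES
  if (any(bad)) {
    abort(paste("Unknown state code(s):",
                paste(unique(rows$state[bad]), collapse = ", ")))
  }
  rows |>
    mutate(start = as.Date(.data$start), end = as.Date(.data$end)) |>
    arrange(.data$patient_id, .data$start) |>
    select("patient_id", code = "state", "start", "end") |>
    mutate(n_events = NA_integer_)
}

# Runs of non-gap characters in an extended string:
# tibble(code, first, last) in 1-based string positions.
extended_runs <- function(extended) {
  r <- rle(strsplit(extended, "")[[1]])
  last <- cumsum(r$lengths)
  out <- tibble(code = r$values, first = last - r$lengths + 1L, last = last)
  filter(out, .data$code != .GAP_CODE)
}

#' Time-lapse between two states, read off the extended form
#'
#' Computes a waiting-time indicator by pattern matching on the extended
#' character chain: the delay between the **last** run of `from_code` and
#' the **first** run of `to_code` occurring after it.  With
#' `anchors = "end_to_start"` (the usual waiting time) the delay is the
#' day count from the end of the source state to the start of the target
#' state; `"start_to_start"` measures from the start of the source state.
#' Because one character is one calendar day, position arithmetic on the
#' string equals date arithmetic on the states.
#'
#' @param extended Character vector of extended-form sequences.
#' @param from_code,to_code Single state codes (one of `A C D N K R O`).
#' @param anchors `"end_to_start"` (default) or `"start_to_start"`.
#' @return An integer vector of day counts, `NA` where the pattern is
#'   absent.
#' @export
#' @examples
#' delay_days("DIIIIR", "D", "R")  # 5
#' delay_days("ADR", "D", "R")     # 1 (adjacent one-day states)
delay_days <- function(extended, from_code, to_code,
                       anchors = c("end_to_start", "start_to_start")) {
  anchors <- match.arg(anchors)
  for (code in c(from_code, to_code)) {
    if (length(code) != 1 || !code %in% .STATE_CODES) {
      abort("`from_code` and `to_code` must be single state codes (A C D N K R O).")
    }
  }
  vapply(extended, function(x) {
    runs <- extended_runs(x)
    from <- filter(runs, .data$code == from_code)
    if (nrow(from) == 0) return(NA_integer_)
    from <- from[nrow(from), ]
    to <- filter(runs, .data$code == to_code, .data$first > from$last)
    if (nrow(to) == 0) return(NA_integer_)
    to <- to[1, ]
    if (anchors == "end_to_start") to$first - from$last else to$first - from$first
  }, integer(1), USE.NAMES = FALSE)
}

#' Guideline-delay indicator flags
#'
#' Evaluates the standard timing recommendations for non-metastatic
#' breast cancer on each sequence, by position arithmetic on the extended
#' form (7-day weeks, 183-day six months):
#'
#' * `rt_within_12w_post_surgery` — radiotherapy starts at most 84 days
#'   after the surgery state ends, evaluated only when no chemotherapy
#'   state lies between surgery and radiotherapy;
#' * `rt_within_5w_post_chemo` — radiotherapy starts at most 35 days
#'   after the chemotherapy state ends (when chemotherapy precedes it);
#' * `rt_within_6m_post_surgery` — radiotherapy starts at most 183 days
#'   after surgery (when chemotherapy precedes the radiotherapy);
#' * `chemo_start_3_to_6w_post_surgery` — adjuvant chemotherapy starts
#'   21 to 42 days after the surgery state ends.
#'
#' Each flag is `NA` when its precondition pattern is absent from the
#' sequence.
#'
#' @param extended Character vector of extended-form sequences.
#' @return A tibble with one row per sequence and one logical column per
#'   flag.
#' @export
guideline_flags <- function(extended) {
  one <- function(x) {
    runs <- extended_runs(x)
    surg <- filter(runs, .data$code %in% c("C", "D"))
    r1 <- filter(runs, .data$code == "R")[1, , drop = FALSE]
    has_r <- nrow(filter(runs, .data$code == "R")) > 0

    rt12 <- NA
    rt5w <- NA
    rt6m <- NA
    chemo36 <- NA

    if (has_r && nrow(surg) > 0) {
      s_before <- filter(surg, .data$last < r1$first)
      if (nrow(s_before) > 0) {
        s <- s_before[nrow(s_before), ]
        between <- filter(runs, .data$first > s$last, .data$last < r1$first)
        k_between <- any(between$code %in% c("K", "O"))
        if (!k_between) {
          rt12 <- (r1$first - s$last) <= 84
        } else {
          k <- filter(between, .data$code %in% c("K", "O"))
          k <- k[nrow(k), ]
          rt5w <- (r1$first - k$last) <= 35
          rt6m <- (r1$first - s$last) <= 183
        }
      }
    }
    if (nrow(surg) > 0) {
      s1 <- surg[1, ]
      k_after <- filter(runs, .data$code == "K", .data$first > s1$last)
      if (nrow(k_after) > 0) {
        delta <- k_after$first[1] - s1$last
        chemo36 <- delta >= 21 && delta <= 42
      }
    }
    tibble(
      rt_within_12w_post_surgery = rt12,
      rt_within_5w_post_chemo = rt5w,
      rt_within_6m_post_surgery = rt6m,
      chemo_start_3_to_6w_post_surgery = chemo36
    )
  }
  purrr::map_dfr(extended, one)
}
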