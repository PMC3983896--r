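#' Aggregate tracer events into ordered care states
#'
#' Scans each patient's date-ordered event stream and aggregates
#' consecutive events of the same family into interval states, applying
#' the rules of the trajectory model:
#'
#' * events of one family aggregate while each inter-event gap is
#'   strictly below the family threshold **and** no event of a different
#'   family intervenes; exceeding a threshold splits two distinct care
#'   episodes;
#' * pathology events form `A` states, surgical events `C`, chemotherapy
#'   `K`, radiotherapy `R`;
#' * a surgery state with at least one pathology investigation — a
#'   pathology record co-occurring on a surgery day (the `with_pathology`
#'   flag set by [resolve_day()]) or a standalone pathology event within
#'   `ap_merge_window_days` after the state end — becomes `D`
#'   (surgery with pathology);
#' * concomitant chemo-radiotherapy days anchor `O` states: a maximal
#'   chain of such days (every gap along the chain strictly below the
#'   smaller of the chemotherapy and radiotherapy thresholds, only
#'   therapy events in between) forms one `O` state spanning its first to
#'   its last concomitant day, absorbing plain chemo/radio days that fall
#'   inside the span;
#' * every chemotherapy state falling entirely before the first surgical
#'   state is relabelled `N` (neoadjuvant).
#'
#' A state is dated by its first and last constituent event (a pathology
#' event absorbed into a surgery state does not extend its dates, which
#' remain those of the surgical acts).
#'
#' @param events A tibble of resolved tracer events as produced by
#'   [extract_events()]: columns `patient_id`, `date`, `event_type`, and
#'   optionally `with_pathology`; within each patient dates must be
#'   strictly increasing (at most one event per day).
#' @param thresholds A [thresholds()] object.
#' @return A tibble of care states: `patient_id`, `code` (one of
#'   `A C D N K R O`), `start`, `end`, `n_events`, and a list-column
#'   `dates` with the constituent event dates.  States of one patient are
#'   non-overlapping and ordered by start.
#' @export
#' @examples
#' ev <- tibble::tibble(
#'   patient_id = "p1",
#'   date = as.Date("2008-01-01") + c(0, 10, 20),
#'   event_type = c("CHEMO", "TUM_REMOVAL", "CHEMO"),
#'   with_pathology = c(FALSE, TRUE, FALSE)
#' )
#' aggregate_states(ev)  # neoadjuvant chemo, surgery+pathology, chemo
aggregate_states <- function(events, thresholds = caretraj::thresholds()) {
  if (nrow(events) == 0) {
    return(tibble(
      patient_id = character(), code = character(),
      start = as.Date(character()), end = as.Date(character()),
      n_events = integer(), dates = list()
    ))
  }
  bad <- !events$event_type %in% names(.EVENT_TYPES)
  if (any(bad)) {
    abort(paste("Unknown event type(s):",
                paste(unique(events$event_type[bad]), collapse = ", ")))
  }
  if (!"with_pathology" %in% names(events)) events$with_pathology <- FALSE

  events |>
    group_by(.data$patient_id) |>
    dplyr::group_modify(function(ev, key) {
      d <- as.integer(diff(ev$date))
      if (any(d <= 0)) {
        abort(paste0(
          "Events of patient ", key$patient_id[1],
          " are not strictly date-ordered (one event per day, ascending)."
        ))
      }
      aggregate_patient(ev, thresholds)
    }) |>
    ungroup()
}

# Relabel event families to "O" where concomitant chemo-radiotherapy
# periods form: chains of therapy events linked by gaps < the smaller
# therapy threshold, spanning first..last same-day co-administration day;
# plain chemo/radio days inside the span are absorbed, days outside stay
# in their own family.
mark_concomitant <- function(fam, dates, th) {
  thr_o <- min(th$gap_chemo_days, th$gap_radio_days)
  n <- length(fam)
  is_ther <- fam %in% c("K", "R", "O")
  chain <- integer(n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (!is_ther[i]) next
    linked <- i > 1 && is_ther[i - 1] &&
      as.integer(dates[i] - dates[i - 1]) < thr_o
    if (linked) {
      chain[i] <- chain[i - 1]
    } else {
      cid <- cid + 1L
      chain[i] <- cid
    }
  }
  for (cc in setdiff(unique(chain), 0L)) {
    idx <- which(chain == cc)
    f <- fam[idx]
    if (any(f == "O")) {
      span <- range(which(f == "O"))
      fam[idx[span[1]:span[2]]] <- "O"
    }
  }
  fam
}

# Single-patient sequential state builder; `ev` sorted, one event/day.
aggregate_patient <- function(ev, th) {
  fam <- event_family(ev$event_type)
  fam <- mark_concomitant(fam, ev$date, th)
  thr <- c(
    A = th$gap_path_days, C = th$gap_surgery_days,
    K = th$gap_chemo_days, R = th$gap_radio_days,
    O = min(th$gap_chemo_days, th$gap_radio_days)
  )

  states <- list()
  cur <- NULL
  close_cur <- function() {
    if (!is.null(cur)) states[[length(states) + 1L]] <<- cur
  }
  for (i in seq_len(nrow(ev))) {
    f <- fam[i]
    d <- ev$date[i]
    wp <- isTRUE(ev$with_pathology[i]) && f == "C"
    if (!is.null(cur)) {
      gap <- as.integer(d - cur$end)
      if (f == cur$fam && gap < thr[[f]]) {
        cur$end <- d
        cur$n <- cur$n + 1L
        cur$dates <- c(cur$dates, d)
        cur$has_path <- cur$has_path || wp
        next
      }
      # pathology of the surgical piece reported shortly after surgery is
      # absorbed into the surgery state without extending its dates
      if (f == "A" && cur$fam == "C" && gap <= th$ap_merge_window_days) {
        cur$n <- cur$n + 1L
        cur$dates <- c(cur$dates, d)
        cur$has_path <- TRUE
        next
      }
      close_cur()
    }
    cur <- list(fam = f, start = d, end = d, n = 1L, dates = d,
                has_path = wp)
  }
  close_cur()

  code <- vapply(states, function(s) {
    if (s$fam == "C" && s$has_path) "D" else s$fam
  }, character(1))

  # chemotherapy given entirely before the first surgery is neoadjuvant
  first_surg <- match(TRUE, code %in% c("C", "D"))
  if (!is.na(first_surg)) {
    before <- seq_len(first_surg - 1L)
    code[before][code[before] == "K"] <- "N"
  }

  tibble(
    code = code,
    start = as.Date(vapply(states, function(s) as.character(s$start),
                           character(1))),
    end = as.Date(vapply(states, function(s) as.character(s$end),
                         character(1))),
    n_events = vapply(states, function(s) s$n, integer(1)),
    dates = lapply(states, function(s) s$dates)
  )
}

#' End of the initial care trajectory
#'
#' @param states A care-state tibble for one patient (non-empty).
#' @return The end date of the last state.
#' @export
trajectory_endpoint <- function(states) {
  if (nrow(states) == 0) abort("Cannot take the endpoint of an empty state list.")
  if ("patient_id" %in% names(states) &&
      length(unique(states$patient_id)) > 1) {
    abort("`trajectory_endpoint()` expects the states of a single patient.")
  }
  max(states$end)
}
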