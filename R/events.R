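#' Source-record schema
#'
#' Coded source records are held one row per record in a data frame with
#' columns `patient_id`, `source` (`"HD"` hospital discharge or `"AP"`
#' anatomical pathology), `event_date` (ISO 8601 date), `reason_icd10`,
#' `linked_icd10`, `ccam_code`, `adicap_code`, `facility_id`; columns that
#' do not apply to a record's source are left empty.  HD rows carry an
#' explicit (reason code, linked cancer code) pair and/or a CCAM procedure
#' code linked to the cancer code; AP rows carry an 8-character ADICAP
#' lesion code.
#'
#' @name record-schema
#' @keywords internal
NULL

.RECORD_COLUMNS <- c(
  "patient_id", "source", "event_date", "reason_icd10", "linked_icd10",
  "ccam_code", "adicap_code", "facility_id"
)

blank_to_na <- function(x) {
  x <- as.character(x)
  x[!is.na(x) & trimws(x) == ""] <- NA_character_
  x
}

# Validate and normalise a raw record data frame. Malformed dates reject
# the whole input with an error naming the offending rows.
validate_records <- function(records, call = rlang::caller_env()) {
  missing_cols <- setdiff(.RECORD_COLUMNS, names(records))
  if (length(missing_cols) > 0) {
    abort(
      c("Record table is missing required columns.",
        x = paste("Missing:", paste(missing_cols, collapse = ", "))),
      call = call
    )
  }
  records <- as_tibble(records)
  bad_source <- !records$source %in% c("HD", "AP")
  if (any(bad_source)) {
    abort(
      c("`source` must be \"HD\" or \"AP\".",
        x = paste("Offending rows:", paste(utils::head(which(bad_source), 5),
                                           collapse = ", "))),
      call = call
    )
  }
  dates <- records$event_date
  if (!inherits(dates, "Date")) {
    parsed <- as.Date(blank_to_na(dates), format = "%Y-%m-%d")
    bad <- is.na(parsed) & !is.na(blank_to_na(dates))
    bad <- bad | is.na(blank_to_na(dates))
    if (any(bad)) {
      abort(
        c("Malformed or missing `event_date` (expected ISO 8601).",
          x = paste("Offending rows:", paste(utils::head(which(bad), 5),
                                             collapse = ", "))),
        call = call
      )
    }
    records$event_date <- parsed
  } else if (anyNA(dates)) {
    abort("Missing `event_date` values.", call = call)
  }
  for (col in c("reason_icd10", "linked_icd10", "ccam_code", "adicap_code")) {
    records[[col]] <- blank_to_na(records[[col]])
  }
  records$patient_id <- as.character(records$patient_id)
  if (!"record_id" %in% names(records)) {
    records$record_id <- seq_len(nrow(records))
  }
  records
}

is_breast_code <- function(code, config) {
  !is.na(code) & startsWith(code, config$breast_icd10_prefix)
}

#' Classify hospital-discharge records into tracer events
#'
#' Each HD row can yield a therapy event (its reason code is the
#' chemotherapy or radiotherapy code and is linked to a cancer code of the
#' configured site) and/or a surgical event (its CCAM procedure code is
#' linked to such a cancer code; the event type is read from the action
#' character, the 3rd character of the CCAM code).  Rows with no
#' site-linked code yield no event.  Unmapped action characters yield no
#' event and are reported in the `anomalies` attribute.
#'
#' @param records A record data frame (see [extract_events()] for the
#'   schema) — only `source == "HD"` rows are considered.
#' @param config A [code_config()].
#' @return A tibble of raw (unresolved) tracer events with columns
#'   `patient_id`, `date`, `event_type`, `source`, `record_id`, carrying
#'   an `anomalies` attribute.
#' @export
classify_hd_records <- function(records, config = code_config()) {
  records <- validate_records(records)
  hd <- filter(records, .data$source == "HD")

  therapy <- hd |>
    filter(
      .data$reason_icd10 %in% c(config$chemo_code, config$radio_code),
      is_breast_code(.data$linked_icd10, config)
    ) |>
    mutate(event_type = as.character(ifelse(
      .data$reason_icd10 == config$chemo_code, "CHEMO", "RADIO"
    )))

  surg <- hd |>
    filter(!is.na(.data$ccam_code), is_breast_code(.data$linked_icd10, config)) |>
    mutate(
      action = substr(.data$ccam_code, 3, 3),
      event_type = unname(config$ccam_action_map[.data$action])
    )

  anomalies <- surg |>
    filter(is.na(.data$event_type)) |>
    mutate(kind = "unmapped_ccam_action", code = .data$ccam_code) |>
    select("patient_id", date = "event_date", "kind", "code", "record_id")

  events <- bind_rows(
    select(therapy, "patient_id", date = "event_date", "event_type", "source",
           "record_id"),
    surg |> filter(!is.na(.data$event_type)) |>
      select("patient_id", date = "event_date", "event_type", "source",
             "record_id")
  )
  structure(arrange(events, .data$patient_id, .data$date),
            anomalies = anomalies)
}

#' Classify anatomical-pathology records into tracer events
#'
#' The sampling mode (1st character of the ADICAP code) distinguishes a
#' biopsy from the examination of a surgical piece; the organ code
#' (characters 3-4) restricts events to the configured tumour site.
#' Unmapped sampling-mode characters are reported in the `anomalies`
#' attribute; records for other organs yield no event.
#'
#' @inheritParams classify_hd_records
#' @return A tibble of raw tracer events (see [classify_hd_records()]).
#' @export
classify_ap_records <- function(records, config = code_config()) {
  records <- validate_records(records)
  ap <- filter(records, .data$source == "AP")
  bad <- is.na(ap$adicap_code)
  if (any(bad)) {
    abort(c("AP records must carry a non-empty `adicap_code`.",
            x = paste("Offending record_id:",
                      paste(utils::head(ap$record_id[bad], 5), collapse = ", "))))
  }
  ap <- ap |>
    mutate(
      topo = substr(.data$adicap_code, 3, 4),
      mode = substr(.data$adicap_code, 1, 1)
    ) |>
    filter(.data$topo %in% config$adicap_topography) |>
    mutate(event_type = unname(config$adicap_sampling_map[.data$mode]))

  anomalies <- ap |>
    filter(is.na(.data$event_type)) |>
    mutate(kind = "unmapped_adicap_mode", code = .data$adicap_code) |>
    select("patient_id", date = "event_date", "kind", "code", "record_id")

  events <- ap |>
    filter(!is.na(.data$event_type)) |>
    select("patient_id", date = "event_date", "event_type", "source",
           "record_id")
  structure(arrange(events, .data$patient_id, .data$date),
            anomalies = anomalies)
}

#' Resolve same-day events to one characterised event per patient-day
#'
#' When several tracer events fall on the same patient-day only the
#' highest-ranked one is retained, following the hierarchy tumour and/or
#' lymph-node removal > chemotherapy and/or radiotherapy > pathology
#' sampling.  Within the surgical rank a tumour removal co-occurring with
#' a lymph-node removal collapses to a combined removal; within the
#' therapy rank a chemotherapy co-occurring with a radiotherapy collapses
#' to a concomitant chemo-radiotherapy event (configurable); within the
#' pathology rank a surgical-piece examination outranks a biopsy.  A
#' pathology event suppressed by the hierarchy is remembered through the
#' `with_pathology` flag of the retained event, which later allows a
#' surgery state to be recognised as surgery-with-pathology.
#'
#' @param events A tibble of raw tracer events (`patient_id`, `date`,
#'   `event_type`, optionally `record_id`), possibly several per
#'   patient-day.
#' @param config A [code_config()]; controls same-day chemo+radio
#'   collapsing.
#' @return A tibble with one row per patient-day: `patient_id`, `date`,
#'   `event_type`, `with_pathology`, `n_src`, `provenance`.
#' @export
resolve_day <- function(events, config = code_config()) {
  if (nrow(events) == 0) {
    abort("`events` is empty: nothing to resolve.")
  }
  bad <- !events$event_type %in% names(.EVENT_TYPES)
  if (any(bad)) {
    abort(paste("Unknown event type(s):",
                paste(unique(events$event_type[bad]), collapse = ", ")))
  }
  if (!"record_id" %in% names(events)) events$record_id <- NA_integer_

  resolve_types <- function(types) {
    rk <- event_rank(types)
    top <- types[rk == max(rk)]
    if (max(rk) == 3) {
      if ("TUM_LN_REMOVAL" %in% top ||
          ("TUM_REMOVAL" %in% top && "LN_REMOVAL" %in% top)) {
        return("TUM_LN_REMOVAL")
      }
      return(top[1])
    }
    if (max(rk) == 2) {
      both <- "CHEMO" %in% top && "RADIO" %in% top
      if ("CHEMO_RADIO" %in% top || (both && config$collapse_chemo_radio)) {
        return("CHEMO_RADIO")
      }
      if (both) return("CHEMO")
      return(top[1])
    }
    if ("PATH_SURGICAL" %in% top) "PATH_SURGICAL" else "PATH_BIOPSY"
  }

  events |>
    group_by(.data$patient_id, .data$date) |>
    summarise(
      with_pathology = any(event_rank(.data$event_type) == 1),
      event_type = resolve_types(.data$event_type),
      n_src = dplyr::n(),
      provenance = paste(sort(unique(stats::na.omit(.data$record_id))),
                         collapse = ";"),
      .groups = "drop"
    ) |>
    select("patient_id", "date", "event_type", "with_pathology", "n_src",
           "provenance") |>
    arrange(.data$patient_id, .data$date)
}

#' Extract the per-patient tracer-event stream from source records
#'
#' Composes the two record classifiers and the per-day resolution rule:
#' records may arrive unordered and multi-patient; the output is grouped
#' by patient, strictly ordered by date, with at most one event per
#' patient-day.  Classification anomalies (unmapped code characters) never
#' abort a run; they are collected in the `anomalies` attribute,
#' retrievable with [anomalies()].
#'
#' @param records A data frame of coded source records with columns
#'   `patient_id`, `source` (`"HD"`/`"AP"`), `event_date` (ISO date),
#'   `reason_icd10`, `linked_icd10`, `ccam_code`, `adicap_code`,
#'   `facility_id` (empty where not applicable).
#' @param config A [code_config()].
#' @return A tibble of resolved tracer events (one row per patient-day)
#'   with columns `patient_id`, `date`, `event_type`, `with_pathology`,
#'   `n_src`, `provenance`, and an `anomalies` attribute.
#' @export
#' @examples
#' recs <- tibble::tibble(
#'   patient_id = "p1", source = c("HD", "AP"),
#'   event_date = c("2008-03-10", "2008-02-20"),
#'   reason_icd10 = c("Z511", NA), linked_icd10 = c("C509", NA),
#'   ccam_code = NA, adicap_code = c(NA, "BHGSA7B2"), facility_id = "F1"
#' )
#' extract_events(recs)
extract_events <- function(records, config = code_config()) {
  records <- validate_records(records)
  hd <- classify_hd_records(records, config)
  ap <- classify_ap_records(records, config)
  anomalies <- bind_rows(attr(hd, "anomalies"), attr(ap, "anomalies"))
  raw <- bind_rows(hd, ap)
  if (nrow(raw) == 0) {
    out <- tibble(
      patient_id = character(), date = as.Date(character()),
      event_type = character(), with_pathology = logical(),
      n_src = integer(), provenance = character()
    )
    return(structure(out, anomalies = anomalies, class = class(out)))
  }
  out <- resolve_day(raw, config)
  structure(out, anomalies = anomalies, class = class(out))
}

#' Retrieve the anomaly log attached to an extraction result
#'
#' @param x A result of [extract_events()], [classify_hd_records()] or
#'   [classify_ap_records()].
#' @return A tibble with one row per unmapped code (`patient_id`, `date`,
#'   `kind`, `code`, `record_id`), empty when the run was clean.
#' @export
anomalies <- function(x) {
  a <- attr(x, "anomalies")
  if (is.null(a)) {
    a <- tibble(patient_id = character(), date = as.Date(character()),
                kind = character(), code = character(), record_id = integer())
  }
  a
}
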