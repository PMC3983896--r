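#' Code classification configuration
#'
#' Holds the coding conventions used to recognise tracer events in the two
#' source streams: which ICD-10 prefix identifies the cancer of interest,
#' which reason codes mark chemotherapy and radiotherapy administrations,
#' how the 3rd (action) character of a CCAM procedure code maps to a
#' surgical event type, and how the 1st (sampling-mode) character of an
#' ADICAP pathology code maps to a biopsy or surgical-piece examination.
#'
#' The shipped action and sampling-mode maps cover only the characters
#' needed for the breast-cancer application and are placeholders for the
#' full nomenclature tables: override them with the complete tables of
#' your registry when deploying on real extracts.  Unmapped characters are
#' never dropped silently; they are reported in the anomaly log of
#' [extract_events()].
#'
#' @param breast_icd10_prefix ICD-10 prefix identifying the tumour site of
#'   interest (default `"C50"`, breast).
#' @param chemo_code ICD-10 reason code for a chemotherapy administration
#'   (default `"Z511"`).
#' @param radio_code ICD-10 reason code for a radiotherapy session
#'   (default `"Z510"`).
#' @param ccam_action_map Named character vector mapping the CCAM action
#'   character (3rd character of the procedure code) to a surgical event
#'   type among `TUM_REMOVAL`, `LN_REMOVAL`, `TUM_LN_REMOVAL`.
#' @param adicap_sampling_map Named character vector mapping the ADICAP
#'   sampling-mode character (1st character of the lesion code) to
#'   `PATH_BIOPSY` or `PATH_SURGICAL`.
#' @param adicap_topography Character vector of 2-character ADICAP organ
#'   codes (positions 3-4) accepted as the tumour site of interest;
#'   records with other organ codes yield no event.
#' @param collapse_chemo_radio Should a chemotherapy and a radiotherapy
#'   event recorded on the same day (in distinct records) be collapsed
#'   into a single concomitant chemo-radiotherapy event?  Default `TRUE`;
#'   with `FALSE` the day resolves to the chemotherapy event.
#'
#' @return An object of class `code_config` (a named list).
#' @seealso [thresholds()], [extract_events()]
#' @export
#' @examples
#' cfg <- code_config()
#' cfg$ccam_action_map
code_config <- function(breast_icd10_prefix = "C50",
                        chemo_code = "Z511",
                        radio_code = "Z510",
                        ccam_action_map = c(
                          "F" = "TUM_LN_REMOVAL",
                          "E" = "TUM_REMOVAL",
                          "J" = "LN_REMOVAL"
                        ),
                        adicap_sampling_map = c(
                          "O" = "PATH_SURGICAL",
                          "P" = "PATH_SURGICAL",
                          "B" = "PATH_BIOPSY",
                          "C" = "PATH_BIOPSY"
                        ),
                        adicap_topography = "GS",
                        collapse_chemo_radio = TRUE) {
  surg_types <- c("TUM_REMOVAL", "LN_REMOVAL", "TUM_LN_REMOVAL")
  if (!all(ccam_action_map %in% surg_types)) {
    abort("`ccam_action_map` values must be surgical event types.")
  }
  if (!all(adicap_sampling_map %in% c("PATH_BIOPSY", "PATH_SURGICAL"))) {
    abort("`adicap_sampling_map` values must be PATH_BIOPSY or PATH_SURGICAL.")
  }
  structure(
    list(
      breast_icd10_prefix = breast_icd10_prefix,
      chemo_code = chemo_code,
      radio_code = radio_code,
      ccam_action_map = ccam_action_map,
      adicap_sampling_map = adicap_sampling_map,
      adicap_topography = adicap_topography,
      collapse_chemo_radio = isTRUE(collapse_chemo_radio)
    ),
    class = "code_config"
  )
}

#' Aggregation thresholds
#'
#' Maximum tolerated time-lapse (in days) between two events of the same
#' family for them to be aggregated into a single care state.  Exceeding a
#' threshold splits the events into two distinct care episodes.  The
#' defaults translate the guideline conventions — six months between
#' chemotherapy administrations, one month between radiotherapy sessions,
#' three months between surgical acts, three months between pathology
#' samples — into fixed day counts (183 / 31 / 92 / 92); aggregation
#' requires the gap to be strictly below the threshold.
#'
#' @param gap_path_days Pathology threshold, days (default 92).
#' @param gap_surgery_days Surgery threshold, days (default 92).
#' @param gap_chemo_days Chemotherapy threshold, days (default 183).
#' @param gap_radio_days Radiotherapy threshold, days (default 31).
#' @param ap_merge_window_days A standalone pathology event falling at most
#'   this many days after the end of a surgery state is absorbed into it,
#'   turning it into a surgery-with-pathology state.  Default 0: only a
#'   pathology record co-occurring on a surgery day is merged.
#'
#' @return An object of class `thresholds` (a named list).
#' @seealso [aggregate_states()]
#' @export
thresholds <- function(gap_path_days = 92,
                       gap_surgery_days = 92,
                       gap_chemo_days = 183,
                       gap_radio_days = 31,
                       ap_merge_window_days = 0) {
  vals <- c(gap_path_days, gap_surgery_days, gap_chemo_days, gap_radio_days)
  if (any(vals < 1)) abort("Gap thresholds must be strictly positive day counts.")
  if (ap_merge_window_days < 0) abort("`ap_merge_window_days` must be >= 0.")
  structure(
    list(
      gap_path_days = as.integer(gap_path_days),
      gap_surgery_days = as.integer(gap_surgery_days),
      gap_chemo_days = as.integer(gap_chemo_days),
      gap_radio_days = as.integer(gap_radio_days),
      ap_merge_window_days = as.integer(ap_merge_window_days)
    ),
    class = "thresholds"
  )
}

#' Read and write configuration as YAML
#'
#' A configuration file holds up to three blocks: `codes` (arguments of
#' [code_config()]), `thresholds` (arguments of [thresholds()]) and `sim`
#' (arguments of [sim_config()]).  Missing blocks and missing entries fall
#' back to the package defaults.
#'
#' @param path Path to a YAML file.
#' @return For `read_config()`, a list with elements `codes`, `thresholds`
#'   and `sim`.  For `write_config()`, the path, invisibly.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  codes <- raw$codes %||% list()
  if (!is.null(codes$ccam_action_map)) {
    codes$ccam_action_map <- unlist(codes$ccam_action_map)
  }
  if (!is.null(codes$adicap_sampling_map)) {
    codes$adicap_sampling_map <- unlist(codes$adicap_sampling_map)
  }
  list(
    codes = do.call(code_config, codes),
    thresholds = do.call(thresholds, raw$thresholds %||% list()),
    sim = do.call(sim_config, raw$sim %||% list())
  )
}

#' @rdname read_config
#' @param config A list as returned by [read_config()], or any subset of
#'   its blocks.
#' @export
write_config <- function(config, path) {
  strip <- function(x) {
    if (is.list(x)) {
      lapply(unclass(x), strip)
    } else if (inherits(x, "Date")) {
      as.character(x)
    } else if (!is.null(names(x))) {
      as.list(x)  # keep named vectors as YAML maps
    } else {
      x
    }
  }
  yaml::write_yaml(strip(config), path)
  invisible(path)
}

#' Default pipeline configuration
#'
#' @return A list with elements `codes`, `thresholds` and `sim`, all at
#'   their package defaults (dumpable with [write_config()]).
#' @export
default_config <- function() {
  list(codes = code_config(), thresholds = thresholds(), sim = sim_config())
}
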