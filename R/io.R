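#' Read coded source records from CSV
#'
#' Expects one row per source record with columns `patient_id`, `source`,
#' `event_date` (ISO 8601), `reason_icd10`, `linked_icd10`, `ccam_code`,
#' `adicap_code`, `facility_id`.  Schema violations and malformed dates
#' reject the file with an error naming the problem; values are never
#' silently coerced.
#'
#' @param path Path to a CSV file.
#' @return A validated record tibble.
#' @export
read_records <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  validate_records(raw)
}

#' @rdname read_records
#' @param records A record tibble.
#' @export
write_records <- function(records, path) {
  out <- as_tibble(records)[, .RECORD_COLUMNS]
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read and write tracer-event tables
#'
#' @param path Path to a CSV file with columns `patient_id`, `date`,
#'   `event_type`, `with_pathology`, `provenance`.
#' @return A tracer-event tibble.
#' @export
read_events <- function(path) {
  ev <- readr::read_csv(
    path,
    col_types = readr::cols(
      patient_id = "c", date = readr::col_date(), event_type = "c",
      with_pathology = "l", .default = "c"
    ),
    progress = FALSE
  )
  needed <- c("patient_id", "date", "event_type")
  missing_cols <- setdiff(needed, names(ev))
  if (length(missing_cols) > 0) {
    abort(paste("Event file is missing columns:",
                paste(missing_cols, collapse = ", ")))
  }
  if (!"with_pathology" %in% names(ev)) ev$with_pathology <- FALSE
  ev
}

#' @rdname read_events
#' @param events A tracer-event tibble.
#' @export
write_events <- function(events, path) {
  keep <- intersect(
    c("patient_id", "date", "event_type", "with_pathology", "n_src",
      "provenance"),
    names(events)
  )
  readr::write_csv(as_tibble(events)[, keep], path, progress = FALSE)
  invisible(path)
}

#' Read and write SPELL files
#'
#' SPELL CSV files store state sequences vertically: columns
#' `patient_id`, `state`, `start`, `end` (ISO dates), one row per state.
#'
#' @param path Path to a CSV file.
#' @return A care-state tibble (see [from_spell()]).
#' @export
read_spell <- function(path) {
  rows <- readr::read_csv(
    path,
    col_types = readr::cols(patient_id = "c", state = "c",
                            start = readr::col_date(),
                            end = readr::col_date()),
    progress = FALSE
  )
  missing_cols <- setdiff(c("patient_id", "state", "start", "end"), names(rows))
  if (length(missing_cols) > 0) {
    abort(paste("SPELL file is missing columns:",
                paste(missing_cols, collapse = ", ")))
  }
  from_spell(rows)
}

#' @rdname read_spell
#' @param states A care-state tibble.
#' @export
write_spell <- function(states, path) {
  readr::write_csv(to_spell(states), path, progress = FALSE)
  invisible(path)
}

#' Read and write sequence tables
#'
#' Sequence CSV files carry one row per patient: `patient_id`, `simple`,
#' `extended`, `origin` (ISO date of the first state start).
#'
#' @param path Path to a CSV file.
#' @return A sequence tibble as produced by [care_sequences()].
#' @export
read_sequences <- function(path) {
  out <- readr::read_csv(
    path,
    col_types = readr::cols(patient_id = "c", simple = "c", extended = "c",
                            .default = "c"),
    progress = FALSE
  )
  missing_cols <- setdiff(c("patient_id", "simple"), names(out))
  if (length(missing_cols) > 0) {
    abort(paste("Sequence file is missing columns:",
                paste(missing_cols, collapse = ", ")))
  }
  if ("origin" %in% names(out)) out$origin <- as.Date(out$origin)
  if ("end" %in% names(out)) out$end <- as.Date(out$end)
  out$simple[is.na(out$simple)] <- ""
  if ("extended" %in% names(out)) out$extended[is.na(out$extended)] <- ""
  out
}

#' @rdname read_sequences
#' @param sequences A sequence tibble.
#' @export
write_sequences <- function(sequences, path) {
  readr::write_csv(as_tibble(sequences), path, progress = FALSE)
  invisible(path)
}

write_manifest <- function(out_dir, stage, inputs, outputs, seed = NULL,
                           config = NULL, extra = list()) {
  manifest <- c(list(
    stage = stage,
    inputs = as.list(inputs),
    outputs = as.list(outputs),
    seed = seed,
    config_hash = rlang::hash(config)
  ), extra)
  path <- file.path(out_dir, paste0("manifest_", stage, ".json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  invisible(path)
}

#' Pipeline stage runners (file in, file out)
#'
#' Thin file-based wrappers around the package pipeline, used by the
#' command-line front-end.  Every runner writes its outputs plus a JSON
#' run manifest (inputs, outputs, configuration hash, seed, anomaly
#' counts) into `out_dir`; reruns with identical inputs, configuration
#' and seed produce identical outputs.
#'
#' * `run_extract()` — records CSV -> tracer events (+ anomaly log);
#' * `run_trajectories()` — events CSV -> SPELL + sequences CSV;
#' * `run_classify()` — sequences CSV -> inventory + category totals;
#' * `run_compare()` — two sequence CSVs -> pair and summary reports;
#' * `run_simulate()` — synthetic records + ground truth + perturbation
#'   log;
#' * `run_validate()` — the full generate/perturb/reconstruct/compare
#'   experiment of [run_validation_experiment()].
#'
#' @param records_csv,events_csv,sequences_csv,algorithm_csv,reference_csv
#'   Input CSV paths.
#' @param out_dir Output directory (created if needed).
#' @param config A configuration list as returned by [read_config()] or
#'   [default_config()].
#' @param form,tolerances Comparison settings for `run_compare()`.
#' @param seed Master seed for the stochastic runners.
#' @return The paths of the written outputs, invisibly.
#' @name runners
NULL

#' @rdname runners
#' @export
run_extract <- function(records_csv, out_dir, config = default_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  records <- read_records(records_csv)
  events <- extract_events(records, config$codes)
  if (nrow(events) == 0) warn("No tracer events found in the input records.")
  anom <- anomalies(events)
  out_events <- file.path(out_dir, "events.csv")
  out_anom <- file.path(out_dir, "anomalies.csv")
  write_events(events, out_events)
  readr::write_csv(anom, out_anom, progress = FALSE)
  write_manifest(out_dir, "extract", records_csv, c(out_events, out_anom),
                 config = config$codes,
                 extra = list(n_records = nrow(records),
                              n_events = nrow(events),
                              n_anomalies = nrow(anom)))
  invisible(c(events = out_events, anomalies = out_anom))
}

#' @rdname runners
#' @export
run_trajectories <- function(events_csv, out_dir, config = default_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  events <- read_events(events_csv)
  states <- aggregate_states(events, config$thresholds)
  seqs <- care_sequences(states)
  out_spell <- file.path(out_dir, "spell.csv")
  out_seq <- file.path(out_dir, "sequences.csv")
  write_spell(states, out_spell)
  write_sequences(seqs, out_seq)
  write_manifest(out_dir, "trajectories", events_csv, c(out_spell, out_seq),
                 config = config$thresholds,
                 extra = list(n_states = nrow(states),
                              n_patients = nrow(seqs)))
  invisible(c(spell = out_spell, sequences = out_seq))
}

#' @rdname runners
#' @export
run_classify <- function(sequences_csv, out_dir, config = default_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seqs <- read_sequences(sequences_csv)
  inv <- tabulate_sequences(seqs$simple)
  out_inv <- file.path(out_dir, "inventory.csv")
  out_cat <- file.path(out_dir, "categories.csv")
  readr::write_csv(inv$sequences, out_inv, progress = FALSE)
  readr::write_csv(inv$categories, out_cat, progress = FALSE)
  write_manifest(out_dir, "classify", sequences_csv, c(out_inv, out_cat),
                 extra = list(n_patients = inv$n_total))
  invisible(c(inventory = out_inv, categories = out_cat))
}

#' @rdname runners
#' @export
run_compare <- function(algorithm_csv, reference_csv, out_dir,
                        form = "simple", tolerances = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  alg <- read_sequences(algorithm_csv)
  ref <- read_sequences(reference_csv)
  report <- pairwise_eval(alg, ref, form = form, tolerances = tolerances)
  out_pairs <- file.path(out_dir, paste0("pairs_", form, ".csv"))
  out_sum <- file.path(out_dir, paste0("summary_", form, ".csv"))
  readr::write_csv(report$pairs, out_pairs, progress = FALSE)
  readr::write_csv(report$summary, out_sum, progress = FALSE)
  print(report)
  write_manifest(out_dir, paste0("compare_", form),
                 c(algorithm_csv, reference_csv), c(out_pairs, out_sum))
  invisible(c(pairs = out_pairs, summary = out_sum))
}

#' @rdname runners
#' @export
run_simulate <- function(out_dir, config = default_config(),
                         seed = config$sim$seed) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- generate_cohort(config$sim, seed)
  pert <- perturb(cohort$records, config$sim$noise,
                  seed = (seed + 104729L) %% .Machine$integer.max)
  out_rec <- file.path(out_dir, "records.csv")
  out_truth <- file.path(out_dir, "truth_spell.csv")
  out_seq <- file.path(out_dir, "truth_sequences.csv")
  out_log <- file.path(out_dir, "perturbations.csv")
  write_records(pert$records, out_rec)
  write_spell(cohort$truth, out_truth)
  write_sequences(cohort$truth_sequences, out_seq)
  readr::write_csv(pert$log, out_log, progress = FALSE)
  write_manifest(out_dir, "simulate", character(),
                 c(out_rec, out_truth, out_seq, out_log),
                 seed = seed, config = config$sim,
                 extra = list(n_patients = nrow(cohort$patients),
                              n_records = nrow(pert$records),
                              n_perturbations = nrow(pert$log)))
  invisible(c(records = out_rec, truth_spell = out_truth,
              truth_sequences = out_seq, log = out_log))
}

#' @rdname runners
#' @export
run_validate <- function(out_dir, config = default_config(),
                         seed = config$sim$seed) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- run_validation_experiment(config$sim, seed = seed,
                                   thresholds = config$thresholds,
                                   code_config = config$codes)
  out_sum <- file.path(out_dir, "validation_summary.csv")
  out_pairs <- file.path(out_dir, "validation_pairs.csv")
  out_log <- file.path(out_dir, "perturbations.csv")
  readr::write_csv(glance(res), out_sum, progress = FALSE)
  readr::write_csv(tidy(res), out_pairs, progress = FALSE)
  readr::write_csv(res$perturbations, out_log, progress = FALSE)
  print(res)
  write_manifest(out_dir, "validate", character(),
                 c(out_sum, out_pairs, out_log),
                 seed = seed, config = config$sim,
                 extra = list(n_patients = nrow(res$simple$pairs),
                              n_perturbations = nrow(res$perturbations)))
  invisible(c(summary = out_sum, pairs = out_pairs, log = out_log))
}
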