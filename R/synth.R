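#' Synthetic-cohort configuration
#'
#' Parameters of the synthetic cohort generator.  The defaults emulate
#' the treatment patterns of the guideline pathways for non-metastatic
#' breast cancer — chemotherapy in 4 to 6 administrations 21 days apart,
#' radiotherapy in 25 weekday fractions spanning about 33 days, adjuvant
#' chemotherapy starting 3 to 6 weeks after surgery, radiotherapy
#' starting at most 5 weeks after chemotherapy — and the cohort
#' composition observed in the published 159-patient evaluation sample
#' (see [observed_breast_cohort()]).  Delay ranges are inclusive day
#' intervals sampled uniformly.
#'
#' @param n_per_category Named integer vector: number of patients drawn
#'   from each category (`a` good prognosis, `b` poor prognosis,
#'   `c` neoadjuvant, `other` non-standard).
#' @param archetype_weights Named list of per-category archetype weights;
#'   each element is a named numeric vector (archetype simple form ->
#'   sampling weight).  Defaults to the observed per-sequence
#'   frequencies.
#' @param chemo_cycles,neoadj_cycles Integer range (length 2) of
#'   chemotherapy administrations per state.
#' @param chemo_interval_days Days between consecutive administrations.
#' @param rt_fractions Number of radiotherapy fractions per state.
#' @param rt_weekdays_only Deliver fractions on weekdays only (5 per
#'   week), so 25 fractions span about 33 days.
#' @param delays Named list of inclusive day ranges for the inter-state
#'   delays; see `sim_config()$delays` for the keys.
#' @param diagnosis_window Character vector of two ISO dates; each
#'   patient's first event date is drawn uniformly in this window.
#' @param noise List of coding-anomaly probabilities applied
#'   independently per patient by [perturb()]: `p_drop_pathology` (drop
#'   one pathology report), `p_drop_boundary_sessions` (drop the coding
#'   of the first or last therapy sessions of a state;
#'   `boundary_drop_range` gives the count range), `p_drop_mid_sessions`
#'   (drop a session in the middle of a state), `p_shift_surgery` (shift
#'   a surgery date by one day).  All default to 0: the default cohort is
#'   noise-free.
#' @param seed Default master seed used when none is passed to
#'   [generate_cohort()].
#' @return A `sim_config` object (named list).
#' @export
sim_config <- function(n_per_category = c(a = 81, b = 54, c = 8, other = 16),
                       archetype_weights = list(
                         a = c(ADR = 47, AD = 16, DR = 13, D = 5),
                         b = c(ADKR = 42, ADKOK = 8, DKR = 2, DKOK = 2),
                         c = c(ANDR = 8),
                         other = c(A = 6, ADK = 2, AK = 2, AR = 2,
                                   ADKDR = 1, ANDRK = 1, DK = 1, DKDKOK = 1)
                       ),
                       chemo_cycles = c(4, 6),
                       chemo_interval_days = 21,
                       rt_fractions = 25,
                       rt_weekdays_only = TRUE,
                       neoadj_cycles = c(4, 6),
                       delays = list(
                         biopsy_to_neoadj = c(7, 21),
                         biopsy_to_surgery = c(14, 35),
                         biopsy_to_chemo = c(14, 35),
                         biopsy_to_rt = c(21, 84),
                         neoadj_to_surgery = c(21, 42),
                         surgery_to_chemo = c(21, 42),
                         surgery_to_rt = c(21, 84),
                         chemo_to_rt = c(7, 35),
                         chemo_to_concomitant = c(7, 35),
                         concomitant_to_chemo = c(7, 21),
                         rt_to_chemo = c(30, 90),
                         chemo_to_surgery = c(120, 180)
                       ),
                       diagnosis_window = c("2008-01-01", "2008-12-31"),
                       noise = list(),
                       seed = 1L) {
  default_noise <- list(
    p_drop_pathology = 0, p_drop_boundary_sessions = 0,
    boundary_drop_range = c(1, 3), p_drop_mid_sessions = 0,
    p_shift_surgery = 0
  )
  noise <- utils::modifyList(default_noise, as.list(noise))
  noise$boundary_drop_range <- unlist(noise$boundary_drop_range)
  # coerce YAML-roundtripped lists back to the vector shapes used internally
  n_per_category <- unlist(n_per_category)
  archetype_weights <- lapply(archetype_weights, unlist)
  chemo_cycles <- unlist(chemo_cycles)
  neoadj_cycles <- unlist(neoadj_cycles)
  delays <- lapply(as.list(delays), unlist)
  diagnosis_window <- unlist(diagnosis_window)
  probs <- unlist(noise[startsWith(names(noise), "p_")])
  if (any(probs < 0 | probs > 1)) {
    abort("Noise probabilities must lie in [0, 1].")
  }
  if (any(n_per_category < 0)) abort("Category counts must be >= 0.")
  default_delays <- eval(formals(sim_config)$delays)
  structure(
    list(
      n_per_category = n_per_category,
      archetype_weights = archetype_weights,
      chemo_cycles = chemo_cycles,
      chemo_interval_days = chemo_interval_days,
      rt_fractions = rt_fractions,
      rt_weekdays_only = isTRUE(rt_weekdays_only),
      neoadj_cycles = neoadj_cycles,
      delays = utils::modifyList(default_delays, as.list(delays)),
      diagnosis_window = as.Date(diagnosis_window),
      noise = noise,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

r_int <- function(range) {
  if (range[1] >= range[2]) return(as.integer(range[1]))
  as.integer(sample(seq(range[1], range[2]), 1))
}

# Dates of n sessions starting at `start`, one per weekday (or per day).
session_dates <- function(start, n, weekdays_only) {
  if (!weekdays_only) return(start + seq_len(n) - 1L)
  d <- start
  # anchor on a weekday
  while (format(d, "%u") %in% c("6", "7")) d <- d + 1L
  out <- d
  while (length(out) < n) {
    d <- d + 1L
    if (!format(d, "%u") %in% c("6", "7")) out <- c(out, d)
  }
  out
}

hd_row <- function(pid, date, reason = NA, linked = NA, ccam = NA, fac) {
  tibble(patient_id = pid, source = "HD", event_date = date,
         reason_icd10 = reason, linked_icd10 = linked, ccam_code = ccam,
         adicap_code = NA_character_, facility_id = fac)
}

ap_row <- function(pid, date, adicap, fac) {
  tibble(patient_id = pid, source = "AP", event_date = date,
         reason_icd10 = NA_character_, linked_icd10 = NA_character_,
         ccam_code = NA_character_, adicap_code = adicap, facility_id = fac)
}

#' Generate one synthetic patient
#'
#' Draws event dates for the given archetype (a simple-form string such
#' as `"ADKR"`) and emits both the coded source records — ICD-10
#' reason/cancer pairs, CCAM procedure codes and ADICAP pathology codes,
#' as the registry streams would carry them — and the analytically known
#' ground-truth care states.  Concomitant (`O`) periods are emitted as
#' radiotherapy fractions each accompanied by a same-day systemic-therapy
#' code, the coding pattern of HER2-targeted therapy administered at
#' radiotherapy visits.
#'
#' @param patient_id Patient identifier.
#' @param archetype Simple-form string over `A N D K O R` describing the
#'   state sequence to realise.
#' @param config A [sim_config()].
#' @return A list with `truth` (care-state tibble) and `records` (source
#'   records).
#' @export
generate_patient <- function(patient_id, archetype, config = sim_config()) {
  letters_ <- strsplit(archetype, "")[[1]]
  if (length(letters_) == 0 || !all(letters_ %in% c("A", "N", "D", "K", "O", "R"))) {
    abort(paste0("Invalid archetype \"", archetype,
                 "\": use letters A N D K O R."))
  }
  dl <- config$delays
  delay_for <- function(prev, cur) {
    key <- paste0(prev, cur)
    range <- switch(key,
      AN = dl$biopsy_to_neoadj, AD = dl$biopsy_to_surgery,
      AK = dl$biopsy_to_chemo, AR = dl$biopsy_to_rt,
      ND = dl$neoadj_to_surgery,
      DK = dl$surgery_to_chemo, DR = dl$surgery_to_rt,
      KR = dl$chemo_to_rt, KO = dl$chemo_to_concomitant,
      OK = dl$concomitant_to_chemo, RK = dl$rt_to_chemo,
      KD = dl$chemo_to_surgery,
      abort(paste0("No delay configured for transition ", prev, " -> ", cur))
    )
    r_int(range)
  }

  win <- config$diagnosis_window
  cursor <- win[1] + r_int(c(0, as.integer(win[2] - win[1])))
  cancer_code <- paste0("C50", sample(0:9, 1))
  hosp <- sample(paste0("HOSP", 1:5), 1)
  lab <- sample(paste0("LAB", 1:3), 1)

  records <- list()
  truth <- list()
  prev <- NULL
  for (st in letters_) {
    if (!is.null(prev)) cursor <- end_prev + delay_for(prev, st)
    if (st == "A") {
      records[[length(records) + 1L]] <-
        ap_row(patient_id, cursor, "BHGSA7B2", lab)
      truth[[length(truth) + 1L]] <-
        tibble(code = "A", start = cursor, end = cursor, n_events = 1L)
      end_prev <- cursor
    } else if (st == "D") {
      records[[length(records) + 1L]] <-
        hd_row(patient_id, cursor, linked = cancer_code, ccam = "QEFA001",
               fac = hosp)
      records[[length(records) + 1L]] <-
        ap_row(patient_id, cursor, "OHGSA7B2", lab)
      truth[[length(truth) + 1L]] <-
        tibble(code = "D", start = cursor, end = cursor, n_events = 1L)
      end_prev <- cursor
    } else if (st %in% c("K", "N")) {
      cycles <- r_int(if (st == "N") config$neoadj_cycles else config$chemo_cycles)
      days <- cursor + (seq_len(cycles) - 1L) * config$chemo_interval_days
      for (d in seq_along(days)) {
        records[[length(records) + 1L]] <-
          hd_row(patient_id, days[d], reason = "Z511", linked = cancer_code,
                 fac = hosp)
      }
      truth[[length(truth) + 1L]] <-
        tibble(code = st, start = days[1], end = days[length(days)],
               n_events = length(days))
      end_prev <- days[length(days)]
    } else if (st %in% c("R", "O")) {
      days <- session_dates(cursor, config$rt_fractions, config$rt_weekdays_only)
      for (d in seq_along(days)) {
        records[[length(records) + 1L]] <-
          hd_row(patient_id, days[d], reason = "Z510", linked = cancer_code,
                 fac = hosp)
        if (st == "O") {
          records[[length(records) + 1L]] <-
            hd_row(patient_id, days[d], reason = "Z511", linked = cancer_code,
                   fac = hosp)
        }
      }
      truth[[length(truth) + 1L]] <-
        tibble(code = st, start = days[1], end = days[length(days)],
               n_events = length(days))
      end_prev <- days[length(days)]
    }
    prev <- st
  }
  truth <- bind_rows(truth)
  truth$patient_id <- patient_id
  truth <- select(truth, "patient_id", "code", "start", "end", "n_events")
  list(truth = truth, records = bind_rows(records))
}

#' Generate a synthetic cohort
#'
#' Draws `n_per_category` patients per category, sampling an archetype
#' per patient from the configured weights.  All randomness flows from
#' the master seed through deterministic per-patient substreams, so a
#' cohort is reproducible record-by-record and a patient's draw does not
#' depend on the rest of the cohort.
#'
#' @param config A [sim_config()].
#' @param seed Master seed (defaults to `config$seed`).
#' @return A list of class `synthetic_cohort`: `truth` (care states per
#'   patient), `truth_sequences` (via [care_sequences()]), `records`
#'   (coded source records, shuffled), `patients` (patient_id, category,
#'   archetype).
#' @export
generate_cohort <- function(config = sim_config(), seed = config$seed) {
  set.seed(seed)
  cats <- config$n_per_category
  roster <- purrr::map_dfr(names(cats), function(cat) {
    k <- cats[[cat]]
    if (k == 0) return(tibble(category = character(), archetype = character()))
    w <- config$archetype_weights[[cat]]
    if (is.null(w)) abort(paste0("No archetype weights for category ", cat))
    tibble(
      category = cat,
      archetype = sample(names(w), k, replace = TRUE, prob = w)
    )
  })
  if (nrow(roster) == 0) {
    empty_states <- tibble(patient_id = character(), code = character(),
                           start = as.Date(character()),
                           end = as.Date(character()), n_events = integer())
    return(structure(list(
      truth = empty_states,
      truth_sequences = tibble(patient_id = character(), simple = character(),
                               extended = character(),
                               origin = as.Date(character()),
                               end = as.Date(character())),
      records = hd_row(character(), as.Date(character()), fac = character())[0, ],
      patients = tibble(patient_id = character(), category = character(),
                        archetype = character())
    ), class = "synthetic_cohort"))
  }
  roster$patient_id <- sprintf("P%04d", seq_len(nrow(roster)))

  out <- purrr::map(seq_len(nrow(roster)), function(i) {
    # deterministic per-patient substream
    set.seed((seed + i * 9973L) %% .Machine$integer.max)
    generate_patient(roster$patient_id[i], roster$archetype[i], config)
  })
  truth <- purrr::map_dfr(out, "truth")
  records <- purrr::map_dfr(out, "records")
  # present the stream unordered, as a multi-source extract would arrive
  set.seed((seed + 7L) %% .Machine$integer.max)
  records <- records[sample(nrow(records)), ]
  records$record_id <- seq_len(nrow(records))
  structure(
    list(
      truth = truth,
      truth_sequences = care_sequences(truth),
      records = records,
      patients = select(roster, "patient_id", "category", "archetype")
    ),
    class = "synthetic_cohort"
  )
}

#' Inject coding anomalies into a record stream
#'
#' Applies the configured noise modes independently per patient and
#' documents every change in a perturbation log:
#'
#' * `drop_pathology` — one randomly chosen pathology report of the
#'   patient is removed (emulating an uncoded sampling procedure);
#' * `drop_boundary_sessions` — the first or last 1-3 session codes of a
#'   randomly chosen therapy (chemo or radio) are removed (absence of
#'   coding at the start or end of a state);
#' * `drop_mid_sessions` — one non-boundary session code is removed
#'   (these have no effect on aggregated state durations);
#' * `shift_surgery` — the hospital-discharge and same-day pathology rows
#'   of one surgery are shifted by one day (a coded-date error).
#'
#' @param records A source-record tibble.
#' @param noise A noise list as in [sim_config()] (or a `sim_config`,
#'   whose `$noise` is used).
#' @param seed Seed for the perturbation draws.
#' @return A list with `records` (perturbed) and `log` (one row per
#'   injected anomaly: `patient_id`, `kind`, `detail`).
#' @export
perturb <- function(records, noise = list(), seed = 1L) {
  if (inherits(noise, "sim_config")) noise <- noise$noise
  noise <- utils::modifyList(
    list(p_drop_pathology = 0, p_drop_boundary_sessions = 0,
         boundary_drop_range = c(1, 3), p_drop_mid_sessions = 0,
         p_shift_surgery = 0),
    as.list(noise)
  )
  set.seed(seed)
  records <- validate_records(records)
  log <- list()
  drop_ids <- integer()

  for (pid in unique(records$patient_id)) {
    idx <- which(records$patient_id == pid)
    rec <- records[idx, ]

    if (runif(1) < noise$p_drop_pathology) {
      ap <- idx[rec$source == "AP"]
      if (length(ap) > 0) {
        pick <- if (length(ap) == 1) ap else sample(ap, 1)
        drop_ids <- c(drop_ids, pick)
        log[[length(log) + 1L]] <- tibble(
          patient_id = pid, kind = "drop_pathology",
          detail = paste0("adicap=", records$adicap_code[pick],
                          " date=", records$event_date[pick])
        )
      }
    }

    if (runif(1) < noise$p_drop_boundary_sessions) {
      codes <- intersect(c("Z511", "Z510"), rec$reason_icd10)
      if (length(codes) > 0) {
        code <- if (length(codes) == 1) codes else sample(codes, 1)
        sess <- idx[!is.na(rec$reason_icd10) & rec$reason_icd10 == code]
        sess <- sess[order(records$event_date[sess])]
        k <- min(r_int(noise$boundary_drop_range), length(sess) - 1L)
        if (k >= 1) {
          side <- sample(c("first", "last"), 1)
          pick <- if (side == "first") utils::head(sess, k) else utils::tail(sess, k)
          drop_ids <- c(drop_ids, pick)
          log[[length(log) + 1L]] <- tibble(
            patient_id = pid, kind = "drop_boundary_sessions",
            detail = paste0(code, " ", side, " k=", k, " dates=",
                            paste(records$event_date[pick], collapse = ","))
          )
        }
      }
    }

    if (runif(1) < noise$p_drop_mid_sessions) {
      codes <- intersect(c("Z511", "Z510"), rec$reason_icd10)
      if (length(codes) > 0) {
        code <- if (length(codes) == 1) codes else sample(codes, 1)
        sess <- idx[!is.na(rec$reason_icd10) & rec$reason_icd10 == code]
        sess <- sess[order(records$event_date[sess])]
        if (length(sess) >= 3) {
          mid <- sess[-c(1, length(sess))]
          pick <- if (length(mid) == 1) mid else sample(mid, 1)
          drop_ids <- c(drop_ids, pick)
          log[[length(log) + 1L]] <- tibble(
            patient_id = pid, kind = "drop_mid_sessions",
            detail = paste0(code, " date=", records$event_date[pick])
          )
        }
      }
    }

    if (runif(1) < noise$p_shift_surgery) {
      surg <- idx[!is.na(rec$ccam_code)]
      if (length(surg) > 0) {
        pick <- if (length(surg) == 1) surg else sample(surg, 1)
        day <- records$event_date[pick]
        shift <- sample(c(-1L, 1L), 1)
        same_day <- idx[records$event_date[idx] == day &
                          (!is.na(records$ccam_code[idx]) |
                             records$source[idx] == "AP")]
        records$event_date[same_day] <- records$event_date[same_day] + shift
        log[[length(log) + 1L]] <- tibble(
          patient_id = pid, kind = "shift_surgery",
          detail = paste0("date=", day, " shift=", shift)
        )
      }
    }
  }

  if (length(drop_ids) > 0) records <- records[-drop_ids, ]
  log <- if (length(log)) bind_rows(log) else
    tibble(patient_id = character(), kind = character(), detail = character())
  list(records = records, log = log)
}

#' Run the end-to-end validation experiment
#'
#' Generates a synthetic cohort with known ground truth, injects the
#' configured coding anomalies, runs the full reconstruction pipeline
#' (event extraction, state aggregation, sequence rendering) on the
#' perturbed records, and confronts the reconstructed sequences with the
#' ground truth — the simple form at tolerance 0, the extended form at
#' day tolerances 1 and 3.
#'
#' @param config A [sim_config()]; its `noise` element drives the
#'   perturbation.
#' @param seed Master seed (defaults to `config$seed`).
#' @param thresholds A [thresholds()] object for the aggregation stage.
#' @param code_config A [code_config()] for the extraction stage.
#' @param tolerances_extended Day tolerances for the extended form.
#' @return A `validation_result`: list with `simple` and `extended`
#'   ([pairwise_eval()] reports), `perturbations` (log), `cohort`
#'   (the `synthetic_cohort`), and `sequences` (reconstructed).
#' @export
#' @examples
#' cfg <- sim_config(n_per_category = c(a = 5, b = 3, c = 1, other = 1))
#' res <- run_validation_experiment(cfg, seed = 7)
#' glance(res)
run_validation_experiment <- function(config = sim_config(),
                                      seed = config$seed,
                                      thresholds = caretraj::thresholds(),
                                      code_config = caretraj::code_config(),
                                      tolerances_extended = c(1L, 3L)) {
  cohort <- generate_cohort(config, seed)
  pert <- perturb(cohort$records, config$noise,
                  seed = (seed + 104729L) %% .Machine$integer.max)
  events <- extract_events(pert$records, code_config)
  states <- aggregate_states(events, thresholds)
  seqs <- care_sequences(states, patients = cohort$patients$patient_id)
  rep_s <- pairwise_eval(seqs, cohort$truth_sequences, "simple", 0L)
  rep_e <- pairwise_eval(seqs, cohort$truth_sequences, "extended",
                         tolerances_extended)
  structure(
    list(simple = rep_s, extended = rep_e, perturbations = pert$log,
         cohort = cohort, sequences = seqs),
    class = "validation_result"
  )
}

#' @export
print.validation_result <- function(x, ...) {
  cat("Validation experiment:", nrow(x$simple$pairs), "patients,",
      nrow(x$perturbations), "injected anomalies\n")
  print(x$simple)
  print(x$extended)
  invisible(x)
}
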