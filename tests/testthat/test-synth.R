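test_that("patient generation realises the requested archetype exactly", {
  archs <- c("ADR", "AD", "DR", "D", "ADKR", "ADKOK", "DKR", "DKOK", "ANDR",
             "A", "ADK", "AK", "AR", "ADKDR", "ANDRK", "DK", "DKDKOK")
  for (a in archs) {
    set.seed(99)
    g <- generate_patient("px", a, sim_config())
    expect_equal(simple_form(g$truth), a, info = a)
    # zero noise: the pipeline reconstructs the truth exactly
    st <- aggregate_states(extract_events(g$records))
    expect_equal(simple_form(st), a, info = a)
    expect_equal(extended_form(st), extended_form(g$truth), info = a)
  }
  expect_error(generate_patient("px", "XYZ", sim_config()), "Invalid archetype")
})

test_that("cohorts are reproducible from the master seed", {
  cfg <- sim_config(n_per_category = c(a = 6, b = 4, c = 1, other = 2))
  c1 <- generate_cohort(cfg, seed = 5)
  c2 <- generate_cohort(cfg, seed = 5)
  expect_identical(c1$records, c2$records)
  expect_identical(c1$truth, c2$truth)
  c3 <- generate_cohort(cfg, seed = 6)
  expect_false(identical(c1$records, c3$records))
})

test_that("zero-noise cohorts reconstruct with LED 0 in both forms", {
  cfg <- sim_config(n_per_category = c(a = 25, b = 18, c = 4, other = 8))
  res <- run_validation_experiment(cfg, seed = 17)
  expect_equal(res$simple$summary$match_rate, 100)
  expect_equal(res$extended$summary$match_rate, c(100, 100))
  expect_true(all(res$simple$pairs$led == 0))
  expect_true(all(res$extended$pairs$led == 0))
  expect_equal(nrow(res$perturbations), 0)
})

test_that("dropping pathology reports removes A states or downgrades D to C", {
  set.seed(2)
  g <- generate_patient("px", "ADR", sim_config())
  # drop the biopsy report: leading A lost
  is_ap_mode <- function(r, mode) {
    r$source == "AP" & !is.na(r$adicap_code) & startsWith(r$adicap_code, mode)
  }
  no_biopsy <- g$records[!is_ap_mode(g$records, "B"), ]
  st <- aggregate_states(extract_events(no_biopsy))
  expect_equal(simple_form(st), "DR")
  # drop the surgical-piece report: D becomes C
  no_piece <- g$records[!is_ap_mode(g$records, "O"), ]
  st2 <- aggregate_states(extract_events(no_piece))
  expect_equal(simple_form(st2), "ACR")
})

test_that("perturb applies, logs and reproduces anomalies deterministically", {
  cfg <- sim_config(n_per_category = c(a = 15, b = 10, c = 2, other = 3))
  co <- generate_cohort(cfg, seed = 31)
  noise <- list(p_drop_pathology = 0.5, p_drop_boundary_sessions = 0.3,
                p_shift_surgery = 0.2)
  p1 <- perturb(co$records, noise, seed = 4)
  p2 <- perturb(co$records, noise, seed = 4)
  expect_identical(p1$records, p2$records)
  expect_identical(p1$log, p2$log)
  expect_gt(nrow(p1$log), 0)
  # zero-probability noise is the identity
  p0 <- perturb(co$records, list(), seed = 4)
  expect_equal(nrow(p0$log), 0)
  expect_equal(nrow(p0$records), nrow(co$records))
})

test_that("every dissimilar pair in a noisy run is attributable to the log", {
  cfg <- sim_config(
    n_per_category = c(a = 30, b = 20, c = 4, other = 8),
    noise = list(p_drop_pathology = 0.3, p_drop_boundary_sessions = 0.3,
                 p_shift_surgery = 0.2)
  )
  res <- run_validation_experiment(cfg, seed = 23)
  dis <- unique(c(
    res$simple$pairs$patient_id[res$simple$pairs$led > 0],
    res$extended$pairs$patient_id[res$extended$pairs$led > 0]
  ))
  expect_true(all(dis %in% res$perturbations$patient_id))
})

test_that("boundary session drops shift the extended form by the dropped days", {
  # construct a patient whose radiotherapy loses its last k sessions
  set.seed(3)
  g <- generate_patient("px", "ADR", sim_config())
  rt_rows <- which(!is.na(g$records$reason_icd10) &
                     g$records$reason_icd10 == "Z510")
  rt_dates <- sort(g$records$event_date[rt_rows])
  k <- 3
  cut <- utils::tail(rt_dates, k)
  pruned <- g$records[!(seq_len(nrow(g$records)) %in%
                          rt_rows[g$records$event_date[rt_rows] %in% cut]), ]
  st <- aggregate_states(extract_events(pruned))
  truth_ext <- extended_form(g$truth)
  got_ext <- extended_form(st)
  # the state ends earlier by the span between old and new last session
  shrink <- as.integer(max(rt_dates) - max(setdiff(rt_dates, cut)))
  expect_equal(nchar(truth_ext) - nchar(got_ext), shrink)
  expect_equal(as.numeric(levenshtein(truth_ext, got_ext)), shrink)
})

test_that("mid-state session drops leave the aggregated states unchanged", {
  cfg <- sim_config(n_per_category = c(a = 10, b = 10, c = 2, other = 0),
                    noise = list(p_drop_mid_sessions = 1))
  res <- run_validation_experiment(cfg, seed = 29)
  expect_gt(nrow(res$perturbations), 0)
  expect_true(all(res$extended$pairs$led == 0))
})

test_that("pathology-drop dissimilarity count is binomial in the drop rate", {
  p <- 0.15
  n <- 300
  mix <- round(n * c(a = 81, b = 54, c = 8, other = 16) / 159)
  cfg <- sim_config(n_per_category = mix, noise = list(p_drop_pathology = p))
  res <- run_validation_experiment(cfg, seed = 41)
  n_eff <- nrow(res$simple$pairs)
  dis <- res$simple$summary$n_dissimilar
  expect_equal(dis, sum(res$perturbations$kind == "drop_pathology"))
  expect_lt(abs(dis - n_eff * p), 3 * sqrt(n_eff * p * (1 - p)))
})
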