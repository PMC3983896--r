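test_that("surgery between chemo sessions splits them; pre-surgery chemo is neoadjuvant", {
  ev <- mk_events(c("CHEMO", "TUM_REMOVAL", "CHEMO"), c(0, 10, 20),
                  with_pathology = c(FALSE, TRUE, FALSE))
  st <- aggregate_states(ev)
  expect_equal(st$code, c("N", "D", "K"))
  expect_equal(as.integer(st$start - as.Date("2008-01-01")), c(0, 10, 20))
  expect_equal(st$start, st$end)
})

test_that("chemo sessions beyond the six-month threshold form distinct episodes", {
  st <- aggregate_states(mk_events(c("CHEMO", "CHEMO"), c(0, 200)))
  expect_equal(st$code, c("K", "K"))
  expect_equal(as.integer(st$end - st$start), c(0, 0))
  # strictly-below comparison: a 183-day gap splits, 182 aggregates
  expect_equal(nrow(aggregate_states(mk_events(c("CHEMO", "CHEMO"), c(0, 183)))), 2)
  expect_equal(nrow(aggregate_states(mk_events(c("CHEMO", "CHEMO"), c(0, 182)))), 1)
})

test_that("radiotherapy sessions within a month aggregate into one dated state", {
  st <- aggregate_states(mk_events(rep("RADIO", 4), c(0, 2, 4, 25)))
  expect_equal(st$code, "R")
  expect_equal(as.integer(st$end - st$start), 25)
  expect_equal(st$n_events, 4L)
})

test_that("empty input and error cases", {
  empty <- tibble::tibble(patient_id = character(), date = as.Date(character()),
                          event_type = character())
  expect_equal(nrow(aggregate_states(empty)), 0)
  unordered <- mk_events(c("CHEMO", "CHEMO"), c(10, 0))
  expect_error(aggregate_states(unordered), "ordered")
  dup_day <- mk_events(c("CHEMO", "RADIO"), c(5, 5))
  expect_error(aggregate_states(dup_day), "ordered")
  unknown <- mk_events("SURGERY", 0)
  expect_error(aggregate_states(unknown), "Unknown event type")
})

test_that("pathology co-occurring with surgery makes D; absent pathology leaves C", {
  with_path <- mk_events("TUM_LN_REMOVAL", 0, with_pathology = TRUE)
  expect_equal(aggregate_states(with_path)$code, "D")
  without <- mk_events("TUM_LN_REMOVAL", 0)
  expect_equal(aggregate_states(without)$code, "C")
})

test_that("a trailing pathology event merges into surgery only within the window", {
  ev <- mk_events(c("TUM_REMOVAL", "PATH_SURGICAL"), c(0, 3))
  # default window 0: separate A state after the surgery
  expect_equal(aggregate_states(ev)$code, c("C", "A"))
  # widened window: absorbed into D without extending the state dates
  th <- thresholds(ap_merge_window_days = 5)
  st <- aggregate_states(ev, th)
  expect_equal(st$code, "D")
  expect_equal(st$start, st$end)
  expect_equal(st$n_events, 2L)
})

test_that("neoadjuvant relabelling needs a later surgery", {
  # chemo with no surgery at all stays K
  st <- aggregate_states(mk_events(c("PATH_BIOPSY", "CHEMO", "CHEMO"),
                                   c(0, 20, 41)))
  expect_equal(st$code, c("A", "K"))
  # every chemo state before the first surgery is relabelled
  ev <- mk_events(c("CHEMO", "CHEMO", "TUM_REMOVAL"), c(0, 200, 240),
                  with_pathology = c(FALSE, FALSE, TRUE))
  expect_equal(aggregate_states(ev)$code, c("N", "N", "D"))
})

test_that("concomitant chemo-radio days anchor O states", {
  # plain chemo before and after a concomitant run stays K (K O K pattern)
  ev <- mk_events(
    c("CHEMO", "CHEMO", "CHEMO_RADIO", "RADIO", "CHEMO_RADIO", "CHEMO"),
    c(0, 21, 45, 50, 55, 70)
  )
  st <- aggregate_states(ev)
  # no surgery in this stream, so the leading chemo stays K
  expect_equal(st$code, c("K", "O", "K"))
  ev2 <- mk_events(c("CHEMO_RADIO"), 0)
  expect_equal(aggregate_states(ev2)$code, "O")
  # interleaved plain days inside the span are absorbed, O dated by
  # first..last concomitant day
  st3 <- aggregate_states(mk_events(
    c("CHEMO_RADIO", "RADIO", "RADIO", "CHEMO_RADIO"), c(0, 1, 2, 7)
  ))
  expect_equal(st3$code, "O")
  expect_equal(as.integer(st3$end - st3$start), 7)
  expect_equal(st3$n_events, 4L)
})

test_that("a chain break beyond the concomitant threshold splits O states", {
  ev <- mk_events(c("CHEMO_RADIO", "CHEMO_RADIO"), c(0, 40))
  expect_equal(aggregate_states(ev)$code, c("O", "O"))
})

test_that("trajectory endpoint is the end of the last state", {
  st <- mk_states(c("A", "D", "R"),
                  c("2008-01-01", "2008-01-10", "2008-02-10"),
                  c("2008-01-01", "2008-01-10", "2008-03-12"))
  expect_equal(trajectory_endpoint(st), as.Date("2008-03-12"))
  expect_error(trajectory_endpoint(st[0, ]), "empty")
  # randomized order: max-scan oracle
  set.seed(1)
  for (i in 1:20) {
    starts <- as.Date("2008-01-01") + sort(sample(0:400, 5)) * 2
    ends <- starts + sample(0:10, 5, replace = TRUE)
    s <- tibble::tibble(patient_id = "p", code = "K", start = starts, end = ends)
    expect_equal(trajectory_endpoint(s), max(ends))
  }
})

test_that("aggregation matches the independent breakpoint oracle on random streams", {
  th <- thresholds()
  for (i in 1:150) {
    ev <- random_stream(sample(1:30, 1), seed = 5000 + i)
    got <- aggregate_states(ev, th)
    want <- oracle_aggregate(ev, th)
    expect_equal(got$code, want$code, info = paste("seed", 5000 + i))
    expect_equal(got$start, want$start, info = paste("seed", 5000 + i))
    expect_equal(got$end, want$end, info = paste("seed", 5000 + i))
    expect_equal(got$n_events, want$n_events, info = paste("seed", 5000 + i))
  }
})

test_that("aggregation matches the exhaustive segmentation oracle on short streams", {
  th <- thresholds()
  for (i in 1:60) {
    ev <- random_stream(sample(1:8, 1), seed = 9000 + i)
    got <- aggregate_states(ev, th)
    want <- exhaustive_aggregate(ev, th)
    expect_equal(got$code, want$code, info = paste("seed", 9000 + i))
    expect_equal(got$start, want$start, info = paste("seed", 9000 + i))
    expect_equal(got$end, want$end, info = paste("seed", 9000 + i))
  }
})

test_that("every event is attributed to exactly one state (conservation)", {
  for (i in 1:40) {
    ev <- random_stream(sample(1:30, 1), seed = 300 + i)
    st <- aggregate_states(ev)
    expect_equal(sum(st$n_events), nrow(ev))
    expect_equal(sort(as.Date(unlist(lapply(st$dates, as.character)))), ev$date)
  }
})

test_that("episode separation holds between consecutive same-code states", {
  th <- thresholds()
  fam_thr <- c(A = th$gap_path_days, C = th$gap_surgery_days, D = th$gap_surgery_days,
               N = th$gap_chemo_days, K = th$gap_chemo_days, R = th$gap_radio_days,
               O = min(th$gap_chemo_days, th$gap_radio_days))
  for (i in 1:40) {
    ev <- random_stream(sample(2:30, 1), seed = 700 + i)
    st <- aggregate_states(ev, th)
    if (nrow(st) < 2) next
    for (k in 2:nrow(st)) {
      if (st$code[k] == st$code[k - 1]) {
        gap <- as.integer(st$start[k] - st$end[k - 1])
        # either the gap exceeds the family threshold or an event of a
        # different family lies between the two states
        intervening <- any(ev$date > st$end[k - 1] & ev$date < st$start[k])
        expect_true(gap >= fam_thr[[st$code[k]]] || intervening)
      }
    }
  }
})

test_that("re-aggregating the single-event expansion of states is idempotent", {
  expand <- function(st) {
    rep_type <- c(A = "PATH_BIOPSY", C = "TUM_REMOVAL", D = "TUM_REMOVAL",
                  N = "CHEMO", K = "CHEMO", R = "RADIO", O = "CHEMO_RADIO")
    purrr::map_dfr(seq_len(nrow(st)), function(k) {
      dates <- sort(unique(st$dates[[k]]))
      tibble::tibble(
        patient_id = st$patient_id[k], date = dates,
        event_type = rep_type[[st$code[k]]],
        with_pathology = st$code[k] == "D" & dates == dates[1]
      )
    }) |> dplyr::arrange(date)
  }
  for (i in 1:40) {
    ev <- random_stream(sample(1:25, 1), seed = 1300 + i)
    st <- aggregate_states(ev)
    st2 <- aggregate_states(expand(st))
    expect_equal(st2$code, st$code, info = paste("seed", 1300 + i))
    expect_equal(st2$start, st$start)
    expect_equal(st2$end, st$end)
  }
})

test_that("raising a family threshold never increases that family's state count", {
  n_states <- function(ev, th) nrow(aggregate_states(ev, th))
  set.seed(11)
  for (i in 1:20) {
    n <- sample(3:20, 1)
    days <- sort(sample(0:600, n))
    chemo <- mk_events(rep("CHEMO", n), days)
    radio <- mk_events(rep("RADIO", n), days)
    path <- mk_events(rep("PATH_BIOPSY", n), days)
    expect_gte(n_states(chemo, thresholds(gap_chemo_days = 90)),
               n_states(chemo, thresholds(gap_chemo_days = 183)))
    expect_gte(n_states(radio, thresholds(gap_radio_days = 31)),
               n_states(radio, thresholds(gap_radio_days = 120)))
    expect_gte(n_states(path, thresholds(gap_path_days = 30)),
               n_states(path, thresholds(gap_path_days = 92)))
  }
})
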