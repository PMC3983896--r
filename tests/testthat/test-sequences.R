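fig_states <- function() {
  mk_states(c("A", "D", "R"),
            c("2008-01-01", "2008-01-10", "2008-02-01"),
            c("2008-01-01", "2008-01-10", "2008-02-05"))
}

test_that("simple form lists state codes in order", {
  expect_equal(simple_form(fig_states()), "ADR")
  expect_equal(simple_form(fig_states()[0, ]), "")
  st <- mk_states(c("A", "N", "D", "R"),
                  c("2008-01-01", "2008-01-15", "2008-04-01", "2008-05-10"))
  expect_equal(simple_form(st), "ANDR")
})

test_that("extended form repeats codes by duration and fills gaps with I", {
  ext <- extended_form(fig_states())
  expect_equal(ext, paste0("A", strrep("I", 8), "D", strrep("I", 21),
                           strrep("R", 5)))
  expect_equal(nchar(ext), 36)  # calendar span of the trajectory
  # single one-day state
  expect_equal(extended_form(mk_states("A", "2008-01-01")), "A")
  # adjacent states produce no I
  adj <- mk_states(c("A", "D"), c("2008-01-01", "2008-01-02"))
  expect_equal(extended_form(adj), "AD")
  # overlap is an error
  bad <- mk_states(c("K", "R"), c("2008-01-01", "2008-01-05"),
                   c("2008-01-10", "2008-01-06"))
  expect_error(extended_form(bad), "overlap")
})

test_that("length conservation and collapse property hold on random cohorts", {
  cfg <- sim_config(n_per_category = c(a = 10, b = 8, c = 2, other = 5))
  co <- generate_cohort(cfg, seed = 21)
  seqs <- co$truth_sequences
  st_by <- split(co$truth, co$truth$patient_id)
  for (i in seq_len(nrow(seqs))) {
    span <- as.integer(seqs$end[i] - seqs$origin[i]) + 1L
    expect_equal(nchar(seqs$extended[i]), span)
    expect_equal(nchar(seqs$simple[i]), nrow(st_by[[seqs$patient_id[i]]]))
    # deleting I and collapsing runs reproduces the code order of simple
    collapsed <- gsub("(.)\\1+", "\\1", gsub("I", "", seqs$extended[i]))
    simple_runs <- gsub("(.)\\1+", "\\1", seqs$simple[i])
    expect_equal(collapsed, simple_runs)
  }
})

test_that("SPELL round trip is the identity on codes and dates", {
  st <- fig_states()
  expect_equal(nrow(to_spell(st)), 3)
  back <- from_spell(to_spell(st))
  expect_equal(back[, c("patient_id", "code", "start", "end")],
               st[, c("patient_id", "code", "start", "end")])
  # unordered rows come back ordered
  rows <- to_spell(st)[c(3, 1, 2), ]
  expect_equal(from_spell(rows)$code, c("A", "D", "R"))
  expect_error(from_spell(dplyr::mutate(rows, state = "Z")), "Unknown state")
  # random cohort round trip
  co <- generate_cohort(sim_config(n_per_category = c(a = 6, b = 6, c = 1,
                                                      other = 3)), seed = 9)
  st2 <- co$truth
  back2 <- from_spell(to_spell(st2))
  orig <- dplyr::arrange(st2, patient_id, start)
  expect_equal(back2[, c("patient_id", "code", "start", "end")],
               orig[, c("patient_id", "code", "start", "end")])
})

test_that("delay_days reads time-lapses off the extended string", {
  expect_equal(delay_days("DIIIIR", "D", "R"), 5L)
  expect_equal(delay_days("ADR", "D", "R"), 1L)
  expect_equal(delay_days("ADR", "D", "R", anchors = "start_to_start"), 1L)
  expect_equal(delay_days("DDDIIRR", "D", "R", anchors = "start_to_start"), 5L)
  expect_true(is.na(delay_days("AD", "D", "R")))
  expect_error(delay_days("ADR", "D", "Z"), "state codes")
  # the delay after the LAST source state run is measured
  expect_equal(delay_days("KIIRIKIR", "K", "R"), 2L)
})

test_that("string delays equal date arithmetic on the states", {
  co <- generate_cohort(sim_config(n_per_category = c(a = 10, b = 10, c = 3,
                                                      other = 0)), seed = 33)
  seqs <- co$truth_sequences
  st_by <- split(co$truth, co$truth$patient_id)
  for (i in seq_len(nrow(seqs))) {
    st <- st_by[[seqs$patient_id[i]]]
    d_str <- delay_days(seqs$extended[i], "D", "R")
    d_last <- max(which(st$code == "D"), -Inf)
    if (is.finite(d_last)) {
      r_after <- which(st$code == "R" & seq_len(nrow(st)) > d_last)
      d_date <- if (length(r_after) > 0) {
        as.integer(st$start[r_after[1]] - st$end[d_last])
      } else NA_integer_
      expect_equal(d_str, d_date, info = seqs$patient_id[i])
    } else {
      expect_true(is.na(d_str))
    }
  }
})

test_that("guideline flags follow the recommended delay bounds", {
  ext <- function(st) extended_form(st)
  # surgery then radio at 80 days, no chemo: within 12 weeks
  s80 <- mk_states(c("D", "R"), c("2008-01-01", "2008-03-21"))
  f <- guideline_flags(ext(s80))
  expect_true(f$rt_within_12w_post_surgery)
  expect_true(is.na(f$rt_within_5w_post_chemo))
  # 90 days exceeds the 84-day bound
  s90 <- mk_states(c("D", "R"), c("2008-01-01", "2008-03-31"))
  expect_false(guideline_flags(ext(s90))$rt_within_12w_post_surgery)
  # chemo between surgery and radio switches to the post-chemo bounds
  skr <- mk_states(c("D", "K", "R"),
                   c("2008-01-01", "2008-01-29", "2008-05-01"),
                   c("2008-01-01", "2008-04-11", "2008-05-20"))
  f2 <- guideline_flags(ext(skr))
  expect_true(is.na(f2$rt_within_12w_post_surgery))
  expect_true(f2$rt_within_5w_post_chemo)       # 20 days after chemo end
  expect_true(f2$rt_within_6m_post_surgery)     # 121 days after surgery
  expect_true(f2$chemo_start_3_to_6w_post_surgery)  # 28 days
  # no radiotherapy: flags absent
  f3 <- guideline_flags(ext(mk_states("D", "2008-01-01")))
  expect_true(all(is.na(unlist(f3))))
})

test_that("care_sequences covers requested patients with empty sequences", {
  st <- fig_states()
  seqs <- care_sequences(st, patients = c("p1", "p2"))
  expect_equal(seqs$simple, c("ADR", ""))
  expect_equal(seqs$extended[2], "")
  expect_true(is.na(seqs$origin[2]))
})
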