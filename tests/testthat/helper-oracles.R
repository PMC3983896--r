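# Independent oracles and generators used across the test files.

# --- brute-force recursive edit distance (memoized on prefix lengths) -------
# Deliberately written as a plain recursion over string prefixes, not as the
# iterative dynamic program of the implementation.
led_oracle <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (i == 0) return(j)
    if (j == 0) return(i)
    key <- paste(i, j)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    res <- min(
      rec(i - 1, j) + 1,
      rec(i, j - 1) + 1,
      rec(i - 1, j - 1) + (ca[i] != cb[j])
    )
    memo[[key]] <- res
    res
  }
  rec(length(ca), length(cb))
}

# --- random tracer-event streams --------------------------------------------
# Mix of short, medium and long inter-event gaps so that all aggregation
# thresholds get exercised.
random_stream <- function(n, seed) {
  set.seed(seed)
  types <- sample(
    c("PATH_BIOPSY", "PATH_SURGICAL", "TUM_REMOVAL", "LN_REMOVAL",
      "TUM_LN_REMOVAL", "CHEMO", "RADIO", "CHEMO_RADIO"),
    n, replace = TRUE,
    prob = c(0.1, 0.1, 0.08, 0.04, 0.08, 0.25, 0.25, 0.1)
  )
  gaps <- sample(c(1:6, 20:40, 85:100, 180:200), n - 1, replace = TRUE,
                 prob = c(rep(6, 6), rep(1, 21), rep(0.6, 16), rep(0.4, 21)))
  dates <- as.Date("2008-01-01") + cumsum(c(0L, as.integer(gaps)))
  tibble::tibble(
    patient_id = "px",
    date = dates,
    event_type = types,
    with_pathology = ifelse(startsWith(types, "TUM") | startsWith(types, "LN"),
                            stats::runif(n) < 0.3, FALSE)
  )
}

# --- independent breakpoint aggregation oracle ------------------------------
# Vectorised restatement of the aggregation rules: mark concomitant periods,
# then break between consecutive events on family change or threshold
# overrun, then relabel surgery-with-pathology and neoadjuvant states.
# Assumes ap_merge_window_days = 0 (the default).
oracle_families <- function(ev, th) {
  fam <- c(PATH_BIOPSY = "A", PATH_SURGICAL = "A", TUM_REMOVAL = "C",
           LN_REMOVAL = "C", TUM_LN_REMOVAL = "C", CHEMO = "K",
           RADIO = "R", CHEMO_RADIO = "O")[ev$event_type]
  n <- nrow(ev)
  if (n == 1) return(unname(fam))
  thr_o <- min(th$gap_chemo_days, th$gap_radio_days)
  ther <- fam %in% c("K", "R", "O")
  gaps <- as.integer(diff(ev$date))
  link <- ther[-n] & ther[-1] & gaps < thr_o
  seg <- cumsum(c(TRUE, !link))
  for (s in unique(seg[ther])) {
    idx <- which(seg == s)
    if (!all(ther[idx])) next
    f <- fam[idx]
    if (any(f == "O")) {
      span <- range(which(f == "O"))
      fam[idx[span[1]:span[2]]] <- "O"
    }
  }
  unname(fam)
}

oracle_aggregate <- function(ev, th = caretraj::thresholds()) {
  stopifnot(th$ap_merge_window_days == 0)
  n <- nrow(ev)
  fam <- oracle_families(ev, th)
  thr <- c(A = th$gap_path_days, C = th$gap_surgery_days,
           K = th$gap_chemo_days, R = th$gap_radio_days,
           O = min(th$gap_chemo_days, th$gap_radio_days))
  if (n == 1) {
    brk <- logical(0)
  } else {
    gaps <- as.integer(diff(ev$date))
    brk <- fam[-n] != fam[-1] | gaps >= thr[fam[-n]]
  }
  block <- cumsum(c(1L, as.integer(brk)))
  out <- lapply(unique(block), function(b) {
    idx <- which(block == b)
    code <- fam[idx[1]]
    if (code == "C" && any(ev$with_pathology[idx])) code <- "D"
    data.frame(code = code, start = min(ev$date[idx]), end = max(ev$date[idx]),
               n_events = length(idx))
  })
  out <- do.call(rbind, out)
  first_surg <- match(TRUE, out$code %in% c("C", "D"))
  if (!is.na(first_surg) && first_surg > 1) {
    pre <- seq_len(first_surg - 1)
    out$code[pre][out$code[pre] == "K"] <- "N"
  }
  tibble::as_tibble(out)
}

# --- exhaustive segmentation oracle (small n) -------------------------------
# Enumerates every contiguous partition of the event stream, keeps the
# partitions whose blocks are all rule-valid states and that are maximal (no
# contiguous run of adjacent blocks merges into one valid block), asserts the
# survivor is unique, and returns it.  Assumes ap_merge_window_days = 0.
exhaustive_aggregate <- function(ev, th = caretraj::thresholds()) {
  stopifnot(th$ap_merge_window_days == 0)
  n <- nrow(ev)
  fam <- c(PATH_BIOPSY = "A", PATH_SURGICAL = "A", TUM_REMOVAL = "C",
           LN_REMOVAL = "C", TUM_LN_REMOVAL = "C", CHEMO = "K",
           RADIO = "R", CHEMO_RADIO = "O")[ev$event_type]
  thr <- c(A = th$gap_path_days, C = th$gap_surgery_days,
           K = th$gap_chemo_days, R = th$gap_radio_days)
  thr_o <- min(th$gap_chemo_days, th$gap_radio_days)

  valid_block <- function(idx) {
    f <- fam[idx]
    g <- if (length(idx) > 1) as.integer(diff(ev$date[idx])) else integer(0)
    if (length(unique(f)) == 1 && f[1] != "O") {
      return(all(g < thr[f[1]]))
    }
    # concomitant block: all therapy, tight gaps, anchored on same-day
    # co-administration days at both ends
    if (!all(f %in% c("K", "R", "O"))) return(FALSE)
    if (!all(g < thr_o)) return(FALSE)
    any(f == "O") && f[1] == "O" && f[length(f)] == "O"
  }

  partitions <- function(n) {
    if (n == 1) return(list(list(1:1)))
    out <- list()
    for (mask in 0:(2^(n - 1) - 1)) {
      cuts <- which(bitwAnd(mask, 2^(0:(n - 2))) > 0)
      bounds <- c(0, cuts, n)
      out[[length(out) + 1L]] <-
        lapply(seq_len(length(bounds) - 1),
               function(k) (bounds[k] + 1):bounds[k + 1])
    }
    out
  }

  good <- list()
  for (p in partitions(n)) {
    if (!all(vapply(p, valid_block, logical(1)))) next
    # maximality: no contiguous run of >= 2 blocks merges into a valid block
    maximal <- TRUE
    nb <- length(p)
    for (i in seq_len(nb)) {
      for (j in seq_len(nb)) {
        if (j <= i) next
        if (valid_block(unlist(p[i:j]))) {
          maximal <- FALSE
          break
        }
      }
      if (!maximal) break
    }
    if (maximal) good[[length(good) + 1L]] <- p
  }
  if (length(good) != 1) {
    stop("exhaustive oracle: expected a unique maximal segmentation, found ",
         length(good))
  }
  p <- good[[1]]
  out <- lapply(p, function(idx) {
    code <- fam[idx[1]]
    f <- fam[idx]
    if (any(f == "O") || (length(unique(f)) > 1)) code <- "O"
    if (code == "C" && any(ev$with_pathology[idx])) code <- "D"
    data.frame(code = code, start = min(ev$date[idx]), end = max(ev$date[idx]),
               n_events = length(idx))
  })
  out <- do.call(rbind, out)
  first_surg <- match(TRUE, out$code %in% c("C", "D"))
  if (!is.na(first_surg) && first_surg > 1) {
    pre <- seq_len(first_surg - 1)
    out$code[pre][out$code[pre] == "K"] <- "N"
  }
  tibble::as_tibble(out)
}

# --- small builders ---------------------------------------------------------
mk_states <- function(codes, starts, ends = starts, pid = "p1") {
  tibble::tibble(
    patient_id = pid, code = codes,
    start = as.Date(starts), end = as.Date(ends)
  )
}

mk_events <- function(types, days, pid = "p1", origin = as.Date("2008-01-01"),
                      with_pathology = FALSE) {
  tibble::tibble(
    patient_id = pid,
    date = origin + days,
    event_type = types,
    with_pathology = rep_len(with_pathology, length(types))
  )
}

mk_hd <- function(pid, date, reason = NA, linked = NA, ccam = NA, fac = "H1") {
  tibble::tibble(
    patient_id = pid, source = "HD", event_date = as.character(date),
    reason_icd10 = reason, linked_icd10 = linked, ccam_code = ccam,
    adicap_code = NA_character_, facility_id = fac
  )
}

mk_ap <- function(pid, date, adicap, fac = "L1") {
  tibble::tibble(
    patient_id = pid, source = "AP", event_date = as.character(date),
    reason_icd10 = NA_character_, linked_icd10 = NA_character_,
    ccam_code = NA_character_, adicap_code = adicap, facility_id = fac
  )
}
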