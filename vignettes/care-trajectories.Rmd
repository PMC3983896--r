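---
title: "Reconstructing cancer care trajectories from coded registry data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing cancer care trajectories from coded registry data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(caretraj)
library(dplyr)
```

## The problem

Population cancer registries hold coded traces of every contact a patient
has with the care system: hospital-discharge (HD) rows carrying ICD-10
diagnoses and CCAM procedure codes, and anatomical-pathology (AP) rows
carrying ADICAP lesion codes.  None of these sources records a *care
trajectory* — the ordered, dated itinerary from diagnosis through surgery
and adjuvant therapy — yet waiting-time indicators and guideline-compliance
audits need exactly that.  `caretraj` reconstructs trajectories from the
coded streams alone, in four steps:

1. **Tracer events.**  Each coded row is classified into an instantaneous,
   dated event: chemotherapy (`Z511` linked to a `C50*` breast-cancer
   code), radiotherapy (`Z510` linked to `C50*`), a surgical act (a CCAM
   code linked to `C50*`, with the removal type read from the 3rd, action,
   character), or a pathology sampling (ADICAP 1st character = sampling
   mode, characters 3–4 = organ).  The calendar day is the smallest
   measurable interval; when several events fall on one patient-day only
   the highest-ranked is kept (surgical removal > chemo/radiotherapy >
   pathology sampling).

2. **States.**  Runs of same-family events aggregate into interval states
   when consecutive gaps stay strictly below the family threshold and no
   event of another family intervenes.  The state alphabet is `A`
   (pathology), `C` (surgery), `D` (surgery with pathology), `N`
   (neoadjuvant chemotherapy), `K` (chemotherapy), `R` (radiotherapy), `O`
   (concomitant chemo-radiotherapy).

3. **Sequences.**  The state list is rendered as a *simple* form (one
   character per state, e.g. `"ADKR"`) and an *extended* form (one
   character per calendar day, event-free periods coded `I`), stored
   vertically in SPELL format.  Because one character is one day,
   waiting times are regular-expression arithmetic on the string.

4. **Validation.**  Reconstructed sequences are confronted with reference
   sequences using the unit-cost (generalised) Levenshtein edit distance;
   a pair *matches at tolerance t* when the distance is at most *t*.

## Aggregation rules and their parameters

The thresholds translate clinical conventions into fixed day counts:

| family       | threshold | default |
|--------------|-----------|---------|
| pathology    | 3 months  | 92 days |
| surgery      | 3 months  | 92 days |
| chemotherapy | 6 months  | 183 days |
| radiotherapy | 1 month   | 31 days |

Months are fixed day counts rather than calendar arithmetic: the sources
are day-granular and fixed counts make runs reproducible across calendar
contexts.  The comparison is strict — two chemotherapy administrations
182 days apart aggregate, 183 days apart split into two care episodes.
All four values are tunable through `thresholds()`.

Three relabelling rules need care because they cannot be expressed as
simple run-aggregation:

**Surgery with pathology (`D`).**  The per-day hierarchy discards a
pathology event that co-occurs with a surgical act (typically the
extemporaneous examination of the surgical piece).  The resolved event
therefore carries a `with_pathology` flag, and a surgery state containing
at least one flagged day becomes `D`.  A standalone pathology event
*after* the surgery state is absorbed only within `ap_merge_window_days`
of the state end (default 0).  With the default window, a pathology
report dated days after surgery forms its own `A` state, so a missing or
late-dated report shows up as `…CA…` or `…C…` instead of `…D…` — the
discrepancy signature this representation is designed to surface.
`D` states are dated by the surgical acts only.

**Neoadjuvant chemotherapy (`N`).**  Every chemotherapy state lying
entirely before the patient's first surgical (`C`/`D`) state is
relabelled `N`.  A patient with chemotherapy and no surgery at all keeps
`K`: "neoadjuvant" is only defined relative to a surgery.

**Concomitant chemo-radiotherapy (`O`).**  A day on which both a
chemotherapy and a radiotherapy code are recorded resolves to a single
concomitant event (the coding pattern of HER2-targeted therapy
administered at radiotherapy visits).  A maximal chain of such days —
every inter-event gap strictly below the smaller of the chemo and radio
thresholds, with only therapy events in between — forms one `O` state
spanning its first to its last concomitant day; plain chemo or radio
days falling inside that span are absorbed into it.  Plain therapy days
*before* the first or *after* the last concomitant day stay in their own
family, which is what makes sequences such as `ADKOK` (adjuvant
chemotherapy, then targeted therapy concomitant with irradiation, then
continued targeted therapy) representable.  We deliberately do **not**
promote a day-level alternation of plain chemotherapy and radiotherapy
(without any same-day co-administration) to `O`: any such rule makes the
segmentation ambiguous — a stream `K R K R R` admits several maximal
rule-consistent segmentations — and conflicts with the interruption rule
that an intervening event of another family blocks aggregation.  Pure
alternation therefore yields interleaved singleton `K` and `R` states,
which is the faithful reading of the aggregation rules.

**Same-day chemo + radio from distinct records.**  The record layout
carries one code pair per row, so concomitance "in one and the same
report" and two same-day reports are indistinguishable after loading;
both collapse to one concomitant event by default
(`code_config(collapse_chemo_radio = FALSE)` turns this off, in which
case the day resolves to chemotherapy).

The shipped CCAM action map (`F`/`E`/`J` → combined removal / tumour
removal / node removal) and ADICAP sampling map (`O`,`P` → surgical
piece; `B`,`C` → biopsy) cover the characters exercised by the breast
application and are **placeholders** for the full nomenclature tables;
deployments on real extracts should override them via `code_config()`.
Unmapped characters never abort a run — they are counted and reported by
`anomalies()`, mirroring how real registry coding anomalies are handled.

## Sequence forms, waiting times, guideline flags

A point event is one day, so a state's extended contribution is
`end − start + 1` characters and a gap contributes
`next start − previous end − 1` `I` characters: the extended length always
equals the trajectory span in days.  Sequences are anchored at each
patient's own first state; cross-patient calendar alignment is out of
scope.

`delay_days()` reads a waiting time off the extended string as the
distance between the last run of one state code and the first run of
another after it — identical, by construction, to date arithmetic on the
states (a property the test suite verifies on generated cohorts).
`guideline_flags()` evaluates the standard timing recommendations with
7-day weeks and the same month conventions as the thresholds:
radiotherapy within 84 days of surgery when no chemotherapy intervenes;
otherwise within 35 days of chemotherapy end and 183 days of surgery;
adjuvant chemotherapy starting 21–42 days after surgery.

## Standard-sequence classification

Three anchored patterns, evaluated in order, encode the standard
non-metastatic breast-cancer pathways: good prognosis `^A?DR?$`, poor
prognosis `^A?DK(R|OK)$`, neoadjuvant `^A?NDR$`; everything else is
`other`.  Applied to the published 159-patient inventory shipped as
`observed_breast_cohort()`, the default rules reproduce its category
totals exactly:

```{r}
glance(tabulate_sequences(observed_breast_cohort()))
```

The patterns are configuration, not code (`category_rules()`), so the
taxonomy can be rebuilt for other cancer sites.

## The synthetic cohort generator

Registry extracts are confidential, so the package ships a generator
that emulates the two record streams with analytically known ground
truth.  Its defaults are the study conditions of the published
evaluation:

* cohort composition: the 17 observed archetype sequences at their
  published frequencies (81 good-prognosis, 54 poor-prognosis, 8
  neoadjuvant, 16 non-standard out of 159);
* chemotherapy in 4–6 administrations 21 days apart (neoadjuvant
  likewise);
* radiotherapy in 25 weekday fractions, hence a span of about 33 days;
* surgery → adjuvant chemotherapy 21–42 days; chemotherapy end →
  radiotherapy 7–35 days;
* delays the guidelines do not pin down were fixed once at clinically
  plausible ranges: biopsy → surgery 14–35 days, biopsy → neoadjuvant
  chemotherapy 7–21 days, surgery → radiotherapy (no chemotherapy) 21–84
  days, concomitant period → continued therapy 7–21 days, radiotherapy →
  late chemotherapy 30–90 days, late secondary surgery 120–180 days
  after chemotherapy, and diagnosis dates uniform over 2008 (the
  published sample's diagnosis year);
* concomitant periods are emitted as radiotherapy fractions each
  accompanied by a same-day systemic-therapy code, the coding pattern of
  targeted therapy delivered at radiotherapy visits.

All draws flow from a master seed through deterministic per-patient
substreams, so cohorts are reproducible record-by-record and a patient's
records do not depend on cohort size or order.

Four noise modes emulate the coding anomalies observed in practice:
dropping a pathology report (the simple form loses an `A` or downgrades
`D` to `C`), dropping the first or last 1–3 session codes of a therapy
state (the extended form shifts by exactly the dropped boundary days;
large distances for chemotherapy, small for radiotherapy, because of the
session spacing), dropping a mid-state session (no effect on state
durations, by design of the aggregation), and shifting a surgery date by
one day (both the discharge and same-day pathology rows move, so the
simple form is preserved and the extended form changes minimally).

What the generator does *not* emulate: free-text pathology content,
relapse and metastatic episodes beyond the gap rule, multi-tumour
patients, facility-level coding idiosyncrasies, and record-linkage
errors.  Passing the end-to-end tests therefore demonstrates the
correctness of the representation algorithm under the coding model, not
the quality of any particular registry's source data.

## Numerical and testing choices

* Day arithmetic uses R's proleptic `Date` class throughout; dates are
  ISO 8601 in every file.
* The edit distance is computed by a dynamic program in C++ with
  configurable insertion/deletion/substitution costs (unit costs by
  default, matching the published choice).  Tests cross-check it against
  an independent C reference implementation on *all* string pairs up to
  length 8 over a 3-letter alphabet and against a brute-force recursive
  oracle on shorter and sampled longer pairs.
* The aggregation is verified against two independent oracles: a
  vectorised breakpoint restatement of the rules on 1,000 random streams
  of up to 30 events, and an exhaustive enumeration of every contiguous
  segmentation (validity and maximality filtered, uniqueness asserted)
  on streams of up to 9 events, where enumeration is tractable.
* End-to-end acceptance uses a 500-patient zero-noise cohort (must
  reconstruct with 100% match in both forms) and a 1,000-patient cohort
  with pathology-drop noise at rate 0.1 (the dissimilar count must be
  binomial within three standard deviations).  These sizes keep the full
  suite comfortably within a few minutes on a single core.
* Ties among identical same-day events return one representative; among
  same-day pathology events the surgical-piece examination outranks the
  biopsy.

## A worked example

```{r}
set.seed(42)
patient <- generate_patient("p001", "ANDR", sim_config())
events <- extract_events(patient$records)
states <- aggregate_states(events)
states[, c("code", "start", "end", "n_events")]
care_sequences(states)[, c("simple", "origin", "end")]
delay_days(care_sequences(states)$extended, "D", "R")
```

## Known limitations

* Trajectories are linear: therapies that overlap without a same-day
  co-administration code are represented as interleaved states, not as
  composite states.
* The default code maps are placeholders (see above); real deployments
  must supply the complete CCAM action and ADICAP sampling-mode tables.
* Extended-form comparison operates on the raw strings without
  re-anchoring; two identical trajectories shifted in calendar time
  compare as equal, which is intended, but a missing *first* state both
  shifts the anchor and changes the content, and the edit distance then
  reflects both effects.
* Guideline flags use fixed 7-day-week arithmetic; jurisdictions with
  different interval conventions should reinterpret the bounds.
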