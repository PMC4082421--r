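---
title: "Detecting the onset of invasive mechanical ventilation in ICU flowsheet data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting the onset of invasive mechanical ventilation in ICU flowsheet data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ventzero)
```

## The measurement problem

"Time zero" is the minute a critically ill patient is connected to a
ventilator after endotracheal intubation. Prospectively it is simply
observed; retrospectively it must be reconstructed from whatever the EMR
charted, and the candidate anchors disagree with each other:

* the **intubation procedure note** is written around, not at, the
  procedure — its timestamp is commonly tens of minutes off;
* **end-tidal CO₂**, though diagnostic of tube placement, is charted for
  only a small minority of ICU patients;
* **PIP** (peak inspiratory pressure) is specific to invasive
  ventilation and is what a human reviewer reads off the full chart, but
  institutional data marts frequently fail to capture it in queryable
  form;
* **PEEP** (positive end-expiratory pressure) downloads automatically and
  near-completely the moment the ventilator is connected — but is charted
  for noninvasive ventilation too.

The method implemented here therefore uses *PEEP in the queryable view*
as the search variable, *PIP in the full-record view* as the reference
standard, and a five-minute error budget: the downstream application is
risk-factor analysis in the hour before and after intubation, for which a
five-minute offset on either side is immaterial.

## Data model

All tables are tibbles on a one-minute timestamp grid (seconds must be
zero; every reported statistic is a whole minute). The flowsheet is long
format — `(patient_id, timestamp, parameter, value, view)` — with two
views of the same chart: `datamart`, the automatically populated
queryable extract the algorithm may use, and `full_record`, everything a
human reviewer can see. Stays and ventilation episodes are half-open
intervals `[start, end)`, so a record exactly at discharge belongs to the
next interval and boundary minutes are never double-counted. Missing
values are empty CSV fields; readers enforce every type invariant and
refuse (never drop) violating rows, naming the file line.

## The algorithm

1. **Filter** the cohort: first ICU admission, research authorization,
   age ≥ 18, and at least one ventilation episode overlapping the stay.
   Patients are counted under the first rule that excludes them, so the
   attrition table mirrors a study flow diagram.
2. **Flag in-ICU initiation.** Whether ventilation began inside the ICU
   is decided by the emergent-intubation flag carried in the event table
   (the output of an upstream note-text classifier, consumed here as an
   input, never recomputed). Only when that flag is absent does a
   fallback heuristic apply: a first ventilator record at least
   `pre_icu_gap_min` (default 60) minutes after admission indicates
   in-ICU onset; anything earlier indicates the patient arrived
   ventilated. The heuristic exists for flag-free data and is labelled as
   such in its output (`reason` field).
3. **Screen candidates** on the derivation cohort. Completeness is
   operationalized *per patient*: the fraction of cohort patients with at
   least one queryable record of the variable during the stay. Variables
   under the 0.85 threshold (the "<15% missing" rule) are excluded
   outright; survivors are scored by percent agreement of their
   first-record time with the reference within five minutes. The data
   could also support a per-record missingness definition; per-patient
   was chosen because the detection step needs only one usable record per
   patient, so patient-level availability is the operative quantity.
4. **Select the variable**: highest agreement wins; ties break by the
   fixed priority PEEP > PIP > note_time > ETCO₂. The priority is a
   documented convention — PEEP first, because completeness is the
   binding constraint in practice.
5. **Detect.** `first_in_stay` mode returns the earliest queryable record
   of the variable in `[icu_admit, icu_discharge)`. The default
   `note_anchored` mode restricts the search to the closed window
   `[note_time − 60, note_time + 60]` minutes. The window is this
   package's explicit resolution of an ambiguity in the method: a patient
   who failed a noninvasive-ventilation trial earlier in the stay has an
   earlier PEEP series that `first_in_stay` would wrongly return; the
   combination with the note (or, equivalently, with the emergent-intubation
   classifier that gates step 2) is what makes the first PEEP trustworthy
   as an intubation marker. When a patient has no note, detection falls
   back to `first_in_stay` and warns.
6. **Reference**: the earliest full-record PIP during the stay, per
   patient. Patients lacking a reference are counted and excluded from
   agreement, never silently dropped.

## Agreement statistics

For each evaluable patient the signed difference (algorithm − reference)
is an integer number of minutes. Percent agreement at tolerance *t* is
`100 · #{|Δ| ≤ t}/n`, computed exactly and reported rounded half away
from zero (87 for 72/83, 94 for 78/83, 92 for 65/71, 99 for 70/71). The
agreement curve evaluates the same quantity over the grid
{0, 1, 2, 3, 4, 5, 10, 15, 30, 60} minutes and is non-decreasing by
construction. A Bland–Altman plot is deliberately not offered: the
outcome is a time point, not a measured quantity with a meaningful
per-patient mean, so averaging the two raters' times makes no sense;
sensitivity/specificity are likewise not reported because no gold
standard exists — PIP is a reference standard adopted for this record
system, not ground truth.

κ is exposed in two conventions, because the convention is genuinely
ambiguous in clinical-agreement reporting:

* `zero_chance` (default): κ = (p₀ − pₑ)/(1 − pₑ) with pₑ = 0, i.e. κ
  equals observed agreement. When two raters place an event on a minute
  grid spanning two years of admissions, the marginal probability of a
  chance match is effectively nil, and reported κ values that equal the
  percent agreement are only reproducible under this convention.
* `minute_category`: the textbook Cohen computation treating each
  rater's per-patient minute as a nominal category, with pₑ summed over
  all category pairs within the tolerance from the two raters' marginal
  frequencies. It requires the paired times, and is provided for rigor;
  on realistic data it is numerically indistinguishable from
  `zero_chance` because pₑ is tiny, but on small toy tables it is
  strictly smaller.

Both conventions are tested against hand-computed tables; the identity
κ(zero_chance) ≡ p₀ is exercised property-style over random difference
multisets.

## The synthetic generator

No institutional EMR can ship with the package, so `simulate_cohort()`
generates cohorts exhibiting the charting pathology the method was built
around, with one RNG stream seeded from the config (the global RNG state
is untouched, and equal seeds give byte-identical output):

* ~82% of patients arrive already intubated (~80% of those from the
  operating room, the rest from the emergency department); their
  ventilation records begin before `icu_admit` and they have no
  procedure note.
* Datamart PEEP starts within 0–5 minutes of true onset (uniform lag),
  runs minute-dense for the first ten minutes — ventilators auto-download
  on connection — then every 30 minutes.
* PIP is always in the full record (0–2 minute lag, every 30 minutes)
  but survives into the datamart for only ~40% of patients; end-tidal
  CO₂ exists for ~15%.
* In-ICU note times sit *after* true onset by an offset whose magnitude
  is drawn as 40% in [1, 30], 20% in [31, 60] and 40% in [61, 65]
  minutes. Only the two exceedance proportions (>30 min: 60%, >60 min:
  40%) are documented properties of real notes; within the >60 band the
  support is a free choice, and it is deliberately kept just above 60 so
  that a ±60-minute anchored window still reaches the dense charting
  that follows onset. This is what makes the truth-recovery guarantee —
  note-anchored detection within 5 minutes of true onset for every
  in-ICU patient — structural rather than statistical: the worst case is
  max(charting lag, offset − 60) ≤ 5 minutes.
* Half of in-ICU intubations are preceded by a noninvasive episode (its
  own PEEP charting every 15 minutes) ending at least 75 minutes before
  the intubation, so the anchored window never reaches it.

What the generator does **not** emulate: physiologic realism of the
charted values (constants with jitter; only timestamps matter to the
method); noninvasive ventilation abutting the intubation minute (where
even a note-anchored window would pick up NIV PEEP — a real failure mode
the method does not claim to solve); charting gaps, device outages,
daylight-saving or timezone effects (all times are naive on one clock);
and notes written *before* the procedure. Passing tests on synthetic
data therefore demonstrate internal correctness of the search under the
documented pathology, not performance on any particular institution's
records.

## Deterministic fixtures

`make_fixture()` builds three RNG-free cohorts whose detection output is
exact by construction; they serve as the benchmark in the test suite:

* **derivation** — 450 patients in 2010; 367 pre-ICU, 83 in-ICU whose
  algorithm-vs-reference absolute differences are exactly {0 ×72, 1 ×6,
  2, 3, 4, 5, 5} minutes. The six one-minute differences follow from the
  printed aggregates: 94% of 83 rounds to 78 patients within one minute,
  and 78 − 72 exact matches leaves 6; the values of the five residual
  differences are only bounded above by five minutes, and {2,3,4,5,5} is
  used because every reported statistic is insensitive to the choice
  within (1, 5]. Completeness patterns make end-tidal CO₂ (11/83) and
  datamart PIP (34/83) fail the 85% rule while PEEP and the note are
  complete, and note offsets cycle over {2, 35, 58, 20, 45} minutes so
  the note survives screening but agrees within five minutes for only
  ~20% of patients.
* **validation** — 450 patients in 2011; 379 pre-ICU, 71 in-ICU with
  differences {0 ×65, 1 ×5, 15}: one genuine 15-minute outlier.
* **master** — 6,714 stays with the eligibility attrition
  −924 (not first admission), −3,000 (never ventilated), −101 (no
  research authorization), −5 (under 18) → 2,684 eligible.

Admissions are spaced on a 977-minute lattice so every patient's times
are distinct minutes — which also makes chance agreement exactly zero in
the `minute_category` κ.

## Numerical and design choices

* **Minute grid by contract.** Input timestamps must have zero seconds;
  all differences are integers, so no floating-point tolerance enters any
  statistic.
* **Rounding** of reported percentages and κ is half away from zero
  (`round_half_away()`); exact values are always available alongside.
* **Window bounds.** The anchored window is closed on both ends; stays
  and episodes are half-open. A record exactly at `note − 60` qualifies;
  a record exactly at discharge does not.
* **Degenerate inputs** error loudly: empty difference multisets, empty
  cohorts, unknown fixture names, a subset request larger than the
  eligible pool. Detection on a patient with no qualifying record
  returns `NA` and the patient is counted as excluded downstream.
* **Determinism.** Fixtures use no RNG; the simulator and subset
  selection use `withr::with_seed`. Pipeline runs on the same inputs are
  byte-identical (the run manifest records a config hash alongside the
  outputs).

## Problem sizes

The test suite exercises the full 450-patient fixtures and the 6,714-stay
master cohort; property-style checks use simulated cohorts of 50–1,000
patients (≈13k–260k flowsheet rows), 25 random record sets for detection
monotonicity, 10,000 repeated single draws for subset uniformity and
1,000 random multisets for the κ identity. These sizes were chosen so the
binomial tolerances in the rate checks are tight (±0.04 at n = 1,000,
about 3.3 standard deviations) while the whole suite stays interactive.

## Limitations

The method presumes timely automatic charting: if the ventilator feed is
delayed or a stay's PEEP series is incomplete, the first queryable record
is late and nothing in the algorithm can recover that. It deliberately
targets *invasive* ventilation onset in the ICU; noninvasive onset,
extubation and ventilation duration are out of scope, as is the upstream
note-text classifier whose output the event table carries. Portability to
another institution reduces to the availability of the same routinely
collected variables in queryable form — the screening step exists
precisely to re-derive the right search variable on a new record system
rather than assuming PEEP everywhere.
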