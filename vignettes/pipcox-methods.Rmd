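---
title: "Methods: criteria-based exposure construction and time-dependent Cox analysis"
author: "pipcox"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: criteria-based exposure construction and time-dependent Cox analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pipcox)
```

## The scientific problem

STOPP/START criteria flag potentially inappropriate prescribing (PIP) in
older adults: STOPP criteria describe potentially inappropriate medications
(PIMs, e.g. high-dose acetylsalicylic acid), START criteria describe
potential prescribing omissions (PPOs, e.g. an NSAID issued to a patient
over 70 without a gastroprotective proton pump inhibitor). `pipcox`
implements, as a reusable and fully testable pipeline, the analysis linking
nonadherence to the nine gastrointestinal-bleeding-related criteria to
gastrointestinal bleeding in routinely collected general-practice records:
patients aged 65 and over, followed over an eight-year window with dynamic
entry (study start or 65th birthday) and exit (study end, death, or leaving
the practice).

The exposure of interest is *time-dependent*: a patient is "nonadherent to
START D2B" only on the days an NSAID episode is active, the patient is over
70, and no PPI is concurrently prescribed. The pipeline therefore resolves
everything to whole calendar days, assembles exposure as sets of closed day
intervals, and fits Cox proportional hazards models on counting-process
data with participant-clustered robust variance:

$$H(t) = h_0(t)\, \exp(b_1\,\mathrm{PIP}(t) + b_2\,\mathrm{age}(t) + b_3\,\mathrm{sex})$$

with variants adding the merged remaining criteria as a confounder
(`PIP_other`), or modelling the potentially harmful START medications as
issued (`meds`) together with PPI coverage and their interaction.

## Interval algebra and drug episodes

All exposure arithmetic uses closed intervals of whole days; two intervals
*touch* when one starts the day after the other ends, and touching or
overlapping intervals are merged. `merge_intervals()`,
`subtract_intervals()` and `intersect_intervals()` implement exact day-set
semantics (property-tested against explicit day-set expansion).

Prescriptions of one drug class are chained into *episodes* by gap-day
extension: every script's end date is extended by a class-specific number
of days reflecting clearance (ASA/ECC 5; platelet aggregation inhibitors 4;
NSAIDs 3; PPIs 3; oral anticoagulants, corticosteroids and SSRIs 2), and
whatever then overlaps or touches is merged. "Scripts at most *g* days
apart belong to one episode" and "extend every expiration date by *g* days,
then merge what touches" coincide under the closed-interval touch rule; the
latter is the single implementation. The extension deliberately applies to
the final script of an episode too (the pharmacological tail does not know
it is last); `default_gap_days()` is overridable per run.

## The criteria engine

Each criterion is a conjunction of day-level conditions
(`criterion_spec()`): primary drug class active; companion class
concurrently active (intersection); qualifying diagnosis on or before the
day; completed age within bounds; daily dose above a threshold; episode
continuously active beyond a minimum duration. Decisions taken where the
printed criteria leave room:

* **Age boundaries are inclusive** (">70" means completed age ≥ 70): the
  canonical worked example applies both the ">70" and the "60–70" criteria
  to a 70-year-old, which forces inclusivity. A strict mode
  (`default_criteria(strict_age = TRUE)`) is provided.
* **Age is evaluated dynamically**: exposure intervals split at birthday
  anniversaries, so a criterion can switch on mid-episode. Leap-day births
  anniversary on Mar 1 in non-leap years.
* **Dose thresholds are agent-specific** (ASA > 160 mg/day, ECC >
  200 mg/day) and applied to scripts before episode merging, giving
  day-resolved dose exposure; on pre-merged episodes the episode's maximum
  daily dose is compared with the lowest applicable threshold.
* **History conditions** (peptic ulcer D85/D86; bleeding disorder B83; gout
  T92) have no look-back limit: any diagnosis on or before the day counts.
  The ICPC sets are configurable because published criteria defer to a
  national code-list adaptation.
* **Duration** (">3 months" of NSAID for gout) is evaluated on merged
  episodes: the exposure starts on day 91 of continuous coverage, not
  retroactively. The allopurinol carve-out of that criterion is not
  computable from prescription/diagnosis data and is not represented.

Two exposure semantics are produced. *Part 1* (nonadherence): for START
criteria, days covered by a PPI episode are subtracted — those days comply
with the criterion. *Part 2* (harmful medication): the medication exposure
is kept as is, and PPI coverage is returned alongside so models can
estimate medication effects with and without gastroprotection (`meds`,
`PPI`, `meds × PPI`). By construction part-1 equals part-2 minus PPI time,
asserted on random cohorts. For per-criterion analyses the remaining
criteria are merged into a single `OTHER` confounder exposure; for combined
analyses all records are merged per patient.

## Bleeding detection

Events come from two channels: coded diagnoses (ICPC D14 hematemesis, D15
melena, D85 duodenal ulcer, D86 other stomach ulcer) and free-text journal
notes. A note is an event iff it contains a Dutch "bleed" stem **and** a
gastrointestinal context stem (case-insensitive substring matching on
diacritic-stripped text — simple and auditable, no stemming), its attached
ICPC code is non-specific or absent, and not a specific code for a
different diagnosis. The coded channel wins same-day duplicates; a new
event less than 30 days after the patient's previous one is regarded as
the same bleeding (the published count of distinct bleedings implies such a
rule without stating one; 30 days is configurable and the generator
enforces the same separation).

## Time splitting and the Cox fit

Follow-up is split into `(t_start, t_stop]` rows on a day grid with delayed
entry at the patient's entry date: cuts at every exposure start, every
exposure end + 1, and every event day. Rows tile the observation window
exactly (person-time is conserved), exposure flags are constant within
rows, events sit on the row ending at the event day, and follow-up
continues after events (recurrent bleedings keep the patient at risk; no
washout is applied). An event on an exposure boundary belongs to the
exposure state of the event day itself, because exposure intervals include
their end day.

One refinement matters statistically: with cuts only at exposure changes,
the age covariate of a long unexposed row is measured at the row start and
can lag the true age by years at later risk sets, while exposed rows are
short and accurately aged. This differential measurement error attenuates
the exposure coefficient and degrades confidence-interval coverage
whenever age carries a real effect. `assemble_model_dataset()`
therefore also cuts rows at birthday anniversaries (`age_splits = TRUE`),
making completed age exact on every row; `build_rows()` keeps the minimal
splitting for illustration of the sequence construction. By
split-invariance of the partial likelihood, extra cuts never change the
estimates when covariates are measured correctly — they only remove the
measurement error.

`fit_cox()` maximizes the partial likelihood via `survival::coxph` with
Efron tie handling (the day grid guarantees ties) and a cluster-robust
sandwich variance over participants (sequences of one participant are
correlated, and exposed participants contribute more sequences than
unexposed ones). Hazard ratios are `exp(coef)`; 95% limits use the normal
quantile 1.959964 on the log scale; p-values are two-sided Wald tests on
the robust SE with significance at 0.05. When no event occurs at one level
of a covariate the partial likelihood has no finite maximizer; the fit is
flagged (`|coef| > 15` or non-convergence) and reported as non-estimable
rather than as a number — no Firth-type correction is applied.
`run_plan()` executes the full battery: combined / STARTs-combined /
STOPPs-combined, nine criteria in multivariable and confounder-adjusted
forms, six part-2 START models in multivariable and interaction forms, and
sensitivity fits restricted to the subpopulation with at least one
bleeding.

## The synthetic cohort generator

`simulate_study()` emulates the structure the analysis assumes, not any
real population: uniform ages 58–92 at study start (so entries occur both
at study start and at 65th birthdays mid-window), 59% female, geometric
death/leave times, chronic medication issued as scripts of 14–90 days with
refill gaps of 0–10 days (exercising the gap-day merge in both
directions), PPI co-prescription over NSAID/ASA episodes with jittered
boundaries (creating both fully protected and partially protected
episodes), pre-entry history diagnoses, keyword-bearing distractor notes
carrying specific excluded ICPC codes, and anodyne noise notes.

Bleeding events are generated at day resolution by Bernoulli thinning of a
piecewise-constant hazard
`lambda0 * exp(b1 PIP(t) + b2 (age(t) - 75) + b3 male)`, with exposure
labels taken from the criteria engine's own output on the emitted
prescriptions — generator and engine agree by construction, and the
consistency test re-derives the labels after a CSV round trip to catch
serialization drift. Events are recorded as D14/D15 diagnoses except a
configured 13% written only as free-text notes; simulated outcome events
are deliberately *not* coded D85/D86, and history diagnoses are dated
before entry, so outcomes never feed back into the peptic-ulcer history
conditions (in real data D85/D86 play both roles; the generator trades
that realism for exact ground truth). Recurrent events are kept at least
30 days apart, matching the detector's distinctness rule.

Default rates were set once so that ~12–14% of patients have at least one
PIP record and the median record lasts about a month, the population shape
the analysis is designed for. The default bleeding baseline hazard
(4e-5/day) is far above a realistic primary-care rate so that a
2,000-patient cohort carries a few hundred events; at a realistic rate a
desk-scale cohort would carry almost none and nothing downstream could be
validated.

## Validation harness and what it shows

Statistical guarantees are checked on `validation_config()`, which further
raises the baseline hazard (1.5e-4/day) and the chronic-use rates of the
gastrointestinal drugs (NSAID 0.35, ASA/ECC 0.30, PPI co-prescription
0.2). The reason is information, not convenience: with the
population-shaped defaults the combined exposure covers ~1% of
person-time, so a cohort yields fewer than ten exposed events and any
mean-estimate criterion would measure small-count artifacts (the
log-rate concavity bias of order 1/(2·events)) rather than estimator
quality. In the harness regime a cohort carries on the order of a hundred
exposed events. The problem sizes used:

* parameter recovery: 200 cohorts of 2,000 patients with a planted
  combined-exposure log hazard ratio of log(5.45); the mean fitted
  coefficient must lie within 5% of truth and the robust 95% CI must cover
  it in 92–98% of replicates;
* type-I error: 500 cohorts of 800 patients with a null exposure effect;
  the robust Wald test at 0.05 must reject in 3–7% of replicates.

A residual attenuation of about 2% remains by design: both generator and
detector treat events within 30 days as one bleeding, so each event is
followed by a short dead zone that the at-risk model does not know about,
and exposed person-time (where events cluster) contains proportionally
more dead-zone days.

What passing these tests does **not** show about real data: the generator
draws from the model family the analysis fits (proportional hazards,
exponential baseline, exact exposure labels), so the tests validate the
*pipeline* — interval algebra, criteria logic, detection, splitting,
fitting, variance — not robustness to confounding by indication,
over-the-counter medication invisible to the EHR, miscoded diagnoses, or
non-proportional hazards, all of which real records contain.

## Numerical and degenerate-input conventions

* Day grid: day 1 is the study start; rows are `(t_start, t_stop]` with
  left truncation at entry; a one-day observation window is a valid single
  row.
* Empty inputs propagate as empty outputs (zero patients, empty interval
  sets, no PPI scripts); zero events refuse to fit with an explicit error.
* Ties in the day grid use Efron's approximation throughout, including the
  test-suite oracle.
* The theoretical maximum number of sequences for a patient present the
  whole 2007–2014 window with daily exposure changes is the window's
  2922 days minus one, 2921.
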