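# pipcox

Time-dependent association between potentially inappropriate prescribing
and gastrointestinal bleeding in older primary-care patients.

## What this package is for

STOPP/START criteria flag potentially inappropriate prescribing (PIP) in
people aged 65 and over: STOPP criteria mark potentially inappropriate
medications (PIMs), START criteria mark potential prescribing omissions
(PPOs) — typically a missing gastroprotective proton pump inhibitor (PPI)
alongside an NSAID, acetylsalicylic acid (ASA/ECC), anticoagulant,
corticosteroid or SSRI. `pipcox` implements, as a tested and reusable R
pipeline, the epidemiological analysis linking *nonadherence* to the nine
gastrointestinal-bleeding-related criteria to gastrointestinal bleeding in
longitudinal GP records:

1. **EHR model** — typed CSV readers/writers for patients, prescriptions
   (ATC-coded, with daily dose), ICPC-coded diagnoses and free-text
   journal notes, with row-level validation.
2. **Episode merging** — exact closed-interval day algebra; prescriptions
   chained into drug episodes by class-specific gap-day extension
   (ASA/ECC 5, platelet inhibitors 4, NSAID/PPI 3, anticoagulants /
   corticosteroids / SSRIs 2 days).
3. **Criteria engine** — the 3 STOPP + 6 START criteria evaluated as
   day-resolved exposure intervals, in *part-1* semantics (nonadherence:
   PPI-covered days subtracted) and *part-2* semantics (harmful
   medication as issued, PPI as a covariate).
4. **Bleeding detector** — coded events (ICPC D14/D15/D85/D86) plus a
   keyword screen of journal notes (Dutch "bleed" stem + gastrointestinal
   context stem, non-specific ICPC only), with a 30-day distinctness rule.
5. **Time splitting** — counting-process rows `(t_start, t_stop]` with
   delayed entry, cut at every exposure change, event and birthday.
6. **Cox analysis** — for each model of the battery,

   `H(t) = h0(t) · exp(b1·PIP + b2·age + b3·sex)`

   (plus confounder-adjusted and PPI-interaction variants), fitted with
   Efron ties and participant-clustered robust variance; monotone
   likelihoods (no event at one exposure level) are flagged
   non-estimable, never reported as numbers.
7. **Synthetic cohorts** — a generator with known ground-truth hazard
   structure, so parameter recovery, CI coverage, type-I error and exact
   detector recovery are all testable without any real data.

The audience is pharmacoepidemiologists and medical informaticians who
want a criteria-to-hazard-ratio pipeline whose every stage is specified,
overridable (YAML criteria/config), and validated against brute-force
oracles.

## Worked example

```r
library(pipcox)

cfg   <- simulation_config(n_patients = 500, seed = 2024)
study <- simulate_study(cfg)
study$cohort
#> pip_cohort: 500 patients, 1629 prescriptions, 153 diagnoses, 44 notes

table(study$ground_truth$pip_records$criterion_code)
#> START_D2A START_D2B START_D2C START_D3A START_D3B START_D3C STOPP_A15  STOPP_A9  STOPP_E5
#>        12        91         9         5         7        62         3        16         1

bld <- detect_bleedings(study$cohort)
nrow(bld)   # 71 bleedings, 6 of them found only in free text

ds <- assemble_model_dataset(study$cohort$patients, bld,
        list(target = "ALL", form = "part1_multivariable"),
        pip_records = study$ground_truth$pip_records,
        study_start = cfg$study_start)
fit_cox(ds)
#> Cox fit (part1_multivariable), 71 events on 3987 rows
#>      term    coef robust_se naive_se hazard_ratio ci95_low ci95_high p_value estimable
#>       PIP 1.19000   0.59650  0.72210        3.288   1.0220    10.580 0.04596      TRUE
#>       age 0.02252   0.01255  0.01342        1.023   0.9979     1.048 0.07282      TRUE
#>  sex_male 0.25450   0.23260  0.23780        1.290   0.8177     2.035 0.27380      TRUE
```

Reading the output: on days flagged as nonadherent to any of the nine
criteria, the bleeding hazard is estimated 3.3 times the baseline (95% CI
1.0–10.6) after adjusting for age and sex — a small-cohort estimate of the
planted effect (true hazard ratio 5.45), with the clustered robust SE
wider than the naive one because exposed patients contribute many
correlated sequences. `run_plan(artifacts, default_analysis_plan())` runs
the full battery (combined, per-criterion multivariable and adjusted,
part-2 multivariable and interaction, bleeding-subpopulation sensitivity)
and returns one summary row per model.

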