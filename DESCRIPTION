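Package: pipcox
Title: Time-Dependent Cox Analysis of Potentially Inappropriate Prescribing
    and Gastrointestinal Bleeding
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A reusable pipeline for studying the time-dependent association
    between nonadherence to gastrointestinal-bleeding-related STOPP/START
    prescribing criteria and gastrointestinal bleeding in longitudinal
    primary-care records. Provides typed readers for patient, prescription,
    diagnosis and journal-note tables; closed-interval date algebra with
    gap-day extension for building drug-exposure episodes; a rule engine for
    three STOPP and six START criteria evaluated as day-resolved exposure
    intervals; a keyword plus ICPC-code detector for bleeding events;
    counting-process time splitting with delayed entry; Cox proportional
    hazards fits with participant-clustered robust variance; and a synthetic
    electronic-health-record cohort generator with a known ground-truth
    hazard structure so the whole pipeline can be validated by parameter
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    survival (>= 3.5),
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
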