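#' Define one STOPP/START criterion
#'
#' A criterion is a conjunction of day-level conditions: a primary drug
#' class must be actively prescribed; optionally a companion class must be
#' concurrently active; optionally a qualifying diagnosis must exist on or
#' before the day; optionally the patient's completed age must lie within
#' bounds; optionally the daily dose must exceed a threshold; optionally the
#' episode must have been continuously active for more than a minimum
#' duration. For START criteria (`ppi_protective = TRUE`) days covered by a
#' proton pump inhibitor comply with the criterion and are removed from the
#' nonadherence exposure.
#'
#' @param code criterion code, e.g. `"START_D2B"`.
#' @param kind `"STOPP"` (potentially inappropriate medication) or
#'   `"START"` (potential prescribing omission).
#' @param primary_classes character vector of drug classes whose active
#'   episode triggers the criterion.
#' @param companion_classes drug classes that must be concurrently active
#'   (empty = no companion condition).
#' @param history_icpc ICPC codes any one of which, diagnosed on or before a
#'   day, satisfies the history condition (empty = none).
#' @param age_min,age_max inclusive bounds on completed age in years
#'   (`NA` = unbounded).
#' @param dose_threshold_mg named numeric vector mapping ATC prefixes to the
#'   daily dose (mg) that must be exceeded, or `NULL` for no dose condition.
#' @param min_duration_days the episode must have been continuously active
#'   for more than this many days (`NA` = no duration condition).
#' @param ppi_protective logical; `TRUE` for all START criteria.
#' @return A list of class `criterion_spec`.
#' @export
criterion_spec <- function(code, kind = c("STOPP", "START"), primary_classes,
                           companion_classes = character(),
                           history_icpc = character(),
                           age_min = NA_integer_, age_max = NA_integer_,
                           dose_threshold_mg = NULL,
                           min_duration_days = NA_integer_,
                           ppi_protective = match.arg(kind) == "START") {
  kind <- match.arg(kind)
  structure(list(code = code, kind = kind,
                 primary_classes = primary_classes,
                 companion_classes = companion_classes,
                 history_icpc = history_icpc,
                 age_min = as.integer(age_min), age_max = as.integer(age_max),
                 dose_threshold_mg = dose_threshold_mg,
                 min_duration_days = as.integer(min_duration_days),
                 ppi_protective = isTRUE(ppi_protective)),
            class = "criterion_spec")
}

#' The nine gastrointestinal-bleeding STOPP/START criteria
#'
#' Three STOPP criteria (inappropriate medication present) and six START
#' criteria (gastroprotective PPI omitted):
#'
#' * `STOPP_A9` - ASA at >160 mg/day or ECC at >200 mg/day.
#' * `STOPP_A15` - platelet aggregation inhibitor or oral anticoagulant with
#'   a concurrent bleeding disorder (ICPC B83 by default).
#' * `STOPP_E5` - NSAID for more than 3 months (from day 91 of continuous
#'   coverage) with a history of gout (ICPC T92 by default).
#' * `START_D2A` - NSAID with a history of peptic ulcer (D85/D86), no PPI.
#' * `START_D2B` - NSAID at age >70, no PPI.
#' * `START_D2C` - NSAID at age 60-70 with concurrent anticoagulant,
#'   corticosteroid, SSRI or ASA/ECC, no PPI.
#' * `START_D3A` - ASA/ECC at age >60 with history of peptic ulcer, no PPI.
#' * `START_D3B` - ASA/ECC at age >70 with concurrent anticoagulant,
#'   corticosteroid or SSRI, no PPI.
#' * `START_D3C` - ASA/ECC at age >80, no PPI.
#'
#' Age thresholds are inclusive at the printed boundary by default
#' (">70" means completed age >= 70, "60-70" means 60 <= age <= 70): the
#' canonical worked example applies both the ">70" and the "60-70" criteria
#' to a 70-year-old, which forces inclusive boundaries. `strict_age = TRUE`
#' instead reads ">x" as age >= x+1.
#'
#' The ICPC history sets (peptic ulcer D85/D86; bleeding disorder B83;
#' gout T92) follow the national criteria adaptation's intent and are
#' overridable via [criterion_spec()]. The E5 carve-out for allopurinol
#' contraindication is not computable from the data model and is not
#' represented.
#'
#' @param strict_age read ">x" age thresholds exclusively (see above).
#' @return Named list of nine [criterion_spec()] objects.
#' @export
default_criteria <- function(strict_age = FALSE) {
  gt <- function(x) if (strict_age) x + 1L else x
  specs <- list(
    criterion_spec("STOPP_A9", "STOPP", "ASA_ECC",
                   dose_threshold_mg = c(B01AC06 = 160, N02BA01 = 160,
                                         B01AC08 = 200, N02BA15 = 200)),
    criterion_spec("STOPP_A15", "STOPP",
                   c("platelet_inhibitor", "oral_anticoagulant"),
                   history_icpc = "B83"),
    criterion_spec("STOPP_E5", "STOPP", "NSAID",
                   history_icpc = "T92", min_duration_days = 90L),
    criterion_spec("START_D2A", "START", "NSAID",
                   history_icpc = c("D85", "D86")),
    criterion_spec("START_D2B", "START", "NSAID", age_min = gt(70L)),
    criterion_spec("START_D2C", "START", "NSAID",
                   companion_classes = c("oral_anticoagulant",
                                         "corticosteroid", "SSRI", "ASA_ECC"),
                   age_min = 60L, age_max = 70L),
    criterion_spec("START_D3A", "START", "ASA_ECC",
                   history_icpc = c("D85", "D86"), age_min = gt(60L)),
    criterion_spec("START_D3B", "START", "ASA_ECC",
                   companion_classes = c("oral_anticoagulant",
                                         "corticosteroid", "SSRI"),
                   age_min = gt(70L)),
    criterion_spec("START_D3C", "START", "ASA_ECC", age_min = gt(80L))
  )
  names(specs) <- vapply(specs, `[[`, character(1), "code")
  specs
}

# ---- internal cohort-level evaluation --------------------------------------

# ctx: list(pts = dt(id, birth Date, lo, hi int window), dx = dt(id, icpc, d),
#           episodes = list per class of dt(id, s, e, v), rx = dt or NULL)
pip_context <- function(cohort, gap_days = default_gap_days(),
                        atc_map = default_atc_map()) {
  p <- cohort$patients
  pts <- data.table(id = p$patient_id, birth = as.Date(p$birth_date),
                    lo = as.integer(as.Date(p$entry_date)),
                    hi = as.integer(as.Date(p$exit_date)))
  dx <- cohort$diagnoses
  dx <- data.table(id = dx$patient_id, icpc = dx$icpc_code,
                   d = as.integer(as.Date(dx$date)))
  rx <- rx_to_dt(cohort$prescriptions, atc_map)
  list(pts = pts, dx = dx, rx = rx,
       gap_days = gap_days,
       episodes = build_class_episodes(rx, gap_days))
}

BIG_DAY <- 2100000000L

eval_raw_g <- function(spec, ctx) {
  # primary exposure, with per-script dose filtering when a threshold applies
  if (!is.null(spec$dose_threshold_mg) && !is.null(ctx$rx)) {
    rx <- ctx$rx[drug_class %in% spec$primary_classes]
    if (nrow(rx)) {
      thr <- rep(NA_real_, nrow(rx))
      for (p in names(spec$dose_threshold_mg)) {
        thr[startsWith(rx$atc, p)] <- spec$dose_threshold_mg[[p]]
      }
      rx <- rx[!is.na(thr) & !is.na(dose) & dose > thr]
    }
    prim <- rbindlist(lapply(spec$primary_classes, function(cl) {
      iv_merge_g(rx[drug_class == cl,
                    .(id, s, e = e + as.integer(ctx$gap_days[[cl]]))])
    }))
    prim <- iv_merge_g(prim)
  } else {
    epi <- rbindlist(ctx$episodes[spec$primary_classes])
    if (!is.null(spec$dose_threshold_mg)) {
      # pre-merged episode path: max daily dose must clear the lowest
      # threshold among the primary classes' agents
      epi <- epi[!is.na(v) & v > min(spec$dose_threshold_mg)]
    }
    prim <- iv_merge_g(epi[, .(id, s, e)])
  }
  if (nrow(prim) == 0L) return(iv_empty())
  if (!is.na(spec$min_duration_days)) {
    prim[, s := s + spec$min_duration_days]
    prim <- prim[s <= e]
    if (nrow(prim) == 0L) return(iv_empty())
  }
  if (!is.na(spec$age_min) || !is.na(spec$age_max)) {
    ids <- unique(prim$id)
    pt <- ctx$pts[id %in% ids]
    lo <- if (!is.na(spec$age_min)) {
      as.integer(anniversary(pt$birth, spec$age_min))
    } else rep(-BIG_DAY, nrow(pt))
    hi <- if (!is.na(spec$age_max)) {
      as.integer(anniversary(pt$birth, spec$age_max + 1L)) - 1L
    } else rep(BIG_DAY, nrow(pt))
    win <- data.table(id = pt$id, s = lo, e = hi)[s <= e]
    prim <- iv_intersect_g(prim, win)
    if (nrow(prim) == 0L) return(iv_empty())
  }
  if (length(spec$history_icpc)) {
    hx <- ctx$dx[icpc %in% spec$history_icpc]
    if (nrow(hx) == 0L) return(iv_empty())
    d0 <- hx[, .(dx0 = min(d)), by = id]
    prim <- d0[prim, on = "id", nomatch = NULL]
    prim[, s := pmax(s, dx0)]
    prim <- prim[s <= e, .(id, s, e)]
    if (nrow(prim) == 0L) return(iv_empty())
  }
  if (length(spec$companion_classes)) {
    comp <- iv_merge_g(rbindlist(lapply(ctx$episodes[spec$companion_classes],
                                        function(x) x[, .(id, s, e)])))
    prim <- iv_intersect_g(prim, comp)
  }
  prim
}

part1_records_g <- function(spec, ctx) {
  raw <- eval_raw_g(spec, ctx)
  if (spec$ppi_protective && nrow(raw)) {
    raw <- iv_subtract_g(raw, ctx$episodes$PPI[, .(id, s, e)])
  }
  bounds <- ctx$pts[, .(id, lo, hi)]
  iv_clip_g(raw, bounds)
}

part2_records_g <- function(spec, ctx) {
  if (spec$kind != "START") stop("part-2 semantics apply to START criteria only")
  bounds <- ctx$pts[, .(id, lo, hi)]
  list(med = iv_clip_g(eval_raw_g(spec, ctx), bounds),
       ppi = iv_clip_g(ctx$episodes$PPI[, .(id, s, e)], bounds))
}

records_from_g <- function(x, code) {
  x <- as.data.table(x)
  setorder(x, id, s)
  data.frame(patient_id = x$id, criterion_code = rep(code, nrow(x)),
             start = as.Date(x$s, origin = "1970-01-01"),
             end = as.Date(x$e, origin = "1970-01-01"))
}

recs_to_dt <- function(records) {
  if (is.null(records) || nrow(records) == 0L) return(iv_empty())
  data.table(id = records$patient_id,
             s = as.integer(as.Date(records$start)),
             e = as.integer(as.Date(records$end)))
}

# ---- public cohort-level API -----------------------------------------------

#' Evaluate all criteria as nonadherence (part-1) exposure records
#'
#' Runs the full criteria engine over a cohort and returns one PIP record
#' per maximal interval of nonadherence to each criterion: days on which all
#' of a criterion's conditions hold and -- for START criteria -- no PPI
#' episode is concurrently active. Records are clipped to each patient's
#' observation window and same-criterion overlaps are merged.
#'
#' @param cohort a cohort list (see [read_cohort()]).
#' @param criteria named list of [criterion_spec()]s
#'   (default: [default_criteria()]).
#' @param gap_days named gap-day table, see [default_gap_days()].
#' @param atc_map ATC prefix map, see [default_atc_map()].
#' @return data.frame: `patient_id`, `criterion_code`, `start`, `end`.
#' @export
derive_pip_records <- function(cohort, criteria = default_criteria(),
                               gap_days = default_gap_days(),
                               atc_map = default_atc_map()) {
  ctx <- pip_context(cohort, gap_days, atc_map)
  out <- lapply(names(criteria), function(code) {
    records_from_g(part1_records_g(criteria[[code]], ctx), code)
  })
  do.call(rbind, out)
}

#' Evaluate START criteria as harmful-medication (part-2) exposure
#'
#' Part-2 semantics keep the potentially harmful medication exposure as is
#' (no PPI subtraction) and return the PPI coverage alongside, so that
#' models can contrast medication with and without concurrent
#' gastroprotection (meds, PPI and meds-by-PPI covariates).
#'
#' @inheritParams derive_pip_records
#' @return list with `med` (data.frame `patient_id`, `criterion_code`,
#'   `start`, `end` for each START) and `ppi` (data.frame `patient_id`,
#'   `start`, `end` of PPI coverage clipped to the observation window).
#' @export
derive_part2_records <- function(cohort, criteria = default_criteria(),
                                 gap_days = default_gap_days(),
                                 atc_map = default_atc_map()) {
  ctx <- pip_context(cohort, gap_days, atc_map)
  starts <- Filter(function(s) s$kind == "START", criteria)
  med <- do.call(rbind, lapply(names(starts), function(code) {
    records_from_g(part2_records_g(starts[[code]], ctx)$med, code)
  }))
  bounds <- ctx$pts[, .(id, lo, hi)]
  ppi <- records_from_g(iv_clip_g(ctx$episodes$PPI[, .(id, s, e)], bounds),
                        "PPI")
  ppi$criterion_code <- NULL
  list(med = med, ppi = ppi)
}

# ---- public per-patient operations -----------------------------------------

one_patient_ctx <- function(patient, episodes, diagnoses,
                            gap_days = default_gap_days()) {
  p <- as.data.frame(patient)
  stopifnot(nrow(p) == 1L)
  pts <- data.table(id = p$patient_id, birth = as.Date(p$birth_date),
                    lo = as.integer(as.Date(p$entry_date)),
                    hi = as.integer(as.Date(p$exit_date)))
  dx <- if (is.null(diagnoses) || nrow(diagnoses) == 0L) {
    data.table(id = character(), icpc = character(), d = integer())
  } else {
    data.table(id = diagnoses$patient_id, icpc = diagnoses$icpc_code,
               d = as.integer(as.Date(diagnoses$date)))
  }
  epi <- lapply(names(gap_days), function(cl) {
    if (is.null(episodes) || nrow(episodes) == 0L) return(iv_empty())
    x <- episodes[episodes$drug_class == cl, , drop = FALSE]
    data.table(id = rep(p$patient_id, nrow(x)),
               s = as.integer(as.Date(x$start)),
               e = as.integer(as.Date(x$end)),
               v = if ("max_daily_dose_mg" %in% names(x))
                 as.numeric(x$max_daily_dose_mg) else rep(NA_real_, nrow(x)))
  })
  names(epi) <- names(gap_days)
  list(pts = pts, dx = dx, rx = NULL, gap_days = gap_days, episodes = epi)
}

#' Raw day-set on which one criterion's conditions all hold
#'
#' Evaluates a single criterion for a single patient on pre-merged drug
#' episodes, without PPI subtraction and without clipping to the
#' observation window (part-2 "as is" semantics). Age conditions are
#' evaluated dynamically: intervals split at birthday anniversaries where
#' the age bound switches.
#'
#' @param spec a [criterion_spec()].
#' @param patient one-row data.frame with `patient_id`, `birth_date`,
#'   `entry_date`, `exit_date`.
#' @param episodes data.frame of merged drug episodes for this patient:
#'   `drug_class`, `start`, `end`, optionally `max_daily_dose_mg`. For a
#'   dose-thresholded criterion an episode qualifies when its maximum daily
#'   dose exceeds the lowest applicable threshold; build episodes from
#'   dose-qualifying prescriptions for script-level resolution.
#' @param diagnoses data.frame of this patient's diagnoses
#'   (`patient_id`, `icpc_code`, `date`), or `NULL`.
#' @param gap_days gap-day table (used only to enumerate drug classes here).
#' @return data.frame of canonical intervals (`start`, `end`).
#' @export
raw_criterion_intervals <- function(spec, patient, episodes, diagnoses = NULL,
                                    gap_days = default_gap_days()) {
  ctx <- one_patient_ctx(patient, episodes, diagnoses, gap_days)
  iv_to_df(eval_raw_g(spec, ctx))
}

#' Part-1 nonadherence records for one patient and criterion
#'
#' Raw criterion intervals minus PPI coverage (for START criteria), clipped
#' to the patient's observation window and merged.
#'
#' @inheritParams raw_criterion_intervals
#' @return data.frame: `patient_id`, `criterion_code`, `start`, `end`.
#' @export
part1_pip_records <- function(spec, patient, episodes, diagnoses = NULL,
                              gap_days = default_gap_days()) {
  ctx <- one_patient_ctx(patient, episodes, diagnoses, gap_days)
  records_from_g(part1_records_g(spec, ctx), spec$code)
}

#' Part-2 medication and PPI records for one patient and START criterion
#'
#' @inheritParams raw_criterion_intervals
#' @return list with `med_intervals` and `ppi_intervals`, both data.frames
#'   of canonical intervals clipped to the observation window.
#' @export
part2_med_records <- function(spec, patient, episodes, diagnoses = NULL,
                              gap_days = default_gap_days()) {
  ctx <- one_patient_ctx(patient, episodes, diagnoses, gap_days)
  res <- part2_records_g(spec, ctx)
  list(med_intervals = iv_to_df(res$med), ppi_intervals = iv_to_df(res$ppi))
}

#' Merge all other criteria's records into a confounder exposure
#'
#' For per-criterion analyses the remaining PIMs and PPOs act as a single
#' confounder: per patient, all records whose code differs from the
#' criterion under analysis are merged into maximal intervals coded
#' `"OTHER"`.
#'
#' @param pip_records data.frame of part-1 records
#'   (`patient_id`, `criterion_code`, `start`, `end`).
#' @param excluded_criterion criterion code to leave out.
#' @return data.frame of merged records with `criterion_code = "OTHER"`.
#' @export
merge_other_pips <- function(pip_records, excluded_criterion) {
  keep <- pip_records[pip_records$criterion_code != excluded_criterion, ,
                      drop = FALSE]
  records_from_g(iv_merge_g(recs_to_dt(keep)), "OTHER")
}

#' Merge part-1 records of selected criteria into combined exposure
#'
#' Per patient, the union of all records whose code is in `codes` (all
#' codes when `NULL`), as used for the combined, STARTs-combined and
#' STOPPs-combined analyses.
#'
#' @param pip_records data.frame of part-1 records.
#' @param codes character vector of criterion codes to include, or `NULL`.
#' @return data.frame: `patient_id`, `start`, `end`.
#' @export
combine_pip_records <- function(pip_records, codes = NULL) {
  keep <- if (is.null(codes)) pip_records else
    pip_records[pip_records$criterion_code %in% codes, , drop = FALSE]
  out <- records_from_g(iv_merge_g(recs_to_dt(keep)), "ALL")
  out$criterion_code <- NULL
  out
}
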