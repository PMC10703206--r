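#' Split follow-up into counting-process rows
#'
#' Each patient's observation time is cut at every exposure start, every
#' exposure end + 1 day and every bleeding event, producing rows
#' `(t_start, t_stop]` on a day grid (day 1 = the study start date) with
#' covariates constant within each row. Entry is delayed at the patient's
#' entry date (left truncation); follow-up continues after an event, so
#' recurrent bleedings keep the patient at risk. The event indicator is 1
#' on the row whose `t_stop` falls on an event day; an event on an exposure
#' boundary is attributed to the exposure status of the event day itself
#' (exposure intervals include their end day). Age is completed years at
#' the row's first day and updates across rows; sex enters as `sex_male`.
#'
#' @param patients patients table (`patient_id`, `birth_date`, `sex`,
#'   `entry_date`, `exit_date`).
#' @param exposure_sets named list of interval tables
#'   (`patient_id`, `start`, `end`); one 0/1 flag column per name.
#'   Intervals are clipped to each patient's observation window.
#' @param events data.frame of event dates (`patient_id`, `date`); must lie
#'   within the patient's observation window.
#' @param study_start `Date`; origin of the day grid.
#' @param age_splits additionally cut rows at birthday anniversaries so the
#'   completed-age covariate is exact on every row (recommended for model
#'   fitting; `FALSE` reproduces the minimal exposure/event splitting, on
#'   which age is measured at the row start and can lag the true age on
#'   long rows).
#' @return data.frame: `patient_id`, `t_start`, `t_stop`, `event`, one
#'   column per exposure set, `age`, `sex_male`.
#' @export
build_model_rows <- function(patients, exposure_sets = list(),
                             events = NULL, study_start,
                             age_splits = FALSE) {
  study_start <- as.Date(study_start)
  tday <- function(d) as.integer(as.Date(d)) - as.integer(study_start) + 1L
  pts <- data.table(id = patients$patient_id,
                    birth = as.Date(patients$birth_date),
                    male = as.integer(patients$sex == "M"),
                    t0 = tday(patients$entry_date) - 1L,
                    t1 = tday(patients$exit_date))
  ev <- if (is.null(events) || nrow(events) == 0L) {
    data.table(id = character(), te = integer())
  } else {
    data.table(id = events$patient_id, te = tday(events$date))
  }
  if (nrow(ev)) {
    chk <- pts[ev, on = "id"]
    bad <- chk[is.na(t0) | te <= t0 | te > t1]
    if (nrow(bad)) {
      stop("event outside observation window for patient(s): ",
           paste(unique(bad$id), collapse = ", "))
    }
  }
  sets <- lapply(exposure_sets, function(x) {
    if (is.null(x) || nrow(x) == 0L) {
      return(data.table(id = character(), s = integer(), e = integer()))
    }
    dt <- data.table(id = x$patient_id, s = tday(x$start), e = tday(x$end))
    # clip to the observation window
    dt <- pts[dt, on = "id", nomatch = NULL][, .(id, s = pmax(s, t0 + 1L),
                                                 e = pmin(e, t1))]
    dt[s <= e]
  })
  cuts <- rbind(pts[, .(id, t = t0)], pts[, .(id, t = t1)],
                ev[, .(id, t = te)],
                rbindlist(c(list(data.table(id = character(), t = integer())),
                            lapply(sets, function(x) {
                              rbind(x[, .(id, t = s - 1L)], x[, .(id, t = e)])
                            }))))
  if (age_splits) {
    for (k in 66:105) {
      ann <- tday(anniversary(pts$birth, k))
      in_win <- ann > pts$t0 + 1L & ann <= pts$t1
      if (any(in_win)) {
        cuts <- rbind(cuts, data.table(id = pts$id[in_win],
                                       t = ann[in_win] - 1L))
      }
    }
  }
  cuts <- unique(cuts)
  cuts <- pts[cuts, on = "id", nomatch = NULL][t >= t0 & t <= t1,
                                               .(id, t, birth, male)]
  setorder(cuts, id, t)
  seg <- cuts[, .(t_start = head(t, -1L), t_stop = tail(t, -1L),
                  birth = birth[1L], male = male[1L]), by = id]
  seg[, seg_row := .I]
  for (nm in names(sets)) {
    seg[, (nm) := 0L]
    set_dt <- sets[[nm]]
    if (nrow(set_dt)) {
      pt <- seg[, .(id, s = t_start + 1L, e = t_start + 1L, seg_row)]
      setkey(set_dt, id, s, e)
      hit <- foverlaps(pt, set_dt, type = "any", nomatch = NULL)
      if (nrow(hit)) seg[hit$seg_row, (nm) := 1L]
    }
  }
  seg[, event := 0L]
  if (nrow(ev)) seg[ev, on = .(id, t_stop = te), event := 1L]
  seg[, age := compute_age(birth, study_start + t_start)]
  out <- data.frame(patient_id = seg$id, t_start = seg$t_start,
                    t_stop = seg$t_stop, event = seg$event)
  for (nm in names(sets)) out[[nm]] <- seg[[nm]]
  out$age <- seg$age
  out$sex_male <- seg$male
  out
}

#' Counting-process rows for a single patient
#'
#' Single-patient convenience wrapper around [build_model_rows()].
#'
#' @param patient one-row patients data.frame.
#' @param exposure_interval_sets named list of interval data.frames
#'   (`start`, `end`).
#' @param events vector of event dates (or `NULL`).
#' @param study_start `Date` origin of the day grid.
#' @return data.frame of counting-process rows.
#' @export
build_rows <- function(patient, exposure_interval_sets = list(),
                       events = NULL, study_start) {
  sets <- lapply(exposure_interval_sets, function(x) {
    if (is.null(x) || nrow(x) == 0L) return(NULL)
    data.frame(patient_id = patient$patient_id, start = x$start, end = x$end)
  })
  ev <- if (length(events)) {
    data.frame(patient_id = patient$patient_id, date = as.Date(events))
  } else NULL
  build_model_rows(patient, sets, ev, study_start)
}

#' Assemble the counting-process dataset for one model form
#'
#' Builds the covariate structure of the four model forms:
#'
#' * `part1_multivariable`: hazard scaled by `exp(b1 PIP + b2 age + b3 sex)`
#'   where `PIP` flags nonadherence to the target criterion or the merged
#'   combined exposure for group targets (`"ALL"`, `"STARTS"`, `"STOPPS"`).
#' * `part1_adjusted`: adds `PIP_other`, the merged remaining criteria, as
#'   confounder.
#' * `part2_multivariable`: `meds` flags the potentially harmful medication
#'   exposure of one START criterion, taken as is.
#' * `part2_interaction`: `meds`, `PPI` and their product `meds_PPI`
#'   (1 on rows lying inside both interval sets).
#'
#' @param patients patients table.
#' @param bleedings detected bleeding events (`patient_id`, `date`).
#' @param model_spec list with `target` (criterion code or one of `"ALL"`,
#'   `"STARTS"`, `"STOPPS"`) and `form` (one of the four names above).
#' @param pip_records part-1 records from [derive_pip_records()] (needed
#'   for part-1 forms).
#' @param part2_records list from [derive_part2_records()] (needed for
#'   part-2 forms).
#' @param study_start `Date` origin of the day grid.
#' @param age_splits cut rows at birthday anniversaries so the age
#'   covariate is exact (default `TRUE`; see [build_model_rows()]).
#' @return list of class `pip_model_dataset`: `rows`, `covariate_names`,
#'   `model_tag`, `target`.
#' @export
assemble_model_dataset <- function(patients, bleedings, model_spec,
                                   pip_records = NULL, part2_records = NULL,
                                   study_start, age_splits = TRUE) {
  target <- model_spec$target
  form <- model_spec$form
  group_codes <- function(target, codes) {
    switch(target,
           ALL = codes,
           STARTS = grep("^START", codes, value = TRUE),
           STOPPS = grep("^STOPP", codes, value = TRUE),
           target)
  }
  if (form %in% c("part1_multivariable", "part1_adjusted")) {
    if (is.null(pip_records)) stop("part-1 forms require pip_records")
    codes <- group_codes(target, unique(pip_records$criterion_code))
    pip <- combine_pip_records(pip_records, codes)
    sets <- list(PIP = pip)
    if (form == "part1_adjusted") {
      if (length(codes) > 1L) {
        stop("the adjusted model applies to a single criterion")
      }
      other <- merge_other_pips(pip_records, target)
      sets$PIP_other <- other
    }
  } else if (form %in% c("part2_multivariable", "part2_interaction")) {
    if (is.null(part2_records)) stop("part-2 forms require part2_records")
    codes <- group_codes(target, unique(part2_records$med$criterion_code))
    med <- combine_pip_records(part2_records$med, codes)
    sets <- list(meds = med)
    if (form == "part2_interaction") sets$PPI <- part2_records$ppi
  } else {
    stop("unknown model form: ", form)
  }
  rows <- build_model_rows(patients, sets, bleedings, study_start,
                           age_splits = age_splits)
  covs <- names(sets)
  if (form == "part2_interaction") {
    rows$meds_PPI <- rows$meds * rows$PPI
    covs <- c(covs, "meds_PPI")
  }
  covs <- c(covs, "age", "sex_male")
  structure(list(rows = rows, covariate_names = covs, model_tag = form,
                 target = target),
            class = "pip_model_dataset")
}

#' Theoretical maximum number of sequences in a study window
#'
#' A patient present for the entire window whose exposure status changes
#' every day generates one sequence per day boundary: the number of days in
#' the closed window minus one. For the default 2007-01-01 to 2014-12-31
#' window (2922 days) this is 2921.
#'
#' @param study_start,study_end `Date` window bounds (inclusive).
#' @return integer.
#' @export
max_sequences <- function(study_start = as.Date("2007-01-01"),
                          study_end = as.Date("2014-12-31")) {
  as.integer(as.Date(study_end) - as.Date(study_start) + 1L) - 1L
}
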