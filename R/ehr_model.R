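#' Read a four-table primary-care cohort from CSV files
#'
#' A cohort is the quartet of tables exported from a general-practice EHR:
#' patients (one row per person with observation window and demographics),
#' prescriptions (ATC-coded drug issues with inclusive start/end dates and a
#' resolved daily dose in mg), diagnoses (ICPC-coded events) and journal
#' notes (free text with an optional ICPC code). Dates are ISO 8601
#' (`YYYY-MM-DD`); sex is coded `"F"`/`"M"`. Every row is validated against
#' the type invariants; any violation is reported with its table, line and
#' patient id, and the read aborts.
#'
#' @param patients,prescriptions,diagnoses,notes paths to the four CSV files.
#' @return A list of class `pip_cohort` with elements `patients`,
#'   `prescriptions`, `diagnoses`, `notes` (typed data.frames).
#' @seealso [write_cohort()], [validate_cohort()]
#' @export
read_cohort <- function(patients, prescriptions, diagnoses, notes) {
  paths <- c(patients = patients, prescriptions = prescriptions,
             diagnoses = diagnoses, notes = notes)
  for (p in paths) {
    if (!file.exists(p)) stop("input file not found: ", p)
  }
  rd <- function(path) {
    as.data.frame(fread(path, colClasses = "character", na.strings = "",
                        encoding = "UTF-8"))
  }
  raw <- lapply(paths, rd)
  cohort <- list(
    patients = parse_patients(raw$patients),
    prescriptions = parse_prescriptions(raw$prescriptions),
    diagnoses = parse_diagnoses(raw$diagnoses),
    notes = parse_notes(raw$notes)
  )
  errs <- validate_cohort(cohort)
  if (length(errs)) {
    stop("cohort validation failed:\n", paste(errs, collapse = "\n"))
  }
  class(cohort) <- "pip_cohort"
  cohort
}

parse_date_col <- function(x, table, col) {
  d <- as.Date(x, format = "%Y-%m-%d")
  bad <- which(!is.na(x) & is.na(d))
  if (length(bad)) {
    stop(sprintf("%s: unparseable %s on line(s) %s", table, col,
                 paste(bad + 1L, collapse = ", ")))
  }
  d
}

require_cols <- function(x, cols, table) {
  miss <- setdiff(cols, names(x))
  if (length(miss)) {
    stop(sprintf("%s: missing column(s) %s", table,
                 paste(miss, collapse = ", ")))
  }
}

parse_patients <- function(x) {
  require_cols(x, c("patient_id", "birth_date", "sex", "entry_date",
                    "exit_date", "exit_reason"), "patients")
  data.frame(
    patient_id = x$patient_id,
    birth_date = parse_date_col(x$birth_date, "patients", "birth_date"),
    sex = x$sex,
    entry_date = parse_date_col(x$entry_date, "patients", "entry_date"),
    exit_date = parse_date_col(x$exit_date, "patients", "exit_date"),
    exit_reason = x$exit_reason
  )
}

parse_prescriptions <- function(x) {
  require_cols(x, c("patient_id", "atc_code", "start_date", "end_date",
                    "daily_dose_mg"), "prescriptions")
  dose <- suppressWarnings(as.numeric(x$daily_dose_mg))
  bad <- which(!is.na(x$daily_dose_mg) & is.na(dose))
  if (length(bad)) {
    stop("prescriptions: unparseable daily_dose_mg on line(s) ",
         paste(bad + 1L, collapse = ", "))
  }
  data.frame(
    patient_id = x$patient_id,
    atc_code = x$atc_code,
    start_date = parse_date_col(x$start_date, "prescriptions", "start_date"),
    end_date = parse_date_col(x$end_date, "prescriptions", "end_date"),
    daily_dose_mg = dose
  )
}

parse_diagnoses <- function(x) {
  require_cols(x, c("patient_id", "icpc_code", "date"), "diagnoses")
  data.frame(
    patient_id = x$patient_id,
    icpc_code = x$icpc_code,
    date = parse_date_col(x$date, "diagnoses", "date")
  )
}

parse_notes <- function(x) {
  require_cols(x, c("patient_id", "date", "icpc_code", "text"), "notes")
  data.frame(
    patient_id = x$patient_id,
    date = parse_date_col(x$date, "notes", "date"),
    icpc_code = x$icpc_code,
    text = ifelse(is.na(x$text), "", x$text)
  )
}

#' Validate cohort tables against their invariants
#'
#' Checks row-level invariants: `entry_date <= exit_date`, prescription
#' `start_date <= end_date`, non-empty ATC codes, non-negative doses, ICPC
#' codes of the form letter + two digits, sex in `F`/`M`, exit reason in
#' `study_end`/`death`/`left_practice`. When study bounds are supplied the
#' observation-window invariants are also checked: entry at or after the
#' later of the study start and the 65th birthday, exit at or before the
#' study end.
#'
#' @param cohort list with `patients`, `prescriptions`, `diagnoses`, `notes`.
#' @param study_start,study_end optional `Date` study window bounds.
#' @return Character vector of row-level diagnostics (empty when valid).
#' @export
validate_cohort <- function(cohort, study_start = NULL, study_end = NULL) {
  errs <- character()
  say <- function(table, line, pid, msg) {
    sprintf("%s line %d (patient %s): %s", table, line + 1L, pid, msg)
  }
  p <- cohort$patients
  if (nrow(p)) {
    for (i in which(is.na(p$entry_date) | is.na(p$exit_date) |
                    is.na(p$birth_date))) {
      errs <- c(errs, say("patients", i, p$patient_id[i], "missing date"))
    }
    for (i in which(!is.na(p$entry_date) & !is.na(p$exit_date) &
                    p$entry_date > p$exit_date)) {
      errs <- c(errs, say("patients", i, p$patient_id[i],
                          "entry_date after exit_date"))
    }
    for (i in which(!p$sex %in% c("F", "M"))) {
      errs <- c(errs, say("patients", i, p$patient_id[i],
                          paste0("invalid sex '", p$sex[i], "'")))
    }
    for (i in which(!p$exit_reason %in% c("study_end", "death",
                                          "left_practice"))) {
      errs <- c(errs, say("patients", i, p$patient_id[i],
                          paste0("invalid exit_reason '", p$exit_reason[i], "'")))
    }
    if (!is.null(study_start)) {
      ok <- !is.na(p$entry_date) & !is.na(p$birth_date)
      floor65 <- pmax(as.Date(study_start), anniversary(p$birth_date, 65L))
      for (i in which(ok & p$entry_date < floor65)) {
        errs <- c(errs, say("patients", i, p$patient_id[i],
                            "entry before max(study start, 65th birthday)"))
      }
    }
    if (!is.null(study_end)) {
      for (i in which(!is.na(p$exit_date) & p$exit_date > as.Date(study_end))) {
        errs <- c(errs, say("patients", i, p$patient_id[i],
                            "exit after study end"))
      }
    }
  }
  rx <- cohort$prescriptions
  if (nrow(rx)) {
    for (i in which(is.na(rx$start_date) | is.na(rx$end_date))) {
      errs <- c(errs, say("prescriptions", i, rx$patient_id[i], "missing date"))
    }
    for (i in which(!is.na(rx$start_date) & !is.na(rx$end_date) &
                    rx$start_date > rx$end_date)) {
      errs <- c(errs, say("prescriptions", i, rx$patient_id[i],
                          "end_date before start_date"))
    }
    for (i in which(is.na(rx$atc_code) | rx$atc_code == "")) {
      errs <- c(errs, say("prescriptions", i, rx$patient_id[i],
                          "empty atc_code"))
    }
    for (i in which(!is.na(rx$daily_dose_mg) & rx$daily_dose_mg < 0)) {
      errs <- c(errs, say("prescriptions", i, rx$patient_id[i],
                          "negative daily_dose_mg"))
    }
  }
  dx <- cohort$diagnoses
  if (nrow(dx)) {
    for (i in which(!grepl("^[A-Z][0-9]{2}$", dx$icpc_code))) {
      errs <- c(errs, say("diagnoses", i, dx$patient_id[i],
                          paste0("invalid ICPC code '", dx$icpc_code[i], "'")))
    }
    for (i in which(is.na(dx$date))) {
      errs <- c(errs, say("diagnoses", i, dx$patient_id[i], "missing date"))
    }
  }
  nt <- cohort$notes
  if (nrow(nt)) {
    for (i in which(is.na(nt$date))) {
      errs <- c(errs, say("notes", i, nt$patient_id[i], "missing date"))
    }
    for (i in which(!is.na(nt$icpc_code) &
                    !grepl("^[A-Z][0-9]{2}$", nt$icpc_code))) {
      errs <- c(errs, say("notes", i, nt$patient_id[i],
                          paste0("invalid ICPC code '", nt$icpc_code[i], "'")))
    }
  }
  errs
}

#' Write a cohort to four CSV files
#'
#' Inverse of [read_cohort()]: dates are serialized as `YYYY-MM-DD`, missing
#' values as empty fields, UTF-8 throughout, so a written cohort re-reads
#' identically.
#'
#' @param cohort a cohort list as returned by [read_cohort()] or
#'   [generate_cohort()].
#' @param patients,prescriptions,diagnoses,notes output file paths.
#' @return Invisibly, the vector of paths written.
#' @export
write_cohort <- function(cohort, patients, prescriptions, diagnoses, notes) {
  wr <- function(x, path) {
    x <- as.data.frame(x)
    for (col in names(x)) {
      if (inherits(x[[col]], "Date")) x[[col]] <- format(x[[col]], "%Y-%m-%d")
    }
    fwrite(x, path, na = "", quote = "auto", bom = FALSE)
  }
  wr(cohort$patients, patients)
  wr(cohort$prescriptions, prescriptions)
  wr(cohort$diagnoses, diagnoses)
  wr(cohort$notes, notes)
  invisible(c(patients, prescriptions, diagnoses, notes))
}

#' Birthday anniversary of a birth date
#'
#' The k-th anniversary of `birth`. Leap-day births (Feb 29) anniversary on
#' Mar 1 in non-leap years, the civil convention under which a person ages
#' one completed year only once the full year has elapsed.
#'
#' @param birth `Date` vector of birth dates.
#' @param k integer vector of years to add (recycled).
#' @return `Date` vector of anniversary dates.
#' @export
anniversary <- function(birth, k) {
  birth <- as.Date(birth)
  bl <- as.POSIXlt(birth)
  y <- bl$year + 1900L + as.integer(k)
  m <- bl$mon + 1L
  d <- bl$mday
  # civil date -> days since 1970-01-01, pure vector arithmetic; an
  # out-of-range Feb 29 rolls over to Mar 1, which is exactly the leap-day
  # anniversary convention
  yy <- ifelse(m <= 2L, y - 1L, y)
  era <- ifelse(yy >= 0L, yy, yy - 399L) %/% 400L
  yoe <- yy - era * 400L
  mp <- ifelse(m > 2L, m - 3L, m + 9L)
  doy <- (153L * mp + 2L) %/% 5L + d - 1L
  doe <- yoe * 365L + yoe %/% 4L - yoe %/% 100L + doy
  as.Date(era * 146097L + doe - 719468L, origin = "1970-01-01")
}

#' Age in completed years on a given date
#'
#' Floor of elapsed whole years under the birthday-anniversary convention
#' (see [anniversary()] for the leap-day rule). Vectorized with recycling.
#'
#' @param birth_date,on_date `Date` vectors; `on_date >= birth_date`.
#' @return Integer vector of completed years.
#' @examples
#' compute_age("1940-03-01", "2005-02-28") # 64
#' compute_age("1940-03-01", "2005-03-01") # 65
#' @export
compute_age <- function(birth_date, on_date) {
  birth <- as.Date(birth_date)
  on <- as.Date(on_date)
  n <- max(length(birth), length(on))
  birth <- rep_len(birth, n)
  on <- rep_len(on, n)
  if (any(on < birth)) stop("on_date before birth_date")
  yrs <- as.POSIXlt(on)$year - as.POSIXlt(birth)$year
  ann <- anniversary(birth, yrs)
  as.integer(yrs - (ann > on))
}

#' @export
print.pip_cohort <- function(x, ...) {
  cat("pip_cohort:",
      nrow(x$patients), "patients,",
      nrow(x$prescriptions), "prescriptions,",
      nrow(x$diagnoses), "diagnoses,",
      nrow(x$notes), "notes\n")
  invisible(x)
}
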