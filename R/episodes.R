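#' Default gap days per drug class
#'
#' Number of days added to the expiration date of every prescription of a
#' class before merging into drug episodes. Consecutive scripts whose
#' original gap does not exceed this value are treated as one uninterrupted
#' episode of use; the allowance reflects the clearance properties of each
#' medication (antiplatelet effects of ASA/ECC outlast the last tablet by
#' several days, NSAIDs and PPIs by fewer).
#'
#' @return Named integer vector: drug class -> gap days
#'   (ASA_ECC 5, platelet_inhibitor 4, NSAID 3, PPI 3,
#'   oral_anticoagulant 2, corticosteroid 2, SSRI 2).
#' @export
default_gap_days <- function() {
  c(ASA_ECC = 5L, platelet_inhibitor = 4L, NSAID = 3L, PPI = 3L,
    oral_anticoagulant = 2L, corticosteroid = 2L, SSRI = 2L)
}

#' Default ATC prefix to drug-class mapping
#'
#' Longest-prefix mapping from ATC codes to the seven drug classes used by
#' the criteria. `B01AC06`/`N02BA01` (acetylsalicylic acid) and
#' `B01AC08`/`N02BA15` (carbasalate calcium) are split out of the broader
#' antiplatelet group `B01AC` into the `ASA_ECC` class. Fully overridable.
#'
#' @return Named character vector: ATC prefix -> drug class.
#' @export
default_atc_map <- function() {
  c(A02BC = "PPI",
    M01A = "NSAID",
    B01AC06 = "ASA_ECC", N02BA01 = "ASA_ECC",
    B01AC08 = "ASA_ECC", N02BA15 = "ASA_ECC",
    B01AC = "platelet_inhibitor",
    B01AA = "oral_anticoagulant", B01AE = "oral_anticoagulant",
    B01AF = "oral_anticoagulant",
    H02AB = "corticosteroid",
    N06AB = "SSRI")
}

#' Map ATC codes to drug classes
#'
#' Longest matching prefix wins, so `B01AC06` resolves to `ASA_ECC` even
#' though `B01AC` maps to `platelet_inhibitor`. Codes with no matching
#' prefix return `NA` (the drug plays no role in the criteria).
#'
#' @param atc character vector of ATC codes.
#' @param atc_map named prefix map, see [default_atc_map()].
#' @return Character vector of drug classes (`NA` when unmapped).
#' @export
atc_class <- function(atc, atc_map = default_atc_map()) {
  prefixes <- names(atc_map)[order(nchar(names(atc_map)))]
  out <- rep(NA_character_, length(atc))
  for (p in prefixes) {
    out[startsWith(atc, p)] <- atc_map[[p]]
  }
  out
}

#' Extend prescriptions by gap days and merge into drug episodes
#'
#' Each prescription's end date is extended by `gap_days`; any two extended
#' intervals that then overlap or touch are merged into one episode with the
#' earliest start and latest extended end. The two textbook formulations --
#' "merge when scripts are at most `gap_days` apart" and "extend every
#' expiration date by `gap_days`, then merge what touches" -- coincide under
#' the closed-interval touch rule, and the latter is implemented as the
#' single source of truth. The extension applies to every script including
#' the last, so an episode ends `gap_days` after its final script.
#'
#' @param prescriptions data.frame of prescriptions of one patient and one
#'   drug class (`patient_id`, `start_date`, `end_date`, optionally
#'   `daily_dose_mg` and `drug_class`).
#' @param gap_days non-negative integer.
#' @return data.frame of episodes: `patient_id`, `drug_class` (if given),
#'   `start`, `end`, `max_daily_dose_mg`, `n_scripts`.
#' @examples
#' rx <- data.frame(patient_id = "p1",
#'                  start_date = as.Date(c("2010-01-01", "2010-01-14")),
#'                  end_date = as.Date(c("2010-01-10", "2010-01-20")),
#'                  daily_dose_mg = c(100, 100))
#' extend_and_merge(rx, gap_days = 3L)  # one episode Jan 1 - Jan 23
#' @export
extend_and_merge <- function(prescriptions, gap_days) {
  stopifnot(length(gap_days) == 1L, gap_days >= 0)
  x <- as.data.frame(prescriptions)
  cls <- if ("drug_class" %in% names(x)) unique(x$drug_class) else NULL
  if (nrow(x) == 0L) {
    return(data.frame(patient_id = character(), start = as.Date(character()),
                      end = as.Date(character()),
                      max_daily_dose_mg = numeric(), n_scripts = integer()))
  }
  if (length(unique(x$patient_id)) > 1L) {
    stop("extend_and_merge expects prescriptions of a single patient")
  }
  if (!is.null(cls) && length(cls) > 1L) {
    stop("extend_and_merge expects prescriptions of a single drug class")
  }
  dt <- data.table(id = x$patient_id,
                   s = as.integer(as.Date(x$start_date)),
                   e = as.integer(as.Date(x$end_date)) + as.integer(gap_days),
                   v = if ("daily_dose_mg" %in% names(x))
                     as.numeric(x$daily_dose_mg) else NA_real_)
  dt[, n := 1L]
  setorder(dt, id, s, e)
  dt[, ce := cummax(e)]
  prev <- shift(dt$ce)
  dt[, g := cumsum(is.na(prev) | s > prev + 1L)]
  out <- dt[, .(id = id[1L], s = s[1L], e = max(e),
                v = if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE),
                n = .N), by = g]
  res <- data.frame(patient_id = out$id,
                    start = as.Date(out$s, origin = "1970-01-01"),
                    end = as.Date(out$e, origin = "1970-01-01"),
                    max_daily_dose_mg = out$v,
                    n_scripts = out$n)
  if (!is.null(cls)) res <- cbind(res[1], drug_class = cls, res[-1])
  res
}

# Cohort-level episode builder: one canonical episode table per drug class.
# Returns data.table(id, s, e, v = max daily dose) keyed by class in a list.
build_class_episodes <- function(rx_dt, gap_days = default_gap_days()) {
  classes <- names(gap_days)
  out <- vector("list", length(classes))
  names(out) <- classes
  for (cl in classes) {
    sub <- rx_dt[drug_class == cl,
                 .(id, s, e = e + as.integer(gap_days[[cl]]), v = dose)]
    out[[cl]] <- iv_merge_g(sub, keep_max = TRUE)
  }
  out
}

# Prescriptions data.frame -> internal data.table with integer days + class.
rx_to_dt <- function(prescriptions, atc_map = default_atc_map()) {
  rx <- as.data.table(prescriptions)
  data.table(id = rx$patient_id,
             s = as.integer(as.Date(rx$start_date)),
             e = as.integer(as.Date(rx$end_date)),
             dose = if ("daily_dose_mg" %in% names(rx))
               as.numeric(rx$daily_dose_mg) else NA_real_,
             atc = rx$atc_code,
             drug_class = atc_class(rx$atc_code, atc_map))
}
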