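#' Keyword configuration for free-text bleeding detection
#'
#' GP journal notes are screened for gastrointestinal bleeding with a
#' two-list conjunction: the note must contain at least one *anchor* term (a
#' Dutch "bleed" stem) and at least one *context* term (stomach / digestive
#' / gastro stems and common abbreviations of "tract" and "digest").
#' Matching is case-insensitive substring matching on diacritic-stripped
#' text. A matching note counts only when its attached ICPC code is
#' non-specific (or absent); notes carrying a specific ICPC code for a
#' different diagnosis are excluded.
#'
#' @param anchor_terms Dutch bleeding stems (default `"bloed"`).
#' @param context_terms gastrointestinal context stems.
#' @param nonspecific_icpc general ICPC codes compatible with an otherwise
#'   uncoded bleeding note.
#' @param exclusion_icpc specific ICPC codes marking a different diagnosis.
#' @param collapse_days events of one patient closer than this many days
#'   are regarded as the same bleeding (see [combine_events()]).
#' @return list of class `keyword_config`.
#' @export
keyword_config <- function(anchor_terms = "bloed",
                           context_terms = c("maag", "gastro", "verter",
                                             "tract", "dig"),
                           nonspecific_icpc = c("A99", "D99"),
                           exclusion_icpc = c("R06", "D84", "U06", "W03"),
                           collapse_days = 30L) {
  stopifnot(length(anchor_terms) > 0L, length(context_terms) > 0L)
  structure(list(anchor_terms = tolower(anchor_terms),
                 context_terms = tolower(context_terms),
                 nonspecific_icpc = nonspecific_icpc,
                 exclusion_icpc = exclusion_icpc,
                 collapse_days = as.integer(collapse_days)),
            class = "keyword_config")
}

#' ICPC codes defining a coded gastrointestinal bleeding
#'
#' Hematemesis (D14), melena (D15), duodenal ulcer (D85) and other stomach
#' ulcers (D86).
#'
#' @return character vector of the four codes.
#' @export
bleeding_icpc_codes <- function() c("D14", "D15", "D85", "D86")

normalize_text <- function(x) {
  x <- tolower(x)
  out <- suppressWarnings(iconv(x, from = "UTF-8", to = "ASCII//TRANSLIT"))
  ifelse(is.na(out), x, out)
}

contains_any <- function(text, terms) {
  hit <- rep(FALSE, length(text))
  for (term in terms) hit <- hit | grepl(term, text, fixed = TRUE)
  hit
}

clip_to_window <- function(events, patients) {
  if (is.null(patients) || nrow(events) == 0L) return(events)
  idx <- match(events$patient_id, patients$patient_id)
  keep <- !is.na(idx) &
    events$date >= as.Date(patients$entry_date)[idx] &
    events$date <= as.Date(patients$exit_date)[idx]
  events[keep, , drop = FALSE]
}

#' Detect bleeding events from coded diagnoses
#'
#' One event per patient per day carrying any of the bleeding ICPC codes.
#' When patients are supplied, events outside the observation window are
#' dropped.
#'
#' @param diagnoses data.frame: `patient_id`, `icpc_code`, `date`.
#' @param patients optional patients table for window clipping.
#' @param codes bleeding ICPC codes, see [bleeding_icpc_codes()].
#' @return data.frame: `patient_id`, `date`, `source = "icpc"`, `matched`.
#' @export
detect_by_icpc <- function(diagnoses, patients = NULL,
                           codes = bleeding_icpc_codes()) {
  hits <- diagnoses[diagnoses$icpc_code %in% codes, , drop = FALSE]
  ev <- data.frame(patient_id = hits$patient_id,
                   date = as.Date(hits$date),
                   source = rep("icpc", nrow(hits)),
                   matched = hits$icpc_code)
  ev <- ev[order(ev$patient_id, ev$date, ev$matched), , drop = FALSE]
  ev <- ev[!duplicated(ev[c("patient_id", "date")]), , drop = FALSE]
  clip_to_window(ev, patients)
}

#' Detect bleeding events from free-text journal notes
#'
#' A note yields an event iff its normalized text contains at least one
#' anchor term and at least one context term, its attached ICPC code is in
#' the non-specific set or absent, and not in the exclusion set.
#'
#' @param notes data.frame: `patient_id`, `date`, `icpc_code`, `text`.
#' @param config a [keyword_config()].
#' @param patients optional patients table for window clipping.
#' @return data.frame: `patient_id`, `date`, `source = "free_text"`,
#'   `matched` (the matched keywords).
#' @export
detect_by_freetext <- function(notes, config = keyword_config(),
                               patients = NULL) {
  txt <- normalize_text(notes$text)
  anchor <- contains_any(txt, config$anchor_terms)
  context <- contains_any(txt, config$context_terms)
  icpc <- notes$icpc_code
  code_ok <- (is.na(icpc) | icpc == "" | icpc %in% config$nonspecific_icpc) &
    !(icpc %in% config$exclusion_icpc)
  hits <- which(anchor & context & code_ok)
  matched <- vapply(hits, function(i) {
    terms <- c(config$anchor_terms, config$context_terms)
    paste(terms[vapply(terms, grepl, logical(1), x = txt[i], fixed = TRUE)],
          collapse = "+")
  }, character(1))
  ev <- data.frame(patient_id = notes$patient_id[hits],
                   date = as.Date(notes$date[hits]),
                   source = rep("free_text", length(hits)),
                   matched = matched)
  ev <- ev[order(ev$patient_id, ev$date), , drop = FALSE]
  ev <- ev[!duplicated(ev[c("patient_id", "date")]), , drop = FALSE]
  clip_to_window(ev, patients)
}

#' Combine coded and free-text bleeding events
#'
#' Union of the two channels. When both fire for the same patient and day
#' the coded event wins. A new event less than `collapse_days` after the
#' patient's previous retained event is regarded as the same bleeding and
#' collapsed into it, so distinct bleedings are at least `collapse_days`
#' apart.
#'
#' @param icpc_events,text_events event data.frames from [detect_by_icpc()]
#'   and [detect_by_freetext()].
#' @param collapse_days minimum day separation of distinct bleedings.
#' @return data.frame of distinct events: `patient_id`, `date`, `source`,
#'   `matched`, sorted by patient and date.
#' @export
combine_events <- function(icpc_events, text_events, collapse_days = 30L) {
  ev <- rbind(icpc_events, text_events)
  if (nrow(ev) == 0L) return(ev)
  # coded source wins the same-day dedup
  ev <- ev[order(ev$patient_id, ev$date,
                 match(ev$source, c("icpc", "free_text"))), , drop = FALSE]
  ev <- ev[!duplicated(ev[c("patient_id", "date")]), , drop = FALSE]
  keep <- logical(nrow(ev))
  last_id <- ""
  last_day <- -Inf
  day <- as.numeric(ev$date)
  for (i in seq_len(nrow(ev))) {
    if (ev$patient_id[i] != last_id || day[i] - last_day >= collapse_days) {
      keep[i] <- TRUE
      last_id <- ev$patient_id[i]
      last_day <- day[i]
    }
  }
  rownames(ev) <- NULL
  ev[keep, , drop = FALSE]
}

#' Detect all gastrointestinal bleedings in a cohort
#'
#' Convenience wrapper: runs both channels, clips to observation windows
#' and combines with the distinctness rule.
#'
#' @param cohort a cohort list.
#' @param config a [keyword_config()].
#' @return data.frame of distinct bleeding events.
#' @export
detect_bleedings <- function(cohort, config = keyword_config()) {
  icpc <- detect_by_icpc(cohort$diagnoses, cohort$patients)
  text <- detect_by_freetext(cohort$notes, config, cohort$patients)
  combine_events(icpc, text, config$collapse_days)
}
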