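#' Write and read criteria configuration as YAML
#'
#' The criteria catalogue (criterion blocks with drug classes, age bounds,
#' dose thresholds, history codes), the gap-day table and the ATC class map
#' round-trip through a single YAML document, so a run can be reproduced or
#' overridden from a plain-text file.
#'
#' @param criteria named list of [criterion_spec()] objects.
#' @param gap_days named gap-day vector.
#' @param atc_map named ATC prefix map.
#' @param path output file path.
#' @return `write_criteria_yaml`: invisibly, the path.
#' @export
write_criteria_yaml <- function(path, criteria = default_criteria(),
                                gap_days = default_gap_days(),
                                atc_map = default_atc_map()) {
  doc <- list(
    gap_days = as.list(gap_days),
    atc_map = as.list(atc_map),
    criteria = lapply(criteria, function(s) {
      out <- unclass(s)
      out$dose_threshold_mg <- if (is.null(s$dose_threshold_mg)) NULL else
        as.list(s$dose_threshold_mg)
      out[!vapply(out, function(v) length(v) == 1L && is.na(v), logical(1))]
    })
  )
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' @rdname write_criteria_yaml
#' @return `read_criteria_yaml`: list with `criteria`, `gap_days`,
#'   `atc_map`.
#' @export
read_criteria_yaml <- function(path) {
  doc <- yaml::read_yaml(path)
  criteria <- lapply(doc$criteria, function(b) {
    criterion_spec(
      code = b$code, kind = b$kind,
      primary_classes = unlist(b$primary_classes),
      companion_classes = unlist(b$companion_classes) %||% character(),
      history_icpc = unlist(b$history_icpc) %||% character(),
      age_min = b$age_min %||% NA_integer_,
      age_max = b$age_max %||% NA_integer_,
      dose_threshold_mg = if (is.null(b$dose_threshold_mg)) NULL else
        unlist(b$dose_threshold_mg),
      min_duration_days = b$min_duration_days %||% NA_integer_,
      ppi_protective = b$ppi_protective %||% (b$kind == "START")
    )
  })
  names(criteria) <- vapply(criteria, `[[`, character(1), "code")
  list(criteria = criteria,
       gap_days = unlist(doc$gap_days),
       atc_map = unlist(doc$atc_map))
}

#' Write and read a simulation configuration as YAML
#'
#' Serializes a [simulation_config()] (including the per-class drug
#' parameters) so a simulated study is fully described by a plain-text
#' manifest; the seed is part of the document.
#'
#' @param config a [simulation_config()].
#' @param path file path.
#' @return `write_simulation_yaml`: invisibly, the path;
#'   `read_simulation_yaml`: a `simulation_config`.
#' @export
write_simulation_yaml <- function(config, path) {
  doc <- unclass(config)
  doc$study_start <- format(doc$study_start)
  doc$study_end <- format(doc$study_end)
  doc$drug_params <- lapply(doc$drug_params, function(pp) {
    pp$agents <- as.list(pp$agents)
    pp
  })
  doc$history_probs <- as.list(doc$history_probs)
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' @rdname write_simulation_yaml
#' @export
read_simulation_yaml <- function(path) {
  doc <- yaml::read_yaml(path)
  doc$drug_params <- lapply(doc$drug_params, function(pp) {
    pp$agents <- as.data.frame(pp$agents)
    pp
  })
  doc$history_probs <- unlist(doc$history_probs)
  doc$seed <- doc$seed %||% NULL
  do.call(simulation_config, doc)
}
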