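#' Fit a Cox model on counting-process rows with clustered robust variance
#'
#' Maximizes the Cox partial likelihood on `(t_start, t_stop]` risk sets
#' (Efron tie handling; the day grid guarantees ties) via
#' [survival::coxph()], treating all rows of one participant as a cluster
#' for the robust sandwich variance. Hazard ratios are `exp(coef)`, 95%
#' Wald confidence limits use `exp(coef +/- 1.959964 * robust SE)` and
#' p-values are two-sided Wald tests on the robust SE.
#'
#' A covariate whose events all fall on one side (e.g. no bleeding ever
#' occurs during exposure) has no finite partial-likelihood maximizer; such
#' monotone-likelihood estimates are flagged non-estimable (divergence past
#' `|coef| > 15` or non-convergence) rather than reported as numbers.
#'
#' @param dataset a `pip_model_dataset` from [assemble_model_dataset()], or
#'   a list with `rows` (counting-process data.frame) and
#'   `covariate_names`.
#' @return Object of class `pip_cox_fit`: `coefficients` (one row per
#'   covariate with `coef`, `robust_se`, `naive_se`, `hazard_ratio`,
#'   `ci95_low`, `ci95_high`, `p_value`, `estimable`), `vcov` (robust),
#'   `n_rows`, `n_events`, `convergence_flag`, `monotone_likelihood_flag`,
#'   `model_tag`.
#' @export
fit_cox <- function(dataset) {
  rows <- dataset$rows
  covs <- dataset$covariate_names
  if (is.null(rows) || nrow(rows) == 0L) stop("empty dataset")
  if (sum(rows$event) == 0L) stop("no events in dataset")
  if (nrow(unique(rows[covs])) < 2L) {
    stop("fewer than 2 distinct covariate patterns")
  }
  f <- as.formula(paste("survival::Surv(t_start, t_stop, event) ~",
                        paste(covs, collapse = " + ")))
  warns <- character()
  fit <- withCallingHandlers(
    survival::coxph(f, data = rows, cluster = patient_id, ties = "efron",
                    control = survival::coxph.control(iter.max = 50)),
    warning = function(w) {
      warns <<- c(warns, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  beta <- fit$coefficients
  rse <- sqrt(diag(fit$var))
  if (length(rse) < length(beta)) rse <- rep(NA_real_, length(beta))
  # coxph omits naive.var when a coefficient is inestimable (singular fit)
  nse <- if (is.null(fit$naive.var)) rep(NA_real_, length(beta)) else
    sqrt(diag(fit$naive.var))
  z975 <- 1.959964
  diverged <- !is.finite(beta) | abs(beta) > 15
  ran_out <- any(grepl("Ran out of iterations|did not converge", warns))
  infinite_warn <- any(grepl("infinite", warns))
  estimable <- !diverged & is.finite(rse) & !ran_out
  tab <- data.frame(
    term = names(beta),
    coef = unname(beta),
    robust_se = unname(rse),
    naive_se = unname(nse),
    hazard_ratio = exp(unname(beta)),
    ci95_low = exp(unname(beta) - z975 * unname(rse)),
    ci95_high = exp(unname(beta) + z975 * unname(rse)),
    p_value = 2 * pnorm(-abs(unname(beta) / unname(rse))),
    estimable = estimable
  )
  tab[!tab$estimable, c("hazard_ratio", "ci95_low", "ci95_high")] <- NA_real_
  structure(list(
    model_tag = dataset$model_tag,
    target = dataset$target,
    coefficients = tab,
    vcov = fit$var,
    n_rows = nrow(rows),
    n_events = sum(rows$event),
    convergence_flag = !ran_out,
    monotone_likelihood_flag = any(diverged) || infinite_warn || ran_out
  ), class = "pip_cox_fit")
}

#' @export
print.pip_cox_fit <- function(x, ...) {
  cat("Cox fit (", x$model_tag %||% "model", "), ",
      x$n_events, " events on ", x$n_rows, " rows\n", sep = "")
  tab <- x$coefficients
  tab[-1] <- lapply(tab[-1], function(v) if (is.numeric(v)) signif(v, 4) else v)
  print(tab, row.names = FALSE)
  if (x$monotone_likelihood_flag) {
    cat("note: monotone likelihood; flagged estimates are non-estimable\n")
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' The full analysis battery
#'
#' One plan entry per fitted model: the all-combined, STARTs-combined and
#' STOPPs-combined part-1 models (age/sex adjustment only), the nine
#' individual criteria in both the multivariable and the confounder-adjusted
#' part-1 forms, the six START criteria plus the all-STARTs group in the
#' part-2 multivariable and interaction forms, and the sensitivity
#' analyses on the subpopulation
#' with at least one bleeding (all STARTs taken as one exposure, and
#' START D3B / START D3C separately).
#'
#' @param criteria named list of criteria (default [default_criteria()]).
#' @return data.frame with columns `label`, `target`, `form`, `population`.
#' @export
default_analysis_plan <- function(criteria = default_criteria()) {
  codes <- names(criteria)
  starts <- grep("^START", codes, value = TRUE)
  plan <- rbind(
    data.frame(target = c("ALL", "STARTS", "STOPPS"),
               form = "part1_multivariable", population = "full"),
    data.frame(target = codes, form = "part1_multivariable",
               population = "full"),
    data.frame(target = codes, form = "part1_adjusted", population = "full"),
    data.frame(target = c("STARTS", starts), form = "part2_multivariable",
               population = "full"),
    data.frame(target = c("STARTS", starts), form = "part2_interaction",
               population = "full"),
    data.frame(target = c("STARTS", "START_D3B", "START_D3C"),
               form = "part1_multivariable", population = "bleeding")
  )
  plan$label <- paste(plan$target, plan$form, plan$population, sep = ".")
  plan[c("label", "target", "form", "population")]
}

count_records <- function(records, target) {
  if (is.null(records)) return(NA_integer_)
  codes <- unique(records$criterion_code)
  keep <- switch(target,
                 ALL = codes,
                 STARTS = grep("^START", codes, value = TRUE),
                 STOPPS = grep("^STOPP", codes, value = TRUE),
                 target)
  sum(records$criterion_code %in% keep)
}

#' Run an analysis plan over prepared cohort artifacts
#'
#' Fits one Cox model per plan entry. Entries whose dataset cannot support
#' a fit (no events, no covariate variation, or a monotone likelihood for
#' the exposure) are recorded as non-estimable rows and the run continues.
#' For interaction models the no-PPI stratum hazard ratio is
#' `exp(b_meds)` and the PPI stratum hazard ratio is
#' `exp(b_meds + b_interaction)` with its variance from the robust
#' covariance matrix.
#'
#' @param artifacts list with `patients`, `pip_records`, `part2_records`,
#'   `bleedings`, `study_start`.
#' @param plan data.frame as returned by [default_analysis_plan()].
#' @return list of class `pip_results`: `results` (one summary row per plan
#'   entry, exposure-term hazard ratio, CI, p, record/event counts and
#'   flags) and `fits` (the underlying `pip_cox_fit` objects, `NULL` where
#'   non-estimable).
#' @export
run_plan <- function(artifacts, plan = default_analysis_plan()) {
  fits <- vector("list", nrow(plan))
  names(fits) <- plan$label
  out <- vector("list", nrow(plan))
  for (i in seq_len(nrow(plan))) {
    entry <- plan[i, ]
    pats <- artifacts$patients
    bld <- artifacts$bleedings
    pip <- artifacts$pip_records
    p2 <- artifacts$part2_records
    if (identical(entry$population, "bleeding")) {
      ids <- unique(bld$patient_id)
      pats <- pats[pats$patient_id %in% ids, , drop = FALSE]
      bld <- bld[bld$patient_id %in% ids, , drop = FALSE]
      if (!is.null(pip)) pip <- pip[pip$patient_id %in% ids, , drop = FALSE]
      if (!is.null(p2)) {
        p2 <- list(med = p2$med[p2$med$patient_id %in% ids, , drop = FALSE],
                   ppi = p2$ppi[p2$ppi$patient_id %in% ids, , drop = FALSE])
      }
    }
    n_rec <- if (startsWith(entry$form, "part2")) {
      count_records(p2$med, entry$target)
    } else {
      count_records(pip, entry$target)
    }
    res <- tryCatch({
      ds <- assemble_model_dataset(pats, bld, list(target = entry$target,
                                                   form = entry$form),
                                   pip_records = pip, part2_records = p2,
                                   study_start = artifacts$study_start)
      fit <- fit_cox(ds)
      fits[[i]] <- fit
      expo <- if (startsWith(entry$form, "part2")) "meds" else "PIP"
      co <- fit$coefficients
      row <- co[co$term == expo, ]
      summ <- data.frame(
        label = entry$label, target = entry$target, form = entry$form,
        population = entry$population, n_records = n_rec,
        n_rows = fit$n_rows, n_events = fit$n_events,
        hr = row$hazard_ratio, ci_low = row$ci95_low,
        ci_high = row$ci95_high, p = row$p_value,
        estimable = row$estimable,
        monotone = fit$monotone_likelihood_flag,
        hr_no_ppi = NA_real_, hr_ppi = NA_real_,
        interaction_coef = NA_real_, interaction_p = NA_real_
      )
      if (entry$form == "part2_interaction") {
        im <- co$term == "meds_PPI"
        b_m <- co$coef[co$term == "meds"]
        b_i <- co$coef[im]
        v <- fit$vcov
        idx_m <- which(co$term == "meds")
        idx_i <- which(im)
        se_sum <- sqrt(v[idx_m, idx_m] + v[idx_i, idx_i] +
                         2 * v[idx_m, idx_i])
        if (row$estimable && co$estimable[im]) {
          summ$hr_no_ppi <- exp(b_m)
          summ$hr_ppi <- exp(b_m + b_i)
        }
        summ$interaction_coef <- b_i
        summ$interaction_p <- co$p_value[im]
        attr(fits[[i]], "ppi_stratum_se") <- se_sum
      }
      summ
    }, error = function(err) {
      data.frame(label = entry$label, target = entry$target,
                 form = entry$form, population = entry$population,
                 n_records = n_rec, n_rows = NA_integer_,
                 n_events = NA_integer_, hr = NA_real_, ci_low = NA_real_,
                 ci_high = NA_real_, p = NA_real_, estimable = FALSE,
                 monotone = NA, hr_no_ppi = NA_real_, hr_ppi = NA_real_,
                 interaction_coef = NA_real_, interaction_p = NA_real_)
    })
    out[[i]] <- res
  }
  structure(list(results = do.call(rbind, out), fits = fits),
            class = "pip_results")
}

#' @export
print.pip_results <- function(x, ...) {
  r <- x$results
  num <- vapply(r, is.numeric, logical(1))
  r[num] <- lapply(r[num], signif, 4)
  print(r, row.names = FALSE)
  invisible(x)
}
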