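test_that("perfectly symmetric two-group data gives a zero exposure coefficient", {
  # same event times in exposed and unexposed arms
  rows <- data.frame(
    patient_id = sprintf("p%d", 1:6),
    t_start = 0L, t_stop = c(10L, 20L, 30L, 10L, 20L, 30L),
    event = c(1L, 1L, 0L, 1L, 1L, 0L),
    x = c(1L, 1L, 1L, 0L, 0L, 0L))
  fit <- fit_cox(list(rows = rows, covariate_names = "x", model_tag = "sym"))
  expect_lt(abs(fit$coefficients$coef), 1e-8)
  expect_equal(fit$n_events, 4L)
})

test_that("fit_cox matches the hand-coded partial-likelihood oracle", {
  for (seed in c(101, 102, 103, 104)) {
    ds <- tiny_cox_dataset(seed, n_patients = sample(5:10, 1),
                           two_covs = seed %% 2 == 0)
    fit <- fit_cox(ds)
    if (!all(fit$coefficients$estimable)) next
    oracle <- oracle_cox_coef(ds$rows, ds$covariate_names)
    expect_equal(fit$coefficients$coef, oracle, tolerance = 1e-6,
                 ignore_attr = TRUE)
  }
})

test_that("splitting rows at non-event times leaves estimates unchanged", {
  ds <- tiny_cox_dataset(105, n_patients = 8L, two_covs = TRUE)
  fit <- fit_cox(ds)
  split_rows <- function(rows) {
    out <- lapply(seq_len(nrow(rows)), function(i) {
      r <- rows[i, ]
      if (r$t_stop - r$t_start < 2L) return(r)
      mid <- r$t_start + sample.int(r$t_stop - r$t_start - 1L, 1L)
      a <- r; a$t_stop <- mid; a$event <- 0L
      b <- r; b$t_start <- mid
      rbind(a, b)
    })
    do.call(rbind, out)
  }
  set.seed(106)
  refit <- fit_cox(list(rows = split_rows(ds$rows),
                        covariate_names = ds$covariate_names,
                        model_tag = "split"))
  expect_equal(refit$coefficients$coef, fit$coefficients$coef,
               tolerance = 1e-8)
  expect_equal(refit$coefficients$robust_se, fit$coefficients$robust_se,
               tolerance = 1e-8)
})

test_that("HR, CI and p recompute exactly from coefficient and robust SE", {
  ds <- tiny_cox_dataset(107, n_patients = 10L, two_covs = TRUE)
  co <- fit_cox(ds)$coefficients
  expect_equal(co$hazard_ratio, exp(co$coef))
  expect_equal(co$ci95_low, exp(co$coef - 1.959964 * co$robust_se))
  expect_equal(co$ci95_high, exp(co$coef + 1.959964 * co$robust_se))
  expect_equal(co$p_value, 2 * pnorm(-abs(co$coef / co$robust_se)))
})

test_that("robust and naive SEs agree with one row per patient, no recurrence", {
  set.seed(108)
  n <- 4000L
  rows <- data.frame(patient_id = sprintf("p%d", 1:n), t_start = 0L,
                     x = rbinom(n, 1, 0.4))
  haz <- 0.02 * exp(0.7 * rows$x)
  tt <- rexp(n, haz)
  cens <- runif(n, 20, 80)
  rows$t_stop <- pmin(tt, cens)
  rows$event <- as.integer(tt <= cens)
  fit <- fit_cox(list(rows = rows, covariate_names = "x", model_tag = "iid"))
  co <- fit$coefficients
  expect_lt(abs(co$robust_se / co$naive_se - 1), 0.1)
})

test_that("zero events and degenerate covariates are refused explicitly", {
  rows <- data.frame(patient_id = c("a", "b"), t_start = 0L, t_stop = 10L,
                     event = 0L, x = c(0L, 1L))
  expect_error(fit_cox(list(rows = rows, covariate_names = "x")),
               "no events")
  rows$event <- c(1L, 0L)
  rows$x <- 1L
  expect_error(fit_cox(list(rows = rows, covariate_names = "x")),
               "covariate patterns")
})

test_that("events never occurring during exposure flag a monotone likelihood", {
  set.seed(109)
  n <- 60L
  rows <- data.frame(patient_id = sprintf("p%d", 1:n), t_start = 0L,
                     t_stop = sample(10:50, n, TRUE),
                     event = 0L, x = rep(c(1L, 0L), n / 2))
  rows$event[rows$x == 0L][1:10] <- 1L  # all events unexposed
  fit <- fit_cox(list(rows = rows, covariate_names = "x", model_tag = "mono"))
  expect_true(fit$monotone_likelihood_flag)
  expect_false(fit$coefficients$estimable)
  expect_true(is.na(fit$coefficients$hazard_ratio))
})

test_that("the interaction model is a reparameterization of stratified coding", {
  st <- simulate_study(simulation_config(n_patients = 500L, seed = 110L,
                                         baseline_hazard_per_day = 8e-5))
  bld <- detect_bleedings(st$cohort)
  p2 <- derive_part2_records(st$cohort)
  ds <- assemble_model_dataset(st$cohort$patients, bld,
                               list(target = "STARTS",
                                    form = "part2_interaction"),
                               part2_records = p2,
                               study_start = st$config$study_start)
  fit <- fit_cox(ds)
  co <- fit$coefficients
  expect_true(all(co$estimable))
  # recode: meds split into meds-without-PPI and meds-with-PPI dummies
  rows <- ds$rows
  rows$meds_noppi <- rows$meds * (1L - rows$PPI)
  rows$meds_ppi <- rows$meds * rows$PPI
  refit <- fit_cox(list(rows = rows,
                        covariate_names = c("meds_noppi", "meds_ppi", "PPI",
                                            "age", "sex_male"),
                        model_tag = "recode"))
  rc <- refit$coefficients
  b_meds <- co$coef[co$term == "meds"]
  b_int <- co$coef[co$term == "meds_PPI"]
  expect_equal(rc$coef[rc$term == "meds_noppi"], b_meds, tolerance = 1e-6)
  expect_equal(rc$coef[rc$term == "meds_ppi"], b_meds + b_int,
               tolerance = 1e-6)
})

test_that("run_plan records non-estimable entries and continues", {
  st <- simulate_study(simulation_config(n_patients = 300L, seed = 111L))
  bld <- detect_bleedings(st$cohort)
  artifacts <- list(patients = st$cohort$patients,
                    pip_records = st$ground_truth$pip_records,
                    part2_records = derive_part2_records(st$cohort),
                    bleedings = bld,
                    study_start = st$config$study_start)
  plan <- rbind(
    data.frame(label = "all", target = "ALL", form = "part1_multivariable",
               population = "full"),
    # a criterion no patient triggers in a cohort this small
    data.frame(label = "ghost", target = "STOPP_E5",
               form = "part1_multivariable", population = "full"),
    data.frame(label = "sens", target = "STARTS",
               form = "part1_multivariable", population = "bleeding"))
  res <- run_plan(artifacts, plan)
  expect_equal(nrow(res$results), 3L)
  expect_true(res$results$estimable[1])
  expect_false(isTRUE(res$results$estimable[2]))
  # the sensitivity run restricts to patients with a bleeding
  expect_equal(res$results$n_events[3],
               sum(bld$patient_id %in% st$cohort$patients$patient_id))
})

test_that("the default plan covers the full analysis battery", {
  plan <- default_analysis_plan()
  expect_equal(sum(plan$form == "part1_multivariable" &
                     plan$population == "full"), 12L)  # 3 groups + 9 criteria
  expect_equal(sum(plan$form == "part1_adjusted"), 9L)
  expect_equal(sum(plan$form == "part2_multivariable"), 7L)  # 6 + group
  expect_equal(sum(plan$form == "part2_interaction"), 7L)
  expect_equal(sum(plan$population == "bleeding"), 3L)
})
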