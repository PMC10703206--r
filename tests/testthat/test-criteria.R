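crit <- default_criteria()

test_that("START D2B requires NSAID and completed age at the inclusive boundary", {
  # 70th birthday 2009-12-15: aged exactly 70 throughout Jan 2010
  pat70 <- demo_patient(birth = "1939-12-15")
  nsaid <- demo_episode("NSAID", "2010-01-11", "2010-01-31")
  r <- raw_criterion_intervals(crit$START_D2B, pat70, nsaid)
  expect_equal(r, interval_set("2010-01-11", "2010-01-31"))
  # aged 64: age condition fails
  pat64 <- demo_patient(birth = "1946-01-01", entry = "2011-01-01")
  expect_equal(nrow(raw_criterion_intervals(crit$START_D2B, pat64, nsaid)), 0L)
  # age condition switches on mid-episode, splitting at the birthday
  span <- demo_episode("NSAID", "2009-12-01", "2010-01-15")
  r2 <- raw_criterion_intervals(crit$START_D2B, pat70, span)
  expect_equal(r2, interval_set("2009-12-15", "2010-01-15"))
})

test_that("STOPP A9 dose threshold gates the exposure", {
  pat <- demo_patient(birth = "1939-12-15")
  lo <- demo_episode("ASA_ECC", "2010-02-01", "2010-03-31", dose = 100)
  hi <- demo_episode("ASA_ECC", "2010-02-01", "2010-03-31", dose = 200)
  expect_equal(nrow(raw_criterion_intervals(crit$STOPP_A9, pat, lo)), 0L)
  expect_equal(raw_criterion_intervals(crit$STOPP_A9, pat, hi),
               interval_set("2010-02-01", "2010-03-31"))
})

test_that("ASA above 160 mg/day triggers A9 while ECC needs above 200 in a cohort", {
  mk_rx <- function(atc, dose) {
    data.frame(patient_id = "p1", atc_code = atc,
               start_date = as.Date("2010-02-01"),
               end_date = as.Date("2010-03-31"), daily_dose_mg = dose)
  }
  base <- list(patients = demo_patient(birth = "1939-12-15"),
               diagnoses = empty <- data.frame(patient_id = character(),
                                               icpc_code = character(),
                                               date = as.Date(character())),
               notes = data.frame(patient_id = character(),
                                  date = as.Date(character()),
                                  icpc_code = character(),
                                  text = character()))
  recs <- function(rx) {
    cohort <- c(base[1], list(prescriptions = rx), base[2:3])
    r <- derive_pip_records(cohort)
    r[r$criterion_code == "STOPP_A9", ]
  }
  expect_equal(nrow(recs(mk_rx("N02BA01", 300))), 1L)   # ASA 300 > 160
  expect_equal(nrow(recs(mk_rx("B01AC06", 100))), 0L)   # ASA 100 <= 160
  expect_equal(nrow(recs(mk_rx("B01AC08", 180))), 0L)   # ECC 180 <= 200
  expect_equal(nrow(recs(mk_rx("B01AC08", 240))), 1L)   # ECC 240 > 200
})

test_that("START D3B intersects primary ASA with companion SSRI time", {
  pat75 <- demo_patient(birth = "1934-06-01")
  eps <- rbind(demo_episode("ASA_ECC", "2010-03-01", "2010-03-31"),
               demo_episode("SSRI", "2010-03-15", "2010-04-15"))
  r <- raw_criterion_intervals(crit$START_D3B, pat75, eps)
  expect_equal(r, interval_set("2010-03-15", "2010-03-31"))
})

test_that("STOPP E5 requires gout history and >3 months of continuous NSAID", {
  pat <- demo_patient(birth = "1939-12-15")
  nsaid <- demo_episode("NSAID", "2010-01-01", "2010-06-30")
  gout <- data.frame(patient_id = "p1", icpc_code = "T92",
                     date = as.Date("2007-03-01"))
  r <- raw_criterion_intervals(crit$STOPP_E5, pat, nsaid, gout)
  expect_equal(r, interval_set("2010-04-01", "2010-06-30"))  # day 91 onward
  # no gout history: nothing
  expect_equal(nrow(raw_criterion_intervals(crit$STOPP_E5, pat, nsaid)), 0L)
  # a 60-day episode never qualifies
  short <- demo_episode("NSAID", "2010-01-01", "2010-03-01")
  expect_equal(nrow(raw_criterion_intervals(crit$STOPP_E5, pat, short, gout)),
               0L)
})

test_that("part-1 START records subtract concurrent PPI coverage", {
  pat <- demo_patient(birth = "1939-12-15")
  nsaid <- demo_episode("NSAID", "2010-01-11", "2010-01-31")
  # full protection
  eps_full <- rbind(nsaid, demo_episode("PPI", "2010-01-11", "2010-01-31"))
  expect_equal(nrow(part1_pip_records(crit$START_D2B, pat, eps_full)), 0L)
  # partial protection splits the record
  eps_part <- rbind(nsaid, demo_episode("PPI", "2010-01-20", "2010-01-25"))
  r <- part1_pip_records(crit$START_D2B, pat, eps_part)
  expect_equal(r$start, as.Date(c("2010-01-11", "2010-01-26")))
  expect_equal(r$end, as.Date(c("2010-01-19", "2010-01-31")))
})

test_that("STOPP A15 ignores PPI but requires a prior bleeding disorder", {
  pat <- demo_patient(birth = "1939-12-15")
  eps <- rbind(demo_episode("oral_anticoagulant", "2010-01-01", "2010-01-14"),
               demo_episode("PPI", "2010-01-01", "2010-01-31"))
  b83 <- data.frame(patient_id = "p1", icpc_code = "B83",
                    date = as.Date("2006-01-01"))
  r <- part1_pip_records(crit$STOPP_A15, pat, eps, b83)
  expect_equal(r$start, as.Date("2010-01-01"))
  expect_equal(r$end, as.Date("2010-01-14"))
  # without the diagnosis there is no record
  expect_equal(nrow(part1_pip_records(crit$STOPP_A15, pat, eps)), 0L)
  # diagnosis made mid-episode: record starts at the diagnosis
  late <- data.frame(patient_id = "p1", icpc_code = "B83",
                     date = as.Date("2010-01-08"))
  r2 <- part1_pip_records(crit$STOPP_A15, pat, eps, late)
  expect_equal(r2$start, as.Date("2010-01-08"))
})

test_that("part-2 keeps medication as is and returns PPI coverage alongside", {
  pat <- demo_patient(birth = "1939-12-15")
  eps <- rbind(demo_episode("NSAID", "2010-01-11", "2010-01-31"),
               demo_episode("PPI", "2010-01-20", "2010-01-25"))
  r <- part2_med_records(crit$START_D2B, pat, eps)
  expect_equal(r$med_intervals, interval_set("2010-01-11", "2010-01-31"))
  expect_equal(r$ppi_intervals, interval_set("2010-01-20", "2010-01-25"))
  # no PPI scripts -> empty ppi set
  r2 <- part2_med_records(crit$START_D2B, pat, eps[1, ])
  expect_equal(nrow(r2$ppi_intervals), 0L)
  expect_error(part2_med_records(crit$STOPP_A9, pat, eps), "START")
})

worked_example_records <- data.frame(
  patient_id = "p1",
  criterion_code = c("STOPP_A15", "START_D2B", "START_D2C"),
  start = as.Date(c("2010-01-01", "2010-01-11", "2010-01-08")),
  end = as.Date(c("2010-01-14", "2010-01-31", "2010-01-14")))

test_that("remaining criteria merge into one OTHER confounder record", {
  other <- merge_other_pips(worked_example_records, "STOPP_A15")
  expect_equal(nrow(other), 1L)
  expect_equal(other$criterion_code, "OTHER")
  expect_equal(other$start, as.Date("2010-01-08"))
  expect_equal(other$end, as.Date("2010-01-31"))
  # excluding the only code present leaves nothing
  expect_equal(nrow(merge_other_pips(worked_example_records[1, ], "STOPP_A15")), 0L)
})

test_that("merge_other_pips equals the day-set union of non-excluded codes", {
  set.seed(405)
  for (i in 1:30) {
    codes <- sample(names(crit), 4L)
    recs <- do.call(rbind, lapply(codes, function(cc) {
      iv <- random_interval_set(sample(1:3, 1))
      data.frame(patient_id = "p1", criterion_code = cc,
                 start = iv$start, end = iv$end)
    }))
    ex <- sample(codes, 1L)
    got <- merge_other_pips(recs, ex)
    keep <- recs[recs$criterion_code != ex, ]
    expect_identical(days_of(got), days_of(keep))
  }
})

test_that("combined analysis merges the three worked-example records into one", {
  comb <- combine_pip_records(worked_example_records)
  expect_equal(nrow(comb), 1L)
  expect_equal(comb$start, as.Date("2010-01-01"))
  expect_equal(comb$end, as.Date("2010-01-31"))
})

test_that("part-1 equals part-2 medication minus PPI for every START", {
  st <- generate_cohort(simulation_config(n_patients = 250L, seed = 21L))
  p1 <- derive_pip_records(st$cohort)
  p2 <- derive_part2_records(st$cohort)
  for (code in grep("^START", names(crit), value = TRUE)) {
    a <- p1[p1$criterion_code == code, ]
    med <- p2$med[p2$med$criterion_code == code, ]
    for (pid in unique(c(a$patient_id, med$patient_id))) {
      lhs <- days_of(a[a$patient_id == pid, ])
      rhs <- setdiff(days_of(med[med$patient_id == pid, ]),
                     days_of(p2$ppi[p2$ppi$patient_id == pid, ]))
      expect_identical(lhs, rhs)
    }
  }
})

test_that("no record extends outside its patient's observation window", {
  st <- generate_cohort(simulation_config(n_patients = 250L, seed = 22L))
  recs <- st$ground_truth$pip_records
  idx <- match(recs$patient_id, st$cohort$patients$patient_id)
  expect_true(all(recs$start >= st$cohort$patients$entry_date[idx]))
  expect_true(all(recs$end <= st$cohort$patients$exit_date[idx]))
})

test_that("the engine reproduces the generator's labels after a file round trip", {
  dir <- withr::local_tempdir()
  st <- simulate_study(simulation_config(n_patients = 200L, seed = 23L))
  paths <- file.path(dir, c("p.csv", "rx.csv", "dx.csv", "nt.csv"))
  do.call(write_cohort, c(list(st$cohort), as.list(paths)))
  back <- do.call(read_cohort, as.list(paths))
  rederived <- derive_pip_records(back)
  rownames(rederived) <- NULL
  expected <- st$ground_truth$pip_records
  rownames(expected) <- NULL
  expect_equal(rederived[order(rederived$criterion_code, rederived$patient_id,
                               rederived$start), ],
               expected[order(expected$criterion_code, expected$patient_id,
                              expected$start), ],
               ignore_attr = TRUE)
})

test_that("criteria configuration round-trips through YAML", {
  path <- withr::local_tempfile(fileext = ".yaml")
  write_criteria_yaml(path)
  back <- read_criteria_yaml(path)
  expect_equal(back$gap_days, default_gap_days())
  expect_equal(back$atc_map, default_atc_map())
  expect_equal(back$criteria, default_criteria())
})
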