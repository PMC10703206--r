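write_demo_cohort <- function(dir) {
  cohort <- list(
    patients = demo_patient(),
    prescriptions = data.frame(patient_id = "p1", atc_code = "M01AE01",
                               start_date = as.Date("2010-01-01"),
                               end_date = as.Date("2010-01-30"),
                               daily_dose_mg = 1200),
    diagnoses = data.frame(patient_id = "p1", icpc_code = "T92",
                           date = as.Date("2009-05-01")),
    notes = data.frame(patient_id = "p1", date = as.Date("2010-06-01"),
                       icpc_code = "A99", text = "controle, geen klachten")
  )
  paths <- file.path(dir, c("patients.csv", "prescriptions.csv",
                            "diagnoses.csv", "notes.csv"))
  do.call(write_cohort, c(list(cohort), as.list(paths)))
  list(cohort = cohort, paths = paths)
}

test_that("read_cohort round-trips a small valid cohort", {
  dir <- withr::local_tempdir()
  demo <- write_demo_cohort(dir)
  got <- do.call(read_cohort, as.list(demo$paths))
  for (tab in names(demo$cohort)) {
    expect_equal(as.data.frame(got[[tab]]), demo$cohort[[tab]],
                 ignore_attr = TRUE)
  }
})

test_that("write then read is the identity on a generated cohort", {
  dir <- withr::local_tempdir()
  st <- generate_cohort(simulation_config(n_patients = 120L, seed = 11L))
  paths <- file.path(dir, c("p.csv", "rx.csv", "dx.csv", "nt.csv"))
  do.call(write_cohort, c(list(st$cohort), as.list(paths)))
  got <- do.call(read_cohort, as.list(paths))
  for (tab in c("patients", "prescriptions", "diagnoses", "notes")) {
    a <- as.data.frame(st$cohort[[tab]])
    b <- as.data.frame(got[[tab]])
    rownames(a) <- rownames(b) <- NULL
    expect_equal(b, a, ignore_attr = TRUE)
  }
})

test_that("an empty cohort writes header-only files that read back empty", {
  dir <- withr::local_tempdir()
  emp <- generate_cohort(simulation_config(n_patients = 0L))$cohort
  paths <- file.path(dir, c("p.csv", "rx.csv", "dx.csv", "nt.csv"))
  do.call(write_cohort, c(list(emp), as.list(paths)))
  expect_equal(length(readLines(paths[1])), 1L)  # header only
  back <- do.call(read_cohort, as.list(paths))
  expect_equal(nrow(back$patients), 0L)
  expect_equal(nrow(back$prescriptions), 0L)
})

test_that("invariant violations are reported with table, line and patient", {
  dir <- withr::local_tempdir()
  demo <- write_demo_cohort(dir)
  # corrupt the prescriptions: end before start
  rx <- read.csv(demo$paths[2])
  rx$end_date <- "2009-12-01"
  write.csv(rx, demo$paths[2], row.names = FALSE, na = "")
  expect_error(do.call(read_cohort, as.list(demo$paths)),
               "prescriptions line 2 \\(patient p1\\).*end_date before start_date")
})

test_that("validate_cohort flags bad sex, ICPC pattern and window violations", {
  cohort <- list(
    patients = data.frame(patient_id = "p1", birth_date = as.Date("1950-01-01"),
                          sex = "X", entry_date = as.Date("2008-01-01"),
                          exit_date = as.Date("2007-01-01"),
                          exit_reason = "abducted"),
    prescriptions = data.frame(patient_id = "p1", atc_code = "",
                               start_date = as.Date("2010-01-01"),
                               end_date = as.Date("2010-01-30"),
                               daily_dose_mg = -5),
    diagnoses = data.frame(patient_id = "p1", icpc_code = "ZZZ",
                           date = as.Date("2010-01-01")),
    notes = data.frame(patient_id = "p1", date = as.Date("2010-01-01"),
                       icpc_code = "A99", text = "x")
  )
  errs <- validate_cohort(cohort, study_start = as.Date("2007-01-01"),
                          study_end = as.Date("2014-12-31"))
  expect_true(any(grepl("invalid sex", errs)))
  expect_true(any(grepl("entry_date after exit_date", errs)))
  expect_true(any(grepl("invalid exit_reason", errs)))
  expect_true(any(grepl("empty atc_code", errs)))
  expect_true(any(grepl("negative daily_dose_mg", errs)))
  expect_true(any(grepl("invalid ICPC", errs)))
  # entry before 65th birthday (born 1950, entry 2008)
  expect_true(any(grepl("65th birthday", errs)))
})

test_that("missing files are fatal", {
  dir <- withr::local_tempdir()
  demo <- write_demo_cohort(dir)
  expect_error(read_cohort(file.path(dir, "nope.csv"), demo$paths[2],
                           demo$paths[3], demo$paths[4]),
               "not found")
})

test_that("compute_age follows the birthday-anniversary convention", {
  expect_identical(compute_age("1940-03-01", "2005-02-28"), 64L)
  expect_identical(compute_age("1940-03-01", "2005-03-01"), 65L)
  # leap-day birth: anniversary is Mar 1 in non-leap years, so Feb 28 2007
  # is still one day short of the 71st anniversary
  expect_identical(compute_age("1936-02-29", "2007-02-28"), 70L)
  expect_identical(compute_age("1936-02-29", "2007-03-01"), 71L)
  expect_identical(compute_age("1936-02-29", "2008-02-29"), 72L)
  expect_error(compute_age("2000-01-02", "2000-01-01"), "before birth")
})

test_that("compute_age agrees with the anniversary-counting oracle", {
  set.seed(404)
  n <- 10000L
  birth <- as.Date("1900-01-01") + sample.int(40000L, n, replace = TRUE)
  on <- birth + sample.int(45000L, n, replace = TRUE)
  got <- compute_age(birth, on)
  # oracle loops per pair; check all of a random subsample plus every
  # leap-day birth (the only non-trivial convention case)
  idx <- unique(c(sample.int(n, 500L),
                  which(format(birth, "%m-%d") == "02-29")))
  oracle <- vapply(idx, function(i) brute_age(birth[i], on[i]), integer(1))
  expect_identical(got[idx], oracle)
})
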