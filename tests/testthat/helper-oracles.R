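# Independent brute-force oracles used across the suite. They work on
# explicit day sets and hand-coded likelihoods, never on the package's own
# interval or fitting code paths.

# expand an interval data.frame to its explicit set of integer days
days_of <- function(intervals) {
  if (is.null(intervals) || nrow(intervals) == 0L) return(integer())
  sort(unique(unlist(Map(
    function(s, e) seq(as.integer(as.Date(s)), as.integer(as.Date(e))),
    intervals$start, intervals$end))))
}

# canonical intervals from an explicit day set (run-length on sorted days)
intervals_of <- function(days) {
  days <- sort(unique(as.integer(days)))
  if (!length(days)) {
    return(data.frame(start = as.Date(character()), end = as.Date(character())))
  }
  brk <- c(0L, which(diff(days) > 1L), length(days))
  data.frame(
    start = as.Date(days[head(brk, -1L) + 1L], origin = "1970-01-01"),
    end = as.Date(days[brk[-1L]], origin = "1970-01-01"))
}

random_interval_set <- function(n, origin = as.Date("2010-01-01"),
                                span = 120L, max_len = 30L) {
  s <- origin + sample.int(span, n, replace = TRUE) - 1L
  data.frame(start = s, end = s + sample.int(max_len, n, replace = TRUE) - 1L)
}

# age oracle: count the anniversaries falling on or before `on`, building
# each anniversary date from its components (invalid Feb 29 -> Mar 1)
brute_age <- function(birth, on) {
  birth <- as.Date(birth); on <- as.Date(on)
  bl <- as.POSIXlt(birth)
  age <- 0L
  for (k in seq_len(150L)) {
    y <- bl$year + 1900L + k
    ann <- as.Date(sprintf("%d-%02d-%02d", y, bl$mon + 1L, bl$mday),
                   format = "%Y-%m-%d")
    if (is.na(ann)) ann <- as.Date(sprintf("%d-03-01", y))
    if (ann <= on) age <- k else break
  }
  age
}

# hand-coded Cox log partial likelihood with Efron tie handling on
# counting-process rows (t_start, t_stop] with delayed entry
efron_loglik <- function(beta, rows, covs) {
  X <- as.matrix(rows[covs])
  eta <- drop(X %*% beta)
  r <- exp(eta)
  ll <- 0
  for (tk in sort(unique(rows$t_stop[rows$event == 1]))) {
    at_risk <- rows$t_start < tk & rows$t_stop >= tk
    D <- which(rows$event == 1 & rows$t_stop == tk)
    d <- length(D)
    sR <- sum(r[at_risk])
    sD <- sum(r[D])
    ll <- ll + sum(eta[D])
    for (l in seq_len(d) - 1L) ll <- ll - log(sR - (l / d) * sD)
  }
  ll
}

# maximize the hand-coded partial likelihood: BFGS start, Newton polish
# with central finite differences
oracle_cox_coef <- function(rows, covs) {
  nll <- function(b) -efron_loglik(b, rows, covs)
  p <- length(covs)
  b <- optim(rep(0, p), nll, method = "BFGS",
             control = list(reltol = 1e-14, maxit = 2000))$par
  h <- 1e-5
  for (it in 1:20) {
    g <- vapply(seq_len(p), function(j) {
      ej <- replace(rep(0, p), j, h)
      (nll(b + ej) - nll(b - ej)) / (2 * h)
    }, numeric(1))
    H <- matrix(0, p, p)
    for (j in seq_len(p)) for (l in seq_len(p)) {
      ej <- replace(rep(0, p), j, h)
      el <- replace(rep(0, p), l, h)
      H[j, l] <- (nll(b + ej + el) - nll(b + ej - el) -
                    nll(b - ej + el) + nll(b - ej - el)) / (4 * h * h)
    }
    step <- tryCatch(solve(H, g), error = function(e) g * 0)
    if (max(abs(step)) < 1e-10) break
    b <- b - step
  }
  b
}

# small deterministic counting-process fixtures for the Cox oracle suite:
# n patients, one binary exposure (optionally one extra covariate)
tiny_cox_dataset <- function(seed, n_patients = 8L, two_covs = FALSE) {
  set.seed(seed)
  rows <- do.call(rbind, lapply(seq_len(n_patients), function(i) {
    n_seg <- sample(1:3, 1)
    cuts <- sort(sample(1:60, n_seg + 1L))
    data.frame(patient_id = sprintf("p%02d", i),
               t_start = head(cuts, -1L), t_stop = cuts[-1L],
               event = 0L,
               x = sample(0:1, n_seg, replace = TRUE),
               z = round(runif(n_seg), 2))
  }))
  # events at some row ends, at least two
  ev <- sample(nrow(rows), max(2L, rbinom(1, nrow(rows), 0.25)))
  rows$event[ev] <- 1L
  covs <- if (two_covs) c("x", "z") else "x"
  list(rows = rows, covariate_names = covs, model_tag = "toy")
}

# tiny four-table cohort used by fixture-level tests
demo_patient <- function(id = "p1", birth = "1938-06-15",
                         sex = "F", entry = "2008-01-01",
                         exit = "2012-12-31") {
  data.frame(patient_id = id, birth_date = as.Date(birth), sex = sex,
             entry_date = as.Date(entry), exit_date = as.Date(exit),
             exit_reason = "study_end")
}

demo_episode <- function(class, start, end, dose = NA_real_) {
  data.frame(drug_class = class, start = as.Date(start), end = as.Date(end),
             max_daily_dose_mg = dose)
}
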