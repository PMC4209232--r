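# Independent oracles and small fixture builders used across tests.

# Brute-force concordance by explicit pair enumeration (ties count 1/2);
# O(n1 * n0) on purpose -- the reference the fast implementation must match.
brute_force_c <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# minimal discharge-record row for unit tests of single operations
make_admission <- function(patient_id = "P1", admission_id = "A1",
                           hospital_id = "H1",
                           admission_date = as.Date("2010-06-01"),
                           principal_dx = "41001", secondary_dx = "",
                           procedures = "", drg = "122",
                           disposition = "discharged", age = 70,
                           gender = "M", resident = TRUE,
                           icu_admission = FALSE, los = 7) {
  data.frame(admission_id = admission_id, patient_id = patient_id,
             hospital_id = hospital_id, admission_date = admission_date,
             admission_time = "12:00",
             discharge_date = admission_date + los,
             principal_dx = principal_dx, secondary_dx = secondary_dx,
             procedures = procedures, drg = drg, disposition = disposition,
             age = age, gender = gender, resident = resident,
             icu_admission = icu_admission, stringsAsFactors = FALSE)
}

# a small cohort-like data frame with binary covariates and a logistic
# outcome, for model-level tests that do not need the registry machinery
sim_cohort_frame <- function(n, beta = c(strong = log(2)), prevalence = 0.2,
                             base_rate = 0.1, n_noise = 3, seed = 1,
                             n_hospitals = 10) {
  set.seed(seed)
  d <- data.frame(age = round(stats::rnorm(n, 70, 10)),
                  female = stats::rbinom(n, 1, 0.4))
  for (nm in names(beta)) d[[nm]] <- stats::rbinom(n, 1, prevalence)
  if (n_noise > 0)
    for (i in seq_len(n_noise))
      d[[paste0("noise", i)]] <- stats::rbinom(n, 1, 0.1 + 0.05 * i)
  lp <- stats::qlogis(base_rate) + 0.02 * (d$age - 70) +
    drop(as.matrix(d[names(beta)]) %*% beta)
  d$hospital_id <- sprintf("H%02d", sample.int(n_hospitals, n, replace = TRUE))
  d$outcome <- stats::rbinom(n, 1, stats::plogis(lp))
  d
}

# forge the minimal standardisation-result shape needed by funnel
# classification from raw per-hospital rates
forge_profile <- function(rates, volumes, overall) {
  structure(list(
    hospitals = data.frame(hospital_id = sprintf("H%04d", seq_along(rates)),
                           n = volumes, observed_events = round(rates * volumes),
                           estimate = stats::qlogis(pmin(pmax(rates, 1e-6), 1 - 1e-6)),
                           p_uncorrected = rates, adjusted_proportion = rates,
                           flag = "ok", stringsAsFactors = FALSE),
    k = 1, total_events = sum(round(rates * volumes)),
    covariate_means = numeric(), covariates = character(),
    overall_rate = overall), class = "standardisation_result")
}

toyreg_dir <- function() system.file("extdata", "toyreg", package = "hosprofile")
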