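# Synthetic registry generator -------------------------------------------
#
# Emulates the four regional data sources consumed by the pipeline:
# hospital discharge records, outpatient drug dispensings, admission-level
# clinical variables and a death registry.  Every patient's true covariate
# vector, hospital effect and event probability are kept in a ground-truth
# table so that downstream stages can be validated against known parameters.

#' Default covariate table for the AMI (acute myocardial infarction) cohort
#'
#' One row per model covariate: marginal prevalence, true odds ratio used in
#' the outcome model, the registry code the generator emits for it, and the
#' kind of registry trace it leaves (`comorbidity` = diagnosis on a prior
#' admission within the two-year lookback; `index_comorbidity` = secondary
#' diagnosis on the index admission; `clinical` = admission-level measured
#' variable, category indicators sharing an `exclusive` group;
#' `drug` = dispensing in the three months before admission).
#'
#' Prevalences correspond to the marginal distribution of a large regional
#' AMI cohort and odds ratios to its fully adjusted 30-day mortality model
#' (e.g. systolic blood pressure <= 100 mmHg, OR 4.60; diuretic use in the
#' prior 3 months, OR 1.69).
#'
#' @return A `data.frame` with columns `name`, `kind`, `prevalence`, `or`,
#'   `code`, `exclusive`.
#' @export
ami_covariate_defaults <- function() {
  data.frame(
    name = c("cancer", "diabetes", "lipid_disorders", "blood_disorders",
             "previous_ami", "heart_failure", "other_ischemic",
             "chronic_renal", "chronic_liver_pancreas_intestine",
             "previous_cabg", "previous_pci",
             "blood_disorders_index", "other_ischemic_index",
             "sbp_le100", "sbp_missing",
             "diuretics", "ace_inhibitors", "arb"),
    kind = c(rep("comorbidity", 11), rep("index_comorbidity", 2),
             rep("clinical", 2), rep("drug", 3)),
    prevalence = c(0.0574, 0.1089, 0.0452, 0.0444,
                   0.1493, 0.0728, 0.0135,
                   0.0552, 0.0112,
                   0.0407, 0.1122,
                   0.0516, 0.0230,
                   0.1005, 0.0336,
                   0.2071, 0.2597, 0.2395),
    or = c(1.42, 1.34, 0.46, 1.28,
           0.71, 1.51, 1.26,
           1.48, 1.92,
           0.52, 0.62,
           0.69, 0.47,
           4.60, 1.33,
           1.69, 0.77, 0.82),
    code = c("1530", "2500", "2720", "2849",
             "412", "4280", "4139",
             "5859", "5715",
             "V4581", "V4582",
             "2849", "4139",
             "", "",
             "C03AA01", "C09AA05", "C09CA01"),
    exclusive = c(rep(NA_character_, 13), "sbp", "sbp", rep(NA_character_, 3)),
    stringsAsFactors = FALSE
  )
}

#' Default covariate table for the HF (hip fracture) cohort
#'
#' Same layout as [ami_covariate_defaults()]; prevalences and odds ratios
#' correspond to a regional hip-fracture cohort modelling surgery within
#' 48 hours of admission (e.g. out-of-range INR, OR 0.56; antiplatelet use
#' in the prior 3 months, OR 0.79).
#'
#' @return A `data.frame`; see [ami_covariate_defaults()].
#' @export
hf_covariate_defaults <- function() {
  data.frame(
    name = c("diabetes", "obesity", "hypertension", "osteoporosis",
             "obesity_index",
             "inr_out_of_range", "inr_missing",
             "antiplatelet", "anticoagulants"),
    kind = c(rep("comorbidity", 4), "index_comorbidity",
             rep("clinical", 2), rep("drug", 2)),
    prevalence = c(0.064, 0.0036, 0.1382, 0.009,
                   0.0065,
                   0.1347, 0.1038,
                   0.1341, 0.0375),
    or = c(0.68, 1.04, 0.80, 1.97,
           2.33,
           0.56, 0.78,
           0.79, 1.00),
    code = c("2500", "2780", "4019", "73300",
             "2780",
             "", "",
             "B01AC06", "B01AA03"),
    exclusive = c(rep(NA_character_, 5), "inr", "inr", NA, NA),
    stringsAsFactors = FALSE
  )
}

#' Configuration for the synthetic registry generator
#'
#' @param cohort `"AMI"` (30-day mortality outcome) or `"HF"` (surgery
#'   within 48 hours outcome).
#' @param n_patients Number of patients (one index episode each); defaults
#'   to the reference cohort sizes, 7613 (AMI) / 6348 (HF).
#' @param n_hospitals Number of hospitals (>= 2); defaults 62 (AMI) /
#'   83 (HF).
#' @param hospital_effect_sd Standard deviation, on the log-odds scale, of
#'   the mean-centred Gaussian per-hospital effects.
#' @param target_event_rate Marginal outcome probability the intercept is
#'   calibrated to (AMI default 0.108; HF default 0.198).
#' @param age_mean,age_sd Age distribution in years (normal, truncated to
#'   the cohort's eligible range).
#' @param age_or Odds ratio per year of age (applied to age centred at
#'   `age_mean`).
#' @param female_prob,female_or Prevalence of female gender and its odds
#'   ratio.
#' @param covariates Covariate table as returned by
#'   [ami_covariate_defaults()] / [hf_covariate_defaults()]; prevalences,
#'   odds ratios and emitted codes may be overridden here.
#' @param lookback_fraction Probability that a comorbid patient's qualifying
#'   prior admission falls inside the two-year lookback window (otherwise
#'   it is emitted before the window and is invisible to the cohort
#'   builder).
#' @param lookback_days,drug_window_days Window lengths used when placing
#'   qualifying events (730 and 90 days).
#' @param complication_fraction Fraction of AMI index admissions presenting
#'   as a myocardial-infarction complication (complication code as the
#'   principal diagnosis, 410.xx secondary).
#' @param readmit_fraction Fraction of patients with a second admission for
#'   the index condition within 28 days (same episode; must be de-duplicated
#'   by the cohort builder).
#' @param decoy_dispensing_prob Probability that a patient receives an
#'   additional dispensing *outside* the exposure window (exercises the
#'   window logic).
#' @param late_death_prob Probability that a patient without the mortality
#'   outcome dies between day 31 and day 365.
#' @param hospital_prevalence_shift Optional named list
#'   `list(name=, low=, high=)`: covariate `name` gets prevalence `low` in
#'   the first half of hospitals and `high` in the second half instead of
#'   its marginal prevalence. Used to create a hospital-heterogeneous
#'   confounder; `NULL` (default) keeps all covariates identically
#'   distributed across hospitals.
#' @param seed Master seed; per-record-type substreams are derived from it.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(cohort = c("AMI", "HF"),
                             n_patients = NULL,
                             n_hospitals = NULL,
                             hospital_effect_sd = 0.2,
                             target_event_rate = NULL,
                             age_mean = NULL, age_sd = NULL,
                             age_or = NULL,
                             female_prob = NULL, female_or = NULL,
                             covariates = NULL,
                             lookback_fraction = 0.9,
                             lookback_days = 730,
                             drug_window_days = 90,
                             complication_fraction = 0.05,
                             readmit_fraction = 0.05,
                             decoy_dispensing_prob = 0.2,
                             late_death_prob = 0.05,
                             hospital_prevalence_shift = NULL,
                             seed = 1L) {
  cohort <- match.arg(cohort)
  if (cohort == "AMI") {
    n_patients <- n_patients %||% 7613
    n_hospitals <- n_hospitals %||% 62
    target_event_rate <- target_event_rate %||% 0.108
    age_mean <- age_mean %||% 70.1; age_sd <- age_sd %||% 13.5
    age_or <- age_or %||% 1.08
    female_prob <- female_prob %||% 0.353; female_or <- female_or %||% 0.96
    covariates <- covariates %||% ami_covariate_defaults()
    age_range <- c(18, 100)
  } else {
    n_patients <- n_patients %||% 6348
    n_hospitals <- n_hospitals %||% 83
    target_event_rate <- target_event_rate %||% 0.198
    age_mean <- age_mean %||% 83.0; age_sd <- age_sd %||% 7.1
    age_or <- age_or %||% 1.00
    female_prob <- female_prob %||% 0.7758; female_or <- female_or %||% 1.37
    covariates <- covariates %||% hf_covariate_defaults()
    age_range <- c(65, 100)
  }
  cfg <- structure(list(
    cohort = cohort, n_patients = as.integer(n_patients),
    n_hospitals = as.integer(n_hospitals),
    hospital_effect_sd = hospital_effect_sd,
    target_event_rate = target_event_rate,
    age_mean = age_mean, age_sd = age_sd, age_or = age_or,
    age_range = age_range,
    female_prob = female_prob, female_or = female_or,
    covariates = covariates,
    lookback_fraction = lookback_fraction,
    lookback_days = as.integer(lookback_days),
    drug_window_days = as.integer(drug_window_days),
    complication_fraction = complication_fraction,
    readmit_fraction = readmit_fraction,
    decoy_dispensing_prob = decoy_dispensing_prob,
    late_death_prob = late_death_prob,
    hospital_prevalence_shift = hospital_prevalence_shift,
    seed = as.integer(seed)
  ), class = "generator_config")
  validate_generator_config(cfg)
  cfg
}

validate_generator_config <- function(cfg) {
  probs <- c(cfg$target_event_rate, cfg$female_prob, cfg$lookback_fraction,
             cfg$complication_fraction, cfg$readmit_fraction,
             cfg$decoy_dispensing_prob, cfg$late_death_prob,
             cfg$covariates$prevalence)
  if (any(probs < 0 | probs > 1))
    stop_config("all probabilities must lie in [0, 1]")
  if (any(c(cfg$covariates$or, cfg$age_or, cfg$female_or) <= 0))
    stop_config("all odds ratios must be > 0")
  if (cfg$n_hospitals < 2L) stop_config("n_hospitals must be >= 2")
  if (cfg$n_patients < 1L) stop_config("n_patients must be >= 1")
  if (cfg$hospital_effect_sd < 0) stop_config("hospital_effect_sd must be >= 0")
  dup <- duplicated(cfg$covariates$name)
  if (any(dup)) stop_config("duplicate covariate name: %s",
                            cfg$covariates$name[dup][1])
  invisible(cfg)
}

#' Read a generator configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [generator_config()]; an optional
#' `covariates` list of records (name/kind/prevalence/or/code/exclusive)
#' overrides the cohort's default covariate table.
#'
#' @param path Path to a YAML file.
#' @return A validated `generator_config`.
#' @export
read_generator_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$covariates)) {
    raw$covariates <- do.call(rbind, lapply(raw$covariates, function(r) {
      data.frame(name = r$name, kind = r$kind, prevalence = r$prevalence,
                 or = r$or, code = r$code %||% "",
                 exclusive = r$exclusive %||% NA_character_,
                 stringsAsFactors = FALSE)
    }))
  }
  do.call(generator_config, raw)
}

#' Calibrate the outcome-model intercept to a target marginal event rate
#'
#' Solves, by monotone root finding, for the intercept `a` such that the
#' average of `plogis(a + lp)` over the supplied linear-predictor sample
#' equals `target_rate`.
#'
#' @param target_rate Desired marginal event probability, in (0, 1).
#' @param lp Numeric vector of linear predictors (without intercept),
#'   typically `X beta + u[hospital]` for the generated sample.
#' @param tol Convergence tolerance on the achieved rate.
#' @return The intercept (log-odds scale).
#' @export
calibrate_intercept <- function(target_rate, lp, tol = 1e-9) {
  if (!is.numeric(target_rate) || length(target_rate) != 1 ||
      target_rate <= 0 || target_rate >= 1)
    stop_config("target_rate must lie strictly inside (0, 1)")
  if (!length(lp)) stop_config("linear-predictor sample must be non-empty")
  f <- function(a) mean(invlogit(a + lp)) - target_rate
  lo <- logit(target_rate) - max(abs(lp)) - 1
  hi <- logit(target_rate) + max(abs(lp)) + 1
  stats::uniroot(f, c(lo, hi), tol = tol)$root
}

#' Draw mean-centred Gaussian hospital effects on the log-odds scale
#'
#' @param n_hospitals Number of hospitals.
#' @param sd Between-hospital standard deviation; `0` returns exact zeros.
#' @param seed Optional seed for this draw.
#' @return Numeric vector of length `n_hospitals` with arithmetic mean 0.
#' @export
sample_hospital_effects <- function(n_hospitals, sd, seed = NULL) {
  if (sd < 0) stop_config("sd must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  if (sd == 0) return(rep(0, n_hospitals))
  u <- stats::rnorm(n_hospitals, 0, sd)
  u - mean(u)
}

# truncated-normal ages by resampling out-of-range draws
draw_ages <- function(n, mean, sd, range) {
  a <- stats::rnorm(n, mean, sd)
  bad <- which(a < range[1] | a > range[2])
  while (length(bad)) {
    a[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[a[bad] < range[1] | a[bad] > range[2]]
  }
  round(a)
}

draw_covariates <- function(cfg, hospital) {
  n <- cfg$n_patients
  cov <- cfg$covariates
  X <- matrix(0L, n, nrow(cov), dimnames = list(NULL, cov$name))
  done <- rep(FALSE, nrow(cov))
  for (g in unique(stats::na.omit(cov$exclusive))) {
    idx <- which(!is.na(cov$exclusive) & cov$exclusive == g)
    p <- cov$prevalence[idx]
    if (sum(p) > 1) stop_config("exclusive group '%s' prevalences sum > 1", g)
    u <- stats::runif(n)
    cum <- cumsum(p)
    cat_idx <- rowSums(outer(u, cum, ">")) + 1L  # 1..k categories, k+1 = ref
    for (j in seq_along(idx))
      X[, idx[j]] <- as.integer(cat_idx == j)
    done[idx] <- TRUE
  }
  shift <- cfg$hospital_prevalence_shift
  for (j in which(!done)) {
    p <- rep(cov$prevalence[j], n)
    if (!is.null(shift) && identical(shift$name, cov$name[j])) {
      half <- cfg$n_hospitals %/% 2L
      p <- ifelse(hospital <= half, shift$low, shift$high)
    }
    X[, j] <- stats::rbinom(n, 1L, p)
  }
  X
}

#' Generate a synthetic registry population with known ground truth
#'
#' Produces one index admission per patient plus the registry traces of the
#' patient's covariates: prior admissions carrying comorbidity diagnoses
#' (placed inside or before the lookback window according to
#' `lookback_fraction`), drug dispensings inside the exposure window (plus
#' decoy dispensings outside it), admission-level clinical values with the
#' configured missingness, and death records.  Outcomes are drawn from
#' `plogis(intercept + X beta + u[hospital])` with the intercept calibrated
#' so the marginal event rate matches `target_event_rate`.
#'
#' @param config A [generator_config()].
#' @return An object of class `hosp_registry`: a list with data frames
#'   `discharges`, `dispensings`, `clinical`, `deaths`, `truth`, and the
#'   `config` used. `truth` holds each patient's true covariates, the
#'   `<name>_recorded` indicators (qualifying trace inside the window),
#'   the linear predictor, hospital effect, event probability and outcome.
#' @export
generate_population <- function(config) {
  cfg <- validate_generator_config(config)
  n <- cfg$n_patients
  cov <- cfg$covariates

  set.seed(substream_seed(cfg$seed, 1L))   # patients, hospitals, covariates
  patient_id <- sprintf("P%06d", seq_len(n))
  hospital <- sample.int(cfg$n_hospitals, n, replace = TRUE)
  hospital_id <- sprintf("H%03d", hospital)
  age <- draw_ages(n, cfg$age_mean, cfg$age_sd, cfg$age_range)
  female <- stats::rbinom(n, 1L, cfg$female_prob)
  X <- draw_covariates(cfg, hospital)

  set.seed(substream_seed(cfg$seed, 2L))   # hospital effects + outcomes
  u <- sample_hospital_effects(cfg$n_hospitals, cfg$hospital_effect_sd)
  beta <- log(cov$or)
  lp <- drop(X %*% beta) + log(cfg$age_or) * (age - cfg$age_mean) +
    log(cfg$female_or) * female + u[hospital]
  alpha <- calibrate_intercept(cfg$target_event_rate, lp)
  p_event <- invlogit(alpha + lp)
  y <- stats::rbinom(n, 1L, p_event)

  set.seed(substream_seed(cfg$seed, 3L))   # index admissions
  adm_date <- as.Date("2010-01-01") + sample.int(334L, n, replace = TRUE) - 1L
  los <- 1L + stats::rpois(n, 6)
  is_ami <- cfg$cohort == "AMI"
  principal_pool <- if (is_ami) c("41001", "41011", "41041", "41071", "41091")
                    else c("82000", "82002", "82020", "82021", "8208")
  principal <- sample(principal_pool, n, replace = TRUE)
  complication_pool <- c("4230", "4270", "4271", "4272", "4273", "4274",
                         "4276", "4278", "4279", "4295", "4296", "5184",
                         "7802", "7991", "9982")
  secondary <- character(n)
  if (is_ami) {
    compl <- stats::runif(n) < cfg$complication_fraction
    secondary[compl] <- principal[compl]
    principal[compl] <- sample(complication_pool, sum(compl), replace = TRUE)
  }
  idx_cov <- which(cov$kind == "index_comorbidity")
  for (j in idx_cov) {
    has <- X[, j] == 1L
    secondary[has] <- ifelse(nzchar(secondary[has]),
                             paste(secondary[has], cov$code[j], sep = ";"),
                             cov$code[j])
  }
  noise <- stats::runif(n) < 0.3
  secondary[noise] <- ifelse(nzchar(secondary[noise]),
                             paste(secondary[noise], "486", sep = ";"), "486")

  set.seed(substream_seed(cfg$seed, 4L))   # outcomes' registry traces
  death_date <- rep(as.Date(NA), n)
  procedures <- character(n)
  if (is_ami) {
    death_date[y == 1L] <- adm_date[y == 1L] +
      sample(0:30, sum(y), replace = TRUE)
    late <- y == 0L & stats::runif(n) < cfg$late_death_prob
    death_date[late] <- adm_date[late] + sample(31:365, sum(late), replace = TRUE)
  } else {
    surg_pool <- c("7935", "8151", "8152")
    d1 <- sample(0:1, n, replace = TRUE)
    surg1 <- y == 1L
    procedures[surg1] <- paste0(sample(surg_pool, sum(surg1), TRUE), ":",
                                adm_date[surg1] + d1[surg1])
    late_surg <- y == 0L & stats::runif(n) < 0.5
    procedures[late_surg] <- paste0(
      sample(surg_pool, sum(late_surg), TRUE), ":",
      adm_date[late_surg] + sample(2:10, sum(late_surg), replace = TRUE))
    late <- stats::runif(n) < cfg$late_death_prob
    death_date[late] <- adm_date[late] + sample(31:365, sum(late), replace = TRUE)
  }
  disposition <- rep("discharged", n)
  disch_date <- adm_date + los
  died_in_hosp <- !is.na(death_date) & death_date <= disch_date
  disposition[died_in_hosp] <- "died"
  disch_date[died_in_hosp] <- death_date[died_in_hosp]

  discharges <- data.frame(
    admission_id = sprintf("A%07d", seq_len(n)),
    patient_id = patient_id, hospital_id = hospital_id,
    admission_date = adm_date,
    admission_time = sprintf("%02d:%02d", sample(0:23, n, TRUE),
                             sample(0:59, n, TRUE)),
    discharge_date = disch_date,
    principal_dx = principal, secondary_dx = secondary,
    procedures = procedures,
    drg = if (is_ami) "122" else "236",
    disposition = disposition,
    age = age, gender = ifelse(female == 1L, "F", "M"),
    resident = TRUE, icu_admission = FALSE,
    stringsAsFactors = FALSE
  )

  set.seed(substream_seed(cfg$seed, 5L))   # prior admissions (comorbidities)
  recorded <- X
  com_cov <- which(cov$kind == "comorbidity")
  prior_list <- vector("list", length(com_cov))
  for (k in seq_along(com_cov)) {
    j <- com_cov[k]
    has <- which(X[, j] == 1L)
    if (!length(has)) next
    inside <- stats::runif(length(has)) < cfg$lookback_fraction
    days_before <- ifelse(inside,
                          sample(30:(cfg$lookback_days - 30L), length(has), TRUE),
                          sample((cfg$lookback_days + 10L):(cfg$lookback_days + 300L),
                                 length(has), TRUE))
    recorded[has[!inside], j] <- 0L
    prior_list[[k]] <- data.frame(
      patient_id = patient_id[has],
      hospital_id = sprintf("H%03d", sample.int(cfg$n_hospitals, length(has), TRUE)),
      admission_date = adm_date[has] - days_before,
      principal_dx = cov$code[j],
      age = pmax(cfg$age_range[1], age[has] - 1L),
      gender = ifelse(female[has] == 1L, "F", "M"),
      stringsAsFactors = FALSE
    )
  }
  prior <- do.call(rbind, prior_list)
  if (!is.null(prior) && nrow(prior)) {
    prior_full <- data.frame(
      admission_id = sprintf("A%07d", n + seq_len(nrow(prior))),
      patient_id = prior$patient_id, hospital_id = prior$hospital_id,
      admission_date = prior$admission_date,
      admission_time = "12:00",
      discharge_date = prior$admission_date + 3L,
      principal_dx = prior$principal_dx, secondary_dx = "",
      procedures = "", drg = "467", disposition = "discharged",
      age = prior$age, gender = prior$gender,
      resident = TRUE, icu_admission = FALSE,
      stringsAsFactors = FALSE
    )
    discharges <- rbind(discharges, prior_full)
  }

  # same-episode readmissions inside the 28-day window
  set.seed(substream_seed(cfg$seed, 6L))
  re <- which(stats::runif(n) < cfg$readmit_fraction & y == 0L)
  if (length(re)) {
    readm <- discharges[re, ]
    readm$admission_id <- sprintf("A%07d", nrow(discharges) + seq_along(re))
    readm$admission_date <- readm$admission_date + sample(3:27, length(re), TRUE)
    readm$discharge_date <- readm$admission_date + 4L
    readm$principal_dx <- sample(principal_pool, length(re), replace = TRUE)
    readm$secondary_dx <- ""
    readm$procedures <- ""
    discharges <- rbind(discharges, readm)
  }

  set.seed(substream_seed(cfg$seed, 7L))   # dispensings
  drug_cov <- which(cov$kind == "drug")
  disp_list <- list()
  for (j in drug_cov) {
    has <- which(X[, j] == 1L)
    if (!length(has)) next
    disp_list[[length(disp_list) + 1L]] <- data.frame(
      patient_id = patient_id[has],
      dispensing_date = adm_date[has] -
        sample.int(cfg$drug_window_days - 1L, length(has), replace = TRUE),
      atc = cov$code[j], stringsAsFactors = FALSE
    )
  }
  decoy <- which(stats::runif(n) < cfg$decoy_dispensing_prob)
  if (length(decoy) && length(drug_cov)) {
    disp_list[[length(disp_list) + 1L]] <- data.frame(
      patient_id = patient_id[decoy],
      dispensing_date = adm_date[decoy] -
        sample((cfg$drug_window_days + 10L):365L, length(decoy), TRUE),
      atc = sample(cov$code[drug_cov], length(decoy), replace = TRUE),
      stringsAsFactors = FALSE
    )
  }
  dispensings <- if (length(disp_list)) do.call(rbind, disp_list) else
    data.frame(patient_id = character(), dispensing_date = as.Date(character()),
               atc = character(), stringsAsFactors = FALSE)

  set.seed(substream_seed(cfg$seed, 8L))   # clinical values
  clinical <- data.frame(
    admission_key = sprintf("A%07d", seq_len(n)),
    sbp = NA_real_, inr = NA_real_, creatinine = NA_real_,
    stringsAsFactors = FALSE
  )
  if (is_ami && all(c("sbp_le100", "sbp_missing") %in% colnames(X))) {
    le <- X[, "sbp_le100"] == 1L
    mis <- X[, "sbp_missing"] == 1L
    clinical$sbp[le] <- round(stats::runif(sum(le), 80, 100))
    clinical$sbp[!le & !mis] <- round(stats::runif(sum(!le & !mis), 105, 180))
  } else if (is_ami) {
    clinical$sbp <- round(stats::runif(n, 105, 180))
  } else if (!all(c("inr_out_of_range", "inr_missing") %in% colnames(X))) {
    clinical$inr <- round(stats::runif(n, 0.9, 1.2), 2)
    clinical$creatinine <- round(stats::runif(n, 0.6, 2.0), 2)
  } else {
    out <- X[, "inr_out_of_range"] == 1L
    mis <- X[, "inr_missing"] == 1L
    inr_in <- !out & !mis
    clinical$inr[inr_in] <- round(stats::runif(sum(inr_in), 0.9, 1.2), 2)
    hi <- stats::runif(sum(out)) < 0.8
    clinical$inr[out] <- round(ifelse(hi, stats::runif(sum(out), 1.3, 3.5),
                                      stats::runif(sum(out), 0.5, 0.85)), 2)
    clinical$creatinine <- round(stats::runif(n, 0.6, 2.0), 2)
  }

  rownames(discharges) <- NULL
  rownames(dispensings) <- NULL
  deaths <- data.frame(patient_id = patient_id[!is.na(death_date)],
                       death_date = death_date[!is.na(death_date)],
                       stringsAsFactors = FALSE)

  truth <- data.frame(patient_id = patient_id,
                      admission_id = sprintf("A%07d", seq_len(n)),
                      hospital_id = hospital_id,
                      age = age, female = female,
                      stringsAsFactors = FALSE)
  truth <- cbind(truth, as.data.frame(X))
  rec <- as.data.frame(recorded)
  names(rec) <- paste0(names(rec), "_recorded")
  truth <- cbind(truth, rec)
  truth$hosp_effect <- u[hospital]
  truth$lp <- alpha + lp
  truth$p_event <- p_event
  truth$outcome <- y

  structure(list(discharges = discharges, dispensings = dispensings,
                 clinical = clinical, deaths = deaths, truth = truth,
                 intercept = alpha, hospital_effects = u, config = cfg),
            class = "hosp_registry")
}

#' @export
print.hosp_registry <- function(x, ...) {
  cat(sprintf(
    "Synthetic %s registry: %d patients, %d hospitals\n  %d discharge rows, %d dispensings, %d deaths; crude event rate %.3f\n",
    x$config$cohort, x$config$n_patients, x$config$n_hospitals,
    nrow(x$discharges), nrow(x$dispensings), nrow(x$deaths),
    mean(x$truth$outcome)))
  invisible(x)
}

#' Write a synthetic registry to CSV files
#'
#' Writes `discharges.csv`, `dispensings.csv`, `clinical.csv`, `deaths.csv`
#' and `ground_truth.csv` (ISO-8601 dates) into `dir`.
#'
#' @param registry A `hosp_registry` from [generate_population()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_registries <- function(registry, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(registry$discharges, file.path(dir, "discharges.csv"),
                   row.names = FALSE)
  utils::write.csv(registry$dispensings, file.path(dir, "dispensings.csv"),
                   row.names = FALSE)
  utils::write.csv(registry$clinical, file.path(dir, "clinical.csv"),
                   row.names = FALSE)
  utils::write.csv(registry$deaths, file.path(dir, "deaths.csv"),
                   row.names = FALSE)
  utils::write.csv(registry$truth, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Read registry CSV files written by [write_registries()]
#'
#' @param dir Directory holding the four registry CSVs (the ground-truth
#'   file is optional and read when present).
#' @return A list with `discharges`, `dispensings`, `clinical`, `deaths`
#'   (and `truth` if available).
#' @export
read_registries <- function(dir) {
  rd <- function(f, classes) utils::read.csv(file.path(dir, f),
                                             stringsAsFactors = FALSE,
                                             colClasses = classes)
  d <- rd("discharges.csv", c(
    admission_id = "character", patient_id = "character",
    hospital_id = "character", admission_date = "Date",
    admission_time = "character", discharge_date = "Date",
    principal_dx = "character", secondary_dx = "character",
    procedures = "character", drg = "character",
    disposition = "character", age = "numeric", gender = "character",
    resident = "logical", icu_admission = "logical"))
  d$secondary_dx[is.na(d$secondary_dx)] <- ""
  d$procedures[is.na(d$procedures)] <- ""
  p <- rd("dispensings.csv", c(patient_id = "character",
                               dispensing_date = "Date", atc = "character"))
  m <- rd("deaths.csv", c(patient_id = "character", death_date = "Date"))
  cl <- rd("clinical.csv", c(admission_key = "character", sbp = "numeric",
                             inr = "numeric", creatinine = "numeric"))
  out <- list(discharges = d, dispensings = p, clinical = cl, deaths = m)
  gt <- file.path(dir, "ground_truth.csv")
  if (file.exists(gt)) out$truth <- utils::read.csv(gt, stringsAsFactors = FALSE)
  out
}
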