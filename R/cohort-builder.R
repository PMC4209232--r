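# Cohort construction ----------------------------------------------------
#
# Turns registry-shaped inputs into the analysis-ready AMI and HF cohorts:
# index-episode selection, 28-day episode de-duplication, two-year
# comorbidity lookback, three-month drug-exposure windows, clinical-variable
# categorisation and outcome definition.  All windows are half-open
# [index - w, index): an event on the index date itself never counts as
# prior exposure.

#' Default ICD-9-CM comorbidity code map for the AMI cohort
#'
#' A deliberately small, fully overridable prefix map (one prefix list per
#' condition, matched on dot-stripped principal and secondary diagnoses of
#' prior admissions). Regional production lists are typically richer; this
#' default covers the canonical three-digit chapters of each condition.
#'
#' @return Named list: condition name -> character vector of code prefixes.
#' @export
ami_comorbidity_map <- function() {
  list(
    cancer = as.character(140:208),
    diabetes = "250",
    lipid_disorders = "272",
    blood_disorders = as.character(280:289),
    previous_ami = c("410", "412"),
    heart_failure = "428",
    other_ischemic = c("411", "413", "414"),
    chronic_renal = c("403", "585", "586"),
    chronic_liver_pancreas_intestine = c("555", "556", "571", "577"),
    previous_cabg = "V4581",
    previous_pci = "V4582"
  )
}

#' Default comorbidity map for the HF (hip fracture) cohort
#' @return Named list of ICD-9-CM prefixes; see [ami_comorbidity_map()].
#' @export
hf_comorbidity_map <- function() {
  list(
    diabetes = "250",
    obesity = "278",
    hypertension = as.character(401:405),
    osteoporosis = "733"
  )
}

#' Default ATC drug-class map for the AMI cohort
#'
#' Each class is a list with `include` prefixes and optional `exclude`
#' prefixes (e.g. other lipid-modifying agents = C10 excluding C10AA).
#'
#' @return Named list: class name -> list(include=, exclude=).
#' @export
ami_drug_map <- function() {
  list(
    anticoagulants = list(include = c("B01AA", "B01AB")),
    antiplatelet = list(include = "B01AC"),
    cardiac_therapy = list(include = "C01"),
    antihypertensives = list(include = "C02"),
    diuretics = list(include = "C03"),
    beta_blockers = list(include = "C07"),
    calcium_channel_blockers = list(include = "C08"),
    ace_inhibitors = list(include = c("C09A", "C09B")),
    arb = list(include = c("C09C", "C09D")),
    statins = list(include = "C10AA"),
    other_lipid_modifying = list(include = "C10", exclude = "C10AA"),
    antidiabetics = list(include = "A10")
  )
}

#' Default ATC drug-class map for the HF cohort
#' @return Named list; see [ami_drug_map()].
#' @export
hf_drug_map <- function() {
  list(
    antiplatelet = list(include = "B01AC"),
    anticoagulants = list(include = c("B01AA", "B01AB"))
  )
}

#' Cohort-building specification
#'
#' Bundles every rule the cohort builder applies. The two constructors
#' [ami_cohort_spec()] and [hf_cohort_spec()] provide the standard settings;
#' any component (code maps, windows, age range) can be overridden.
#'
#' @param cohort `"AMI"` or `"HF"`.
#' @param index_codes ICD-9-CM prefix(es) defining the index condition.
#' @param complication_codes For AMI: principal-diagnosis codes under which
#'   a secondary AMI diagnosis still defines an index admission
#'   (myocardial-infarction complications).
#' @param age_range Inclusive eligible age range in years.
#' @param episode_window_days Re-admissions for the index condition within
#'   this many days of the episode's first admission are the same episode.
#' @param lookback_days Comorbidity lookback window length.
#' @param drug_window_days Drug-exposure window length.
#' @param comorbidity_map,index_map,drug_map Code maps (see
#'   [ami_comorbidity_map()], [ami_drug_map()]); `index_map` lists the
#'   conditions also ascertainable from index-admission secondary
#'   diagnoses.
#' @param surgery_codes For HF: procedure-code prefixes counting as hip
#'   surgery.
#' @param cancer_range,trauma_drg HF exclusion parameters: ICD-9-CM
#'   three-digit cancer range and multiple-trauma DRG codes.
#' @param study_period Two dates; only admissions inside this window can
#'   be index episodes (prior admissions outside it still feed the
#'   lookback). `NULL` disables the filter.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(cohort, index_codes, complication_codes = character(),
                        age_range, episode_window_days = 28L,
                        lookback_days = 730L, drug_window_days = 90L,
                        comorbidity_map, index_map = list(),
                        drug_map = list(), surgery_codes = character(),
                        cancer_range = c(140L, 208L),
                        trauma_drg = c("484", "485", "486", "487"),
                        study_period = as.Date(c("2010-01-01", "2010-11-30"))) {
  stopifnot(length(age_range) == 2, age_range[1] < age_range[2],
            episode_window_days > 0, lookback_days > 0, drug_window_days > 0)
  structure(list(cohort = cohort, index_codes = index_codes,
                 study_period = study_period,
                 complication_codes = strip_dots(complication_codes),
                 age_range = age_range,
                 episode_window_days = as.integer(episode_window_days),
                 lookback_days = as.integer(lookback_days),
                 drug_window_days = as.integer(drug_window_days),
                 comorbidity_map = comorbidity_map, index_map = index_map,
                 drug_map = drug_map, surgery_codes = surgery_codes,
                 cancer_range = cancer_range, trauma_drg = trauma_drg),
            class = "cohort_spec")
}

#' @rdname cohort_spec
#' @param ... Overrides passed on to [cohort_spec()].
#' @export
ami_cohort_spec <- function(...) {
  defaults <- list(
    cohort = "AMI", index_codes = "410",
    complication_codes = c("423.0", "427.0", "427.1", "427.2", "427.3",
                           "427.4", "427.6", "427.8", "427.9", "429.5",
                           "429.6", "518.4", "780.2", "799.1", "998.2"),
    age_range = c(18, 100),
    comorbidity_map = ami_comorbidity_map(),
    index_map = list(blood_disorders_index = as.character(280:289),
                     other_ischemic_index = c("411", "413", "414")),
    drug_map = ami_drug_map()
  )
  overrides <- list(...)
  defaults[names(overrides)] <- overrides
  do.call(cohort_spec, defaults)
}

#' @rdname cohort_spec
#' @export
hf_cohort_spec <- function(...) {
  defaults <- list(
    cohort = "HF", index_codes = "820",
    age_range = c(65, 100),
    comorbidity_map = hf_comorbidity_map(),
    index_map = list(obesity_index = "278"),
    drug_map = hf_drug_map(),
    surgery_codes = c("790", "791", "793", "8151", "8152")
  )
  overrides <- list(...)
  defaults[names(overrides)] <- overrides
  do.call(cohort_spec, defaults)
}

#' Cohort spec matching a synthetic generator configuration
#'
#' Builds a [cohort_spec()] whose comorbidity, index-condition and drug
#' maps point exactly at the codes a [generator_config()] emits, so the
#' cohort builder recovers the generator's covariates under their own
#' names. Useful when simulating with a custom covariate table.
#'
#' @param config A [generator_config()].
#' @return A `cohort_spec`.
#' @export
spec_for_generator <- function(config) {
  cov <- config$covariates
  pick <- function(kind) {
    rows <- cov[cov$kind == kind, ]
    stats::setNames(as.list(rows$code), rows$name)
  }
  drug_rows <- cov[cov$kind == "drug", ]
  drug_map <- stats::setNames(
    lapply(drug_rows$code, function(cd) list(include = cd)), drug_rows$name)
  base <- if (config$cohort == "AMI") ami_cohort_spec else hf_cohort_spec
  base(comorbidity_map = pick("comorbidity"),
       index_map = pick("index_comorbidity"),
       drug_map = drug_map,
       age_range = config$age_range)
}

#' Collapse re-admissions into index episodes
#'
#' Per patient, admissions are scanned in date order; an admission is part
#' of the current episode (and dropped) iff it begins at most
#' `window_days` after the episode's *first* admission, which anchors the
#' window. A later admission starts a new episode.
#'
#' @param admissions Data frame with `patient_id`, `admission_date`,
#'   `hospital_id`.
#' @param window_days Episode window (days).
#' @return The subset of `admissions` that are episode index admissions.
#' @export
dedupe_episodes <- function(admissions, window_days = 28L) {
  if (!nrow(admissions)) return(admissions)
  dup <- duplicated(admissions[c("patient_id", "admission_date", "hospital_id")])
  if (any(dup)) {
    warning(sprintf("%d duplicate (patient, date, hospital) rows; keeping one",
                    sum(dup)))
    admissions <- admissions[!dup, ]
  }
  ord <- order(admissions$patient_id, admissions$admission_date)
  adm <- admissions[ord, ]
  keep <- logical(nrow(adm))
  idx_by_pat <- split(seq_len(nrow(adm)), adm$patient_id)
  for (rows in idx_by_pat) {
    anchor <- adm$admission_date[rows[1]]
    keep[rows[1]] <- TRUE
    for (i in rows[-1]) {
      if (as.numeric(adm$admission_date[i] - anchor) > window_days) {
        keep[i] <- TRUE
        anchor <- adm$admission_date[i]
      }
    }
  }
  adm[keep, ]
}

ami_presentation <- function(discharges, spec) {
  principal <- strip_dots(discharges$principal_dx)
  sec <- strip_dots(discharges$secondary_dx)
  prim_ami <- startsWith(principal, spec$index_codes[1])
  sec_ami <- match_any_prefix(sec, spec$index_codes)
  compl <- principal %in% spec$complication_codes
  prim_ami | (sec_ami & compl)
}

#' Select AMI index admissions
#'
#' Keeps admissions with a principal 410.xx diagnosis, or a secondary
#' 410.xx diagnosis with a myocardial-infarction complication code as the
#' principal diagnosis; then collapses 28-day episodes and applies the age
#' and residence filters.
#'
#' @param discharges Discharge-record data frame.
#' @param spec An [ami_cohort_spec()].
#' @return `list(index = <data frame>, attrition = <rule, n_excluded>)`.
#' @export
select_ami_index <- function(discharges, spec = ami_cohort_spec()) {
  cand <- discharges[ami_presentation(discharges, spec), ]
  steps <- list()
  if (!is.null(spec$study_period)) {
    inp <- cand$admission_date >= spec$study_period[1] &
      cand$admission_date <= spec$study_period[2]
    steps$outside_study_period <- sum(!inp)
    cand <- cand[inp, ]
  }
  n0 <- nrow(cand)
  dedup <- dedupe_episodes(cand, spec$episode_window_days)
  steps$same_episode_readmission <- n0 - nrow(dedup)
  ok_age <- !is.na(dedup$age) & dedup$age >= spec$age_range[1] &
    dedup$age <= spec$age_range[2]
  steps$age_out_of_range <- sum(!ok_age)
  dedup <- dedup[ok_age, ]
  ok_res <- !is.na(dedup$resident) & dedup$resident
  steps$non_resident <- sum(!ok_res)
  dedup <- dedup[ok_res, ]
  list(index = dedup,
       attrition = data.frame(rule = names(steps),
                              n_excluded = unlist(steps, use.names = FALSE)))
}

#' Select HF (hip fracture) index admissions
#'
#' Keeps admissions with a principal or secondary 820.xx diagnosis and
#' applies, in order, the seven exclusions: (1) hip fracture in the
#' previous two years, (2) age outside 65-100, (3) non-resident,
#' (4) cancer on the index admission or in the previous two years,
#' (5) multiple-trauma DRG, (6) direct admission to intensive care,
#' (7) no surgery and death within the first 48 hours.
#'
#' @param discharges Discharge-record data frame (the full registry; prior
#'   admissions are looked up here).
#' @param deaths Death-registry data frame.
#' @param spec A [hf_cohort_spec()].
#' @return `list(index = <data frame>, attrition = <rule, n_excluded>)`.
#' @export
select_hf_index <- function(discharges, deaths, spec = hf_cohort_spec()) {
  all_dx <- dx_string(discharges$principal_dx, discharges$secondary_dx)
  is_hf <- match_any_prefix(all_dx, spec$index_codes)
  cand <- discharges[is_hf, ]
  cand_dx <- all_dx[is_hf]
  steps <- list()

  # history of HF-coded admissions is kept from the *full* registry, so a
  # pre-study-period fracture still triggers exclusion 1
  hf_hist <- discharges[is_hf, c("patient_id", "admission_date")]
  if (!is.null(spec$study_period)) {
    inp <- cand$admission_date >= spec$study_period[1] &
      cand$admission_date <= spec$study_period[2]
    steps$outside_study_period <- sum(!inp)
    cand <- cand[inp, ]; cand_dx <- cand_dx[inp]
  }

  # 1) hip fracture in the previous two years (any prior HF-coded admission)
  prior_hf <- mapply(function(pid, d) {
    h <- hf_hist$admission_date[hf_hist$patient_id == pid]
    any(h >= d - spec$lookback_days & h < d)
  }, cand$patient_id, cand$admission_date)
  steps$hip_fracture_previous_2y <- sum(prior_hf)
  cand <- cand[!prior_hf, ]; cand_dx <- cand_dx[!prior_hf]

  # 2) age
  ok <- !is.na(cand$age) & cand$age >= spec$age_range[1] &
    cand$age <= spec$age_range[2]
  steps$age_out_of_range <- sum(!ok)
  cand <- cand[ok, ]; cand_dx <- cand_dx[ok]

  # 3) residence
  ok <- !is.na(cand$resident) & cand$resident
  steps$non_resident <- sum(!ok)
  cand <- cand[ok, ]; cand_dx <- cand_dx[ok]

  # 4) cancer on index or in previous two years
  idx_cancer <- match_code_range(cand_dx, spec$cancer_range[1],
                                 spec$cancer_range[2])
  hist_cancer <- mapply(function(pid, d) {
    h <- discharges[discharges$patient_id == pid &
                      discharges$admission_date >= d - spec$lookback_days &
                      discharges$admission_date < d, ]
    if (!nrow(h)) return(FALSE)
    any(match_code_range(dx_string(h$principal_dx, h$secondary_dx),
                         spec$cancer_range[1], spec$cancer_range[2]))
  }, cand$patient_id, cand$admission_date)
  excl <- idx_cancer | hist_cancer
  steps$cancer <- sum(excl)
  cand <- cand[!excl, ]

  # 5) multiple-trauma DRG
  excl <- as.character(cand$drg) %in% spec$trauma_drg
  steps$multiple_trauma_drg <- sum(excl)
  cand <- cand[!excl, ]

  # 6) direct intensive-care admission
  icu <- if ("icu_admission" %in% names(cand)) cand$icu_admission else FALSE
  icu <- !is.na(icu) & as.logical(icu)
  steps$direct_icu_admission <- sum(icu)
  cand <- cand[!icu, ]

  # 7) no surgery and death within the first 48 hours
  if (nrow(cand)) {
    surg <- outcome_surgery_48h(cand, spec$surgery_codes)
    dmat <- deaths[match(cand$patient_id, deaths$patient_id), "death_date"]
    died48 <- (!is.na(dmat) &
                 as.numeric(dmat - cand$admission_date) <= 1) |
      (cand$disposition == "died" &
         as.numeric(cand$discharge_date - cand$admission_date) <= 1)
    excl <- surg == 0L & died48
  } else excl <- logical(0)
  steps$death_within_48h_no_surgery <- sum(excl)
  cand <- cand[!excl, ]

  list(index = cand,
       attrition = data.frame(rule = names(steps),
                              n_excluded = unlist(steps, use.names = FALSE)))
}

#' Comorbidity flags from the two-year lookback
#'
#' For each index admission, a condition is flagged iff any admission of
#' the same patient with an admission date in `[index - lookback_days,
#' index)` carries a mapped code prefix as principal or secondary
#' diagnosis. Index-admission diagnoses never set these flags (conditions
#' ascertainable at the index admission are handled separately by
#' [index_secondary_flags()]).
#'
#' @param index Data frame of index admissions (`admission_id`,
#'   `patient_id`, `admission_date`).
#' @param history Discharge data frame to search (may contain the index
#'   rows themselves; they are excluded by the half-open window).
#' @param map Named list of ICD-9-CM prefixes per condition.
#' @param lookback_days Window length in days.
#' @return Integer matrix, one row per index admission, one column per
#'   condition.
#' @export
lookback_comorbidities <- function(index, history, map, lookback_days = 730L) {
  if (is.null(names(map)) || any(!nzchar(names(map))))
    stop_config("comorbidity map must be a named list of prefix vectors")
  out <- matrix(0L, nrow(index), length(map),
                dimnames = list(NULL, names(map)))
  if (!nrow(index) || !nrow(history)) return(out)
  h <- history[history$patient_id %in% index$patient_id,
               c("patient_id", "admission_date", "principal_dx", "secondary_dx")]
  if (!nrow(h)) return(out)
  h$dx <- dx_string(h$principal_dx, h$secondary_dx)
  pairs <- merge(
    data.frame(row = seq_len(nrow(index)), patient_id = index$patient_id,
               index_date = index$admission_date, stringsAsFactors = FALSE),
    h, by = "patient_id")
  inwin <- pairs$admission_date >= pairs$index_date - lookback_days &
    pairs$admission_date < pairs$index_date
  pairs <- pairs[inwin, ]
  if (!nrow(pairs)) return(out)
  for (cond in names(map)) {
    hit <- match_any_prefix(pairs$dx, map[[cond]])
    if (any(hit)) out[unique(pairs$row[hit]), cond] <- 1L
  }
  out
}

#' Condition flags from index-admission secondary diagnoses
#'
#' Only conditions listed in the spec's `index_map` may be set from the
#' index admission itself (they are kept distinct from the lookback flags,
#' as acute-phase and chronic ascertainment can act differently).
#'
#' @param index Data frame of index admissions.
#' @param index_map Named list of ICD-9-CM prefixes.
#' @return Integer matrix, one column per listed condition.
#' @export
index_secondary_flags <- function(index, index_map) {
  out <- matrix(0L, nrow(index), length(index_map),
                dimnames = list(NULL, names(index_map)))
  if (!nrow(index) || !length(index_map)) return(out)
  sec <- strip_dots(index$secondary_dx)
  for (cond in names(index_map))
    out[, cond] <- as.integer(match_any_prefix(sec, index_map[[cond]]))
  out
}

#' Drug-exposure flags from the dispensing registry
#'
#' A class is flagged iff at least one dispensing dated in
#' `[index - window_days, index)` has an ATC code starting with one of the
#' class's `include` prefixes and none of its `exclude` prefixes. A
#' dispensing on the index date itself does not count ("preceding the
#' admission"). Malformed ATC codes (not letter-digit-digit) are skipped
#' with a warning.
#'
#' @param index Data frame of index admissions.
#' @param dispensings Dispensing data frame (`patient_id`,
#'   `dispensing_date`, `atc`).
#' @param class_map Named list: class -> `list(include=, exclude=)`.
#' @param window_days Exposure window in days.
#' @return Integer matrix, one column per drug class.
#' @export
drug_exposure_flags <- function(index, dispensings, class_map,
                                window_days = 90L) {
  out <- matrix(0L, nrow(index), length(class_map),
                dimnames = list(NULL, names(class_map)))
  if (!nrow(index) || !length(class_map) || !nrow(dispensings)) return(out)
  bad <- !grepl("^[A-Z][0-9]{2}", dispensings$atc)
  if (any(bad)) {
    warning(sprintf("%d dispensing(s) with malformed ATC code skipped",
                    sum(bad)))
    dispensings <- dispensings[!bad, ]
  }
  d <- dispensings[dispensings$patient_id %in% index$patient_id, ]
  if (!nrow(d)) return(out)
  pairs <- merge(
    data.frame(row = seq_len(nrow(index)), patient_id = index$patient_id,
               index_date = index$admission_date, stringsAsFactors = FALSE),
    d, by = "patient_id")
  inwin <- pairs$dispensing_date >= pairs$index_date - window_days &
    pairs$dispensing_date < pairs$index_date
  pairs <- pairs[inwin, ]
  if (!nrow(pairs)) return(out)
  for (cls in names(class_map)) {
    m <- class_map[[cls]]
    hit <- rep(FALSE, nrow(pairs))
    for (p in m$include) hit <- hit | startsWith(pairs$atc, p)
    for (p in m$exclude %||% character()) hit <- hit & !startsWith(pairs$atc, p)
    if (any(hit)) out[unique(pairs$row[hit]), cls] <- 1L
  }
  out
}

#' Categorise systolic blood pressure
#'
#' @param sbp Numeric vector of mmHg values; `NA` = not measured.
#' @return Character vector in `{"le100", "gt100", "missing"}` (100 mmHg
#'   belongs to `le100`).
#' @export
categorize_sbp <- function(sbp) {
  if (any(!is.na(sbp) & sbp <= 0))
    stop_config("systolic blood pressure must be positive")
  ifelse(is.na(sbp), "missing", ifelse(sbp <= 100, "le100", "gt100"))
}

#' Categorise the International Normalised Ratio
#'
#' @param inr Numeric vector; `NA` = not measured.
#' @return Character vector in `{"in_range", "out_of_range", "missing"}`;
#'   the normal range 0.9-1.2 is inclusive at both bounds.
#' @export
categorize_inr <- function(inr) {
  if (any(!is.na(inr) & inr <= 0)) stop_config("INR must be positive")
  ifelse(is.na(inr), "missing",
         ifelse(inr >= 0.9 & inr <= 1.2, "in_range", "out_of_range"))
}

#' 30-day mortality outcome
#'
#' 1 iff the patient died within 30 days of the index admission date
#' (inclusive day 30), using the death registry or an in-hospital death
#' disposition with discharge within 30 days.
#'
#' @param index Data frame of index admissions.
#' @param deaths Death-registry data frame (at most one row per patient).
#' @return Integer 0/1 vector.
#' @export
outcome_30d_mortality <- function(index, deaths) {
  if (anyDuplicated(deaths$patient_id))
    stop_config("death registry must have at most one record per patient")
  dd <- deaths$death_date[match(index$patient_id, deaths$patient_id)]
  if (any(!is.na(dd) & dd < index$admission_date))
    stop_config("death date precedes admission date")
  reg <- !is.na(dd) & as.numeric(dd - index$admission_date) <= 30
  his <- index$disposition == "died" &
    as.numeric(index$discharge_date - index$admission_date) <= 30
  as.integer(reg | his)
}

#' Surgery-within-48-hours outcome
#'
#' 1 iff the earliest procedure matching `surgery_codes` falls on calendar
#' day 0 or 1 relative to the admission date. Procedure fields use the
#' `"code:YYYY-MM-DD"` format, `;`-separated.
#'
#' @param index Data frame of index admissions with a `procedures` column.
#' @param surgery_codes Procedure-code prefixes.
#' @return Integer 0/1 vector.
#' @export
outcome_surgery_48h <- function(index, surgery_codes) {
  vapply(seq_len(nrow(index)), function(i) {
    pr <- index$procedures[i]
    if (is.na(pr) || !nzchar(pr)) return(0L)
    parts <- strsplit(strsplit(pr, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
    dates <- as.Date(vapply(parts, `[`, "", 2L))
    codes <- strip_dots(vapply(parts, `[`, "", 1L))
    hit <- rep(FALSE, length(codes))
    for (p in strip_dots(surgery_codes)) hit <- hit | startsWith(codes, p)
    if (!any(hit)) return(0L)
    d <- min(dates[hit])
    if (d < index$admission_date[i])
      stop_config("procedure date precedes admission date (%s)",
                  index$admission_id[i])
    as.integer(as.numeric(d - index$admission_date[i]) <= 1)
  }, integer(1))
}

#' Drop episodes with incomplete administrative data
#'
#' Removes rows missing any of the required administrative fields.
#' Missing *clinical* values are never dropped: they form an explicit
#' `missing` category.
#'
#' @param rows Cohort data frame.
#' @param required Administrative fields that must be present.
#' @return `list(rows = <filtered>, n_removed = <count>)`.
#' @export
complete_case_filter <- function(rows,
                                 required = c("age", "gender", "hospital_id")) {
  if (!nrow(rows)) return(list(rows = rows, n_removed = 0L))
  ok <- rep(TRUE, nrow(rows))
  for (f in required) {
    v <- rows[[f]]
    ok <- ok & !is.na(v) & (!is.character(v) | nzchar(v))
  }
  list(rows = rows[ok, ], n_removed = sum(!ok))
}

#' Build an analysis-ready cohort from registry tables
#'
#' Runs the full pipeline for the spec's cohort: index selection (with the
#' AMI complication-presentation rule or the seven HF exclusions), episode
#' de-duplication, two-year comorbidity lookback, index-admission condition
#' flags, three-month drug exposure, clinical categorisation, outcome
#' definition and the complete-administrative-data filter.
#'
#' @param registries List with `discharges`, `dispensings`, `clinical`,
#'   `deaths` (as produced by [generate_population()] or
#'   [read_registries()]).
#' @param spec An [ami_cohort_spec()] or [hf_cohort_spec()].
#' @return `list(cohort = <one row per episode>, attrition = <rule,
#'   n_excluded>)`. The cohort carries `episode_id`, `patient_id`,
#'   `hospital_id`, `outcome`, `age`, `female`, one 0/1 column per
#'   comorbidity / index condition / drug class, the clinical category
#'   column and its 0/1 indicators (reference levels: SBP > 100, INR in
#'   range).
#' @export
build_cohort <- function(registries, spec) {
  disch <- registries$discharges
  if (spec$cohort == "AMI") {
    sel <- select_ami_index(disch, spec)
  } else {
    sel <- select_hf_index(disch, registries$deaths, spec)
  }
  idx <- sel$index
  attrition <- sel$attrition

  com <- lookback_comorbidities(idx, disch, spec$comorbidity_map,
                                spec$lookback_days)
  ind <- index_secondary_flags(idx, spec$index_map)
  drg <- drug_exposure_flags(idx, registries$dispensings, spec$drug_map,
                             spec$drug_window_days)

  clin <- registries$clinical
  row <- match(idx$admission_id, clin$admission_key)
  cohort <- data.frame(
    episode_id = idx$admission_id, patient_id = idx$patient_id,
    hospital_id = idx$hospital_id, age = idx$age, gender = idx$gender,
    female = as.integer(idx$gender == "F"),
    stringsAsFactors = FALSE
  )
  cohort <- cbind(cohort, as.data.frame(com), as.data.frame(ind),
                  as.data.frame(drg))
  if (spec$cohort == "AMI") {
    sbp <- clin$sbp[row]
    cohort$sbp_cat <- categorize_sbp(sbp)
    cohort$sbp_le100 <- as.integer(cohort$sbp_cat == "le100")
    cohort$sbp_missing <- as.integer(cohort$sbp_cat == "missing")
    cohort$outcome <- outcome_30d_mortality(idx, registries$deaths)
  } else {
    inr <- clin$inr[row]
    cohort$inr_cat <- categorize_inr(inr)
    cohort$inr_out_of_range <- as.integer(cohort$inr_cat == "out_of_range")
    cohort$inr_missing <- as.integer(cohort$inr_cat == "missing")
    cohort$outcome <- outcome_surgery_48h(idx, spec$surgery_codes)
  }

  cc <- complete_case_filter(cohort)
  attrition <- rbind(attrition,
                     data.frame(rule = "incomplete_administrative_data",
                                n_excluded = cc$n_removed))
  rownames(cc$rows) <- NULL
  list(cohort = cc$rows, attrition = attrition)
}
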