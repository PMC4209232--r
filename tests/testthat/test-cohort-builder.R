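# Cohort construction rules

test_that("episode de-duplication anchors at the first admission", {
  mk <- function(days) {
    do.call(rbind, lapply(seq_along(days), function(i)
      make_admission(admission_id = paste0("A", i),
                     admission_date = as.Date("2010-01-01") + days[i])))
  }
  expect_equal(nrow(dedupe_episodes(mk(c(0, 20)), 28)), 1)     # 20 < 28
  expect_equal(nrow(dedupe_episodes(mk(c(0, 30)), 28)), 2)     # 30 > 28
  expect_equal(nrow(dedupe_episodes(mk(c(0, 28)), 28)), 1)     # boundary: same episode
  got <- dedupe_episodes(mk(c(0, 20, 40)), 28)                 # windows re-anchor
  expect_equal(as.numeric(got$admission_date - as.Date("2010-01-01")), c(0, 40))
  # exact duplicates: warn, keep one
  dup <- rbind(mk(0), mk(0))
  expect_warning(out <- dedupe_episodes(dup, 28), "duplicate")
  expect_equal(nrow(out), 1)
})

test_that("AMI presentation includes complication-coded admissions", {
  spec <- ami_cohort_spec()
  a <- rbind(
    make_admission("P1", "A1", principal_dx = "41071"),
    make_admission("P2", "A2", principal_dx = "4275", secondary_dx = "4109"),
    make_admission("P3", "A3", principal_dx = "4271", secondary_dx = "4101"),
    make_admission("P4", "A4", principal_dx = "486"))
  got <- select_ami_index(a, spec)$index
  expect_setequal(got$admission_id, c("A1", "A3"))
})

test_that("lookback comorbidity flags respect the half-open two-year window", {
  idx <- make_admission("P1", "IDX", admission_date = as.Date("2010-06-01"))
  hist_at <- function(days_before, dx = "2500")
    make_admission("P1", paste0("H", days_before),
                   admission_date = as.Date("2010-06-01") - days_before,
                   principal_dx = dx)
  map <- list(diabetes = "250")
  flag <- function(h) unname(lookback_comorbidities(idx, h, map, 730)[1, "diabetes"])
  expect_equal(flag(hist_at(365)), 1L)
  expect_equal(flag(hist_at(800)), 0L)
  expect_equal(flag(hist_at(730)), 1L)   # exactly at the window start: inside
  expect_equal(flag(hist_at(0)), 0L)     # index date itself: not prior
  # code only on the index secondary dx does not set the lookback flag
  idx2 <- make_admission("P1", "IDX", secondary_dx = "2500")
  expect_equal(unname(lookback_comorbidities(idx2, idx2, map, 730)[1, "diabetes"]), 0L)
  expect_equal(unname(index_secondary_flags(idx2, list(diabetes_index = "250"))[1, 1]), 1L)
  expect_error(lookback_comorbidities(idx, hist_at(10), list("250"), 730),
               "named")
})

test_that("drug exposure uses a half-open 90-day window with ATC prefixes", {
  idx <- make_admission("P1", "IDX", admission_date = as.Date("2010-06-01"))
  disp <- function(days_before, atc)
    data.frame(patient_id = "P1",
               dispensing_date = as.Date("2010-06-01") - days_before,
               atc = atc, stringsAsFactors = FALSE)
  map <- list(ace_inhibitors = list(include = c("C09A", "C09B")),
              other_lipid = list(include = "C10", exclude = "C10AA"))
  flags <- function(d) drug_exposure_flags(idx, d, map, 90)
  expect_equal(unname(flags(disp(10, "C09AA05"))[1, "ace_inhibitors"]), 1L)
  expect_equal(unname(flags(disp(100, "C09AA05"))[1, "ace_inhibitors"]), 0L)
  expect_equal(unname(flags(disp(0, "C09AA05"))[1, "ace_inhibitors"]), 0L)  # index day
  expect_equal(unname(flags(disp(90, "C09AA05"))[1, "ace_inhibitors"]), 1L) # window start
  # exclusion prefix: statin is C10 but explicitly excluded
  expect_equal(unname(flags(disp(10, "C10AA05"))[1, "other_lipid"]), 0L)
  expect_equal(unname(flags(disp(10, "C10AB01"))[1, "other_lipid"]), 1L)
  expect_warning(out <- flags(disp(10, "badcode")), "malformed ATC")
  expect_equal(sum(out), 0L)
})

test_that("clinical variables are categorised with inclusive bounds", {
  expect_equal(categorize_sbp(c(95, 100, 101, NA)),
               c("le100", "le100", "gt100", "missing"))
  expect_error(categorize_sbp(-5), "positive")
  expect_equal(categorize_inr(c(1.0, 0.9, 1.2, 1.3, 0.85, NA)),
               c("in_range", "in_range", "in_range", "out_of_range",
                 "out_of_range", "missing"))
  expect_error(categorize_inr(0), "positive")
})

test_that("outcomes use inclusive day-30 mortality and day-0/1 surgery", {
  idx <- make_admission("P1", "IDX", admission_date = as.Date("2010-06-01"))
  death_on <- function(day)
    data.frame(patient_id = "P1", death_date = as.Date("2010-06-01") + day)
  expect_equal(outcome_30d_mortality(idx, death_on(10)), 1L)
  expect_equal(outcome_30d_mortality(idx, death_on(30)), 1L)
  expect_equal(outcome_30d_mortality(idx, death_on(31)), 0L)
  expect_error(outcome_30d_mortality(idx, death_on(-1)), "precedes")
  # in-hospital death disposition counts even without a registry row
  idx2 <- make_admission("P2", "IDX2", disposition = "died", los = 5)
  expect_equal(outcome_30d_mortality(idx2, death_on(10)[0, ]), 1L)

  surg <- function(day, code = "8151")
    make_admission("P1", "IDX", admission_date = as.Date("2010-06-01"),
                   procedures = sprintf("%s:%s", code,
                                        as.Date("2010-06-01") + day))
  codes <- hf_cohort_spec()$surgery_codes
  expect_equal(outcome_surgery_48h(surg(0), codes), 1L)
  expect_equal(outcome_surgery_48h(surg(1), codes), 1L)
  expect_equal(outcome_surgery_48h(surg(2), codes), 0L)
  expect_equal(outcome_surgery_48h(make_admission("P1", "IDX"), codes), 0L)
  expect_equal(outcome_surgery_48h(surg(1, code = "9999"), codes), 0L)
  expect_error(outcome_surgery_48h(surg(-2), codes), "precedes")
})

test_that("complete-case filter drops administrative but not clinical gaps", {
  rows <- data.frame(age = c(70, NA, 65), gender = c("M", "F", ""),
                     hospital_id = c("H1", "H1", "H2"),
                     sbp_cat = c("missing", "gt100", "le100"),
                     stringsAsFactors = FALSE)
  got <- complete_case_filter(rows)
  expect_equal(got$n_removed, 2)
  expect_equal(got$rows$age, 70)           # sbp 'missing' row retained
  empty <- complete_case_filter(rows[0, ])
  expect_equal(empty$n_removed, 0)
  expect_equal(nrow(empty$rows), 0)
})

test_that("the cohort builder recovers generator ground truth end to end", {
  cfg <- generator_config("AMI", n_patients = 3000, n_hospitals = 12, seed = 17)
  reg <- generate_population(cfg)
  b <- build_cohort(reg, ami_cohort_spec())
  co <- b$cohort
  # one row per surviving episode, never more than input admissions
  expect_lte(nrow(co), nrow(reg$discharges))
  expect_equal(anyDuplicated(co$episode_id), 0)
  tr <- reg$truth[match(co$episode_id, reg$truth$admission_id), ]
  expect_equal(co$outcome, tr$outcome)
  # flags equal the generator's recorded (in-window) status exactly:
  # comorbidities placed outside the lookback must come back 0
  for (nm in cfg$covariates$name)
    expect_equal(co[[nm]], tr[[paste0(nm, "_recorded")]],
                 info = nm, ignore_attr = TRUE)
  # attrition accounts exactly for candidates minus cohort
  n_candidates <- sum(startsWith(reg$discharges$principal_dx, "410") |
                        (grepl("(^|;)410", reg$discharges$secondary_dx) &
                           reg$discharges$principal_dx %in%
                           ami_cohort_spec()$complication_codes))
  expect_equal(sum(b$attrition$n_excluded), n_candidates - nrow(co))
})
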