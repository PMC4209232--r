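# Direct standardisation, K correction, funnel classification

test_that("covariate centring is exact and idempotent", {
  X <- cbind(ones = rep(1, 10), bin = rep(c(1, 0), c(4, 6)))
  cc <- center_covariates(X)
  expect_equal(unname(cc$means), c(1, 0.4))
  expect_equal(unique(cc$X[, "ones"]), 0)
  expect_setequal(round(unique(cc$X[, "bin"]), 10), c(0.6, -0.4))
  twice <- center_covariates(cc$X)
  expect_equal(twice$X, cc$X)
  # exact reconstruction from the returned means
  expect_equal(sweep(cc$X, 2, -cc$means), X, ignore_attr = TRUE)
})

test_that("the saturated hospital model reproduces observed log-odds", {
  hosp <- rep(c("A", "B"), each = 100)
  y <- c(rep(1, 20), rep(0, 80), rep(1, 35), rep(0, 65))
  hm <- fit_hospital_model(NULL, hosp, y, min_volume = 10)
  expect_equal(hm$estimates$estimate, qlogis(c(0.2, 0.35)), tolerance = 1e-6)
  # two identical hospitals get equal estimates
  hosp2 <- rep(c("A", "B"), 100)
  y2 <- rep(c(1, 1, 0, 0), 50)
  hm2 <- fit_hospital_model(NULL, hosp2, y2, min_volume = 10)
  expect_equal(hm2$estimates$estimate[1], hm2$estimates$estimate[2],
               tolerance = 1e-8)
  # a constant adjustment covariate changes nothing (centred to zero)
  hm3 <- fit_hospital_model(center_covariates(cbind(k = rep(1, 200)))$X,
                            hosp, y, min_volume = 10)
  expect_equal(hm3$estimates$estimate, hm$estimates$estimate,
               tolerance = 1e-8)
})

test_that("degenerate hospitals are penalised or excluded by volume", {
  hosp <- rep(c("A", "B", "C"), c(100, 100, 5))
  y <- c(rbinom(100, 1, 0.3), rep(0, 100), rep(1, 5))
  y[1:30] <- 1
  hm <- fit_hospital_model(NULL, hosp, y, min_volume = 10)
  tab <- hm$estimates
  expect_equal(tab$flag[tab$hospital_id == "C"], "low_volume")
  expect_true(is.na(tab$estimate[tab$hospital_id == "C"]))
  expect_equal(tab$flag[tab$hospital_id == "B"], "penalised")
  expect_true(is.finite(tab$estimate[tab$hospital_id == "B"]))
  expect_lt(tab$estimate[tab$hospital_id == "B"], qlogis(0.01))
})

test_that("penalised IRLS agrees with glm on regular data", {
  set.seed(81)
  X <- cbind(1, rbinom(500, 1, 0.4), rnorm(500))
  colnames(X) <- c("i", "b", "z")
  y <- rbinom(500, 1, plogis(-1 + 0.8 * X[, "b"] + 0.5 * X[, "z"]))
  ref <- glm.fit(X, y, family = binomial())
  alt <- fit_logistic(X, y, intercept = FALSE, penalty = rep(0, 3))
  expect_equal(unname(alt$coefficients), unname(ref$coefficients),
               tolerance = 1e-6)
})

test_that("back-transform and the correction coefficient follow the formulas", {
  expect_equal(back_transform(0, 1), 0.5)
  expect_equal(back_transform(qlogis(0.2), 1), 0.2)
  expect_equal(back_transform(0, 1.2), 0.6)
  expect_warning(back_transform(3, 1.2), "above 1")
  expect_error(back_transform(0, 0), "> 0")
  expect_equal(correction_k(c(0.5, 0.5), c(10, 10), 10), 1)
  expect_equal(correction_k(c(0.2, 0.4), c(100, 100), 75), 1.25)
  expect_equal(correction_k(c(0.2, 0.4), c(200, 200), 150),
               correction_k(c(0.2, 0.4), c(100, 100), 75))
  expect_error(correction_k(c(0, 0), c(10, 10), 5), "> 0")
  expect_error(correction_k(c(0.1), c(10, 10), 5), "equal length")
})

test_that("standardisation conserves events and tracks true excess risk", {
  cfg <- generator_config("AMI", n_patients = 6000, n_hospitals = 15,
                          hospital_effect_sd = 0.3, seed = 23)
  reg <- generate_population(cfg)
  co <- build_cohort(reg, ami_cohort_spec())$cohort
  std <- standardise(co, c("age", "female", "diabetes", "sbp_le100",
                           "sbp_missing"), min_volume = 10)
  tab <- std$hospitals
  expect_lt(abs(sum(tab$adjusted_proportion * tab$n, na.rm = TRUE) -
                  std$total_events) / std$total_events, 1e-8)
  expect_true(all(tab$adjusted_proportion >= 0, na.rm = TRUE))
  expect_gt(std$k, 0)
  # the hospital with the largest true effect has the largest adjusted rate
  u <- reg$hospital_effects
  top <- sprintf("H%03d", which.max(u))
  est <- tab$adjusted_proportion[match(top, tab$hospital_id)]
  expect_gte(rank(tab$adjusted_proportion)[match(top, tab$hospital_id)],
             nrow(tab) - 2)  # among the top three
  # ranking of adjusted proportions correlates with the true effects
  expect_gt(cor(u[as.integer(substring(tab$hospital_id, 2))],
                tab$adjusted_proportion, method = "spearman"), 0.6)
})

test_that("funnel limits follow the normal approximation and clip at 0", {
  lim <- funnel_limits(0.5, 100, 0.95)
  expect_equal(lim$lower, 0.402, tolerance = 1e-3)
  expect_equal(lim$upper, 0.598, tolerance = 1e-3)
  l100 <- funnel_limits(0.3, 100, 0.95)
  l400 <- funnel_limits(0.3, 400, 0.95)
  expect_equal((l100$upper - 0.3) / (l400$upper - 0.3), 2, tolerance = 1e-10)
  expect_equal(funnel_limits(0.05, 10, 0.998)$lower, 0)
  expect_error(funnel_limits(0, 10), "\\(0, 1\\)")
  bin <- funnel_limits(0.1, 200, 0.95, method = "binomial")
  expect_equal(bin$lower, qbinom(0.025, 200, 0.1) / 200)
})

test_that("hospitals on a control limit are classified inside", {
  lim <- funnel_limits(0.2, 100, 0.95)
  prof <- forge_profile(c(lim$upper, lim$upper + 1e-9, 0.2,
                          funnel_limits(0.2, 100, 0.998)$upper + 0.05),
                        rep(100, 4), overall = 0.2)
  chart <- funnel_chart(prof, target = 0.2)
  cls <- chart$points$classification
  expect_equal(cls[1], "inside")        # exactly on the 95% limit
  expect_equal(cls[2], "outside_95")    # a hair above it
  expect_equal(cls[3], "inside")
  expect_equal(cls[4], "outside_998")
  expect_equal(chart$points$direction[4], "high")
})

test_that("funnel charts draw without error on a file device", {
  set.seed(95)
  prof <- forge_profile(rbinom(30, 150, 0.12) / 150, rep(150, 30),
                        overall = 0.12)
  chart <- funnel_chart(prof, target = 0.12)
  f <- withr::local_tempfile(fileext = ".pdf")
  grDevices::pdf(f)
  expect_no_error(plot(chart, overlay = chart))
  grDevices::dev.off()
  expect_gt(file.size(f), 0)
})

test_that("rank agreement matches its oracle cases", {
  p <- data.frame(hospital_id = sprintf("H%02d", 1:20),
                  adjusted_proportion = seq(0.05, 0.24, by = 0.01),
                  classification = "inside", stringsAsFactors = FALSE)
  same <- rank_agreement(p, p)
  expect_equal(same$rho, 1)
  expect_equal(same$concordance, 1)
  rev <- p; rev$adjusted_proportion <- base::rev(p$adjusted_proportion)
  expect_equal(rank_agreement(p, rev)$rho, -1)
  # independent profiles decorrelate
  set.seed(91)
  q <- p; q$adjusted_proportion <- runif(20)
  r <- replicate(30, {
    qq <- q; qq$adjusted_proportion <- runif(20)
    rank_agreement(p, qq)$rho
  })
  expect_lt(abs(mean(r)), 0.15)
  expect_error(rank_agreement(p, p[-1, ]), "same hospitals")
})

test_that("multilevel sensitivity shrinks to the mean when hospitals are alike", {
  cfg <- generator_config("AMI", n_patients = 2000, n_hospitals = 10,
                          hospital_effect_sd = 0, seed = 29)
  reg <- generate_population(cfg)
  co <- build_cohort(reg, ami_cohort_spec())$cohort
  ml <- multilevel_sensitivity(co, c("age", "female"))
  expect_lt(ml$sd, 0.15)
  spread <- diff(range(ml$hospitals$shrunken_proportion))
  obs <- tapply(co$outcome, co$hospital_id, mean)
  expect_lt(spread, diff(range(obs)) + 1e-12)
  expect_error(multilevel_sensitivity(co[co$hospital_id == "H001", ],
                                      character(0)), "at least 2")
})
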