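# Risk-adjustment models and bootstrap stepwise selection

test_that("logistic fits match closed-form oracles", {
  # 2x2 table (a,b,c,d) = (30,70,10,90): OR must equal the cross-product
  x <- c(rep(1, 100), rep(0, 100))
  y <- c(rep(1, 30), rep(0, 70), rep(1, 10), rep(0, 90))
  f <- fit_logistic(cbind(exposed = x), y)
  expect_equal(unname(f$or["exposed"]), (30 * 90) / (70 * 10),
               tolerance = 1e-6)
  # intercept-only fit on 40% events
  f0 <- fit_logistic(matrix(numeric(0), nrow = 100, ncol = 0),
                     rep(c(1, 0), c(40, 60)))
  expect_equal(unname(f0$coefficients["(Intercept)"]), qlogis(0.4),
               tolerance = 1e-6)
  # a covariate independent of the outcome has OR ~ 1
  set.seed(21)
  z <- rbinom(10000, 1, 0.5)
  yy <- rbinom(10000, 1, 0.3)
  fn <- fit_logistic(cbind(z = z), yy)
  expect_lt(abs(fn$coefficients["z"]), 3 * fn$se["z"])
  expect_error(fit_logistic(cbind(zero = rep(0, 50)), rbinom(50, 1, .5)),
               "constant-zero")
})

test_that("separation is flagged rather than thrown", {
  x <- c(rep(0, 20), rep(1, 20))
  y <- x                                  # perfect separation
  f <- fit_logistic(cbind(x = x), y)
  expect_false(f$ok)
})

test_that("c-statistic equals brute-force pair counting, ties included", {
  expect_equal(c_statistic(c(0.9, 0.1), c(1, 0)), 1)
  expect_equal(c_statistic(rep(0.3, 6), c(1, 0, 1, 0, 0, 1)), 0.5)
  expect_equal(c_statistic(c(0.2, 0.4, 0.6, 0.8), c(0, 1, 0, 1)), 0.75)
  set.seed(33)
  for (i in 1:25) {
    n <- sample(10:200, 1)
    scores <- sample(seq(0, 1, by = 0.05), n, replace = TRUE)  # force ties
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
    expect_equal(c_statistic(scores, labels), brute_force_c(scores, labels),
                 tolerance = 1e-12)
  }
  # invariance under strictly monotone transforms
  set.seed(34)
  s <- runif(300); l <- rbinom(300, 1, 0.3); l[1:2] <- c(0, 1)
  expect_equal(c_statistic(s, l), c_statistic(qlogis(s), l))
  expect_equal(c_statistic(s, l), c_statistic(s^3, l))
  expect_error(c_statistic(s, rep(1, 300)), "both outcome classes")
})

test_that("c-statistic agrees with an independent ROC implementation", {
  set.seed(35)
  s <- runif(500); l <- rbinom(500, 1, 0.25); l[1:2] <- c(0, 1)
  ref <- as.numeric(pROC::auc(pROC::roc(l, s, quiet = TRUE,
                                        direction = "<")))
  expect_equal(c_statistic(s, l), ref, tolerance = 1e-10)
})

test_that("stepwise selection finds signal and respects forced terms", {
  d <- sim_cohort_frame(2000, beta = c(strong = log(3)), prevalence = 0.3,
                        base_rate = 0.15, n_noise = 2, seed = 41)
  res <- stepwise_select(d, d$outcome, c("strong", "noise1", "noise2"),
                         forced = c("age", "female"))
  expect_true("strong" %in% res$selected)
  expect_true(all(c("age", "female") %in% names(res$fit$coefficients)))
  # empty candidate list: forced-only model
  res0 <- stepwise_select(d, d$outcome, character(0), c("age", "female"))
  expect_identical(res0$selected, character(0))
  expect_error(stepwise_select(d, d$outcome, c("age"), c("age", "female")),
               "disjoint")
})

test_that("stepwise type-I behaviour: null candidates rarely enter", {
  kept_null <- 0L
  for (i in 1:50) {
    d <- sim_cohort_frame(600, beta = c(strong = 0), prevalence = 0.3,
                          base_rate = 0.2, n_noise = 0, seed = 100 + i)
    d$pure_noise <- rbinom(600, 1, 0.25)
    res <- stepwise_select(d, d$outcome, "pure_noise", c("age", "female"))
    if (length(res$selected) == 0) kept_null <- kept_null + 1L
  }
  expect_gte(kept_null / 50, 0.9)
})

test_that("bootstrap stepwise is reproducible and honours thresholds", {
  d <- sim_cohort_frame(1200, beta = c(strong = log(2.5)), prevalence = 0.25,
                        base_rate = 0.15, n_noise = 2, seed = 51)
  cfg <- selection_config(n_bootstrap = 30, seed = 7)
  s1 <- bootstrap_stepwise(d, d$outcome, c("strong", "noise1", "noise2"), cfg)
  s2 <- bootstrap_stepwise(d, d$outcome, c("strong", "noise1", "noise2"), cfg)
  expect_identical(s1$frequencies, s2$frequencies)
  expect_identical(s1$retained, s2$retained)
  expect_true("strong" %in% s1$retained)
  expect_true(all(s1$frequencies >= 0 & s1$frequencies <= 1))
  # forced covariates never appear in the frequency table
  expect_false(any(c("age", "female") %in% names(s1$frequencies)))
  # degenerate threshold: anything selected at least once is retained
  tiny <- selection_config(n_bootstrap = 30, retain_fraction = 1e-9, seed = 7)
  s3 <- bootstrap_stepwise(d, d$outcome, c("strong", "noise1", "noise2"), tiny)
  expect_setequal(s3$retained,
                  names(s3$frequencies)[s3$frequencies > 0])
  # absolute-count alternative
  cnt <- selection_config(n_bootstrap = 30, retain_fraction = 1e-9,
                          retain_count = 31, seed = 7)
  s4 <- bootstrap_stepwise(d, d$outcome, c("strong", "noise1", "noise2"), cnt)
  expect_identical(s4$retained, character(0))
})

test_that("model pair comparison reports the discrimination gain", {
  d <- sim_cohort_frame(4000, beta = c(strong = log(4), mild = log(1.3)),
                        prevalence = 0.25, base_rate = 0.12, n_noise = 1,
                        seed = 61)
  cfg <- selection_config(n_bootstrap = 20, seed = 13)
  pair <- build_model_pair(d, d$outcome,
                           candidates_a = c("mild", "noise1"),
                           candidates_b = c("mild", "noise1", "strong"), cfg)
  expect_gt(pair$delta_c, 0)            # true extra signal raises apparent c
  expect_equal(pair$delta_c, pair$c_b - pair$c_a)
  # A = B gives delta exactly 0
  pair2 <- build_model_pair(d, d$outcome, c("mild"), c("mild"), cfg)
  expect_equal(pair2$delta_c, 0)
  expect_error(build_model_pair(d, d$outcome, c("strong"), c("mild"), cfg),
               "extend")
  rep <- model_pair_report(pair, d, d$outcome)
  expect_true("area_under_roc" %in% rep$risk_factor)
  expect_true(all(c("crude_or", "adjusted_or_full") %in% names(rep)))
})

test_that("categorical indicator blocks enter and leave together", {
  set.seed(71)
  n <- 3000
  cat3 <- sample(c("a", "b", "c"), n, replace = TRUE, prob = c(.5, .3, .2))
  d <- data.frame(age = round(rnorm(n, 70, 10)), female = rbinom(n, 1, .4),
                  ind_b = as.integer(cat3 == "b"),
                  ind_c = as.integer(cat3 == "c"))
  lp <- qlogis(0.15) + log(3) * d$ind_b + log(2.5) * d$ind_c
  d$outcome <- rbinom(n, 1, plogis(lp))
  res <- stepwise_select(d, d$outcome,
                         list(category = c("ind_b", "ind_c")),
                         forced = c("age", "female"))
  expect_identical(res$selected, "category")
  expect_true(all(c("ind_b", "ind_c") %in% names(res$fit$coefficients)))
})
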