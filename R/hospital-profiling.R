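# Hospital profiling by direct standardisation ---------------------------
#
# A logistic model with no global intercept, one indicator per hospital and
# mean-centred adjustment covariates estimates each hospital's log odds of
# the outcome for the cohort's average case mix.  Back-transformed
# proportions are rescaled by the correction coefficient
# K = observed events / sum_j p_j n_j so that adjusted expected events sum
# exactly to observed events.  Hospitals are then displayed on a funnel
# plot around the overall rate.

#' Centre covariate columns at their cohort means
#'
#' Each column (continuous covariates and category indicators alike) has
#' its mean subtracted, so that a hospital indicator's coefficient refers
#' to a patient with the cohort-average covariate profile.
#'
#' @param X Numeric matrix or data frame of adjustment covariates.
#' @return `list(X = <centred matrix>, means = <column means>)`.
#' @export
center_covariates <- function(X) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  m <- colMeans(X)
  list(X = sweep(X, 2, m), means = m)
}

#' Fit the no-intercept hospital-indicator logistic model
#'
#' Design: one 0/1 column per hospital (no global intercept) plus the
#' centred adjustment covariates. Hospitals with fewer than `min_volume`
#' episodes are excluded from the model (their estimate is `NA`, flagged
#' `low_volume`). Hospitals with zero or all events among the remainder
#' make the indicator unbounded; they are fitted with a small ridge
#' penalty (1e-4) on the hospital indicators only and flagged `penalised`.
#'
#' @param Xc Centred covariate matrix (may have zero columns).
#' @param hospital Hospital id per episode.
#' @param y 0/1 outcome vector.
#' @param min_volume Minimum episodes per hospital.
#' @return `list(estimates = <per-hospital data frame>, fit = <hosp_logit>,
#'   used = <logical: episode entered the model>)`; the data frame has
#'   `hospital_id`, `n`, `observed_events`, `estimate`, `flag`.
#' @export
fit_hospital_model <- function(Xc, hospital, y, min_volume = 10L) {
  hospital <- as.character(hospital)
  hosp_ids <- sort(unique(hospital))
  n_j <- table(factor(hospital, levels = hosp_ids))
  ev_j <- tapply(y, factor(hospital, levels = hosp_ids), sum)
  flag <- rep("ok", length(hosp_ids))
  flag[n_j < min_volume] <- "low_volume"
  keep_h <- hosp_ids[flag != "low_volume"]
  used <- hospital %in% keep_h
  degen <- keep_h[ev_j[keep_h] == 0 | ev_j[keep_h] == n_j[keep_h]]
  flag[hosp_ids %in% degen] <- "penalised"

  H <- stats::model.matrix(~ f - 1,
                           data.frame(f = factor(hospital[used], levels = keep_h)))
  colnames(H) <- keep_h
  X <- H
  if (!is.null(Xc) && ncol(as.matrix(Xc)) > 0) {
    A <- as.matrix(Xc)[used, , drop = FALSE]
    # a centred constant covariate is identically zero and carries no
    # information: drop it rather than fail
    A <- A[, colSums(A != 0) > 0, drop = FALSE]
    if (ncol(A)) X <- cbind(H, A)
  }
  penalty <- NULL
  if (length(degen)) {
    penalty <- rep(0, ncol(X))
    penalty[seq_along(keep_h)] <- 1e-4
  }
  fit <- fit_logistic(X, y[used], intercept = FALSE, penalty = penalty)
  est <- rep(NA_real_, length(hosp_ids))
  est[match(keep_h, hosp_ids)] <- fit$coefficients[keep_h]
  list(estimates = data.frame(hospital_id = hosp_ids,
                              n = as.integer(n_j),
                              observed_events = as.integer(ev_j),
                              estimate = est, flag = flag,
                              stringsAsFactors = FALSE),
       fit = fit, used = used)
}

#' Back-transform a hospital log-odds estimate to an adjusted proportion
#'
#' `adjusted = plogis(estimate) * k`; values above 1 (possible with a large
#' correction coefficient) are reported with a warning, never clipped.
#'
#' @param estimate Log-odds estimate(s).
#' @param k Correction coefficient (> 0).
#' @return Adjusted proportion(s).
#' @export
back_transform <- function(estimate, k = 1) {
  if (k <= 0) stop_config("correction coefficient k must be > 0")
  out <- invlogit(estimate) * k
  if (any(out > 1, na.rm = TRUE))
    warning("adjusted proportion(s) above 1 after K correction")
  out
}

#' Correction coefficient K
#'
#' `K = actual number of events / sum_j p_j * n_j`, computed in a single
#' pass from the uncorrected back-transformed proportions. Multiplying the
#' p_j by K forces the sum of adjusted expected events to equal the
#' observed event count.
#'
#' @param p Uncorrected per-hospital proportions.
#' @param n Per-hospital group sizes.
#' @param total_events Observed number of events.
#' @return The scalar K.
#' @export
correction_k <- function(p, n, total_events) {
  if (length(p) != length(n)) stop_config("p and n must have equal length")
  denom <- sum(p * n)
  if (!is.finite(denom) || denom <= 0) stop_config("sum of p_j * n_j must be > 0")
  if (total_events <= 0) stop_config("total_events must be > 0")
  total_events / denom
}

#' Risk-adjusted hospital proportions by direct standardisation
#'
#' Composes [center_covariates()], [fit_hospital_model()],
#' [back_transform()] (with k = 1) and [correction_k()]: each hospital's
#' log-odds estimate for the cohort-average case mix is back-transformed
#' and rescaled so adjusted expected events sum to observed events.
#'
#' @param cohort Cohort data frame (one row per episode, with
#'   `hospital_id` and `outcome`).
#' @param covariates Character vector of adjustment covariate columns
#'   (may be empty: the model is then saturated in the hospitals and
#'   adjusted proportions equal observed rates).
#' @param min_volume Minimum hospital volume for inclusion.
#' @return An object of class `standardisation_result` with the
#'   per-hospital table (`hospital_id`, `n`, `observed_events`,
#'   `estimate`, `p_uncorrected`, `adjusted_proportion`, `flag`), the
#'   correction coefficient `k`, `total_events` and the centring vector.
#' @export
standardise <- function(cohort, covariates = character(), min_volume = 10L) {
  y <- cohort$outcome
  if (length(covariates)) {
    cc <- center_covariates(cohort[, covariates, drop = FALSE])
    Xc <- cc$X; means <- cc$means
  } else {
    Xc <- NULL; means <- numeric()
  }
  hm <- fit_hospital_model(Xc, cohort$hospital_id, y, min_volume)
  tab <- hm$estimates
  total_events <- sum(y[hm$used])
  tab$p_uncorrected <- back_transform(tab$estimate, 1)
  in_model <- !is.na(tab$estimate)
  k <- correction_k(tab$p_uncorrected[in_model], tab$n[in_model], total_events)
  tab$adjusted_proportion <- back_transform(tab$estimate, k)
  structure(list(hospitals = tab, k = k, total_events = total_events,
                 covariate_means = means, covariates = covariates,
                 fit = hm$fit,
                 overall_rate = mean(y)),
            class = "standardisation_result")
}

#' @export
print.standardisation_result <- function(x, ...) {
  cat(sprintf(
    "Direct standardisation: %d hospitals, %d events, k = %.4f, overall rate %.3f\n",
    nrow(x$hospitals), x$total_events, x$k, x$overall_rate))
  print(utils::head(x$hospitals, 10))
  if (nrow(x$hospitals) > 10) cat("  ...\n")
  invisible(x)
}

#' Funnel-plot control limits around a target proportion
#'
#' Default limits use the normal approximation on the proportion scale,
#' `target +/- z * sqrt(target (1 - target) / n)` with z the two-sided
#' quantile of the level (1.96 for 95%, 3.09 for 99.8%), clipped to
#' \[0, 1\]. `method = "binomial"` uses exact binomial quantiles instead.
#'
#' @param target Overall outcome proportion, in (0, 1).
#' @param volumes Vector of group sizes at which to evaluate the limits.
#' @param level Two-sided coverage level (e.g. 0.95 or 0.998).
#' @param method `"normal"` or `"binomial"`.
#' @return Data frame `n`, `lower`, `upper`.
#' @export
funnel_limits <- function(target, volumes, level = 0.95,
                          method = c("normal", "binomial")) {
  if (target <= 0 || target >= 1) stop_config("target must be in (0, 1)")
  method <- match.arg(method)
  if (method == "normal") {
    z <- stats::qnorm(1 - (1 - level) / 2)
    hw <- z * sqrt(target * (1 - target) / volumes)
    lower <- pmax(0, target - hw)
    upper <- pmin(1, target + hw)
  } else {
    a <- (1 - level) / 2
    lower <- stats::qbinom(a, volumes, target) / volumes
    upper <- stats::qbinom(1 - a, volumes, target) / volumes
  }
  data.frame(n = volumes, lower = lower, upper = upper)
}

#' Build a funnel chart for a standardisation result
#'
#' @param result A `standardisation_result`.
#' @param levels Control-limit levels (default 95% and 99.8%).
#' @param method Limit construction; see [funnel_limits()].
#' @param target Target proportion; defaults to the cohort's overall rate.
#' @return An object of class `funnel_chart` holding the target, the limit
#'   curves per level and the classified per-hospital points.
#' @export
funnel_chart <- function(result, levels = c(0.95, 0.998),
                         method = c("normal", "binomial"), target = NULL) {
  method <- match.arg(method)
  target <- target %||% result$overall_rate
  tab <- result$hospitals[!is.na(result$hospitals$adjusted_proportion), ]
  grid <- sort(unique(c(tab$n, round(seq(max(min(tab$n) - 5, 1),
                                         max(tab$n) * 1.05, length.out = 200)))))
  limits <- lapply(levels, function(lv)
    funnel_limits(target, grid, lv, method))
  names(limits) <- sprintf("%g", levels)
  chart <- structure(list(target = target, levels = sort(levels),
                          method = method, limits = limits, grid = grid),
                     class = "funnel_chart")
  chart$points <- classify_hospitals(result, chart)
  chart
}

#' Classify hospitals against funnel limits
#'
#' Limits are closed: a point exactly on a limit is inside it. The widest
#' exceeded level wins (`outside_998` over `outside_95`), with the
#' direction of divergence (`high` / `low`).
#'
#' @param result A `standardisation_result`.
#' @param chart A `funnel_chart` built at the cohort's overall rate.
#' @return Data frame `hospital_id`, `n`, `adjusted_proportion`,
#'   `classification`, `direction`.
#' @export
classify_hospitals <- function(result, chart) {
  tab <- result$hospitals[!is.na(result$hospitals$adjusted_proportion), ]
  lv <- sort(chart$levels)   # ascending: widest level last
  cls <- rep("inside", nrow(tab))
  dir <- rep("", nrow(tab))
  for (i in seq_along(lv)) {
    lim <- funnel_limits(chart$target, tab$n, lv[i], chart$method)
    hi <- tab$adjusted_proportion > lim$upper
    lo <- tab$adjusted_proportion < lim$lower
    lab <- if (lv[i] >= 0.998) "outside_998"
           else sprintf("outside_%g", 100 * lv[i])
    cls[hi | lo] <- lab
    dir[hi] <- "high"; dir[lo] <- "low"
  }
  data.frame(hospital_id = tab$hospital_id, n = tab$n,
             adjusted_proportion = tab$adjusted_proportion,
             classification = cls, direction = dir,
             stringsAsFactors = FALSE)
}

#' Plot a funnel chart
#'
#' Base-graphics funnel plot: per-hospital adjusted proportions against
#' volume with the control-limit curves; a second standardisation result
#' may be overlaid for model comparison.
#'
#' @param x A `funnel_chart`.
#' @param overlay Optional second `funnel_chart` (drawn as open triangles).
#' @param main,xlab,ylab Plot annotations.
#' @param ... Passed to `plot`.
#' @export
plot.funnel_chart <- function(x, overlay = NULL,
                              main = "Risk-adjusted hospital outcomes",
                              xlab = "Hospital volume (episodes)",
                              ylab = "Adjusted proportion", ...) {
  ymax <- max(x$points$adjusted_proportion,
              vapply(x$limits, function(l) max(l$upper), 0))
  graphics::plot(x$points$n, x$points$adjusted_proportion, pch = 16,
                 xlab = xlab, ylab = ylab, main = main,
                 ylim = c(0, min(1, ymax * 1.1)), ...)
  graphics::abline(h = x$target, lty = 3)
  lts <- c(2, 1)
  for (i in seq_along(x$limits)) {
    l <- x$limits[[i]]
    graphics::lines(l$n, l$lower, lty = lts[min(i, 2)])
    graphics::lines(l$n, l$upper, lty = lts[min(i, 2)])
  }
  if (!is.null(overlay))
    graphics::points(overlay$points$n, overlay$points$adjusted_proportion,
                     pch = 2)
  out <- x$points[x$points$classification != "inside", ]
  if (nrow(out))
    graphics::text(out$n, out$adjusted_proportion, out$hospital_id,
                   pos = 3, cex = 0.7)
  invisible(x)
}

#' Random-intercept sensitivity analysis
#'
#' Fits `outcome ~ covariates + (1 | hospital_id)` by Laplace-approximate
#' maximum likelihood (`lme4::glmer`) and returns the between-hospital
#' standard deviation together with each hospital's shrunken log-odds
#' (fixed intercept + conditional mode of its random effect, at the
#' cohort-average covariate profile thanks to centring).
#'
#' @param cohort Cohort data frame.
#' @param covariates Adjustment covariate columns (centred internally).
#' @return `list(hospitals = <hospital_id, shrunken_logodds,
#'   shrunken_proportion>, sd = <between-hospital sd>, converged, fit)`.
#'   On non-convergence the fixed-effect estimates from [standardise()]
#'   are returned with `converged = FALSE`.
#' @export
multilevel_sensitivity <- function(cohort, covariates = character()) {
  if (length(unique(cohort$hospital_id)) < 2)
    stop_config("need at least 2 hospitals")
  dat <- cohort[, c("hospital_id", "outcome"), drop = FALSE]
  if (length(covariates)) {
    cc <- center_covariates(cohort[, covariates, drop = FALSE])
    dat <- cbind(dat, as.data.frame(cc$X))
  }
  rhs <- paste(c(covariates, "(1 | hospital_id)"), collapse = " + ")
  form <- stats::as.formula(paste("outcome ~", rhs))
  fit <- tryCatch(
    lme4::glmer(form, data = dat, family = stats::binomial(), nAGQ = 1L),
    error = function(e) NULL)
  bad <- is.null(fit) ||
    length(unlist(fit@optinfo$conv$lme4$messages %||% character())) > 0
  if (is.null(fit)) {
    std <- standardise(cohort, covariates, min_volume = 1L)
    tab <- std$hospitals
    return(list(hospitals = data.frame(hospital_id = tab$hospital_id,
                                       shrunken_logodds = tab$estimate,
                                       shrunken_proportion = tab$p_uncorrected),
                sd = NA_real_, converged = FALSE, fit = NULL))
  }
  sdval <- sqrt(unname(lme4::VarCorr(fit)$hospital_id[1, 1]))
  re <- lme4::ranef(fit)$hospital_id
  b0 <- lme4::fixef(fit)[["(Intercept)"]]
  lo <- b0 + re[["(Intercept)"]]
  list(hospitals = data.frame(hospital_id = rownames(re),
                              shrunken_logodds = lo,
                              shrunken_proportion = invlogit(lo),
                              stringsAsFactors = FALSE),
       sd = sdval, converged = !bad, fit = fit)
}

#' Rank agreement between two hospital profiles
#'
#' Spearman rank correlation of the adjusted proportions plus concordance
#' of the funnel outlier classifications over the common hospital set.
#'
#' @param profile_a,profile_b Data frames with `hospital_id` and
#'   `adjusted_proportion` (and optionally `classification`), e.g. the
#'   `points` of two [funnel_chart()]s.
#' @return `list(rho = <Spearman>, concordance = <fraction of hospitals
#'   with identical classification>, n_changed = <count>)`.
#' @export
rank_agreement <- function(profile_a, profile_b) {
  if (!setequal(profile_a$hospital_id, profile_b$hospital_id))
    stop_config("the two profiles must cover the same hospitals")
  m <- match(profile_a$hospital_id, profile_b$hospital_id)
  rho <- stats::cor(profile_a$adjusted_proportion,
                    profile_b$adjusted_proportion[m], method = "spearman")
  conc <- NA_real_; changed <- NA_integer_
  if (!is.null(profile_a$classification) && !is.null(profile_b$classification)) {
    same <- profile_a$classification == profile_b$classification[m]
    conc <- mean(same); changed <- sum(!same)
  }
  list(rho = rho, concordance = conc, n_changed = changed)
}
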