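# Risk-adjustment models --------------------------------------------------
#
# Pairs of multivariable logistic models per outcome: "discharge data only"
# versus "discharge data + clinical variables + drug prescriptions".
# Candidate predictors are screened by a bootstrap stepwise procedure with
# forced demographics; model discrimination is summarised by the
# c-statistic (area under the ROC curve).

#' Configuration of the bootstrap stepwise selection
#'
#' @param n_bootstrap Number of bootstrap resamples (classically 1000; the
#'   package tests use smaller values).
#' @param alpha Significance threshold for counting a candidate as
#'   selected in a replicate (final-model Wald p <= alpha).
#' @param retain_fraction A candidate is retained when selected in at
#'   least this fraction of usable replicates.
#' @param retain_count Optional absolute-count alternative: retain when
#'   selected in at least this many usable replicates (whichever of the
#'   two thresholds is supplied/larger wins; `NULL` disables it).
#' @param alpha_entry,alpha_stay Stepwise entry (score test) and stay
#'   (Wald test) thresholds.
#' @param forced Covariates always kept in the model (demographics).
#' @param seed Seed for the resampling stream.
#' @return An object of class `selection_config`.
#' @export
selection_config <- function(n_bootstrap = 1000L, alpha = 0.05,
                             retain_fraction = 0.30, retain_count = NULL,
                             alpha_entry = 0.05, alpha_stay = 0.05,
                             forced = c("age", "female"), seed = 1L) {
  stopifnot(alpha > 0, alpha < 1, retain_fraction > 0, retain_fraction <= 1,
            n_bootstrap >= 1)
  structure(list(n_bootstrap = as.integer(n_bootstrap), alpha = alpha,
                 retain_fraction = retain_fraction,
                 retain_count = retain_count,
                 alpha_entry = alpha_entry, alpha_stay = alpha_stay,
                 forced = forced, seed = as.integer(seed)),
            class = "selection_config")
}

# design matrix (with leading intercept) from a cohort data frame or an
# already-numeric matrix
design_matrix <- function(rows, columns, intercept = TRUE) {
  X <- if (is.matrix(rows)) rows[, columns, drop = FALSE]
       else as.matrix(rows[, columns, drop = FALSE])
  storage.mode(X) <- "double"
  if (intercept) X <- cbind(`(Intercept)` = 1, X)
  X
}

#' Fit a logistic regression by maximum likelihood
#'
#' Thin matrix interface over `stats::glm.fit` returning Wald standard
#' errors, two-sided p-values, odds ratios and the apparent c-statistic.
#' Non-convergence and (quasi-)separation are reported through `ok =
#' FALSE` rather than an error, so bootstrap replicates can skip unstable
#' resamples.
#'
#' @param X Numeric design matrix *without* intercept column (added
#'   internally unless `intercept = FALSE`).
#' @param y 0/1 outcome vector.
#' @param intercept Add a global intercept column?
#' @param penalty Optional ridge penalty vector (one entry per final
#'   design column, intercept included); used by the hospital model for
#'   degenerate hospitals, 0 elsewhere.
#' @return An object of class `hosp_logit`: coefficients, `se`, `z`, `p`,
#'   `or`, fitted probabilities, `c` (c-statistic), log-likelihood, `ok`
#'   flag and covariance matrix.
#' @export
fit_logistic <- function(X, y, intercept = TRUE, penalty = NULL) {
  if (intercept) X <- cbind(`(Intercept)` = 1, X)
  p <- ncol(X)
  if (length(y) <= p)
    stop_config("need more observations (%d) than parameters (%d)",
                length(y), p)
  const0 <- apply(X, 2, function(col) all(col == 0))
  if (any(const0))
    stop_config("constant-zero design column(s): %s",
                paste(colnames(X)[const0], collapse = ", "))
  if (is.null(penalty)) {
    fit <- suppressWarnings(
      stats::glm.fit(X, y, family = stats::binomial(), intercept = FALSE))
    beta <- fit$coefficients
    mu <- fit$fitted.values
    converged <- fit$converged
  } else {
    irls <- penalized_irls(X, y, penalty)
    beta <- irls$beta; mu <- irls$mu; converged <- irls$converged
  }
  ok <- isTRUE(converged) && all(is.finite(beta)) && max(abs(beta)) < 20 &&
    all(mu > 1e-10) && all(mu < 1 - 1e-10)
  # plain large-sample covariance (penalty, if any, is tiny and ignored here)
  W <- mu * (1 - mu)
  info <- crossprod(X * sqrt(W))
  if (!is.null(penalty)) diag(info) <- diag(info) + penalty
  cov <- tryCatch(chol2inv(chol(info)), error = function(e) NULL)
  if (is.null(cov)) {
    se <- rep(NA_real_, p); ok <- FALSE
    cov <- matrix(NA_real_, p, p)
  } else se <- sqrt(diag(cov))
  dimnames(cov) <- list(colnames(X), colnames(X))
  z <- beta / se
  pv <- 2 * stats::pnorm(-abs(z))
  ll <- sum(y * log(pmax(mu, 1e-12)) + (1 - y) * log(pmax(1 - mu, 1e-12)))
  cs <- if (length(unique(y)) == 2) c_statistic(mu, y) else NA_real_
  structure(list(coefficients = stats::setNames(beta, colnames(X)),
                 se = stats::setNames(se, colnames(X)),
                 z = z, p = stats::setNames(pv, colnames(X)),
                 or = exp(beta), fitted = mu, cov = cov,
                 loglik = ll, c = cs, n = length(y), ok = ok),
            class = "hosp_logit")
}

#' @export
print.hosp_logit <- function(x, ...) {
  cat(sprintf("Logistic model: n = %d, c = %.3f%s\n", x$n, x$c,
              if (!x$ok) " [flagged: not converged / separation]" else ""))
  tab <- data.frame(coef = x$coefficients, se = x$se, or = x$or, p = x$p)
  print(round(tab, 4))
  invisible(x)
}

# IRLS with a fixed diagonal ridge; used only when some hospital indicator
# would otherwise be unbounded (all or no events in a hospital).
penalized_irls <- function(X, y, penalty, max_iter = 100L, tol = 1e-10) {
  beta <- rep(0, ncol(X))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- invlogit(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    A <- crossprod(X * sqrt(w))
    diag(A) <- diag(A) + penalty
    new <- tryCatch(drop(solve(A, crossprod(X, w * z))),
                    error = function(e) NULL)
    if (is.null(new)) break
    if (max(abs(new - beta)) < tol) { beta <- new; converged <- TRUE; break }
    beta <- new
  }
  eta <- drop(X %*% beta)
  list(beta = stats::setNames(beta, colnames(X)), mu = invlogit(eta),
       converged = converged)
}

#' Concordance statistic (area under the ROC curve)
#'
#' Computed by the midrank (Mann-Whitney) method in O(n log n):
#' (concordant + 0.5 x tied) / (n1 x n0) over all event/non-event pairs.
#'
#' @param scores Predicted probabilities or any risk score.
#' @param labels 0/1 outcome vector; both classes must be present.
#' @return The c-statistic in \[0, 1\].
#' @export
c_statistic <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L)
    stop_config("c-statistic undefined: both outcome classes must be present")
  r <- rank(scores)  # midranks handle ties as 1/2
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Multi-df Rao score test for adding block Z to a fitted model with design
# X and fitted probabilities mu: U = Z'(y - mu),
# V = Z'WZ - Z'WX (X'WX)^{-1} X'WZ, stat = U' V^{-1} U ~ chisq(df = ncol Z).
block_score_test <- function(X, mu, y, Z) {
  w <- mu * (1 - mu)
  U <- crossprod(Z, y - mu)
  XtWX <- crossprod(X * sqrt(w))
  ZtWX <- crossprod(Z * w, X)
  V <- crossprod(Z * sqrt(w)) - ZtWX %*% solve(XtWX, t(ZtWX))
  stat <- tryCatch(drop(crossprod(U, solve(V, U))), error = function(e) NA_real_)
  if (!is.finite(stat) || stat < 0) return(NA_real_)
  stats::pchisq(stat, df = ncol(Z), lower.tail = FALSE)
}

# Multi-df Wald test of a coefficient block in a fitted model.
block_wald_p <- function(fit, cols) {
  b <- fit$coefficients[cols]
  V <- fit$cov[cols, cols, drop = FALSE]
  stat <- tryCatch(drop(crossprod(b, solve(V, b))), error = function(e) NA_real_)
  if (!is.finite(stat)) return(NA_real_)
  stats::pchisq(stat, df = length(cols), lower.tail = FALSE)
}

# Normalise a candidate specification into a named list of column blocks.
# Plain character vectors become single-column blocks; list elements may
# group indicator columns (e.g. sbp = c("sbp_le100", "sbp_missing")) that
# enter and leave the model together.
as_candidate_blocks <- function(candidates) {
  if (is.character(candidates)) {
    blocks <- as.list(candidates)
    names(blocks) <- candidates
  } else blocks <- candidates
  if (is.null(names(blocks)) || any(!nzchar(names(blocks))))
    stop_config("candidate blocks must be named")
  blocks[order(names(blocks))]  # deterministic tie-break order
}

#' Bidirectional stepwise selection with forced covariates
#'
#' Starts from the forced-only model, repeatedly adds the candidate block
#' with the smallest score-test p-value (if <= `alpha_entry`), then removes
#' any non-forced block whose Wald p-value exceeds `alpha_stay`, until the
#' model no longer changes. Ties are broken by block name so the procedure
#' is deterministic.
#'
#' @param rows Cohort data frame.
#' @param y 0/1 outcome vector.
#' @param candidates Character vector of columns, or a named list of
#'   column blocks (indicator sets of one categorical variable move as a
#'   block).
#' @param forced Columns always in the model.
#' @param alpha_entry,alpha_stay Entry and stay thresholds.
#' @return `list(selected = <block names>, fit = <hosp_logit or NULL>,
#'   ok = <logical>)`.
#' @export
stepwise_select <- function(rows, y, candidates, forced,
                            alpha_entry = 0.05, alpha_stay = 0.05) {
  blocks <- as_candidate_blocks(candidates)
  if (any(unlist(blocks) %in% forced))
    stop_config("candidates must be disjoint from forced covariates")
  selected <- character()
  fit <- fit_logistic(design_matrix(rows, forced, intercept = FALSE), y)
  if (!fit$ok) return(list(selected = selected, fit = fit, ok = FALSE))
  X <- design_matrix(rows, forced)
  seen <- character()
  repeat {
    state <- paste(sort(selected), collapse = "|")
    if (state %in% seen) break   # cycle guard
    seen <- c(seen, state)
    changed <- FALSE
    # forward: best score-test p among blocks not in the model
    out_blocks <- setdiff(names(blocks), selected)
    if (length(out_blocks)) {
      ps <- vapply(out_blocks, function(b) {
        Z <- design_matrix(rows, blocks[[b]], intercept = FALSE)
        block_score_test(X, fit$fitted, y, Z)
      }, numeric(1))
      ps[is.na(ps)] <- Inf
      if (min(ps) <= alpha_entry) {
        add <- out_blocks[which.min(ps)]   # names sorted -> deterministic
        cand_sel <- c(selected, add)
        cols <- c(forced, unlist(blocks[cand_sel], use.names = FALSE))
        new_fit <- fit_logistic(design_matrix(rows, cols, intercept = FALSE), y)
        if (new_fit$ok) {
          selected <- cand_sel; fit <- new_fit
          X <- design_matrix(rows, cols)
          changed <- TRUE
        }
      }
    }
    # backward: drop the worst block with Wald p > alpha_stay
    if (length(selected)) {
      wp <- vapply(selected, function(b)
        block_wald_p(fit, blocks[[b]]), numeric(1))
      wp[is.na(wp)] <- 1
      if (max(wp) > alpha_stay) {
        drop_b <- selected[which.max(wp)]
        selected <- setdiff(selected, drop_b)
        cols <- c(forced, unlist(blocks[selected], use.names = FALSE))
        fit <- fit_logistic(design_matrix(rows, cols, intercept = FALSE), y)
        X <- design_matrix(rows, cols)
        if (!fit$ok) return(list(selected = selected, fit = fit, ok = FALSE))
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  list(selected = selected, fit = fit, ok = fit$ok)
}

#' Bootstrap stepwise variable selection
#'
#' Runs [stepwise_select()] on `n_bootstrap` resamples (size n, with
#' replacement) of the cohort. A candidate's selection frequency is the
#' fraction of usable (converged) replicates in which it appears in the
#' final model with Wald p <= `alpha`. Candidates with frequency >=
#' `retain_fraction` (and, when set, count >= `retain_count`) are retained
#' for the final risk-adjustment model. Forced covariates are always in
#' and never counted.
#'
#' @param rows Cohort data frame.
#' @param y 0/1 outcome vector.
#' @param candidates Candidate columns or named blocks
#'   (see [stepwise_select()]).
#' @param config A [selection_config()].
#' @return An object of class `selection_result`: `frequencies`,
#'   `retained`, `n_converged`, `n_bootstrap`.
#' @export
bootstrap_stepwise <- function(rows, y, candidates, config = selection_config()) {
  if (!nrow(rows)) stop_config("empty cohort")
  blocks <- as_candidate_blocks(candidates)
  hits <- stats::setNames(integer(length(blocks)), names(blocks))
  n <- nrow(rows)
  # resampling a numeric matrix is far cheaper than a data frame
  use_cols <- unique(c(config$forced, unlist(blocks, use.names = FALSE)))
  rows_m <- as.matrix(rows[, use_cols, drop = FALSE])
  storage.mode(rows_m) <- "double"
  n_conv <- 0L
  set.seed(config$seed)
  for (b in seq_len(config$n_bootstrap)) {
    idx <- sample.int(n, n, replace = TRUE)
    res <- tryCatch(
      stepwise_select(rows_m[idx, , drop = FALSE], y[idx], blocks, config$forced,
                      config$alpha_entry, config$alpha_stay),
      error = function(e) list(ok = FALSE))
    if (!isTRUE(res$ok)) next
    n_conv <- n_conv + 1L
    for (s in res$selected) {
      if (block_wald_p(res$fit, blocks[[s]]) <= config$alpha)
        hits[s] <- hits[s] + 1L
    }
  }
  if (n_conv < 0.5 * config$n_bootstrap)
    stop_config("only %d of %d bootstrap replicates converged; data too unstable",
                n_conv, config$n_bootstrap)
  freq <- hits / n_conv
  thr_n <- ceiling(config$retain_fraction * n_conv)
  if (!is.null(config$retain_count)) thr_n <- max(thr_n, config$retain_count)
  structure(list(frequencies = freq,
                 retained = names(freq)[hits >= thr_n],
                 n_converged = n_conv,
                 n_bootstrap = config$n_bootstrap,
                 blocks = blocks, config = config),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("Bootstrap stepwise selection: %d/%d usable replicates\n",
              x$n_converged, x$n_bootstrap))
  f <- sort(x$frequencies, decreasing = TRUE)
  for (nm in names(f))
    cat(sprintf("  %-34s %5.1f%% %s\n", nm, 100 * f[nm],
                if (nm %in% x$retained) "[retained]" else ""))
  invisible(x)
}

#' Build and compare the two risk-adjustment models
#'
#' Runs [bootstrap_stepwise()] independently on the discharge-data
#' candidate set A and on the extended set B (A plus clinical categories
#' and drug flags), fits each final model on the full cohort (forced
#' demographics plus retained blocks) and reports both apparent
#' c-statistics and their difference.
#'
#' @param rows Cohort data frame.
#' @param y 0/1 outcome vector.
#' @param candidates_a,candidates_b Candidate blocks for the two models;
#'   B is expected to extend A.
#' @param config A [selection_config()].
#' @return An object of class `model_pair`: `selection_a`, `selection_b`,
#'   `fit_a`, `fit_b`, `c_a`, `c_b`, `delta_c` and the column sets used.
#' @export
build_model_pair <- function(rows, y, candidates_a, candidates_b,
                             config = selection_config()) {
  blocks_a <- as_candidate_blocks(candidates_a)
  blocks_b <- as_candidate_blocks(candidates_b)
  if (!all(names(blocks_a) %in% names(blocks_b)))
    stop_config("candidate set B must extend candidate set A")
  sel_a <- bootstrap_stepwise(rows, y, blocks_a, config)
  sel_b <- bootstrap_stepwise(rows, y, blocks_b, config)
  cols_a <- c(config$forced, unlist(blocks_a[sel_a$retained], use.names = FALSE))
  cols_b <- c(config$forced, unlist(blocks_b[sel_b$retained], use.names = FALSE))
  fit_a <- fit_logistic(design_matrix(rows, cols_a, intercept = FALSE), y)
  fit_b <- fit_logistic(design_matrix(rows, cols_b, intercept = FALSE), y)
  structure(list(selection_a = sel_a, selection_b = sel_b,
                 fit_a = fit_a, fit_b = fit_b,
                 columns_a = cols_a, columns_b = cols_b,
                 c_a = fit_a$c, c_b = fit_b$c,
                 delta_c = fit_b$c - fit_a$c),
            class = "model_pair")
}

#' @export
print.model_pair <- function(x, ...) {
  cat(sprintf(
    "Risk-adjustment model pair\n  A (discharge data):     c = %.3f  [%s]\n  B (+ clinical, drugs):  c = %.3f  [%s]\n  delta c = %.3f\n",
    x$c_a, paste(x$selection_a$retained, collapse = ", "),
    x$c_b, paste(x$selection_b$retained, collapse = ", "), x$delta_c))
  invisible(x)
}

#' Tabulate a model pair in the style of a published risk-factor table
#'
#' One row per covariate: number of admissions with the factor, crude OR
#' (univariable, adjusted for nothing), adjusted OR and p from each model,
#' plus an `area_under_roc` footer row.
#'
#' @param pair A `model_pair`.
#' @param rows,y The cohort and outcome the pair was built on.
#' @return A data frame ready for `write.csv`.
#' @export
model_pair_report <- function(pair, rows, y) {
  covs <- union(pair$columns_a, pair$columns_b)
  crude <- vapply(covs, function(v) {
    f <- fit_logistic(design_matrix(rows, v, intercept = FALSE), y)
    unname(f$or[v])
  }, numeric(1))
  n_adm <- vapply(covs, function(v) {
    x <- rows[[v]]
    if (all(x %in% c(0, 1))) sum(x == 1) else NA_integer_
  }, numeric(1))
  g <- function(fit, v, what) if (v %in% names(fit$coefficients))
    unname(fit[[what]][v]) else NA_real_
  rep <- data.frame(
    risk_factor = covs, n_admissions = n_adm, crude_or = round(crude, 2),
    adjusted_or_discharge = round(vapply(covs, g, 0, fit = pair$fit_a, what = "or"), 2),
    p_discharge = round(vapply(covs, g, 0, fit = pair$fit_a, what = "p"), 3),
    adjusted_or_full = round(vapply(covs, g, 0, fit = pair$fit_b, what = "or"), 2),
    p_full = round(vapply(covs, g, 0, fit = pair$fit_b, what = "p"), 3),
    stringsAsFactors = FALSE
  )
  rbind(rep, data.frame(risk_factor = "area_under_roc", n_admissions = NA,
                        crude_or = NA,
                        adjusted_or_discharge = round(pair$c_a, 3),
                        p_discharge = NA,
                        adjusted_or_full = round(pair$c_b, 3), p_full = NA))
}
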