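# End-to-end orchestration ------------------------------------------------
#
# generate/load registries -> build cohort -> fit the risk-adjustment model
# pair -> profile hospitals with both models -> compare.  Every filter count
# and artefact is written to the output directory; a manifest records the
# seed and a hash of the configuration for reproducibility.

#' Configuration of a full pipeline run
#'
#' @param outdir Output directory.
#' @param generator A [generator_config()], or `NULL` when reading
#'   registries from `input_dir`.
#' @param input_dir Directory with registry CSVs (see [read_registries()]);
#'   exactly one of `generator` / `input_dir` must be given.
#' @param cohort `"AMI"` or `"HF"`.
#' @param cohort_spec Cohort-building rules; defaults to
#'   [ami_cohort_spec()] / [hf_cohort_spec()].
#' @param selection A [selection_config()].
#' @param min_volume Minimum hospital volume for profiling.
#' @param funnel_levels Funnel control-limit levels.
#' @param limit_method `"normal"` or `"binomial"`.
#' @param make_plots Write funnel-plot PNGs (skipped with a message if no
#'   graphics device is available).
#' @param seed Master seed for the run (propagated to generator and
#'   selection unless they carry their own).
#' @return An object of class `run_config`.
#' @export
run_config <- function(outdir, generator = NULL, input_dir = NULL,
                       cohort = c("AMI", "HF"), cohort_spec = NULL,
                       selection = NULL, min_volume = 10L,
                       funnel_levels = c(0.95, 0.998),
                       limit_method = c("normal", "binomial"),
                       make_plots = TRUE, seed = 1L) {
  cohort <- match.arg(cohort)
  limit_method <- match.arg(limit_method)
  if (is.null(generator) == is.null(input_dir))
    stop_config("exactly one of generator / input_dir must be supplied")
  if (any(funnel_levels <= 0 | funnel_levels >= 1))
    stop_config("funnel levels must lie in (0, 1)")
  if (is.null(cohort_spec))
    cohort_spec <- if (cohort == "AMI") ami_cohort_spec() else hf_cohort_spec()
  if (is.null(selection))
    selection <- selection_config(seed = substream_seed(seed, 101L))
  structure(list(outdir = outdir, generator = generator,
                 input_dir = input_dir, cohort = cohort,
                 cohort_spec = cohort_spec, selection = selection,
                 min_volume = as.integer(min_volume),
                 funnel_levels = funnel_levels, limit_method = limit_method,
                 make_plots = make_plots, seed = as.integer(seed)),
            class = "run_config")
}

# candidate blocks available in a cohort, grouped so that the category
# indicators of one clinical variable move together; constant columns are
# not candidates (no information)
candidate_blocks_for <- function(cohort_df, spec, stage = c("discharge", "full")) {
  stage <- match.arg(stage)
  non_const <- function(cols) {
    cols[vapply(cols, function(cl) {
      v <- cohort_df[[cl]]
      !is.null(v) && length(unique(v)) > 1
    }, logical(1))]
  }
  blocks <- as.list(non_const(c(names(spec$comorbidity_map),
                                names(spec$index_map))))
  names(blocks) <- unlist(blocks)
  if (stage == "full") {
    clin <- if (spec$cohort == "AMI") c("sbp_le100", "sbp_missing")
            else c("inr_out_of_range", "inr_missing")
    clin <- non_const(clin)
    if (length(clin))
      blocks[[if (spec$cohort == "AMI") "sbp" else "inr"]] <- clin
    for (d in non_const(names(spec$drug_map))) blocks[[d]] <- d
  }
  blocks
}

# Table-1-style descriptive summary of a cohort
describe_cohort <- function(cohort_df) {
  flag_cols <- names(cohort_df)[vapply(cohort_df, function(v)
    is.numeric(v) && all(v %in% c(0, 1)), logical(1))]
  flag_cols <- setdiff(flag_cols, "outcome")
  rows <- lapply(flag_cols, function(cl)
    data.frame(variable = cl, n = sum(cohort_df[[cl]]),
               value = round(100 * mean(cohort_df[[cl]]), 2),
               statistic = "percent"))
  rbind(data.frame(variable = "episodes", n = nrow(cohort_df),
                   value = NA_real_, statistic = "count"),
        data.frame(variable = "age_mean", n = nrow(cohort_df),
                   value = round(mean(cohort_df$age), 1), statistic = "mean"),
        data.frame(variable = "age_sd", n = nrow(cohort_df),
                   value = round(stats::sd(cohort_df$age), 1), statistic = "sd"),
        do.call(rbind, rows),
        data.frame(variable = "crude_outcome_rate", n = sum(cohort_df$outcome),
                   value = round(100 * mean(cohort_df$outcome), 2),
                   statistic = "percent"))
}

config_hash <- function(config) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, force = TRUE,
                              digits = NA), f)
  unname(tools::md5sum(f))
}

stage_try <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE))
}

#' Run the full profiling experiment
#'
#' Executes, in order: registry generation (or loading), cohort
#' construction, bootstrap-stepwise model-pair fitting, hospital
#' standardisation and funnel classification with both models, the
#' random-intercept sensitivity analysis and the between-model comparison.
#' All artefacts are written under `config$outdir`:
#' `registries/` (if generated), `cohort.csv`, `attrition.csv`,
#' `table1.csv`, `model_report.csv`, `hospital_profiles.csv`,
#' `summary.csv`, `funnel.png` (when plotting is possible) and
#' `manifest.json`.
#'
#' @param config A [run_config()].
#' @param stage Run up to this stage: `"generate"`, `"cohort"`, `"model"`,
#'   `"profile"` or `"all"` (profile and comparison).
#' @return Invisibly, a list with the in-memory results of each completed
#'   stage (`registries`, `cohort`, `attrition`, `pair`, `profiles`,
#'   `comparison`, `manifest`).
#' @export
run_pipeline <- function(config, stage = c("all", "generate", "cohort",
                                           "model", "profile")) {
  stage <- match.arg(stage)
  rank_of <- c(generate = 1, cohort = 2, model = 3, profile = 4, all = 5)
  upto <- rank_of[[stage]]
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  out <- list()

  out$registries <- stage_try("generate", {
    if (!is.null(config$generator)) {
      reg <- generate_population(config$generator)
      write_registries(reg, file.path(config$outdir, "registries"))
      reg
    } else read_registries(config$input_dir)
  })
  if (upto < 2) return(invisible(out))

  built <- stage_try("cohort", build_cohort(out$registries, config$cohort_spec))
  out$cohort <- built$cohort
  out$attrition <- built$attrition
  utils::write.csv(built$cohort, file.path(config$outdir, "cohort.csv"),
                   row.names = FALSE)
  utils::write.csv(built$attrition, file.path(config$outdir, "attrition.csv"),
                   row.names = FALSE)
  utils::write.csv(describe_cohort(built$cohort),
                   file.path(config$outdir, "table1.csv"), row.names = FALSE)
  message(sprintf("cohort: %d episodes (%s excluded by rule: %s)",
                  nrow(built$cohort),
                  sum(built$attrition$n_excluded),
                  paste(sprintf("%s=%d", built$attrition$rule,
                                built$attrition$n_excluded), collapse = ", ")))
  if (upto < 3) return(invisible(out))

  pair <- stage_try("model", {
    blocks_a <- candidate_blocks_for(built$cohort, config$cohort_spec, "discharge")
    blocks_b <- candidate_blocks_for(built$cohort, config$cohort_spec, "full")
    build_model_pair(built$cohort, built$cohort$outcome, blocks_a, blocks_b,
                     config$selection)
  })
  out$pair <- pair
  utils::write.csv(model_pair_report(pair, built$cohort, built$cohort$outcome),
                   file.path(config$outdir, "model_report.csv"),
                   row.names = FALSE)
  if (upto < 4) return(invisible(out))

  out <- c(out, stage_try("profile", {
    std_a <- standardise(built$cohort, pair$columns_a, config$min_volume)
    std_b <- standardise(built$cohort, pair$columns_b, config$min_volume)
    ch_a <- funnel_chart(std_a, config$funnel_levels, config$limit_method)
    ch_b <- funnel_chart(std_b, config$funnel_levels, config$limit_method)
    prof <- merge(ch_a$points, ch_b$points, by = c("hospital_id", "n"),
                  suffixes = c("_discharge", "_full"))
    obs <- std_a$hospitals[, c("hospital_id", "observed_events")]
    prof <- merge(obs, prof, by = "hospital_id")
    utils::write.csv(prof[order(prof$hospital_id), ],
                     file.path(config$outdir, "hospital_profiles.csv"),
                     row.names = FALSE)
    agree <- rank_agreement(ch_a$points, ch_b$points)
    ml <- multilevel_sensitivity(built$cohort, pair$columns_a)
    common <- intersect(ml$hospitals$hospital_id, ch_a$points$hospital_id)
    ml_rho <- stats::cor(
      ml$hospitals$shrunken_proportion[match(common, ml$hospitals$hospital_id)],
      ch_a$points$adjusted_proportion[match(common, ch_a$points$hospital_id)],
      method = "spearman")
    summary_df <- data.frame(
      measure = c("c_discharge", "c_full", "delta_c",
                  "k_discharge", "k_full", "crude_rate",
                  "spearman_rho_models", "classification_concordance",
                  "n_classification_changed",
                  "multilevel_sd", "spearman_rho_multilevel_vs_fixed"),
      value = c(pair$c_a, pair$c_b, pair$delta_c, std_a$k, std_b$k,
                mean(built$cohort$outcome), agree$rho, agree$concordance,
                agree$n_changed, ml$sd, ml_rho))
    utils::write.csv(summary_df, file.path(config$outdir, "summary.csv"),
                     row.names = FALSE)
    if (isTRUE(config$make_plots)) {
      ok <- tryCatch({
        grDevices::png(file.path(config$outdir, "funnel.png"),
                       width = 900, height = 650)
        plot(ch_a, overlay = ch_b,
             main = sprintf("%s: adjusted outcome by hospital",
                            config$cohort))
        grDevices::dev.off()
        TRUE
      }, error = function(e) {
        message("funnel plot skipped: ", conditionMessage(e))
        FALSE
      })
      if (!ok && file.exists(file.path(config$outdir, "funnel.png")))
        unlink(file.path(config$outdir, "funnel.png"))
    }
    list(profiles = prof, chart_a = ch_a, chart_b = ch_b,
         standardisation_a = std_a, standardisation_b = std_b,
         comparison = c(agree, list(delta_c = pair$delta_c,
                                    multilevel_sd = ml$sd,
                                    multilevel_rho = ml_rho)))
  }))

  manifest <- list(
    package = "hosprofile",
    version = as.character(utils::packageVersion("hosprofile")),
    seed = config$seed,
    cohort = config$cohort,
    config_md5 = config_hash(config[setdiff(names(config), "outdir")]),
    n_episodes = nrow(built$cohort),
    stage = stage)
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  out$manifest <- manifest
  invisible(out)
}
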