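# End-to-end orchestration: cohort derivation -> screening -> refit ->
# shape profiling -> score construction -> evaluation, with every
# intermediate serialized to disk and a structured JSON-lines log.

#' Pipeline configuration
#'
#' @param study A [study_config()].
#' @param outcome `"AMI"` or `"non_AMI_SCD"`.
#' @param candidates Candidate predictor columns of the feature table.
#' @param profile_vars Continuous candidates profiled for a J/U shape
#'   (default: window-mean HbA1c, HDL-C, total cholesterol).
#' @param alpha_screen,alpha_select Selection thresholds.
#' @param seed Seed controlling every random operation in the run.
#' @param simulation Optional [sim_config()]; when supplied the pipeline
#'   generates its input tables instead of reading them.
#' @param ami_contamination Passed to [write_cohort_tables()] for simulated
#'   SCD runs.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(study = study_config(),
                            outcome = c("AMI", "non_AMI_SCD"),
                            candidates = c("age_at_index", "sex_male",
                                           "hypertension", "ihd", "heart_failure",
                                           "atrial_fibrillation", "anaemia",
                                           "hba1c_mean", "hdl_c", "chol_total",
                                           "creatinine"),
                            profile_vars = c("hba1c_mean", "hdl_c", "chol_total"),
                            alpha_screen = 0.10, alpha_select = 0.05,
                            seed = 1L, simulation = NULL,
                            ami_contamination = 0) {
  outcome <- match.arg(outcome)
  stopifnot(alpha_screen > 0, alpha_screen < 1, alpha_select > 0, alpha_select < 1)
  if (!all(profile_vars %in% candidates))
    stop("profile_vars must be a subset of candidates")
  structure(list(study = study, outcome = outcome, candidates = candidates,
                 profile_vars = profile_vars, alpha_screen = alpha_screen,
                 alpha_select = alpha_select, seed = as.integer(seed),
                 simulation = simulation, ami_contamination = ami_contamination),
            class = "pipeline_config")
}

#' Build the per-patient feature table from raw tables
#'
#' For each retained patient: age at index, sex indicator, pre-index
#' comorbidity flags (prefix-matched diagnosis codes from the configured
#' code lists), baseline anaemia (from the baseline-window mean haemoglobin
#' and sex), baseline-window means of HDL-C, total cholesterol and
#' creatinine, and the window-mean HbA1c over the mean-lab window.
#'
#' @param cohort Retained patients from [apply_inclusion()].
#' @param tables List from [read_cohort_tables()].
#' @param config A [study_config()].
#' @return Data frame, one row per cohort patient.
#' @export
build_feature_table <- function(cohort, tables, config) {
  idx <- config$index_date
  feats <- data.frame(patient_id = cohort$patient_id,
                      age_at_index = cohort$age_at_index,
                      sex_male = as.integer(cohort$sex == "male"),
                      stringsAsFactors = FALSE)
  pre <- tables$episodes[tables$episodes$kind == "diagnosis_code" &
                           tables$episodes$episode_date < idx, ]
  for (cond in c("hypertension", "ihd", "heart_failure", "atrial_fibrillation")) {
    prefixes <- config$code_lists[[cond]]
    with_cond <- unique(pre$patient_id[code_matches(pre$code, prefixes)])
    feats[[cond]] <- as.integer(feats$patient_id %in% with_cond)
  }
  base <- window_mean_labs_by_patient(tables$labs,
                                      c("haemoglobin", "hdl_c", "chol_total", "creatinine"),
                                      config$baseline_lab_window, cohort$patient_id)
  feats$anaemia <- as.integer(flag_anaemia(cohort$sex, base$haemoglobin))
  feats$hdl_c <- base$hdl_c
  feats$chol_total <- base$chol_total
  feats$creatinine <- base$creatinine
  mw <- window_mean_labs_by_patient(tables$labs, "hba1c",
                                    config$mean_lab_window, cohort$patient_id)
  feats$hba1c_mean <- mw$hba1c
  feats
}

pipeline_log <- function(path, stage, ...) {
  rec <- c(list(stage = stage), list(...))
  cat(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA, null = "null"),
      "\n", sep = "", file = path, append = TRUE)
  message(sprintf("[%s] %s", stage,
                  paste(names(rec)[-1], unlist(lapply(rec[-1], paste, collapse = ",")),
                        sep = "=", collapse = " ")))
}

stage_wrap <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Executes, in order: input acquisition (reading the three raw tables, or
#' generating them from the configured simulation), cohort inclusion,
#' feature derivation, outcome derivation, score fitting
#' (screen/refit/profile/build via [risk_score()]) and evaluation. Every
#' intermediate is serialized under `out_dir` (`cohort.csv`,
#' `features.csv`, `outcomes.csv`, `audit.json`, `screen.json`,
#' `refit.json`, `profiles.json`, `score_spec.json`, `evaluation.json`,
#' `scores.csv`) and a JSON-lines log (`log.jsonl`) records per-stage
#' counts, exclusions and warnings. Deterministic given `config$seed`.
#'
#' @param config A [pipeline_config()].
#' @param tables_dir Directory with `patients.csv`/`episodes.csv`/`labs.csv`
#'   (ignored when `config$simulation` is set).
#' @param out_dir Output directory for artifacts.
#' @return Invisibly, a list with the fitted `risk_score`, the audits and
#'   the event-rate summary.
#' @export
run_pipeline <- function(config, tables_dir = NULL, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "log.jsonl")
  if (file.exists(log_path)) file.remove(log_path)
  set.seed(config$seed)

  if (!is.null(config$simulation)) {
    tables_dir <- file.path(out_dir, "input_tables")
    stage_wrap("simulate", {
      sim <- simulate_cohort(config$simulation)
      write_cohort_tables(sim, tables_dir,
                          outcome = if (config$outcome == "AMI") "AMI" else "SCD",
                          config = config$study,
                          ami_contamination = config$ami_contamination)
      pipeline_log(log_path, "simulate", n = config$simulation$n_patients,
                   seed = config$simulation$seed)
    })
  }
  if (is.null(tables_dir)) stop("either tables_dir or config$simulation is required")

  tables <- stage_wrap("read_tables", read_cohort_tables(tables_dir))
  pipeline_log(log_path, "read_tables", n_patients = nrow(tables$patients),
               n_episodes = nrow(tables$episodes), n_labs = nrow(tables$labs))

  cohort <- stage_wrap("inclusion",
                       apply_inclusion(tables$patients, tables$episodes,
                                       tables$labs, config$study))
  audit_incl <- attr(cohort, "audit")
  pipeline_log(log_path, "inclusion", n_input = audit_incl$n_input,
               n_retained = audit_incl$n_retained,
               exclusions = audit_incl$exclusions)

  features <- stage_wrap("features", build_feature_table(cohort, tables, config$study))
  pipeline_log(log_path, "features", n = nrow(features),
               candidates = config$candidates)

  outcomes <- stage_wrap("outcomes",
                         derive_outcome(cohort, tables$episodes,
                                        outcome = config$outcome, config = config$study))
  audit_out <- attr(outcomes, "audit")
  rate <- event_rate_summary(outcomes)
  pipeline_log(log_path, "outcomes", outcome = config$outcome,
               n_events = audit_out$n_events, n_excluded = audit_out$n_excluded,
               exclusions = audit_out$exclusions,
               annualized_rate_pct_per_year = rate$annualized_rate_pct_per_year)

  if (!length(config$candidates))
    stop("pipeline stage 'screen' failed: empty candidate list")
  keep <- !outcomes$excluded
  model_data <- cbind(outcomes[keep, c("time_days", "event")],
                      features[keep, config$candidates, drop = FALSE])
  fml <- stats::as.formula(paste("survival::Surv(time_days, event) ~",
                                 paste(config$candidates, collapse = " + ")))
  fit <- stage_wrap("score_fit",
                    risk_score(fml, model_data, profile_vars = config$profile_vars,
                               alpha_screen = config$alpha_screen,
                               alpha_select = config$alpha_select,
                               outcome_name = config$outcome))
  pipeline_log(log_path, "score_fit", screened = fit$screened,
               refit = fit$refit$term, max_score = fit$spec$max_score)

  stage_wrap("serialize", {
    utils::write.csv(cohort, file.path(out_dir, "cohort.csv"), row.names = FALSE, na = "")
    utils::write.csv(features, file.path(out_dir, "features.csv"), row.names = FALSE, na = "")
    utils::write.csv(outcomes, file.path(out_dir, "outcomes.csv"), row.names = FALSE, na = "")
    jsonlite::write_json(list(inclusion = audit_incl, outcome = audit_out,
                              event_rate = rate),
                         file.path(out_dir, "audit.json"),
                         auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)
    jsonlite::write_json(fit$screen, file.path(out_dir, "screen.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows", pretty = TRUE)
    jsonlite::write_json(as.data.frame(fit$refit), file.path(out_dir, "refit.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows", pretty = TRUE)
    jsonlite::write_json(lapply(fit$profiles, function(p)
      list(variable = p$variable, breaks = p$breaks, table = p$table,
           reference_index = p$reference_index, shape = p$shape,
           cutoff_low = p$cutoff_low, cutoff_high = p$cutoff_high)),
      file.path(out_dir, "profiles.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "rows", null = "null", pretty = TRUE)
    write_score_spec(fit$spec, file.path(out_dir, "score_spec.json"))
    utils::write.csv(data.frame(patient_id = features$patient_id[keep],
                                score = fit$scores),
                     file.path(out_dir, "scores.csv"), row.names = FALSE, na = "")
    if (!is.null(fit$evaluation))
      jsonlite::write_json(list(auc = fit$evaluation$auc,
                                auc_ci = fit$evaluation$auc_ci,
                                c_index = fit$evaluation$c_index,
                                precision = fit$evaluation$precision,
                                recall = fit$evaluation$recall,
                                threshold = fit$evaluation$threshold),
                           file.path(out_dir, "evaluation.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
  })
  pipeline_log(log_path, "done", out_dir = out_dir)
  invisible(list(fit = fit, inclusion_audit = audit_incl, outcome_audit = audit_out,
                 event_rate = rate, cohort = cohort, features = features,
                 outcomes = outcomes))
}
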