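# simple FNV-1a hash of the deparsed config, embedded in every output so
# reruns are attributable to their exact settings
config_hash <- function(config) {
  txt <- paste(deparse(config[order(names(config))]), collapse = "")
  h <- 2166136261
  for (b in utf8ToInt(txt)) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' Assemble and validate a pipeline configuration
#'
#' @param input Optional path to a cohort CSV; when `NULL`, a synthetic
#'   cohort is generated.
#' @param n Synthetic cohort size (ignored when `input` is given).
#' @param seed Integer master seed (mandatory).
#' @param classifier Backend name, `"random_forest"` or `"logistic"`.
#' @param ntree,mtry Random-forest hyperparameters.
#' @param R_select,R_score Repetition counts.
#' @param retention_threshold Selection retention frequency.
#' @param proportions Split proportions (train/validate/test).
#' @param B,conf_level Bootstrap replications and confidence level.
#' @param out_dir Output directory.
#' @return Validated config list of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, n = 1448, seed,
                            classifier = "random_forest",
                            ntree = 500, mtry = 2,
                            R_select = 100, R_score = 100,
                            retention_threshold = 0.5,
                            proportions = c(train = 0.6, validate = 0.2,
                                            test = 0.2),
                            B = 1000, conf_level = 0.95,
                            out_dir = "thyro_out") {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  if (!is.null(input) && !file.exists(input))
    stop("input cohort file does not exist: ", input)
  cfg <- list(input = input, n = as.integer(n), seed = as.integer(seed),
              classifier = match.arg(classifier,
                                     c("random_forest", "logistic")),
              ntree = as.integer(ntree), mtry = as.integer(mtry),
              R_select = as.integer(R_select),
              R_score = as.integer(R_score),
              retention_threshold = retention_threshold,
              proportions = proportions, B = as.integer(B),
              conf_level = conf_level, out_dir = out_dir)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file whose keys mirror the [pipeline_config()]
#'   arguments.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  # YAML 1.1 parses the bare key "n" as a boolean; map it (and the
  # friendlier alias cohort_size) back to the n argument
  names(vals)[names(vals) %in% c("FALSE", "cohort_size")] <- "n"
  if (!is.null(vals$proportions))
    vals$proportions <- unlist(vals$proportions)
  do.call(pipeline_config, vals)
}

pipeline_log <- function(...) message("[thyroRisk] ", ...)

load_or_generate <- function(config) {
  if (!is.null(config$input)) {
    pipeline_log("reading cohort from ", config$input)
    read_cohort(config$input)
  } else {
    pipeline_log("generating synthetic cohort (n=", config$n, ")")
    generate_cohort(default_generator_config(n = config$n,
                                             seed = config$seed))
  }
}

write_run_info <- function(config, out_dir, stage) {
  info <- list(stage = stage, seed = config$seed,
               config_hash = config_hash(unclass(config)),
               config = unclass(config)[setdiff(names(config), "schema")])
  jsonlite::write_json(info, file.path(out_dir, "run_info.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
}

#' Generate and write a synthetic cohort
#'
#' Writes `cohort.csv` (the generated records) and
#' `marginal_report.csv` (empirical-vs-target class-conditional
#' frequencies) to the configured output directory.
#'
#' @param config A `pipeline_config`.
#' @return Path of the written cohort CSV, invisibly.
#' @export
cmd_simulate <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  gen <- default_generator_config(n = config$n, seed = config$seed)
  cohort <- generate_cohort(gen)
  path <- file.path(config$out_dir, "cohort.csv")
  write_cohort(cohort, path)
  write.csv(marginal_report(cohort, gen),
            file.path(config$out_dir, "marginal_report.csv"),
            row.names = FALSE)
  write_run_info(config, config$out_dir, "simulate")
  pipeline_log("wrote ", path)
  invisible(path)
}

#' Per-characteristic diagnostic report
#'
#' Writes `characteristic_report.csv` (per-level counts, metrics and
#' Fisher p-values), `er_profile.csv` (the cutoff scan), and
#' `er_cutoff.json` (the AUC-maximising cutoff with its metrics).
#'
#' @param config A `pipeline_config`.
#' @return The `characteristic_report`, invisibly.
#' @export
cmd_diagnose <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- load_or_generate(config)
  rep <- characteristic_report(cohort)
  write.csv(as.data.frame(rep),
            file.path(config$out_dir, "characteristic_report.csv"),
            row.names = FALSE)
  prof <- er_profile(cohort)
  write.csv(as.data.frame(prof),
            file.path(config$out_dir, "er_profile.csv"), row.names = FALSE)
  best <- optimal_er_cutoff(prof)
  jsonlite::write_json(list(cutoff = best$cutoff,
                            metrics = unclass(best$metrics)),
                       file.path(config$out_dir, "er_cutoff.json"),
                       auto_unbox = TRUE, digits = NA)
  write_run_info(config, config$out_dir, "diagnose")
  pipeline_log("wrote characteristic report (",
               sum(!rep$reference), " non-reference levels)")
  invisible(rep)
}

#' Run the full selection/scoring/stratification pipeline
#'
#' Fits [nodule_risk_model()] under the configured settings and writes
#' every artifact: `selection_summary.csv`, `risk_scores.csv`,
#' `metric_summary.csv`, `thresholds.json`,
#' `category_train_validate.csv`, `category_test.csv`, `run_info.json`.
#'
#' @param config A `pipeline_config`.
#' @return The fitted `nodule_risk_model`, invisibly.
#' @export
cmd_run <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- load_or_generate(config)
  pipeline_log("stage: selection (R=", config$R_select, ")")
  fit <- nodule_risk_model(
    cohort,
    classifier = classifier_spec(config$classifier,
                                 list(ntree = config$ntree,
                                      mtry = config$mtry)),
    R_select = config$R_select, R_score = config$R_score,
    retention_threshold = config$retention_threshold,
    proportions = config$proportions,
    B = config$B, conf_level = config$conf_level,
    seed = config$seed)
  pipeline_log("selected: ", paste(fit$features, collapse = ", "))

  od <- config$out_dir
  if (!is.null(fit$selection))
    write.csv(fit$selection$frequency,
              file.path(od, "selection_summary.csv"), row.names = FALSE)
  write.csv(fit$ensemble$scores, file.path(od, "risk_scores.csv"),
            row.names = FALSE)
  write.csv(as.data.frame(fit$metrics),
            file.path(od, "metric_summary.csv"), row.names = FALSE)
  jsonlite::write_json(list(l_c = fit$thresholds$l_c, mid = 0.5,
                            h_c = fit$thresholds$h_c,
                            provenance = fit$thresholds$provenance),
                       file.path(od, "thresholds.json"),
                       auto_unbox = TRUE, digits = NA)
  write.csv(as.data.frame(fit$reports$train_validate),
            file.path(od, "category_train_validate.csv"), row.names = FALSE)
  write.csv(as.data.frame(fit$reports$test),
            file.path(od, "category_test.csv"), row.names = FALSE)
  write_run_info(config, od, "run")
  pipeline_log("pipeline complete; outputs in ", od)
  invisible(fit)
}
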