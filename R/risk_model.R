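#' Fit the full nodule risk-scoring model
#'
#' Runs the complete pipeline on a cohort: (1) screen characteristics by
#' L1-penalized logistic regression at the cross-validated `lambda_1se`
#' over `R_select` repeated stratified 60/20/20 splits, retaining those
#' selected in at least half the repetitions; (2) compute
#' repetition-averaged risk scores with the chosen classifier backend over
#' `R_score` fresh splits; (3) draw one seeded reference partition, derive
#' the category thresholds (bootstrap-percentile lower limit of the benign
#' mean score, 0.5, and the ROC corner cutoff) on its training+validating
#' portion, and report the four-category composition on both the
#' training+validating and the held-out test portions, together with the
#' repetition-averaged classification metrics.
#'
#' @param cohort A `nodule_cohort`.
#' @param classifier A [classifier_spec()] (default random forest,
#'   ntree 500, mtry 2).
#' @param features Optional characteristic names to use directly, skipping
#'   the selection stage.
#' @param R_select,R_score Repetition counts for the selection and scoring
#'   stages (default 100 each).
#' @param retention_threshold Selection-frequency cutoff (default 0.5).
#' @param proportions Stratified split proportions (default 60/20/20).
#' @param B,conf_level Bootstrap settings for the lower threshold.
#' @param benign_only Bootstrap the benign scores' mean (default TRUE).
#' @param mode Score averaging mode, see [ensemble_risk_scores()].
#' @param folds,n_lambda Penalty-path settings, see [lambda_path()].
#' @param seed Integer master seed (required); all stage seeds derive
#'   from it.
#' @return An object of class `nodule_risk_model` with components
#'   `selection`, `features`, `ensemble`, `thresholds`, `reports` (train
#'   +validate and test `category_report`s), `metrics`
#'   (repetition-averaged), `final_fit` (penalized fit at `lambda_1se` on
#'   the reference training split), `reference_partition`, `seed`.
#' @examples
#' \donttest{
#' coh <- generate_cohort(default_generator_config(n = 300))
#' fit <- nodule_risk_model(coh, R_select = 3, R_score = 3, seed = 7,
#'                          classifier = classifier_spec("logistic"))
#' summary(fit)
#' }
#' @export
nodule_risk_model <- function(cohort,
                              classifier = classifier_spec("random_forest"),
                              features = NULL,
                              R_select = 100, R_score = 100,
                              retention_threshold = 0.5,
                              proportions = c(train = 0.6, validate = 0.2,
                                              test = 0.2),
                              B = 1000, conf_level = 0.95,
                              benign_only = TRUE,
                              mode = c("all_predictions", "out_of_split"),
                              folds = 10, n_lambda = 100, seed) {
  stopifnot(inherits(cohort, "nodule_cohort"),
            inherits(classifier, "classifier_spec"))
  mode <- match.arg(mode)
  if (missing(seed)) stop("seed is required")

  selection <- NULL
  if (is.null(features)) {
    selection <- repeated_selection(cohort, R = R_select,
                                    retention_threshold = retention_threshold,
                                    seed = derive_seed(seed, 11L),
                                    proportions = proportions,
                                    folds = folds, n_lambda = n_lambda)
    features <- selection$retained
    if (length(features) == 0L)
      stop("no characteristic reached the retention threshold")
  }

  ensemble <- ensemble_risk_scores(cohort, classifier, features,
                                   R = R_score,
                                   seed = derive_seed(seed, 22L),
                                   mode = mode, proportions = proportions)

  ref_part <- stratified_split(cohort, proportions,
                               seed = derive_seed(seed, 33L))
  dev_idx <- ref_part != "test"
  y <- as.integer(cohort$records$outcome == "malignant")
  s <- ensemble$scores$score
  thresholds <- derive_thresholds(s[dev_idx], y[dev_idx],
                                  benign_only = benign_only,
                                  B = B, level = conf_level,
                                  seed = derive_seed(seed, 44L))
  reports <- list(
    train_validate = category_report(s[dev_idx], y[dev_idx], thresholds),
    test = category_report(s[!dev_idx], y[!dev_idx], thresholds))

  rep_metrics <- repetition_metrics(ensemble)
  metrics <- summarize_over_repetitions(rep_metrics)

  # reference penalized fit for coef(): lambda_1se on the reference
  # training split
  train_coh <- cohort_subset(cohort, ref_part == "train")
  design <- encode_design(train_coh)
  path <- lambda_path(design, folds = folds, n_lambda = n_lambda,
                      seed = derive_seed(seed, 55L))
  final_fit <- fit_penalized_lr(design, path$lambda_1se)

  structure(list(selection = selection, features = features,
                 classifier = classifier, ensemble = ensemble,
                 thresholds = thresholds, reports = reports,
                 metrics = metrics, repetition_metrics = rep_metrics,
                 final_fit = final_fit, final_path = path,
                 reference_partition = ref_part,
                 outcome = cohort$records$outcome,
                 nodule_id = cohort$records$nodule_id,
                 proportions = proportions, mode = mode, seed = seed,
                 call = match.call()),
            class = "nodule_risk_model")
}

#' @export
print.nodule_risk_model <- function(x, ...) {
  cat("Nodule malignancy risk-scoring model\n")
  cat(sprintf("  classifier: %s, %d scoring repetitions (%s)\n",
              x$classifier$name, x$ensemble$R, x$mode))
  cat(sprintf("  features (%d): %s\n", length(x$features),
              paste(x$features, collapse = ", ")))
  cat(sprintf("  thresholds: l_c=%.3f, 0.5, h_c=%.3f\n",
              x$thresholds$l_c, x$thresholds$h_c))
  invisible(x)
}

#' @export
summary.nodule_risk_model <- function(object, ...) {
  structure(list(model = object), class = "summary.nodule_risk_model")
}

#' @export
print.summary.nodule_risk_model <- function(x, ...) {
  m <- x$model
  print(m)
  if (!is.null(m$selection)) {
    cat("\nSelection frequencies:\n")
    print(m$selection)
  }
  cat("\nRepetition-averaged classification metrics:\n")
  df <- as.data.frame(m$metrics)
  df[, sapply(df, is.numeric)] <- round(df[, sapply(df, is.numeric)], 3)
  print(df, row.names = FALSE)
  cat("\nRisk categories, training+validating:\n")
  print(m$reports$train_validate)
  cat("\nRisk categories, testing:\n")
  print(m$reports$test)
  invisible(x)
}

#' @export
coef.nodule_risk_model <- function(object, ...) {
  coef(object$final_fit)
}

#' Fitted risk scores and categories
#'
#' With `newdata = NULL`, returns the repetition-averaged fitted risk
#' scores (`type = "score"`) or their risk categories
#' (`type = "category"`) for the modelled cohort.  Scoring unseen nodules
#' requires retraining and is not supported from the stored object.
#'
#' @param object A `nodule_risk_model`.
#' @param newdata Must be `NULL`.
#' @param type `"score"` or `"category"`.
#' @param ... Unused.
#' @export
predict.nodule_risk_model <- function(object, newdata = NULL,
                                      type = c("score", "category"), ...) {
  type <- match.arg(type)
  if (!is.null(newdata))
    stop("predict() on new data is not supported: the per-repetition ",
         "classifier ensemble is not stored; refit with the new records ",
         "included")
  s <- setNames(object$ensemble$scores$score, object$nodule_id)
  if (type == "score") s else assign_category(s, object$thresholds)
}

#' @export
fitted.nodule_risk_model <- function(object, ...) {
  predict(object, type = "score")
}

#' @export
residuals.nodule_risk_model <- function(object, ...) {
  y <- as.integer(object$outcome == "malignant")
  y - predict(object, type = "score")
}

#' Risk-score strip plot by outcome
#'
#' One jittered point per nodule, risk score on the vertical axis, with
#' the three category boundaries drawn as horizontal lines.
#'
#' @param x A `nodule_risk_model`.
#' @param ... Passed to [graphics::stripchart()].
#' @export
plot.nodule_risk_model <- function(x, ...) {
  s <- predict(x, type = "score")
  grp <- factor(x$outcome, levels = c("benign", "malignant"))
  stripchart(s ~ grp, vertical = TRUE, method = "jitter", jitter = 0.25,
             pch = 20, col = adjustcolor(c("steelblue", "firebrick"), 0.5),
             ylab = "risk score", ylim = c(0, 1), ...)
  abline(h = c(x$thresholds$l_c, 0.5, x$thresholds$h_c),
         lty = c(2, 3, 2), col = "grey40")
  invisible(x)
}
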