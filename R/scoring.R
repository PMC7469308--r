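#' Classifier backend specification
#'
#' A backend satisfies a small contract: fitted on the training records
#' restricted to the selected characteristics, it emits a malignancy
#' probability for arbitrary records, deterministically under a seed.
#' `random_forest` (probability = fraction of trees voting malignant;
#' defaults ntree = 500, mtry = 2) and `logistic` (unpenalized logistic
#' regression) are built in.
#'
#' @param name `"random_forest"` or `"logistic"`.
#' @param hyperparameters Named list overriding backend defaults.
#' @param seed Integer seed used when the backend is stochastic.
#' @return An object of class `classifier_spec`.
#' @export
classifier_spec <- function(name = c("random_forest", "logistic"),
                            hyperparameters = list(), seed = 1L) {
  name <- match.arg(name)
  defaults <- switch(name,
                     random_forest = list(ntree = 500, mtry = 2),
                     logistic = list())
  hp <- utils::modifyList(defaults, hyperparameters)
  structure(list(name = name, hyperparameters = hp,
                 seed = as.integer(seed)),
            class = "classifier_spec")
}

#' @export
print.classifier_spec <- function(x, ...) {
  hp <- if (length(x$hyperparameters))
    paste(names(x$hyperparameters), unlist(x$hyperparameters),
          sep = "=", collapse = ", ") else "defaults"
  cat(sprintf("<classifier_spec> %s (%s)\n", x$name, hp))
  invisible(x)
}

# model frame for the classifier backends: factors for categorical
# characteristics (reference level first), numerics for continuous
classifier_frame <- function(cohort, features) {
  stopifnot(length(features) > 0L)
  unknown <- setdiff(features, names(cohort$schema))
  if (length(unknown))
    stop("unknown feature(s): ", paste(unknown, collapse = ", "))
  rec <- cohort$records
  out <- list()
  for (nm in features) {
    s <- cohort$schema[[nm]]
    out[[nm]] <- if (s$kind == "categorical")
      factor(rec[[nm]], levels = c(s$reference,
                                   setdiff(s$levels, s$reference)))
    else as.numeric(rec[[nm]])
  }
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Train a classifier and score every nodule
#'
#' Fits the backend on the training subset restricted to the selected
#' characteristics and returns a malignancy probability for every record
#' of the cohort (training records included).
#'
#' @param cohort A `nodule_cohort`.
#' @param train Logical or integer index of the training records.
#' @param spec A [classifier_spec()].
#' @param features Names of the characteristics to use as predictors.
#' @return Numeric vector of P(malignant), one per cohort record.
#' @export
train_and_score <- function(cohort, train, spec, features) {
  stopifnot(inherits(cohort, "nodule_cohort"),
            inherits(spec, "classifier_spec"))
  frame <- classifier_frame(cohort, features)
  y <- factor(cohort$records$outcome, levels = c("benign", "malignant"))
  if (is.logical(train)) train <- which(train)
  if (length(unique(y[train])) < 2L)
    stop("training split contains a single outcome class")

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)

  if (spec$name == "random_forest") {
    hp <- spec$hyperparameters
    model <- randomForest::randomForest(
      x = frame[train, , drop = FALSE], y = y[train],
      ntree = hp$ntree, mtry = min(hp$mtry, ncol(frame)))
    prob <- predict(model, newdata = frame, type = "prob")[, "malignant"]
  } else {
    df <- cbind(frame, .y = as.integer(y == "malignant"))
    model <- suppressWarnings(
      glm(.y ~ ., data = df[train, , drop = FALSE], family = binomial()))
    prob <- suppressWarnings(
      predict(model, newdata = df, type = "response"))
  }
  unname(prob)
}

#' Repetition-averaged risk scores
#'
#' Repeats the stratified 60/20/20 partition `R` times, trains the
#' classifier per repetition, and averages each nodule's malignancy
#' probability into its risk score.  Mode `"all_predictions"` averages
#' every repetition's probability (the convention behind the published
#' score plots); `"out_of_split"` averages only repetitions in which the
#' nodule was outside the training split, avoiding the optimism of
#' in-training forest votes.
#'
#' @param cohort A `nodule_cohort`.
#' @param spec A [classifier_spec()].
#' @param features Predictor characteristic names.
#' @param R Number of repetitions (default 100).
#' @param seed Integer master seed.
#' @param mode `"all_predictions"` (default) or `"out_of_split"`.
#' @param proportions Split proportions.
#' @return An object of class `risk_score_table`: data.frame `scores`
#'   (`nodule_id`, `score`, `n_repetitions`), the per-repetition
#'   probability matrix `prob`, partition-label matrix `partition`, and the
#'   settings used.
#' @export
ensemble_risk_scores <- function(cohort, spec, features, R = 100, seed,
                                 mode = c("all_predictions", "out_of_split"),
                                 proportions = c(train = 0.6, validate = 0.2,
                                                 test = 0.2)) {
  mode <- match.arg(mode)
  if (R < 1) stop("R must be at least 1")
  if (missing(seed)) stop("seed is required")
  n <- nrow(cohort$records)
  prob <- matrix(NA_real_, n, R)
  part <- matrix(NA_character_, n, R)
  for (r in seq_len(R)) {
    seed_r <- derive_seed(seed, 1000L + r)
    labels <- stratified_split(cohort, proportions, seed = seed_r)
    spec_r <- spec; spec_r$seed <- derive_seed(seed_r, 2L)
    prob[, r] <- train_and_score(cohort, labels == names(proportions)[1L],
                                 spec_r, features)
    part[, r] <- as.character(labels)
  }
  use <- if (mode == "all_predictions") matrix(TRUE, n, R)
         else part != names(proportions)[1L]
  n_rep <- rowSums(use)
  if (any(n_rep == 0L))
    stop("nodule never held out of training: ",
         cohort$records$nodule_id[which(n_rep == 0L)[1L]])
  score <- rowSums(prob * use) / n_rep
  structure(list(
    scores = data.frame(nodule_id = cohort$records$nodule_id,
                        score = score, n_repetitions = n_rep,
                        stringsAsFactors = FALSE),
    prob = prob, partition = part, mode = mode, spec = spec,
    features = features, R = R, seed = seed,
    outcome = cohort$records$outcome),
    class = "risk_score_table")
}

#' @export
print.risk_score_table <- function(x, ...) {
  cat(sprintf("<risk_score_table> %d nodules, %d repetitions (%s, %s)\n",
              nrow(x$scores), x$R, x$spec$name, x$mode))
  invisible(x)
}

#' Probability threshold closest to the perfect ROC corner
#'
#' Scans the midpoints of adjacent sorted unique scores (plus -Inf/+Inf)
#' and returns the threshold minimizing the Euclidean distance
#' \eqn{\sqrt{(1-SEN)^2 + (1-SPE)^2}} to the (0,1) corner of the ROC plane;
#' ties break toward the smaller threshold.  Predicted-positive means
#' score strictly above the threshold.
#'
#' @param scores Numeric scores.
#' @param labels 0/1 outcomes (1 = malignant).
#' @return The optimal threshold.
#' @export
optimal_probability_cutoff <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  u <- sort(unique(scores))
  cand <- c(-Inf, if (length(u) > 1L) (u[-1L] + u[-length(u)]) / 2, Inf)
  dist <- vapply(cand, function(th) {
    pos <- scores > th
    sen <- sum(pos & labels == 1L) / n1
    spe <- sum(!pos & labels == 0L) / n0
    sqrt((1 - sen)^2 + (1 - spe)^2)
  }, numeric(1))
  cand[which.min(dist)]  # candidates ascend; first minimum = smallest
}

#' Threshold-based classification metrics of a score vector
#'
#' Predicted malignant iff `score > threshold`.  Reports the rank AUC
#' (threshold-free), sensitivity, specificity, predictive values, and the
#' benign-class F1 score, the harmonic mean of the benign precision (NPV)
#' and benign recall (SPE) — the convention under which the published
#' classifier table is internally consistent.  Metrics with an empty
#' denominator are `NA`.
#'
#' @param scores Numeric scores.
#' @param labels 0/1 outcomes (1 = malignant).
#' @param threshold Decision threshold.
#' @return Named list: `auc`, `sen`, `f1`, `spe`, `ppv`, `npv`.
#' @export
classifier_metrics <- function(scores, labels, threshold) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  pos <- scores > threshold
  tp <- sum(pos & labels == 1L); fp <- sum(pos & labels == 0L)
  fn <- n1 - tp; tn <- n0 - fp
  sen <- tp / n1; spe <- tn / n0
  ppv <- if (tp + fp > 0L) tp / (tp + fp) else NA_real_
  npv <- if (tn + fn > 0L) tn / (tn + fn) else NA_real_
  f1 <- if (!is.na(npv) && npv + spe > 0) 2 * npv * spe / (npv + spe)
        else NA_real_
  list(auc = rank_auc(scores, labels), sen = sen, f1 = f1,
       spe = spe, ppv = ppv, npv = npv)
}

#' Per-repetition evaluation of an ensemble
#'
#' For each repetition of a [ensemble_risk_scores()] object, derives the
#' ROC-corner threshold on the validation split of that repetition and
#' computes the six classification metrics on the validation and test
#' splits.
#'
#' @param ensemble A `risk_score_table`.
#' @return data.frame with columns `repetition`, `split`, and the six
#'   metrics.
#' @export
repetition_metrics <- function(ensemble) {
  stopifnot(inherits(ensemble, "risk_score_table"))
  y <- as.integer(ensemble$outcome == "malignant")
  rows <- list()
  for (r in seq_len(ensemble$R)) {
    p <- ensemble$prob[, r]
    lab <- ensemble$partition[, r]
    iv <- lab == "validate"; it <- lab == "test"
    th <- optimal_probability_cutoff(p[iv], y[iv])
    for (split in c("validating", "testing")) {
      ii <- if (split == "validating") iv else it
      met <- classifier_metrics(p[ii], y[ii], th)
      rows[[length(rows) + 1L]] <- data.frame(
        repetition = r, split = split, threshold = th,
        auc = met$auc, sen = met$sen, f1 = met$f1,
        spe = met$spe, ppv = met$ppv, npv = met$npv)
    }
  }
  do.call(rbind, rows)
}

#' Average repetition metrics into a summary table
#'
#' Arithmetic mean of each metric per split, ignoring `NA` entries
#' (reported via `n_used`).
#'
#' @param metrics data.frame from [repetition_metrics()] (or any frame
#'   with a `split` column and metric columns).
#' @return data.frame of class `metric_summary`, one row per split.
#' @export
summarize_over_repetitions <- function(metrics) {
  stopifnot(is.data.frame(metrics), nrow(metrics) >= 1L)
  cols <- intersect(c("auc", "sen", "f1", "spe", "ppv", "npv"),
                    names(metrics))
  out <- lapply(split(metrics, metrics$split), function(df) {
    means <- vapply(cols, function(cn) mean(df[[cn]], na.rm = TRUE),
                    numeric(1))
    used <- vapply(cols, function(cn) sum(!is.na(df[[cn]])), numeric(1))
    cbind(data.frame(split = df$split[1L], n_repetitions = nrow(df)),
          as.data.frame(as.list(means)),
          data.frame(n_used_min = min(used)))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  class(out) <- c("metric_summary", "data.frame")
  out
}
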