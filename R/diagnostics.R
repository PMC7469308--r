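#' 2x2 contingency table for a dichotomous malignancy predictor
#'
#' Cross-classifies a positive/negative predictor with the
#' malignant/benign outcome: `tp` malignant & positive, `fp` benign &
#' positive, `fn` malignant & negative, `tn` benign & negative.
#'
#' @param tp,fp,fn,tn Non-negative integer counts.
#' @return An object of class `contingency_2x2`.
#' @export
contingency_2x2 <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(is.na(counts)) || any(counts < 0) ||
      any(counts != round(counts)))
    stop("counts must be non-negative integers")
  structure(lapply(as.list(counts), as.integer), class = "contingency_2x2")
}

#' @export
print.contingency_2x2 <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(c("positive", "negative"),
                              c("malignant", "benign")))
  print(m)
  invisible(x)
}

as_matrix_2x2 <- function(tab) {
  matrix(c(tab$tp, tab$fn, tab$fp, tab$tn), 2, 2,
         dimnames = list(predictor = c("positive", "negative"),
                         outcome = c("malignant", "benign")))
}

#' One-vs-rest contingency table for a characteristic level
#'
#' A record is "positive" when it carries exactly the given level and
#' "negative" otherwise; for characteristics with three levels the two
#' remaining levels are pooled into the negative margin.  This pooling is
#' the convention under which the published per-level metrics reproduce.
#'
#' @param cohort A `nodule_cohort`.
#' @param characteristic Name of a categorical characteristic.
#' @param level Level treated as the positive call.
#' @return A `contingency_2x2`.
#' @export
level_contingency <- function(cohort, characteristic, level) {
  stopifnot(inherits(cohort, "nodule_cohort"))
  spec <- cohort$schema[[characteristic]]
  if (is.null(spec) || spec$kind != "categorical")
    stop("unknown categorical characteristic '", characteristic, "'")
  if (!level %in% spec$levels)
    stop("unknown level '", level, "' for '", characteristic, "'")
  pos <- cohort$records[[characteristic]] == level
  mal <- cohort$records$outcome == "malignant"
  contingency_2x2(tp = sum(pos & mal), fp = sum(pos & !mal),
                  fn = sum(!pos & mal), tn = sum(!pos & !mal))
}

#' Diagnostic accuracy metrics of a dichotomous predictor
#'
#' Sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, positive and
#' negative predictive values, and the AUC of the dichotomised predictor,
#' which for a binary score equals `(SEN + SPE) / 2`.  A predictive value
#' whose denominator is zero is reported as `NA`.
#'
#' @param table A `contingency_2x2`.
#' @return Named list with elements `sen`, `spe`, `ppv`, `npv`, `auc`,
#'   class `diagnostic_metrics`.
#' @examples
#' # irregular margin in the reference cohort
#' m <- diagnostic_metrics(contingency_2x2(tp = 1020, fp = 74,
#'                                         fn = 180, tn = 174))
#' round(m$auc, 3)  # 0.776
#' @export
diagnostic_metrics <- function(table) {
  stopifnot(inherits(table, "contingency_2x2"))
  with(table, {
    if (tp + fn == 0L || fp + tn == 0L)
      stop("both outcome margins must be positive")
    sen <- tp / (tp + fn)
    spe <- tn / (tn + fp)
    ppv <- if (tp + fp > 0L) tp / (tp + fp) else NA_real_
    npv <- if (tn + fn > 0L) tn / (tn + fn) else NA_real_
    structure(list(sen = sen, spe = spe, ppv = ppv, npv = npv,
                   auc = (sen + spe) / 2),
              class = "diagnostic_metrics")
  })
}

#' @export
print.diagnostic_metrics <- function(x, ...) {
  cat(sprintf("SEN %.1f%%  SPE %.1f%%  PPV %s  NPV %s  AUC %.3f\n",
              100 * x$sen, 100 * x$spe,
              if (is.na(x$ppv)) "--" else sprintf("%.1f%%", 100 * x$ppv),
              if (is.na(x$npv)) "--" else sprintf("%.1f%%", 100 * x$npv),
              x$auc))
  invisible(x)
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value under the probability-ordering rule: the sum of
#' hypergeometric probabilities (margins fixed) of all tables no more
#' probable than the observed one.
#'
#' @param table A `contingency_2x2`.
#' @return Two-sided p-value in `[0, 1]`.
#' @export
fisher_exact <- function(table) {
  stopifnot(inherits(table, "contingency_2x2"))
  m <- as_matrix_2x2(table)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("all margins must be positive")
  stats::fisher.test(m)$p.value
}

#' Rank-based AUC (Mann-Whitney statistic scaled to [0, 1])
#'
#' Probability that a randomly chosen positive scores above a randomly
#' chosen negative, ties counting one half.
#'
#' @param scores Numeric vector.
#' @param labels 0/1 vector (1 = positive class), same length.
#' @return AUC in `[0, 1]`.
#' @export
rank_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Mann-Whitney rank test (normal approximation with tie correction)
#'
#' @param values_a,values_b Non-empty numeric vectors.
#' @return List with the U statistic of the first sample and the
#'   two-sided p-value.
#' @export
mann_whitney <- function(values_a, values_b) {
  if (length(values_a) == 0L || length(values_b) == 0L)
    stop("both samples must be non-empty")
  wt <- suppressWarnings(
    stats::wilcox.test(values_a, values_b, exact = FALSE, correct = FALSE))
  list(u = unname(wt$statistic), p = wt$p.value)
}

#' Published per-characteristic counts and metrics
#'
#' Reference tables transcribed from the source clinical study: per level
#' of each categorical US characteristic, the benign and malignant counts
#' and (for non-reference levels) the printed NPV/PPV/SEN/SPE percentages
#' and AUC.  `"disease"` is the 1448-nodule surgical cohort; `"overall"`
#' additionally includes the 110 abnormal nodules.
#'
#' @param group `"disease"` or `"overall"`.
#' @return data.frame with columns `characteristic`, `level`, `reference`,
#'   `benign`, `malignant`, `npv`, `ppv`, `sen`, `spe`, `auc`.
#' @export
study_characteristic_counts <- function(group = c("disease", "overall")) {
  group <- match.arg(group)
  path <- system.file("extdata",
                      paste0("characteristic_counts_", group, ".csv"),
                      package = "thyroRisk", mustWork = TRUE)
  read.csv(path, stringsAsFactors = FALSE)
}

#' Published classifier performance table
#'
#' Repetition-averaged AUC/SEN/F1/SPE/PPV/NPV of the ten classifiers on the
#' validating and testing splits, as printed in the source study.
#'
#' @return data.frame with columns `classifier`, `split`, `auc`, `sen`,
#'   `f1`, `spe`, `ppv`, `npv`.
#' @export
study_classifier_metrics <- function() {
  path <- system.file("extdata", "classifier_metrics.csv",
                      package = "thyroRisk", mustWork = TRUE)
  read.csv(path, stringsAsFactors = FALSE)
}

#' Reconstruct a cohort with given per-characteristic marginals
#'
#' Builds a cohort whose class-conditional level counts match a counts
#' table exactly (characteristics filled independently within each outcome,
#' so joint structure is arbitrary but every one-vs-rest contingency table
#' is exact).  ER is set to 1.0 for hypoechoic and 2.0 for hyperechoic
#' records; age and size get nominal constants.
#'
#' @param counts data.frame as returned by [study_characteristic_counts()].
#' @param schema Characteristic schema; defaults to [default_schema()].
#' @return A `nodule_cohort`.
#' @export
cohort_from_counts <- function(counts, schema = default_schema()) {
  schema <- as_schema(schema)
  first <- counts[counts$characteristic == counts$characteristic[1L], ]
  n_ben <- sum(first$benign); n_mal <- sum(first$malignant)
  outcome <- c(rep("benign", n_ben), rep("malignant", n_mal))
  rec <- data.frame(nodule_id = sprintf("nod%05d", seq_along(outcome)),
                    outcome = outcome, age = 50, size = 10,
                    stringsAsFactors = FALSE)
  for (s in categorical_specs(schema)) {
    sub <- counts[counts$characteristic == s$name, ]
    if (nrow(sub) == 0L) stop("no counts for characteristic '", s$name, "'")
    if (sum(sub$benign) != n_ben || sum(sub$malignant) != n_mal)
      stop("inconsistent outcome totals for '", s$name, "'")
    rec[[s$name]] <- c(rep(sub$level, sub$benign), rep(sub$level, sub$malignant))
  }
  if ("echogenicity" %in% names(rec))
    rec$er <- ifelse(rec$echogenicity == "hypoechoic", 1.0, 2.0)
  new_cohort(rec, schema)
}

#' Per-level diagnostic report for every characteristic
#'
#' One row per non-reference level of each categorical characteristic with
#' its one-vs-rest counts, diagnostic metrics and Fisher exact p-value;
#' reference levels appear as marker rows with counts only.
#'
#' @param cohort A `nodule_cohort`.
#' @return data.frame of class `characteristic_report`.
#' @export
characteristic_report <- function(cohort) {
  stopifnot(inherits(cohort, "nodule_cohort"))
  if (length(unique(cohort$records$outcome)) < 2L)
    stop("cohort must contain both outcomes")
  rows <- list()
  for (s in categorical_specs(cohort$schema)) {
    for (lev in s$levels) {
      tab <- level_contingency(cohort, s$name, lev)
      ref <- lev == s$reference
      if (ref) {
        met <- list(sen = NA, spe = NA, ppv = NA, npv = NA, auc = NA)
        p <- NA_real_
      } else {
        met <- diagnostic_metrics(tab)
        p <- fisher_exact(tab)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        characteristic = s$name, level = lev, reference = ref,
        benign = tab$fp, malignant = tab$tp,
        npv = 100 * met$npv, ppv = 100 * met$ppv,
        sen = 100 * met$sen, spe = 100 * met$spe,
        auc = met$auc, fisher_p = p, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("characteristic_report", "data.frame")
  out
}

#' @export
print.characteristic_report <- function(x, digits = 1, ...) {
  df <- as.data.frame(x)
  fmt <- function(v, d) ifelse(is.na(v), "--", formatC(v, format = "f", digits = d))
  disp <- data.frame(
    characteristic = df$characteristic,
    level = ifelse(df$reference, paste0(df$level, " (ref)"), df$level),
    benign = df$benign, malignant = df$malignant,
    NPV = fmt(df$npv, digits), PPV = fmt(df$ppv, digits),
    SEN = fmt(df$sen, digits), SPE = fmt(df$spe, digits),
    AUC = fmt(df$auc, 3),
    p = ifelse(is.na(df$fisher_p), "--",
               ifelse(df$fisher_p < 0.001, "<0.001",
                      formatC(df$fisher_p, format = "f", digits = 3))))
  print(disp, row.names = FALSE)
  invisible(x)
}
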