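#' Bootstrap-percentile lower confidence limit of a mean
#'
#' Resamples the scores with replacement `B` times, takes the mean of each
#' resample, and returns the lower percentile of the resulting bootstrap
#' distribution (the 2.5th percentile for the default 95\% two-sided
#' interval).  Deterministic given the seed.
#'
#' @param scores Numeric vector (at least 10 values).
#' @param B Number of bootstrap replications (default 1000).
#' @param level Two-sided confidence level (default 0.95).
#' @param seed Integer seed.
#' @return The lower confidence limit of the mean.
#' @export
bootstrap_lower_limit <- function(scores, B = 1000, level = 0.95, seed) {
  if (length(scores) < 10L) stop("need at least 10 scores")
  if (missing(seed)) stop("seed is required")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  n <- length(scores)
  means <- vapply(seq_len(B),
                  function(b) mean(scores[sample.int(n, n, replace = TRUE)]),
                  numeric(1))
  unname(quantile(means, (1 - level) / 2))
}

category_levels <- c("benign", "low_suspicion",
                     "intermediate_suspicion", "high_suspicion")

management_text <- c(
  benign = "After a 6-month sonographic follow-up",
  low_suspicion = "After 3-month sonographic follow-up or Fine Needle Aspiration (FNA) biopsy",
  intermediate_suspicion = "FNA biopsy",
  high_suspicion = "FNA biopsy or surgical treatment")

#' Derive the four-category risk thresholds
#'
#' The lower boundary `l_c` is the bootstrap-percentile 95\% lower
#' confidence limit of the mean risk score (of the benign nodules by
#' default — the only reading under which the published boundary near 0.27
#' is attainable at 83\% malignancy prevalence); the upper boundary `h_c`
#' is the ROC threshold closest to (0,1) via
#' [optimal_probability_cutoff()]; the middle boundary is fixed at 0.5.
#' The ordering `l_c < 0.5 < h_c` is validated.
#'
#' @param scores Numeric risk scores, or a `risk_score_table`.
#' @param labels 0/1 outcomes (1 = malignant); taken from the table when
#'   `scores` is a `risk_score_table`.
#' @param benign_only Bootstrap the benign nodules' mean (default TRUE)
#'   rather than all scores.
#' @param B,level Bootstrap settings, see [bootstrap_lower_limit()].
#' @param seed Integer seed.
#' @return An object of class `risk_thresholds`: `l_c`, `mid` (0.5),
#'   `h_c`, and a `provenance` record of the settings.
#' @export
derive_thresholds <- function(scores, labels = NULL, benign_only = TRUE,
                              B = 1000, level = 0.95, seed) {
  if (inherits(scores, "risk_score_table")) {
    labels <- as.integer(scores$outcome == "malignant")
    scores <- scores$scores$score
  }
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) stop("both classes must be present")
  if (missing(seed)) stop("seed is required")
  pool <- if (benign_only) scores[labels == 0L] else scores
  l_c <- bootstrap_lower_limit(pool, B = B, level = level, seed = seed)
  h_c <- optimal_probability_cutoff(scores, labels)
  if (!(l_c < 0.5))
    stop("threshold ordering violated: l_c = ", signif(l_c, 4),
         " is not below 0.5 (scores of the lower-risk class sit too high)")
  if (!(h_c > 0.5))
    stop("threshold ordering violated: h_c = ", signif(h_c, 4),
         " is not above 0.5 (score/label orientation looks inverted)")
  structure(list(l_c = unname(l_c), mid = 0.5, h_c = unname(h_c),
                 provenance = list(benign_only = benign_only, B = B,
                                   level = level, seed = seed,
                                   n_scores = length(pool))),
            class = "risk_thresholds")
}

#' @export
print.risk_thresholds <- function(x, ...) {
  cat(sprintf("<risk_thresholds> l_c=%.3f < 0.5 < h_c=%.3f (bootstrap B=%d, %s scores)\n",
              x$l_c, x$h_c, x$provenance$B,
              if (x$provenance$benign_only) "benign" else "all"))
  invisible(x)
}

#' Assign risk scores to the four-level category system
#'
#' `benign` below `l_c`; `low_suspicion` in `[l_c, 0.5)`;
#' `intermediate_suspicion` in `[0.5, h_c)`; `high_suspicion` at or above
#' `h_c`.  Boundaries are left-closed, matching the published inequalities.
#'
#' @param score Numeric vector of risk scores in `[0, 1]`.
#' @param thresholds A `risk_thresholds`.
#' @return Factor with levels benign, low_suspicion,
#'   intermediate_suspicion, high_suspicion.
#' @export
assign_category <- function(score, thresholds) {
  stopifnot(inherits(thresholds, "risk_thresholds"))
  if (any(is.na(score) | score < 0 | score > 1))
    stop("scores must lie in [0, 1]")
  out <- ifelse(score < thresholds$l_c, "benign",
         ifelse(score < thresholds$mid, "low_suspicion",
         ifelse(score < thresholds$h_c, "intermediate_suspicion",
                "high_suspicion")))
  factor(out, levels = category_levels)
}

#' Category-wise composition and malignancy rates
#'
#' Counts of benign and malignant nodules, the malignancy rate, and the
#' fixed management recommendation per risk category.
#'
#' @param scores Numeric risk scores, or a `risk_score_table`.
#' @param labels 0/1 outcomes (1 = malignant).
#' @param thresholds A `risk_thresholds`.
#' @return data.frame of class `category_report`: `category`, `benign`,
#'   `malignant`, `n`, `malignancy_rate`, `management`.
#' @export
category_report <- function(scores, labels = NULL, thresholds) {
  if (inherits(scores, "risk_score_table")) {
    labels <- as.integer(scores$outcome == "malignant")
    scores <- scores$scores$score
  }
  labels <- as.integer(labels)
  cat <- assign_category(scores, thresholds)
  out <- data.frame(category = category_levels,
                    benign = as.integer(table(cat[labels == 0L])),
                    malignant = as.integer(table(cat[labels == 1L])),
                    stringsAsFactors = FALSE)
  out$n <- out$benign + out$malignant
  out$malignancy_rate <- ifelse(out$n > 0, out$malignant / out$n, NA_real_)
  out$management <- unname(management_text[out$category])
  class(out) <- c("category_report", "data.frame")
  out
}

#' @export
print.category_report <- function(x, ...) {
  df <- as.data.frame(x)
  df$malignancy_rate <- ifelse(is.na(df$malignancy_rate), "--",
                               sprintf("%.1f%%", 100 * df$malignancy_rate))
  df$management <- strtrim(df$management, 40)
  print(df, row.names = FALSE)
  invisible(x)
}
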