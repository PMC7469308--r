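# Independent oracles used across the suite.  Each reimplements the target
# quantity by a different route than the package (enumeration, geometric
# integration, direct objective evaluation) so agreement is evidence, not
# tautology.

# trapezoidal integration of the empirical ROC curve (ties grouped)
trapezoid_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  thr <- sort(unique(scores), decreasing = TRUE)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  tpr <- c(0, vapply(thr, function(t) sum(scores >= t & labels == 1L) / n1,
                     numeric(1)))
  fpr <- c(0, vapply(thr, function(t) sum(scores >= t & labels == 0L) / n0,
                     numeric(1)))
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

# two-sided Fisher p by full enumeration of the hypergeometric support
# under the probability-ordering rule
fisher_enum_p <- function(tp, fp, fn, tn) {
  mal <- tp + fn; ben <- fp + tn; pos <- tp + fp
  support <- max(0, pos - ben):min(mal, pos)
  probs <- dhyper(support, mal, ben, pos)
  p_obs <- dhyper(tp, mal, ben, pos)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# mean penalized log-likelihood objective on the standardized scale,
# evaluated directly from raw x/y and original-scale coefficients
penalized_objective <- function(x, y, beta0, beta, lambda) {
  eta <- beta0 + drop(x %*% beta)
  ctr <- colMeans(x)
  scl <- sqrt(colMeans(sweep(x, 2, ctr)^2))
  beta_std <- beta * scl
  mean(y * eta - log1p(exp(eta))) - lambda * sum(abs(beta_std))
}

# exhaustive closest-to-(0,1) threshold search by direct tabulation
brute_force_cutoff <- function(scores, labels) {
  labels <- as.integer(labels)
  u <- sort(unique(scores))
  cand <- c(-Inf, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, Inf)
  best <- Inf; best_th <- NA
  for (th in cand) {
    tp <- 0; fp <- 0; fn <- 0; tn <- 0
    for (i in seq_along(scores)) {
      if (scores[i] > th) {
        if (labels[i] == 1L) tp <- tp + 1 else fp <- fp + 1
      } else {
        if (labels[i] == 1L) fn <- fn + 1 else tn <- tn + 1
      }
    }
    d <- sqrt((1 - tp / (tp + fn))^2 + (1 - tn / (tn + fp))^2)
    if (d < best - 1e-15) { best <- d; best_th <- th }
  }
  best_th
}

# small synthetic schema/cohort used by unit tests that do not need the
# full 14-characteristic default
toy_schema <- function() {
  list(
    characteristic_spec("grade", "categorical", c("A", "B", "C"),
                        reference = "A"),
    characteristic_spec("halo", "categorical", c("absent", "present"),
                        reference = "absent"),
    characteristic_spec("size", "continuous")
  )
}

toy_cohort <- function(n = 40, seed = 1) {
  set.seed(seed)
  rec <- data.frame(
    nodule_id = sprintf("t%03d", seq_len(n)),
    grade = sample(c("A", "B", "C"), n, replace = TRUE),
    halo = sample(c("absent", "present"), n, replace = TRUE),
    size = rlnorm(n, log(10), 0.4),
    outcome = sample(c("benign", "malignant"), n, replace = TRUE,
                     prob = c(0.4, 0.6)),
    stringsAsFactors = FALSE)
  new_cohort(rec, toy_schema())
}

# recomputed (not printed) diagnostic metrics from raw one-vs-rest counts
recount_metrics <- function(tp, fp, fn, tn) {
  list(sen = tp / (tp + fn), spe = tn / (tn + fp),
       ppv = tp / (tp + fp), npv = tn / (tn + fn),
       auc = (tp / (tp + fn) + tn / (tn + fp)) / 2)
}
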