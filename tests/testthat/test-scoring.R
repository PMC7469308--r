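test_that("logistic backend saturates on linearly separable toy data", {
  rec <- data.frame(
    nodule_id = sprintf("s%02d", 1:40),
    grade = "A", halo = rep(c("absent", "present"), each = 20),
    size = c(rnorm(20, 5, 0.1), rnorm(20, 30, 0.1)),
    outcome = rep(c("benign", "malignant"), each = 20),
    stringsAsFactors = FALSE)
  coh <- new_cohort(rec, toy_schema())
  p <- train_and_score(coh, rep(TRUE, 40), classifier_spec("logistic"),
                       features = c("size", "halo"))
  expect_true(all(p[21:40] >= 0.99))
  expect_true(all(p[1:20] <= 0.01))
})

test_that("forest probabilities on a pure-noise feature hover at prevalence", {
  # balanced prevalence: majority-vote fractions are only calibrated when
  # neither class dominates every leaf
  cfg <- add_null_characteristic(default_generator_config(n = 400))
  cfg$prevalence <- 0.5
  coh <- generate_cohort(cfg, seed = 8)
  spec <- classifier_spec("random_forest", list(ntree = 500, mtry = 1))
  train <- seq_len(400) <= 240
  p <- train_and_score(coh, train, spec, features = "speckle")
  # judge on held-out records: in-training forest votes memorize labels
  held <- p[!train]
  prev <- mean(coh$records$outcome[train] == "malignant")
  se <- sd(held) / sqrt(length(held)) +
    sqrt(prev * (1 - prev) / sum(train))
  expect_lt(abs(mean(held) - prev), 3 * se + 0.02)
})

test_that("scoring is deterministic under the seed contract", {
  coh <- generate_cohort(default_generator_config(n = 120), seed = 3)
  spec <- classifier_spec("random_forest", list(ntree = 100), seed = 42)
  train <- seq_len(120) <= 72
  p1 <- train_and_score(coh, train, spec, features = c("component", "margin"))
  p2 <- train_and_score(coh, train, spec, features = c("component", "margin"))
  expect_identical(p1, p2)
  expect_error(train_and_score(coh, which(coh$records$outcome == "benign"),
                               spec, "component"), "single outcome")
})

test_that("ensemble scores average per-repetition probabilities and respect bounds", {
  coh <- generate_cohort(default_generator_config(n = 150), seed = 4)
  spec <- classifier_spec("logistic")
  ens1 <- ensemble_risk_scores(coh, spec, c("component", "margin", "age"),
                               R = 1, seed = 11)
  expect_equal(ens1$scores$score, ens1$prob[, 1], tolerance = 1e-12)
  ens <- ensemble_risk_scores(coh, spec, c("component", "margin", "age"),
                              R = 4, seed = 11)
  expect_equal(ens$scores$score, rowMeans(ens$prob), tolerance = 1e-12)
  expect_true(all(ens$scores$score >= 0 & ens$scores$score <= 1))
  expect_equal(ens$scores$n_repetitions, rep(4L, 150),
               ignore_attr = TRUE)
  # determinism
  ens2 <- ensemble_risk_scores(coh, spec, c("component", "margin", "age"),
                               R = 4, seed = 11)
  expect_identical(ens$prob, ens2$prob)
})

test_that("out-of-split averaging uses only held-out repetitions", {
  coh <- generate_cohort(default_generator_config(n = 80), seed = 5)
  spec <- classifier_spec("logistic")
  ens <- ensemble_risk_scores(coh, spec, c("component", "age"),
                              R = 15, seed = 3, mode = "out_of_split")
  held <- ens$partition != "train"
  manual <- rowSums(ens$prob * held) / rowSums(held)
  expect_equal(ens$scores$score, manual, tolerance = 1e-12)
  expect_true(all(ens$scores$n_repetitions < 15))
})

test_that("malignant nodules outscore benign ones on calibrated synthetic data", {
  coh <- generate_cohort(default_generator_config(n = 300), seed = 6)
  ens <- ensemble_risk_scores(coh, classifier_spec("random_forest",
                                                   list(ntree = 200)),
                              c("component", "margin", "hackly_border",
                                "echogenicity", "age"),
                              R = 3, seed = 21)
  s <- ens$scores$score
  mal <- coh$records$outcome == "malignant"
  expect_gt(mean(s[mal]), mean(s[!mal]))
})

test_that("optimal probability cutoff matches the brute-force oracle", {
  set.seed(19)
  for (k in 1:200) {
    n <- sample(8:40, 1)
    s <- round(runif(n), 2)
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    expect_equal(optimal_probability_cutoff(s, y), brute_force_cutoff(s, y))
  }
})

test_that("perfectly separated scores give the gap midpoint at distance zero", {
  s <- c(0.1, 0.2, 0.8, 0.9); y <- c(0, 0, 1, 1)
  th <- optimal_probability_cutoff(s, y)
  expect_equal(th, 0.5)
  met <- classifier_metrics(s, y, th)
  expect_equal(met$sen, 1); expect_equal(met$spe, 1)
})

test_that("label inversion swaps the roles of SEN and SPE around the cutoff", {
  set.seed(2)
  s <- runif(30); y <- rbinom(30, 1, 0.5)
  if (length(unique(y)) < 2) y[1:2] <- 0:1
  th <- 0.5
  a <- classifier_metrics(s, y, th)
  b <- classifier_metrics(1 - s, 1 - y, 1 - th - 1e-12)
  expect_equal(a$sen, b$spe, tolerance = 1e-12)
  expect_equal(a$spe, b$sen, tolerance = 1e-12)
})

test_that("benign-class F1 equals its confusion-matrix recomputation and the published identity", {
  # published random-forest testing row: SPE 0.880, NPV 0.611 -> F1 0.721
  expect_equal(round(2 * 0.611 * 0.880 / (0.611 + 0.880), 3), 0.721)
  set.seed(9)
  for (k in 1:50) {
    s <- runif(40); y <- rbinom(40, 1, 0.6)
    if (length(unique(y)) < 2) next
    th <- runif(1)
    met <- classifier_metrics(s, y, th)
    pos <- s > th
    tn <- sum(!pos & y == 0); fn <- sum(!pos & y == 1)
    fp <- sum(pos & y == 0)
    prec <- tn / (tn + fn); rec <- tn / (tn + fp)  # benign precision/recall
    if (is.finite(prec) && is.finite(rec) && prec + rec > 0)
      expect_equal(met$f1, 2 * prec * rec / (prec + rec), tolerance = 1e-12)
  }
})

test_that("AUC from classifier_metrics is threshold-free", {
  set.seed(4)
  s <- runif(50); y <- rbinom(50, 1, 0.5)
  if (length(unique(y)) < 2) y[1:2] <- 0:1
  aucs <- vapply(c(-1, 0.2, 0.5, 0.9, 2),
                 function(th) classifier_metrics(s, y, th)$auc, numeric(1))
  expect_true(all(abs(aucs - aucs[1]) < 1e-15))
})

test_that("summaries average metrics per split and ignore missing entries", {
  df <- data.frame(repetition = c(1, 2, 1, 2),
                   split = c("validating", "validating", "testing", "testing"),
                   auc = c(0.9, 1.0, 0.8, 0.9),
                   sen = c(0.8, 0.8, 0.7, 0.7),
                   f1 = c(0.7, NA, 0.6, 0.6),
                   spe = c(0.9, 0.9, 0.85, 0.95),
                   ppv = c(0.95, 0.95, 0.9, 0.9),
                   npv = c(0.6, 0.6, 0.5, 0.7))
  sm <- summarize_over_repetitions(df)
  v <- sm[sm$split == "validating", ]
  expect_equal(v$auc, 0.95)
  expect_equal(v$f1, 0.7)      # NA ignored
  expect_equal(v$n_used_min, 1)
  # identical repetitions collapse to themselves
  one <- summarize_over_repetitions(df[c(1, 1), ])
  expect_equal(one$auc, 0.9)
})

test_that("risk scores are invariant to nodule ordering", {
  coh <- generate_cohort(default_generator_config(n = 80), seed = 14)
  perm <- sample(80)
  coh_p <- new_cohort(coh$records[perm, ], coh$schema)
  spec <- classifier_spec("logistic")
  # same split seeds act on permuted strata, so compare via a fixed split:
  # train on everyone, score everyone (deterministic logistic fit)
  p <- train_and_score(coh, rep(TRUE, 80), spec, c("component", "age"))
  p_p <- train_and_score(coh_p, rep(TRUE, 80), spec, c("component", "age"))
  expect_equal(p_p, p[perm], tolerance = 1e-10)
})
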