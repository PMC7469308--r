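test_that("one-vs-rest pooling reproduces the published calcification table", {
  # micro-calcifications vs (macro + none): fn and tn pool the other levels
  coh <- cohort_from_counts(study_characteristic_counts("disease"))
  tab <- level_contingency(coh, "calcification", "micro")
  expect_equal(tab$tp, 711L)
  expect_equal(tab$fp, 78L)
  expect_equal(tab$fn, 489L)   # 137 + 352
  expect_equal(tab$tn, 170L)   # 30 + 140
})

test_that("binary characteristics give their natural 2x2 and row sums match outcome totals", {
  coh <- toy_cohort(n = 60, seed = 2)
  tab <- level_contingency(coh, "halo", "present")
  rec <- coh$records
  expect_equal(tab$tp, sum(rec$halo == "present" & rec$outcome == "malignant"))
  expect_equal(tab$tp + tab$fn, sum(rec$outcome == "malignant"))
  expect_equal(tab$fp + tab$tn, sum(rec$outcome == "benign"))
  # complementary level swaps the positive/negative margins
  tab2 <- level_contingency(coh, "halo", "absent")
  expect_equal(tab2$tp, tab$fn)
  expect_equal(tab2$fp, tab$tn)
})

test_that("diagnostic metrics reproduce the irregular-margin worked example", {
  met <- diagnostic_metrics(contingency_2x2(tp = 1020, fp = 74,
                                            fn = 180, tn = 174))
  expect_equal(round(100 * met$sen, 1), 85.0)
  expect_equal(round(100 * met$spe, 1), 70.2)
  expect_equal(round(100 * met$ppv, 1), 93.2)
  expect_equal(round(100 * met$npv, 1), 49.2)
  expect_equal(round(met$auc, 3), 0.776)
})

test_that("balanced tables score at chance and random tables match a recount oracle", {
  met <- diagnostic_metrics(contingency_2x2(30, 20, 30, 20))
  expect_equal(met$auc, 0.5)
  set.seed(42)
  for (k in 1:1000) {
    cnt <- sample(1:80, 4, replace = TRUE)
    met <- diagnostic_metrics(contingency_2x2(cnt[1], cnt[2], cnt[3], cnt[4]))
    ora <- recount_metrics(cnt[1], cnt[2], cnt[3], cnt[4])
    expect_equal(unclass(met)[c("sen", "spe", "ppv", "npv", "auc")], ora,
                 tolerance = 1e-12)
  }
})

test_that("metrics with empty predicted classes report NA, empty margins reject", {
  met <- diagnostic_metrics(contingency_2x2(0, 0, 10, 10))
  expect_true(is.na(met$ppv))
  expect_equal(met$sen, 0)
  expect_error(diagnostic_metrics(contingency_2x2(0, 0, 0, 5)),
               "margins")
})

test_that("Fisher exact p matches full hypergeometric enumeration", {
  # published echogenicity split is overwhelmingly significant
  expect_lt(fisher_exact(contingency_2x2(920, 117, 280, 131)), 0.001)
  expect_equal(fisher_exact(contingency_2x2(5, 5, 5, 5)), 1)
  set.seed(7)
  for (k in 1:60) {
    cnt <- sample(1:15, 4, replace = TRUE)
    expect_equal(fisher_exact(contingency_2x2(cnt[1], cnt[2], cnt[3], cnt[4])),
                 fisher_enum_p(cnt[1], cnt[2], cnt[3], cnt[4]),
                 tolerance = 1e-12)
  }
})

test_that("Fisher exact is symmetric under transposition and rejects zero margins", {
  p1 <- fisher_exact(contingency_2x2(12, 3, 7, 9))
  p2 <- fisher_exact(contingency_2x2(12, 7, 3, 9))  # rows <-> columns
  expect_equal(p1, p2, tolerance = 1e-12)
  expect_error(fisher_exact(contingency_2x2(0, 0, 5, 5)), "margins")
})

test_that("rank AUC handles separation, ties, and agrees with trapezoidal ROC integration", {
  expect_equal(rank_auc(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1)), 1.0)
  expect_equal(rank_auc(rep(2, 10), rep(0:1, 5)), 0.5)
  expect_error(rank_auc(1:5, rep(1, 5)), "both classes")
  set.seed(11)
  for (k in 1:500) {
    n <- sample(10:40, 1)
    s <- sample(seq(0, 1, by = 0.05), n, replace = TRUE)  # force ties
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    expect_equal(rank_auc(s, y), trapezoid_auc(s, y), tolerance = 1e-10)
  }
})

test_that("rank AUC of a 0/1 indicator equals (SEN+SPE)/2 from its contingency table", {
  set.seed(3)
  for (k in 1:50) {
    n <- 60
    pred <- rbinom(n, 1, 0.4)
    y <- rbinom(n, 1, 0.6)
    if (length(unique(y)) < 2) next
    tp <- sum(pred & y); fp <- sum(pred & !y)
    fn <- sum(!pred & y); tn <- sum(!pred & !y)
    met <- diagnostic_metrics(contingency_2x2(tp, fp, fn, tn))
    expect_equal(rank_auc(pred, y), met$auc, tolerance = 1e-12)
  }
})

test_that("Mann-Whitney U is consistent with rank AUC and behaves at the extremes", {
  expect_gt(mann_whitney(1:30, 1:30)$p, 0.99)
  expect_lt(mann_whitney(101:130, 1:30)$p, 0.001)
  expect_error(mann_whitney(numeric(0), 1:3), "non-empty")
  set.seed(21)
  for (k in 1:40) {
    a <- rnorm(sample(5:25, 1)); b <- rnorm(sample(5:25, 1), 0.4)
    mw <- mann_whitney(a, b)
    auc <- rank_auc(c(a, b), c(rep(1, length(a)), rep(0, length(b))))
    expect_equal(mw$u, auc * length(a) * length(b), tolerance = 1e-9)
  }
})

test_that("characteristic report covers every level once and flags references", {
  coh <- generate_cohort(default_generator_config(n = 300), seed = 6)
  rep <- characteristic_report(coh)
  sch <- categorical_specs <- Filter(function(s) s$kind == "categorical",
                                     coh$schema)
  expect_equal(nrow(rep), sum(vapply(sch, function(s) length(s$levels),
                                     integer(1))))
  expect_equal(sum(rep$reference), length(sch))
  expect_true(all(is.na(rep$auc[rep$reference])))
  expect_true(all(!is.na(rep$auc[!rep$reference])))
})
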