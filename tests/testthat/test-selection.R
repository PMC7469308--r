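# shared small random instance generator for solver checks
random_instance <- function(seed, n = 60, m = 5) {
  set.seed(seed)
  x <- matrix(rnorm(n * m), n, m,
              dimnames = list(NULL, paste0("v", seq_len(m))))
  beta <- c(1.2, -0.8, 0.5, rep(0, m - 3))
  y <- rbinom(n, 1, plogis(0.2 + drop(x %*% beta)))
  if (length(unique(y)) < 2) y[1:2] <- 0:1
  list(x = x, y = y, column_characteristic = colnames(x))
}

test_that("full shrinkage collapses to the intercept-only closed form", {
  d <- random_instance(1)
  std <- scale(d$x, scale = apply(d$x, 2, function(c)
    sqrt(mean((c - mean(c))^2))))
  lam_max <- max(abs(colMeans(std * (d$y - mean(d$y)))))
  fit <- fit_penalized_lr(d, lam_max * 1.001)
  expect_true(all(abs(fit$beta) < 1e-10))
  expect_equal(fit$beta0, qlogis(mean(d$y)), tolerance = 1e-7)
})

test_that("the unpenalized fit matches the maximum-likelihood oracle", {
  for (s in 1:5) {
    d <- random_instance(s)
    fit <- fit_penalized_lr(d, 0)
    ml <- glm(d$y ~ d$x, family = binomial())
    expect_lt(max(abs(c(fit$beta0, fit$beta) - coef(ml))), 1e-6)
  }
})

test_that("KKT residuals vanish at returned solutions across random instances", {
  worst <- 0
  for (s in 1:100) {
    d <- random_instance(s)
    lam <- runif(1, 0.001, 0.15)
    fit <- fit_penalized_lr(d, lam)
    worst <- max(worst, max(fit$kkt))
  }
  expect_lt(worst, 1e-6)
})

test_that("achieved objective is optimal against the reference convex solver", {
  skip_if_not_installed("glmnet")
  for (s in 1:5) {
    d <- random_instance(s, n = 80, m = 6)
    lam <- 0.05
    fit <- fit_penalized_lr(d, lam)
    g <- glmnet::glmnet(d$x, d$y, family = "binomial", lambda = lam,
                        standardize = TRUE, thresh = 1e-14)
    ours <- penalized_objective(d$x, d$y, fit$beta0, fit$beta, lam)
    theirs <- penalized_objective(d$x, d$y, as.numeric(g$a0),
                                  as.numeric(g$beta), lam)
    expect_gt(ours, theirs - 1e-8)
    expect_lt(max(abs(fit$beta - as.numeric(g$beta))), 1e-4)
  }
})

test_that("slope l1 norm shrinks monotonically along the penalty grid", {
  d <- random_instance(2, n = 100, m = 6)
  design <- list(x = d$x, y = d$y, column_characteristic = d$column_characteristic)
  path <- lambda_path(design, seed = 4, n_lambda = 40)
  l1 <- colSums(abs(path$beta_std))
  expect_true(all(diff(l1) >= -1e-8))  # lambdas decrease, norms grow
  expect_true(all(abs(path$beta_std[, 1]) < 1e-10))  # all-zero at lambda_max
})

test_that("lambda_1se dominates lambda_min and the CV curve is reproducible", {
  d <- random_instance(3, n = 120, m = 5)
  design <- list(x = d$x, y = d$y, column_characteristic = d$column_characteristic)
  p1 <- lambda_path(design, seed = 9)
  p2 <- lambda_path(design, seed = 9)
  expect_gte(p1$lambda_1se, p1$lambda_min)
  expect_identical(p1$cv_mean, p2$cv_mean)
  expect_true(all(p1$cv_se >= 0))
  expect_error(lambda_path(design, folds = 200, seed = 1), "folds")
})

test_that("grouped selection maps level indicators back to characteristics", {
  sch <- default_schema()
  beta <- setNames(rep(0, 4), c("calcification=micro", "calcification=macro",
                                "margin=irregular", "size"))
  mapping <- c("calcification", "calcification", "margin", "size")
  expect_identical(select_active(beta, sch, mapping), character(0))
  beta["calcification=micro"] <- 0.8
  expect_identical(select_active(beta, sch, mapping), "calcification")
  beta["size"] <- -1e-12  # below the nonzero threshold
  expect_identical(select_active(beta, sch, mapping), "calcification")
  beta["size"] <- -0.2
  expect_identical(select_active(beta, sch, mapping),
                   c("calcification", "size"))
})

test_that("repeated selection is deterministic and separates signal from noise at small scale", {
  cfg <- add_null_characteristic(default_generator_config(n = 350))
  coh <- generate_cohort(cfg, seed = 2)
  s1 <- repeated_selection(coh, R = 4, seed = 5, folds = 5, n_lambda = 40)
  s2 <- repeated_selection(coh, R = 4, seed = 5, folds = 5, n_lambda = 40)
  expect_identical(s1$frequency, s2$frequency)
  expect_true(all(s1$frequency$frequency >= 0 & s1$frequency$frequency <= 1))
  fr <- setNames(s1$frequency$frequency, s1$frequency$characteristic)
  expect_gt(fr[["component"]], fr[["speckle"]])
})
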