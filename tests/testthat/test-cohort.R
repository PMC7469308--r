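test_that("CSV round trip preserves records field by field", {
  coh <- toy_cohort(n = 25, seed = 4)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(coh, path)
  back <- read_cohort(path, toy_schema())
  expect_equal(nrow(back$records), 25)
  for (col in c("nodule_id", "grade", "halo", "outcome"))
    expect_identical(back$records[[col]], coh$records[[col]])
  expect_equal(back$records$size, coh$records$size, tolerance = 1e-12)
})

test_that("malformed cohorts are rejected naming the row and field", {
  rec <- toy_cohort(n = 5)$records
  bad <- rec; bad$grade[3] <- "Solidd"
  expect_error(new_cohort(bad, toy_schema()), "row 3.*grade.*Solidd")
  bad <- rec; bad$outcome[2] <- NA
  expect_error(new_cohort(bad, toy_schema()), "row 2")
  bad <- rec; bad$nodule_id[4] <- bad$nodule_id[1]
  expect_error(new_cohort(bad, toy_schema()), "duplicate nodule_id")
  expect_error(new_cohort(rec[, setdiff(names(rec), "outcome")],
                          toy_schema()), "outcome")
})

test_that("dummy coding maps non-reference levels to indicators and the reference to zero", {
  sch <- list(characteristic_spec("grade", "categorical", c("A", "B", "C"),
                                  reference = "A"))
  coh <- new_cohort(data.frame(grade = c("B", "A", "C"),
                               outcome = c("malignant", "benign",
                                           "malignant")), sch)
  d <- encode_design(coh, continuous = character(0))
  expect_equal(d$columns, c("grade=B", "grade=C"))
  expect_equal(unname(d$x[1, ]), c(1, 0))
  expect_equal(unname(d$x[2, ]), c(0, 0))
  expect_equal(unname(d$x[3, ]), c(0, 1))
  expect_equal(d$y, c(1L, 0L, 1L))
})

test_that("default schema encodes to one column per non-reference level plus two continuous", {
  sch <- default_schema()
  expected_m <- sum(vapply(sch, function(s)
    if (s$kind == "categorical") length(s$levels) - 1L else 1L, integer(1)))
  cfg <- default_generator_config(n = 60)
  d <- encode_design(generate_cohort(cfg, seed = 2))
  expect_equal(d$m, expected_m)
  expect_equal(d$m, 17L)  # 9 binary + 3 three-level + size + age
  # indicators of one characteristic never co-fire
  for (nm in c("calcification", "blood_flow", "vascularity")) {
    idx <- which(d$column_characteristic == nm)
    expect_true(all(rowSums(d$x[, idx, drop = FALSE]) <= 1))
  }
})

test_that("encoding then decoding recovers the original level labels", {
  coh <- toy_cohort(n = 30, seed = 8)
  d <- encode_design(coh, continuous = character(0))
  dec <- decode_design(d, toy_schema())
  expect_identical(dec$grade, coh$records$grade)
  expect_identical(dec$halo, coh$records$halo)
})

test_that("stratified split matches proportions per stratum and is seeded", {
  rec <- data.frame(outcome = rep(c("benign", "malignant"), each = 10),
                    grade = "A", halo = "absent", size = 10)
  coh <- new_cohort(rec, toy_schema())
  part <- stratified_split(coh, seed = 5)
  tab <- table(coh$records$outcome, part)
  expect_equal(unname(tab["benign", ]), c(6, 2, 2))
  expect_equal(unname(tab["malignant", ]), c(6, 2, 2))
  expect_identical(part, stratified_split(coh, seed = 5))
  expect_false(identical(part, stratified_split(coh, seed = 6)))
})

test_that("split labels cover every record and per-stratum counts are within one of target", {
  coh <- toy_cohort(n = 53, seed = 3)
  part <- stratified_split(coh, seed = 1)
  expect_equal(length(part), 53)
  expect_false(anyNA(part))
  for (cls in c("benign", "malignant")) {
    ns <- sum(coh$records$outcome == cls)
    tab <- table(part[coh$records$outcome == cls])
    expect_true(all(abs(tab - ns * c(0.6, 0.2, 0.2)) <= 1))
  }
})

test_that("train fraction averages to 0.6 per stratum over many seeds", {
  rec <- data.frame(outcome = c(rep("benign", 50), rep("malignant", 150)),
                    grade = "B", halo = "present", size = 8)
  coh <- new_cohort(rec, toy_schema())
  fr <- vapply(1:200, function(s) {
    part <- stratified_split(coh, seed = s)
    c(mean(part[coh$records$outcome == "benign"] == "train"),
      mean(part[coh$records$outcome == "malignant"] == "train"))
  }, numeric(2))
  # exact divisibility: largest-remainder gives exactly 30/90 every time
  expect_equal(mean(fr[1, ]), 0.6, tolerance = 1e-12)
  expect_equal(mean(fr[2, ]), 0.6, tolerance = 1e-12)
})

test_that("degenerate strata and bad proportions are rejected", {
  rec <- data.frame(outcome = c("benign", "benign", rep("malignant", 10)),
                    grade = "A", halo = "absent", size = 10)
  coh <- new_cohort(rec, toy_schema())
  expect_error(stratified_split(coh, seed = 1), "stratum")
  coh2 <- toy_cohort(20)
  expect_error(stratified_split(coh2, proportions = c(0.7, 0.2, 0.2),
                                seed = 1), "sum to 1")
})
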