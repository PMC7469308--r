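cohort_subset <- function(cohort, idx) {
  structure(list(schema = cohort$schema,
                 records = cohort$records[idx, , drop = FALSE]),
            class = "nodule_cohort")
}

#' Characteristics active in a penalized fit
#'
#' A categorical characteristic counts as selected when any of its level
#' indicators has a nonzero coefficient (grouped rule); a continuous one
#' when its own coefficient is nonzero.  "Nonzero" means
#' `|beta| > 1e-10`.
#'
#' @param fit A `penalized_lr_fit`, or a coefficient vector named by design
#'   columns together with `column_characteristic` via the `mapping`
#'   argument.
#' @param schema Characteristic schema (for ordering the result).
#' @param mapping Optional character vector mapping coefficients to
#'   characteristics when `fit` is a bare numeric vector.
#' @return Character vector of selected characteristic names.
#' @export
select_active <- function(fit, schema, mapping = NULL) {
  schema <- as_schema(schema)
  if (inherits(fit, "penalized_lr_fit")) {
    if (!fit$converged) stop("fit did not converge")
    beta <- fit$beta
    mapping <- fit$column_characteristic
  } else {
    beta <- fit
    if (is.null(mapping)) stop("mapping required for a bare coefficient vector")
  }
  nz <- abs(beta) > 1e-10
  hit <- unique(mapping[nz])
  intersect(schema_names(schema), hit)
}

#' Repeated split-and-select screening of characteristics
#'
#' For each of `R` repetitions: draw a fresh stratified 60/20/20 split,
#' run the cross-validated penalty path on the training portion, refit at
#' `lambda_1se`, and record which characteristics are active.  A
#' characteristic's selection frequency is its number of selections over
#' `R`; those at or above `retention_threshold` are retained.
#'
#' Repetitions whose penalty path fails are skipped with a warning and
#' still count in the denominator; more than 10\% failures aborts the run.
#'
#' @param cohort A `nodule_cohort`.
#' @param R Number of repetitions (default 100).
#' @param retention_threshold Minimum frequency to retain (default 0.5).
#' @param seed Integer master seed; each repetition derives its own.
#' @param proportions Split proportions (default 60/20/20).
#' @param folds,n_lambda,lambda_min_ratio Passed to [lambda_path()].
#' @return An object of class `selection_summary`: data.frame `frequency`
#'   (characteristic, frequency, retained), `retained` names, per-repetition
#'   log (`lambda_1se` and selected sets), `R`.
#' @export
repeated_selection <- function(cohort, R = 100, retention_threshold = 0.5,
                               seed,
                               proportions = c(train = 0.6, validate = 0.2,
                                               test = 0.2),
                               folds = 10, n_lambda = 100,
                               lambda_min_ratio = 0.01) {
  stopifnot(inherits(cohort, "nodule_cohort"))
  if (R < 2) stop("R must be at least 2")
  if (missing(seed)) stop("seed is required")
  chars <- schema_names(cohort$schema)
  counts <- setNames(numeric(length(chars)), chars)
  log <- vector("list", R)
  failures <- 0L
  for (r in seq_len(R)) {
    seed_r <- derive_seed(seed, r)
    sel <- tryCatch({
      part <- stratified_split(cohort, proportions, seed = seed_r)
      train <- cohort_subset(cohort, part == names(proportions)[1L])
      design <- encode_design(train)
      path <- lambda_path(design, folds = folds, n_lambda = n_lambda,
                          seed = derive_seed(seed_r, 1L),
                          lambda_min_ratio = lambda_min_ratio)
      beta <- path$beta[, path$index_1se]
      list(active = select_active(beta, cohort$schema,
                                  mapping = path$column_characteristic),
           lambda_1se = path$lambda_1se)
    }, error = function(e) e)
    if (inherits(sel, "error")) {
      failures <- failures + 1L
      warning("repetition ", r, " failed: ", conditionMessage(sel))
      log[[r]] <- list(repetition = r, failed = TRUE)
      next
    }
    counts[sel$active] <- counts[sel$active] + 1
    log[[r]] <- list(repetition = r, failed = FALSE,
                     lambda_1se = sel$lambda_1se, selected = sel$active)
  }
  if (failures > 0.1 * R)
    stop("more than 10% of repetitions failed (", failures, "/", R, ")")
  freq <- counts / R
  summary <- data.frame(characteristic = chars,
                        frequency = unname(freq),
                        retained = unname(freq >= retention_threshold),
                        stringsAsFactors = FALSE)
  structure(list(frequency = summary,
                 retained = summary$characteristic[summary$retained],
                 R = R, failures = failures,
                 retention_threshold = retention_threshold, seed = seed),
            class = "selection_summary")
}

#' @export
print.selection_summary <- function(x, ...) {
  cat(sprintf("<selection_summary> %d repetitions (%d failed), threshold %.2f\n",
              x$R, x$failures, x$retention_threshold))
  df <- x$frequency[order(-x$frequency$frequency), ]
  df$frequency <- sprintf("%.2f", df$frequency)
  print(df, row.names = FALSE)
  invisible(x)
}
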