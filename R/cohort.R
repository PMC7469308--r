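#' Assemble and validate a nodule cohort
#'
#' A cohort couples a characteristic schema with one record per nodule.
#' Records carry an identifier, optional patient id / sex / group, the
#' surgical outcome (`benign` or `malignant`), the continuous measurements
#' (`age` in years, `size` in mm, `er` echogenicity ratio) and one column
#' per categorical characteristic holding a level label.
#'
#' @param records A data.frame, one row per nodule.
#' @param schema List of [characteristic_spec()]; defaults to
#'   [default_schema()].
#' @return An object of class `nodule_cohort`.
#' @export
new_cohort <- function(records, schema = default_schema()) {
  schema <- as_schema(schema)
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0L) stop("cohort has no records")
  records <- as.data.frame(records, stringsAsFactors = FALSE)

  if (is.null(records$nodule_id))
    records$nodule_id <- sprintf("nod%05d", seq_len(nrow(records)))
  records$nodule_id <- as.character(records$nodule_id)
  dup <- records$nodule_id[duplicated(records$nodule_id)]
  if (length(dup))
    stop("duplicate nodule_id: ", paste(unique(dup), collapse = ", "))

  if (is.null(records$outcome))
    stop("missing outcome column")
  bad <- which(!records$outcome %in% c("benign", "malignant"))
  if (length(bad))
    stop("row ", bad[1L], ": outcome must be 'benign' or 'malignant', got '",
         records$outcome[bad[1L]], "'")

  for (s in categorical_specs(schema)) {
    col <- records[[s$name]]
    if (is.null(col))
      stop("missing characteristic column '", s$name, "'")
    col <- as.character(col)
    bad <- which(is.na(col) | !col %in% s$levels)
    if (length(bad))
      stop("row ", bad[1L], ", field '", s$name, "': unknown level '",
           col[bad[1L]], "'")
    records[[s$name]] <- col
  }
  for (nm in continuous_names(schema)) {
    col <- records[[nm]]
    if (is.null(col)) stop("missing continuous column '", nm, "'")
    col <- as.numeric(col)
    bad <- which(is.na(col))
    if (length(bad))
      stop("row ", bad[1L], ", field '", nm, "': missing or non-numeric value")
    records[[nm]] <- col
  }
  if (!is.null(records$age) && any(records$age < 0))
    stop("row ", which(records$age < 0)[1L], ", field 'age': negative value")
  if (!is.null(records$size) && any(records$size <= 0))
    stop("row ", which(records$size <= 0)[1L],
         ", field 'size': must be positive")
  if (!is.null(records$er)) {
    records$er <- as.numeric(records$er)
    if (any(is.na(records$er) | records$er <= 0))
      stop("row ", which(is.na(records$er) | records$er <= 0)[1L],
           ", field 'er': must be a positive number")
  }
  rownames(records) <- NULL
  structure(list(schema = schema, records = records),
            class = "nodule_cohort")
}

#' @export
print.nodule_cohort <- function(x, ...) {
  tab <- table(x$records$outcome)
  cat(sprintf("<nodule_cohort> %d nodules (%d benign, %d malignant), %d characteristics\n",
              nrow(x$records),
              if ("benign" %in% names(tab)) tab[["benign"]] else 0L,
              if ("malignant" %in% names(tab)) tab[["malignant"]] else 0L,
              length(x$schema)))
  invisible(x)
}

#' @export
dim.nodule_cohort <- function(x) dim(x$records)

outcome01 <- function(cohort) {
  as.integer(cohort$records$outcome == "malignant")
}

#' Read a cohort from CSV
#'
#' Expects a comma-separated file with a header row and one row per nodule;
#' level labels must match the schema.  Row order is preserved.  Unknown
#' level labels, missing outcomes or duplicate `nodule_id`s are rejected
#' with the offending row and field named.
#'
#' @param path Path to a CSV file.
#' @param schema List of [characteristic_spec()].
#' @return A `nodule_cohort`.
#' @seealso [write_cohort()]
#' @export
read_cohort <- function(path, schema = default_schema()) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  new_cohort(df, schema)
}

#' Write a cohort to CSV
#'
#' @param cohort A `nodule_cohort`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "nodule_cohort"))
  write.csv(cohort$records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Encode a cohort as a design matrix
#'
#' Dummy (treatment) coding: one 0/1 indicator per non-reference level of
#' each categorical characteristic, the reference level encoding as all
#' zeros, plus one column per requested continuous characteristic.  The
#' outcome is returned as a 0/1 vector with `1 = malignant`.
#'
#' @param cohort A `nodule_cohort`.
#' @param continuous Names of continuous characteristics to include;
#'   defaults to all continuous specs in the schema.
#' @return An object of class `design_matrix`: list with elements `x`
#'   (numeric matrix), `y` (0/1 integer vector), `columns` (labels),
#'   `column_characteristic` (characteristic each column belongs to).
#' @examples
#' sch <- list(characteristic_spec("grade", "categorical",
#'                                 c("A", "B", "C"), reference = "A"))
#' coh <- new_cohort(data.frame(grade = c("B", "A", "C"),
#'                              outcome = c("malignant", "benign", "malignant")),
#'                   sch)
#' encode_design(coh, continuous = character(0))$x
#' @export
encode_design <- function(cohort, continuous = NULL) {
  stopifnot(inherits(cohort, "nodule_cohort"))
  rec <- cohort$records
  if (nrow(rec) == 0L) stop("empty cohort")
  continuous <- continuous %||% continuous_names(cohort$schema)
  missing_cont <- setdiff(continuous, names(rec))
  if (length(missing_cont))
    stop("unknown continuous characteristic: ",
         paste(missing_cont, collapse = ", "))

  cols <- list()
  labels <- character(0)
  owner <- character(0)
  for (s in categorical_specs(cohort$schema)) {
    for (lev in setdiff(s$levels, s$reference)) {
      cols[[length(cols) + 1L]] <- as.numeric(rec[[s$name]] == lev)
      labels <- c(labels, paste0(s$name, "=", lev))
      owner <- c(owner, s$name)
    }
  }
  for (nm in continuous) {
    cols[[length(cols) + 1L]] <- as.numeric(rec[[nm]])
    labels <- c(labels, nm)
    owner <- c(owner, nm)
  }
  x <- do.call(cbind, cols)
  colnames(x) <- labels
  structure(list(x = x, y = outcome01(cohort), columns = labels,
                 column_characteristic = owner,
                 n = nrow(x), m = ncol(x)),
            class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf("<design_matrix> %d x %d (%d malignant)\n",
              x$n, x$m, sum(x$y)))
  invisible(x)
}

#' Decode indicator columns back to level labels
#'
#' Inverse of the categorical part of [encode_design()]; mainly used to
#' verify the encoding round-trips.
#'
#' @param design A `design_matrix`.
#' @param schema The schema used to encode it.
#' @return data.frame of level labels, one column per categorical spec.
#' @export
decode_design <- function(design, schema) {
  schema <- as_schema(schema)
  out <- list()
  for (s in categorical_specs(schema)) {
    idx <- which(design$column_characteristic == s$name)
    lev <- rep(s$reference, design$n)
    for (j in idx) {
      labl <- sub(paste0("^", s$name, "="), "", design$columns[j])
      lev[design$x[, j] == 1] <- labl
    }
    out[[s$name]] <- lev
  }
  as.data.frame(out, stringsAsFactors = FALSE)
}

# largest-remainder allocation of n into round(n * props) parts
largest_remainder <- function(n, props) {
  raw <- n * props
  base <- floor(raw)
  rem <- raw - base
  left <- n - sum(base)
  if (left > 0) {
    take <- order(rem, decreasing = TRUE)[seq_len(left)]
    base[take] <- base[take] + 1
  }
  as.integer(base)
}

#' Stratified train/validate/test partition
#'
#' Splits the cohort within each outcome stratum so that, per stratum, the
#' partition sizes match the requested proportions to within one record
#' (largest-remainder rounding).  Deterministic given `seed`.
#'
#' @param cohort A `nodule_cohort`.
#' @param proportions Named numeric vector summing to 1; defaults to the
#'   60/20/20 train/validate/test split.
#' @param seed Integer seed.
#' @return Factor of partition labels, one per record, levels
#'   `train`, `validate`, `test` (or the names of `proportions`).
#' @export
stratified_split <- function(cohort,
                             proportions = c(train = 0.6, validate = 0.2,
                                             test = 0.2),
                             seed) {
  stopifnot(inherits(cohort, "nodule_cohort"))
  if (is.null(names(proportions)))
    names(proportions) <- c("train", "validate", "test")[seq_along(proportions)]
  if (abs(sum(proportions) - 1) > 1e-8)
    stop("proportions must sum to 1")
  if (missing(seed)) stop("seed is required")
  y <- cohort$records$outcome
  strata <- split(seq_along(y), y)
  if (any(lengths(strata) < 3L))
    stop("outcome stratum smaller than 3 records")
  labels <- character(length(y))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  for (idx in strata) {
    counts <- largest_remainder(length(idx), proportions)
    shuffled <- sample(idx)
    labels[shuffled] <- rep(names(proportions), counts)
  }
  factor(labels, levels = names(proportions))
}

# save/restore global RNG state so seeded helpers do not clobber the caller
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
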