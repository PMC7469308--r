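#' Define an ultrasonographic characteristic
#'
#' A characteristic is either categorical (with an ordered set of levels and
#' a designated reference level) or continuous.  The reference level of a
#' categorical characteristic is, by the convention used throughout this
#' package, the level with the lowest malignancy rate; it encodes as all-zero
#' in the design matrix.
#'
#' @param name Character scalar, the characteristic's label.
#' @param kind `"categorical"` or `"continuous"`.
#' @param levels Character vector of unique level labels (categorical only).
#' @param reference One of `levels`, the reference category (categorical
#'   only; defaults to the first level).
#' @return An object of class `characteristic_spec`.
#' @examples
#' characteristic_spec("component", "categorical",
#'                     levels = c("mixed", "solid"), reference = "mixed")
#' characteristic_spec("size", "continuous")
#' @export
characteristic_spec <- function(name, kind = c("categorical", "continuous"),
                                levels = NULL, reference = NULL) {
  kind <- match.arg(kind)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (kind == "categorical") {
    if (is.null(levels) || length(levels) == 0L)
      stop("categorical characteristic '", name, "' needs non-empty levels")
    if (anyDuplicated(levels))
      stop("levels of '", name, "' must be unique")
    reference <- reference %||% levels[1L]
    if (!reference %in% levels)
      stop("reference '", reference, "' is not a level of '", name, "'")
  } else {
    if (!is.null(levels))
      stop("continuous characteristic '", name, "' must not declare levels")
    reference <- NULL
  }
  structure(list(name = name, kind = kind,
                 levels = levels, reference = reference),
            class = "characteristic_spec")
}

#' @export
print.characteristic_spec <- function(x, ...) {
  if (x$kind == "categorical") {
    lev <- ifelse(x$levels == x$reference, paste0(x$levels, "*"), x$levels)
    cat(sprintf("<characteristic> %s: %s (* = reference)\n",
                x$name, paste(lev, collapse = ", ")))
  } else {
    cat(sprintf("<characteristic> %s: continuous\n", x$name))
  }
  invisible(x)
}

#' Default ultrasonographic characteristic schema
#'
#' The twelve categorical US characteristics (shape AP/T, margin, border,
#' hackly border, component, calcification, halo, posterior echo
#' attenuation, lateral shadow, blood flow degree, vascularity,
#' echogenicity) plus the two continuous covariates (nodule size in mm,
#' patient age in years).  Reference levels are the categories with the
#' lowest malignancy rate in the reference cohort.
#'
#' @return A named list of [characteristic_spec()] objects.
#' @export
default_schema <- function() {
  cat_spec <- function(name, ref, other) {
    characteristic_spec(name, "categorical",
                        levels = c(ref, other), reference = ref)
  }
  specs <- list(
    cat_spec("shape",          "apt_lt_1",    "apt_ge_1"),
    cat_spec("margin",         "regular",     "irregular"),
    cat_spec("border",         "clear",       "unclear"),
    cat_spec("hackly_border",  "absent",      "present"),
    cat_spec("component",      "mixed",       "solid"),
    cat_spec("calcification",  "none",        c("macro", "micro")),
    cat_spec("halo",           "absent",      "present"),
    cat_spec("attenuation",    "absent",      "present"),
    cat_spec("lateral_shadow", "absent",      "present"),
    cat_spec("blood_flow",     "medium",      c("low", "high")),
    cat_spec("vascularity",    "peripheral",  c("mixed", "central")),
    cat_spec("echogenicity",   "hyperechoic", "hypoechoic"),
    characteristic_spec("size", "continuous"),
    characteristic_spec("age",  "continuous")
  )
  names(specs) <- vapply(specs, `[[`, character(1), "name")
  specs
}

schema_names <- function(schema) {
  vapply(schema, `[[`, character(1), "name")
}

categorical_specs <- function(schema) {
  Filter(function(s) s$kind == "categorical", schema)
}

continuous_names <- function(schema) {
  names(Filter(function(s) s$kind == "continuous", schema))
}

as_schema <- function(schema) {
  if (inherits(schema, "characteristic_spec")) schema <- list(schema)
  stopifnot(all(vapply(schema, inherits, logical(1), "characteristic_spec")))
  names(schema) <- schema_names(schema)
  schema
}
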