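#' Dichotomise an echogenicity ratio
#'
#' A nodule is hypoechoic when its echogenicity ratio (nodule echogenicity
#' over anterior-cervical-muscle echogenicity) is less than or equal to the
#' cutoff, hyperechoic otherwise.
#'
#' @param er Positive numeric vector of echogenicity ratios.
#' @param cutoff Cutoff value.
#' @return Character vector, `"hypoechoic"` or `"hyperechoic"`.
#' @export
dichotomize_er <- function(er, cutoff) {
  if (any(is.na(er) | er <= 0)) stop("er must be positive")
  ifelse(er <= cutoff, "hypoechoic", "hyperechoic")
}

#' Diagnostic profile of the echogenicity ratio over a cutoff grid
#'
#' For each candidate cutoff, dichotomises ER and computes the diagnostic
#' metrics of the hypoechoic indicator for malignancy, plus the malignancy
#' rate among hypoechoic and among hyperechoic nodules.  The default grid
#' is the sorted unique observed ER values clipped to `[0, 5]`; a
#' fixed-step grid can be supplied for smooth cutoff-vs-rate curves.
#'
#' @param cohort A `nodule_cohort` with an `er` column and both outcomes.
#' @param grid Optional numeric vector of cutoffs.
#' @param range Cutoff window applied to the default grid (default
#'   `c(0, 5)`).
#' @return data.frame of class `er_profile` with columns `cutoff`, `sen`,
#'   `spe`, `ppv`, `npv`, `auc`, `rate_hypo`, `rate_hyper`.
#' @export
er_profile <- function(cohort, grid = NULL, range = c(0, 5)) {
  stopifnot(inherits(cohort, "nodule_cohort"))
  er <- cohort$records$er
  if (is.null(er)) stop("cohort has no 'er' column")
  mal <- cohort$records$outcome == "malignant"
  if (all(mal) || !any(mal)) stop("cohort must contain both outcomes")
  if (is.null(grid)) {
    grid <- sort(unique(er))
    grid <- grid[grid >= range[1] & grid <= range[2]]
  } else {
    grid <- sort(unique(as.numeric(grid)))
  }
  if (length(grid) == 0L) stop("empty cutoff grid after clipping")

  rows <- lapply(grid, function(ct) {
    hypo <- er <= ct
    tab <- contingency_2x2(tp = sum(hypo & mal), fp = sum(hypo & !mal),
                           fn = sum(!hypo & mal), tn = sum(!hypo & !mal))
    met <- diagnostic_metrics(tab)
    data.frame(cutoff = ct, sen = met$sen, spe = met$spe,
               ppv = met$ppv, npv = met$npv, auc = met$auc,
               rate_hypo = if (any(hypo)) mean(mal[hypo]) else NA_real_,
               rate_hyper = if (any(!hypo)) mean(mal[!hypo]) else NA_real_)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("er_profile", "data.frame")
  out
}

#' AUC-maximising echogenicity-ratio cutoff
#'
#' Returns the profile entry with maximal AUC; ties are broken toward the
#' smallest cutoff (the more sensitive rule).
#'
#' @param profile An `er_profile`.
#' @return List with elements `cutoff` and `metrics`
#'   (a `diagnostic_metrics`).
#' @export
optimal_er_cutoff <- function(profile) {
  stopifnot(inherits(profile, "er_profile"), nrow(profile) > 0L)
  i <- which.max(profile$auc)  # which.max takes the first maximum; cutoffs
                               # are sorted increasing, so ties resolve low
  structure(list(cutoff = profile$cutoff[i],
                 metrics = structure(list(sen = profile$sen[i],
                                          spe = profile$spe[i],
                                          ppv = profile$ppv[i],
                                          npv = profile$npv[i],
                                          auc = profile$auc[i]),
                                     class = "diagnostic_metrics")),
            class = "er_cutoff")
}

#' @export
print.er_cutoff <- function(x, ...) {
  cat(sprintf("optimal ER cutoff %.3g (AUC %.3f)\n", x$cutoff, x$metrics$auc))
  invisible(x)
}
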