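#' Composite immunohistochemistry staining score
#'
#' The positivity percentage maps to a 0-4 score (0-5% -> 0, 6-25% -> 1,
#' 26-50% -> 2, 51-75% -> 3, >75% -> 4; fractional percentages are assigned
#' by value: <= 5 -> 0, (5, 25] -> 1, ...) and staining intensity to 0-3
#' (negative, weak, moderate, strong). The final score is their product,
#' ranging 0-12, with categories negative (0), weak (1-4), moderate (5-8),
#' strong (9-12), and a dichotomized \code{high} flag at final >= 4.
#'
#' @param positivity_pct percent of positive cells, in [0, 100]; vectorized.
#' @param intensity staining intensity in 0, 1, 2, 3; vectorized.
#' @return data.frame with \code{positivity_score, intensity_score, final,
#'   category, high}.
#' @export
composite_score <- function(positivity_pct, intensity) {
  if (any(is.na(positivity_pct)) ||
      any(positivity_pct < 0 | positivity_pct > 100))
    stopf("positivity_pct must lie in [0, 100]")
  if (any(is.na(intensity)) || any(!intensity %in% 0:3))
    stopf("intensity must be one of 0, 1, 2, 3")
  ps <- findInterval(positivity_pct, c(5, 25, 50, 75), left.open = TRUE)
  final <- ps * as.integer(intensity)
  category <- cut(final, breaks = c(-1, 0, 4, 8, 12),
                  labels = c("negative", "weak", "moderate", "strong"))
  data.frame(positivity_score = as.integer(ps),
             intensity_score = as.integer(intensity),
             final = as.integer(final),
             category = as.character(category),
             high = final >= 4)
}

#' Chi-square association test for a contingency table
#'
#' Pearson's chi-square with expected counts from the margins and p from
#' the upper chi-square tail at df = (r-1)(c-1). With \code{yates =
#' "auto"} (the default), the Yates continuity correction is applied
#' exactly when the table is 2x2, matching the default behaviour of the
#' standard R test.
#'
#' @param table r x c matrix of non-negative counts (r, c >= 2).
#' @param yates \code{"auto"}, \code{TRUE}, or \code{FALSE}.
#' @return object of class \code{contingency_result}: list with
#'   \code{table, statistic, df, p, correction}.
#' @export
chi_square <- function(table, yates = "auto") {
  table <- as.matrix(table)
  if (any(is.na(table)) || any(table < 0)) stopf("counts must be >= 0")
  if (nrow(table) < 2 || ncol(table) < 2) stopf("table must be at least 2x2")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stopf("zero row or column margin")
  correct <- if (identical(yates, "auto"))
    nrow(table) == 2 && ncol(table) == 2 else isTRUE(yates)
  res <- suppressWarnings(chisq.test(table, correct = correct))
  structure(list(table = table,
                 statistic = unname(res$statistic),
                 df = unname(res$parameter),
                 p = res$p.value,
                 correction = correct),
            class = "contingency_result")
}

#' @export
print.contingency_result <- function(x, ...) {
  cat(sprintf("chi-square = %.4f, df = %d, p = %.4g%s\n", x$statistic, x$df,
              x$p, if (x$correction) " (Yates-corrected)" else ""))
  invisible(x)
}

#' Published cohort contingency counts
#'
#' The printed high/low composite-score counts of the 71-sample POSTN IHC
#' cohort, per clinical covariate (rows = covariate levels, columns = IHC
#' score >= 4 / < 4). These counts serve as inputs for reproducing the
#' association tests; patients with a missing covariate are already
#' excluded, as in the source table.
#'
#' @return named list of integer matrices.
#' @export
table1_counts <- function() {
  mk <- function(v, rn) matrix(v, ncol = 2, byrow = TRUE,
                               dimnames = list(rn, c("high", "low")))
  list(
    stage = mk(c(5, 24, 10, 10, 9, 7), c("I", "II", "III")),
    nodal = mk(c(10, 10, 13, 28), c(">=N1", "N0")),
    differentiation = mk(c(16, 12, 8, 29), c("low", "well_moderate")),
    tumor_size = mk(c(10, 23, 10, 5), c("<4cm", ">=4cm")),
    scc_antigen = mk(c(3, 17, 16, 17), c("<=1.5", ">1.5")),
    age = mk(c(6, 25, 18, 16), c("<=50", ">50"))
  )
}

#' Covariate association report for an IHC cohort
#'
#' Dichotomizes each sample's composite score at final >= 4 and tests the
#' association with every clinical covariate by chi-square (Yates-corrected
#' on 2x2 tables). Rows with a missing covariate value are excluded per
#' test (listwise within covariate); covariates that are entirely missing
#' or have fewer than two observed levels are skipped with a warning.
#'
#' @param records data.frame with columns \code{positivity_pct},
#'   \code{intensity}, and one column per covariate.
#' @param covariates covariate column names to test.
#' @return named list of \code{\link{chi_square}} results, with the tested
#'   tables accessible via each result's \code{table}.
#' @export
table1_report <- function(records,
                          covariates = c("stage", "nodal", "differentiation",
                                         "tumor_size", "scc_antigen", "age")) {
  cs <- composite_score(records$positivity_pct, records$intensity)
  high <- factor(ifelse(cs$high, "high", "low"), levels = c("high", "low"))
  out <- list()
  for (cov in covariates) {
    if (!cov %in% names(records)) stopf("covariate '%s' missing", cov)
    v <- records[[cov]]
    ok <- !is.na(v)
    if (!any(ok)) { warnf("covariate '%s' entirely NA; skipped", cov); next }
    lev <- unique(v[ok])
    if (length(lev) < 2) {
      warnf("covariate '%s' has < 2 observed levels; skipped", cov)
      next
    }
    tab <- table(v[ok], high[ok])
    out[[cov]] <- chi_square(as.matrix(unclass(tab)))
  }
  out
}
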