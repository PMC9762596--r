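#' Two-sided Wald test p-value
#'
#' @param coef Estimated coefficient.
#' @param se Its standard error (> 0).
#' @return Two-sided normal-reference p-value for `z = coef / se`.
#' @export
wald_p <- function(coef, se) {
  assert_that(all(is.finite(se)) && all(se > 0), "se must be positive")
  2 * pnorm(-abs(coef / se))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate adjustment (wrapper over
#' [stats::p.adjust()] with input validation); monotone, order-preserving,
#' bounded by 1.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]` (NAs pass through).
#' @return Adjusted q-values in the input order.
#' @export
bh_adjust <- function(pvals) {
  ok <- is.na(pvals) | (pvals >= 0 & pvals <= 1)
  assert_that(all(ok), "p-values must lie in [0, 1]")
  p.adjust(pvals, method = "BH")
}

#' Screen battery results for significant clades
#'
#' Marks as significant the clades with `q < alpha`, a converged fit and a
#' non-negative fitted intercept; clades failing only the intercept condition
#' are recorded with `excluded_reason = "negative_intercept"` (count-based
#' models are bounded below by zero, so a negative predicted baseline
#' indicates a spurious fit). The intercept screen removes clades from the
#' reported significant set after the BH adjustment, not from the BH family.
#'
#' @param results A battery result data frame (see [run_age_battery()]) with
#'   columns `q`, `intercept`, `converged`, `excluded_reason`.
#' @param alpha Significance level for the adjusted p-values.
#' @return `results` with updated `significant` and `excluded_reason`
#'   columns.
#' @export
filter_significant <- function(results, alpha = 0.05) {
  assert_that(is.data.frame(results) &&
                all(c("q", "intercept", "converged") %in% colnames(results)),
              "results must contain q, intercept and converged columns")
  assert_that(alpha > 0 && alpha < 1, "alpha must be in (0, 1)")
  if (is.null(results$excluded_reason))
    results$excluded_reason <- "none"
  hit <- !is.na(results$q) & results$q < alpha
  results$significant <- hit & results$converged & results$intercept >= 0
  results$excluded_reason[hit & results$converged & results$intercept < 0] <-
    "negative_intercept"
  results$excluded_reason[!results$converged &
                            results$excluded_reason == "none"] <- "nonconverged"
  results
}

#' @rdname filter_significant
#' @return `significant_clades()`: character vector of significant clade ids.
#' @export
significant_clades <- function(results) {
  unique(results$clade_id[results$significant])
}
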