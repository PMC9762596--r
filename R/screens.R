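#' Wilcoxon rank-sum screen over a taxon table
#'
#' Per-taxon two-sided rank-sum test between two groups, on relative
#' abundances. The exact null distribution is enumerated when both groups
#' have at most 10 observations and there are no ties; otherwise the
#' tie-corrected normal approximation (with continuity correction) is used.
#' P-values are BH-adjusted across taxa.
#'
#' @param table Samples x taxa matrix (typically relative abundances).
#' @param groups Two-level grouping vector aligned with the rows of `table`.
#' @return Data frame with one row per taxon: `statistic` (rank-sum W), `p`,
#'   `q`, group medians and means.
#' @export
wilcoxon_screen <- function(table, groups) {
  groups <- as.character(groups)
  assert_that(nrow(table) == length(groups),
              "groups must align with table rows")
  lv <- sort(unique(groups))
  assert_that(length(lv) == 2, "groups must have exactly 2 non-empty levels")
  g1 <- groups == lv[1]; g2 <- groups == lv[2]
  res <- lapply(colnames(table), function(tax) {
    x <- table[g1, tax]; y <- table[g2, tax]
    exact <- length(x) <= 10 && length(y) <= 10 && !anyDuplicated(c(x, y))
    wt <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = TRUE))
    data.frame(taxon = tax, statistic = unname(wt$statistic), p = wt$p.value,
               median_1 = stats::median(x), median_2 = stats::median(y),
               mean_1 = mean(x), mean_2 = mean(y), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  names(out)[4:7] <- c(paste0("median_", lv), paste0("mean_", lv))
  out$q <- bh_adjust(out$p)
  out
}

#' Kruskal-Wallis screen across diet groups within age strata
#'
#' Per-taxon Kruskal-Wallis test (tie-corrected, via [stats::kruskal.test()])
#' of abundance across multi-level groups, run separately within each
#' stratum; BH adjustment is applied across taxa within a stratum. Strata
#' with fewer than two group levels are skipped with a message (recorded in
#' the `"skipped"` attribute).
#'
#' @param table Samples x taxa matrix (typically relative abundances).
#' @param groups Multi-level grouping vector (e.g. diet) aligned with rows.
#' @param strata Stratifying vector (e.g. age) aligned with rows.
#' @return Data frame stacking per-stratum results: `stratum`, `taxon`,
#'   `statistic` (H), `df`, `p`, `q`.
#' @export
kruskal_screen <- function(table, groups, strata) {
  groups <- as.character(groups); strata <- as.character(strata)
  assert_that(nrow(table) == length(groups) && nrow(table) == length(strata),
              "groups and strata must align with table rows")
  out <- list(); skipped <- character(0)
  for (s in unique(strata)) {
    sel <- strata == s
    g <- factor(groups[sel])
    if (nlevels(g) < 2) {
      message(sprintf("kruskal screen: skipping stratum %s (single group level)", s))
      skipped <- c(skipped, s)
      next
    }
    res <- lapply(colnames(table), function(tax) {
      kt <- kruskal.test(table[sel, tax], g)
      data.frame(stratum = s, taxon = tax, statistic = unname(kt$statistic),
                 df = unname(kt$parameter), p = kt$p.value,
                 stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, res)
    df$q <- bh_adjust(df$p)
    out[[s]] <- df
  }
  res <- if (length(out)) do.call(rbind, c(out, list(make.row.names = FALSE)))
         else data.frame(stratum = character(0), taxon = character(0),
                         statistic = numeric(0), df = numeric(0),
                         p = numeric(0), q = numeric(0))
  attr(res, "skipped") <- skipped
  res
}
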