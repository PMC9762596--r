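#' ASV count tables
#'
#' An ASV table is a samples x features matrix of non-negative integer counts
#' with unique sample row names and unique feature (ASV) column names.
#' `as_asv_table()` validates and returns such a matrix.
#'
#' @param x A numeric matrix (samples in rows, features in columns) with
#'   dimnames.
#' @return The validated integer-valued matrix.
#' @export
as_asv_table <- function(x) {
  assert_that(is.matrix(x) && is.numeric(x), "counts must be a numeric matrix")
  assert_that(!is.null(rownames(x)) && !is.null(colnames(x)),
              "counts must have sample rownames and feature colnames")
  assert_that(!anyDuplicated(rownames(x)), "duplicate sample ids")
  assert_that(!anyDuplicated(colnames(x)), "duplicate feature ids")
  assert_that(all(is.finite(x)) && all(x >= 0) && all(x == round(x)),
              "counts must be finite non-negative integers")
  storage.mode(x) <- "double"
  x
}

#' Read / write a TSV count table
#'
#' The default layout has samples in rows and features in columns with a header
#' row of feature ids and a first column of sample ids. `features_in_rows =
#' TRUE` accepts the transposed (BIOM-style) layout.
#'
#' @param path File path.
#' @param features_in_rows Logical; set `TRUE` for feature-by-sample layout.
#' @return A validated ASV count matrix (samples x features).
#' @export
read_counts_tsv <- function(path, features_in_rows = FALSE) {
  x <- as.matrix(read.table(path, header = TRUE, sep = "\t", row.names = 1,
                            check.names = FALSE))
  if (features_in_rows) x <- t(x)
  as_asv_table(x)
}

#' @rdname read_counts_tsv
#' @param table A validated ASV count matrix.
#' @export
write_counts_tsv <- function(table, path, features_in_rows = FALSE) {
  x <- if (features_in_rows) t(table) else table
  df <- data.frame(id = rownames(x), x, check.names = FALSE)
  colnames(df)[1] <- if (features_in_rows) "feature_id" else "sample_id"
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Filter features by prevalence
#'
#' Retains the features observed (count > 0) in at least `min_samples`
#' samples. The default of 5 corresponds to half an experimental unit of 10
#' animals.
#'
#' @param table ASV count matrix (samples x features).
#' @param min_samples Positive integer prevalence threshold; features present
#'   in at least this many samples are retained.
#' @return The filtered count matrix (same samples).
#' @export
prevalence_filter <- function(table, min_samples = 5) {
  table <- as_asv_table(table)
  assert_that(length(min_samples) == 1 && min_samples >= 1 &&
                min_samples == round(min_samples),
              "min_samples must be a positive integer")
  assert_that(min_samples <= nrow(table),
              sprintf("min_samples (%d) exceeds number of samples (%d)",
                      min_samples, nrow(table)))
  prev <- colSums(table > 0)
  table[, prev >= min_samples, drop = FALSE]
}

#' Rarefy samples to a common depth
#'
#' Subsamples each sample's reads without replacement to exactly `depth`
#' reads, by sequential multivariate-hypergeometric draws (one
#' [stats::rhyper()] call per feature). Samples whose total is below `depth`
#' are dropped with a warning. Reproducible for a fixed `seed`.
#'
#' @param table ASV count matrix (samples x features).
#' @param depth Positive integer target depth. Default: the minimum sample
#'   total.
#' @param seed Integer seed controlling the subsampling.
#' @return Rarefied count matrix; every row sums to `depth`.
#' @export
rarefy <- function(table, depth = NULL, seed) {
  table <- as_asv_table(table)
  totals <- rowSums(table)
  if (is.null(depth)) depth <- min(totals)
  assert_that(length(depth) == 1 && depth > 0 && depth == round(depth),
              "depth must be a positive integer")
  assert_that(!missing(seed), "seed is required for rarefaction")
  drop <- totals < depth
  if (any(drop)) {
    warning(sprintf("dropping %d sample(s) below depth %d: %s",
                    sum(drop), depth,
                    paste(rownames(table)[drop], collapse = ", ")))
    table <- table[!drop, , drop = FALSE]
    totals <- totals[!drop]
  }
  assert_that(nrow(table) > 0, "no samples at or above the requested depth")
  set.seed(as.integer(seed))
  out <- table
  for (i in seq_len(nrow(table))) {
    if (totals[i] == depth) next        # keep all reads
    out[i, ] <- rarefy_row(table[i, ], depth)
  }
  out
}

# Exact without-replacement subsample of one sample's counts: sequentially,
# feature j receives a hypergeometric draw of the remaining quota from its
# count_j reads versus the reads of the features not yet visited.
#' @noRd
rarefy_row <- function(counts, depth) {
  remaining_total <- sum(counts)
  remaining_depth <- depth
  out <- numeric(length(counts))
  for (j in seq_along(counts)) {
    if (remaining_depth == 0) break
    cj <- counts[j]
    if (cj == 0) next
    other <- remaining_total - cj
    x <- if (other == 0) remaining_depth
         else rhyper(1, cj, other, remaining_depth)
    out[j] <- x
    remaining_depth <- remaining_depth - x
    remaining_total <- other
  }
  out
}

#' Convert counts to relative abundances
#'
#' @param table ASV count matrix (samples x features); every sample total must
#'   be positive.
#' @return Matrix of per-sample proportions; rows sum to 1.
#' @export
relative_abundance <- function(table) {
  table <- as_asv_table(table)
  totals <- rowSums(table)
  zero <- totals == 0
  if (any(zero))
    stop(sprintf("zero-total sample(s): %s",
                 paste(rownames(table)[zero], collapse = ", ")), call. = FALSE)
  sweep(table, 1, totals, "/")
}
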