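#' Taxonomy tables
#'
#' A taxonomy table is a data frame with one row per ASV (row names are ASV
#' ids) and the ordered rank columns `phylum`, `class`, `order`, `family`,
#' `genus`. Unassigned ranks hold the string `"unknown"`.
#'
#' @param x A data frame with ASV row names and the five rank columns.
#' @return The validated taxonomy data frame (columns coerced to character).
#' @export
as_taxonomy <- function(x) {
  assert_that(is.data.frame(x), "taxonomy must be a data frame")
  missing_ranks <- setdiff(tax_ranks(), colnames(x))
  assert_that(length(missing_ranks) == 0,
              sprintf("taxonomy missing rank column(s): %s",
                      paste(missing_ranks, collapse = ", ")))
  assert_that(!is.null(rownames(x)) && !anyDuplicated(rownames(x)),
              "taxonomy must have unique ASV row names")
  x <- x[, tax_ranks(), drop = FALSE]
  x[] <- lapply(x, as.character)
  x[is.na(x)] <- "unknown"
  x
}

#' @rdname as_taxonomy
#' @export
tax_ranks <- function() c("phylum", "class", "order", "family", "genus")

#' Read a taxonomy TSV
#'
#' @param path TSV with ASV ids in the first column and the rank columns.
#' @return Validated taxonomy data frame.
#' @export
read_taxonomy_tsv <- function(path) {
  as_taxonomy(read.table(path, header = TRUE, sep = "\t", row.names = 1,
                         check.names = FALSE, stringsAsFactors = FALSE))
}

#' Assign placeholder genus names
#'
#' ASVs without a genus assignment receive a placeholder of the form
#' `<Family>_Genus_<ASVid>`, so that each unassigned ASV is treated as its own
#' genus in genus-level comparisons (balancing over-grouping at the family
#' level against discarding unassigned ASVs). Known genera are untouched; an
#' unknown family propagates literally into the placeholder.
#'
#' @param tax Taxonomy data frame (see [as_taxonomy()]).
#' @return Taxonomy data frame with no `"unknown"` genus entries.
#' @export
assign_placeholder_genus <- function(tax) {
  tax <- as_taxonomy(tax)
  unk <- tax$genus == "unknown"
  tax$genus[unk] <- paste0(tax$family[unk], "_Genus_", rownames(tax)[unk])
  tax
}

#' Agglomerate counts at a taxonomic rank
#'
#' Sums member-ASV counts within each distinct label at the requested rank.
#' Per-sample totals are conserved. For `rank = "genus"`, placeholder genus
#' names should be assigned first so no feature is labelled `"unknown"`.
#'
#' @param table ASV count matrix (samples x features).
#' @param tax Taxonomy data frame covering every feature of `table`.
#' @param rank One of `tax_ranks()`.
#' @return Count matrix with one column per distinct label at `rank`.
#' @export
agglomerate <- function(table, tax, rank) {
  table <- as_asv_table(table)
  tax <- as_taxonomy(tax)
  assert_that(length(rank) == 1 && rank %in% tax_ranks(),
              sprintf("unknown rank '%s'; must be one of: %s",
                      as.character(rank)[1], paste(tax_ranks(), collapse = ", ")))
  missing_tax <- setdiff(colnames(table), rownames(tax))
  assert_that(length(missing_tax) == 0,
              sprintf("features missing from taxonomy: %s",
                      paste(head(missing_tax, 10), collapse = ", ")))
  labels <- tax[colnames(table), rank]
  groups <- unique(labels)
  out <- matrix(0, nrow(table), length(groups),
                dimnames = list(rownames(table), groups))
  for (g in groups)
    out[, g] <- rowSums(table[, labels == g, drop = FALSE])
  out
}
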