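#' Sample metadata
#'
#' Per-sample covariates for the two-study, two-age, two-timepoint design:
#' `sample_id`, `host_id`, `age` (`young`/`old`), `diet` (`ZD`/`ZA`/`ZS`),
#' `study` (`ZAM1`/`ZAM2`), `timepoint` (`wk0`/`wk6`) and `il6`, the
#' LPS-induced whole-blood IL-6 concentration in pg/ml (non-negative, may be
#' missing at week 0). Validated invariants: each (host, timepoint) pair
#' occurs once, and diet, study and age are constant within a host.
#'
#' @param x Data frame with the columns above.
#' @return The validated metadata data frame, row names set to `sample_id`.
#' @export
as_sample_metadata <- function(x) {
  assert_that(is.data.frame(x), "metadata must be a data frame")
  needed <- c("sample_id", "host_id", "age", "diet", "study", "timepoint", "il6")
  miss <- setdiff(needed, colnames(x))
  assert_that(length(miss) == 0,
              sprintf("metadata missing column(s): %s", paste(miss, collapse = ", ")))
  for (col in c("sample_id", "host_id", "age", "diet", "study", "timepoint"))
    x[[col]] <- as.character(x[[col]])
  assert_that(all(x$age %in% c("young", "old")), "age must be 'young' or 'old'")
  assert_that(all(x$diet %in% c("ZD", "ZA", "ZS")), "diet must be ZD, ZA or ZS")
  assert_that(all(x$study %in% c("ZAM1", "ZAM2")), "study must be ZAM1 or ZAM2")
  assert_that(all(x$timepoint %in% c("wk0", "wk6")), "timepoint must be wk0 or wk6")
  assert_that(!anyDuplicated(x$sample_id), "duplicate sample ids")
  assert_that(!anyDuplicated(paste(x$host_id, x$timepoint)),
              "duplicate (host, timepoint) pairs")
  per_host <- unique(x[, c("host_id", "age", "diet", "study")])
  assert_that(!anyDuplicated(per_host$host_id),
              "age, diet and study must be constant within a host")
  assert_that(all(is.na(x$il6) | x$il6 >= 0), "il6 must be non-negative")
  rownames(x) <- x$sample_id
  x
}

#' Read a sample metadata TSV
#'
#' @param path TSV file with the metadata columns of [as_sample_metadata()].
#' @return Validated metadata data frame.
#' @export
read_metadata_tsv <- function(path) {
  as_sample_metadata(read.table(path, header = TRUE, sep = "\t",
                                check.names = FALSE, stringsAsFactors = FALSE))
}
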