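#' Score battery discoveries against a simulation truth table
#'
#' Sensitivity is the fraction of planted (clade, battery) pairs detected by
#' their own battery (diet effects must be found in their planted family;
#' IL-6 effects may be found in either age group, since the covariate spans
#' both). Because an effect planted on a clade also makes its sub- and
#' super-clades genuinely differential, and the design's covariates are
#' correlated, a discovery is counted as false only when the discovered
#' clade's tip set is disjoint from every planted clade's tip set; the false
#' discovery rate is false discoveries over all discoveries, pooled across
#' batteries.
#'
#' @param batteries Named list of battery result data frames (as returned by
#'   [run_age_battery()] etc.), or a single stacked data frame.
#' @param truth Truth table from [simulate_counts()].
#' @param members Named list mapping clade ids to member tip sets (from a
#'   `"clade_matrix"`).
#' @return List with `sensitivity`, `fdr`, `n_detected`, `n_planted`,
#'   `n_discoveries`, `n_false`.
#' @export
evaluate_recovery <- function(batteries, truth, members) {
  if (is.data.frame(batteries)) batteries <- list(batteries)
  res <- do.call(rbind, lapply(unname(batteries), function(b)
    b[, c("clade_id", "battery", "family", "significant")]))
  disc <- res[res$significant, , drop = FALSE]

  planted_tips <- lapply(truth$clade_id, function(id) members[[id]])
  detected <- logical(nrow(truth))
  for (k in seq_len(nrow(truth))) {
    hits <- disc$battery == truth$covariate[k] &
      disc$clade_id == truth$clade_id[k]
    if (truth$covariate[k] == "diet")
      hits <- hits & disc$family == truth$family[k]
    detected[k] <- any(hits)
  }

  all_planted <- unique(unlist(planted_tips))
  false_disc <- vapply(disc$clade_id, function(id)
    !any(members[[id]] %in% all_planted), logical(1))

  list(sensitivity = if (nrow(truth)) mean(detected) else NA_real_,
       fdr = if (nrow(disc)) mean(false_disc) else 0,
       n_detected = sum(detected), n_planted = nrow(truth),
       n_discoveries = nrow(disc), n_false = sum(false_disc))
}
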