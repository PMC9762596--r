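# Per-clade regression batteries over a clade abundance matrix.

# Fit one battery family: a NB GLM (group = NULL) or NB GLMM per clade on a
# fixed two-column design (intercept + one covariate of interest), then BH
# across the tested clades and the intercept-sign screen. Clades that are
# all-zero in the subset, or nonzero in fewer than `min_nonzero` samples, are
# reported as degenerate and not fitted (unidentifiable fits would pollute
# the FDR family).
#' @noRd
fit_clade_family <- function(abund, covariate, group = NULL, battery, family,
                             alpha = 0.05, min_nonzero = 3, nAGQ = 7) {
  stopifnot(nrow(abund) == length(covariate))
  X <- cbind(`(Intercept)` = 1, covariate = covariate)
  ids <- colnames(abund)
  m <- length(ids)
  slope <- se <- p <- q <- intercept <- theta <- sigma_b <- rep(NA_real_, m)
  converged <- boundary <- rep(FALSE, m)
  reason <- rep("none", m)
  for (j in seq_len(m)) {
    y <- abund[, j]
    nz <- sum(y > 0)
    if (nz < min_nonzero) {
      reason[j] <- "degenerate"
      next
    }
    fit <- tryCatch({
      if (is.null(group)) fit_nb_glm_core(y, X)
      else fit_nb_glmm_core(y, X, group, nAGQ = nAGQ)
    }, error = function(e) NULL)
    if (is.null(fit)) {
      reason[j] <- "degenerate"
      next
    }
    intercept[j] <- fit$coefficients[1]
    slope[j] <- fit$coefficients[2]
    se[j] <- fit$se[2]
    theta[j] <- fit$theta
    sigma_b[j] <- fit$sigma_b
    converged[j] <- fit$converged
    boundary[j] <- fit$boundary
    if (is.finite(fit$se[2]) && fit$se[2] > 0)
      p[j] <- wald_p(fit$coefficients[2], fit$se[2])
    else converged[j] <- FALSE
  }
  out <- data.frame(clade_id = ids, battery = battery, family = family,
                    n_obs = nrow(abund), n_nonzero = colSums(abund > 0),
                    slope = slope, se = se, p = p, q = q,
                    intercept = intercept, theta = theta, sigma_b = sigma_b,
                    converged = converged, boundary = boundary,
                    excluded_reason = reason, significant = FALSE,
                    stringsAsFactors = FALSE, row.names = NULL)
  tested <- out$excluded_reason != "degenerate" & !is.na(out$p)
  out$q[tested] <- bh_adjust(out$p[tested])
  filter_significant(out, alpha = alpha)
}

#' @noRd
align_meta <- function(ctu, meta) {
  meta <- as_sample_metadata(meta)
  miss <- setdiff(rownames(ctu$abundance), meta$sample_id)
  assert_that(length(miss) == 0,
              sprintf("samples missing from metadata: %s",
                      paste(head(miss, 10), collapse = ", ")))
  meta[rownames(ctu$abundance), ]
}

#' Age battery: per-clade NB GLM of abundance on age
#'
#' Fits `abundance ~ age` (young = 0, old = 1) for every clade over all week
#' 0 and week 6 samples, Wald-tests the age coefficient, BH-adjusts across
#' the tested clades, and applies the negative-intercept exclusion.
#'
#' @param ctu A `"clade_matrix"` (see [build_clade_matrix()]).
#' @param meta Sample metadata covering all `ctu` samples.
#' @param alpha BH significance level.
#' @return Data frame with one row per clade: slope, SE, Wald `p`, BH `q`,
#'   intercept, `theta`, convergence flags, `excluded_reason` and
#'   `significant`.
#' @export
run_age_battery <- function(ctu, meta, alpha = 0.05) {
  meta <- align_meta(ctu, meta)
  age01 <- as.numeric(meta$age == "old")
  fit_clade_family(ctu$abundance, age01, group = NULL,
                   battery = "age", family = "age", alpha = alpha)
}

#' Diet battery: per-clade NB GLMM of abundance on diet with host random intercept
#'
#' Four model families are fitted — \{young, old\} x \{ZAM1: ZA vs ZS, ZAM2:
#' ZA vs ZD\} — so that age and study effects are controlled by design. Each
#' family fits `abundance ~ diet + (1 | host)` per clade on that family's
#' week 0 and week 6 samples, with diet coded control (ZA) = 0 and
#' zinc-modified = 1; the host random intercept absorbs the repeated-measures
#' correlation. BH is applied within each family. Families with fewer than 2
#' hosts per arm are skipped with a message (recorded in the `"skipped"`
#' attribute).
#'
#' @inheritParams run_age_battery
#' @param nAGQ Quadrature points for the random-intercept integral.
#' @return Data frame stacking the per-family results (column `family` holds
#'   `"<age>.<study>"`).
#' @export
run_diet_battery <- function(ctu, meta, alpha = 0.05, nAGQ = 7) {
  meta <- align_meta(ctu, meta)
  arms <- c(ZAM1 = "ZS", ZAM2 = "ZD")
  out <- list(); skipped <- character(0)
  for (age in c("young", "old")) for (study in names(arms)) {
    fam <- paste(age, study, sep = ".")
    trt <- arms[[study]]
    sel <- meta$age == age & meta$study == study & meta$diet %in% c("ZA", trt)
    sub <- meta[sel, ]
    n_ctrl <- length(unique(sub$host_id[sub$diet == "ZA"]))
    n_trt <- length(unique(sub$host_id[sub$diet == trt]))
    if (n_ctrl < 2 || n_trt < 2) {
      message(sprintf("diet battery: skipping family %s (%d control / %d treated hosts)",
                      fam, n_ctrl, n_trt))
      skipped <- c(skipped, fam)
      next
    }
    diet01 <- as.numeric(sub$diet == trt)
    out[[fam]] <- fit_clade_family(ctu$abundance[sel, , drop = FALSE], diet01,
                                   group = sub$host_id, battery = "diet",
                                   family = fam, alpha = alpha, nAGQ = nAGQ)
  }
  res <- if (length(out)) do.call(rbind, c(out, list(make.row.names = FALSE)))
         else empty_battery()
  attr(res, "skipped") <- skipped
  res
}

#' IL-6 battery: per-clade NB GLM of week-6 abundance on LPS-induced IL-6
#'
#' Restricted to week 6 samples with a non-missing IL-6 measurement, one
#' model family per age group: `abundance ~ il6` with IL-6 in pg/ml. BH is
#' applied within each age group. A group with constant IL-6 is skipped.
#'
#' @inheritParams run_age_battery
#' @return Data frame stacking the per-age-group results (column `family`).
#' @export
run_il6_battery <- function(ctu, meta, alpha = 0.05) {
  meta <- align_meta(ctu, meta)
  out <- list(); skipped <- character(0)
  for (age in c("young", "old")) {
    sel <- meta$age == age & meta$timepoint == "wk6" & !is.na(meta$il6)
    if (sum(sel) < 3 || sd(meta$il6[sel]) == 0) {
      message(sprintf("il6 battery: skipping %s (constant or insufficient IL-6)", age))
      skipped <- c(skipped, age)
      next
    }
    out[[age]] <- fit_clade_family(ctu$abundance[sel, , drop = FALSE],
                                   meta$il6[sel], group = NULL,
                                   battery = "il6", family = age,
                                   alpha = alpha)
  }
  res <- if (length(out)) do.call(rbind, c(out, list(make.row.names = FALSE)))
         else empty_battery()
  attr(res, "skipped") <- skipped
  res
}

#' @noRd
empty_battery <- function() {
  data.frame(clade_id = character(0), battery = character(0),
             family = character(0), n_obs = integer(0),
             n_nonzero = integer(0), slope = numeric(0), se = numeric(0),
             p = numeric(0), q = numeric(0), intercept = numeric(0),
             theta = numeric(0), sigma_b = numeric(0),
             converged = logical(0), boundary = logical(0),
             excluded_reason = character(0), significant = logical(0),
             stringsAsFactors = FALSE)
}
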