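#' Configuration for a full cladal analysis run
#'
#' Either file paths (`tree`, `counts`, `taxonomy`, `metadata`) or a
#' [simulation_design()] must be supplied, not neither. The configuration
#' records every threshold and seed, so a run is fully reconstructible.
#'
#' @param tree,counts,taxonomy,metadata Input file paths (newick and TSVs),
#'   or `NULL` when simulating.
#' @param design Optional [simulation_design()] used instead of input files.
#' @param plant_defaults Plant the default effects when simulating.
#' @param prevalence_min Prevalence threshold (samples) for ASV filtering.
#' @param rarefy_depth Rarefaction depth; `NULL` uses the minimum retained
#'   sample total.
#' @param alpha BH significance level, in (0, 1).
#' @param batteries Character subset of `c("age", "diet", "il6")`.
#' @param screens Run the genus-level nonparametric screens.
#' @param seed Master seed for rarefaction (and simulation, when no design
#'   seed is given).
#' @param out_dir Output directory, or `NULL` to skip writing files.
#' @return A validated `"run_config"` list.
#' @export
run_config <- function(tree = NULL, counts = NULL, taxonomy = NULL,
                       metadata = NULL, design = NULL, plant_defaults = FALSE,
                       prevalence_min = 5, rarefy_depth = NULL, alpha = 0.05,
                       batteries = c("age", "diet", "il6"), screens = TRUE,
                       seed = 1, out_dir = NULL) {
  have_files <- !is.null(counts)
  assert_that(have_files || !is.null(design),
              "config requires either input paths or a simulation design")
  assert_that(is.numeric(alpha) && length(alpha) == 1 && alpha > 0 && alpha < 1,
              sprintf("alpha must lie in (0, 1), got %s", alpha))
  assert_that(all(batteries %in% c("age", "diet", "il6")),
              "batteries must be a subset of c('age', 'diet', 'il6')")
  if (have_files) {
    for (p in c(tree, counts, taxonomy, metadata))
      assert_that(file.exists(p), sprintf("input not found: %s", p))
  }
  structure(list(tree = tree, counts = counts, taxonomy = taxonomy,
                 metadata = metadata, design = design,
                 plant_defaults = plant_defaults,
                 prevalence_min = prevalence_min, rarefy_depth = rarefy_depth,
                 alpha = alpha, batteries = batteries, screens = screens,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' Read a flat YAML run configuration
#'
#' @param path YAML file whose keys are [run_config()] arguments.
#' @return A validated `"run_config"`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

#' Run the full cladal analysis pipeline
#'
#' Orchestrates: input loading (or simulation) -> prevalence filtering ->
#' tree pruning to retained ASVs (midpoint rooting if the tree is unrooted)
#' -> rarefaction -> clade matrix construction -> regression batteries (age
#' GLM, diet GLMM, IL-6 GLM) with BH-FDR and intercept screening -> genus
#' screens (Wilcoxon by age on all samples; Kruskal-Wallis across diets
#' within age strata at week 6). When `out_dir` is set, writes the clade
#' matrix and manifest, per-battery TSVs, a combined significant-clade TSV,
#' screen TSVs, the annotated newick and a YAML manifest of seeds, thresholds
#' and stage-by-stage feature counts. Identical configurations produce
#' byte-identical outputs.
#'
#' @param config A [run_config()].
#' @return An object of class `"cladal_run"`: list with the processed data,
#'   clade matrix, battery results, screen results, truth table (when
#'   simulated) and the run manifest.
#' @export
run_pipeline <- function(config) {
  assert_that(inherits(config, "run_config"), "config must be a run_config")
  manifest <- list(package_version = as.character(utils::packageVersion("cladal")),
                   seed = config$seed, alpha = config$alpha,
                   prevalence_min = config$prevalence_min)
  truth <- NULL
  if (!is.null(config$design)) {
    sim <- simulate_dataset(config$design, plant_defaults = config$plant_defaults)
    tree <- sim$tree; counts <- sim$counts
    taxonomy <- sim$taxonomy; metadata <- sim$metadata; truth <- sim$truth
    manifest$design_seed <- config$design$seed
  } else {
    tree <- read_newick(config$tree)
    counts <- read_counts_tsv(config$counts)
    taxonomy <- read_taxonomy_tsv(config$taxonomy)
    metadata <- read_metadata_tsv(config$metadata)
  }
  manifest$n_samples <- nrow(counts)
  manifest$n_asv_input <- ncol(counts)

  counts <- prevalence_filter(counts, config$prevalence_min)
  manifest$n_asv_retained <- ncol(counts)
  message(sprintf("prevalence filter (>= %d samples): %d of %d ASVs retained",
                  config$prevalence_min, manifest$n_asv_retained,
                  manifest$n_asv_input))

  keep <- intersect(tree$tip.label, colnames(counts))
  assert_that(length(keep) >= 2, "fewer than 2 retained ASVs are in the tree")
  if (length(keep) < length(tree$tip.label))
    tree <- prune_tips(tree, keep)
  if (!ape::is.rooted(tree)) tree <- midpoint_root(tree)
  counts <- counts[, tree$tip.label, drop = FALSE]

  depth <- config$rarefy_depth %||% min(rowSums(counts))
  counts <- rarefy(counts, depth, seed = derive_seed(config$seed, "rarefy"))
  manifest$rarefy_depth <- depth
  manifest$rarefy_seed <- derive_seed(config$seed, "rarefy")
  manifest$n_samples_rarefied <- nrow(counts)
  metadata <- metadata[metadata$sample_id %in% rownames(counts), ]
  message(sprintf("rarefied %d samples to depth %d",
                  nrow(counts), as.integer(depth)))

  ctu <- build_clade_matrix(tree, counts)
  manifest$n_clades <- nrow(ctu$clades)
  message(sprintf("clade matrix: %d clades", manifest$n_clades))

  batteries <- list()
  if ("age" %in% config$batteries)
    batteries$age <- run_age_battery(ctu, metadata, alpha = config$alpha)
  if ("diet" %in% config$batteries)
    batteries$diet <- run_diet_battery(ctu, metadata, alpha = config$alpha)
  if ("il6" %in% config$batteries)
    batteries$il6 <- run_il6_battery(ctu, metadata, alpha = config$alpha)
  for (b in names(batteries))
    message(sprintf("battery %s: %d significant of %d clade tests",
                    b, sum(batteries[[b]]$significant), nrow(batteries[[b]])))

  screens <- NULL
  if (isTRUE(config$screens)) {
    taxonomy <- assign_placeholder_genus(taxonomy)
    genus <- agglomerate(counts, taxonomy, "genus")
    rel <- relative_abundance(genus)
    md <- metadata[match(rownames(rel), metadata$sample_id), ]
    wk6 <- md$timepoint == "wk6"
    screens <- list(
      wilcoxon_age = wilcoxon_screen(rel, md$age),
      kruskal_diet = kruskal_screen(rel[wk6, , drop = FALSE],
                                    md$diet[wk6], md$age[wk6]))
    message(sprintf("genus screens: %d genera; %d age-significant (q < %s)",
                    ncol(rel), sum(screens$wilcoxon_age$q < config$alpha),
                    format(config$alpha)))
  }

  bundle <- structure(list(config = config, tree = tree, counts = counts,
                           taxonomy = taxonomy, metadata = metadata,
                           ctu = ctu, batteries = batteries,
                           screens = screens, truth = truth,
                           manifest = manifest),
                      class = "cladal_run")
  if (!is.null(config$out_dir)) write_bundle(bundle, config$out_dir)
  bundle
}

#' @noRd
write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(f) file.path(out_dir, f)
  write_clade_matrix_tsv(bundle$ctu, fp("clade_matrix.tsv"))
  write_clade_manifest_tsv(bundle$ctu, fp("clade_manifest.tsv"),
                           tax = bundle$taxonomy)
  write_newick(annotate_tree(bundle$ctu), fp("annotated_tree.nwk"))
  sig <- list()
  for (b in names(bundle$batteries)) {
    res <- bundle$batteries[[b]]
    write.table(res, fp(sprintf("battery_%s.tsv", b)), sep = "\t",
                quote = FALSE, row.names = FALSE)
    sig[[b]] <- res[res$significant, , drop = FALSE]
  }
  sig <- do.call(rbind, c(sig, list(make.row.names = FALSE)))
  if (!is.null(sig) && nrow(sig) > 0) {
    labels <- clade_taxonomy(bundle$ctu, bundle$taxonomy)
    sig$consensus_taxonomy <- unname(labels[sig$clade_id])
    sig$direction <- ifelse(sig$slope >= 0, "+", "-")
  }
  write.table(sig %||% empty_battery(), fp("significant_clades.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(bundle$screens)) {
    write.table(bundle$screens$wilcoxon_age, fp("screen_wilcoxon_age.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(bundle$screens$kruskal_diet, fp("screen_kruskal_diet.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  manifest <- bundle$manifest
  manifest$skipped_diet_families <-
    as.list(attr(bundle$batteries$diet, "skipped") %||% character(0))
  yaml::write_yaml(manifest, fp("manifest.yaml"))
  invisible(out_dir)
}

#' Summarize a pipeline run
#'
#' Counts per battery (tested, significant, excluded by intercept sign,
#' degenerate, non-converged), a per-family breakdown for the diet and IL-6
#' batteries, and the top clades by absolute slope with their consensus
#' taxonomy.
#'
#' @param bundle A `"cladal_run"` from [run_pipeline()].
#' @param n_top Number of top clades to list.
#' @return An object of class `"cladal_summary"` with a print method.
#' @export
summarize_run <- function(bundle, n_top = 10) {
  assert_that(inherits(bundle, "cladal_run"), "bundle must be a cladal_run")
  per_battery <- do.call(rbind, lapply(names(bundle$batteries), function(b) {
    res <- bundle$batteries[[b]]
    fams <- unique(res$family)
    rows <- lapply(fams, function(f) {
      r <- res[res$family == f, ]
      data.frame(battery = b, family = f,
                 tested = sum(r$excluded_reason != "degenerate"),
                 significant = sum(r$significant),
                 excluded_intercept = sum(r$excluded_reason == "negative_intercept"),
                 degenerate = sum(r$excluded_reason == "degenerate"),
                 nonconverged = sum(r$excluded_reason == "nonconverged"),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    skipped <- attr(res, "skipped")
    if (length(skipped))
      out <- rbind(out, data.frame(battery = b, family = paste0(skipped, " [skipped]"),
                                   tested = 0L, significant = 0L,
                                   excluded_intercept = 0L, degenerate = 0L,
                                   nonconverged = 0L, stringsAsFactors = FALSE))
    out
  }))
  all_res <- do.call(rbind, c(unname(bundle$batteries),
                              list(make.row.names = FALSE)))
  sig <- all_res[all_res$significant, , drop = FALSE]
  top <- sig[order(-abs(sig$slope)), , drop = FALSE]
  top <- head(top, n_top)
  if (nrow(top) > 0) {
    labels <- clade_taxonomy(bundle$ctu, bundle$taxonomy)
    top$consensus_taxonomy <- unname(labels[top$clade_id])
  }
  structure(list(per_battery = per_battery,
                 pooled_significant = length(unique(sig$clade_id)),
                 top = top, manifest = bundle$manifest),
            class = "cladal_summary")
}

#' @export
print.cladal_summary <- function(x, ...) {
  cat(sprintf("cladal run: %d samples, %d clades (depth %d)\n\n",
              x$manifest$n_samples_rarefied, x$manifest$n_clades,
              as.integer(x$manifest$rarefy_depth)))
  print(x$per_battery, row.names = FALSE)
  cat(sprintf("\npooled significant clades (union): %d\n", x$pooled_significant))
  if (nrow(x$top) > 0) {
    cat("\ntop clades by |slope|:\n")
    print(x$top[, c("clade_id", "battery", "family", "slope", "q",
                    "consensus_taxonomy")], row.names = FALSE, digits = 3)
  }
  invisible(x)
}
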