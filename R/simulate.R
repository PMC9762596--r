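#' Simulation design for the two-study dietary-zinc mouse experiment
#'
#' Describes the generative model the synthetic data module draws from,
#' emulating the design the analysis targets: two studies (ZAM1, zinc
#' supplementation: ZA 30 mg/kg vs ZS 300 mg/kg; ZAM2, marginal deficiency:
#' ZA vs ZD 6 mg/kg), young and old mice with `hosts_per_cell` animals per
#' age x diet x study cell (default 10, hence 80 mice in total), fecal
#' samples at weeks 0 and 6, negative-binomial counts with per-(host, tip)
#' random intercepts, lognormal library sizes around 130,000 reads, and an
#' LPS-induced whole-blood IL-6 covariate (pg/ml) that increases with age and
#' with zinc deficiency.
#'
#' @param n_tips Number of ASVs (tree tips).
#' @param hosts_per_cell Mice per age x diet x study cell.
#' @param theta NB dispersion of the counts (variance `mu + mu^2/theta`).
#' @param sigma_b SD of the per-(host, tip) lognormal random intercept.
#' @param baseline_sdlog SD of the per-ASV baseline log-abundances (natural
#'   log; 2.3 spans roughly four orders of magnitude, mimicking the dominance
#'   structure of real gut communities).
#' @param library_meanlog,library_sdlog Lognormal library-size model (reads
#'   per sample before rarefaction).
#' @param il6_baseline,il6_age,il6_deficiency,il6_sd IL-6 model: baseline,
#'   age increment (old), deficiency increment (ZD), and normal noise SD, all
#'   pg/ml; values truncated at 0, observed at week 6 only.
#' @param effects List of planted effects, each a list with `tips` (member
#'   ASV ids), `covariate` (`"age"`, `"diet"` or `"il6"`), `logfc` and, for
#'   diet effects, `scope = list(age =, study =)`. See
#'   [plant_default_effects()].
#' @param seed Master seed; every stochastic stage derives its own stream
#'   from it.
#' @return An object of class `"simulation_design"`.
#' @export
simulation_design <- function(n_tips = 361, hosts_per_cell = 10, theta = 2,
                              sigma_b = 0.5, baseline_sdlog = 2.3,
                              library_meanlog = log(130000),
                              library_sdlog = 0.3,
                              il6_baseline = 60, il6_age = 40,
                              il6_deficiency = 30, il6_sd = 20,
                              effects = list(), seed = 1) {
  assert_that(n_tips >= 2, "n_tips must be >= 2")
  assert_that(hosts_per_cell >= 1, "hosts_per_cell must be >= 1")
  assert_that(theta > 0, "theta must be > 0")
  assert_that(sigma_b >= 0 && il6_sd >= 0 && baseline_sdlog >= 0 &&
                library_sdlog >= 0, "SD parameters must be >= 0")
  structure(list(
    n_tips = n_tips, hosts_per_cell = hosts_per_cell,
    studies = list(ZAM1 = c(control = "ZA", treatment = "ZS"),
                   ZAM2 = c(control = "ZA", treatment = "ZD")),
    timepoints = c("wk0", "wk6"),
    theta = theta, sigma_b = sigma_b, baseline_sdlog = baseline_sdlog,
    library_meanlog = library_meanlog, library_sdlog = library_sdlog,
    il6_baseline = il6_baseline, il6_age = il6_age,
    il6_deficiency = il6_deficiency, il6_sd = il6_sd,
    effects = effects, seed = as.integer(seed)
  ), class = "simulation_design")
}

#' Simulate a random rooted phylogeny over ASV tips
#'
#' Random fully bifurcating rooted topology ([ape::rtree()]) with
#' exponential branch lengths; tips are labelled `ASV1..ASVn`.
#'
#' @param n_tips Number of tips (>= 2).
#' @param seed Integer seed.
#' @return A rooted `"phylo"` object.
#' @export
simulate_tree <- function(n_tips, seed) {
  assert_that(n_tips >= 2, "n_tips must be >= 2")
  set.seed(as.integer(seed))
  tree <- ape::rtree(n_tips, br = function(n) rexp(n, rate = 10))
  tree$tip.label <- paste0("ASV", seq_len(n_tips))
  tree
}

#' Simulate a taxonomy table for ASV tips
#'
#' Assigns ASVs to a nested hierarchy (4 phyla down to ~n/12 genera) in
#' contiguous blocks, with a fraction of ASVs left genus-unassigned
#' (`"unknown"`) to exercise placeholder naming.
#'
#' @param tip_labels Character vector of ASV ids.
#' @param seed Integer seed.
#' @param p_unknown_genus Fraction of ASVs with unknown genus.
#' @return A taxonomy data frame (see [as_taxonomy()]).
#' @export
simulate_taxonomy <- function(tip_labels, seed, p_unknown_genus = 0.2) {
  n <- length(tip_labels)
  set.seed(as.integer(seed))
  n_gen <- max(3, round(n / 12))
  n_fam <- max(2, round(n_gen / 3))
  n_ord <- max(2, round(n_fam / 2))
  n_cls <- max(2, round(n_ord / 2))
  n_phy <- min(4, n_cls)
  idx <- function(k) sort(sample.int(k, n, replace = TRUE))
  gen <- idx(n_gen)
  gen2fam <- sort(sample.int(n_fam, n_gen, replace = TRUE))
  fam2ord <- sort(sample.int(n_ord, n_fam, replace = TRUE))
  ord2cls <- sort(sample.int(n_cls, n_ord, replace = TRUE))
  cls2phy <- sort(sample.int(n_phy, n_cls, replace = TRUE))
  phyla <- c("Bacteroidetes", "Firmicutes", "Verrucomicrobia", "Actinobacteria")
  fam <- gen2fam[gen]; ord <- fam2ord[fam]; cls <- ord2cls[ord]
  tax <- data.frame(
    phylum = phyla[cls2phy[cls]],
    class = sprintf("Class%02d", cls),
    order = sprintf("Order%02d", ord),
    family = sprintf("Family%02d", fam),
    genus = sprintf("Genus%03d", gen),
    row.names = tip_labels, stringsAsFactors = FALSE)
  unk <- runif(n) < p_unknown_genus
  tax$genus[unk] <- "unknown"
  as_taxonomy(tax)
}

#' Simulate sample metadata
#'
#' One host per mouse with age, diet and study assignments, two samples per
#' host (weeks 0 and 6), and the week-6 IL-6 value drawn as baseline +
#' age increment + deficiency increment + normal noise, truncated at 0
#' (missing at week 0, as in the study).
#'
#' @param design A [simulation_design()].
#' @param seed Integer seed (defaults to a stream derived from the design's
#'   master seed).
#' @return A validated metadata data frame.
#' @export
simulate_metadata <- function(design, seed = derive_seed(design$seed, "meta")) {
  set.seed(as.integer(seed))
  hosts <- expand.grid(study = names(design$studies), age = c("young", "old"),
                       arm = c("control", "treatment"),
                       rep = seq_len(design$hosts_per_cell),
                       stringsAsFactors = FALSE)
  hosts$diet <- mapply(function(s, a) design$studies[[s]][[a]],
                       hosts$study, hosts$arm)
  hosts$host_id <- sprintf("M%03d", seq_len(nrow(hosts)))
  md <- do.call(rbind, lapply(design$timepoints, function(tp) {
    data.frame(sample_id = paste(hosts$host_id, tp, sep = "_"),
               host_id = hosts$host_id, age = hosts$age, diet = hosts$diet,
               study = hosts$study, timepoint = tp, il6 = NA_real_,
               stringsAsFactors = FALSE)
  }))
  wk6 <- md$timepoint == "wk6"
  mu <- design$il6_baseline + design$il6_age * (md$age[wk6] == "old") +
    design$il6_deficiency * (md$diet[wk6] == "ZD")
  md$il6[wk6] <- pmax(0, mu + rnorm(sum(wk6), 0, design$il6_sd))
  as_sample_metadata(md[order(md$host_id, md$timepoint), ])
}

#' Simulate per-ASV baseline relative abundances
#'
#' Lognormal baseline propensities, normalised to sum to 1; drawn once per
#' community so that planted-effect selection and count generation share the
#' same dominance structure.
#'
#' @param design A [simulation_design()].
#' @param tip_labels ASV ids.
#' @param seed Integer seed.
#' @return Named vector of relative propensities summing to 1.
#' @export
simulate_baselines <- function(design, tip_labels,
                               seed = derive_seed(design$seed, "baseline")) {
  set.seed(as.integer(seed))
  b <- rnorm(length(tip_labels), 0, design$baseline_sdlog)
  w <- exp(b - max(b))
  setNames(w / sum(w), tip_labels)
}

#' Plant default differential-abundance effects
#'
#' Selects clades to carry planted effects for each regression battery: by
#' default 5 clades per battery (age, diet, IL-6) with log fold change 1.5.
#' Candidate clades have 2-8 member tips and baseline relative abundance
#' inside `[min_rel_abund, max_rel_abund]`, and selected clades have pairwise
#' disjoint tip sets. The lower bound keeps planted clades comfortably above
#' the detection floor at realistic sequencing depth; the upper bound keeps
#' the total compositional footprint of the spike-ins small, so that the
#' closure-induced suppression of unplanted clades in the rarefied counts
#' stays below detectability and false-discovery evaluation remains
#' well-defined (the usual convention of differential-abundance spike-in
#' benchmarks). Diet effects are assigned round-robin to the four
#' age-by-study families; IL-6 effects are expressed per SD of the generated
#' IL-6 values.
#'
#' @param tree Rooted `"phylo"` whose clades are candidates.
#' @param baselines Baseline relative abundances (see [simulate_baselines()]).
#' @param n_per_battery Planted clades per battery.
#' @param logfc Planted log fold change.
#' @param min_rel_abund,max_rel_abund Clade baseline relative abundance
#'   window for planting.
#' @param seed Integer seed.
#' @return List of effect descriptors (fields `clade_id`, `tips`,
#'   `covariate`, `scope`, `logfc`).
#' @export
plant_default_effects <- function(tree, baselines, n_per_battery = 5,
                                  logfc = 1.5, min_rel_abund = 1e-3,
                                  max_rel_abund = 3e-3, seed = 1) {
  cs <- enumerate_clades(tree)
  sizes <- cs$clades$n_tips
  rel <- vapply(cs$members, function(m) sum(baselines[m]), numeric(1))
  # every member tip must be common enough to survive prevalence filtering,
  # or the clade's content-addressed id would change on the pruned tree
  min_member <- vapply(cs$members, function(m) min(baselines[m]), numeric(1))
  ok_shape <- sizes >= 2 & sizes <= 8 & min_member >= 2e-6
  cand <- which(ok_shape & rel >= min_rel_abund & rel <= max_rel_abund)
  # fallback pool: communities whose dominance structure leaves too few
  # mid-abundance clades borrow from just below the window (still well
  # above the detection floor, and a smaller compositional footprint)
  fallback <- which(ok_shape & rel >= min_rel_abund / 2 & rel < min_rel_abund)
  set.seed(as.integer(seed))
  shuffle <- function(x) if (length(x) <= 1) x else sample(x)
  cand <- c(shuffle(cand), shuffle(fallback))
  chosen <- integer(0); used_tips <- character(0)
  for (j in cand) {
    tips <- cs$members[[j]]
    if (!any(tips %in% used_tips)) {
      chosen <- c(chosen, j)
      used_tips <- c(used_tips, tips)
    }
    if (length(chosen) >= 3 * n_per_battery) break
  }
  assert_that(length(chosen) >= 3 * n_per_battery,
              "not enough disjoint candidate clades for the requested effects")
  fams <- expand.grid(age = c("young", "old"), study = c("ZAM1", "ZAM2"),
                      stringsAsFactors = FALSE)
  effects <- list()
  for (k in seq_len(3 * n_per_battery)) {
    j <- chosen[k]
    battery <- c("age", "diet", "il6")[ceiling(k / n_per_battery)]
    scope <- NULL
    if (battery == "diet") {
      f <- fams[((k - 1) %% nrow(fams)) + 1, ]
      scope <- list(age = f$age, study = f$study)
    }
    effects[[k]] <- list(clade_id = cs$clades$clade_id[j],
                         tips = cs$members[[j]], covariate = battery,
                         scope = scope, logfc = logfc)
  }
  effects
}

#' Simulate ASV counts with planted cladal effects
#'
#' For sample `s` of host `h` and tip `t`, the expected count is
#' `exp(log(L) + log(w_t) + lib_s + b_h + delta_ts)` where `L` is the target
#' library size, `w_t` the baseline relative propensity, `lib_s` a lognormal
#' per-sample library offset, `b_h ~ N(0, sigma_b^2)` a host random
#' intercept shared by that host's two timepoints (a host-level load effect:
#' it induces within-host correlation of the raw counts and is removed by
#' rarefaction, like the library offset), and `delta_ts` the
#' sum of planted log fold changes active for the sample's covariates
#' (applied uniformly to all member tips of a planted clade, so hierarchical
#' consistency of the clade matrix is preserved). Counts are drawn
#' `NB(mu, theta)`. Diet effects apply to treated hosts of the scoped age and
#' study at both timepoints; IL-6 effects scale with the z-scored week-6 IL-6
#' and leave week-0 samples (IL-6 unobserved) untouched.
#'
#' @param design A [simulation_design()].
#' @param tree Simulated or supplied phylogeny over the ASVs.
#' @param meta Sample metadata (see [simulate_metadata()]).
#' @param baselines Optional baseline propensities (drawn from the design's
#'   master seed when omitted).
#' @param seed Integer seed for the count noise.
#' @return List with `counts` (samples x tips ASV table) and `truth` (data
#'   frame of planted effects: `clade_id`, `covariate`, `family`, `logfc`).
#' @export
simulate_counts <- function(design, tree, meta, baselines = NULL,
                            seed = derive_seed(design$seed, "counts")) {
  tips <- tree$tip.label
  if (is.null(baselines)) baselines <- simulate_baselines(design, tips)
  assert_that(all(names(baselines) == tips), "baselines must align with tips")
  for (ef in design$effects) {
    bad <- setdiff(ef$tips, tips)
    assert_that(length(bad) == 0,
                sprintf("planted effect references unknown tips: %s",
                        paste(bad, collapse = ", ")))
  }
  set.seed(as.integer(seed))
  n_s <- nrow(meta); n_t <- length(tips)
  hosts <- unique(meta$host_id)

  lib <- rnorm(n_s, 0, design$library_sdlog)
  b_host <- setNames(rnorm(length(hosts), 0, design$sigma_b), hosts)

  delta <- matrix(0, n_s, n_t, dimnames = list(meta$sample_id, tips))
  wk6 <- meta$timepoint == "wk6" & !is.na(meta$il6)
  il6_z <- rep(0, n_s)
  if (any(wk6) && sd(meta$il6[wk6]) > 0)
    il6_z[wk6] <- (meta$il6[wk6] - mean(meta$il6[wk6])) / sd(meta$il6[wk6])
  truth <- list()
  for (ef in design$effects) {
    active <- switch(ef$covariate,
      age = meta$age == "old",
      diet = {
        trt <- design$studies[[ef$scope$study]][["treatment"]]
        meta$age == ef$scope$age & meta$study == ef$scope$study &
          meta$diet == trt
      },
      il6 = wk6,
      stop(sprintf("unknown planted covariate '%s'", ef$covariate)))
    # continuous covariate: logfc is the change realized across +/- 1 SD of
    # IL-6, so the per-sample shift is logfc * z / 2 (bounded footprint)
    amount <- if (ef$covariate == "il6") ef$logfc * il6_z[active] / 2
              else ef$logfc
    delta[active, ef$tips] <- delta[active, ef$tips] + amount
    truth[[length(truth) + 1]] <- data.frame(
      clade_id = ef$clade_id %||% NA_character_, covariate = ef$covariate,
      family = if (is.null(ef$scope)) NA_character_
               else paste(ef$scope$age, ef$scope$study, sep = "."),
      logfc = ef$logfc, n_tips = length(ef$tips), stringsAsFactors = FALSE)
  }
  truth <- if (length(truth)) do.call(rbind, truth)
           else data.frame(clade_id = character(0), covariate = character(0),
                           family = character(0), logfc = numeric(0),
                           n_tips = integer(0))

  logmu <- design$library_meanlog + rep(log(baselines), each = n_s) +
    lib + b_host[meta$host_id] + delta
  counts <- matrix(rnbinom(n_s * n_t, mu = exp(logmu), size = design$theta),
                   n_s, n_t, dimnames = list(meta$sample_id, tips))
  list(counts = as_asv_table(counts), truth = truth)
}

#' Simulate a complete dataset
#'
#' Draws tree, taxonomy, metadata, baselines, (optionally) default planted
#' effects and counts, all from streams derived from the design's master
#' seed, so the whole dataset is reproducible bit-for-bit.
#'
#' @param design A [simulation_design()].
#' @param plant_defaults If `TRUE` and the design carries no effects, plant
#'   the default 5-clades-per-battery log-FC-1.5 effects.
#' @return List with `design`, `tree`, `taxonomy`, `metadata`, `baselines`,
#'   `counts` and `truth`.
#' @export
simulate_dataset <- function(design, plant_defaults = FALSE) {
  tree <- simulate_tree(design$n_tips, derive_seed(design$seed, "tree"))
  taxonomy <- simulate_taxonomy(tree$tip.label, derive_seed(design$seed, "tax"))
  metadata <- simulate_metadata(design)
  baselines <- simulate_baselines(design, tree$tip.label)
  if (plant_defaults && length(design$effects) == 0)
    design$effects <- plant_default_effects(
      tree, baselines, seed = derive_seed(design$seed, "effects"))
  sim <- simulate_counts(design, tree, metadata, baselines)
  list(design = design, tree = tree, taxonomy = taxonomy, metadata = metadata,
       baselines = baselines, counts = sim$counts, truth = sim$truth)
}
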