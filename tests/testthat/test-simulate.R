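test_that("simulated trees are bifurcating, labelled and reproducible", {
  tr <- simulate_tree(2, seed = 1)
  expect_equal(tr$Nnode, 1)
  expect_setequal(tr$tip.label, c("ASV1", "ASV2"))

  big <- simulate_tree(361, seed = 2)
  expect_equal(big$Nnode, 360)
  expect_true(ape::is.rooted(big) && ape::is.binary(big))
  expect_true(all(big$edge.length >= 0))

  expect_identical(ape::write.tree(simulate_tree(50, seed = 3)),
                   ape::write.tree(simulate_tree(50, seed = 3)))
  expect_false(identical(ape::write.tree(simulate_tree(50, seed = 3)),
                         ape::write.tree(simulate_tree(50, seed = 4))))
  expect_error(simulate_tree(1, seed = 1), "n_tips")
})

test_that("simulated metadata matches the two-study design", {
  des <- simulation_design(seed = 5)
  md <- simulate_metadata(des)
  expect_equal(length(unique(md$host_id)), 80)
  expect_equal(nrow(md), 160)
  expect_equal(as.integer(table(md$study)), c(80L, 80L))
  expect_true(all(table(md$host_id) == 2))
  expect_true(all(is.na(md$il6[md$timepoint == "wk0"])))
  expect_true(all(!is.na(md$il6[md$timepoint == "wk6"])))
  # ZS appears only in ZAM1, ZD only in ZAM2
  expect_false(any(md$diet == "ZD" & md$study == "ZAM1"))
  expect_false(any(md$diet == "ZS" & md$study == "ZAM2"))

  # zero-noise, zero-increment design: IL-6 equals the baseline
  des0 <- simulation_design(il6_age = 0, il6_deficiency = 0, il6_sd = 0, seed = 6)
  md0 <- simulate_metadata(des0)
  expect_true(all(md0$il6[md0$timepoint == "wk6"] == des0$il6_baseline))
})

test_that("IL-6 increases with age and zinc deficiency in expectation", {
  deltas <- vapply(1:50, function(s) {
    md <- simulate_metadata(simulation_design(seed = s))
    wk6 <- md[md$timepoint == "wk6" & md$age == "old", ]
    mean(wk6$il6[wk6$diet == "ZD"]) - mean(wk6$il6[wk6$diet == "ZA"])
  }, numeric(1))
  expect_gt(mean(deltas), 0)
  expect_gt(mean(deltas), 30 - 3 * sd(deltas) / sqrt(50))
})

test_that("planted effects shift clade means by the requested fold change", {
  des <- simulation_design(n_tips = 31, sigma_b = 0, library_sdlog = 0,
                           library_meanlog = log(20000), seed = 7)
  tree <- simulate_tree(des$n_tips, seed = 8)
  md <- simulate_metadata(des)
  w <- simulate_baselines(des, tree$tip.label)
  cs <- enumerate_clades(tree)
  target <- cs$clades$clade_id[which(cs$clades$n_tips == 3)[1]]
  tips <- cs$members[[target]]

  des$effects <- list(list(clade_id = target, tips = tips,
                           covariate = "age", logfc = 1.0))
  ratios <- null_ratios <- numeric(200)
  null_clade <- setdiff(tree$tip.label, tips)[1:3]
  for (s in 1:200) {
    sim <- simulate_counts(des, tree, md, baselines = w, seed = 1000 + s)
    clade <- rowSums(sim$counts[, tips])
    old <- md$age == "old"
    ratios[s] <- mean(clade[old]) / mean(clade[!old])
    nc <- rowSums(sim$counts[, null_clade])
    null_ratios[s] <- mean(nc[old]) / mean(nc[!old])
  }
  expect_lt(abs(mean(ratios) - exp(1)) / exp(1), 0.1)
  expect_lt(abs(mean(null_ratios) - 1), 3 * sd(null_ratios) / sqrt(200) + 0.02)
  expect_equal(sim$truth$clade_id, target)
  des_bad <- des
  des_bad$effects <- list(list(tips = "nope", covariate = "age", logfc = 1))
  expect_error(simulate_counts(des_bad, tree, md, baselines = w),
               "unknown tips")
})

test_that("host random intercepts induce within-host correlation of raw counts", {
  des <- simulation_design(n_tips = 40, sigma_b = 1.0, library_sdlog = 0,
                           library_meanlog = log(20000), seed = 9)
  tree <- simulate_tree(des$n_tips, seed = 10)
  md <- simulate_metadata(des)
  within_r <- between_r <- numeric(20)
  for (s in 1:20) {
    sim <- simulate_counts(des, tree, md, seed = 2000 + s)
    tot <- log1p(rowSums(sim$counts))
    wk0 <- md$timepoint == "wk0"; wk6 <- md$timepoint == "wk6"
    h0 <- md$host_id[wk0]
    t0 <- tot[wk0][order(h0)]
    t6 <- tot[wk6][order(md$host_id[wk6])]
    within_r[s] <- cor(t0, t6)
    between_r[s] <- cor(t0, sample(t6))
  }
  expect_gt(mean(within_r), mean(between_r) + 0.3)
})

test_that("whole datasets are reproducible bit-for-bit from the master seed", {
  des <- simulation_design(n_tips = 30, seed = 11)
  a <- simulate_dataset(des, plant_defaults = FALSE)
  b <- simulate_dataset(des, plant_defaults = FALSE)
  expect_identical(a$counts, b$counts)
  expect_identical(a$metadata, b$metadata)
  expect_identical(ape::write.tree(a$tree), ape::write.tree(b$tree))
  expect_identical(a$taxonomy, b$taxonomy)
})

test_that("default planted effects are disjoint, in-window and per battery", {
  des <- simulation_design(seed = 12)
  tree <- simulate_tree(des$n_tips, seed = 13)
  w <- simulate_baselines(des, tree$tip.label)
  eff <- plant_default_effects(tree, w, seed = 14)
  expect_length(eff, 15)
  expect_equal(as.integer(table(vapply(eff, `[[`, character(1), "covariate"))),
               c(5L, 5L, 5L))
  tips <- unlist(lapply(eff, `[[`, "tips"))
  expect_false(anyDuplicated(tips) > 0)
  rel <- vapply(eff, function(e) sum(w[e$tips]), numeric(1))
  expect_true(all(rel >= 5e-4 & rel <= 3e-3))
  expect_true(mean(rel >= 1e-3) >= 0.5)   # fallback pool is the exception
  fams <- vapply(eff, function(e)
    if (is.null(e$scope)) NA_character_
    else paste(e$scope$age, e$scope$study, sep = "."), character(1))
  expect_setequal(stats::na.omit(fams),
                  c("young.ZAM1", "old.ZAM1", "young.ZAM2", "old.ZAM2"))
})
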