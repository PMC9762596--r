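test_that("prevalence filter keeps features seen in at least min_samples samples", {
  set.seed(1)
  counts <- matrix(0, 20, 3,
                   dimnames = list(paste0("S", 1:20), c("keep5", "drop4", "rare")))
  counts[1:5, "keep5"] <- 7
  counts[1:4, "drop4"] <- 7
  counts[1, "rare"] <- 1
  out <- prevalence_filter(counts, 5)
  expect_identical(colnames(out), "keep5")
  expect_identical(rownames(out), rownames(counts))

  # threshold 1 removes only all-zero features
  counts2 <- cbind(counts, zero = 0)
  expect_setequal(colnames(prevalence_filter(counts2, 1)),
                  c("keep5", "drop4", "rare"))
  # idempotence
  expect_identical(prevalence_filter(out, 5), out)
  expect_error(prevalence_filter(counts, 21), "exceeds")
})

test_that("rarefaction subsamples without replacement to the exact depth", {
  set.seed(2)
  counts <- random_table(6, paste0("ASV", 1:8), lambda = 30, p_zero = 0.2)
  counts["S1", ] <- 0; counts["S1", 1] <- 10   # below-depth sample
  depth <- 40
  expect_warning(r <- rarefy(counts, depth, seed = 9), "dropping 1 sample")
  expect_true(all(rowSums(r) == depth))
  expect_true(all(r <= counts[rownames(r), ]))          # without replacement
  expect_true(all(r[, colSums(counts[rownames(r), ]) == 0] == 0))
  # a sample whose total equals the depth is returned unchanged
  tot <- rowSums(counts)[2]
  r2 <- suppressWarnings(rarefy(counts, tot, seed = 9))
  expect_identical(r2["S2", ], counts["S2", ])
  # determinism
  expect_identical(suppressWarnings(rarefy(counts, depth, seed = 9)), r)
  expect_error(rarefy(counts, 0, seed = 1), "positive")
})

test_that("rarefaction matches the hypergeometric expectation", {
  counts <- matrix(c(60, 40), 1, 2, dimnames = list("S1", c("a", "b")))
  draws <- vapply(1:1000, function(s) rarefy(counts, 50, seed = s)[1, "a"],
                  numeric(1))
  # mean of a ~ Hypergeom(N = 100, K = 60, n = 50): mean 30, var 6.0606
  se <- sqrt(50 * 0.6 * 0.4 * 50 / 99 / 1000)
  expect_lt(abs(mean(draws) - 30), 3 * se)
  # and distributionally agrees with the vegan reference implementation
  ref <- vapply(1:1000, function(s) {
    set.seed(s + 2000)
    suppressWarnings(vegan::rrarefy(counts, 50)[1, "a"])
  }, numeric(1))
  expect_lt(abs(mean(draws) - mean(ref)), 4 * sqrt(2) * se)
  expect_lt(abs(sd(draws) - sd(ref)) / sd(ref), 0.2)
})

test_that("placeholder genus naming gives each unassigned ASV its own genus", {
  tax <- data.frame(
    phylum = "Firmicutes", class = "Clostridia", order = "Clostridiales",
    family = c("Lachnospiraceae", "Bacteroidaceae", "Lachnospiraceae"),
    genus = c("unknown", "Bacteroides", "unknown"),
    row.names = c("ASV17", "ASV2", "ASV30"))
  out <- assign_placeholder_genus(tax)
  expect_identical(out["ASV17", "genus"], "Lachnospiraceae_Genus_ASV17")
  expect_identical(out["ASV2", "genus"], "Bacteroides")
  expect_identical(out["ASV30", "genus"], "Lachnospiraceae_Genus_ASV30")
  expect_false(any(out$genus == "unknown"))
  expect_equal(length(unique(out$genus)), 3)
})

test_that("agglomeration sums member counts and conserves sample totals", {
  counts <- matrix(c(2, 3, 5, 1, 0, 4), 1, 6,
                   dimnames = list("S1", paste0("ASV", 1:6)))
  tax <- data.frame(
    phylum = "Bacteroidetes", class = "c", order = "o", family = "f",
    genus = rep(c("Bacteroides", "Prevotella"), each = 3),
    row.names = paste0("ASV", 1:6))
  g <- agglomerate(counts, tax, "genus")
  expect_equal(g[1, "Bacteroides"], 2 + 3 + 5)
  expect_equal(g[1, "Prevotella"], 5)
  p <- agglomerate(counts, tax, "phylum")
  expect_equal(unname(p[1, 1]), sum(counts))

  set.seed(3)
  counts2 <- random_table(5, paste0("ASV", 1:8))
  tax2 <- simulate_taxonomy(paste0("ASV", 1:8), seed = 4)
  for (rank in tax_ranks())
    expect_equal(rowSums(agglomerate(counts2, tax2, rank)), rowSums(counts2))
  expect_error(agglomerate(counts2, tax2, "kingdom"), "unknown rank")
})

test_that("relative abundances are row-normalised proportions", {
  counts <- matrix(c(1, 1, 10, 0), 2, 2, byrow = TRUE,
                   dimnames = list(c("S1", "S2"), c("a", "b")))
  rel <- relative_abundance(counts)
  expect_equal(rel["S1", ], c(a = 0.5, b = 0.5))
  expect_equal(rel["S2", ], c(a = 1, b = 0))
  set.seed(5)
  r <- random_table(10, paste0("f", 1:7), p_zero = 0.2) + 1
  expect_equal(unname(rowSums(relative_abundance(r))), rep(1, 10),
               tolerance = 1e-12)
  bad <- counts; bad["S2", ] <- 0
  expect_error(relative_abundance(bad), "S2")
})
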