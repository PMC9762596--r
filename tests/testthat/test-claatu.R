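test_that("clade enumeration yields one clade per internal node", {
  tr <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  cs <- enumerate_clades(tr)
  expect_equal(nrow(cs$clades), 3)
  sets <- lapply(cs$members, identity)
  expect_true(any(vapply(sets, identical, logical(1), c("a", "b"))))
  expect_true(any(vapply(sets, identical, logical(1), c("c", "d"))))
  expect_true(any(vapply(sets, identical, logical(1), c("a", "b", "c", "d"))))
  # preorder: root clade first
  expect_identical(cs$members[[1]], c("a", "b", "c", "d"))

  star <- ape::read.tree(text = "(a:1,b:1,c:1,d:1,e:1);")
  expect_equal(nrow(enumerate_clades(star)$clades), 1)

  big <- simulate_tree(361, seed = 1)
  expect_equal(nrow(enumerate_clades(big)$clades), 360)

  unrooted <- ape::unroot(ape::rtree(6))
  expect_error(enumerate_clades(unrooted), "unrooted")
})

test_that("clade ids are stable content hashes of the member sets", {
  tr <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  tr2 <- ape::read.tree(text = "((d:2,c:1):1,(b:1,a:3):2);")  # reordered file
  expect_setequal(enumerate_clades(tr)$clades$clade_id,
                  enumerate_clades(tr2)$clades$clade_id)
})

test_that("clade abundances are descendant-tip sums with hierarchical consistency", {
  tr <- ape::read.tree(text = "(a:1,b:1);")
  counts <- matrix(c(2, 3), 1, 2, dimnames = list("S1", c("a", "b")))
  cm <- build_clade_matrix(tr, counts)
  expect_equal(unname(cm$abundance[1, 1]), 5)

  # all-zero sample stays zero
  counts0 <- rbind(counts, S2 = c(0, 0))
  cm0 <- build_clade_matrix(tr, counts0)
  expect_equal(unname(cm0$abundance["S2", ]), 0)

  set.seed(8)
  for (i in 1:20) {
    n <- sample(4:50, 1)
    tr <- ape::rtree(n)
    counts <- random_table(sample(2:20, 1), tr$tip.label)
    cm <- build_clade_matrix(tr, counts)
    # brute-force subset-sum oracle via independent ancestor walk
    oracle <- oracle_clade_members(tr)
    ntip <- length(tr$tip.label)
    for (k in seq_len(nrow(cm$clades))) {
      node <- cm$clades$node[k]
      tipset <- oracle[[node - ntip]]
      expect_identical(unname(cm$abundance[, k]),
                       unname(rowSums(counts[, tipset, drop = FALSE])))
    }
    # parent equals sum of children, root equals sample totals
    expect_equal(unname(cm$abundance[, 1]), unname(rowSums(counts)))
    for (k in seq_len(nrow(cm$clades))) {
      node <- cm$clades$node[k]
      kids <- tr$edge[tr$edge[, 1] == node, 2]
      kid_vals <- vapply(kids, function(ch) {
        if (ch <= ntip) counts[, tr$tip.label[ch]]
        else cm$abundance[, cm$clades$clade_id[match(ch, cm$clades$node)]]
      }, numeric(nrow(counts)))
      expect_equal(unname(cm$abundance[, k]), unname(rowSums(kid_vals)))
    }
  }
})

test_that("sample permutation permutes clade matrix rows identically", {
  set.seed(9)
  tr <- ape::rtree(10)
  counts <- random_table(6, tr$tip.label)
  cm <- build_clade_matrix(tr, counts)
  perm <- sample(nrow(counts))
  cm_p <- build_clade_matrix(tr, counts[perm, ])
  expect_identical(cm_p$abundance, cm$abundance[perm, ])
})

test_that("tip/feature mismatches are reported", {
  tr <- ape::rtree(5)
  counts <- random_table(3, tr$tip.label[1:4])
  expect_error(build_clade_matrix(tr, counts), tr$tip.label[5])
  counts2 <- random_table(3, c(tr$tip.label, "extraASV"))
  expect_message(build_clade_matrix(tr, counts2), "ignoring 1 feature")
})

test_that("consensus taxonomy reports the deepest shared rank", {
  tax <- data.frame(
    phylum = c("Bacteroidetes", "Bacteroidetes", "Firmicutes"),
    class = c("Bacteroidia", "Bacteroidia", "Clostridia"),
    order = c("Bacteroidales", "Bacteroidales", "Clostridiales"),
    family = c("Bacteroidaceae", "Bacteroidaceae", "Lachnospiraceae"),
    genus = c("Bacteroides", "Parabacteroides", "Acetatifactor"),
    row.names = c("t1", "t2", "t3"))
  expect_identical(clade_consensus_taxonomy(c("t1"), tax), "genus:Bacteroides")
  expect_identical(clade_consensus_taxonomy(c("t1", "t2"), tax),
                   "family:Bacteroidaceae")
  expect_identical(clade_consensus_taxonomy(c("t1", "t3"), tax), "mixed")
  tax2 <- tax; tax2$genus <- "unknown"
  expect_identical(clade_consensus_taxonomy(c("t1", "t2"), tax2),
                   "family:Bacteroidaceae")
})
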