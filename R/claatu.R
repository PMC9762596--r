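#' Enumerate the monophyletic clades of a rooted tree
#'
#' Every internal node (root included, tips excluded) defines one clade whose
#' members are its descendant tips; a fully bifurcating rooted tree with n
#' tips therefore yields n - 1 clades. Polytomies contribute a single clade
#' each. Clades are returned in deterministic preorder (root first) and carry
#' content-addressed ids — a hash of the sorted member tip labels — so that
#' the same clade gets the same id across reruns and tree file orderings.
#'
#' @param tree A rooted `"phylo"` object whose tips are ASV ids.
#' @return An object of class `"clade_set"`: a list with `clades` (data frame
#'   with `clade_id`, `node`, `n_tips`), `members` (named list of tip-label
#'   vectors) and `tree`.
#' @export
enumerate_clades <- function(tree) {
  assert_that(inherits(tree, "phylo"), "tree must be a 'phylo' object")
  # a star tree (single internal node) is a valid rooted tree with one clade,
  # even though its root is polytomous; any other basal polytomy is treated
  # as an unrooted tree
  if (!ape::is.rooted(tree) && tree$Nnode > 1)
    stop("tree is unrooted; root it first (e.g. midpoint_root())", call. = FALSE)
  ntip <- length(tree$tip.label)
  root <- ntip + 1L

  post <- ape::reorder.phylo(tree, "postorder")
  members <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) members[[i]] <- tree$tip.label[i]
  for (r in seq_len(nrow(post$edge))) {
    p <- post$edge[r, 1]; ch <- post$edge[r, 2]
    members[[p]] <- c(members[[p]], members[[ch]])
  }

  clade <- ape::reorder.phylo(tree, "cladewise")
  preorder_nodes <- unique(c(root, clade$edge[, 2]))
  internal <- preorder_nodes[preorder_nodes > ntip]

  member_sets <- lapply(members[internal], sort)
  ids <- vapply(member_sets,
                function(m) paste0("ctu_", content_hash(m)), character(1))
  if (anyDuplicated(ids))   # distinct member sets colliding in the hash
    ids[duplicated(ids)] <- paste0(ids[duplicated(ids)], "b")
  names(member_sets) <- ids

  structure(list(
    clades = data.frame(clade_id = ids, node = internal,
                        n_tips = lengths(member_sets),
                        stringsAsFactors = FALSE),
    members = member_sets,
    tree = tree
  ), class = "clade_set")
}

#' @export
print.clade_set <- function(x, ...) {
  cat(sprintf("clade_set: %d clades over %d tips\n",
              nrow(x$clades), length(x$tree$tip.label)))
  invisible(x)
}

#' Build the clade-by-sample abundance matrix
#'
#' Performs the root-to-tip agglomeration: for each monophyletic clade the
#' counts of all descendant tips are summed, giving a matrix `ctu` in which
#' entry `ctu[i, j]` is the abundance of clade `j` in sample `i`. The root
#' clade equals each sample's total and every parent clade equals the sum of
#' its children (hierarchical consistency).
#'
#' @param tree A rooted `"phylo"` object; every tip must appear in `table`.
#'   Table features absent from the tree are reported and ignored.
#' @param table ASV count matrix (samples x features).
#' @return An object of class `"clade_matrix"`: list with `abundance`
#'   (samples x clades matrix), `clades`, `members` and `tree` (see
#'   [enumerate_clades()]).
#' @export
build_clade_matrix <- function(tree, table) {
  table <- as_asv_table(table)
  cs <- enumerate_clades(tree)
  tips <- tree$tip.label
  missing_tips <- setdiff(tips, colnames(table))
  if (length(missing_tips) > 0)
    stop(sprintf("tree tips absent from count table: %s",
                 paste(head(missing_tips, 10), collapse = ", ")), call. = FALSE)
  extra <- setdiff(colnames(table), tips)
  if (length(extra) > 0)
    message(sprintf("ignoring %d feature(s) absent from the tree", length(extra)))

  indicator <- matrix(0, length(tips), nrow(cs$clades),
                      dimnames = list(tips, cs$clades$clade_id))
  for (id in cs$clades$clade_id) indicator[cs$members[[id]], id] <- 1
  abundance <- table[, tips, drop = FALSE] %*% indicator

  structure(list(abundance = abundance, clades = cs$clades,
                 members = cs$members, tree = tree),
            class = "clade_matrix")
}

#' @export
print.clade_matrix <- function(x, ...) {
  cat(sprintf("clade_matrix: %d samples x %d clades\n",
              nrow(x$abundance), ncol(x$abundance)))
  invisible(x)
}

#' Consensus taxonomy label of a clade
#'
#' Reports the deepest rank (walking genus, family, order, class, phylum) at
#' which all member ASVs share a single known value, as `"<rank>:<value>"`;
#' ranks where the shared value is `"unknown"` are skipped. If no rank is
#' shared the label is `"mixed"`.
#'
#' @param members Character vector of member ASV ids.
#' @param tax Taxonomy data frame covering all members (see [as_taxonomy()]).
#' @return A single label string.
#' @export
clade_consensus_taxonomy <- function(members, tax) {
  tax <- as_taxonomy(tax)
  miss <- setdiff(members, rownames(tax))
  assert_that(length(miss) == 0,
              sprintf("members missing from taxonomy: %s",
                      paste(miss, collapse = ", ")))
  for (rank in rev(tax_ranks())) {
    vals <- unique(tax[members, rank])
    if (length(vals) == 1 && vals != "unknown")
      return(paste0(rank, ":", vals))
  }
  "mixed"
}

#' Consensus taxonomy for every clade of a clade matrix
#'
#' @param cm A `"clade_matrix"` or `"clade_set"` object.
#' @param tax Taxonomy data frame.
#' @return Named character vector of labels, one per clade.
#' @export
clade_taxonomy <- function(cm, tax) {
  vapply(cm$members, clade_consensus_taxonomy, character(1), tax = tax)
}

#' Annotate a tree with clade ids as internal node labels
#'
#' @param cm A `"clade_matrix"` or `"clade_set"` object.
#' @return The tree with `node.label` set to the clade ids.
#' @export
annotate_tree <- function(cm) {
  tree <- cm$tree
  ntip <- length(tree$tip.label)
  labs <- character(tree$Nnode)
  labs[cm$clades$node - ntip] <- cm$clades$clade_id
  tree$node.label <- labs
  tree
}

#' Write clade matrix and manifest TSVs
#'
#' @param cm A `"clade_matrix"` object.
#' @param path Output TSV path.
#' @param tax Optional taxonomy for consensus labels in the manifest.
#' @return `path`, invisibly.
#' @export
write_clade_matrix_tsv <- function(cm, path) {
  df <- data.frame(sample_id = rownames(cm$abundance), cm$abundance,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_clade_matrix_tsv
#' @export
write_clade_manifest_tsv <- function(cm, path, tax = NULL) {
  manifest <- cm$clades
  manifest$members <- vapply(cm$members[manifest$clade_id],
                             paste, character(1), collapse = ",")
  manifest$consensus_taxonomy <-
    if (is.null(tax)) NA_character_ else unname(clade_taxonomy(cm, tax))
  write.table(manifest, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
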