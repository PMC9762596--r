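#' Read a phylogenetic tree from a newick file
#'
#' Reads a single newick-encoded tree and validates it for use as a source of
#' clade definitions: tip labels must be unique and non-empty, and branch
#' lengths must be non-negative. Missing branch lengths are replaced by 0 with
#' a warning. Polytomies are preserved.
#'
#' @param path Path to a file containing one newick string terminated by `;`.
#' @return An [ape::read.tree()] `"phylo"` object.
#' @export
read_newick <- function(path) {
  assert_that(is.character(path) && length(path) == 1 && file.exists(path),
              sprintf("file not found: %s", path))
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  parse_newick_text(txt)
}

#' @noRd
parse_newick_text <- function(txt) {
  txt <- trimws(txt)
  if (!nzchar(txt) || !grepl(";", txt, fixed = TRUE))
    stop(sprintf("newick parse error at character %d: missing terminating ';'",
                 nchar(txt) + 1L), call. = FALSE)
  chars <- strsplit(txt, "", fixed = TRUE)[[1]]
  open_stack <- integer(0)
  for (i in seq_along(chars)) {
    if (chars[i] == "(") open_stack <- c(open_stack, i)
    else if (chars[i] == ")") {
      if (length(open_stack) == 0)
        stop(sprintf("newick parse error at character %d: unmatched ')'", i),
             call. = FALSE)
      open_stack <- open_stack[-length(open_stack)]
    }
  }
  if (length(open_stack) > 0)
    stop(sprintf("newick parse error at character %d: unclosed '('",
                 open_stack[1]), call. = FALSE)
  tree <- tryCatch(ape::read.tree(text = txt), error = function(e) NULL,
                   warning = function(w) NULL)
  if (is.null(tree))
    stop("newick parse error at character 1: not a parseable newick string",
         call. = FALSE)
  validate_tree(tree)
}

#' @noRd
validate_tree <- function(tree) {
  labs <- tree$tip.label
  if (any(!nzchar(labs)))
    stop("invalid tree: empty tip labels", call. = FALSE)
  dup <- unique(labs[duplicated(labs)])
  if (length(dup) > 0)
    stop(sprintf("invalid tree: duplicate tip labels: %s",
                 paste(dup, collapse = ", ")), call. = FALSE)
  if (is.null(tree$edge.length)) {
    warning("tree has no branch lengths; all set to 0")
    tree$edge.length <- rep(0, nrow(tree$edge))
  }
  if (anyNA(tree$edge.length)) {
    warning(sprintf("%d missing branch lengths set to 0",
                    sum(is.na(tree$edge.length))))
    tree$edge.length[is.na(tree$edge.length)] <- 0
  }
  if (any(tree$edge.length < 0))
    stop("invalid tree: negative branch lengths", call. = FALSE)
  tree
}

#' Write a tree to a newick file
#'
#' @param tree A `"phylo"` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Midpoint-root a phylogenetic tree
#'
#' Places the root at the midpoint of the longest tip-to-tip path, preserving
#' all pairwise tip path lengths. When several tip pairs attain the maximal
#' distance, the pair whose (sorted) labels are lexicographically smallest is
#' used, so the result is deterministic. When the midpoint falls exactly on an
#' existing node the tree is rooted at that node and no zero-length edge is
#' introduced.
#'
#' @param tree A `"phylo"` object with at least 2 tips and at least one
#'   positive branch length.
#' @return A rooted `"phylo"` object.
#' @export
midpoint_root <- function(tree) {
  assert_that(inherits(tree, "phylo"), "tree must be a 'phylo' object")
  assert_that(length(tree$tip.label) >= 2, "tree must have at least 2 tips")
  tree <- validate_tree(tree)
  if (all(tree$edge.length == 0))
    stop("midpoint undefined: all branch lengths are zero", call. = FALSE)

  D <- ape::cophenetic.phylo(tree)
  dmax <- max(D)
  tol <- 1e-9 * max(dmax, 1)
  hits <- which(D >= dmax - tol & upper.tri(D), arr.ind = TRUE)
  labs <- rownames(D)
  pairs <- t(apply(hits, 1, function(ij) sort(c(labs[ij[1]], labs[ij[2]]))))
  ord <- order(pairs[, 1], pairs[, 2])
  t1 <- pairs[ord[1], 1]
  t2 <- pairs[ord[1], 2]

  i1 <- match(t1, tree$tip.label)
  i2 <- match(t2, tree$tip.label)
  path <- ape::nodepath(tree, i1, i2)
  target <- D[t1, t2] / 2

  # cumulative distance from t1 to each node on the path
  edge_len <- numeric(length(path) - 1)
  edge_row <- integer(length(path) - 1)
  for (k in seq_len(length(path) - 1)) {
    a <- path[k]; b <- path[k + 1]
    r <- which((tree$edge[, 1] == a & tree$edge[, 2] == b) |
                 (tree$edge[, 1] == b & tree$edge[, 2] == a))
    edge_row[k] <- r
    edge_len[k] <- tree$edge.length[r]
  }
  cum <- c(0, cumsum(edge_len))

  at_node <- which(abs(cum - target) <= tol)
  if (length(at_node) > 0) {
    node <- path[at_node[1]]
    if (ape::is.rooted(tree) && node == length(tree$tip.label) + 1)
      return(tree)
    out <- ape::root(tree, node = node, resolve.root = FALSE)
    return(ape::collapse.singles(out))
  }

  k <- max(which(cum < target))           # midpoint inside edge path[k]-path[k+1]
  r <- edge_row[k]
  parent <- tree$edge[r, 1]; child <- tree$edge[r, 2]
  dA <- cum[k]; dB <- cum[k + 1]
  # position for phytools::reroot is measured from the parent end of the
  # edge subtending `child`
  pos <- if (path[k] == parent) target - dA else dB - target
  out <- phytools::reroot(tree, node.number = child, position = pos)
  ape::collapse.singles(out)
}

#' Prune a tree to a set of tips
#'
#' Retains exactly the requested tips; internal nodes left with a single child
#' are collapsed and their branch lengths summed (as when guide sequences are
#' removed from a reference-aligned phylogeny).
#'
#' @param tree A `"phylo"` object.
#' @param keep_ids Character vector of tip labels to retain (at least 2, all
#'   present in the tree).
#' @return The pruned `"phylo"` object.
#' @export
prune_tips <- function(tree, keep_ids) {
  assert_that(inherits(tree, "phylo"), "tree must be a 'phylo' object")
  keep_ids <- unique(as.character(keep_ids))
  if (length(keep_ids) == 0)
    stop("keep_ids must be non-empty", call. = FALSE)
  unknown <- setdiff(keep_ids, tree$tip.label)
  if (length(unknown) > 0)
    stop(sprintf("keep_ids not present in tree: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  if (length(keep_ids) < 2)
    stop("cannot prune to fewer than 2 tips", call. = FALSE)
  if (length(keep_ids) == length(tree$tip.label)) return(tree)
  ape::keep.tip(tree, keep_ids)
}

#' Pairwise tip-to-tip path distances
#'
#' @param tree A `"phylo"` object.
#' @return A symmetric matrix of patristic distances between tips.
#' @export
tip_distances <- function(tree) {
  ape::cophenetic.phylo(tree)
}
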