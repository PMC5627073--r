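# User-facing tree operations. Trees are ape "phylo" objects, handled
# unrooted; a clade is represented by the bipartition (split) separating its
# terminals from the rest. Canonical form of a split: the side not containing
# the alphabetically first taxon, indices taken in sorted taxon order.

#' Normalize a tree for unrooted parsimony work
#'
#' Unroots the tree (suppressing a degree-2 root) and collapses any other
#' degree-2 internal nodes. Branch lengths are irrelevant in a parsimony
#' context and are dropped.
#'
#' @param tree a `phylo`.
#' @return An unrooted `phylo` with no degree-2 nodes.
#' @export
normalize_tree <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  tree$edge.length <- NULL
  tree$node.label <- NULL
  tree <- ape::collapse.singles(tree)
  if (ape::is.rooted(tree) && length(tree$tip.label) > 2L) {
    tree <- ape::unroot(tree)
  }
  tree
}

#' Parse a newick string
#'
#' @param text newick description, terminated by `;`.
#' @param expected_taxa optional set of taxon labels the tree must carry
#'   exactly.
#' @return An unrooted, normalized `phylo`.
#' @examples
#' tr <- parse_newick("((A,B),(C,D));")
#' bipartitions(tr)
#' @export
parse_newick <- function(text, expected_taxa = NULL) {
  tr <- tryCatch(ape::read.tree(text = text), error = function(e) NULL,
                 warning = function(w) NULL)
  if (is.null(tr)) stop("malformed newick: ", text)
  if (anyDuplicated(tr$tip.label)) {
    stop("duplicate leaf label: ", tr$tip.label[duplicated(tr$tip.label)][1L])
  }
  if (!is.null(expected_taxa)) {
    extra <- setdiff(tr$tip.label, expected_taxa)
    if (length(extra)) stop("unknown taxon in tree: ", extra[1L])
    miss <- setdiff(expected_taxa, tr$tip.label)
    if (length(miss)) stop("taxon missing from tree: ", miss[1L])
  }
  normalize_tree(tr)
}

#' Write a tree as newick
#'
#' @param tree a `phylo`.
#' @return A newick string.
#' @export
write_newick <- function(tree) ape::write.tree(tree)

# Canonical split keys of a phylo, in the space of `taxa_ref` (defaults to
# sorted tip labels).
phylo_split_keys <- function(tree, taxa_ref = sort(tree$tip.label)) {
  u <- ut_from_phylo(normalize_tree(tree), taxa_ref)
  ut_splits(u$edge, u$n)
}

#' Nontrivial bipartitions of a tree
#'
#' One bipartition per internal edge; trivial splits (single taxon or its
#' complement) are excluded. A fully resolved unrooted tree on n leaves has
#' exactly n - 3 of them.
#'
#' @param tree a `phylo` with at least 4 leaves.
#' @return A list of character vectors: each element is the canonical side
#'   of one split (the side not containing the alphabetically first taxon).
#' @export
bipartitions <- function(tree) {
  taxa <- sort(tree$tip.label)
  keys <- phylo_split_keys(tree, taxa)
  out <- lapply(keys, function(k) taxa[key_side(k)])
  names(out) <- keys
  out
}

#' Does a tree contain a clade?
#'
#' True iff the bipartition `terminals | complement` is an edge of the tree.
#'
#' @param tree a `phylo`.
#' @param terminals character vector of taxon labels, a proper subset of the
#'   leaves with 2 <= size <= n - 2.
#' @return Logical scalar.
#' @export
contains_clade <- function(tree, terminals) {
  taxa <- sort(tree$tip.label)
  terminals <- unique(as.character(terminals))
  if (!all(terminals %in% taxa)) {
    stop("unknown taxon: ",
         paste(setdiff(terminals, taxa), collapse = ", "))
  }
  if (length(terminals) < 2L || length(terminals) > length(taxa) - 2L) {
    stop("clade must contain between 2 and n-2 terminals")
  }
  key <- split_key(match(terminals, taxa), length(taxa))
  key %in% phylo_split_keys(tree, taxa)
}

#' Strict consensus of a tree collection
#'
#' The strict consensus contains exactly the bipartitions present in every
#' input tree. All trees must share one leaf set. Works on a list /
#' `multiPhylo` of trees or directly on an [heuristic_search()] /
#' [exhaustive_search()] result.
#'
#' @param trees a list of `phylo`, a `multiPhylo`, or an `mp_search` object.
#' @param ... unused.
#' @return An unrooted `phylo` (generally multifurcating).
#' @export
strict_consensus <- function(trees, ...) UseMethod("strict_consensus")

#' @export
strict_consensus.mp_search <- function(trees, ...) {
  keys <- Reduce(intersect, trees$keys)
  tree_from_splits(keys, trees$taxa)
}

#' @export
strict_consensus.multiPhylo <- function(trees, ...) {
  strict_consensus.default(unclass(trees), ...)
}

#' @export
strict_consensus.phylo <- function(trees, ...) normalize_tree(trees)

#' @export
strict_consensus.default <- function(trees, ...) {
  if (!length(trees)) stop("empty tree collection")
  taxa <- sort(trees[[1L]]$tip.label)
  for (tr in trees) {
    if (!setequal(tr$tip.label, taxa)) {
      stop("trees do not share one leaf set")
    }
  }
  keys <- Reduce(intersect, lapply(trees, phylo_split_keys, taxa_ref = taxa))
  tree_from_splits(keys, taxa)
}

# Build the (multifurcating) tree displaying a set of pairwise compatible
# canonical splits. Splits from a strict-consensus intersection are always
# mutually compatible because they co-occur in at least one input tree.
tree_from_splits <- function(keys, taxa) {
  n <- length(taxa)
  sides <- lapply(unique(keys), key_side)
  sides <- sides[order(-lengths(sides))]
  build <- function(members, avail) {
    inside <- avail[vapply(avail, function(s) all(s %in% members), TRUE)]
    taken <- logical(length(members))
    parts <- character(0)
    while (length(inside)) {
      s <- inside[[1L]]             # largest remaining clade inside `members`
      inside <- inside[-1L]
      parts <- c(parts, build(s, inside))
      inside <- inside[vapply(inside, function(z) !any(z %in% s), TRUE)]
      taken[match(s, members)] <- TRUE
    }
    singles <- members[!taken]
    grp <- c(parts, paste0("L", singles, recycle0 = TRUE))
    if (length(grp) == 1L) grp else paste0("(", paste(grp, collapse = ","), ")")
  }
  nwk <- build(seq_len(n), sides)
  tr <- ape::read.tree(text = paste0(nwk, ";"))
  tr$tip.label <- taxa[as.integer(sub("^L", "", tr$tip.label))]
  normalize_tree(tr)
}
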