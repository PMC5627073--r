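# Parsimony length of a tree for unordered, equally weighted characters.
# Binary nodes follow Fitch's intersection/union rule; multifurcating nodes
# use Hartigan's exact generalization (the state-frequency maximum over the
# children's state sets; cost = number of children minus that maximum), which
# reduces to Fitch on binary nodes and stays exact on polytomies, so strict
# consensus trees can be scored. An unknown cell behaves as the set of all
# states observed in its character column; states never observed in a column
# are never invented.

check_tree_matrix <- function(tree, m) {
  stopifnot(inherits(tree, "phylo"), inherits(m, "char_matrix"))
  if (!setequal(tree$tip.label, m$taxa)) {
    stop("tree leaves and matrix taxa differ: ",
         paste(c(setdiff(tree$tip.label, m$taxa),
                 setdiff(m$taxa, tree$tip.label)), collapse = ", "))
  }
}

#' Fitch parsimony length of a tree
#'
#' Minimum total number of state changes needed to explain every character of
#' the matrix on the given tree (unordered states, equal weights, missing
#' data free). The value is invariant under rooting and equals the sum of
#' [per_character_length()].
#'
#' @param tree a `phylo` (may be multifurcating) whose leaves are exactly the
#'   matrix taxa.
#' @param m a [character_matrix()].
#' @param weights optional per-character non-negative weights (used e.g. for
#'   bootstrap resampling); default all 1.
#' @return A single non-negative number (integer-valued when weights are
#'   integers).
#' @examples
#' m <- character_matrix(rbind(A = "0", B = "0", C = "1", D = "1"))
#' fitch_length(parse_newick("((A,B),(C,D));"), m)  # 1
#' fitch_length(parse_newick("((A,C),(B,D));"), m)  # 2
#' @export
fitch_length <- function(tree, m, weights = NULL) {
  st <- per_character_length(tree, m)
  if (is.null(weights)) sum(st) else sum(st * weights)
}

#' Per-character parsimony lengths
#'
#' @inheritParams fitch_length
#' @return Integer vector with one minimum step count per character; its sum
#'   is [fitch_length()].
#' @export
per_character_length <- function(tree, m) {
  check_tree_matrix(tree, m)
  u <- ut_from_phylo(normalize_tree(tree), m$taxa)
  ut_steps(u$edge, u$n, cm_masks(m), cm_nstates(m))
}
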