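# Independent brute-force parsimony oracle: enumerates every assignment of
# states to internal nodes and counts changed edges, taking the minimum. Works
# on multifurcating trees and leaf state sets (missing / polymorphic cells).
# Deliberately built only on ape's edge matrix, not on the package's scoring
# path.
oracle_fitch_length <- function(tree, m) {
  tree <- ape::collapse.singles(tree)
  edge <- tree$edge
  ntip <- length(tree$tip.label)
  taxa_row <- match(tree$tip.label, m$taxa)
  states <- m$states
  # column observed alphabet, recomputed here from raw bitmasks
  obs <- rep(0L, ncol(states))
  for (r in seq_len(nrow(states))) obs <- bitwOr(obs, states[r, ])
  internals <- sort(unique(edge[, 1]))
  total <- 0L
  for (ch in seq_len(ncol(states))) {
    alph <- which(bitwAnd(bitwShiftR(obs[ch], 0:9), 1L) == 1L) - 1L
    grid <- as.matrix(expand.grid(rep(list(alph), length(internals))))
    cost <- integer(nrow(grid))
    for (e in seq_len(nrow(edge))) {
      p <- match(edge[e, 1], internals)
      child <- edge[e, 2]
      if (child <= ntip) {
        mask <- states[taxa_row[child], ch]
        if (mask == 0L) mask <- obs[ch]
        cost <- cost + as.integer(bitwAnd(mask, bitwShiftL(1L, grid[, p])) == 0L)
      } else {
        q <- match(child, internals)
        cost <- cost + as.integer(grid[, p] != grid[, q])
      }
    }
    total <- total + min(cost)
  }
  total
}

# Random test case: tree (optionally multifurcating, by dropping a random
# subset of the splits of a random binary tree) plus a small matrix with
# 2-3 states and missing cells.
random_case <- function(seed, n_taxa = NULL, n_chars = NULL,
                        multifurcate = TRUE, missing_prob = 0.15,
                        n_states = NULL) {
  set.seed(seed)
  n_taxa <- n_taxa %||% sample(4:7, 1)
  n_chars <- n_chars %||% sample(3:10, 1)
  n_states <- n_states %||% sample(2:3, 1)
  taxa <- paste0("t", seq_len(n_taxa))
  tree <- random_tree(n_taxa, seed = sample.int(1e6, 1), taxa = taxa)
  if (multifurcate && n_taxa >= 5 && runif(1) < 0.5) {
    keys <- names(bipartitions(tree))
    keep <- keys[runif(length(keys)) < 0.6]
    tree <- cladecontrib:::tree_from_splits(keep, sort(taxa))
  }
  st <- matrix(sample(0:(n_states - 1), n_taxa * n_chars, replace = TRUE),
               n_taxa, n_chars, dimnames = list(taxa, NULL))
  st[runif(length(st)) < missing_prob] <- NA
  # keep every column at least partly observed
  for (j in seq_len(ncol(st))) {
    if (all(is.na(st[, j]))) st[1, j] <- 0L
  }
  list(tree = tree, matrix = character_matrix(st, taxa = taxa))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# k clean binary synapomorphy columns for a clade plus constant filler.
clean_signal_matrix <- function(taxa, clade, k, filler = 4L) {
  member <- as.integer(taxa %in% clade)
  st <- cbind(matrix(member, length(taxa), k),
              matrix(0L, length(taxa), filler))
  rownames(st) <- taxa
  character_matrix(st)
}
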