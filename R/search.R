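# Maximum-parsimony tree search: random addition sequence starting trees,
# TBR branch swapping with breadth-wise exploration of equal-length plateaus,
# and an exhaustive enumeration backend for small instances (<= 9 taxa) used
# both as a search method and as the exact oracle behind bootstrap and Bremer
# support on desk-scale problems.

#' Search configuration
#'
#' @param n_replicates number of random-addition + branch-swapping replicates.
#' @param trees_per_replicate maximum trees retained per replicate.
#' @param max_trees_total cap on the pooled tree buffer.
#' @param suboptimal_margin retain trees up to this many steps above the best
#'   (0 = optimal trees only).
#' @param seed master seed; every random choice in the search derives from it.
#' @return A `search_config` list.
#' @export
search_config <- function(n_replicates = 10L, trees_per_replicate = 10L,
                          max_trees_total = 100L, suboptimal_margin = 0L,
                          seed = 1L) {
  stopifnot(n_replicates >= 1L, trees_per_replicate >= 1L,
            max_trees_total >= trees_per_replicate, suboptimal_margin >= 0L)
  structure(list(n_replicates = as.integer(n_replicates),
                 trees_per_replicate = as.integer(trees_per_replicate),
                 max_trees_total = as.integer(max_trees_total),
                 suboptimal_margin = as.integer(suboptimal_margin),
                 seed = as.integer(seed)),
            class = "search_config")
}

#' Named search presets
#'
#' `"paper-150"` and `"paper-10000"` encode the two published traditional-
#' search profiles (150 or 10000 replicates, 200 trees saved per replicate,
#' 30000 trees in memory); `"fast"` is a light profile suitable for
#' per-pseudoreplicate bootstrap searches and continuous testing.
#'
#' @param name preset name.
#' @param seed master seed.
#' @return A [search_config()].
#' @export
search_preset <- function(name = c("fast", "paper-150", "paper-10000"),
                          seed = 1L) {
  name <- match.arg(name)
  switch(name,
    "fast" = search_config(10L, 10L, 100L, 0L, seed),
    "paper-150" = search_config(150L, 200L, 30000L, 0L, seed),
    "paper-10000" = search_config(10000L, 200L, 30000L, 0L, seed)
  )
}

new_mp_search <- function(trees, keys, lengths, taxa, config, method) {
  structure(list(trees = trees, keys = keys, lengths = lengths,
                 best_length = if (length(lengths)) min(lengths) else NA_real_,
                 taxa = taxa, config = config, method = method),
            class = "mp_search")
}

#' @export
print.mp_search <- function(x, ...) {
  cat("Maximum-parsimony search (", x$method, ")\n", sep = "")
  cat("  trees retained:", length(x$trees),
      " best length:", x$best_length, "\n")
  invisible(x)
}

#' @export
summary.mp_search <- function(object, ...) {
  cons <- strict_consensus(object)
  cat("Maximum-parsimony search (", object$method, ")\n", sep = "")
  cat("  taxa:", length(object$taxa), "\n")
  cat("  trees retained:", length(object$trees), "\n")
  cat("  best length:", object$best_length, "steps\n")
  cat("  strict consensus:", length(Reduce(intersect, object$keys)),
      "nontrivial clades\n")
  invisible(cons)
}

#' Trees retained by a search
#'
#' @param x an `mp_search` result.
#' @return A `multiPhylo` list of the retained trees.
#' @export
optimal_trees <- function(x) {
  stopifnot(inherits(x, "mp_search"))
  structure(lapply(x$trees, ut_to_phylo, taxa = x$taxa),
            class = "multiPhylo")
}

clade_key <- function(m, terminals) {
  terminals <- unique(as.character(terminals))
  idx <- match(terminals, m$taxa)
  if (anyNA(idx)) {
    stop("unknown taxon: ",
         paste(terminals[is.na(idx)], collapse = ", "))
  }
  if (length(idx) < 2L || length(idx) > n_taxa(m) - 2L) {
    stop("clade must contain between 2 and n-2 terminals")
  }
  split_key(idx, n_taxa(m))
}

key_taxa <- function(key, taxa) taxa[key_side(key)]

# Random addition over the internal representation. `avoid_key`: reject the
# final tree containing that split (repaired by TBR moves if needed).
random_addition_ut <- function(m, seed, weights = NULL, avoid_key = NULL) {
  n <- n_taxa(m)
  if (n < 4L) stop("need at least 4 taxa")
  masks <- cm_masks(m)
  S <- cm_nstates(m)
  with_seed(seed, {
    ord <- sample.int(n)
    u <- ut_star3(ord[1:3], n)
    for (leaf in ord[-(1:3)]) {
      best <- Inf
      cands <- list()
      for (i in seq_len(nrow(u$edge))) {
        cand <- ut_attach(u, i, leaf)
        len <- ut_length(cand$edge, n, masks, S, weights)
        if (len < best - 1e-9) {
          best <- len
          cands <- list(cand)
        } else if (len <= best + 1e-9) {
          cands[[length(cands) + 1L]] <- cand
        }
      }
      u <- if (length(cands) == 1L) cands[[1L]] else
        cands[[sample.int(length(cands), 1L)]]
    }
    u <- ut_compact(u)
    if (!is.null(avoid_key) && avoid_key %in% ut_splits(u$edge, n)) {
      u <- break_split(u, masks, S, weights, avoid_key)
    }
    u
  })
}

# Cheapest TBR neighbor lacking the given split (always exists for any
# nontrivial split of a binary tree).
break_split <- function(u, masks, S, weights, avoid_key) {
  nbs <- ut_tbr_neighbors(u)
  best <- Inf; pick <- NULL
  for (nb in nbs) {
    if (avoid_key %in% nb$splits) next
    len <- ut_length(nb$u$edge, u$n, masks, S, weights)
    if (len < best) { best <- len; pick <- nb$u }
  }
  if (is.null(pick)) stop("could not construct a tree lacking the clade")
  pick
}

#' Random-addition starting tree
#'
#' Builds a binary tree by inserting the taxa in seeded-random order, each at
#' the parsimony-optimal attachment edge (ties broken by a seeded draw).
#'
#' @param m a [character_matrix()].
#' @param seed integer seed (same seed, same tree).
#' @return A binary unrooted `phylo`.
#' @export
random_addition_tree <- function(m, seed = 1L) {
  ut_to_phylo(random_addition_ut(m, seed), m$taxa)
}

#' TBR neighborhood of a binary tree
#'
#' All distinct topologies reachable by one tree-bisection-reconnection move:
#' an edge is bisected, the detached part is rerooted on any of its edges and
#' reattached to any edge of the other part. The neighborhood contains every
#' SPR neighbor and never the input topology itself.
#'
#' @param tree a binary unrooted `phylo`.
#' @return A `multiPhylo` of neighbor topologies.
#' @export
tbr_neighborhood <- function(tree) {
  tree <- normalize_tree(tree)
  taxa <- sort(tree$tip.label)
  u <- ut_from_phylo(tree, taxa)
  if (!ape::is.binary(tree)) stop("TBR swapping requires a binary tree")
  nbs <- ut_tbr_neighbors(u)
  structure(lapply(nbs, function(nb) ut_to_phylo(nb$u, taxa)),
            class = "multiPhylo")
}

# One replicate: hill-climb by TBR accepting strictly better trees, exploring
# equal-or-near-length plateaus breadth-wise up to the per-replicate cap.
swap_replicate <- function(u0, m, masks, S, weights, cap, margin,
                           avoid_key = NULL) {
  n <- n_taxa(m)
  len0 <- ut_length(u0$edge, n, masks, S, weights)
  key0 <- ut_key(u0$edge, n)
  pool <- list(); lens <- numeric(0)
  pool[[key0]] <- u0; lens[key0] <- len0
  best <- len0
  queue <- key0
  seen <- key0
  while (length(queue)) {
    k <- queue[[1L]]
    queue <- queue[-1L]
    if (lens[[k]] > best + margin) next       # stale after an improvement
    nbs <- ut_tbr_neighbors(pool[[k]])
    for (nb in nbs) {
      if (nb$key %in% seen) next
      seen <- c(seen, nb$key)
      if (!is.null(avoid_key) && avoid_key %in% nb$splits) next
      l <- ut_length(nb$u$edge, n, masks, S, weights)
      if (l > best + margin) next
      live <- sum(lens[names(pool)] <= best + margin)
      if (l >= best && live >= cap) next
      pool[[nb$key]] <- nb$u
      lens[nb$key] <- l
      queue <- c(queue, nb$key)
      if (l < best) best <- l
    }
  }
  keep <- names(pool)[lens[names(pool)] <= best + margin]
  list(trees = pool[keep], lengths = lens[keep], best = best)
}

#' Heuristic maximum-parsimony search
#'
#' For each replicate: a random-addition starting tree, then TBR branch
#' swapping accepting equal-or-better topologies until no improvement,
#' retaining up to `trees_per_replicate` trees within `suboptimal_margin`
#' steps of the replicate best. Replicates are pooled, deduplicated by
#' topology, filtered to the global margin and truncated to
#' `max_trees_total`. Fully deterministic given the config seed.
#'
#' @param m a [character_matrix()] with at least 4 taxa.
#' @param config a [search_config()].
#' @param weights optional per-character weights (bootstrap resampling).
#' @param forbid optional character vector of taxon labels: the search is
#'   constrained to trees *not* containing that clade (used for Bremer
#'   support via converse-constrained search).
#' @return An `mp_search` object: retained trees, their lengths and
#'   `best_length`, plus the provenance config.
#' @export
heuristic_search <- function(m, config = search_config(), weights = NULL,
                             forbid = NULL) {
  stopifnot(inherits(m, "char_matrix"))
  n <- n_taxa(m)
  if (n < 4L) stop("need at least 4 taxa")
  masks <- cm_masks(m)
  S <- cm_nstates(m)
  avoid_key <- if (!is.null(forbid)) clade_key(m, forbid) else NULL
  rep_seeds <- seed_stream(config$seed, config$n_replicates)
  pool <- list(); lens <- numeric(0)
  for (r in seq_len(config$n_replicates)) {
    u0 <- random_addition_ut(m, rep_seeds[r], weights, avoid_key)
    res <- swap_replicate(u0, m, masks, S, weights,
                          cap = config$trees_per_replicate,
                          margin = config$suboptimal_margin,
                          avoid_key = avoid_key)
    for (k in names(res$trees)) {
      if (is.null(pool[[k]])) {
        pool[[k]] <- res$trees[[k]]
        lens[k] <- res$lengths[[k]]
      }
    }
  }
  best <- min(lens)
  keep <- names(pool)[lens[names(pool)] <= best + config$suboptimal_margin]
  keep <- keep[order(lens[keep], keep)]
  if (length(keep) > config$max_trees_total) {
    keep <- keep[seq_len(config$max_trees_total)]
  }
  new_mp_search(trees = unname(pool[keep]),
                keys = lapply(pool[keep], function(u) ut_splits(u$edge, n)),
                lengths = unname(lens[keep]),
                taxa = m$taxa, config = config, method = "heuristic")
}

# Exhaustive per-topology tables for a matrix: topologies (cached per n),
# their split sets (cached per n) and the per-character length matrix L
# (topologies x characters). Bootstrap pseudoreplicates and Bremer values on
# small instances reduce to weighted column sums of L.
ex_tables <- function(m) {
  n <- n_taxa(m)
  topos <- all_topologies(n)
  skey <- paste0("splits", n)
  if (is.null(.cc_cache[[skey]])) {
    .cc_cache[[skey]] <- lapply(topos, function(u) ut_splits(u$edge, n))
  }
  masks <- cm_masks(m)
  S <- cm_nstates(m)
  L <- matrix(0L, length(topos), n_chars(m))
  for (i in seq_along(topos)) {
    L[i, ] <- ut_steps(topos[[i]]$edge, n, masks, S)
  }
  list(topos = topos, splits = .cc_cache[[skey]], L = L, n = n)
}

#' Exhaustive maximum-parsimony search
#'
#' Enumerates every unrooted binary topology (at most 9 taxa, 135135
#' topologies) and returns all trees attaining the global minimum length
#' (or within `margin` steps of it). Serves as the exact oracle for the
#' heuristic search and for support values on small instances.
#'
#' @param m a [character_matrix()] with 4-9 taxa.
#' @param margin retain trees up to `margin` steps above the minimum.
#' @param weights optional per-character weights.
#' @param tables precomputed per-topology tables (internal reuse).
#' @return An `mp_search` object.
#' @export
exhaustive_search <- function(m, margin = 0L, weights = NULL, tables = NULL) {
  stopifnot(inherits(m, "char_matrix"))
  n <- n_taxa(m)
  if (n < 4L) stop("need at least 4 taxa")
  tb <- tables %||% ex_tables(m)
  tot <- if (is.null(weights)) rowSums(tb$L) else as.vector(tb$L %*% weights)
  best <- min(tot)
  keep <- which(tot <= best + margin)
  keep <- keep[order(tot[keep])]
  new_mp_search(trees = tb$topos[keep], keys = tb$splits[keep],
                lengths = tot[keep], taxa = m$taxa,
                config = list(margin = margin), method = "exhaustive")
}
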