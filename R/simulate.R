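# Synthetic fixtures with known ground truth: a (random or given) tree,
# binary characters planted as clean synapomorphies on chosen clades, optional
# homoplastic characters guaranteed to conflict with the clade, constant
# filler and a simple per-edge Markov noise model. Default character types
# mirror a three-type morphological matrix (general external / copulatory /
# photophore characters) with sizes proportional to the published 116/74/59
# split.

#' Uniform random unrooted binary tree
#'
#' Built by sequential random edge attachment, which generates every labelled
#' unrooted binary topology with equal probability.
#'
#' @param n_taxa number of leaves (>= 4).
#' @param seed integer seed (same seed, same tree).
#' @param taxa leaf labels; default `t1..tn`.
#' @return A binary unrooted `phylo`.
#' @export
random_tree <- function(n_taxa, seed = 1L, taxa = paste0("t", seq_len(n_taxa))) {
  stopifnot(n_taxa >= 4L, length(taxa) == n_taxa)
  u <- with_seed(seed, {
    u <- ut_star3(1:3, n_taxa)
    for (k in 4:n_taxa) {
      u <- ut_attach(u, sample.int(nrow(u$edge), 1L), k,
                     newint = n_taxa + (k - 2L))
    }
    u
  })
  ut_to_phylo(u, taxa)
}

# Random binary tree constrained to contain each of the given clades (taxon
# label vectors, pairwise nested or disjoint). Subtree shapes are drawn by
# random coalescence; used by plant_matrix so planted clades are always
# clades of the generated tree.
random_tree_with_clades <- function(taxa, clades, seed) {
  clades <- unique(lapply(clades, function(x) sort(unique(x))))
  for (i in seq_along(clades)) {
    for (j in seq_len(i - 1L)) {
      a <- clades[[i]]; b <- clades[[j]]
      ab <- intersect(a, b)
      if (length(ab) && !(all(a %in% b) || all(b %in% a))) {
        stop("planted clades must be nested or disjoint: ",
             paste(a, collapse = ","), " vs ", paste(b, collapse = ","))
      }
    }
  }
  join_random <- function(units, down_to) {
    while (length(units) > down_to) {
      pick <- sample.int(length(units), 2L)
      units <- c(units[-pick],
                 paste0("(", units[[pick[1L]]], ",", units[[pick[2L]]], ")"))
    }
    units
  }
  build2 <- function(members, avail) {
    avail <- avail[order(-lengths(avail))]
    units <- character(0)
    used <- character(0)
    while (length(avail)) {
      s <- avail[[1L]]; avail <- avail[-1L]
      nested <- Filter(function(z) all(z %in% s), avail)
      avail <- Filter(function(z) !all(z %in% s), avail)
      sub_units <- build2(s, nested)
      units <- c(units, join_random(sub_units, 1L))
      used <- c(used, s)
    }
    c(units, setdiff(members, used))
  }
  with_seed(seed, {
    top <- build2(taxa, clades)
    top <- join_random(top, 3L)
    top <- paste0("(", paste(top, collapse = ","), ")")
    parse_newick(paste0(top, ";"), expected_taxa = taxa)
  })
}

#' Specification of a planted-signal fixture
#'
#' Describes a synthetic matrix: for each character type, a list of planting
#' instructions `list(clade = <taxon vector>, clean = <k>, homoplastic =
#' <h>)`. Clean columns are uncontradicted binary synapomorphies of the clade
#' (state 1 inside, 0 outside); each clean count k equals the clade's Bremer
#' support when nothing in the matrix conflicts with the clade. Homoplastic
#' columns mark a random taxon subset that is guaranteed to straddle the
#' clade boundary (all four intersections with the clade bipartition
#' non-empty), so they always conflict with it.
#'
#' @param n_taxa number of terminal taxa.
#' @param per_type_plan named list: type label -> list of planting
#'   instructions (see above). May be empty lists for pure-filler types.
#' @param tree a `phylo` on the fixture taxa (every planted clade must be one
#'   of its clades), or `"random"`: a seeded random binary tree constrained
#'   to contain the planted clades.
#' @param background_constant number of constant filler characters,
#'   distributed over the types so that type sizes approximate the 116/74/59
#'   proportions (for the default type names) or equal sizes otherwise.
#' @param noise_rate probability that a planted column receives one extra
#'   random state flip.
#' @param seed integer seed.
#' @param taxa leaf labels; default `t1..tn`.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_taxa,
                         per_type_plan = list(general = list(),
                                              copulatory = list(),
                                              photophores = list()),
                         tree = "random",
                         background_constant = 6L,
                         noise_rate = 0,
                         seed = 1L,
                         taxa = paste0("t", seq_len(n_taxa))) {
  stopifnot(n_taxa >= 4L, noise_rate >= 0, noise_rate <= 1,
            background_constant >= 0L)
  if (is.null(names(per_type_plan))) stop("per_type_plan must be named")
  for (tp in names(per_type_plan)) {
    for (inst in per_type_plan[[tp]]) {
      cl <- inst$clade
      if (length(cl) < 2L || length(cl) > n_taxa - 2L) {
        stop("planted clade must be a nontrivial subset of the taxa")
      }
      if (!all(cl %in% taxa)) stop("planted clade names unknown taxa")
    }
  }
  structure(list(n_taxa = as.integer(n_taxa), per_type_plan = per_type_plan,
                 tree = tree, background_constant = as.integer(background_constant),
                 noise_rate = noise_rate, seed = as.integer(seed),
                 taxa = taxa),
            class = "fixture_spec")
}

# Published three-type size proportions used to spread filler characters.
type_weights <- function(type_names) {
  std <- c(general = 116, copulatory = 74, photophores = 59)
  w <- std[type_names]
  if (anyNA(w)) w <- rep(1, length(type_names))
  unname(w)
}

#' Generate the planted matrix of a fixture
#'
#' Pure function of the spec: the same spec always yields the same matrix,
#' partition and ground-truth record.
#'
#' @param spec a [fixture_spec()].
#' @return A list with elements `matrix` ([character_matrix()]), `partition`
#'   ([character_partition()]), `tree` (the generating `phylo`) and `truth`
#'   (data frame: type, clade taxa, planted clean count `k_clean`,
#'   homoplastic count `k_homoplastic`).
#' @export
plant_matrix <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  n <- spec$n_taxa
  taxa <- spec$taxa
  seeds <- seed_stream(spec$seed, 3L)
  plan_clades <- unlist(lapply(spec$per_type_plan, function(pl)
    lapply(pl, function(inst) inst$clade)), recursive = FALSE)
  tree <- if (identical(spec$tree, "random")) {
    if (length(plan_clades)) {
      random_tree_with_clades(taxa, unname(plan_clades), seeds[1L])
    } else {
      random_tree(n, seeds[1L], taxa)
    }
  } else normalize_tree(spec$tree)
  if (!setequal(tree$tip.label, taxa)) stop("tree does not match fixture taxa")
  tree_keys <- phylo_split_keys(tree, taxa)
  n_internal_edges <- length(tree_keys)
  planted_clades <- unique(unlist(lapply(spec$per_type_plan, function(pl)
    vapply(pl, function(inst)
      split_key(match(inst$clade, taxa), n), "")), use.names = FALSE))
  if (length(planted_clades) > n_internal_edges) {
    stop("plan demands more clades (", length(planted_clades),
         ") than the tree has internal edges (", n_internal_edges, ")")
  }
  bad <- setdiff(planted_clades, tree_keys)
  if (length(bad)) {
    stop("planted clade is not a clade of the fixture tree: ",
         paste(vapply(bad, function(k)
           paste(taxa[key_side(k)], collapse = ","), ""), collapse = "; "))
  }

  types <- names(spec$per_type_plan)
  cols <- list(); col_type <- character(0)
  truth <- list()
  with_seed(seeds[2L], {
    for (tp in types) {
      for (inst in spec$per_type_plan[[tp]]) {
        member <- taxa %in% inst$clade
        k <- inst$clean %||% 0L
        h <- inst$homoplastic %||% 0L
        for (i in seq_len(k)) {
          cols[[length(cols) + 1L]] <- as.integer(member)
          col_type <- c(col_type, tp)
        }
        for (i in seq_len(h)) {
          repeat {
            x <- runif(n) < 0.5
            if (any(x & member) && any(x & !member) &&
                any(!x & member) && any(!x & !member)) break
          }
          cols[[length(cols) + 1L]] <- as.integer(x)
          col_type <- c(col_type, tp)
        }
        truth[[length(truth) + 1L]] <- data.frame(
          type = tp, clade = paste(sort(inst$clade), collapse = ","),
          k_clean = k, k_homoplastic = h, stringsAsFactors = FALSE)
      }
    }
  })
  # constant filler spread over types toward the published proportions
  planted_per_type <- vapply(types, function(tp) sum(col_type == tp), 0L)
  w <- type_weights(types)
  total <- sum(planted_per_type) + spec$background_constant
  ideal <- total * w / sum(w)
  fill <- pmax(0L, as.integer(round(ideal - planted_per_type)))
  while (sum(fill) > spec$background_constant) {
    i <- which.max(fill); fill[i] <- fill[i] - 1L
  }
  while (sum(fill) < spec$background_constant) {
    i <- which.min(planted_per_type + fill); fill[i] <- fill[i] + 1L
  }
  for (ti in seq_along(types)) {
    for (i in seq_len(fill[ti])) {
      cols[[length(cols) + 1L]] <- rep(0L, n)
      col_type <- c(col_type, types[ti])
    }
  }
  if (!length(cols)) stop("fixture has no characters")
  st <- do.call(cbind, cols)
  if (spec$noise_rate > 0) {
    st <- with_seed(seeds[3L], {
      for (j in seq_len(ncol(st))) {
        if (runif(1) < spec$noise_rate) {
          r <- sample.int(n, 1L)
          st[r, j] <- 1L - st[r, j]
        }
      }
      st
    })
  }
  rownames(st) <- taxa
  ord <- order(match(col_type, types))
  st <- st[, ord, drop = FALSE]
  col_type <- col_type[ord]
  if (any(vapply(types, function(tp) sum(col_type == tp), 0L) == 0L)) {
    stop("a character type ended up empty; increase background_constant")
  }
  part <- character_partition(
    lapply(setNames(types, types), function(tp) which(col_type == tp)),
    n_chars = ncol(st))
  truth <- do.call(rbind, truth) %||% data.frame(
    type = character(0), clade = character(0),
    k_clean = integer(0), k_homoplastic = integer(0))
  list(matrix = character_matrix(st, taxa = taxa),
       partition = part, tree = tree, truth = truth)
}

#' Simulate discrete characters on a tree
#'
#' Simple symmetric Markov noise model: the root state is uniform over
#' `n_states`; along each edge, with probability `change_prob_per_edge` the
#' state jumps to a uniformly chosen different state.
#'
#' @param tree a `phylo`.
#' @param n_chars number of characters to simulate.
#' @param n_states number of states (>= 2).
#' @param change_prob_per_edge per-edge change probability in \[0, 1\].
#' @param seed integer seed.
#' @return A [character_matrix()] on the tree's taxa.
#' @export
mk_simulate <- function(tree, n_chars, n_states = 2L,
                        change_prob_per_edge = 0.1, seed = 1L) {
  stopifnot(n_states >= 2L, change_prob_per_edge >= 0,
            change_prob_per_edge <= 1, n_chars >= 1L)
  tree <- normalize_tree(tree)
  taxa <- tree$tip.label
  u <- ut_from_phylo(tree, taxa)
  r <- ut_rooted(u$edge, u$n)
  m <- max(u$edge)
  st <- with_seed(seed, {
    states <- matrix(0L, m, n_chars)
    states[r$root, ] <- sample.int(n_states, n_chars, replace = TRUE) - 1L
    for (v in r$pre) {
      if (v == r$root) next
      p <- r$parent[v]
      jump <- stats::runif(n_chars) < change_prob_per_edge
      states[v, ] <- states[p, ]
      if (any(jump)) {
        shift <- sample.int(n_states - 1L, sum(jump), replace = TRUE)
        states[v, jump] <- (states[p, jump] + shift) %% n_states
      }
    }
    states
  })
  leaf <- st[seq_along(taxa), , drop = FALSE]
  rownames(leaf) <- taxa
  character_matrix(leaf, taxa = taxa)
}
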