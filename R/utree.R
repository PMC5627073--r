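# Internal light-weight unrooted tree machinery used by the search and
# scoring code. A "ut" is list(edge = 2-column integer matrix, n = n_leaves);
# leaves are node ids 1..n (mapped to a fixed reference taxon order by the
# caller), internal node ids are arbitrary integers > n. All functions here
# are internal; user-facing code works with ape "phylo" objects.

ut <- function(edge, n) {
  storage.mode(edge) <- "integer"
  list(edge = edge, n = as.integer(n))
}

ut_adjacency <- function(edge, m = max(edge)) {
  adj <- vector("list", m)
  for (i in seq_len(nrow(edge))) {
    a <- edge[i, 1L]; b <- edge[i, 2L]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

# Root the unrooted tree at an internal node; returns postorder node list and
# children per node. Exact choice of root does not affect parsimony length.
ut_rooted <- function(edge, n, root = NULL) {
  m <- max(edge)
  adj <- ut_adjacency(edge, m)
  if (is.null(root)) {
    ids <- unique(as.vector(edge))
    root <- ids[ids > n][1L]
    if (is.na(root)) root <- ids[1L]   # degenerate: no internal node
  }
  parent <- integer(m)
  pre <- integer(m)
  k <- 0L
  stack <- root
  parent[root] <- 0L
  while (length(stack)) {
    v <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    k <- k + 1L
    pre[k] <- v
    for (w in adj[[v]]) {
      if (w != parent[v]) {
        parent[w] <- v
        stack <- c(stack, w)
      }
    }
  }
  pre <- pre[seq_len(k)]
  kids <- vector("list", m)
  for (v in pre) {
    p <- parent[v]
    if (p > 0L) kids[[p]] <- c(kids[[p]], v)
  }
  list(post = rev(pre), kids = kids, parent = parent, root = root, pre = pre)
}

# Per-character minimum number of state changes (unordered characters) on a
# possibly multifurcating tree: Hartigan's exact generalization of the Fitch
# downpass. leafmask is an n x n_chars integer matrix of state bitmasks with
# missing cells already expanded to the column's observed alphabet.
ut_steps <- function(edge, n, leafmask, S) {
  r <- ut_rooted(edge, n)
  nc <- ncol(leafmask)
  m <- max(edge)
  NM <- matrix(0L, m, nc)
  NM[seq_len(min(n, m)), ] <- leafmask[seq_len(min(n, m)), , drop = FALSE]
  steps <- integer(nc)
  for (v in r$post) {
    ch <- r$kids[[v]]
    if (is.null(ch)) next
    K <- integer(nc)
    cnts <- vector("list", S)
    for (s in seq_len(S) - 1L) {
      cs <- integer(nc)
      for (cn in ch) cs <- cs + bitwAnd(bitwShiftR(NM[cn, ], s), 1L)
      cnts[[s + 1L]] <- cs
      K <- pmax.int(K, cs)
    }
    V <- integer(nc)
    for (s in seq_len(S) - 1L) V <- V + bitwShiftL(as.integer(cnts[[s + 1L]] == K), s)
    NM[v, ] <- V
    steps <- steps + (length(ch) - K)
  }
  steps
}

ut_length <- function(edge, n, leafmask, S, weights = NULL) {
  st <- ut_steps(edge, n, leafmask, S)
  if (is.null(weights)) sum(st) else sum(st * weights)
}

# Canonical key of one split: indices (in the reference taxon order) of the
# side not containing taxon 1, comma-separated.
canon_side <- function(idx, n) {
  idx <- sort(unique(as.integer(idx)))
  if (1L %in% idx) sort(setdiff(seq_len(n), idx)) else idx
}

split_key <- function(idx, n) paste(canon_side(idx, n), collapse = ",")

key_side <- function(key) as.integer(strsplit(key, ",", fixed = TRUE)[[1L]])

# All nontrivial splits of a complete tree on leaves 1..n.
ut_splits <- function(edge, n) {
  r <- ut_rooted(edge, n)
  m <- max(edge)
  sets <- vector("list", m)
  keys <- character(0)
  for (v in r$post) {
    ch <- r$kids[[v]]
    if (is.null(ch)) {
      sets[[v]] <- v
      next
    }
    s <- sort(unlist(sets[ch], use.names = FALSE))
    sets[[v]] <- s
    if (v != r$root && length(s) >= 2L && length(s) <= n - 2L) {
      keys <- c(keys, split_key(s, n))
    }
  }
  unique(keys)
}

# Topology signature (equality of unrooted topologies = equality of split sets).
ut_key <- function(edge, n) paste(sort(ut_splits(edge, n)), collapse = ";")

# Renumber internal node ids to n+1..n+k (keeps ids small across long swaps).
ut_compact <- function(u) {
  edge <- u$edge; n <- u$n
  ids <- sort(unique(as.vector(edge)))
  internal <- ids[ids > n]
  map <- integer(max(ids))
  map[ids[ids <= n]] <- ids[ids <= n]
  map[internal] <- n + seq_along(internal)
  ut(matrix(map[edge], ncol = 2L), n)
}

# Attach a new leaf in the middle of edge i; new internal node id supplied.
ut_attach <- function(u, i, leaf, newint = max(u$edge) + 1L) {
  e <- u$edge
  a <- e[i, 1L]; b <- e[i, 2L]
  e[i, ] <- c(a, newint)
  ut(rbind(e, c(newint, b), c(newint, leaf)), u$n)
}

ut_star3 <- function(leaves, n, internal = n + 1L) {
  ut(cbind(rep(internal, 3L), leaves), n)
}

reachable_nodes <- function(edge, start) {
  if (nrow(edge) == 0L) return(start)
  m <- max(max(edge), start)
  adj <- ut_adjacency(edge, m)
  seen <- logical(m)
  seen[start] <- TRUE
  stack <- start
  while (length(stack)) {
    v <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    for (w in adj[[v]]) {
      if (!seen[w]) { seen[w] <- TRUE; stack <- c(stack, w) }
    }
  }
  which(seen)
}

# After bisection one endpoint drops to degree 2; suppress it. Returns
# list(edges, node): node is set when the part is a single vertex.
suppress_endpoint <- function(edges, w) {
  if (nrow(edges) == 0L) return(list(edges = edges, node = w))
  hit <- which(edges[, 1L] == w | edges[, 2L] == w)
  if (length(hit) == 2L) {
    nb <- setdiff(as.vector(edges[hit, ]), w)
    edges <- rbind(edges[-hit, , drop = FALSE], nb)
  } else if (length(hit) == 0L) {
    return(list(edges = edges, node = w))
  }
  list(edges = edges, node = NULL)
}

# Full tree-bisection-reconnection neighborhood of a binary unrooted tree.
# Bisects every edge (pendant edges give the SPR leaf moves), suppresses the
# cut endpoints, and reconnects every edge/vertex of one part to every
# edge/vertex of the other. Deduplicated by topology signature; the input
# topology itself is excluded.
ut_tbr_neighbors <- function(u) {
  edge <- u$edge; n <- u$n
  selfkey <- ut_key(edge, n)
  seen <- character(0)
  out <- list()
  for (i in seq_len(nrow(edge))) {
    uu <- edge[i, 1L]; vv <- edge[i, 2L]
    E2 <- edge[-i, , drop = FALSE]
    compU <- reachable_nodes(E2, uu)
    inU <- E2[, 1L] %in% compU
    partU <- suppress_endpoint(E2[inU, , drop = FALSE], uu)
    partV <- suppress_endpoint(E2[!inU, , drop = FALSE], vv)
    base <- max(edge)
    attU <- if (!is.null(partU$node)) list(partU$node) else seq_len(nrow(partU$edges))
    attV <- if (!is.null(partV$node)) list(partV$node) else seq_len(nrow(partV$edges))
    for (a in attU) {
      for (b in attV) {
        eu <- partU$edges; ev <- partV$edges
        if (is.list(attU) && !is.null(partU$node)) {
          x <- partU$node
        } else {
          x <- base + 1L
          pa <- eu[a, ]
          eu[a, ] <- c(pa[1L], x)
          eu <- rbind(eu, c(x, pa[2L]))
        }
        if (is.list(attV) && !is.null(partV$node)) {
          y <- partV$node
        } else {
          y <- base + 2L
          pb <- ev[b, ]
          ev[b, ] <- c(pb[1L], y)
          ev <- rbind(ev, c(y, pb[2L]))
        }
        cand <- ut_compact(ut(rbind(eu, ev, c(x, y)), n))
        spl <- ut_splits(cand$edge, n)
        k <- paste(sort(spl), collapse = ";")
        if (k == selfkey || k %in% seen) next
        seen <- c(seen, k)
        out[[length(out) + 1L]] <- list(u = cand, splits = spl, key = k)
      }
    }
  }
  out
}

# Enumerate all unrooted binary topologies on leaves 1..n by sequential
# attachment; cached per n. n <= 9 (135135 topologies).
.cc_cache <- new.env(parent = emptyenv())

all_topologies <- function(n) {
  if (n < 3L) stop("need at least 3 taxa")
  if (n > 9L) {
    stop("exhaustive enumeration supports at most 9 taxa (",
         "135135 topologies); use heuristic search instead")
  }
  key <- paste0("topo", n)
  if (!is.null(.cc_cache[[key]])) return(.cc_cache[[key]])
  trees <- list(ut_star3(1:3, n, internal = n + 1L))
  if (n > 3L) {
    for (k in 4:n) {
      newint <- n + (k - 2L)
      nxt <- vector("list", length(trees) * (2L * k - 5L))
      j <- 0L
      for (tr in trees) {
        for (i in seq_len(nrow(tr$edge))) {
          j <- j + 1L
          nxt[[j]] <- ut_attach(tr, i, k, newint = newint)
        }
      }
      trees <- nxt
    }
  }
  .cc_cache[[key]] <- trees
  trees
}

# Conversions between ut and ape phylo. `taxa` fixes the leaf-id <-> label map.
ut_to_phylo <- function(u, taxa) {
  r <- ut_rooted(u$edge, u$n)
  lab <- function(v) {
    ch <- r$kids[[v]]
    if (is.null(ch)) return(paste0("L", v))
    paste0("(", paste(vapply(ch, lab, ""), collapse = ","), ")")
  }
  tr <- ape::read.tree(text = paste0(lab(r$root), ";"))
  tr$tip.label <- taxa[as.integer(sub("^L", "", tr$tip.label))]
  tr
}

ut_from_phylo <- function(tree, taxa) {
  if (!setequal(tree$tip.label, taxa)) {
    stop("tree leaf set does not match the expected taxon set")
  }
  ntip <- length(tree$tip.label)
  map <- integer(ntip + tree$Nnode)
  map[seq_len(ntip)] <- match(tree$tip.label, taxa)
  # ape numbers internal nodes ntip+1.. which already exceed n (= ntip)
  map[(ntip + 1L):(ntip + tree$Nnode)] <- (ntip + 1L):(ntip + tree$Nnode)
  edge <- matrix(map[tree$edge], ncol = 2L)
  ut(edge, length(taxa))
}
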