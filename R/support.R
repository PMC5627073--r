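# Clade support: nonparametric bootstrap percentages and Bremer (decay)
# values, plus the significance rule (bootstrap > 80% AND Bremer > 3, both
# strict). On instances with <= 9 taxa both measures are computed exactly
# from the exhaustive per-topology tables; larger instances fall back to
# heuristic searches (a reduced-preset search per pseudoreplicate; a
# converse-constrained search for Bremer).

support_method <- function(method, m) {
  method <- match.arg(method, c("auto", "exhaustive", "heuristic"))
  if (method == "auto") method <- if (n_taxa(m) <= 9L) "exhaustive" else "heuristic"
  if (method == "exhaustive" && n_taxa(m) > 9L) {
    stop("exhaustive support computation limited to 9 taxa")
  }
  method
}

reference_search <- function(m, config, method, tables = NULL) {
  if (method == "exhaustive") {
    exhaustive_search(m, margin = 0L, tables = tables)
  } else {
    heuristic_search(m, config)
  }
}

consensus_keys <- function(search) Reduce(intersect, search$keys)

#' The published clade-significance rule
#'
#' A clade is called statistically significant when it is simultaneously
#' supported by a bootstrap value greater than 80% and a Bremer (decay)
#' value greater than 3. Both comparisons are strict: bootstrap = 80 or
#' Bremer = 3 do not qualify.
#'
#' @param bootstrap_pct bootstrap percentages in \[0, 100\].
#' @param bremer Bremer decay values (non-negative integers).
#' @return Logical vector.
#' @export
significance_rule <- function(bootstrap_pct, bremer) {
  bootstrap_pct > 80 & bremer > 3
}

new_support_table <- function(df, reference, m, n_pseudoreplicates = NA) {
  structure(df, class = c("support_table", "data.frame"),
            reference = reference, taxa = m$taxa,
            n_pseudoreplicates = n_pseudoreplicates)
}

#' @export
print.support_table <- function(x, ...) {
  cat("Clade support table (", nrow(x), " clades",
      if (!is.na(attr(x, "n_pseudoreplicates")))
        paste0(", ", attr(x, "n_pseudoreplicates"), " pseudoreplicates"),
      ")\n", sep = "")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Bootstrap clade support
#'
#' Standard nonparametric bootstrap over characters: each pseudoreplicate
#' resamples `n_chars` columns with replacement, the resampled matrix is
#' analysed (exactly, via the exhaustive tables, on <= 9 taxa; otherwise by a
#' reduced heuristic search), and a clade is counted when it appears in the
#' pseudoreplicate's strict consensus. The reported percentage is
#' `100 * count / n_pseudoreplicates` for every clade of the reference strict
#' consensus (clades absent from it are, by convention, unsupported).
#'
#' @param m a [character_matrix()].
#' @param n_pseudoreplicates number of bootstrap pseudoreplicates.
#' @param seed seed governing resampling (and derived search seeds).
#' @param config [search_config()] used for heuristic searches.
#' @param method `"auto"`, `"exhaustive"` or `"heuristic"`.
#' @param reference optional precomputed unconstrained `mp_search`.
#' @param tables optional precomputed exhaustive tables (internal reuse).
#' @return A `support_table` data frame: `clade` (canonical key), `taxa`
#'   (comma-separated terminals), `bootstrap_pct`.
#' @export
bootstrap_support <- function(m, n_pseudoreplicates = 100L, seed = 1L,
                              config = search_config(),
                              method = c("auto", "exhaustive", "heuristic"),
                              reference = NULL, tables = NULL) {
  stopifnot(n_pseudoreplicates >= 1L)
  method <- support_method(method, m)
  if (method == "exhaustive" && is.null(tables)) tables <- ex_tables(m)
  if (is.null(reference)) {
    reference <- reference_search(m, config, method, tables)
  }
  ref_keys <- consensus_keys(reference)
  counts <- setNames(numeric(length(ref_keys)), ref_keys)
  nc <- n_chars(m)
  if (method == "exhaustive") {
    W <- with_seed(seed, {
      vapply(seq_len(n_pseudoreplicates),
             function(i) tabulate(sample.int(nc, nc, replace = TRUE), nc),
             integer(nc))
    })
    chunk <- 256L
    starts <- seq(1L, n_pseudoreplicates, by = chunk)
    for (s0 in starts) {
      cols <- s0:min(s0 + chunk - 1L, n_pseudoreplicates)
      TOT <- tables$L %*% W[, cols, drop = FALSE]
      for (j in seq_along(cols)) {
        tot <- TOT[, j]
        opt <- which(tot == min(tot))
        pk <- psr_consensus_keys(tables$splits, opt)
        counts <- counts + (ref_keys %in% pk)
      }
    }
  } else {
    sub_seeds <- seed_stream(seed, 2L * n_pseudoreplicates)
    for (i in seq_len(n_pseudoreplicates)) {
      w <- with_seed(sub_seeds[i],
                     tabulate(sample.int(nc, nc, replace = TRUE), nc))
      cfg <- config
      cfg$seed <- sub_seeds[n_pseudoreplicates + i]
      s <- heuristic_search(m, cfg, weights = w)
      counts <- counts + (ref_keys %in% consensus_keys(s))
    }
  }
  df <- data.frame(
    clade = ref_keys,
    taxa = vapply(ref_keys, function(k)
      paste(key_taxa(k, m$taxa), collapse = ","), ""),
    bootstrap_pct = 100 * as.numeric(counts) / n_pseudoreplicates,
    stringsAsFactors = FALSE
  )
  new_support_table(df, reference, m, n_pseudoreplicates)
}

# Strict-consensus split keys of a set of enumerated topologies.
psr_consensus_keys <- function(splits, opt) {
  if (length(opt) == 1L) return(splits[[opt]])
  ks <- unlist(splits[opt], use.names = FALSE)
  tab <- table(ks)
  names(tab)[tab == length(opt)]
}

#' Bremer (decay) support of a clade
#'
#' The number of extra steps needed by the shortest tree *not* containing the
#' clade: `L(best without clade) - L(best)`. Returns 0 when the clade is
#' absent from the strict consensus of the unconstrained optimal trees (an
#' unsupported clade, by convention). On small instances the constrained
#' optimum is found by exhaustive enumeration; otherwise by a
#' converse-constrained heuristic search that rejects every tree containing
#' the clade. A `"buffer"` method (decay read from the suboptimal tree buffer
#' of a single search, capped by its margin) is available as a cross-check.
#'
#' @param m a [character_matrix()].
#' @param clade character vector of the clade's terminal taxa.
#' @param config [search_config()] for heuristic searches.
#' @param method `"auto"`, `"exhaustive"`, `"heuristic"` or `"buffer"`.
#' @param reference optional precomputed unconstrained `mp_search`.
#' @param tables optional precomputed exhaustive tables.
#' @return A single non-negative number.
#' @export
bremer_support <- function(m, clade, config = search_config(),
                           method = c("auto", "exhaustive", "heuristic",
                                      "buffer"),
                           reference = NULL, tables = NULL) {
  method0 <- match.arg(method)
  key <- clade_key(m, clade)
  if (method0 == "buffer") {
    cfg <- config
    if (cfg$suboptimal_margin < 1L) cfg$suboptimal_margin <- 3L
    s <- heuristic_search(m, cfg)
    opt_keys <- Reduce(intersect, s$keys[s$lengths == s$best_length])
    if (!key %in% opt_keys) return(0)
    lacking <- !vapply(s$keys, function(ks) key %in% ks, TRUE)
    if (!any(lacking)) return(NA_real_)   # decay exceeds the buffer margin
    return(min(s$lengths[lacking]) - s$best_length)
  }
  method <- support_method(method0, m)
  if (method == "exhaustive" && is.null(tables)) tables <- ex_tables(m)
  if (is.null(reference)) {
    reference <- reference_search(m, config, method, tables)
  }
  if (!key %in% consensus_keys(reference)) return(0)
  if (method == "exhaustive") {
    tot <- rowSums(tables$L)
    lack <- !vapply(tables$splits, function(ks) key %in% ks, TRUE)
    min(tot[lack]) - min(tot)
  } else {
    cfg <- config
    cfg$seed <- seed_stream(config$seed, 1L)
    s2 <- heuristic_search(m, cfg, forbid = clade)
    s2$best_length - reference$best_length
  }
}

#' Full clade-support table
#'
#' Runs the unconstrained search, takes the strict consensus, computes
#' bootstrap and Bremer support for every consensus clade and applies the
#' significance rule.
#'
#' @inheritParams bootstrap_support
#' @return A `support_table` data frame with columns `clade`, `taxa`,
#'   `bootstrap_pct`, `bremer`, `significant`; the reference consensus tree
#'   is attached as attribute `"reference_tree"`.
#' @export
support_table <- function(m, config = search_config(),
                          n_pseudoreplicates = 100L, seed = 1L,
                          method = c("auto", "exhaustive", "heuristic")) {
  method <- support_method(method, m)
  tables <- if (method == "exhaustive") ex_tables(m) else NULL
  reference <- reference_search(m, config, method, tables)
  bs <- bootstrap_support(m, n_pseudoreplicates, seed, config, method,
                          reference = reference, tables = tables)
  ref_keys <- bs$clade
  br <- vapply(ref_keys, function(k) {
    bremer_support(m, key_taxa(k, m$taxa), config, method,
                   reference = reference, tables = tables)
  }, 0)
  df <- data.frame(clade = ref_keys, taxa = bs$taxa,
                   bootstrap_pct = bs$bootstrap_pct,
                   bremer = as.numeric(br),
                   significant = significance_rule(bs$bootstrap_pct, br),
                   stringsAsFactors = FALSE)
  out <- new_support_table(df, reference, m, n_pseudoreplicates)
  attr(out, "reference_tree") <- strict_consensus(reference)
  out
}
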