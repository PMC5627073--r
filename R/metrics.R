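# Contribution of a character-type partition to clade support (Cs) and to
# divergence within a clade (Cd).
#
# For character type i and a clade: S_plus is the clade's support when only
# the type-i characters are analysed, S_minus when all but the type-i
# characters are analysed; Cs_i = S_plus - S_minus. D_plus / D_minus are the
# sums of support over resolved branches strictly inside the clade in the
# same two analyses, and Cd_i = (D_plus - D_minus) / (n - 1) with n the
# number of terminal taxa in the clade. A clade absent from an analysis's
# strict consensus has support 0 in that analysis. Both metrics are computed
# on the Bremer and the bootstrap basis; the combined verdict is positive if
# any basis gives a positive value.

# Run the full search + support pipeline on one matrix subset. Returns the
# consensus split keys, bootstrap percentages and a memoised Bremer lookup
# for arbitrary consensus splits.
analyze_subset <- function(sub, config, n_pseudoreplicates, seed, method,
                           tables = NULL) {
  method <- support_method(method, sub)
  if (method == "exhaustive" && is.null(tables)) tables <- ex_tables(sub)
  search <- reference_search(sub, config, method, tables)
  ck <- consensus_keys(search)
  boot <- bootstrap_support(sub, n_pseudoreplicates, seed, config, method,
                            reference = search, tables = tables)
  bootv <- setNames(boot$bootstrap_pct, boot$clade)
  cache <- new.env(parent = emptyenv())
  bremer_of <- function(key) {
    if (!key %in% ck) return(0)
    if (!is.null(cache[[key]])) return(cache[[key]])
    v <- bremer_support(sub, key_taxa(key, sub$taxa), config, method,
                        reference = search, tables = tables)
    cache[[key]] <- v
    v
  }
  list(search = search, cons = ck, boot = bootv, bremer = bremer_of,
       taxa = sub$taxa)
}

subset_support <- function(ans, key, basis) {
  if (!key %in% ans$cons) return(0)
  if (basis == "bremer") ans$bremer(key) else unname(ans$boot[key])
}

# Sum of support over resolved branches strictly inside the clade (the stem
# split equal to the clade itself is excluded unless include_stem).
divergence_sum <- function(ans, clade_idx, basis, include_stem = FALSE) {
  n_all <- length(ans$taxa)
  total <- 0
  for (k in ans$cons) {
    side <- key_side(k)
    comp <- setdiff(seq_len(n_all), side)
    inside <- if (all(side %in% clade_idx)) side
              else if (all(comp %in% clade_idx)) comp
              else next
    if (!include_stem && length(inside) == length(clade_idx)) next
    total <- total + subset_support(ans, k, basis)
  }
  total
}

#' Clade support from a partitioned analysis
#'
#' Subsets the matrix to one character type (`mode = "include"`) or its
#' complement (`mode = "exclude"`), runs the full search + support pipeline
#' on the subset, and returns the clade's support on the requested basis
#' (0 when the clade is absent from the subset analysis's strict consensus).
#'
#' @param m a [character_matrix()].
#' @param partition a [character_partition()].
#' @param type_name character type to include / exclude.
#' @param mode `"include"` or `"exclude"`.
#' @param clade character vector of the clade's terminal taxa.
#' @param basis `"bremer"` or `"bootstrap"`.
#' @param config [search_config()] for heuristic searches.
#' @param n_pseudoreplicates bootstrap pseudoreplicates.
#' @param seed master seed of the sub-analysis.
#' @param method support backend, see [bootstrap_support()].
#' @return A single support value (Bremer steps or bootstrap percent).
#' @export
clade_support_under_partition <- function(m, partition, type_name,
                                          mode = c("include", "exclude"),
                                          clade,
                                          basis = c("bremer", "bootstrap"),
                                          config = search_config(),
                                          n_pseudoreplicates = 100L,
                                          seed = 1L,
                                          method = "auto") {
  mode <- match.arg(mode)
  basis <- match.arg(basis)
  sub <- subset_matrix(m, partition, type_name, mode)
  ans <- analyze_subset(sub, config, n_pseudoreplicates, seed, method)
  subset_support(ans, clade_key(sub, clade), basis)
}

metric_engine <- function(m, partition, clades, config, n_pseudoreplicates,
                          seed, method, include_stem, types = NULL) {
  stopifnot(inherits(m, "char_matrix"), inherits(partition, "char_partition"))
  if (is.null(names(clades)) && length(clades)) {
    names(clades) <- paste0("clade", seq_along(clades))
  }
  for (cl in clades) clade_key(m, cl)   # validate taxa early
  types <- types %||% names(partition)
  if (!length(clades)) {
    return(structure(
      data.frame(clade = character(0), type = character(0),
                 basis = character(0), S_plus = numeric(0),
                 S_minus = numeric(0), cs = numeric(0),
                 D_plus = numeric(0), D_minus = numeric(0),
                 n = integer(0), cd = numeric(0),
                 cs_positive_overall = logical(0),
                 cd_positive_overall = logical(0)),
      class = c("contribution_table", "data.frame")))
  }
  method <- support_method(method, m)
  tables_full <- if (method == "exhaustive") ex_tables(m) else NULL
  seeds <- seed_stream(seed, 2L * length(types))
  bases <- c("bremer", "bootstrap")
  rows <- list()
  for (ti in seq_along(types)) {
    tp <- types[ti]
    ans <- list()
    for (mi in 1:2) {
      mode <- c("include", "exclude")[mi]
      sub <- subset_matrix(m, partition, tp, mode)
      tb <- if (!is.null(tables_full)) {
        idx <- if (mode == "include") sort(partition[[tp]]) else
          setdiff(seq_len(n_chars(m)), partition[[tp]])
        list(topos = tables_full$topos, splits = tables_full$splits,
             L = tables_full$L[, sort(idx), drop = FALSE], n = tables_full$n)
      } else NULL
      ans[[mode]] <- analyze_subset(sub, config, n_pseudoreplicates,
                                    seeds[2L * (ti - 1L) + mi], method,
                                    tables = tb)
    }
    for (cn in names(clades)) {
      cl <- clades[[cn]]
      key <- clade_key(m, cl)
      idx <- key_side(key)
      cl_idx <- if (setequal(m$taxa[idx], cl)) idx else
        setdiff(seq_len(n_taxa(m)), idx)
      n_in <- length(cl)
      for (b in bases) {
        sp <- subset_support(ans$include, key, b)
        sm <- subset_support(ans$exclude, key, b)
        dp <- divergence_sum(ans$include, cl_idx, b, include_stem)
        dm <- divergence_sum(ans$exclude, cl_idx, b, include_stem)
        rows[[length(rows) + 1L]] <- data.frame(
          clade = cn, type = tp, basis = b,
          S_plus = sp, S_minus = sm, cs = sp - sm,
          D_plus = dp, D_minus = dm, n = n_in,
          cd = (dp - dm) / (n_in - 1),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  df <- do.call(rbind, rows)
  if (is.null(df)) {
    df <- data.frame(clade = character(0), type = character(0),
                     basis = character(0), S_plus = numeric(0),
                     S_minus = numeric(0), cs = numeric(0),
                     D_plus = numeric(0), D_minus = numeric(0),
                     n = integer(0), cd = numeric(0))
  }
  # any-positive combination across bases, per clade x type
  grp <- paste(df$clade, df$type)
  cs_pos <- tapply(df$cs > 0, grp, any)
  cd_pos <- tapply(df$cd > 0, grp, any)
  df$cs_positive_overall <- as.logical(cs_pos[grp])
  df$cd_positive_overall <- as.logical(cd_pos[grp])
  structure(df, class = c("contribution_table", "data.frame"))
}

#' Cs: contribution of a character type to a clade's support
#'
#' `Cs_i = S_plus - S_minus`, the change in the clade's support between the
#' analysis using only the type-i characters and the analysis using all but
#' the type-i characters. Positive values mean the type contributes support.
#'
#' @inheritParams clade_support_under_partition
#' @param basis `"both"` (default), `"bremer"` or `"bootstrap"`.
#' @return A `contribution_table` data frame with one row per basis.
#' @export
cs_metric <- function(m, partition, type_name, clade,
                      basis = c("both", "bremer", "bootstrap"),
                      config = search_config(), n_pseudoreplicates = 100L,
                      seed = 1L, method = "auto") {
  basis <- match.arg(basis)
  df <- metric_engine(m, partition, list(clade = clade), config,
                      n_pseudoreplicates, seed, method,
                      include_stem = FALSE, types = type_name)
  if (basis != "both") df <- df[df$basis == basis, , drop = FALSE]
  df[, c("clade", "type", "basis", "S_plus", "S_minus", "cs",
         "cs_positive_overall")]
}

#' Cd: contribution of a character type to divergence within a clade
#'
#' `Cd_i = D_plus / (n - 1) - D_minus / (n - 1)`, where `D_plus`/`D_minus`
#' sum the support of resolved branches strictly inside the clade in the
#' only-type-i and all-but-type-i analyses and `n` is the number of terminal
#' taxa in the clade. For a 2-taxon clade there are no internal branches and
#' `Cd = 0` by construction. Setting `include_stem = TRUE` also counts the
#' clade's own stem branch in the sums (the default excludes it: the stem's
#' support is the clade's own support, already measured by Cs).
#'
#' @inheritParams cs_metric
#' @param include_stem count the clade's stem branch in the D sums.
#' @return A `contribution_table` data frame with one row per basis.
#' @export
cd_metric <- function(m, partition, type_name, clade,
                      basis = c("both", "bremer", "bootstrap"),
                      config = search_config(), n_pseudoreplicates = 100L,
                      seed = 1L, method = "auto", include_stem = FALSE) {
  basis <- match.arg(basis)
  df <- metric_engine(m, partition, list(clade = clade), config,
                      n_pseudoreplicates, seed, method,
                      include_stem = include_stem, types = type_name)
  if (basis != "both") df <- df[df$basis == basis, , drop = FALSE]
  df[, c("clade", "type", "basis", "D_plus", "D_minus", "n", "cd",
         "cd_positive_overall")]
}

#' Full contribution table: every clade x type x basis
#'
#' Computes Cs and Cd for every combination of the named clades, the
#' partition's character types and both support bases, in long format. All
#' sub-analyses derive their seeds deterministically from `seed`, so the
#' whole table is reproducible from one integer.
#'
#' @inheritParams cs_metric
#' @param clades named list of character vectors (terminal taxa per clade).
#' @param include_stem count each clade's stem branch in the D sums.
#' @return A `contribution_table` data frame with columns `clade`, `type`,
#'   `basis`, `S_plus`, `S_minus`, `cs`, `D_plus`, `D_minus`, `n`, `cd`,
#'   `cs_positive_overall`, `cd_positive_overall`.
#' @export
contribution_table <- function(m, partition, clades,
                               config = search_config(),
                               n_pseudoreplicates = 100L, seed = 1L,
                               method = "auto", include_stem = FALSE) {
  metric_engine(m, partition, clades, config, n_pseudoreplicates, seed,
                method, include_stem)
}

#' @export
print.contribution_table <- function(x, ...) {
  cat("Character-type contribution table (", nrow(x), " rows)\n", sep = "")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
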