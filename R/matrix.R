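#' Discrete morphological character matrix
#'
#' Container for a taxa x characters matrix of discrete, unordered character
#' states. States are stored internally as bitmasks so that polymorphic cells
#' (e.g. `(01)` in NEXUS) and unknown cells (`?` or `-`, both treated as
#' missing) are handled natively by the parsimony engine: a missing cell
#' behaves as the set of all states observed in that character's column.
#'
#' @param x a character matrix of state tokens (single symbols, `"?"`/`"-"`
#'   for unknown, or `"(01)"` / `"{01}"` for polymorphic cells), or an integer
#'   matrix of state codes with `NA` for unknown.
#' @param taxa taxon labels; defaults to `rownames(x)`. Must be unique,
#'   non-empty strings, compared case-sensitively.
#' @param symbols ordered state symbols; symbol `i` maps to state code
#'   `i - 1`. Defaults to `"0"`-`"9"`.
#' @param char_index original 1-based character (column) indices, kept as
#'   metadata when a matrix is subset by character type.
#'
#' @return An object of class `char_matrix` with elements `taxa`, `states`
#'   (integer bitmask matrix), `symbols` and `char_index`.
#'
#' @details A character column in which every cell is unknown carries no
#'   information and is rejected. Note the field convention of numbering
#'   characters from 0 in print: in R, columns are addressed 1-based; the
#'   plain-text partition format accepted by [read_partition()] uses 0-based
#'   ranges while NEXUS `charset` lines use the NEXUS-standard 1-based ones.
#'
#' @seealso [read_nexus()], [subset_matrix()], [fitch_length()]
#' @export
character_matrix <- function(x, taxa = rownames(x),
                             symbols = as.character(0:9),
                             char_index = NULL) {
  if (is.null(taxa)) stop("taxon labels are required (rownames or `taxa`)")
  taxa <- as.character(taxa)
  if (anyDuplicated(taxa)) {
    stop("duplicate taxon label: ", taxa[duplicated(taxa)][1L])
  }
  if (any(!nzchar(taxa))) stop("empty taxon label")
  if (length(taxa) != nrow(x)) stop("taxa length does not match rows")
  if (is.numeric(x)) {
    if (any(x < 0, na.rm = TRUE)) stop("negative state code")
    if (any(x >= length(symbols), na.rm = TRUE)) {
      stop("state code outside the symbol alphabet")
    }
    states <- matrix(0L, nrow(x), ncol(x))
    ok <- !is.na(x)
    states[ok] <- bitwShiftL(1L, as.integer(x[ok]))
  } else if (is.character(x)) {
    states <- matrix(vapply(x, parse_state_token, 0L, symbols = symbols),
                     nrow(x), ncol(x))
  } else {
    stop("`x` must be a character or integer matrix")
  }
  obs <- column_alphabet(states)
  if (any(obs == 0L)) {
    stop("character column(s) entirely unknown: ",
         paste(which(obs == 0L), collapse = ", "))
  }
  if (is.null(char_index)) char_index <- seq_len(ncol(states))
  rownames(states) <- taxa
  structure(
    list(taxa = taxa, states = states, symbols = symbols,
         char_index = as.integer(char_index)),
    class = "char_matrix"
  )
}

parse_state_token <- function(tok, symbols) {
  tok <- trimws(tok)
  if (tok %in% c("?", "-")) return(0L)
  if (grepl("^[({].*[})]$", tok)) {
    tok <- substr(tok, 2L, nchar(tok) - 1L)
    syms <- strsplit(gsub("[ ,]", "", tok), "")[[1L]]
  } else {
    syms <- tok
  }
  idx <- match(syms, symbols)
  if (anyNA(idx) || length(idx) == 0L) {
    stop("state symbol not in the declared alphabet: '", tok, "'")
  }
  mask <- 0L
  for (i in idx) mask <- bitwOr(mask, bitwShiftL(1L, i - 1L))
  mask
}

# Bitmask of states observed per column (union over non-missing cells).
column_alphabet <- function(states) {
  obs <- integer(ncol(states))
  for (r in seq_len(nrow(states))) obs <- bitwOr(obs, states[r, ])
  obs
}

# Missing-expanded masks: unknown cells become the column's observed alphabet.
cm_masks <- function(m) {
  st <- m$states
  obs <- column_alphabet(st)
  miss <- st == 0L
  if (any(miss)) {
    st[miss] <- matrix(obs, nrow(st), ncol(st), byrow = TRUE)[miss]
  }
  st
}

# Number of bit positions needed to cover every observed state.
cm_nstates <- function(m) {
  mx <- max(column_alphabet(m$states))
  s <- 0L
  while (bitwShiftR(mx, s) > 0L) s <- s + 1L
  max(s, 1L)
}

#' @export
print.char_matrix <- function(x, ...) {
  cat("Character matrix:", n_taxa(x), "taxa x", n_chars(x), "characters\n")
  inf <- parsimony_informative(x)
  cat("  parsimony-informative characters:", sum(inf), "\n")
  nshow <- min(5L, n_taxa(x))
  tok <- state_tokens(x)
  for (i in seq_len(nshow)) {
    row <- paste(tok[i, seq_len(min(40L, n_chars(x)))], collapse = "")
    cat(sprintf("  %-20s %s%s\n", x$taxa[i], row,
                if (n_chars(x) > 40L) "..." else ""))
  }
  if (n_taxa(x) > nshow) cat("  ...\n")
  invisible(x)
}

#' Matrix dimensions
#'
#' @param m a `char_matrix`.
#' @return Integer count of taxa (rows) or characters (columns).
#' @export
n_taxa <- function(m) length(m$taxa)

#' @rdname n_taxa
#' @export
n_chars <- function(m) ncol(m$states)

# Symbolic tokens for writing/printing (inverse of parse_state_token).
state_tokens <- function(m) {
  st <- m$states
  out <- matrix("?", nrow(st), ncol(st))
  for (s in seq_along(m$symbols)) {
    bit <- bitwShiftL(1L, s - 1L)
    one <- st == bit
    out[one] <- m$symbols[s]
  }
  multi <- which(st != 0L & bitwAnd(st, st - 1L) != 0L)
  for (i in multi) {
    bits <- which(bitwAnd(bitwShiftR(st[i], seq_along(m$symbols) - 1L), 1L) == 1L)
    out[i] <- paste0("(", paste(m$symbols[bits], collapse = ""), ")")
  }
  rownames(out) <- m$taxa
  out
}

#' Identify parsimony-informative characters
#'
#' A character is parsimony-informative when at least two states are each
#' present (unambiguously) in at least two taxa; constant characters and
#' autapomorphies carry no grouping signal and always score the same number
#' of steps on every tree.
#'
#' @param m a `char_matrix`.
#' @return Logical vector, one entry per character.
#' @export
parsimony_informative <- function(m) {
  st <- m$states
  vapply(seq_len(ncol(st)), function(j) {
    col <- st[, j]
    col <- col[col != 0L & bitwAnd(col, col - 1L) == 0L]  # resolved cells
    sum(table(col) >= 2L) >= 2L
  }, logical(1L))
}

#' Subset a matrix by character type
#'
#' Keeps exactly the columns belonging to (`mode = "include"`) or outside
#' (`mode = "exclude"`) the given character type. Taxa are unchanged; the
#' original column indices are retained in `char_index`.
#'
#' @param m a `char_matrix`.
#' @param partition a `char_partition` over the matrix columns.
#' @param type_name a type label present in the partition.
#' @param mode `"include"` or `"exclude"`.
#' @return A `char_matrix` with the selected columns.
#' @export
subset_matrix <- function(m, partition, type_name,
                          mode = c("include", "exclude")) {
  mode <- match.arg(mode)
  stopifnot(inherits(m, "char_matrix"), inherits(partition, "char_partition"))
  if (attr(partition, "n_chars") != n_chars(m)) {
    stop("partition covers ", attr(partition, "n_chars"),
         " characters but the matrix has ", n_chars(m))
  }
  if (!type_name %in% names(partition)) {
    stop("unknown character type: '", type_name, "'")
  }
  idx <- partition[[type_name]]
  if (mode == "exclude") idx <- setdiff(seq_len(n_chars(m)), idx)
  idx <- sort(idx)
  if (length(idx) == 0L) stop("subset would leave 0 characters")
  out <- m
  out$states <- m$states[, idx, drop = FALSE]
  out$char_index <- m$char_index[idx]
  out
}

#' Character-type partition
#'
#' Assigns every character column to exactly one named type (e.g. general
#' external characters, copulatory organs, photophores). The assignment must
#' be total: every column of the matrix belongs to exactly one type.
#'
#' @param types named list of integer vectors of 1-based column indices.
#' @param n_chars total number of characters the partition must cover.
#' @return An object of class `char_partition`: the named list of sorted
#'   index vectors with an `n_chars` attribute.
#' @export
character_partition <- function(types, n_chars) {
  if (is.null(names(types)) || any(!nzchar(names(types)))) {
    stop("every character type needs a name")
  }
  if (anyDuplicated(names(types))) stop("duplicate type name")
  types <- lapply(types, function(v) sort(unique(as.integer(v))))
  if (any(lengths(types) == 0L)) stop("empty character type")
  all_idx <- unlist(types, use.names = FALSE)
  if (anyDuplicated(all_idx)) {
    stop("overlapping types: character(s) ",
         paste(unique(all_idx[duplicated(all_idx)]), collapse = ", "),
         " assigned more than once")
  }
  if (any(all_idx < 1L) || any(all_idx > n_chars)) {
    stop("character index outside 1..", n_chars)
  }
  missing_idx <- setdiff(seq_len(n_chars), all_idx)
  if (length(missing_idx)) {
    stop("characters not assigned to any type (1-based): ",
         paste(missing_idx, collapse = ", "))
  }
  structure(types, n_chars = as.integer(n_chars), class = "char_partition")
}

#' @export
print.char_partition <- function(x, ...) {
  cat("Character partition over", attr(x, "n_chars"), "characters\n")
  for (nm in names(x)) {
    cat(sprintf("  %-14s %d characters\n", nm, length(x[[nm]])))
  }
  invisible(x)
}

#' The Sergestoidea three-type partition as printed
#'
#' The published character-type ranges for the sergestoid shrimp matrix:
#' general external characters 0-115, copulatory organs 116-189, photophores
#' 190-248 (0-based, as printed; 249 characters in total). Provided for
#' documentation and as a convenient default; the full study matrix has 253
#' characters, so analyses of the real data should load the partition from
#' its character list rather than rely on these ranges.
#'
#' @return A `char_partition` over 249 characters.
#' @export
sergestoid_partition <- function() {
  character_partition(
    list(general = 1:116, copulatory = 117:190, photophores = 191:249),
    n_chars = 249L
  )
}

#' Export a matrix as a data frame of state tokens
#'
#' @param x a `char_matrix`.
#' @param row.names,optional,... passed on / ignored (S3 signature).
#' @return A data frame: `taxon` column plus one character column per
#'   matrix column, named by original character index.
#' @export
as.data.frame.char_matrix <- function(x, row.names = NULL, optional = FALSE, ...) {
  tok <- state_tokens(x)
  df <- data.frame(taxon = x$taxa, tok, stringsAsFactors = FALSE,
                   row.names = row.names)
  names(df)[-1L] <- paste0("c", x$char_index)
  df
}

#' Write the matrix as tab-separated text
#'
#' Debug-friendly plain export: taxon label then one column per character.
#'
#' @param m a `char_matrix`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path) {
  utils::write.table(as.data.frame(m), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
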