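# NEXUS character-matrix and SETS/charset I/O. Newick and TREES blocks are
# delegated to ape. The matrix parser is written here because standard R
# readers do not honour FORMAT SYMBOLS order, polymorphic "(01)" cells or
# SETS blocks, all of which this package needs.

strip_nexus_comments <- function(lines) {
  depth <- 0L
  out <- character(length(lines))
  for (i in seq_along(lines)) {
    chars <- strsplit(lines[i], "", fixed = TRUE)[[1L]]
    keep <- character(0)
    for (ch in chars) {
      if (ch == "[") depth <- depth + 1L
      else if (ch == "]") depth <- max(0L, depth - 1L)
      else if (depth == 0L) keep <- c(keep, ch)
    }
    out[i] <- paste(keep, collapse = "")
  }
  out
}

#' Read a character matrix from a NEXUS file
#'
#' Parses the `DATA` or `CHARACTERS` block of a NEXUS file into a
#' [character_matrix()]. State symbols are mapped to integer codes by the
#' file's `FORMAT SYMBOLS` order (default `"0123456789"`); the missing
#' (`?`) and gap (`-`) symbols are both treated as unknown; polymorphic
#' cells written `(01)` or `{01}` become state sets. Both interleaved and
#' non-interleaved matrices are supported; taxon labels are case-preserved
#' and compared case-sensitively.
#'
#' @param path path to a NEXUS file containing a DATA/CHARACTERS block.
#' @return A [character_matrix()].
#' @examples
#' f <- tempfile(fileext = ".nex")
#' writeLines(c("#NEXUS", "BEGIN DATA;",
#'   "DIMENSIONS NTAX=4 NCHAR=3;",
#'   "FORMAT DATATYPE=STANDARD MISSING=? GAP=- SYMBOLS=\"01\";",
#'   "MATRIX", "taxA 001", "taxB 011", "taxC 0?1", "taxD 110", ";",
#'   "END;"), f)
#' m <- read_nexus(f)
#' n_taxa(m); n_chars(m)
#' @export
read_nexus <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readLines(path, warn = FALSE)
  if (!length(raw) || !grepl("^\\s*#nexus", tolower(raw[1L]))) {
    stop("not a NEXUS file (missing #NEXUS header): ", path)
  }
  lines <- strip_nexus_comments(raw)
  low <- tolower(lines)

  beg <- grep("^\\s*begin\\s+(data|characters)\\s*;", low)
  if (!length(beg)) stop("no DATA or CHARACTERS block in ", path)
  beg <- beg[1L]
  ends <- grep("^\\s*end\\s*;", low)
  blockend <- ends[ends > beg][1L]
  if (is.na(blockend)) stop("unterminated DATA block (line ", beg, ")")
  block <- lines[(beg + 1L):(blockend - 1L)]
  blow <- tolower(block)

  getcmd <- function(name) {
    i <- grep(paste0("^\\s*", name, "\\b"), blow)
    if (!length(i)) return(NULL)
    # a command runs to its terminating ';'
    j <- i[1L]
    txt <- block[j]
    while (!grepl(";", txt) && j < length(block)) {
      j <- j + 1L
      txt <- paste(txt, block[j])
    }
    txt
  }

  dim_cmd <- getcmd("dimensions")
  if (is.null(dim_cmd)) stop("DIMENSIONS command missing (line ", beg, ")")
  ntax <- as.integer(sub(".*ntax\\s*=\\s*(\\d+).*", "\\1",
                         tolower(dim_cmd), perl = TRUE))
  nchar_ <- as.integer(sub(".*nchar\\s*=\\s*(\\d+).*", "\\1",
                           tolower(dim_cmd), perl = TRUE))
  if (is.na(ntax) || is.na(nchar_)) {
    stop("cannot parse NTAX/NCHAR from: ", trimws(dim_cmd))
  }

  symbols <- as.character(0:9)
  missing_sym <- "?"; gap_sym <- "-"
  fmt <- getcmd("format")
  if (!is.null(fmt)) {
    sm <- regmatches(fmt, regexpr('symbols\\s*=\\s*"[^"]*"', tolower(fmt)))
    if (length(sm)) {
      raw_syms <- sub('^[^"]*"', "", regmatches(fmt, regexpr('(?i)symbols\\s*=\\s*"[^"]*"', fmt, perl = TRUE)))
      raw_syms <- sub('"$', "", raw_syms)
      symbols <- strsplit(gsub("\\s", "", raw_syms), "")[[1L]]
    }
    mm <- regmatches(tolower(fmt), regexpr("missing\\s*=\\s*\\S", tolower(fmt)))
    if (length(mm)) missing_sym <- substr(mm, nchar(mm), nchar(mm))
    gm <- regmatches(tolower(fmt), regexpr("gap\\s*=\\s*\\S", tolower(fmt)))
    if (length(gm)) gap_sym <- substr(gm, nchar(gm), nchar(gm))
  }

  mline <- grep("^\\s*matrix\\b", blow)
  if (!length(mline)) stop("MATRIX command missing in DATA block of ", path)
  mstart <- mline[1L] + 1L
  rows <- list()
  i <- mstart
  done <- FALSE
  while (i <= length(block)) {
    txt <- trimws(block[i])
    if (grepl("^;", txt)) { done <- TRUE; break }
    hit_end <- grepl(";\\s*$", txt)
    txt <- sub(";\\s*$", "", txt)
    if (nzchar(txt)) {
      lineno <- beg + i
      parsed <- parse_matrix_row(txt, symbols, missing_sym, gap_sym, lineno)
      lab <- parsed$label
      if (!is.null(rows[[lab]]) && length(rows[[lab]]) >= nchar_) {
        stop("duplicate taxon '", lab, "' (line ", lineno, ")")
      }
      rows[[lab]] <- c(rows[[lab]], parsed$tokens)
    }
    if (hit_end) { done <- TRUE; break }
    i <- i + 1L
  }
  if (!done) stop("MATRIX not terminated by ';' in ", path)
  if (length(rows) != ntax) {
    stop("matrix has ", length(rows), " taxa but DIMENSIONS declares ", ntax)
  }
  bad <- names(rows)[lengths(rows) != nchar_]
  if (length(bad)) {
    stop("row length mismatch (expected ", nchar_, " characters) for: ",
         paste(bad, collapse = ", "))
  }
  tok <- do.call(rbind, rows)
  character_matrix(tok, taxa = names(rows), symbols = symbols)
}

parse_matrix_row <- function(txt, symbols, missing_sym, gap_sym, lineno) {
  # taxon label: quoted or first whitespace-delimited token
  if (grepl("^'", txt)) {
    close <- regexpr("'", substring(txt, 2L), fixed = TRUE)
    if (close < 0) stop("unterminated quoted label (line ", lineno, ")")
    label <- substr(txt, 2L, close)
    rest <- substring(txt, close + 2L)
  } else {
    sp <- regexpr("\\s", txt)
    if (sp < 0) stop("matrix row without states (line ", lineno, "): ", txt)
    label <- substr(txt, 1L, sp - 1L)
    rest <- substring(txt, sp + 1L)
  }
  chars <- strsplit(rest, "", fixed = TRUE)[[1L]]
  tokens <- character(0)
  j <- 1L
  while (j <= length(chars)) {
    ch <- chars[j]
    if (grepl("^\\s$", ch)) { j <- j + 1L; next }
    if (ch %in% c("(", "{")) {
      closer <- if (ch == "(") ")" else "}"
      k <- j + 1L
      while (k <= length(chars) && chars[k] != closer) k <- k + 1L
      if (k > length(chars)) {
        stop("unclosed polymorphic state set (line ", lineno, ")")
      }
      inner <- chars[(j + 1L):(k - 1L)]
      inner <- inner[!inner %in% c(" ", ",")]
      if (!length(inner) || !all(inner %in% symbols)) {
        stop("invalid polymorphic state set (line ", lineno, "): (",
             paste(inner, collapse = ""), ")")
      }
      tokens <- c(tokens, paste0("(", paste(inner, collapse = ""), ")"))
      j <- k + 1L
    } else if (ch == missing_sym || ch == gap_sym) {
      tokens <- c(tokens, "?")
      j <- j + 1L
    } else if (ch %in% symbols) {
      tokens <- c(tokens, ch)
      j <- j + 1L
    } else {
      stop("symbol '", ch, "' outside the declared alphabet (line ",
           lineno, ")")
    }
  }
  list(label = label, tokens = tokens)
}

#' Read a character-type partition
#'
#' Two formats are accepted. A NEXUS file (`#NEXUS` header) is scanned for
#' `charset` lines in the NEXUS-standard **1-based** range notation, e.g.
#' `charset general = 1-116;`. Any other file is read as the plain-text
#' dialect: one type per line, `name<TAB or spaces>ranges`, where ranges are
#' comma-separated **0-based** inclusive spans exactly as printed in
#' character lists (e.g. `general 0-115`). Every character must be assigned
#' to exactly one type; unlisted or doubly listed indices are an error.
#'
#' @param path partition file.
#' @param n_chars number of characters the partition must cover.
#' @return A [character_partition()].
#' @export
read_partition <- function(path, n_chars) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readLines(path, warn = FALSE)
  types <- list()
  if (length(raw) && grepl("^\\s*#nexus", tolower(raw[1L]))) {
    lines <- strip_nexus_comments(raw)
    text <- paste(lines, collapse = "\n")
    stmts <- regmatches(text,
      gregexpr("(?i)charset\\s+[^=;]+=[^;]+;", text, perl = TRUE))[[1L]]
    if (!length(stmts)) stop("no charset definitions found in ", path)
    for (s in stmts) {
      nm <- trimws(sub("(?i)charset\\s+([^=]+)=.*", "\\1", s, perl = TRUE))
      body <- sub(";$", "", sub("^[^=]*=", "", s))
      types[[nm]] <- parse_index_ranges(body, n_chars, base = 1L)
    }
  } else {
    for (ln in raw) {
      ln <- trimws(sub("#.*$", "", ln))
      if (!nzchar(ln)) next
      sp <- regexpr("\\s", ln)
      if (sp < 0) stop("cannot parse partition line: ", ln)
      nm <- substr(ln, 1L, sp - 1L)
      body <- substring(ln, sp + 1L)
      types[[nm]] <- parse_index_ranges(body, n_chars, base = 0L)
    }
  }
  character_partition(types, n_chars)
}

parse_index_ranges <- function(body, n_chars, base) {
  parts <- trimws(strsplit(body, ",", fixed = TRUE)[[1L]])
  parts <- parts[nzchar(parts)]
  idx <- integer(0)
  for (p in parts) {
    # NEXUS also allows '.' for "last character"
    p <- gsub("\\.", as.character(n_chars - 1L + base), p)
    if (grepl("^\\d+\\s*-\\s*\\d+$", p)) {
      ab <- as.integer(strsplit(p, "-")[[1L]])
      if (ab[2L] < ab[1L]) stop("descending range: ", p)
      idx <- c(idx, seq(ab[1L], ab[2L]))
    } else if (grepl("^\\d+$", p)) {
      idx <- c(idx, as.integer(p))
    } else {
      stop("cannot parse character range: '", p, "'")
    }
  }
  idx + (1L - base)
}

#' Write a matrix (and optionally partition and trees) to NEXUS
#'
#' Writes a `DATA` block; a `SETS` block with 1-based `charset` lines when a
#' partition is given; and a `TREES` block (newick via ape) when trees are
#' given.
#'
#' @param m a [character_matrix()].
#' @param path output file.
#' @param partition optional [character_partition()].
#' @param trees optional `phylo` or `multiPhylo`.
#' @return `path`, invisibly.
#' @export
write_nexus <- function(m, path, partition = NULL, trees = NULL) {
  stopifnot(inherits(m, "char_matrix"))
  tok <- state_tokens(m)
  lab <- m$taxa
  quoted <- ifelse(grepl("\\s", lab), paste0("'", lab, "'"), lab)
  width <- max(nchar(quoted)) + 2L
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w("#NEXUS")
  w("BEGIN DATA;")
  w("  DIMENSIONS NTAX=", n_taxa(m), " NCHAR=", n_chars(m), ";")
  w("  FORMAT DATATYPE=STANDARD MISSING=? GAP=- SYMBOLS=\"",
    paste(m$symbols, collapse = ""), "\";")
  w("  MATRIX")
  for (i in seq_len(n_taxa(m))) {
    w("    ", formatC(quoted[i], width = -width),
      paste(tok[i, ], collapse = ""))
  }
  w("  ;")
  w("END;")
  if (!is.null(partition)) {
    w("BEGIN SETS;")
    for (nm in names(partition)) {
      w("  charset ", nm, " = ",
        paste(format_ranges(partition[[nm]]), collapse = " "), ";")
    }
    w("END;")
  }
  if (!is.null(trees)) {
    if (inherits(trees, "phylo")) trees <- list(trees)
    w("BEGIN TREES;")
    for (i in seq_along(trees)) {
      w("  TREE tree_", i, " = ",
        ape::write.tree(trees[[i]]))
    }
    w("END;")
  }
  invisible(path)
}

# Collapse sorted 1-based indices into NEXUS "a-b" range tokens.
format_ranges <- function(idx) {
  idx <- sort(idx)
  breaks <- c(0L, which(diff(idx) != 1L), length(idx))
  out <- character(0)
  for (k in seq_len(length(breaks) - 1L)) {
    a <- idx[breaks[k] + 1L]; b <- idx[breaks[k + 1L]]
    out <- c(out, if (a == b) as.character(a) else paste0(a, "-", b))
  }
  out
}

#' Read trees from a NEXUS TREES block
#'
#' Thin wrapper around [ape::read.nexus()] returning a list of unrooted,
#' normalized trees.
#'
#' @param path NEXUS file with a TREES block.
#' @return A `multiPhylo` list of trees.
#' @export
read_nexus_trees <- function(path) {
  tr <- ape::read.nexus(path)
  if (inherits(tr, "phylo")) tr <- structure(list(tr), class = "multiPhylo")
  structure(lapply(tr, normalize_tree), class = "multiPhylo")
}
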