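write_toy_nexus <- function(lines, path = tempfile(fileext = ".nex")) {
  writeLines(lines, path)
  path
}

toy_nexus <- function() {
  write_toy_nexus(c(
    "#NEXUS",
    "BEGIN DATA;",
    "DIMENSIONS NTAX=4 NCHAR=3;",
    "FORMAT DATATYPE=STANDARD MISSING=? GAP=- SYMBOLS=\"01\";",
    "MATRIX",
    "taxA 001",
    "taxB 011",
    "taxC 0?1",
    "taxD 110",
    ";",
    "END;"
  ))
}

test_that("a toy NEXUS matrix parses with declared dimensions and missing cells", {
  m <- read_nexus(toy_nexus())
  expect_s3_class(m, "char_matrix")
  expect_equal(n_taxa(m), 4L)
  expect_equal(n_chars(m), 3L)
  expect_equal(m$taxa, c("taxA", "taxB", "taxC", "taxD"))
  # '?' is stored as the empty state set (unknown)
  expect_identical(unname(m$states["taxC", 2L]), 0L)
  # observed states are bitmasks by SYMBOLS order
  expect_identical(unname(m$states["taxD", 1L]), 2L)  # state "1" -> bit 2
})

test_that("SYMBOLS order in the file, not numeric value, defines state codes", {
  f <- write_toy_nexus(c(
    "#NEXUS", "BEGIN DATA;",
    "DIMENSIONS NTAX=4 NCHAR=2;",
    "FORMAT SYMBOLS=\"210\" MISSING=?;",
    "MATRIX", "a 22", "b 11", "c 00", "d 2?", ";", "END;"
  ))
  m <- read_nexus(f)
  expect_identical(m$symbols, c("2", "1", "0"))
  expect_identical(unname(m$states["a", 1L]), 1L)  # "2" is the first symbol
  expect_identical(unname(m$states["c", 1L]), 4L)  # "0" is the third
})

test_that("interleaved matrices and polymorphic state sets are parsed", {
  f <- write_toy_nexus(c(
    "#NEXUS", "BEGIN DATA;",
    "DIMENSIONS NTAX=4 NCHAR=4;",
    "FORMAT DATATYPE=STANDARD MISSING=? GAP=- SYMBOLS=\"012\";",
    "MATRIX",
    "A 01", "B (01)2", "C ?-", "D 00",
    "A 22", "B 10", "C 21", "D 0(12)",
    ";", "END;"
  ))
  m <- read_nexus(f)
  expect_equal(n_chars(m), 4L)
  expect_identical(unname(m$states["B", 1L]), 3L)   # {0,1}
  expect_identical(unname(m$states["D", 4L]), 6L)   # {1,2}
  expect_identical(unname(m$states["C", 2L]), 0L)   # gap == unknown
})

test_that("parser rejects malformed input with informative errors", {
  ragged <- write_toy_nexus(c(
    "#NEXUS", "BEGIN DATA;", "DIMENSIONS NTAX=3 NCHAR=3;",
    "FORMAT SYMBOLS=\"01\";", "MATRIX",
    "a 001", "b 01", "c 111", ";", "END;"
  ))
  expect_error(read_nexus(ragged), "length mismatch")

  dup <- write_toy_nexus(c(
    "#NEXUS", "BEGIN DATA;", "DIMENSIONS NTAX=2 NCHAR=2;",
    "FORMAT SYMBOLS=\"01\";", "MATRIX",
    "a 00", "a 11", ";", "END;"
  ))
  expect_error(read_nexus(dup), "duplicate taxon")

  alien <- write_toy_nexus(c(
    "#NEXUS", "BEGIN DATA;", "DIMENSIONS NTAX=2 NCHAR=2;",
    "FORMAT SYMBOLS=\"01\";", "MATRIX",
    "a 0X", "b 11", ";", "END;"
  ))
  expect_error(read_nexus(alien), "outside the declared alphabet.*line",
               perl = TRUE)

  allmiss <- write_toy_nexus(c(
    "#NEXUS", "BEGIN DATA;", "DIMENSIONS NTAX=2 NCHAR=2;",
    "FORMAT SYMBOLS=\"01\";", "MATRIX",
    "a 0?", "b 1-", ";", "END;"
  ))
  expect_error(read_nexus(allmiss), "entirely unknown")

  expect_error(read_nexus(tempfile()), "file not found")
})

test_that("reader agrees with ape's NEXUS data reader on a plain file", {
  f <- toy_nexus()
  m <- read_nexus(f)
  a <- ape::read.nexus.data(f)
  expect_setequal(names(a), m$taxa)
  tok <- cladecontrib:::state_tokens(m)
  for (tx in m$taxa) {
    expect_identical(tolower(unlist(a[[tx]])), tolower(tok[tx, ]))
  }
})

test_that("write_nexus / read_nexus round-trips taxa, states and missing mask", {
  fx <- plant_matrix(fixture_spec(
    7,
    per_type_plan = list(
      general = list(list(clade = c("t1", "t2", "t3"), clean = 3,
                          homoplastic = 1)),
      copulatory = list(),
      photophores = list()
    ),
    background_constant = 6, seed = 42
  ))
  f <- tempfile(fileext = ".nex")
  write_nexus(fx$matrix, f, partition = fx$partition, trees = fx$tree)
  m2 <- read_nexus(f)
  expect_identical(m2$taxa, fx$matrix$taxa)
  expect_identical(unname(m2$states), unname(fx$matrix$states))
  p2 <- read_partition(f, n_chars(m2))
  expect_identical(lapply(p2, as.integer), lapply(fx$partition, as.integer))
  tr <- read_nexus_trees(f)
  expect_setequal(names(bipartitions(tr[[1L]])), names(bipartitions(fx$tree)))
})

test_that("partition files parse in both dialects and enforce totality", {
  # NEXUS charset: 1-based ranges
  f1 <- write_toy_nexus(c(
    "#NEXUS", "BEGIN SETS;",
    "charset general = 1-116;",
    "charset copulatory = 117-190;",
    "charset photophores = 191-249;",
    "END;"
  ))
  p <- read_partition(f1, 249L)
  expect_equal(lengths(p), c(general = 116L, copulatory = 74L,
                             photophores = 59L))

  # plain dialect: 0-based ranges as printed in character lists
  f2 <- write_toy_nexus(c(
    "general\t0-115",
    "copulatory\t116-189",
    "photophores\t190-248"
  ))
  p2 <- read_partition(f2, 249L)
  expect_identical(lapply(p2, as.integer), lapply(p, as.integer))

  # same ranges cannot cover a 253-character matrix
  expect_error(read_partition(f2, 253L), "not assigned")

  # degenerate single-type partition is valid
  f3 <- write_toy_nexus("all\t0-248")
  expect_silent(p3 <- read_partition(f3, 249L))
  expect_equal(length(p3$all), 249L)

  # overlapping ranges rejected
  f4 <- write_toy_nexus(c("a\t0-10", "b\t10-20"))
  expect_error(read_partition(f4, 21L), "overlap")

  # out-of-range index rejected
  f5 <- write_toy_nexus(c("a\t0-10", "b\t11-30"))
  expect_error(read_partition(f5, 21L), "outside")
})

test_that("subset_matrix keeps exactly the requested columns, with metadata", {
  part <- sergestoid_partition()
  st <- matrix(sample(0:1, 6 * 249, replace = TRUE), 6, 249,
               dimnames = list(paste0("t", 1:6), NULL))
  st[1, ] <- 0L; st[2, ] <- 1L   # no all-missing columns possible here
  m <- character_matrix(st)
  inc <- subset_matrix(m, part, "photophores", "include")
  exc <- subset_matrix(m, part, "photophores", "exclude")
  expect_equal(n_chars(inc), 59L)
  expect_equal(n_chars(exc), 190L)
  expect_identical(inc$taxa, m$taxa)
  # include and exclude column sets partition the original indices
  expect_length(intersect(inc$char_index, exc$char_index), 0L)
  expect_setequal(c(inc$char_index, exc$char_index), seq_len(249L))
  expect_error(subset_matrix(m, part, "nope", "include"), "unknown")
  one <- character_partition(list(all = 1:249), 249L)
  expect_error(subset_matrix(m, one, "all", "exclude"), "0 characters")
})

test_that("partition constructor validates names, disjointness and coverage", {
  expect_error(character_partition(list(a = 1:3, b = 3:5), 5L), "overlap")
  expect_error(character_partition(list(a = 1:3), 5L), "not assigned")
  expect_error(character_partition(list(a = integer(0), b = 1:5), 5L),
               "empty")
  expect_error(character_partition(list(1:5), 5L), "name")
  p <- character_partition(list(b = 4:5, a = 1:3), 5L)
  expect_named(p, c("b", "a"))
})

test_that("parsimony informativeness flags constant and autapomorphic columns", {
  st <- cbind(c(0, 0, 0, 0), c(0, 0, 0, 1), c(0, 0, 1, 1), c(0, 1, 0, 1))
  rownames(st) <- paste0("t", 1:4)
  m <- character_matrix(st)
  expect_identical(parsimony_informative(m), c(FALSE, FALSE, TRUE, TRUE))
})

test_that("the TSV export carries one column per character", {
  m <- read_nexus(toy_nexus())
  f <- tempfile(fileext = ".tsv")
  write_matrix_tsv(m, f)
  df <- utils::read.delim(f, colClasses = "character")
  expect_equal(dim(df), c(4L, 4L))
  expect_equal(df$taxon, m$taxa)
  expect_equal(df$c2[3L], "?")
})
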