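# A reusable 7-taxon driver fixture: the focal clade's support comes from one
# character type; a second type carries within-clade signal only.
driver_fixture <- function(seed = 11) {
  plant_matrix(fixture_spec(
    7,
    per_type_plan = list(
      general = list(list(clade = c("t1", "t2", "t3"), clean = 3)),
      copulatory = list(list(clade = c("t6", "t7"), clean = 2)),
      photophores = list(list(clade = c("t1", "t2"), clean = 2))
    ),
    tree = parse_newick("(((t1,t2),t3),(t4,(t5,(t6,t7))));"),
    background_constant = 6, seed = seed
  ))
}

test_that("cs and cd satisfy their defining identities exactly", {
  fx <- driver_fixture()
  tab <- contribution_table(fx$matrix, fx$partition,
                            list(ABC = c("t1", "t2", "t3")),
                            n_pseudoreplicates = 50, seed = 4)
  expect_equal(nrow(tab), 6L)   # 1 clade x 3 types x 2 bases
  expect_equal(tab$cs, tab$S_plus - tab$S_minus)
  expect_equal(tab$cd, (tab$D_plus - tab$D_minus) / (tab$n - 1))
  expect_true(all(tab$n == 3L))
})

test_that("a 2-taxon clade always has cd = 0", {
  fx <- driver_fixture()
  tab <- cd_metric(fx$matrix, fx$partition, "photophores",
                   clade = c("t1", "t2"), n_pseudoreplicates = 30, seed = 2)
  expect_true(all(tab$D_plus == 0))
  expect_true(all(tab$D_minus == 0))
  expect_true(all(tab$cd == 0))
})

test_that("the driver type gets positive cs, others non-positive (Bremer basis)", {
  fx <- driver_fixture()
  tab <- contribution_table(fx$matrix, fx$partition,
                            list(ABC = c("t1", "t2", "t3")),
                            n_pseudoreplicates = 30, seed = 9)
  br <- tab[tab$basis == "bremer", ]
  expect_gt(br$cs[br$type == "general"], 0)
  expect_lte(br$cs[br$type == "copulatory"], 0)
  expect_lte(br$cs[br$type == "photophores"], 0)
  # figure-style pattern: the S_minus of the driver type is 0 (clade collapses
  # without its own characters)
  expect_equal(br$S_minus[br$type == "general"], 0)
  expect_equal(br$S_plus[br$type == "general"], 3)
})

test_that("within-clade signal shows up in cd for its type", {
  fx <- driver_fixture()
  tab <- contribution_table(fx$matrix, fx$partition,
                            list(ABC = c("t1", "t2", "t3")),
                            n_pseudoreplicates = 30, seed = 5)
  br <- tab[tab$basis == "bremer", ]
  expect_gt(br$cd[br$type == "photophores"], 0)   # t1,t2 resolved only by Ph
  expect_lt(br$cd[br$type == "general"], 0)
  expect_true(unique(br$cd_positive_overall[br$type == "photophores"]))
})

test_that("include-mode single-type analysis reproduces the unpartitioned pipeline", {
  fx <- driver_fixture()
  m <- fx$matrix
  one <- character_partition(list(all = seq_len(n_chars(m))), n_chars(m))
  s_inc <- clade_support_under_partition(
    m, one, "all", "include", clade = c("t1", "t2", "t3"),
    basis = "bremer", seed = 3)
  expect_equal(s_inc, bremer_support(m, c("t1", "t2", "t3")))
  b_inc <- clade_support_under_partition(
    m, one, "all", "include", clade = c("t1", "t2", "t3"),
    basis = "bootstrap", n_pseudoreplicates = 200, seed = 3)
  b_ref <- bootstrap_support(m, 200, seed = 3)
  k <- cladecontrib:::clade_key(m, c("t1", "t2", "t3"))
  expect_equal(b_inc, b_ref$bootstrap_pct[b_ref$clade == k])
})

test_that("an uninformative type has S_plus = 0 and cs = -(full support)", {
  taxa <- paste0("t", 1:6)
  st <- cbind(matrix(c(1, 1, 1, 0, 0, 0), 6, 4),  # informative: type A
              matrix(0L, 6, 3))                   # constant: type B
  rownames(st) <- taxa
  m <- character_matrix(st)
  part <- character_partition(list(A = 1:4, B = 5:7), 7L)
  cs <- cs_metric(m, part, "B", clade = c("t1", "t2", "t3"),
                  basis = "bremer", n_pseudoreplicates = 20, seed = 1)
  full <- bremer_support(m, c("t1", "t2", "t3"))
  expect_equal(cs$S_plus, 0)
  expect_equal(cs$S_minus, full)
  expect_equal(cs$cs, -full)
  expect_false(cs$cs_positive_overall)
})

test_that("metrics are invariant to type relabeling and column order within types", {
  fx <- driver_fixture()
  m <- fx$matrix; part <- fx$partition
  tab <- contribution_table(m, part, list(ABC = c("t1", "t2", "t3")),
                            n_pseudoreplicates = 40, seed = 8)
  # relabel types and shuffle columns within each type
  set.seed(77)
  idx <- unlist(lapply(part, sample), use.names = FALSE)
  tok <- cladecontrib:::state_tokens(m)[, idx]
  m2 <- character_matrix(tok, taxa = m$taxa)
  sizes <- lengths(part)
  bounds <- cumsum(sizes)
  part2 <- character_partition(
    list(X = seq_len(bounds[1]),
         Y = (bounds[1] + 1):bounds[2],
         Z = (bounds[2] + 1):bounds[3]), n_chars(m))
  tab2 <- contribution_table(m2, part2, list(ABC = c("t1", "t2", "t3")),
                             n_pseudoreplicates = 40, seed = 8)
  map <- c(general = "X", copulatory = "Y", photophores = "Z")
  for (tp in names(map)) {
    r1 <- tab[tab$basis == "bremer" & tab$type == tp, ]
    r2 <- tab2[tab2$basis == "bremer" & tab2$type == map[[tp]], ]
    # Bremer-based values are deterministic: exactly invariant
    expect_equal(r1$cs, r2$cs, info = tp)
    expect_equal(r1$cd, r2$cd, info = tp)
    # bootstrap-based values are invariant in expectation only
    b1 <- tab[tab$basis == "bootstrap" & tab$type == tp, ]
    b2 <- tab2[tab2$basis == "bootstrap" & tab2$type == map[[tp]], ]
    expect_lte(abs(b1$cs - b2$cs), 15)
    expect_lte(abs(b1$cd - b2$cd), 15)
  }
})

test_that("the contribution table has clade x type x basis cardinality", {
  fx <- driver_fixture()
  tab <- contribution_table(fx$matrix, fx$partition,
                            list(ABC = c("t1", "t2", "t3"),
                                 FG = c("t6", "t7")),
                            n_pseudoreplicates = 20, seed = 3)
  expect_equal(nrow(tab), 2L * 3L * 2L)
  expect_setequal(unique(tab$basis), c("bremer", "bootstrap"))
  empty <- contribution_table(fx$matrix, fx$partition, list(),
                              n_pseudoreplicates = 20, seed = 3)
  expect_equal(nrow(empty), 0L)
  expect_error(contribution_table(fx$matrix, fx$partition,
                                  list(bad = c("t1", "nope")),
                                  n_pseudoreplicates = 20, seed = 3),
               "unknown taxon")
})

test_that("three planted driver types give exactly the diagonal positive-cs pattern", {
  tree <- parse_newick("(((t1,t2),(t3,t4)),((t5,t6),(t7,t8)));")
  fx <- plant_matrix(fixture_spec(
    8,
    per_type_plan = list(
      general = list(list(clade = c("t1", "t2"), clean = 3)),
      copulatory = list(list(clade = c("t5", "t6"), clean = 3)),
      photophores = list(list(clade = c("t7", "t8"), clean = 3))
    ),
    tree = tree, background_constant = 6, seed = 21
  ))
  clades <- list(C1 = c("t1", "t2"), C2 = c("t5", "t6"), C3 = c("t7", "t8"))
  tab <- contribution_table(fx$matrix, fx$partition, clades,
                            n_pseudoreplicates = 25, seed = 13)
  br <- tab[tab$basis == "bremer", ]
  driver <- c(C1 = "general", C2 = "copulatory", C3 = "photophores")
  for (cn in names(clades)) {
    for (tp in names(fx$partition)) {
      v <- br$cs[br$clade == cn & br$type == tp]
      if (driver[[cn]] == tp) expect_gt(v, 0) else expect_lte(v, 0)
    }
  }
})
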