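# cladecontrib

Maximum-parsimony phylogenetics for morphological character matrices whose
characters fall into named **types** — e.g. general external characters,
copulatory organs and photophores in pelagic shrimps — with metrics that
quantify how much each character type contributes to the support of a clade
and to the resolved divergence within it.

Morphologists routinely ask not only *whether* a clade is robust but *which
kind of evidence* makes it robust: does a genus stand on its copulatory
morphology, its photophores, or on general external characters? This package
implements the full analysis chain needed to answer that question on a
discrete, unordered, equally weighted character matrix:

- **NEXUS I/O** — `DATA`/`CHARACTERS` matrices (interleaved or not, custom
  `SYMBOLS`, `?`/`-` unknowns, polymorphic `(01)` cells), `SETS`/`charset`
  partitions, `TREES` blocks (via ape), plus a plain-text partition dialect
  using the 0-based ranges found in printed character lists.
- **Fitch parsimony** — minimum state changes for unordered multistate
  characters with missing data; exact on multifurcating trees through
  Hartigan's generalization of the Fitch downpass, so strict consensus trees
  can be scored.
- **Tree search** — "traditional" heuristic search (random addition sequence
  + TBR branch swapping with a bounded tree buffer), named presets matching
  the published profiles (150 or 10 000 replicates, 200 trees per replicate,
  30 000 in memory), and an exhaustive-enumeration search for up to 9 taxa
  that serves as an exact oracle.
- **Clade support** — nonparametric bootstrap over characters and Bremer
  (decay) values via converse-constrained search, with the published
  significance rule: a clade is significant iff bootstrap > 80% **and**
  Bremer > 3 (both strict).
- **Cs / Cd contribution metrics** — for character type *i* and a clade,

  ```
  Cs_i = S_i+ − S_i−            (clade support:   only type i  vs  all but type i)
  Cd_i = D_i+/(n−1) − D_i−/(n−1)  (within-clade divergence, n = clade terminals)
  ```

  where `S_i+` is the clade's support when only the type-*i* characters are
  analysed and `S_i−` when all but the type-*i* characters are analysed;
  `D_i±` sum the support of resolved branches strictly inside the clade in
  the same two analyses. A clade absent from an analysis's strict consensus
  has support 0 there. Both metrics are computed on the Bremer and the
  bootstrap basis; a type's contribution is called positive when any basis
  gives a positive value.
- **Synthetic fixtures** — planted synapomorphies with known Bremer values,
  guaranteed-conflicting homoplasy, constant filler in realistic type
  proportions, and a simple Markov character simulator, so the whole chain is
  testable without any external data.

## Worked example

Plant a 7-taxon fixture in which the focal clade `t1+t2+t3` owes all of its
support to "general" characters while "photophores" only resolve structure
inside the clade:

```r
library(cladecontrib)

spec <- fixture_spec(
  7,
  per_type_plan = list(
    general     = list(list(clade = c("t1","t2","t3"), clean = 5)),
    copulatory  = list(list(clade = c("t6","t7"),      clean = 2)),
    photophores = list(list(clade = c("t1","t2"),      clean = 2))
  ),
  tree = parse_newick("(((t1,t2),t3),(t4,(t5,(t6,t7))));"),
  background_constant = 6, seed = 11)
fx <- plant_matrix(spec)

s <- heuristic_search(fx$matrix, search_config(n_replicates = 10, seed = 1))
s
#> Maximum-parsimony search (heuristic)
#>   trees retained: 3  best length: 9

support_table(fx$matrix, n_pseudoreplicates = 1000, seed = 1)
#> Clade support table (3 clades, 1000 pseudoreplicates)
#>      clade           taxa bootstrap_pct bremer significant
#>        6,7          t6,t7          88.4      2       FALSE
#>    4,5,6,7    t4,t5,t6,t7          99.9      5        TRUE
#>  3,4,5,6,7 t3,t4,t5,t6,t7          89.8      2       FALSE

contribution_table(fx$matrix, fx$partition,
                   clades = list(ABC = c("t1","t2","t3")),
                   n_pseudoreplicates = 1000, seed = 1)
#> Character-type contribution table (6 rows)
#>  clade        type     basis S_plus S_minus   cs D_plus D_minus n     cd
#>    ABC     general    bremer      5       0    5    0.0     2.0 3  -1.00
#>    ABC     general bootstrap    100       0  100    0.0    90.9 3 -45.45
#>    ABC  copulatory    bremer      0       5   -5    0.0     2.0 3  -1.00
#>    ABC  copulatory bootstrap      0     100 -100    0.0    89.8 3 -44.90
#>    ABC photophores    bremer      0       5   -5    2.0     0.0 3   1.00
#>    ABC photophores bootstrap      0     100 -100   94.5     0.0 3  47.25
```

Reading the table: the best trees need 9 steps (one per planted character);
the clade `t1+t2+t3` is reported as the split `4,5,6,7` (its complement —
splits are shown by the side not containing the first taxon) with Bremer 5
and bootstrap 99.9%, hence significant. In the contribution table, `general`
is the only type with positive Cs (the clade collapses without it: `S_minus
= 0`), while `photophores` is the only type with positive Cd — exactly the
planted design. Both clades at Bremer 2 show that the significance rule is
strict: high bootstrap alone does not qualify.

A command-line front end wraps the same functions
(`inst/scripts/cladecontrib`): subcommands `search`, `consensus`,
`bootstrap`, `bremer`, `metrics`, `simulate`, each writing a reproducibility
log (version, config, seed, input checksums) next to its output.

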