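Package: cladecontrib
Title: Character-Partition Contribution to Clade Support under Maximum Parsimony
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maximum-parsimony analysis of morphological character matrices
    with partitioned characters. Implements Fitch parsimony for unordered,
    equally weighted characters with missing data (exact on multifurcating
    trees via Hartigan's generalization), heuristic tree search by random
    addition sequence and tree-bisection-reconnection branch swapping with an
    exhaustive-search oracle for small instances, strict consensus,
    nonparametric bootstrap and Bremer (decay) clade support, and the Cs/Cd
    metrics quantifying the contribution of a character-type partition to
    clade support and to divergence within a clade. Includes NEXUS matrix and
    charset input/output and a synthetic-fixture generator with known ground
    truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
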