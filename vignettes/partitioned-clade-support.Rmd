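---
title: "Partitioned character contribution to clade support: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioned character contribution to clade support: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cladecontrib)
```

## The problem

Morphological phylogenies are built from heterogeneous evidence. In groups
such as sergestoid shrimps, three character complexes evolve with some
independence: general external morphology, the copulatory apparatus (petasma
and clasping organ), and photophores. Two questions follow once a parsimony
analysis has produced a tree and support values. First, which clades are
robust at all; second, *which character type makes them robust*. This package
implements the machinery for both: a maximum-parsimony toolchain (matrix
input, tree search, strict consensus, bootstrap and Bremer support) and the
Cs/Cd contribution metrics layered on top of it.

## Parsimony model

Characters are discrete, **unordered** (any state-to-state change costs one
step) and **equally weighted**; missing entries (`?`, and `-` which we treat
identically) are "unknown": at a leaf they behave as the set of all states
*observed in that character's column*. The engine never invents a state that
no taxon exhibits. Polymorphic cells such as `(01)` are genuine state sets
and are handled by the same mechanism.

The length of a tree is the minimum number of changes summed over characters.
For binary nodes this is Fitch's intersection/union rule. Internally every
node carries one bitmask per character and the whole matrix is scored in a
single vectorized post-order sweep. For **multifurcating** nodes — which
strict consensus trees routinely contain — we use Hartigan's exact
generalization: at a node with children state-sets `S_1..S_m`, count for each
state how many child sets contain it, keep the states attaining the maximum
count `K`, and add `m − K` steps. On binary nodes this reduces exactly to
Fitch; on polytomies it remains the exact minimum, which we verify in the
test suite against a brute-force oracle that enumerates every assignment of
states to internal nodes. Parsimony length is invariant under rooting, so
trees are handled unrooted and rooted arbitrarily at an internal node for
scoring.

## Tree search

The heuristic search mirrors the "traditional search" idiom of parsimony
programs:

1. **Random addition sequence**: taxa are inserted in seeded-random order,
   each at the parsimony-optimal attachment edge, ties broken by a seeded
   draw.
2. **TBR branch swapping**: every edge is bisected, the detached part is
   rerooted on each of its edges and reattached to each edge of the other
   part. The neighborhood is deduplicated by bipartition-set signature and
   contains all SPR (and hence NNI) neighbors.
3. **Plateau exploration**: strictly better neighbors restart the climb;
   equal-length (or within-margin) topologies are queued breadth-wise up to
   `trees_per_replicate`, then replicates are pooled, deduplicated and
   truncated to `max_trees_total`.

Two presets encode the published search profiles (`paper-150`,
`paper-10000`: 150 / 10 000 replicates, 200 trees per replicate, 30 000 trees
in memory); `fast` (10 replicates) is the default for per-pseudoreplicate
bootstrap searches and testing. The published analysis retrieved more optimal
trees than its per-replicate save limit suggests; rather than emulate any one
program's buffer quirks, this package documents its own semantics (above) and
guarantees: every retained tree re-scores within the margin, no topological
duplicates, deterministic output for a given seed.

For at most 9 taxa (135 135 topologies) `exhaustive_search()` enumerates all
unrooted binary topologies. This is the oracle against which the heuristic is
regression-tested, and it also powers an exact fast path for support values:
per-topology, per-character lengths are computed once, after which any
bootstrap pseudoreplicate is a weighted column sum and any constrained
optimum a filtered minimum.

## Clade support

**Bootstrap.** Each pseudoreplicate resamples the characters with
replacement and re-analyses the resampled matrix; a clade is counted iff it
appears in the pseudoreplicate's **strict consensus** (not
frequency-weighted among tied trees — the stricter, more conservative
reading). The reported percentage is over all pseudoreplicates, for every
clade of the reference strict consensus. On ≤ 9 taxa the per-pseudoreplicate
analysis is exact (exhaustive tables); above that, a reduced-preset heuristic
search runs per pseudoreplicate, a documented fidelity/runtime trade-off. The
two backends agree within Monte-Carlo error on small instances
(regression-tested), and the Monte-Carlo standard error scales as 1/√B in
the number of pseudoreplicates.

**Bremer (decay).** Defined as `L(best tree without the clade) − L(best
tree)`, computed by **converse-constrained search**: the search rejects every
topology containing the clade. We deliberately do not compute decay from a
buffer of suboptimal trees as the published protocol describes ("up to three
steps longer"), because a buffer capped at margin *k* cannot measure decay
values beyond *k* — and the study itself reports values of 20–34. The
buffer reading is available as `method = "buffer"` for cross-checking small
decays. A clade absent from the strict consensus of the unconstrained optima
is unsupported and has Bremer 0 by convention.

**Significance.** A clade is flagged significant iff bootstrap > 80% *and*
Bremer > 3, both strictly (a clade at exactly Bremer 3 with 99% bootstrap
does not qualify).

## The Cs and Cd metrics

For character type *i* and a clade with *n* terminal taxa:

- `Cs_i = S_i+ − S_i−`, where `S_i+` is the clade's support when **only**
  the type-*i* characters are included and `S_i−` its support when **all
  but** the type-*i* characters are included. Positive values mean the type
  contributes support; larger is stronger.
- `Cd_i = D_i+/(n−1) − D_i−/(n−1)`, where `D_i±` is the sum of support over
  **resolved branches within the clade** in the same two analyses.

Conventions and open choices, resolved as follows:

- A clade absent from a sub-analysis's strict consensus contributes support
  0 (the `S_i− = 0` convention for unsupported clades).
- "Within the clade" excludes the clade's own stem branch by default: the
  stem's support *is* the clade's support and is already measured by Cs.
  `include_stem = TRUE` provides the alternative reading.
- The divisor `n − 1` is applied literally as defined; it is not rescaled to
  the number of possible internal branches.
- For `n = 2` there are no internal branches, so `D_i± = 0` and `Cd = 0` by
  construction.
- Both metrics are computed on the Bremer **and** the bootstrap basis; the
  combined verdict (`*_positive_overall`) is positive if any basis is
  positive.
- Cs is undefined for a partition with a single type (the "all but type i"
  matrix would be empty); `subset_matrix()` refuses empty subsets.

`contribution_table()` computes the full clade × type × basis long table.
All sub-analyses (each type × include/exclude, their bootstraps, every
constrained Bremer search) derive their seeds deterministically from one
master seed, so an entire metrics run is reproducible from a single integer.
Bremer-based Cs/Cd values are exactly invariant under relabeling of types
and reordering of columns within types; bootstrap-based values are invariant
in expectation only (the resampling indices attach to column positions).

## Synthetic data: what it emulates, and what it does not

`plant_matrix()` builds matrices with known ground truth. Clean columns are
uncontradicted binary synapomorphies of a chosen clade (state 1 inside, 0
outside); *k* clean columns give the clade a Bremer value of exactly *k*
when nothing else conflicts, which is the anchor for the Bremer tests.
Homoplastic columns mark a random taxon subset constrained to straddle the
clade boundary (all four intersections with the bipartition non-empty), so
they are guaranteed to conflict. Constant filler is spread over the types so
that type sizes approximate the 116/74/59 proportions of the three-type
shrimp matrix — tests therefore exercise realistically imbalanced
partitions. A `noise_rate` optionally flips one random cell per planted
column. Generation is a pure function of the spec (same spec, same output),
and `"random"` trees are drawn uniformly (unconstrained case) or by random
coalescence constrained to contain the planted clades.

`mk_simulate()` adds a minimal Markov noise model (uniform root state; with
probability *p* per edge the state jumps to a uniformly chosen different
state) for robustness checks.

What the generator does **not** emulate: correlated characters, ordered or
weighted states, clade-dependent rates, or realistic morphological
integration. Passing tests on planted fixtures demonstrate that the
machinery is correct — that supports, decay values and Cs/Cd behave exactly
as their definitions require — not that any empirical matrix has a
particular property.

## Numerical and design choices

- **State sets as bitmasks** (≤ 10 states, matching the `0-9` symbol
  alphabet); one integer vector per node scores all characters at once.
- **Canonical splits**: a bipartition is stored as the side not containing
  the first taxon, giving deterministic hashing, comparison and tie-breaks.
  Support tables print that side; read it as "this split", not "this side is
  the clade".
- **Strict consensus** is the intersection of canonical split sets followed
  by reconstruction of the (generally multifurcating) tree; it is
  cross-checked against an independent implementation (ape's) in the tests.
- **Determinism**: every exported function that uses randomness takes a seed
  and restores the caller's RNG state; derived sub-seeds are drawn once from
  the master seed, so replicate-level results do not depend on execution
  order.
- **Degenerate inputs**: all-missing characters are rejected at load time;
  all-constant matrices are legal and yield star consensuses and empty
  support tables; 0-character subsets are errors rather than silently empty
  analyses.
- **Indexing**: printed character lists in this field are 0-based, and the
  plain-text partition dialect follows them; NEXUS `charset` lines are
  1-based per the NEXUS standard; in-memory R indices are 1-based.

## Problem sizes used in validation

The shipped tests and the acceptance script run entirely at desk scale,
chosen so the exhaustive oracle stays exact: Fitch-vs-oracle on 200 random
cases of ≤ 7 taxa × ≤ 10 characters (including multifurcations, polymorphism
and missing data); search optimality on 50 matrices of 6–8 taxa; Bremer
recovery for planted k = 1..5 on 6–8 taxa; Cs/Cd sign recovery on 20 seeded
7-taxon driver fixtures; bootstrap behaviour at up to 2 500 pseudoreplicates
on 6-taxon fixtures. Reproducing the published shrimp results (tree lengths
470/467, the support spot-checks, Cs_G = 26/4) requires the study's
supplementary matrix and character-type list, which cannot be redistributed
here; the corresponding acceptance tests fail visibly — not silently — until
those files are supplied under `inst/extdata/`.

## Known limitations

- No ordered/weighted characters, step matrices (Sankoff), or implied
  weighting; no ancestral-state or synapomorphy mapping output.
- No ratchet, tree fusing or sectorial search; very large matrices will be
  slower than dedicated C implementations, though the same algorithms apply.
- Bootstrap above 9 taxa inherits the variance of its reduced per-replicate
  searches; raise the per-pseudoreplicate preset when fidelity matters more
  than runtime.
- Bremer values from heuristic search are upper-bound estimates in
  principle (a missed shorter constrained tree inflates the decay); on ≤ 9
  taxa the exhaustive backend is exact, and the converse-constrained search
  is regression-tested against it.
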