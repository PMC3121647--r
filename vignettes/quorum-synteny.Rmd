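---
title: "Quorum-aware synteny detection: model, algorithm and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quorum-aware synteny detection: model, algorithm and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synton)
```

## The model

`synton` looks for conserved blocks of genes — syntons — shared by `n`
gene-ordered genomes. The model has three layers.

**Primary graphs.** Each genome is an interval graph on gene ranks: genes
`u`, `v` of one genome are neighbours when their rank distance is at most
`delta_gap` (`min(|dr|, L - |dr|)` on circular chromosomes). This is the
only place gene order enters the model; everything downstream is symmetric
under gene-order permutation, so inversions and shuffling inside a block do
not break it. Ranks must be unique positive integers but need not be dense:
a gene table restricted to a subset of genes keeps meaningful distances.
A gene is its own neighbour (distance 0).

**Correspondence.** A pairwise relation `S` links genes of different
genomes. In practice `S` is thresholded sequence similarity or an orthology
call — many-to-many and not transitive, which the model embraces rather
than repairs. `filter_blast_pairs()` builds `S` from BLASTP tabular output
with the conventional thresholds (p ≤ 1e−10, identity ≥ 40 %, alignment
covering ≥ 80 % of the smaller protein); any two-column pair table works as
well. Intra-genome pairs are rejected: the package does not look for
intra-genomic syntenies.

**Spines and syntons.** `S` is aggregated into spines — tuples with one
slot per genome holding a gene (a gene *set* in connected-component mode)
or the don't-care mark `*` — under one of three rules: `clique` (all
covered genes pairwise related), `cc` (covered genes connected in `S`), or
`quasi` (every covered gene related to at least `gamma * (k - 1)` of the
other `k - 1` covered genes). The quorum `q` requires at least `q` covered
slots, i.e. at most `n - q` don't-cares; `q = n` forbids missing genes
entirely. Spines form a multigraph with `n` colour-indexed edge sets —
colour `i` joins two spines whose slot-`i` genes are interval-graph
neighbours — and a synton is a maximal spine set with a uniform cover `I`
(`|I| >= q`) that is connected on every colour of `I` *using only its own
members*. Syntons partition the spine set.

Two modelling choices deserve emphasis:

* **Distance-0 colour edges.** Two distinct spines sharing the identical
  gene at slot `i` are colour-`i` neighbours. Without this rule a gene
  belonging to two spines (routine under many-to-many `S`) would
  disconnect blocks that visibly overlap on the chromosome; the
  three-spine synton of the `"F1"` fixture exists only because its two
  `b1`-sharing spines are blue-connected through that shared gene. The
  rule is applied globally.
* **Connectivity is evaluated inside the candidate set.** A synton may not
  borrow connectivity from outside vertices; two spines far apart on some
  covered genome belong together only if member spines bridge them.

## Parameters

| Parameter | Meaning | Default | Notes |
|---|---|---|---|
| `delta_gap` | neighbour radius in ranks | 1 | `g` tolerates `g - 1` intervening genes; the common "gaps of up to 3 genes" screening setting is therefore `delta_gap = 4`. Raising it only merges syntons within a cover group (tested invariant). |
| `q` | quorum, in genomes | 2 | `2 <= q <= n`. Low quorums on many close genomes explode the search space — that is a property of the problem, not of the implementation; the `spine_cap` guard turns it into a clean resource error advising a higher quorum. |
| `mode`, `gamma` | aggregation rule | `clique` | `cc` is the permissive choice for functional screening; `clique` the stringent choice for evolutionary work; `quasi` interpolates with `gamma` in (0, 1]. |
| `min_size` | spines per reported synton | 1 | 1 is the pure definition; screening studies typically use 3 to suppress trivial blocks. Size is counted in spines (anchor tuples), not genes. |
| `maximal_only` | subsumption filter | `FALSE` | applied after `min_size`, as a final filter, never inside the algorithm. |

## The algorithm

The multigraph can grow exponentially with `n` (and the don't-care slots
multiply it further), so the engine never builds it. `otfq_partition()`
runs a depth-first recursion over genomes:

1. **Initialise** with one class per connected component of genome 1's
   interval graph, plus — when `q < n` — a class holding the don't-care
   1-tuple.
2. **Split** the current class on each processed colour: members covered at
   colour `j` are partitioned into colour-`j` connected components; members
   with `*` at `j` are replicated into *every* part. If any colour splits
   the class, recurse into the parts.
3. **Expand** a stable class to the next genome: each member gains every
   terminal gene compatible with the aggregation rule, plus a don't-care
   when its budget `n - q` allows; members with no extension die.
4. **Finalize** the stable layer-`n` classes: drop members failing the
   exact quorum/aggregation test, split by cover signature, re-refine each
   group by per-colour connectivity, deduplicate across branches, and
   assert the partition property.

Per-colour connectivity inside the engine is computed by clustering the
*occupied* ranks (sorted ranks chain whenever consecutive occupied ranks
are within `delta_gap`; a member spanning several clusters merges them).
This is exactly member-adjacency connectivity, in `O(m log m)`.

**Terminal pruning.** For cliques, a prefix of a valid spine is itself a
clique, so terminals are the genes related to every covered prefix gene —
exact and cheap. For quasi-cliques no such prefix property holds: a prefix
pair may be unrelated while the completed spine passes the degree rule.
The engine therefore prunes with the relaxed bound
`deg_prefix(w) + r >= gamma * (k_prefix + r - 1)` (with `r` genomes left),
which is provably satisfied by every prefix of every valid spine (take the
completion as witness; the slack `(r - a)(1 - gamma)` is non-negative), and
re-checks tuples exactly at finalization. With `gamma = 1` the bound
reduces to the clique rule. Connected-component aggregation bypasses
incremental expansion altogether — its spines are whole `S`-components,
precomputed — and reuses split/finalize.

**Why finalization is needed at all.** Replicating don't-care members into
every branch of a split is what makes the quorum search complete, but it
means the same spine can surface in several final classes, and invalid
partial tuples can transiently glue classes together. Cover-uniformity
saves the day: members of one final synton share their don't-care slots, so
they are replicated *together* and re-emerge identically in every branch
that contains any of them — deduplication by canonical form then restores a
partition, and the engine asserts it (an internal error, never a silent
repair). The decisive evidence that this consolidation is correct is the
oracle-equivalence test: on hundreds of random instances spanning 2–4
genomes, all aggregation modes, quorums and gap radii, the engine's output
equals the explicit, definition-driven `oracle_partition()` exactly.

## The oracle path

`enumerate_spines()` (igraph clique enumeration for cliques; a vectorised
candidate product for quasi-cliques; component scanning for `cc`),
`build_pnam()` (all colour edges materialised pairwise) and
`oracle_partition()` (fixpoint refinement: split a part into one colour's
components, cycle colours until stable) implement the definitions with no
shortcuts shared with the engine. The refinement is order-independent —
permuting colour or part order yields the same partition (tested) — which
is why "the" partition is well defined. The oracle is deliberately
unscalable; it exists to pin the engine down, and is exposed in the CLI via
`--oracle` for desk-scale verification.

## Synthetic data

`generate_instance()` emulates the structural features the detector runs
on: background genes with globally unique families (they can never join a
spine), planted blocks of shared families on a chosen genome subset —
contiguous, optionally permuted per genome, interleaved with gap genes at a
configurable rate, separated by at least three background genes so blocks
do not merge at small `delta_gap` — plus `S`-edge dropout (breaking
transitivity, as thresholded similarity does) and paralog copies (making
`S` many-to-many). Everything derives from a mandatory seed and the
generator restores the caller's RNG state.

What it does *not* emulate: sequence-level evolution, realistic
inversion/transposition processes, genome-scale gene-family size
distributions, or tandem arrays. Passing the recovery tests therefore
shows that the detector finds blocks under permutation, gaps, missing
genomes and relational noise — not that any particular biological dataset
will yield biologically meaningful blocks; threshold choices for `S`
dominate that question.

## Numerical and degenerate-input choices

* Ties and ordering: spines, syntons and reports are canonicalised
  (slot-sorted gene sets, lexicographic spine order), so identical inputs
  give byte-identical outputs regardless of processing order.
* The quasi-clique degree comparison uses a `1e-9` slack so that
  `gamma * (k - 1)` values like `0.4 * 3` do not flip on floating-point
  representation.
* Empty relation, empty pair table, single-gene genomes: valid inputs,
  empty partitions, exit code 0.
* Genomes given without ranks get dense ranks from row order; explicit
  ranks may be sparse; circular wrap uses `L = max(rank)`.
* Problem sizes: the bundled verification suites run the oracle on
  instances of 2–4 genomes with 8–30 genes each and correspondence
  densities up to 0.3, and the recovery suite plants blocks of 3–5
  families in genomes of 40 genes — comfortable desk-scale sizes chosen so
  the whole suite runs in minutes while still exercising thousands of
  spines per instance.

## Worked example

```{r example}
fx <- otfq_fixture("F2")
part <- otfq_partition(fx$graph, q = 2)
part
maximal_syntons(part)
```

The partition lists four syntons over the five quorum-2 clique spines; the
subsumption filter keeps the two whose gene projections are not contained
in another synton's.

## Known limitations

* Projections report linear rank spans; on circular genomes a synton
  straddling the origin is reported with the enclosing linear span.
* Strand/orientation columns are parsed and ignored by design.
* Partial gene-order conservation (bounding how far matched neighbourhoods
  may shuffle) is outside the model: connectivity is the only order
  constraint.
* The explicit oracle and low quorums on many similar genomes are
  exponential by nature; the engine's `spine_cap` converts runaway cases
  into a clean resource error rather than an out-of-memory crash.
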