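# synton

Exact, quorum-aware detection of synteny blocks across multiple genomes.

## The problem

Comparative genomics routinely needs the conserved gene neighbourhoods —
synteny blocks, gene clusters, gene teams — shared by a set of (typically
bacterial) genomes. The difficulty is that real gene-to-gene correspondence
is messy: thresholded sequence similarity is many-to-many and not
transitive, gene order inside a conserved block gets shuffled, unrelated
genes intrude as gaps, and a block may simply be missing from some of the
genomes. `synton` implements an exact (non-heuristic) detector that handles
all four phenomena with a clear-cut formal definition of the blocks it
reports, so that what is found — and what is missed — is fully specified.

## The model

* Each of the *n* genomes is an **interval graph**: genes carry ranks along
  the chromosome and two genes are neighbours when their rank distance is at
  most δ_gap (circular chromosomes wrap). δ_gap = g tolerates up to g − 1
  intervening gap genes.
* A pairwise correspondence relation **S** links genes of different genomes
  (e.g. BLASTP hits filtered at p ≤ 1e−10, identity ≥ 40 %, alignment
  covering ≥ 80 % of the smaller protein — `filter_blast_pairs()`).
* S is aggregated into **spines**: *n*-tuples assigning to each genome a
  gene or a don't-care mark `*`, with at least *q* (the **quorum**) covered
  genomes, under a topology rule — all genes pairwise related (**clique**),
  merely connected (**connected component**), or each gene related to at
  least γ·(k−1) of the other k−1 covered genes (**γ-quasi-clique**).
* Spines are the vertices of a **partial network alignment multigraph**
  (PNAM) with *n* colour-indexed edge sets: spines are colour-*i* neighbours
  when their genome-*i* genes are interval-graph neighbours.
* A **synton** is a maximal set of spines with a common cover *I* (|I| ≥ q)
  that is connected on every colour in *I*. Syntons partition the PNAM
  vertices; gene-order permutations inside a block are irrelevant to the
  definition.

Two routes compute the partition:

* `enumerate_spines()` + `build_pnam()` + `oracle_partition()` — explicit,
  definition-driven brute force (the oracle path, for verification and
  small instances);
* `otfq_partition()` — the production engine: a depth-first, on-the-fly
  search that alternates **Split** (partition the current class into
  per-colour connected components, replicating don't-care members into each
  part) and **Expand** (add the next genome via terminal genes and
  budget-limited don't-cares), and never materialises the multigraph.

The test suite proves the two routes identical on hundreds of random
instances across all aggregation modes. Post-processing provides the
subsumption (⊑) maximality filter, size filtering, per-genome projections
with gap-gene counts, and the size of the largest synton containing each
correspondence pair.

## Worked example

The package ships a tiny quorum-2 instance (`otfq_fixture("F2")`): genomes
`[a1, b1]`, `[a2, b2]`, `[a3]` with S = {a1–a2, a1–a3, a2–a3, b1–b2}.

```r
library(synton)
fx <- otfq_fixture("F2")
part <- otfq_partition(fx$graph, q = 2)
part
#> synton partition: 4 syntons (quorum 2, 3 genomes)
#>  synton n_spines    cover
#>       1        1    G2+G3
#>       2        1    G1+G3
#>       3        2    G1+G2
#>       4        1 G1+G2+G3
```

Five clique spines exist — (a1,a2,a3), (a1,a2,\*), (a1,\*,a3), (\*,a2,a3),
(b1,b2,\*) — and they fall into four syntons; the largest, on cover
G1+G2, holds the two spines (a1,a2,\*) and (b1,b2,\*) because a1/b1 and
a2/b2 are chromosome neighbours. The subsumption filter then discards the
two singletons whose genes are contained in the full three-genome spine:

```r
maximal_syntons(part)
#> synton partition: 2 syntons (quorum 2, 3 genomes)
#>  synton n_spines    cover
#>       1        2    G1+G2
#>       2        1 G1+G2+G3
max_synton_size_per_pair(part, fx$graph)
#>   gene1 gene2 max_size
#> 1    a1    a2        2
#> 2    a1    a3        1
#> 3    a2    a3        1
#> 4    b1    b2        2
```

`synton_report(part, fx$graph)` tabulates per-genome gene lists, rank spans
and gap-gene counts; `run_pipeline()` does the same from TSV files and
writes `syntons.tsv/json`, `spines.tsv`, `projections.bed`,
`pair_max_size.tsv` and `summary.json`.

The same workflow is available from a shell:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "otfq.R", package = "synton"))') \
    run --genes genes.tsv --pairs pairs.tsv --out results \
    --quorum 2 --gap 1 --mode clique --min-size 1
```

with subcommands `run`, `simulate` (seeded planted-block instances),
`fixtures` and `blast-filter`. Note `--gap G` means rank distance ≤ G,
i.e. up to G − 1 intervening genes.

## Scope

The package detects inter-genomic syntenies from gene order and a given
correspondence relation. It does not compute sequence alignments or BLAST
hits, infer orthology, look for intra-genomic (self) syntenies, use gene
strand/orientation, or score partial gene-order conservation.
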