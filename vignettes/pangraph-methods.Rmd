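---
title: "Gene graphs and generalized bibubbles: models and methods"
author: "pangraph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene graphs and generalized bibubbles: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its models: what is computed,
under which assumptions, which knobs matter, and where design was genuinely
open and a choice had to be made. It states no empirical result that the
test suite or `scripts/acceptance.R` does not itself compute.

## The gene graph

The unit of analysis is the gene, never the nucleotide. An input panel is a
set of genome assemblies, each already aligned against a common protein set
with a spliced protein-to-genome aligner; one PAF file per assembly is the
interface. After annotation (below), every contig is encoded as a *walk* of
oriented genes `>v` / `<v`, and each consecutive pair `(x, y)` on a walk
contributes the directed edge `x -> y` together with its skew twin
`flip(y) -> flip(x)`. Edges are stored once, in a canonical orientation (the
smaller integer pair of the two twins), with both directed views synthesised
on access — skew symmetry therefore cannot be violated by any mutation.
Multi-edges do not exist (edge identity is the ordered oriented pair;
repeated contig support accumulates in the support set) and self-edges
(`>B -> >B`, the signature of a tandem duplication) are legal everywhere.
Isolated genes may exist, but edges arise only from walks: a gene appearing
in no walk carries no edges.

Each directed view carries the score `S(x|y)`: the mean over supporting
contigs of the alignment score of `x`'s placed hit there, averaging within a
contig first when an adjacency repeats on it. The twin view averages the
other endpoint's scores, so `S(x|y)` and `S(flip(y)|flip(x))` generally
differ.

## Annotation: from raw hits to one consistent placement

Raw hits are noisy in three specific ways, each with its own mechanism:

* **Redundant proteins.** Several proteins may name the same gene
  (`gene:protein` identifiers); the protein maximising the summed best-hit
  score over genomes is kept, ties by hash.
* **Orthologs competing for a locus.** For every gene `v`, `b(v)` counts the
  genomes where `v`'s best hit out-scores all genes overlapping it. Genes
  are selected greedily in descending order of the *current* `b(v)`
  (lazy-deletion priority queue; hash tie-breaks); selecting `v` decrements
  `b(w)` once for every genome where `w` overlaps `v` but out-scores it,
  floored at zero, and genes popped at zero are rejected. Orthologs share
  loci and collapse to one representative; paralogs at distinct loci all
  survive.
* **Processed pseudogenes.** An intronless hit of a gene that aligns with
  splicing elsewhere is suppressed (`default` mode); `strict` additionally
  drops genes with no spliced hit anywhere, and `off` disables the filter —
  the correct setting for bacteria, where nothing is spliced.

Placement is per-contig greedy: hits of selected genes are taken in
(unmarked, score, hash) order and accepted when they do not overlap an
accepted hit. A gene may be placed several times on a contig — that is how
copy gains are representable at all.

Two score-ratio heuristics then use graph topology to fix systematic
mis-placements. When a gene's true locus is missing from an assembly
entirely (a lost chromosome, a real deletion), its hit is dragged onto a
paralogous locus and creates edges joining unrelated regions. An edge
`x -> y` is a *false edge* when some competitor `x -> z` exists with
`S(x|y) < S(x|z) * r1` and the genes of `y` and `z` never share a contig in
any genome; every placed hit of `x`'s gene incident to a false edge is
deleted and walks are rebuilt with adjacency re-joined. When `y`'s and `z`'s
genes do co-occur somewhere (the competing loci are genuinely nearby), the
weaker edge is instead marked *low priority* at `r2`, the incident hits
inherit the mark, and placement is re-run once preferring unmarked genes at
each locus. We evaluate the contig condition on the placements of the genes
of `y` and `z` — not on the adjacency instances themselves — because
presence of the two neighbours on one contig is exactly the evidence that
the competing loci are parts of one region.

Finally, topology filters remove genes whose bidirected degree exceeds
`max_gene_edges`, genes placed at more than `max_distant_loci` distinct loci
(same-contig placements closer than `locus_merge_distance` merge into one
locus — the merge distance is a coordinate-space choice, 100 kb by default,
comfortably above intergenic spacing and below chromosome scale), rare genes
below `min_gene_freq`, and optionally single-coding-exon genes; edges with
fewer than `min_edge_support` supporting contigs are pruned last. Gene
removal elides walk steps and re-joins adjacency, so pruning can never
fragment a chromosome into disconnected walk pieces.

### Parameters that matter

| parameter | default | unit | why |
|---|---|---|---|
| `r1` | 0.95 | score ratio | false-edge threshold; mirrors the reporting cutoff of spliced aligners for secondary hits |
| `r2` | 0.98 | score ratio | low-priority threshold; tighter because the competing loci are nearby and scores comparable |
| `overlap_min` | 0.5 | fraction of shorter interval | two hits compete only when they genuinely share a locus; 1 bp contact is not competition |
| `min_edge_support` | 1 | contigs | raise to 2 to drop adjacencies seen on a single contig |
| `max_gene_edges` | 10 | edges | promiscuous genes (collapsed repeat families) add hub noise |
| `max_distant_loci` | 3 | loci/genome | a gene hit at many distant loci is a repeat, not a gene |
| `min_gene_freq` | 0.05 | fraction of genomes | set to ~0.001 to keep everything |
| `locus_merge_distance` | 1e5 | bp | cluster radius for the locus count |

## Bibubbles

`U(x, y)` is the set of genes reachable from `x` without passing through
`x`, `flip(x)` or `y`; passage through `flip(y)` is allowed, contributes the
exit's gene, and traversal continues through it — without this allowance,
inversions adjacent to the exit would be misclassified. The checker accepts
`(x, y)` when:

1. `U(x,y) = U(flip(y), flip(x))` and both are non-empty;
2. every interior gene lies on some `x -> y` walk (operationally: some
   orientation `z` of the gene is reachable from `x` and reaches `y`, the
   latter via the skew-symmetric closure from `flip(y)`);
3. *minimality*: no oriented gene over the interior heads a nested pair with
   a non-empty two-sided-equal interior against `x` or `y`;
4. *variation*: the enclosed subgraph admits at least two distinct `x -> y`
   traversals — operationally, out-branching (two or more distinct
   successors, self-loops counted) at some oriented gene on the entrance
   side or, symmetrically, on the twin side;
5. *boundary*: the entrance and exit genes are cycle equivalent in the net
   graph.

Conditions 4 and 5 deserve their derivations, because the plain conditions
1–3 admit two families of degenerate pairs.

**Why non-emptiness in 3, and why condition 4 exists.** If the nested-pair
veto in condition 3 admits the trivial case where both sides are empty, the
tandem-duplication bubble (`>A >B >C` vs `>A >B >B >C`) is vetoed by its own
interior gene — every `U` involving an adjacent pair is empty — and
copy-number gains become undetectable. Requiring non-emptiness repairs that,
but then an invariant run `A-B-C` seen identically in every genome
satisfies conditions 1–3 verbatim (`U = {B}` on both sides, and no non-empty
nested pair exists to veto it). No checker built from `U`-set comparisons
alone can tell these two cases apart: the tandem-duplication graph and the
invariant chain have *identical* `U` sets for every oriented pair, because a
self-loop adds no new vertex to any reachability set. The distinguishing
feature is the number of distinct traversals — one in the chain, several
through a self-loop, deletion edge or inversion — and that is precisely
condition 4. Any two distinct `x -> y` walks must diverge at some forward
branch point, so out-branching among the visited nodes is an exact
operational test; it is evaluated on both twin sides to keep the checker
symmetric under reverse complement.

**Why condition 5 exists.** The two-edge cut-set characterisation links
bubble boundaries to cycle equivalence in the net graph. The converse
direction fails for pairs involving a self-loop: a tandem entrance `>B` has
two distinct walks to any downstream gene (through its self-loop), passes
conditions 1–4 against a neighbour, yet `{B, neighbour}` is no two-edge
cut — the putative bubble straddles the *adjacent* event instead of
enclosing its own. Making cycle equivalence an explicit condition of the
checker rather than a pruning trick of the enumerator keeps the brute-force
definition scan and the fast search in exact agreement, which the test suite
asserts on hundreds of seeded random graphs.

### Cycle equivalence

The net graph splits gene `v` into ports `(v,s)` and `(v,e)`, turns every
adjacency into a link edge between the head of `x` and the tail of `y`, and
contracts all links (union-find); genes become the edges of an undirected
multigraph. Two edges are cycle equivalent when every cycle through one
passes the other. All bridges share one designated acyclic class — the
definition holds vacuously on them, and this convention is what co-classes
the entrance and exit of a bubble embedded in a linear chromosome. The
implementation builds a spanning forest, gives every non-tree edge a
deterministic 62-bit label from two fixed Lehmer streams, and propagates XOR
sums bottom-up so that each edge's signature encodes exactly the set of
fundamental cycles covering it; two edges are cycle equivalent iff they are
covered by the same set (for non-bridge pairs this is the two-edge cut-set
criterion). Signature collisions would require two distinct cover sets whose
labels XOR equal over 62 bits; the labels are fixed, so results are
reproducible across platforms, and the construction is checked against a
definition-level oracle that enumerates every simple cycle on small graphs.

### Enumeration

For each candidate entrance the search runs a BFS over at most `m` genes
(default 100; entrance excluded, boundary candidates still tested), testing
co-classed exits in discovery order. Three facts keep this fast and exact:

* an entrance can head a bubble only if out-branching is reachable along
  its unique-successor chain (condition 4), which is precomputed for all
  oriented genes by vectorised propagation;
* once any candidate exit passes condition 1, no later exit in search order
  can head a bubble for this entrance — minimality vetoes it through that
  candidate — so the entrance is settled by the first two-sided-equal
  candidate, which in a chain is at distance two;
* interior expansions during candidate tests are capped at the traversal
  budget `m`: a bubble larger than `m` genes is not reported, matching the
  enumeration budget, and an aborted expansion simply fails the candidate
  (or, inside minimality, vetoes nothing). The cap never binds on graphs
  smaller than the budget, so the oracle-equivalence tests compare the
  uncapped semantics.

The default entrance set is *all* oriented genes: a degree-one entrance can
head a real bubble (the tandem toy), so the branching-entrance heuristic is
available as an option for speed but not as the default. The enumerator
expands past failed candidates rather than stopping at them; stopping is
safe only for the successful exit, and exactness against the brute-force
scan is the acceptance bar. Twin pairs are reported once; the canonical
representative prefers a forward-oriented entrance (hash of the entrance
string as tie-break), and the result is ordered by entrance hash.

## The simulator

`simulate_pangenome()` emulates what the real pipeline consumes: an
ancestral order of `n_genes` split into chromosomes, per-genome deletions,
inversions (spans of 1–3 genes) and tandem duplications (one or two extra
copies) applied independently at per-gene rates (defaults 2%/1%/1%),
coordinates on a fixed geometry (1 kb genes, 10 kb intergenic), alignment
scores around 500 with 1% relative noise, 10% single-exon genes, and
optional paralog families whose members produce cross-hits at each other's
loci at 93% of the local score. Cross-hit scores are derived as
ratio × (noisy local score), not independently noised, so the `r1`/`r2`
threshold comparisons are exact at the default margins — with independent
noise the 2% margin between 0.93 and 0.95 would be crossed by chance and
fixture behaviour would not be deterministic.

With `enforce_spacing` (the default), sampled events closer than three
unaffected genes to another event site or lacking a flank inside the
chromosome are dropped; every surviving site then yields exactly one
expected bubble — the forward flanking pair around the affected span —
unless all genomes display the same local haplotype (no variation, no
bubble). The chromosome-end margin is part of the same study condition: an
inversion touching a contig end produces an entrance-only topology that is
not a two-sided bubble. With `enforce_spacing = FALSE` the generator
produces dense, overlapping events and derives no expected list; this messy
mode is what the oracle-equivalence tests feed on.

What the simulator does **not** model: sequence-level alignment error,
partial hits and split exons, score heterogeneity between genes,
translocations and chromosome-scale rearrangements, assembly gaps, and
genuinely nested or interacting events. Passing the recovery tests therefore
shows that the pipeline inverts the generator's event classes exactly under
clean alignments; it does not show robustness to alignment artefacts beyond
the paralog cross-hit and chromosome-loss scenarios, which are modelled
explicitly (`simulate_ortholog_pair()`, `simulate_chrx_loss()`).

## Numerical and degenerate-input choices

* All tie-breaks (protein choice, best hits, selection order, bubble
  canonical form and ordering) use a 64-bit FNV-1a hash of identifiers,
  verified against the published test vectors, so runs are byte-identical
  across platforms; nothing depends on R's locale-sensitive string order.
* Score ties in the "aligned better" relation resolve by gene-name hash, so
  `b(v)` and the selection are total and deterministic.
* `classify_core` accepts thresholds in `[0, 1]` inclusive; a gene must be
  present somewhere to be core, so threshold 0 marks exactly the present
  genes.
* Empty graphs, edgeless graphs, single-gene walks and empty bubble sets
  are legal everywhere and covered by tests; `compute_U` requires `x != y`,
  and pairs over one gene are rejected by the checker directly.
* The low-priority re-annotation is a single pass, not a fixpoint
  iteration: the marks encode one round of evidence, and iterating could
  oscillate between competing paralogs.
* GFA W lines store only the walk interval, so per-step coordinates are
  synthesised on reading (preserving the interval); graph structure, walks
  and scores round-trip exactly, coordinates do not.

## Problem sizes used by the tests

Oracle equivalence runs 200 random pangenomes of 6–25 genes (bubbles) and
200 random multigraphs of up to 12 edges (cycle classes); end-to-end
recovery runs twenty panels of 10 genomes × 200 genes from PAF input; the
scale check builds one panel of 20,000 genes × 10 genomes at event rates an
order of magnitude lower (0.2%/0.1%/0.1%), chosen so the graph has the
edge-to-gene ratio and the order of hundreds of bubbles characteristic of a
real single-species panel of that size rather than of the dense toy
configurations.

## Known limitations

Bubbles are local by construction: chromosome-scale inversions,
translocations and events at contig ends do not form two-sided bubbles and
are out of scope. The gene is atomic — exon gain/loss and gene fusions are
invisible. Orthology is positional, not phylogenetic: a paralog that
out-scores the true ortholog in most genomes will absorb it, and the
presence/absence report inherits such artefacts. The quadratic definition
scan is a test oracle only; the fast enumerator is near-linear on sparse
gene graphs but still tests every oriented entrance, so dense hub-rich
graphs benefit from the degree and locus filters first.
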