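---
title: "Rank and rank-indel distances: model, algorithms, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rank and rank-indel distances: model, algorithms, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rankindel)
```

## The model

A *marker* is a conserved genomic unit (a gene, operon, or synteny block)
with two *extremities*, a tail $g_t$ and a head $g_h$. Given a universe $G$
of $n$ markers, the $2n$ extremities are identified with the canonical basis
of $\mathbb{R}^{2n}$ (tail of the $i$-th marker at index $2i-1$, head at
$2i$). A genome $A$ is a set $V(A)$ of present extremities plus a matching
$E(A)$ of *adjacencies* on them; extremities outside any adjacency are
*free ends* (linear chromosome termini). Crucially, $V(A)$ need not cover
$G$: missing markers are simply zero rows/columns. The genome becomes the
symmetric binary matrix with $Ax = y$ for adjacencies $\{x, y\}$, $Ax = x$
for free ends, and $Ax = 0$ for absent extremities; a binary matrix is
genomic iff $A^\top = A$ and $A^2$ is diagonal with 0/1 diagonal.

The **rank distance** between two genomes is
$d_r(A, B) = r(B - A)$, the rank of the matrix difference. It is a metric,
and it equals the minimum total weight of a *sorting scenario* built from
six basic operations whose weights are the ranks of their matrices:

| operation | weight |
|---|---|
| cut (remove one adjacency) | 1 |
| join (create one adjacency) | 1 |
| double swap (re-match two adjacencies) | 2 |
| delete a whole (semi-)chromosome of $k$ extremities | $k$ (i.e. $2k$ markers-wise) |
| insert a whole (semi-)chromosome | same |
| substitute one present extremity by an absent one | 2 |

Extremity substitutions can leave a marker with only one extremity present
(a *relaxed* genome, with *semi-chromosomes* ending in a lone extremity).
To avoid that, the **rank-indel distance** $d_i$ allows only the first five
operations and whole-marker genomes throughout.

Both distances have closed forms over the *augmented breakpoint graph*
$BG(A, B)$: nodes are all $2n$ extremities, black edges $E(A)$, gray edges
$E(B)$. Components are paths and cycles; paths are classified by their
endpoints (free end vs. absent in $A$ or $B$) as proper, $A$-null,
$B$-null, $AA$-null, $BB$-null, or $AB$-null. With $c$ cycles, $p_0$ proper
paths and $p_{AB}$ $AB$-null paths:

$$d_r = 2n - 2c - p_0 - p_{AB}, \qquad d_i = 2n - 2c - p_0 + p_{AB},$$

so $d_i = d_r + 2\,p_{AB} \ge d_r$, with equality iff no $AB$-null path
exists. A node absent from both genomes is counted as a proper path — the
convention that keeps both formulas consistent (for $d_r$ either choice
works; for $d_i$ only this one does).

`rank_distance_bfs()` evaluates $d_r$ in $O(n)$ by a single traversal: each
component scores $s$ = (#A-null) − (#B-null) extremities; zero-score
components decrement the running total $2n$ by 1 (path) or 2 (cycle).
The package also evaluates both closed forms from classified components and
the exact integer rank of $B - A$; the three routes are asserted equal on
randomized suites, and that triple redundancy is the package's primary
self-check.

## Numerical choices

* **Exact rank.** `exact_rank()` uses fraction-free (Bareiss) elimination.
  Entries here are in $\{-1, 0, 1\}$ and extremely sparse, so intermediates
  stay tiny; a guard aborts (rather than silently losing exactness) if any
  intermediate exceeds $2^{52}$. No floating-point tolerance exists
  anywhere in the distance computations — distances are integers.
* **Ties and determinism.** Breakpoint-graph components are emitted in
  ascending minimum-node order; chromosome walks start from the
  lower-indexed endpoint; candidate operations in sorting are scanned in a
  fixed order. Identical inputs always give identical outputs.
* **2-cycles.** A shared adjacency contributes a black and a gray parallel
  edge forming a 2-cycle, so $A = B$ yields $c = |E(A)|$ and distance 0.

## Sorting scenarios

`sort_rank()` and `sort_rank_indel()` return explicit operation sequences
whose total weight equals $d_r$ and $d_i$ respectively. The implementation
is a *verified greedy*: at each step it enumerates candidate operations and
accepts the first whose application decreases the remaining distance by
exactly its weight. Because the distance provably equals the optimal
scenario weight, every state with positive distance admits such a step, and
any such step keeps the trajectory optimal — so the greedy never needs
backtracking; an internal error is raised if no candidate qualifies (this
would indicate a bug, not an input problem).

Candidates are exhaustive for cuts, joins, double swaps, whole
(semi-)chromosome deletions and (in rank mode) extremity substitutions.
Insertions cannot be enumerated exhaustively — any chromosome over absent
markers could be inserted — so the candidate set is restricted to
components of the target's adjacency-plus-marker-edge structure over absent
extremities, *augmented with one closing edge per AA-null path* linking its
two endpoints. The closing edges matter: when a path of $BG(A, B)$ has both
endpoints absent from $A$, the optimal insertion places those two
extremities adjacent *inside* the inserted chromosome (even though that
adjacency is in neither genome), turning the path into a cycle. Without
them the greedy provably stalls on such configurations; with them the
weight contract holds on every randomized suite we run (200+ pairs per
mode, all intermediates validated against the matrix route).

Per-component weight accounting is deliberately *not* asserted anywhere:
only scenario-total optimality is part of the contract.

## The simulator's stated world

`simulate_replicate()` emulates a benchmark design at desk scale: a random
binary tree (topology via `ape::rtree`, exponential branch lengths), a root
genome of `n_genes` markers over `n_chromosomes` linear chromosomes, and on
each branch of length $\ell$: Poisson($\ell$) DCJ steps, Poisson($\ell
\cdot$ insertion rate) insertions and Poisson($\ell \cdot$ deletion rate)
deletions, with segment lengths from a Zipf distribution. Defaults are 20
chromosomes, 5000 genes, insertion rate 0.2, deletion rate 0.4, duplication
rate pinned at 0 (the model excludes repeated markers), Zipf exponent 3.5.

Choices the source design left open, fixed here once:

* **Branch-length units.** Branch lengths are *expected DCJ event counts*
  (mean 10 per branch by default) — the natural reading of "Poisson with
  expectation equal to the edge weight" that also gives desk-scale trees a
  realistic signal-to-noise ratio.
* **DCJ realization.** Two distinct cut points (adjacencies or free ends)
  chosen uniformly, rejoined by a uniformly chosen non-identity
  reassembly; fissions arise through the adjacency-plus-free-end case,
  circularizations through free-end joins.
* **Indel placement.** Deletions remove a uniform contiguous run (truncated
  at the chromosome boundary, flanks rejoined); insertions splice a fresh
  run into a uniform adjacency or free end. Inserted markers get globally
  fresh names, so duplications are structurally impossible. Zipf lengths
  truncated at 50.

What the generator does *not* emulate: duplications and paralogy, unequal
rates across lineages, hotspots, or any sequence-level signal. A green
end-to-end test therefore establishes that the distances recover simulated
rearrangement histories — not that they resolve real phylogenies, where
homology assignment dominates the error budget.

## Phylogenetic evaluation

`distance_matrix()` feeds `neighbor_joining()` (own implementation of
standard NJ with the Studier–Keppler criterion; `ape::nj` is used only as a
test oracle). Negative branch-length estimates are clamped to zero.
Tree accuracy is measured two ways:

* `rf_normalized()`: symmetric difference of non-trivial bipartitions over
  the total bipartition count of both trees.
* `quartet_distance()`: fraction of leaf quartets with different induced
  topologies, by explicit enumeration over $\binom{n}{4}$ subsets
  (practical to $n \approx 25$; no sub-quadratic algorithm is attempted).
  Convention for non-binary trees: a quartet agrees when both trees induce
  the same resolved split or both leave it a star; a star never matches a
  resolved split. Two random resolved trees agree on about $1/3$ of
  quartets, so ~$2/3$ is the no-signal baseline the end-to-end test must
  beat.

## Known limitations

* Duplicated markers are rejected by construction (a DuplicateMarkerError);
  handling paralogs requires a different model entirely.
* The sorting construction is quadratic-ish in genome size because of its
  candidate scans; it is meant for explanation-sized genomes, while the
  distances themselves scale linearly to full bacterial genomes.
* `quartet_distance()` is brute force; use dedicated tools beyond ~25 taxa.
* The gene-order dialect is this package's own (UniMoG-inspired: `$`
  linear, `)` circular terminators); no byte-level interoperability with
  other tools is guaranteed.
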