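---
title: "Recursive module extraction: model, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recursive module extraction: model, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(modrec)
```

## The problem

Molecular networks — protein–protein interaction, co-expression,
signalling, homology — are modular: groups of genes or proteins that are
densely interconnected often share a biological function or a disease
association. `modrec` extracts such modules under a hard size constraint:
every emitted module must contain between 3 and $k$ nodes ($k \le 100$),
modules must be disjoint, and nodes may remain unassigned. The size cap is
what makes this different from ordinary graph partitioning: the best
modularity partition of a large network routinely contains communities of
thousands of nodes, and the biologically interesting structure can hide
*inside* them.

## The model

### Standardization

All clustering operates on undirected graphs with weights in $[0, 1]$.
Two preprocessing operations bring heterogeneous networks into that form:

* `to_undirected()` replaces each ordered arc pair by one undirected edge
  carrying the average of the two directed weights,
  $w_{\{u,v\}} = (w_{uv} + w_{vu})/2$, with a missing reverse arc counting
  as 0. We take the literal average even for one-directional arcs (so a
  lone arc of weight $w$ becomes an edge of weight $w/2$): the alternative
  of keeping $w$ unchanged would make the conversion discontinuous as the
  reverse weight approaches zero. Pairs that average to exactly 0 are
  dropped — a zero-weight edge is invisible to both weighted modularity
  and weighted PageRank.
* `normalize_weights()` divides all weights by the global maximum, once,
  before any clustering. Subnetworks extracted later keep their original
  weights: re-normalizing at each recursion level would silently change
  the relative importance of edges between levels.

### Modularity and Louvain

Community quality is the Newman–Girvan modularity
$$
Q = \frac{1}{2m} \sum_{ij} \left[ A_{ij} - \frac{s_i s_j}{2m} \right]
    \delta(c_i, c_j),
$$
with $A$ the weighted adjacency, $s_i$ the node strength and $m$ the
total weight. Self-loops (which arise only from Louvain aggregation)
enter with $A_{ii}$ equal to *twice* the loop weight, so that
$\sum_i s_i = 2m$ holds exactly and the one-community partition scores
exactly 0.

`louvain()` is the standard two-phase greedy maximizer — local single-node
moves until no gain, then aggregation of communities into supernodes,
repeated until $Q$ stops increasing — with one deliberate extension of the
classic algorithm: it accepts an **arbitrary initial partition**, honored
as-is before any move. Move gains are computed incrementally from
per-community accumulators $\Sigma_{tot}$ (member strength) and
$\Sigma_{in}$ (internal adjacency); the test suite asserts after every
accepted move that the incremental $Q$ agrees with a from-scratch
recomputation to $10^{-10}$.

Two numerical conventions keep runs reproducible: ties among equally good
destination communities go to the smallest community label, and a move is
only accepted when its gain exceeds $10^{-12}$ (guarding against
floating-point livelock). The node visit order is reshuffled every sweep
from a caller-supplied seed, which reproduces the restart-to-restart
variability the method is known for while keeping any single run
bit-reproducible.

### PageRank seeding

Started from all singletons, Louvain is highly variable. The seed
partition reduces that variability by exploiting the intuition that an
idealized module resembles a clique around locally authoritative nodes.
`weighted_pagerank()` computes
$$
PR(v) = \frac{1-d}{N} + d \sum_{u \sim v} PR(u) \frac{w_{uv}}{s_u},
$$
by power iteration (damping $d = 0.85$, the classic default, exposed as a
parameter; L1 tolerance $10^{-9}$; dangling nodes teleport uniformly).
`seed_partition()` then points every node at its highest-scored neighbor
— or at itself if no neighbor scores *strictly* higher, so that uniform
regions fall back to the classic singleton start — and takes the
connected components of the pointer graph as the starting communities.
Ties among equally scored neighbors go to the lexicographically smallest
node id.

### Recursion

`extract_modules()` maintains a work list, initially the whole network.
Each popped network gets fresh PageRank scores, a fresh seed partition
(never inherited from the parent), and a Louvain run. Communities of size
$3..k$ are emitted; size $< 3$ discarded; size $> k$ extracted as an
induced subgraph and pushed back. Child RNG seeds are derived
deterministically from the run seed and the subnetwork's emission index,
so one integer reproduces an entire run byte-for-byte.

## Design choices made where the design was open

**Escape-to-singleton moves.** Classic local moves only relocate a node
into a *neighbor's* community. That is complete when starting from
singletons, but with a coarse initial partition it can leave obviously bad
blocks intact. We therefore also offer each node a fresh empty community
(gain 0 after removal), taken only when strictly better than every
existing destination. From singleton starts this option never fires, so
the classic behavior is unchanged; monotonicity of $Q$ is preserved.

**The degenerate seed and the unsplittable-discard rule.** The pointer
components of a dense subnetwork frequently collapse into a *single* seed
block. The all-in-one partition is a strict local optimum of single-node
moves — removing any node changes $Q$ by $-s_v^2/(2m)^2 < 0$ — so a
seeded Louvain run returns such a subnetwork whole, whatever its internal
structure. Declaring it unsplittable at that point would silently discard
recoverable modules. `extract_modules()` therefore retries exactly once
from the all-singletons start (with a deterministic child seed) before
discarding. Genuinely cohesive graphs — cliques are the canonical case —
come back whole from singletons too and are then discarded: an oversized
community that cannot be split is dropped rather than emitted, the only
policy that both terminates and never emits an invalid module. Every
subnetwork pushed onto the work list is strictly smaller than its parent,
so termination needs no depth bound; `max_depth = 50` exists purely as
defense in depth.

**Level used for module emission.** Louvain produces a hierarchy; modules
are read off the final (coarsest) partition of each subnetwork, since the
recursion itself supplies the refinement that reading earlier hierarchy
layers would approximate.

**Duplicate edges.** The interchange format gives no sanctioned meaning to
a repeated unordered pair, so the reader rejects duplicates rather than
summing or overwriting.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `k` | 100 | maximum module size (3–100); smaller values force deeper recursion |
| `damping` | 0.85 | PageRank teleportation damping, dimensionless |
| `tol` | 1e-9 | PageRank L1 convergence tolerance |
| `max_iter` | 200 | PageRank iteration cap; non-convergence warns and returns |
| `rng_seed` | — | single integer controlling sweep shuffles and all child seeds |
| `max_depth` | 50 | recursion guard; never reached on valid inputs |

## What the synthetic benchmarks emulate — and what they do not

`planted_partition()` generates the classic planted-block model: blocks of
given sizes, intra-block edge probability `p_in`, inter-block `p_out`,
weights uniform on `[weight_low, weight_high]`. `nested_planted()` adds a
second tier (sub-blocks inside super-blocks with
`p_sub > p_super > p_bg`), which is exactly the structure that defeats a
single clustering pass when super-blocks exceed $k$: the standard
recursion-recovery check uses 4 super-blocks of 2 ten-node sub-blocks at
probabilities 0.9/0.3/0.01 and $k = 15$.

These generators have uniform weights and Bernoulli edges; real molecular
networks have heavy-tailed degrees, weight structure correlated with
topology, and noise that no block model captures. A green recovery test
therefore establishes that the recursion mechanics work — oversized
communities are re-clustered and planted structure at the stated
separation is found — not that any particular biological network will
yield significant modules. The published evaluation of this method relied
on GWAS-based module scoring of six benchmark networks; that scoring
pipeline and those networks are external and deliberately out of scope
here.

`nmi()` scores recovery: mutual information of the block contingency
table normalized by the arithmetic mean of the two entropies (one fixed,
documented convention — mixing normalizations across tools is a classic
source of silent inconsistency). Two single-block partitions compare as 1.

## Known limitations

* Only the Newman–Girvan criterion is implemented; no resolution
  parameter. The resolution limit of modularity is partially mitigated by
  the recursion itself (small structure is recovered inside extracted
  subnetworks), which is the method's point.
* Pure-R implementation: comfortable to a few thousand nodes; the
  million-edge scale of real molecular networks would want a compiled
  inner loop.
* One directed-to-undirected policy (averaging) and one weight
  normalization (max-division); alternatives (sum, max, union;
  quantile normalization) are out of scope.
* Unassigned nodes are reported only in aggregate (`stats$discarded_nodes`).
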