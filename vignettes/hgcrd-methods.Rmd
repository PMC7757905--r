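---
title: "Local hypergraph clustering by capacity-releasing diffusion: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Local hypergraph clustering by capacity-releasing diffusion: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hgcrd)
```

## The problem

Biological interaction networks — metabolic networks in particular — are
often better described by *hypergraphs* than by graphs: one reaction couples
several metabolites at once, and one higher-order pattern (motif) couples
several nodes at once. Given one node of interest (a seed), we want the
well-connected cluster around it, where "well-connected" is measured with
respect to motifs rather than single edges. The method implemented here is a
*local* algorithm: its work scales with the size of the output cluster, not
with the size of the network, so it never needs to touch most of a large
graph.

## Cluster quality: motif conductance

For a graph $G = (V, E)$ and a set $S$, conductance is
$\phi(S) = |\mathrm{cut}(S)| / \min(\mathrm{vol}(S), \mathrm{vol}(V \setminus S))$,
with cut edges counted once and volume the sum of (weighted) degrees. The
motif generalization replaces edges by motif instances. Writing $M$ for a
motif of size $k$ and treating each instance as a hyperedge:

* $\mathrm{cut}_M(S)$ — number of instances with at least one end point on
  each side of the boundary;
* $\mathrm{vol}_M(S)$ — number of instance end points in $S$, i.e.
  $\sum_{v \in S} \eta(v)$ with $\eta(v)$ the number of hyperedges containing
  $v$;
* $\phi_M(S) = \mathrm{cut}_M(S) / \min(\mathrm{vol}_M(S), \mathrm{vol}_M(V \setminus S))$.

We use end-point counts (not the $(k-1)$-scaled "degree volume"
$\sum_{v \in S} d_M(v)$) in the ratio; for uniform hypergraphs the scale
factor cancels, so the two conventions give the same $\phi_M$, and end-point
counts stay meaningful for variable hyperedge sizes. A set whose smaller
side carries no end points has *undefined* conductance: the package raises
an error rather than returning a sentinel, because a silent 0 or `Inf`
corrupts the argmin taken in sweep cuts (the sweep skips such prefixes
instead).

The motif degree is $d_M(v) = (k - 1)\,\eta(v)$ for $k$-uniform hypergraphs.
For variable sizes we define $d_M(v) = \sum_{e \ni v} (|e| - 1)$ — the
unique per-edge-additive extension, consistent with the per-edge eligibility
threshold $|e| - 1$ used by the diffusion and reducing to the uniform
formula when all sizes agree.

## The diffusion

`hgcrd()` finds a low-$\phi_M$ cluster by pushing integer units of *flow*
through hyperedges until a bottleneck reveals the cluster boundary. Each
node $v$ carries a flow $m_M(v)$, an excess
$\mathrm{ex}(v) = \max(m_M(v) - d_M(v), 0)$, and an integer level
$l(v) \le h$; each hyperedge carries a flow $m_M(e)$ bounded by the capacity
$C$.

One **inner run** is a push–relabel process. A node is *active* when its
excess reaches $\min_{e \ni v}(|e| - 1)$ and its level is below $h$. Active
nodes are processed lowest level first (FIFO among equal levels). The node
scans its incident hyperedges in order and pushes through the first
*eligible* one — at least $\alpha$ co-members strictly below its level,
positive residual capacity $\min(l(v), C) - m_M(e)$, and excess at least
$|e| - 1$ — sending
$\Psi = \min\left(\lfloor \mathrm{ex}(v)/(|e|-1) \rfloor,\; r(e),\; \min_{u}(2 d_M(u) - m_M(u))\right)$
units to every co-member and losing $(|e|-1)\Psi$ itself. If no eligible
hyperedge exists, or the chosen one admits $\Psi = 0$ (receivers saturated
at their $2 d_M$ cap can force this), the node's level rises by one; at
level $h$ it retires. Total node flow is conserved exactly, all quantities
stay integral, and levels never decrease within a run — properties the test
suite re-checks by replaying recorded event logs.

The **outer loop** (iterations $j = 0, \dots, t$) starts from
$m_M(\mathrm{seed}) = d_M(\mathrm{seed})$ and each round doubles all flows,
runs the inner routine, sweep-cuts the resulting levels, then truncates
every node's flow to its degree ("capacity releasing": retained flow doubles
next round). If nothing piles up as excess, the total after truncation would
be $2 d_M(s) 2^j$; the loop stops early once the retained total drops to
$1/\tau$ of that, i.e. more than a $1 - 1/\tau$ fraction was removed as
excess — the signature of a bottleneck. The **sweep cut** orders touched
nodes by level (descending; ties by flow descending, then label), evaluates
$\phi_M$ of every prefix, and the best prefix over all iterations is
returned, together with the *excess cluster*
$\{v : m_M(v) \ge d_M(v)\}$ that the theory characterizes
(`excess_cluster()`), the per-iteration history, and the termination reason.

### Variants

* `crd()` — the edge-based ancestor, realized exactly as the diffusion on
  the 2-uniform hypergraph of the graph's edges ($d_M$ = degree,
  eligibility reduces to $l(v) > l(u)$). The suite verifies the reduction
  push for push.
* `crd_m()` — the motif-adjacency variant: the weighted graph $W_M$, with
  $W_M(u, v)$ the number of motif instances containing both $u$ and $v$, is
  built from the motif hypergraph, and the edge diffusion runs with every
  capacity scaled by the weight (residual
  $\min(l(v), C)\,W_M(u,v) - m_M(e)$, node caps at twice the weighted
  degree $\sum_j W_M(v, j)$, which equals $d_M$ for 3-node motifs). Sweep
  prefixes are still scored by motif conductance on the motif hypergraph,
  so all three algorithms report comparable numbers. For 3-node motifs,
  conductance on $W_M$ *equals* motif conductance — an identity the suite
  checks exhaustively on small random graphs.

## Parameters

| name | meaning | default |
|---|---|---|
| `phi` | target conductance scale in $(0, 1]$ | — (optional if `C`, `h` given) |
| `C` | hyperedge capacity (integer units of flow) | $\lceil 1/\phi \rceil$ |
| `h` | maximum node level | $\lceil 3 \ln(\text{total flow}) / \phi \rceil$ |
| `tau` | excess-removal stopping factor ($> 1$); larger = stop later | 2 |
| `t` | outer iteration cap; larger = larger clusters explored | 20 |
| `alpha` | lower-level co-members required for eligibility, in $[1, k-1]$ | 1 |

Explicit `C`/`h` win over `phi`-derived values: small-network worked
examples use `C = 2, h = 2`, and the community-detection settings in the
tests use `C = 3, h = 3, tau = 2, t = 20, alpha = 1`. The logarithm base in
`h` is not dictated by the derivation; we use the natural log and round up,
which preserves the bound direction. Both defaults only matter when `phi`
alone is supplied.

## Decisions where the design was open

* **Stopping test direction.** Read literally, a stopping rule of the form
  "stop when total flow $\le \tau \cdot 2 d_M(s) 2^j$" with $\tau = 2$ is
  vacuous: the total can never exceed $2 d_M(s) 2^j$. The only reading
  consistent with $\tau$ as an excess-tolerance ("stop when retained flow is
  significantly less than the doubling total") is the one implemented: stop
  when $\mathbf{e}^T m_M \le 2 d_M(s) 2^j / \tau$ after truncation.
* **Level initialization.** Levels start at 0 each inner run; the seed must
  relabel once before its first push. (Starting at 1 would let the first
  push happen immediately; the hand-traceable examples behave per the
  0-start.)
* **Hyperedge flows reset per inner run.** Each inner run is a fresh flow
  problem; carrying saturated hyperedges across doubling rounds would
  permanently block pushes and contradict the restart framing of the outer
  loop.
* **Tie-breaking.** Active nodes: FIFO within a level. Hyperedge choice:
  first eligible edge in the node's incidence list (file/enumeration
  order). Sweep ordering ties: flow descending, then label ascending.
  Nothing in the method requires randomness, so the core algorithm is fully
  deterministic.
* **Sweep support.** Only nodes the diffusion touched (positive level or
  flow, plus the seed) are ordered. Ordering all $n$ nodes would break the
  local-algorithm contract and flood the order with level-0 ties.
* **A corner case.** When the support covers a whole connected component
  *and* that component is the entire hypergraph, the full prefix has
  undefined conductance and is skipped; with every other prefix tied, the
  first (the seed alone) is returned. On any input with a nonempty
  complement — the realistic case — this does not arise.
* **Motif multiplicity.** Directed triads are emitted once per unordered
  node triple, however many orientations realize the pattern; cut counts
  are instance counts at the triple level, which keeps $\mathrm{cut}_M$
  well defined. "Triangle in any direction" (M1) means every pair joined by
  at least one arc.
* **Baselines.** The one-hop neighborhood of a seed is taken as all nodes
  co-occurring with it in at least one hyperedge; the seed itself is always
  included on top of the `k` ranked neighbors, since ground-truth classes
  contain the seed. Ties break by ascending label.
* **Medians** in the robustness protocol use the lower middle element for
  even counts — deterministic and always an attained value.

## Synthetic generators

All test inputs are generated in code; every generator is a pure function
of its seed and specification.

* `metabolic_fixture()` — a fixed 10-node, 9-hyperedge metabolic motif
  hypergraph, small enough that all $2^{10}$ subsets can be checked
  exhaustively against brute force.
* `fig3_family(p, l)` — the localization family: `p` strips of `l`
  edge-sharing triangles attached to a hub, with a single bridging triangle
  to a dense outside clique of size $2l$. The outside structure is only
  loosely constrained by the localization argument (it needs a sparse
  bridge and a non-trivial outside); the clique choice makes the outside
  triangle-rich so that leakage, if any, would be measurable.
* `planted_hypergraph()` — two (or more) blocks; within-block candidate
  hyperedges kept with probability `p_in`, cross-block with `p_out`.
  Candidate enumeration is capped at 200,000 sets, beyond which candidates
  are uniformly subsampled with acceptance probabilities scaled to preserve
  expected counts.
* `lfr_sweep()` — a mixing-parameter benchmark in the spirit of the
  standard LFR model (power-law degrees, exponent 2, average 10, maximum
  50; power-law community sizes, exponent 1, sizes 20–100), realized as a
  degree-corrected planted-partition sampler: each node splits its degree
  into a $1-\mu$ internal and $\mu$ external part and pairs are wired
  Chung–Lu style within and across communities. This reproduces the
  *controlled* features (heavy-tailed degrees, bounded community sizes, a
  tunable mixing fraction) but not LFR's exact degree-sequence matching or
  its rewiring scheme, and the default size is $n = 300$ rather than 1000 —
  chosen so the whole recovery-vs-mixing property runs comfortably inside a
  routine test suite. Passing tests on these generators therefore
  demonstrate correct *mechanics* and qualitative recovery behaviour, not
  performance on real metabolic or social networks.

## What the tests establish

The suite re-derives every hand-countable example; replays push/relabel
event logs to confirm conservation, capacity, integrality and level
monotonicity; checks the sweep cut against independent prefix
recomputation; compares triangle enumeration with brute force over all
triples; verifies the $k = 3$ equivalence between motif conductance and
weighted-graph conductance exhaustively on small random graphs; confirms
the edge diffusion is the 2-uniform special case push for push; and runs
the recovery (two 30-node planted blocks, 20 generator seeds) and
localization (`fig3_family(8, 8)`, 20 label shuffles) experiments at the
sizes quoted. Problem sizes throughout were picked as the smallest that
still exercise the property (e.g. exhaustive subset checks cap at 12
nodes).

## Limitations

* Built-in motif enumeration covers 3-node patterns only (triangle, M1,
  M2, M3); larger motifs must be supplied as a ready-made hypergraph.
* The diffusion's guarantees degrade for very large hyperedges: the flow a
  node must amass before it can push grows with $|e| - 1$.
* The mixing-parameter generator is an approximation of LFR, suitable for
  trend checks rather than benchmark-exact replication.
* No attempt is made to certify asymptotic running time; the
  implementation is simply local by construction (work is proportional to
  hyperedges incident to touched nodes, times $h$ and $C$).

## A worked call

```{r}
H <- metabolic_fixture()
res <- hgcrd(H, seed = 7, crd_params(C = 2, h = 2, tau = 2, t = 5, alpha = 1))
res
glance(res)
```
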