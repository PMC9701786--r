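---
title: "Measuring geometrical congruence and greedy navigability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring geometrical congruence and greedy navigability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Many complex networks — hyperbolic random graphs by construction, brain
connectomes by hypothesis — are thought to be shaped by an underlying
geometry: nodes live in some metric space and connections preferentially
join nearby nodes. A long-standing qualitative claim is that in such
networks the topological shortest paths "follow" the geodesics of the
space. This package turns that claim into numbers.

Between two nonadjacent nodes $i$ and $j$ we distinguish four objects:

* **GEO**, the geodesic: the direct distance in the underlying space.
* **TSP**, a topological shortest path: a minimum-hop path in the
  unweighted network; many may exist for one pair. Its geometrical
  projection **pTSP** is the sum of the geometric lengths of its hops, and
  $\overline{\mathrm{pTSP}}(i,j)$ is the mean projection over *all* TSPs of
  the pair.
* **GSP**, the geometrical shortest path: the minimum-total-weight path
  when edges carry geometric distances; it may use more hops than a TSP.
* **GRP**, the greedy routing path produced by myopic transfer: from the
  current node, move to the neighbor closest to the destination in the
  guide geometry. It is directed, possibly asymmetric, and may fail by
  revisiting a node. Its projection is **pGRP** (infinite on failure).

## The measures

For a connected network with $n$ nodes, $e$ edges and nonadjacent pair set
$\tilde E$, the **geometrical congruence** is

$$\mathrm{GC}(\overline{\mathrm{pTSP}}, \mathrm{RD}) =
  \frac{2}{n(n-1)-2e} \sum_{i<j,\ (i,j)\in\tilde E}
  \frac{\mathrm{RD}(i,j)}{\overline{\mathrm{pTSP}}(i,j)}$$

where RD is any pairwise reference distance — the geodesic when coordinates
are known (patent geometry), the GSP when only link weights are available
(latent geometry). Because the GSP (and, for metric weights, the geodesic)
can never exceed any path projection, GC lies in $(0, 1]$; we attach the
qualitative scale negligible $[0,0.4)$, low $[0.4,0.6)$, medium
$[0.6,0.8)$, high $[0.8,1]$. *Hard congruence* — the statistical
indistinguishability of the GEO and $\overline{\mathrm{pTSP}}$
distributions — is tested with a two-sided Mann–Whitney U test at
$\alpha = 0.01$ (exact for combined samples of at most 20 values, normal
approximation with tie correction otherwise).

The **greedy routing efficiency** aggregates success and stretch of myopic
transfer over directed nonadjacent pairs:

$$\mathrm{GRE}(\mathrm{pGRP}, \mathrm{RD}) = \frac{1}{n(n-1)-2e}
  \sum_{(i,j)} \frac{\mathrm{RD}(i,j)}{\mathrm{pGRP}(i,j)},$$

with failed routes contributing 0. A legacy variant
(`include_adjacent = TRUE`) averages over all $n(n-1)$ ordered pairs as in
the measure's original formulation. Ties among equidistant neighbors go to
the lowest node index; this choice is not dictated by the measure's
definition, so any comparison against implementations with a different
tie-break is only meaningful at low temperature, where ties are rare.
Failure is declared as soon as the chosen next node was already visited on
the route: with a deterministic memoryless rule any revisit implies an
infinite loop, of which the classic "packet returns to the previous node"
is the 2-cycle case.

## Enumerating all shortest paths

$\overline{\mathrm{pTSP}}$ needs *every* TSP of every nonadjacent pair.
The engine (`mean_ptsp()`) enumerates them by depth-limited recursion over
simple paths from each source, accumulating a pair's projection whenever the
target is reached at depth exactly equal to its hop distance. Three
schedules are provided and give identical statistics:

* **naive** — one recursion per pair, depth $\mathrm{TSP}(i,j)$;
* **brute-force** — one recursion per source at depth equal to its
  eccentricity, recording all targets at once;
* **memoization + prioritization** — sources are ordered by decreasing mean
  shortest-path length (`prioritize()`), and the $i$-th source's depth is
  reduced to the maximum hop distance to *strictly later* nodes
  (`depth_schedule()`); each unordered pair is then recorded exactly once,
  by whichever endpoint comes first. Traversal may still pass *through*
  earlier nodes — the symmetry argument removes pairs from the recording
  set, not transit nodes.

The enumeration cost is governed by $O\!\left(N \sum_{L=2}^{d} M_L
k^L\right)$, with $k$ the average degree, $d$ the diameter and $M_L$ the
proportion of nodes at recursion depth $L$ (`complexity_estimate()`); the
whole benefit of memoization is the downward shift of the $M_L$ profile.
Per-source recursions are independent, so they parallelize trivially
(`workers`) and can be checkpointed per source (`checkpoint_dir`, atomic
write-then-rename; a resumed run merges to identical output).

Numerical choices: hop distances come from per-source BFS (exact on
unweighted graphs, equivalent to running Johnson's algorithm with unit
weights), weighted distances from Dijkstra per source via igraph. Path
counts are accumulated in doubles, which represent integers exactly below
$2^{53}$ — far above any count arising at tractable sizes; projection sums
are floating point with a documented $10^{-9}$ relative tolerance against
the independent oracle. That oracle (`mean_ptsp_dp()`) computes the same
quantities by dynamic programming over the BFS shortest-path DAG
(`count(v) = \sum_u count(u)`, `sum(v) = \sum_u sum(u) + count(u) w(u,v)`
over predecessors $u$) and shares no code with the recursion. An optional
`dag_pruned` mode restricts descent to neighbors one BFS level deeper;
since every prefix of a shortest path is a shortest path, the recorded
statistics are provably unchanged — only the $k^L$ recursion tree shrinks.
The unpruned mode is the default because its cost profile is the one the
complexity formula describes; the pruned mode is used where only the
results matter.

## Generating networks with known geometry

`npso()` grows nonuniform popularity-similarity optimization (nPSO)
networks: soft random geometric graphs on the hyperbolic disk (curvature
−1) with tailored communities. Parameters and defaults:

* `n` — nodes; `m` — links per new node, about half the final average
  degree (the generator links each newcomer to exactly `m` distinct
  targets, sampled without replacement proportionally to the connection
  probability, so the realized mean degree is slightly below `2m` due to
  early saturation);
* `temperature` $T \in [0,1)$ — inverse clustering; at $T = 0$ the
  newcomer links deterministically to its `m` hyperbolically closest
  predecessors, for $T > 0$ through the logistic probability
  $p(x) = 1/(1+\exp((x - R_t)/(2T)))$ with the standard cutoff radius
  $R_t$ that makes the expected number of new links `m` (separate closed
  form at $\gamma = 2$);
* `gamma` $\ge 2$ — degree power-law exponent, via popularity fading
  $r_s(t) = \beta\, 2\ln s + (1-\beta)\, 2\ln t$, $\beta = 1/(\gamma-1)$;
* `communities` — 0 for the uniform (classical PSO) angular distribution;
  $C \ge 2$ draws angles from an equal-weight Gaussian mixture with means
  $2\pi(i-1)/C$ and standard deviation one sixth of the distance between
  adjacent means, assigning each node to the circularly nearest mean
  (ties to the lower index).

All randomness flows through one seeded generator with a fixed draw order
(angles first, then one sampling draw per new node), so a seed reproduces a
network bit-for-bit. Connectivity is required by every measure here; the
generator retries with fresh seeds up to 10 times and otherwise keeps the
largest connected component with a warning.

## Connectome markers

For cohorts of weighted connectomes the navigable geometry is latent, so
GC is computed against the GSP in the networks' own distance weights.
Streamline counts express closeness, not cost, and are reversed by
$w^* = 1/(1+w) \in (0,1]$ (`reverse_weights()`); alternatively edges carry
Euclidean distances between the 3D region centroids (`mode = "3d"`). The
navigation-efficiency marker $E_R$ runs greedy routing with the Euclidean
centroid geometry as the myopic guide in both modes — navigation needs node
positions, which reversed counts cannot supply — while path cost and
reference distance stay in the mode's edge distances. Whether published
connectome analyses weight the guide the same way is not decidable from
their descriptions; this package's convention is documented here rather
than asserted as theirs.

Group discrimination is scored by the area under the precision–recall
curve (step-wise integration over a descending-score sweep, tied scores
entering as blocks; the positive class defaults to the smaller group and is
configurable, since AUPR is prevalence-dependent). Significance comes from
permutation trustworthiness, $p = (1 + \#\{\mathrm{AUPR}_{perm} \ge
\mathrm{AUPR}_{obs}\})/(1+B)$ with $B = 1000$ by default and a Bonferroni
helper for the four-marker design (GC and $E_R$ under two weightings).

`synthetic_cohort()` exists so the whole stage is testable without any
data download. It emulates the structure of tractography cohorts — positive
streamline-count-like integer weights on sparse connected graphs, a shared
parcellation, a shared 3D embedding — by giving each subject an nPSO
network and Poisson(+1) counts decaying with the subject's hyperbolic edge
distances; the group effect is a temperature shift, so `effect_size = 0`
makes groups exchangeable by construction. What it does **not** emulate:
spatial autocorrelation of real parcellations, heavy-tailed streamline
counts, subject-level covariates (age, sex, head motion), or any
correspondence between the 3D embedding and the latent hyperbolic
coordinates. Passing tests therefore demonstrate that the marker pipeline
is statistically calibrated and sensitive to planted geometric differences,
not that it reproduces effect sizes in real cohorts, which require the
original data.

## Problem sizes and reproducibility

The test suite and the acceptance script run at the sizes the measures were
designed around: $N = 100$ networks (where full enumeration takes
milliseconds) for congruence and navigability claims, averaged over 10
seeds; $N = 10^4$ networks for the depth-schedule and degree-tail analyses,
where only BFS statistics are needed and `depth_summary()` avoids
materializing the full hop matrix; cohorts of 16–20 subjects on 25-node
parcellations for the 200-repetition null calibration of trustworthiness.
Larger runs (e.g. $N = 10^5$ enumeration) use the same code paths with
`workers` and `checkpoint_dir`; they are long-running batch jobs by nature
and are not part of the default checks.

## Known limitations

* The repulsion–attraction (RA) dissimilarity sometimes used to weight
  unweighted networks is not implemented; `ebc_weights()` (edge
  betweenness) is the provided fallback.
* GC assumes `RD` does not exceed the mean projection; with an arbitrary
  custom RD the ratio average can exceed 1 and the qualitative bands no
  longer apply.
* The greedy tie-break (lowest index) makes results deterministic but, on
  high-temperature networks with many ties, other implementations may
  differ in individual routes.
* `mean_ptsp()` stores dense $n \times n$ accumulators; for very large
  sparse networks the per-source recursion itself is fine but the merge
  step assumes the pair statistics fit in memory.
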