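---
title: "Adaptive and spatial rewiring of directed weighted networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive and spatial rewiring of directed weighted networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adaptrewire)
```

## The model

`adaptrewire` simulates the self-organization of a directed, weighted network
embedded in the plane. The state is a digraph $G = (V, E, W)$ on $n$ nodes
with $m$ directed edges, stored as an adjacency matrix with the convention
that entry $A_{ij}$ holds the weight $w_{ij}$ of the edge $j \to i$: rows
collect a node's in-links, columns its out-links. Most graph libraries use
the transpose, so all import/export (igraph, GraphML, edge lists) converts
at the boundary. Every node also carries fixed coordinates
$\vec{x}_i \in \mathbb{R}^2$ drawn uniformly by area from the unit disk.

Network evolution is pure rewiring: node and edge counts and the multiset of
edge weights never change. One step picks a pivot node $v$, a side (in-link
with probability $p_{in}$, out-link otherwise), cuts one existing link of
$v$ on that side and adds one new link on the same side, transferring the
cut link's weight to the new link. The pivot's degree and strength on the
rewired side are therefore invariant at every step, while the rest of the
network redistributes. Which link is cut and which added is decided by one
of four principles, drawn each step with fixed probabilities
($p_{distance}$, $p_{wave}$, $p_{function}$, and the remainder
$p_{random}$):

* **Functional (adaptive) principle.** Signal traffic is modeled as
  generalized diffusion on the digraph. The in-degree Laplacian
  $L_{in} = D_{in} - A$ generates *consensus* dynamics
  $\dot{x} = -L_{in} x$, whose kernel $c(t) = e^{-L_{in} t}$ has unit row
  sums; the out-degree Laplacian $L_{out} = D_{out} - A$ generates
  *advection* $\dot{x} = -L_{out} x$, whose kernel $a(t) = e^{-L_{out} t}$
  has unit column sums (total concentration is conserved). Kernel entry
  $(i, j)$ measures the flow from $j$ to $i$ over the rewiring interval $t$
  via all paths, and is positive exactly when $j$ reaches $i$. When an
  in-link of $v$ is rewired, the $v$-th row of the consensus kernel scores
  the candidates: the in-neighbor with the smallest value is cut and the
  unconnected node with the largest is added (ties uniform at random).
  Out-links use the $v$-th column of the advection kernel symmetrically. In
  the *stochastic* variant the cut is drawn with probability proportional
  to $1/\text{value}$ and the addition with probability proportional to the
  value; members with kernel value exactly 0 dominate the cut draw (the
  $1/c$ rule diverges there), and an all-zero complement falls back to a
  uniform draw.
* **Distance principle.** Cut the spatially longest link at $v$, add the
  spatially closest available one — wiring-cost minimization.
* **Wave principle.** Score each candidate edge by the cosine of its angle
  to a vector field evaluated at the pivot: the constant lateral field
  $(1, 0)$ or the radial field $\vec{x}/\lVert\vec{x}\rVert$. Cut the most
  misaligned member, add the best aligned candidate. The radial field is
  undefined at the exact origin (a measure-zero event for area-uniform
  coordinates); such a step falls back to uniform random rewiring and the
  swap is tagged `wave_random_fallback` in the log.
* **Random principle.** Uniform cut and uniform addition; this is the
  classical baseline mixed with adaptive rewiring.

The pivot must have degree in $\{1, \dots, n-2\}$ on the drawn side so that
both a removable link and a free slot exist. If no node on the drawn side
qualifies, the run stops with an error carrying the step index rather than
silently re-drawing the side — the regimes studied here never approach that
state, and silent re-drawing would bias the side mixture.

## Defaults and parameters

Defaults reproduce the study conditions: $n = 100$ nodes, $m = 912$ edges,
weights drawn from $\mathcal{N}(1, 0.25^2)$ with non-positive draws (a
$4\sigma$ event, probability $3.17\times10^{-5}$) replaced by $0.05$ before
the sample is rescaled to sum exactly to $m$ (division by the sample mean);
kernel interval $t = 1$; hub threshold 15; $M = 15000$ steps and 10
instantiations per condition at full scale. The clamp-then-normalize order
matters: clamping first guarantees strictly positive weights, and the
rescale makes the mean weight exactly 1 so Laplacian spectra are comparable
across runs. A lognormal weight family is available (parameters are the
user's choice; none are canonical). The edge count has no closed formula —
it is a required argument for other $n$.

The kernel is recomputed from the current adjacency at every functional
step, since each swap changes the Laplacian; nothing is cached across
steps. The matrix exponential is evaluated densely in compiled code
(scaling-and-squaring Padé via RcppArmadillo), accurate to well below
$10^{-9}$ entrywise at $n \le 200$. Kernels are provably non-negative, so
entries below $-10^{-9}$ raise an error while smaller negative rounding
noise is clamped to zero; the support test (entry positive iff a directed
path exists) uses a $10^{-12}$ floor.

A single RNG stream seeded from the run configuration drives every draw in
a fixed order — side, pivot, principle, then principle-specific draws — so
a trajectory is reproducible byte-for-byte from `(g0, config)`.

## Measures

* **Average efficiency**: mean inverse shortest directed path length over
  ordered pairs $i \ne j$ under the topological edge length $1/w$
  (strong links are easy to traverse); unreachable pairs contribute 0.
* **Connected node pairs**: ordered pairs joined by a directed path of
  length $\ge 1$, *including* self-pairs when the node lies on a directed
  cycle, so the maximum $n^2$ is attained by strongly connected graphs.
  Note the deliberate asymmetry with efficiency, whose sum excludes $i = j$.
* **Hubs**: convergent hubs have in-degree strictly above the threshold
  (binary link counts, not strengths) and at least one out-link; divergent
  hubs symmetrically. "Above" is read strictly (threshold 15 means degree
  $\ge 16$); an inclusive flag exists.
* **Convergent-divergent units (CDUs)**: ordered pairs of a convergent hub
  $c$ and a divergent hub $d$ joined by a directed path $c \to d$. Each
  unit carries source nodes (which reach $c$), target nodes (reached from
  $d$) and intermediate nodes: nodes other than the hubs reached from $c$
  that also reach $d$, i.e. lying on at least one directed *walk* between
  the hubs. Membership on a simple path is NP-hard to enumerate in general;
  the walk definition is used throughout and cross-checked against DFS
  reachability oracles on small graphs. The intermediate subgraph's binary
  density (edges over $k(k-1)$, defined for $k \ge 2$) measures how
  encapsulated the unit's processing is, compared against the whole-graph
  density $m/(n(n-1))$.
* **Modularity**: the directed weighted (Leicht–Newman style) objective
  $Q = \sum_c \left[ E_{cc}/m - \gamma\, s^{in}_c s^{out}_c / m^2 \right]$,
  optimized by a deterministic greedy agglomeration from singletons with a
  first-maximum tie-break. The optimizer is intentionally seed-free and
  reproducible; no published method is canonical for this quantity here, so
  the routine is documented and fixed rather than delegated to a stochastic
  community detector.

## The experiment runner

`run_condition()` executes $r$ independent instantiations (fresh random
initial graph and trajectory per seed, seeds `base_seed + 0:(r-1)`) and
aggregates final-checkpoint metrics as mean ± sd; `run_sweep()` maps a
parameter grid to a long results table with disjoint seed blocks per
condition. `stabilization_step()` reports the first checkpoint after which
a series stays within a relative band (default ±10%) of its terminal mean
(the mean of the last 10% of checkpoints) — the band is exposed because
"relatively stable" is qualitative. Metric checkpoints default to every 100
steps; a cheap CDU-existence flag can be evaluated at a finer cadence
(`cdu_every`) to estimate the proportion of steps without any CDU.

The shipped tests and the acceptance script run at desk scale — typically 3
instantiations of 3000–10000 steps per condition, and 5000-step sweeps for
the CDU analyses — rather than the full 10 × 15000 protocol; full scale is
a flag away. At desk scale the directional results (connectedness and
efficiency rising with random or distance mixing, the convergent/divergent
hub trade governed by $p_{in}$, CDU emergence requiring mixed rewiring, the
stochastic variant stabilizing CDUs) reproduce clearly. Two quantitative
calibrations do not, and the corresponding checks are left failing rather
than softened: the *pointwise* ±10% stabilization band is never satisfied
around step 2500 because checkpoint-level excursions of 20–30% persist
indefinitely even though the running mean plateaus there (the network stays
plastic — hubs collapse and reform); and the intermediate-density "floor"
detection against the spread at $p_{distance} = 0.9$ is degenerate at this
scale because that reference spread collapses to $\sim 2\times10^{-4}$,
even though the density means themselves visibly flatten from
$p_{distance} = 0.5$ exactly as expected.

## What the generator does and does not emulate

Synthetic networks are Erdős–Rényi-style random digraphs (uniform ordered
pairs without replacement) with i.i.d. near-unit weights and area-uniform
disk coordinates. This matches the study design: the point is the
*self-organization* from an unstructured start, not fidelity to any
empirical connectome. Passing tests therefore demonstrate properties of the
rewiring dynamics, not of real brain networks: there is no spatial
correlation in the initial wiring, no degree heterogeneity at start, no
inhibitory population (the homeostatic character of consensus/advection
stands in for it), and the principle probabilities are fixed over a run.

## Numerical and degenerate-input choices

* Ties in the distance and wave principles are broken uniformly at random,
  extending the rule stated for the functional principle; exact float ties
  are rare but structural zeros in kernels are common.
* Coincident node coordinates give a zero-length candidate edge under the
  wave principle; its cosine is treated as 0 (neutral) rather than an
  error, since the pair remains comparable by every other principle.
* `stabilization_step()` returns the final step as a sentinel when the
  band is never entered; constant series stabilize at the first checkpoint.
* Aggregations over CDUs report `NA` when no unit exists (undefined, not
  zero); densities of single-node intermediate subgraphs are excluded.
* The greedy modularity merge stops at gains $\le 10^{-12}$ to avoid
  chasing rounding noise.

## Known limitations

The dense $O(n^3)$ matrix exponential per functional step targets
$n \approx 100$; larger networks would need Krylov or sparse exponential
methods, deliberately out of scope. CDU counting is per ordered hub pair,
which scales with the product of hub counts; alternative unit definitions
(e.g. maximal hub-set components) would change magnitudes but not the
reported trends. The modularity optimizer is greedy and can undershoot the
optimum; it is used as a consistent relative measure across conditions, not
as a state-of-the-art partitioner.
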