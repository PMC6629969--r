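---
title: "Strategic network formation for neural connectomes: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Strategic network formation for neural connectomes: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stratnet)
```

## The model

`stratnet` models the wiring of a small neural network as a
non-cooperative game. Each neuron is an agent; its strategy towards every
other neuron is binary — keep or form a link (`L`) versus drop or refuse
one (`D`). A network state `g` is scored by each neuron `i`, facing a
partner `j`, with the linear utility

$$u_{i \leftrightarrow j}(g) \;=\; \mathbf{1}[ij \in g]\,
  \bigl(\alpha D_{ij} + \beta B_{ij}\bigr)
  + \lambda S_i + \rho P_i + \theta C_i + \omega Be_i,$$

with two *link costs* that are only paid while the link exists —
`D_ij`, the Euclidean distance between the two somata (µm), and `B_ij`,
the absolute difference of the neurons' birth times (min) — and four
*structural features* of neuron `i` in the current network: `S_i`, its
mean shortest-path length to reachable peers; `P_i`, its PageRank;
`C_i`, its closeness (the reciprocal of the mean distance to reachable
peers); and `Be_i`, its normalized betweenness. The six weights
$(\alpha, \beta, \lambda, \rho, \theta, \omega)$ are the model's
parameters. Negative weights on `D` and `B` express that long or
developmentally asynchronous connections are costly; a negative $\lambda$
rewards networks in which the neuron sits close (in hops) to everyone
else.

The solution concept is **pairwise stability** rather than Nash
equilibrium, because forming a link takes two consenting endpoints while
severing one is unilateral: `g` is pairwise stable when (i) no endpoint
of any existing link would strictly gain from deleting it, and (ii) no
absent link could be added such that one endpoint strictly gains while
the other at least weakly gains. Condition (ii) is sometimes printed
with a strict loss required of the second endpoint; under the floating
point tolerance used here (`1e-12`, see below) the two readings coincide
except on exact ties, which the tolerance already collapses, so the
package implements a single check.

### Directionality conventions

Chemical synapses are directed, so the container is a simple digraph,
but the game itself is pairwise: a node pair counts as *linked* when an
edge exists in either direction, deletion removes all edges of the pair,
and an added link is one directed edge. The structural features `S`,
`C`, `Be` are computed on the undirected projection — matching the
pairwise framing — while PageRank is computed on the directed graph.
Consequently the direction of a hypothetically added edge matters only
when $\rho \neq 0$. The stability checker and the constraint builder use
the deterministic lexicographic direction (smaller id is the source);
`evolve()` defaults to a seeded fair coin (`edge_direction = "coin"`,
also `"low_to_high"` and `"both"`). With $\rho \neq 0$ and the coin
convention, a converged run can in principle disagree with the
lexicographic stability check on an unlinked pair; use
`edge_direction = "low_to_high"` when exact fixed-point agreement under
$\rho \neq 0$ is required. All validation fixtures in this package use
$\rho = 0$.

## The inverse model: estimating the weights

Assume the observed connectome `g*` is pairwise stable. Toggling the
link of one node pair, with all other edges fixed, changes each
endpoint's utility by a known linear function of the six weights:
the feature difference vector between the linked and unlinked state
(`D` and `B` enter un-differenced, since they exist only in the linked
state). Every unordered pair therefore contributes two linear
inequalities — one per endpoint, `n(n-1)` records in all — and the
weights are estimated by linear programming: minimize the total network
utility (the sum of both endpoints' linked-state utilities over all
linked pairs, a linear function of the weights) subject to all records
and box bounds on the coefficients.

Three design points deserve comment.

* **Sense conventions.** `convention = "standard"` gives linked pairs
  the sense "keeping the link is weakly preferred" ($\geq 0$ on the
  linked-minus-unlinked delta) and unlinked pairs the opposite; a
  network that truly is pairwise stable satisfies every linked record
  under this reading. `convention = "as_printed"` flips both senses;
  it is the reading under which all-negative coefficient signatures
  arise on real connectome data and is the default of the pipeline
  driver. Both are first-class; the constraint deltas are identical and
  only the senses differ.
* **Box bounds.** The system of constraints is homogeneous, so the zero
  vector is always feasible and the scale of the solution is not
  identified — only the sign pattern and ratios are. The default bounds
  $[-1, 1]$ anchor the scale; entries that saturate a bound should be
  read as "negative with unidentified magnitude". When no linked pair
  exists the objective is identically zero and the fit returns the zero
  vector explicitly flagged as degenerate.
* **The solver.** The LP is solved by an internal dense two-phase
  tableau simplex (largest-reduced-cost entering rule with a switch to
  Bland's rule after a pivot budget, guaranteeing termination on the
  highly degenerate homogeneous systems this model produces). Global
  optimality is not a modelling requirement — any feasible bounded
  optimum is acceptable — and the returned solution is always
  re-verified against every constraint independently of the solver
  (`check_constraints()`). An optional soft mode adds one penalized
  slack per record for deliberately infeasible systems; it grows the LP
  by one variable per record and is intended for small networks.

Memory note: the dense tableau holds roughly
$(n(n{-}1) + 6) \times (2\,n(n{-}1))$ doubles; at $n = 131$ (17,030
records) that is on the order of a few gigabytes, so fitting full-size
connectomes is possible but memory-hungry. The validation suite works at
$n = 30$ (870 records, well under a second per solve).

## The forward model: evolving to equilibrium

The strategic network is grown from a *base network* that preserves the
reference's degree structure: the reference's in/out degree sequences
are realized exactly by a directed Havel–Hakimi construction, nodes of
the base are paired with reference neurons by ascending total degree
(ties lexicographic by id), and the paired neuron's soma position and
birth time are transferred. `evolve()` then sweeps all unordered pairs
in seeded-random order (the dynamics specify no order; a fresh uniform
permutation per sweep avoids order artifacts):

* a linked pair is deleted when at least one endpoint strictly gains
  from deletion (`deletion_rule = "either"`, reflecting unilateral
  severance; `"both"` requires bilateral consent);
* an unlinked pair is added when both endpoints strictly gain;
* "strictly" means an improvement greater than `tol = 1e-12`, so exact
  ties never trigger moves;
* the run stops when a full sweep makes no move (converged — by
  construction the final state passes the stability check) or at
  `max_sweeps`; non-convergence is reported, not raised.

During move evaluation only the features with non-zero weights are
computed (betweenness is the cost hotspot); single-source distances run
on an internal BFS over the undirected adjacency matrix, and a node left
with no reachable peer is assigned the penalty sentinel $S_i = n$ (and
$C_i = 0$) so that isolation is strongly discouraged and the dynamics
remain well defined. The public `node_features()` reports `S = NA` for
isolated nodes instead; the sentinel is a dynamics device, not a
measurement.

## Random-network baselines

Six reference-matched generators serve as base-network candidates and
comparison baselines. Three undirected: a *distance-based
Watts–Strogatz* network (each neuron wired to its `k = 5` nearest
neighbours by soma distance — the distance-driven replacement for the
classical ring, which is the generator's stated intent for spatial
networks — followed by rewiring each edge with probability `0.5`; `k`
counts total neighbours, so minimum degree is `k`); an *expected-degree*
(Chung–Lu) network with edge probability $w_u w_v / \sum w$ using the
reference's undirected degrees; and a *power-law clustering*
(Holme–Kim) network with `m = 6` edges per added node and triangle
probability `0.2`. Three directed: the *Havel–Hakimi* realization of
the reference's in/out sequences (Kleitman–Wang greedy, randomized
among exact ties, so the family of realizations is sampled); a
*directed scale-free* growth model with event probabilities
$\alpha = 0.15$, $\beta = 0.8$, $\gamma = 0.05$ and attachment offsets
$\delta_{in} = 0.2$, $\delta_{out} = 0$, stopped at the reference's
edge count (its node count is therefore not guaranteed); and a directed
*Erdős–Rényi* network. The Erdős–Rényi density parameter defaults to
`0.5`; note that at reference sizes this produces networks far denser
than a connectome, which is exactly why it is a contrast baseline, and
the parameter is user-settable (`er_p`).

All generators are seed-deterministic: the same parameters and seed
produce an identical edge set.

## Comparison metrics

`compute_metrics()` reports average local clustering (undirected
projection, degree-<2 nodes contribute 0), average shortest path over
reachable ordered pairs, average neighbour count
($2\,|E_{und}|/n$), diameter (largest finite distance), mean normalized
betweenness, degree homogeneity and density, plus degree, shortest-path
and betweenness distributions. Homogeneity — a summary of
degree-distribution uniformity that is not standardized in the
literature — is implemented as $\langle k \rangle^2 / \langle k^2
\rangle$ over undirected degrees: it equals 1 for regular graphs and
falls towards 0 for heavy-tailed ones, reproducing the
regular-high / heavy-tail-low ordering one expects from such a measure.
Path metrics on disconnected graphs average over reachable pairs only,
and a graph with no reachable pair reports `NA` rather than erroring.
Mean betweenness of a reference network depends strongly on the
normalization convention, so cross-study comparisons of that column
should be made with care.

## The synthetic-data module

`synth_attributes()` draws soma positions uniformly in a cubic box and
birth times uniformly (or from a two-component early/late mixture, a
crude nod to embryonic versus post-embryonic neurogenesis, offered as a
convenience and not as a biological claim). The defaults use unit
scales — box edge 1, birth-time range 1. This is a deliberate modelling
choice: the utility is linear in *raw* features, so the feature scales
set the dynamic regime, and unit scales put all six features at order
one, the regime in which link costs and structural rewards genuinely
compete and equilibria are non-trivial. With micron-scale distances and
minute-scale birth times against O(1) structural features, any O(1)
negative weight on distance makes every link unaffordable and the only
equilibrium is empty — informative about scale, not about structure.
Real-data fits face the same issue in reverse: their fitted distance
weights are correspondingly tiny, or features are min–max normalized
(`build_constraints` exposes raw features; normalization can be applied
to the attribute table by the caller).

`synth_reference_network()` draws heavy-tailed (discretized log-normal,
default meanlog 1.6, sdlog 0.6) in/out degree sequences, equalizes
their sums by seeded unit increments and realizes them exactly via the
directed Havel–Hakimi generator. `synth_stable_network()` evolves a
sparse random digraph (default edge probability 0.08, mean total degree
≈ 4.6 at n = 30) to convergence under known true coefficients, yielding
ground truth for inverse-model validation.

What the synthetic fixtures do *not* emulate: spatial correlation of
wiring (positions are independent of the degree sequence), lineage
structure in birth times, synapse weights and multiplicity, and any
distinction between chemical synapses and gap junctions (the model is
unweighted and agnostic; a loaded connectome edge list is taken as-is).
Passing tests on synthetic data therefore demonstrate the correctness
of the machinery — constraint construction, LP identification of sign
patterns, fixed-point behaviour of the dynamics — not the biological
adequacy of the utility.

### Validation conditions and what they show

The validation suite (and `scripts/acceptance.R`) uses: 200 random
attributed digraphs with $n \le 6$ and random coefficient vectors for
exhaustive agreement between the stability checker and a brute-force
deviation enumerator; 20 evolution runs at $n = 30$ for the fixed-point
property; and 20 synthetic stable networks at $n = 30$ under true
coefficients $(-1, -0.5, -0.1, 0, -0.25, 0)$ for recovery — the fitted
vector must satisfy at least 99% of each network's constraints and
recover the sign of every non-zero true entry in at least 18 of 20
replicates. Problem sizes were chosen so the whole suite runs in a few
minutes on one core; the equilibria at these scales are sparse
(near-matching) networks, which is the honest equilibrium structure of
this utility at unit feature scales, not an artifact.

## Known limitations

* The LP identifies sign patterns and active constraints, not
  magnitudes; saturated bounds are the expected outcome and should be
  reported as such.
* Pairwise-stability dynamics need not converge in general; the
  `max_sweeps` budget with an explicit `converged` flag is the honest
  interface. Every converged run is a true fixed point.
* Betweenness and PageRank recomputation per candidate move makes
  $\rho \neq 0$ or $\omega \neq 0$ evolution substantially slower; with
  the fitted signatures used here both are zero and are skipped.
* Dense-tableau memory limits hard fits to a few thousand constraint
  records comfortably; full 131-node connectome fits are possible but
  slow and memory-hungry.
* The degree-rank attribute transfer is a bijection on equal node
  counts only; it does not attempt partial matching.
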