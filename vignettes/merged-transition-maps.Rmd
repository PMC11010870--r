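---
title: "Merged transition maps: ranking synergistic partner targets in asynchronous Boolean networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Merged transition maps: ranking synergistic partner targets in asynchronous Boolean networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtmap)
```

## The problem

Targeted cancer drugs often fail not because the target is wrong but
because the cell's regulatory network responds heterogeneously: after
the drug pins its target, the network's state drifts stochastically and
different cells stabilise in different attractors, some of them
drug-resistant.  In an asynchronous Boolean model this adaptive
resistance has a concrete signature.  The network is a set of nodes
with 0/1 states and logical update rules; one randomly chosen node is
updated per step, so a treated cell performs a random walk on the
state-transition graph (STG) until it is absorbed in an attractor.
When two multi-stable motifs — self-sustaining positive-feedback units
— are driven into incompatible states by the same perturbation, their
conflict is resolved by the random update order, and the population
splits between a desired attractor and a resistant one.

`mtmap` implements a target-search strategy built on this picture: the
nodes that flip most frequently along the *undesired* transition paths
are the carriers of the conflict, and pinning the right one in the
right direction removes the resistant outcome.  The package identifies
such synergistic partner targets for a given drug and benchmarks them
against exhaustive screening and structural control baselines.

## The merged transition map

For a network $N$, a phenotype specification (marker nodes with signed
weights) and a perturbation that pins a target $T$:

1. **Landscapes.** The attractors of $N$ (original landscape) and of
   $N$ with $T$ pinned (regulated landscape) are identified exactly:
   constant rules are propagated iteratively until a fixed point
   (`reduce_by_constants()`), and the attractors of the residual
   network are the terminal strongly connected components of its full
   asynchronous STG, re-expanded with the forced assignments and
   verified closed under updates.  Exhaustive enumeration is used for
   residuals up to 24 free nodes; beyond that the search is restricted
   to the STG reachable from caller-supplied seed states, where
   terminal SCCs of the reachability closure are still genuine
   attractors.
2. **Segments.** For each original attractor, a *regulated segment* is
   the reachable STG of the pinned network seeded from that attractor's
   states (pinned bits clamped), with all regulated-attractor states
   absorbing: this is where the network goes when treatment starts.
   For each regulated attractor, a *reversal segment* runs the
   unpinned dynamics from its states back into the original landscape:
   where the network goes when treatment is withdrawn.  Reversal
   segments are built for every regulated attractor; attractors that
   remain stable after unpinning simply produce trivial segments that
   contribute nothing.
3. **Path ensembles.** Each segment is factorised by absorbing
   Markov chain first-step analysis with uniform branch probabilities
   (every transient state distributes probability $1/\text{outdegree}$
   over its outgoing flips).  For each destination attractor $d$ the
   absorption probability $p_d$ and the conditional expected per-node
   flip counts $E[f_n \mid d]$ are obtained from two sparse linear
   solves: with $h_d$ the absorption probabilities and $u$ the
   expected visit counts, the expected traversals of an edge
   $(s \to s')$ jointly with absorption in $d$ equal
   $u(s)\,p(s,s')\,h_d(s')$, and summing over the edges that flip node
   $n$ gives $E[f_n \wedge d]$.  This equals the probability-weighted
   sum over all paths, including cyclic transients that naive path
   enumeration cannot handle; Monte Carlo trajectory sampling
   (`simulate_trajectories()`) is kept in the test suite as an
   independent oracle.
4. **Scores.** Every ensemble carries a phenotypic-preference sign
   `pp` ($\operatorname{sign}$ of the preference change from source to
   destination attractor; preference is the weighted mean marker
   activity, averaged uniformly over a complex attractor's states), a
   type sign (+1 regulated, −1 reversal), and a significance (the
   source attractor's basin fraction on its own landscape).  The
   weighted flipping frequency of node $n$ is
   $$\mathrm{wff}(n) = \sum_e \text{significance}_e \cdot p_e \cdot
   E[f_n \mid e] \cdot \mathrm{pp}_e \cdot \mathrm{type}_e .$$
   Candidates (all nodes except the given target, pinned inputs and
   the markers) are ranked by $|\mathrm{wff}|$; the per-ensemble
   decomposition is retained so a ranking can be audited, and signed
   and undesired-mass-only rankings are available as alternatives.
   The magnitude is the default because desired-path and
   undesired-path flip mass are equally actionable: either marks the
   conflict carrier, and the control *type* is chosen separately.
5. **Control type.** The direction to pin a partner is taken from
   signal-flow analysis on the signed interaction graph: the influence
   of the pinned target propagates along directed paths with damping
   $\alpha^L$ (default $\alpha = 0.5$, $L$ up to the graph diameter),
   each path weighted by the product of its edge signs over the
   product of branch out-degrees.  A candidate whose net tendency
   under the drug is ON is pinned OFF and vice versa — the pin must
   interfere with the propagated state flip, not reinforce it.  A zero
   net tendency is reported as an explicit error advising exhaustive
   screening of both types.

## Basins of attraction

Basin fractions weight the ensembles and define control effectiveness.
For small networks (at most `n_samples` admissible states over the
free nodes) the package computes them exactly as absorption
probabilities from the uniform initial distribution, so they sum to
one by construction.  Otherwise it samples distinct initial states
without replacement (the reading of "non-overlapping" sampling) and
follows one uniformly random asynchronous trajectory from each until
an attractor state is hit, with a step budget of $10^4 \times$ the
node count; trajectories that exhaust the budget are reported in a
censored bucket and more than 1% censoring is an error.  At each step
the update is chosen uniformly among the *eligible* nodes (those whose
rule value differs from their state).  Choosing among all nodes and
discarding no-ops would visit the same states with the same hitting
probabilities — eligible-only sampling merely skips the wasted draws —
so the basin estimates are unchanged; only notional step counts
differ.  The default of 10,000 sampled states keeps the binomial
standard error of a basin fraction below 0.005.

## Comparator baselines and control effectiveness

Control effectiveness of a pin set is the basin-weighted mean
phenotypic preference of the pinned network's attractors minus that of
the unperturbed network (a flag switches the reference to the
given-target-only network for synergy-specific reporting; the
unperturbed default makes single-target and pair effects directly
comparable on one scale).  `sps_search()` is the exhaustive oracle: it
pins the given target together with every candidate in both
directions and sorts by effectiveness with deterministic tie-breaks.
`minimal_fvs()` computes a minimum feedback vertex set — exact
branch-and-bound over cycles up to 30 nodes, greedy above, self-loops
always included — whose pairs, pinned to their values in the desired
attractor, give the structural-control baseline;
`evaluate_pair_sets()` averages effectiveness over all two-node
subsets of a suggested set.

## Motifs, interconnecting nodes and the conflict census

Multi-stability requires positive feedback, so motifs are built from
simple cycles whose edge-sign product is positive.  Cycles are
clustered in order of increasing length: a cycle disjoint from
existing units founds a new motif, one overlapping a single unit is
merged into it, and one spanning two or more units is discarded.  The
discarded cycles are exactly the inter-motif double-negative loops:
two mutually inhibiting motifs compose their net-negative paths into a
positive cycle, which is why a maximal-SCC decomposition of the signed
graph would fuse every mutually inhibiting pair into one component and
make interconnecting-node analysis vacuous.  Each retained unit is
strongly connected by construction, and is reported as a multi-stable
motif if the attractor states project onto at least two distinct
patterns over its nodes (every state of a complex attractor is
projected — the only definition computable from attractor sets alone).

Interconnecting nodes between two motifs are the interior nodes of the
k shortest loopless directed paths between the motif node sets (both
directions, Yen's algorithm via igraph on the simple digraph), ranked
by path coverage and then by shortest covering path.  The
conflict-pair census counts pairs of node-disjoint positive loops (up
to a configurable size cap, default 3) connected in both directions by
net-negative paths of length at most 2 with interior nodes outside
both loops, by enumerating and joining the loops; degree-preserving
double-edge swaps (`randomize_degree_preserving()`, sign travelling
with its source edge, self-loops and duplicate signed edges rejected)
provide the null model, and `curate_interaction_network()` applies the
sign/direction/whitelist filters to user-supplied interaction tables
and keeps the largest weakly connected component.

## The synthetic fixtures

The shipped generators provide ground-truth-annotated networks so every
stage is testable without external model files.

`make_conflict_network()` is the core fixture (default instance frozen
in `inst/extdata/conflict_default.bnet`): a perturbation input `P`,
nominally OFF, drives two positive-feedback chains — yellow (`Y1`,
`Y2`), whose terminal produces the desired marker `M`, and green
(`G1`, `G2`), producing the resistance marker `R` and inhibited
directly by the yellow terminal.  Green inhibits yellow through the
interconnecting relay `I1`, and this inhibition is engaged only under
the perturbation (`Y2 = Y1 & !(P & I1)`): the drug itself opens the
bypass through which the resistant motif fights back, which is the
defining dynamics of adaptive resistance.  The unperturbed network has
three attractors (all-off, yellow-win, green-win).  Pinning `P = 1`
yields exactly two attractors, desired (`M = 1`) and resistant
(`R = 1`), reached stochastically — the heterogeneous response.  On
this fixture the interconnect attains the top weighted-flipping
magnitude among candidates, the signal-flow rule assigns it OFF, and
pinning `P = 1, I1 = 0` collapses the regulated landscape to the
single desired attractor, matching the exhaustive screen's optimum.
This architecture was selected by a systematic search over small
template rule spaces during fixture design; architectures in which the
perturbation drives both motifs unconditionally resolve the conflict
in a single race and spread the flipping over the motif entry nodes
instead of the relay.

`make_exemplar_network()` adds a purple motif (driven by `P`, not
interacting) and a blue motif (not driven by `P`, forced ON when green
wins), giving four motifs in distinct topological positions and
exactly three attractors under the perturbation.
`make_random_boolean_network()` draws seeded random truth-table rules
(in-degree $1 + \mathrm{Poisson}(\bar d - 1)$, capped; DNF rendering)
for the property-test corpus.

What the fixtures do not emulate: biological networks are larger, have
heavy-tailed degree distributions, nested and overlapping feedback
rather than clean disjoint chains, multi-valued readouts, and markers
that are themselves dynamically entangled with the motifs.  Passing
tests on the fixtures therefore demonstrates correctness of the
algorithms and the qualitative conflict phenomenology, not predictive
performance on real signalling models.

## Numerical and design choices

* Bit order is declaration order; states print as 0/1 strings in that
  order, attractor identifiers sort by minimal state key — all outputs
  are stable across runs, and a single integer seed drives every
  stochastic step.
* Pinning replaces the rule with the constant *and* clamps the pinned
  bits of every entry state (segment seeds, basin samples, trajectory
  starts), so a pinned node never flips and contributes exactly zero
  flips to regulated ensembles.
* Ensembles with zero preference change are retained with zero
  contribution, keeping score decompositions auditable.
* Absorption systems are solved with sparse LU on the transient
  submatrix; probabilities per (source, label) are verified to sum to
  1 within $10^{-9}$.
* The signal-flow damping $\alpha = 0.5$ halves each additional step's
  influence; out-degree normalisation makes the score a weighted path
  count rather than a walk count, and dual-signed (non-monotone)
  dependencies cancel to zero net influence rather than being given an
  arbitrary sign.
* Capacity limits (state budget $2^{22}$, exhaustive limit 24 free
  nodes, trajectory budget $10^4 N$) raise explicit errors naming the
  remedy rather than degrading silently.
* Reported problem sizes in the test-suite and acceptance runs — 8–12
  node fixtures, 100 random networks up to 12 nodes, 10,000 sampled
  states and trajectories — were chosen so the exhaustive oracles
  (full STG enumeration, brute-force monotonicity, subset-search FVS)
  remain feasible while the Monte Carlo standard errors stay below the
  assertion tolerances.

## Known limitations

* Attractor search beyond the exhaustive limit is reachability-based
  and therefore only finds attractors reachable from the supplied
  seeds; SAT/BDD-based complete search is out of scope.
* Only single-node given perturbations are supported in the pipeline
  (multi-target treatments would need multi-pin MTMs).
* The signal-flow control-type rule is a topological heuristic; when
  positive and negative channels balance it abstains, and the
  exhaustive screen should arbitrate.
* The conflict-pair census is exact but enumerative; it is not
  engineered for database-scale (thousands of nodes) graphs.
* Multi-valued nodes are supported through the nested level-indicator
  encoding only; level logic that is not threshold-like is rejected.
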