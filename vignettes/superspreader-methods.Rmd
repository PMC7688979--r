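---
title: "Methods: predicting SIR superspreaders from node centralities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: predicting SIR superspreaders from node centralities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Given a directed, unweighted contact or interaction network, which nodes
would spread an epidemic (or a piece of information) farthest if they were
the seed? `superspreadr` frames this as predicting the top fraction *f* of
nodes by *SIR influence* — the expected final outbreak size when the node
seeds a susceptible–infectious–recovered process — from topological node
indicators that are cheap to compute, either by ranking on a single
centrality or by training a classifier on several of them.

## The epidemic model and its simulation

The SIR process is continuous-time and Markovian: an infectious node
transmits along each out-edge at rate β (events per unit time, so β may
exceed 1) and recovers at rate μ. Only the ratio λ = β/μ matters for the
final outcome, so μ is normalized to 1. Influence is estimated as the mean
final size over `runs_per_node` (default 10⁴) independent realizations.

The simulator does not schedule events explicitly. For the *final size*
(though not for timing) the process is equivalent to a reachability
percolation: each infected node u draws an infectious period
τᵤ ~ Exp(μ), and each of its out-edges transmits independently with
probability 1 − exp(−β τᵤ) conditional on τᵤ; the ever-infected set is
the set reachable from the seed through transmitting edges. This is exact,
not an approximation — event order affects only timing, which the final
size does not depend on — and makes one realization a single randomized
BFS (implemented in C++).

For graphs of at most 12 nodes the package also enumerates the embedded
jump chain exactly (`exact_expected_spread()`): from a state
(susceptible set, infectious set), each possible recovery (rate μ) or
transmission to a susceptible neighbour (rate β) occurs next with
probability proportional to its rate, and the expected final size is
accumulated over all absorbing paths with memoized states. This is the
independent oracle the Monte-Carlo path is tested against; on the 2-node
graph a→b it reduces to the closed form 1 + λ/(λ+1).

## The epidemic threshold

The interesting regime is near the epidemic threshold λ_c, where outbreaks
transition from local to network-scale. On finite, structured networks
λ_c is estimated numerically as the peak of the outbreak-size variability

Δ(λ) = sqrt(⟨ρ²⟩ − ⟨ρ⟩²) / ⟨ρ⟩,

where ρ is the final size seeded at a node drawn uniformly at random
(10⁴ sampled seeds, or the whole network if smaller; one realization per
sampled seed by default, `runs_per_seed` realizations if the scan is noisy
on a small network). `epidemic_threshold()` evaluates Δ on a user-supplied
grid and returns the grid argmax, ties resolved to the smallest λ; no
interpolation is attempted since thresholds are conventionally reported at
coarse precision.

## Centrality indicators

Seven per-node indicators serve as ranking scores and classifier features.
Edges are oriented along the direction of spreading (use `reverse_edges()`
when the raw data points the other way), and all computations run on the
largest strongly connected component so that directed distances are finite:

* **degree** — out-degree;
* **k_sum** — sum of out-degrees over out-neighbours (distance exactly 1);
* **k_2sum** — the same over nodes at directed distance exactly 2;
* **core number** — k-shell decomposition peeling on total (in + out)
  degree, the common library convention for directed graphs;
* **closeness** — (N−1)/Σ d(u,·) over outgoing shortest paths;
* **PageRank** — damping 0.85, computed by in-package power iteration to
  an L1 tolerance of 1e−10 (the damping factor bounds the spectral gap,
  so convergence is guaranteed);
* **eigenvector** — the Perron vector of the adjacency matrix, unit
  Euclidean norm, in the "out" orientation (a node scores high if its
  out-neighbours do). Computed with ARPACK rather than plain power
  iteration: on networks made of several weakly coupled dense blocks the
  two leading eigenvalues nearly coincide and power iteration stalls,
  which is exactly the situation the planted benchmark creates.

Where the directed-graph convention is genuinely ambiguous (closeness and
eigenvector orientation), both orientations are exposed as options and the
defaults follow the spreading interpretation.

## Ranking by one centrality and its metrics

The ranking predictor selects the top round(f·N) nodes by a centrality
(at least 1; boundary ties filled uniformly at random — discrete-valued
indicators tie often). Performance against the influence ranking I_f uses

* the **recognition rate** r(f) = |I_f ∩ C_f| / |I_f| (a recall), and
* the **precision function** p(f) = avg_{i∈C_f} ρ_i / avg_{i∈I_f} ρ_i,
  capped at 1.0 — it does not penalise swapping a top spreader for an
  equally influential substitute.

Uncertainty comes from a node bootstrap: 10² resamples of the N node
labels with replacement; each resample is reduced to its unique nodes,
the ranking and the truth are re-derived inside that subset, and the
2.5/97.5 empirical percentiles of the B scores give the 95% interval.
Duplicates affect inclusion only, not weighting — the simplest reading of
applying "the ranking method among the sampled nodes"; re-ranking within
each resample (rather than subsampling a fixed global ranking) is the
package's chosen interpretation.

## Classification by several centralities

`build_dataset()` labels the top round(f·N) nodes by influence as
positives (influence ties broken by node label for determinism) and
exposes any subset of the seven indicators as features.
`train_classifier()` fits a soft-margin SVM with a second-degree
polynomial kernel; since no suitable SVM implementation is available to
depend on, the dual problem is solved in-package by SMO with second-order
working-set selection (the LIBSVM formulation), stopping when the maximal
KKT violation drops below 5e−4. The kernel is K(x,z) = (x·z/p + 1)², with
p the feature count: the inhomogeneous form keeps linear terms
representable, and the 1/p scaling plays the role of the usual gamma
normalization. Features are z-scored with training-split statistics
(polynomial kernels are scale-sensitive and centrality magnitudes differ
by orders of magnitude); no class weights are applied. The regularisation
constant C is selected from {1, 3, 10, 30, 100} — log-spaced within the
prescribed range [1, 100] — by 5-fold cross-validation maximizing F1,
which is also the reported headline metric.

Evaluation is by repeated holdout: 10² random splits at training fraction
t = 0.5, scored on the held-out nodes by F1 (classification recall and
precision in harmonic mean) and by p(f) applied to the predicted-positive
set (capped at 1.0; a classifier may flag fewer than f·N nodes). If a
model predicts no positives, both scores are defined as 0, the
conservative convention. Single-class training draws are redrawn, at most
10 times.

## The synthetic world

All tests run on generated data. Deterministic fixtures (stars, cycles,
paths, complete graphs, barbells) carry closed-form expectations. Random
generators (Erdős–Rényi, preferential attachment, the planted
core-periphery model) return the largest strongly connected component with
bidirectional edges, reproducibly from a seed.

The planted benchmark operationalizes the phenomenon motivating the
package: the best spreaders are nodes that are *both* locally dense and
globally central, which no single indicator captures. Its stated world
(defaults chosen once, on structural grounds):

* a 60-node 5-regular relay core (mean degree 5 — subcritical on its own,
  so core nodes are weak seeds but good conduits, and regular so that
  relay quality is uniform);
* three 26-node 14-regular circulant target blocks, each tied to the core
  by 52 bridge edges attached round-robin at both ends (two per target
  node, uniformly spread over the core);
* four K15 decoy cliques and 120 K7 filler cliques, one bridge edge each.

Targets and decoys share degree 14 and hence an adjacency spectral radius
of exactly 14; the degeneracy is resolved by coupling, which routes the
Perron mass to the strongly tied targets rather than the locally densest
decoys. Target nodes have the top influence (home block plus
core-mediated reach into the other strong blocks); decoy cliques trap the
local indicators (higher k_sum and equal core number, but outbreaks that
stay home); core relay nodes trap the global ones (top closeness, high
eigenvector, weak seeds). The target population (78) deliberately exceeds
the top-5% quota (52 of 1038): within the targets, influence differences
are engineered down to Monte-Carlo noise (regular blocks, uniform ties,
regular core), so any single-centrality ranking is capped near
quota/population ≈ 2/3 recognition, while a classifier that learns the
joint (local, global) signature flags the whole population and scores
F1 ≈ 2·52/(52+78) ≈ 0.8. A green benchmark test therefore establishes the
qualitative claim — pairs of centralities beat single rankings where the
top spreaders are defined by a conjunction — not any quantitative figure
from real networks, which have heavy-tailed degrees, overlapping
communities and degree assortativity the generator does not emulate.

Ground-truth influence is computed at the benchmark's own estimated λ_c
with per-node run escalation until the Monte-Carlo standard error is
below 1% of the mean (runs doubled from 10⁴, capped at 8×10⁴). The truth stream is seeded
independently of the analysis stream. For graphs of at most 12 nodes the
exact enumeration replaces Monte Carlo outright.

## Numerical and design choices

* Quota rounding: round-half-up of f·N, floored at 1 — deterministic on
  small networks.
* SCC ties: the component containing the smallest node label wins.
* Node order is canonical (sorted labels, numerically when all labels are
  numbers), so all outputs are reproducible across runs and platforms.
* RNG: every stochastic routine takes or derives a seed; per-node
  influence streams are derived from (root seed, node index), so results
  are independent of node subset, processing order, and worker count.
* Δ at λ = 0 is exactly 0 (all outbreaks have size 1); Δ needs at least
  2 sampled seeds.
* Test-time scaling: the repeated-holdout evaluations in the test suite
  use 20 repeats instead of the default 100, and the reduced benchmark in
  the module tests shrinks all block counts; the defaults are unchanged.

## Known limitations

* The SIR simulator returns final sizes only; temporal quantities (peak
  prevalence, time to extinction) are out of scope.
* Weighted, temporal and attributed graphs are not supported; extra edge
  annotations in input files are discarded.
* The variability-peak threshold estimate inherits grid resolution; on
  very small networks the Δ curve is noisy and `runs_per_seed` should be
  raised.
* The planted benchmark demonstrates the mechanism, not the magnitude, of
  the multi-centrality advantage; real-network performance depends on
  structure the generator intentionally controls away.
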