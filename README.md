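# superspreadr

Predicting the top spreaders of a directed network under the SIR epidemic
model, for network epidemiologists and computational social scientists who
need to know *which* nodes would seed the largest outbreaks without
simulating every candidate.

## The problem and the method

The **influence** ρ_i of node *i* is the expected final size of a
continuous-time SIR epidemic seeded at *i* (per-edge transmission rate β,
recovery rate μ, effective ratio λ = β/μ, μ normalized to 1), estimated by
Monte Carlo (default 10⁴ runs per node). Analyses are run at the
**epidemic threshold** λ_c, estimated as the peak over λ of the
outbreak-size variability

Δ(λ) = √(⟨ρ²⟩ − ⟨ρ⟩²) / ⟨ρ⟩

over uniformly sampled seed nodes.

Two predictors of the top fraction *f* of nodes by influence (the set
I_f) are implemented:

1. **Ranking by a single centrality** C: predict C_f, the top round(f·N)
   nodes by C (ties randomized), out of seven indicators: out-degree,
   neighbourhood degree sum (k_sum), two-hop neighbourhood sum (k_2sum),
   core number, closeness, PageRank (damping 0.85), and eigenvector
   centrality. Evaluated by the recognition rate
   r(f) = |I_f ∩ C_f| / |I_f| and the precision function
   p(f) = avg_{i∈C_f} ρ_i / avg_{i∈I_f} ρ_i (capped at 1), with 95%
   bootstrap confidence intervals (10² node resamples).
2. **Classification by several centralities**: a polynomial-kernel
   (degree 2) soft-margin SVM on any feature subset, C tuned in [1, 100]
   by 5-fold cross-validation, solver tolerance 5e−4, no class weights;
   evaluated by F1 and p(f) over 10² random holdout splits at training
   fraction t = 0.5.

The package also ships deterministic fixtures, seeded random-network
generators, and a planted core-periphery benchmark whose ground-truth top
spreaders are jointly (not marginally) identifiable from a local and a
global centrality — the structure that makes multi-centrality classifiers
outperform any single-centrality ranking.

## Worked example

```r
library(superspreadr)

g <- random_network("erdos_renyi", n = 500, mean_degree = 6, rng_seed = 1)
scan <- epidemic_threshold(g, seq(0.05, 0.6, by = 0.05),
                           sir_config(lam = 0, rng_seed = 7))
scan
#> Epidemic threshold scan: 12 grid points
#>   lam_c = 0.2 (peak Delta = 2.331192 )

inf <- influence_all(g, sir_config(lam = scan$lam_c, runs_per_node = 2000,
                                   rng_seed = 7))
head(inf, 3)
#>   node mean_spread    stderr runs
#> 1 n001     14.5210 0.7061102 2000
#> 2 n002      7.3325 0.4910973 2000
#> 3 n003     15.6615 0.7551553 2000

tab <- centrality_table(g)
influence <- setNames(inf$mean_spread, inf$node)
bootstrap_rank_eval(setNames(tab$k_sum, tab$node), influence,
                    f = 0.05, B = 100, centrality_name = "k_sum",
                    rng_seed = 7)
#> Ranker k_sum at f = 0.050 (B = 100):
#>   r(f) = 0.815 [0.717, 0.875]
#>   p(f) = 0.989 [0.982, 0.996]

ev <- repeated_holdout_eval(tab, influence, f = 0.05,
                            classifier_config(repeats = 20),
                            features = c("k_sum", "eigenvector"),
                            rng_seed = 7)
ev
#> Classifier [k_sum+eigenvector] at f = 0.050 (20 repeats):
#>   F1 = 0.789   p(f) = 0.993
```

Read: at this network's threshold (λ_c = 0.2), ranking by k_sum recovers
about 82% of the true top-5% spreaders, and the nodes it proposes are
nearly as influential as the true ones (p ≈ 0.99). On a plain
Erdős–Rényi graph the two-feature classifier has no planted structure to
exploit and matches the ranker; on the planted core-periphery benchmark
(`planted_benchmark()`) it beats every single-centrality ranking — see
the methods vignette and `tests/testthat/test-acceptance.R`.

Command-line drivers mirror the R API (`cmd_centrality`, `cmd_threshold`,
`cmd_influence`, `cmd_rank_eval`, `cmd_classify_eval`; wrapper script in
`inst/cli/`); every run writes a JSON manifest with config, seeds and
input checksums.

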