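test_that("sir_run limit cases", {
  g <- fixture("cycle", 10)
  set.seed(1)
  expect_true(all(sir_run(g, "n01", lam = 0, runs = 50) == 1))
  sizes <- sir_run(g, "n01", lam = 1e6, runs = 100)
  expect_gte(mean(sizes == 10), 0.95)

  iso <- largest_scc(read_edge_list(write_lines_tmp("a b")))  # single node
  set.seed(1)
  expect_equal(sir_run(iso, 1, lam = 5, runs = 10), rep(1L, 10))
})

test_that("exact_expected_spread: closed forms and size guard", {
  two <- read_edge_list(write_lines_tmp("a b"))
  for (lam in c(0.1, 0.5, 1, 2, 10)) {
    expect_equal(exact_expected_spread(two, "a", lam), 1 + lam / (lam + 1),
                 tolerance = 1e-12)
  }
  iso <- largest_scc(two)
  expect_equal(exact_expected_spread(iso, 1, 3), 1.0)
  expect_error(exact_expected_spread(fixture("cycle", 13), 1, 1), "12")
})

test_that("Monte Carlo agrees with the jump-chain oracle", {
  p3 <- read_edge_list(write_lines_tmp(c("a b", "b c")))
  exact <- exact_expected_spread(p3, "a", 1)
  set.seed(99)
  sizes <- sir_run(p3, "a", lam = 1, runs = 40000)
  se <- sd(sizes) / sqrt(length(sizes))
  expect_lt(abs(mean(sizes) - exact), 3 * se)

  st <- fixture("star", 5)
  exact <- exact_expected_spread(st, "n1", 0.5)
  set.seed(100)
  sizes <- sir_run(st, "n1", lam = 0.5, runs = 40000)
  expect_lt(abs(mean(sizes) - exact), 3 * sd(sizes) / sqrt(length(sizes)))
})

test_that("influence_all: zero-rate case, reproducibility, subset streams", {
  g <- fixture("cycle", 8)
  cfg <- sir_config(lam = 0, runs_per_node = 100, rng_seed = 4)
  inf <- influence_all(g, cfg)
  expect_true(all(inf$mean_spread == 1))
  expect_true(all(inf$stderr == 0))

  cfg <- sir_config(lam = 0.8, runs_per_node = 500, rng_seed = 4)
  i1 <- influence_all(g, cfg)
  i2 <- influence_all(g, cfg)
  expect_identical(i1, i2)

  # per-node RNG streams: a subset run reproduces the full-run rows
  sub <- influence_all(g, cfg, nodes = c("n3", "n6"))
  expect_equal(sub$mean_spread, i1$mean_spread[match(c("n3", "n6"), i1$node)])
})

test_that("Monte-Carlo error shrinks with run count", {
  g <- fixture("star", 6)
  se1 <- influence_all(g, sir_config(0.5, runs_per_node = 400, rng_seed = 1),
                       nodes = "n1")$stderr
  se2 <- influence_all(g, sir_config(0.5, runs_per_node = 6400, rng_seed = 1),
                       nodes = "n1")$stderr
  expect_lt(se2, se1 / 2)  # 16x runs: expect 4x reduction, allow slack
})

test_that("mean spread is statistically monotone in lambda", {
  g <- largest_scc(random_digraph(40, 0.12, seed = 8))
  lo <- influence_all(g, sir_config(0.3, runs_per_node = 4000, rng_seed = 2),
                      nodes = igraph::V(g)$name[1])
  hi <- influence_all(g, sir_config(1.0, runs_per_node = 4000, rng_seed = 3),
                      nodes = igraph::V(g)$name[1])
  expect_gte(hi$mean_spread - lo$mean_spread,
             -3 * sqrt(hi$stderr^2 + lo$stderr^2))
})

test_that("delta_variability limits and interior behaviour", {
  g <- random_network("erdos_renyi", n = 300, mean_degree = 6, rng_seed = 5)
  cfg <- sir_config(lam = 0, rng_seed = 11)
  expect_equal(delta_variability(g, 0, cfg), 0)
  d_lo <- delta_variability(g, 1e-4, cfg)
  d_hi <- delta_variability(g, 50, cfg)
  d_mid <- delta_variability(g, 0.2, cfg)
  expect_gt(d_mid, d_lo)
  expect_gt(d_mid, d_hi)

  solo <- largest_scc(read_edge_list(write_lines_tmp("a b")))
  expect_error(delta_variability(solo, 0.5, cfg), "at least 2")
})

test_that("epidemic_threshold returns a reproducible argmax scan", {
  g <- random_network("erdos_renyi", n = 200, mean_degree = 6, rng_seed = 6)
  cfg <- sir_config(lam = 0, rng_seed = 21)
  grid <- seq(0.05, 0.8, by = 0.15)
  s1 <- epidemic_threshold(g, grid, cfg)
  s2 <- epidemic_threshold(g, grid, cfg)
  expect_identical(s1, s2)
  expect_equal(s1$lam_c, grid[which.max(s1$delta_values)])
  expect_error(epidemic_threshold(g, c(0.1, 0.2), cfg), "3")
})

test_that("spread sizes always lie in [1, N]", {
  g <- largest_scc(random_digraph(25, 0.15, seed = 12))
  n <- igraph::vcount(g)
  for (lam in c(0.05, 0.5, 5)) {
    set.seed(lam * 100)
    sizes <- sir_run(g, 1, lam = lam, runs = 300)
    expect_true(all(sizes >= 1 & sizes <= n))
  }
})
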