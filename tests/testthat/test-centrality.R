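test_that("out_degree on canonical fixtures", {
  star <- fixture("star", 6)                     # bidirectional, center n1
  expect_equal(unname(out_degree(star)[c("n1", "n2")]), c(5, 1))
  expect_true(all(out_degree(fixture("cycle", 4)) == 1))
  expect_true(all(out_degree(fixture("complete", 4)) == 3))
})

test_that("neighbourhood sums on forced examples", {
  p3 <- read_edge_list(write_lines_tmp(c("a b", "b c")))
  expect_equal(unname(neighbourhood_sum(p3)), c(1, 0, 0))
  expect_true(all(neighbourhood_sum(fixture("cycle", 4)) == 1))

  p4 <- read_edge_list(write_lines_tmp(c("a b", "b c", "c d")))
  expect_equal(unname(two_hop_neighbourhood_sum(p4)["a"]), 1)
  star <- fixture("star", 5)
  expect_equal(unname(two_hop_neighbourhood_sum(star)["n1"]), 0)
})

test_that("k_sum and k_2sum match brute-force oracles on random graphs", {
  for (seed in 1:20) {
    g <- random_digraph(sample(5:30, 1), stats::runif(1, 0.05, 0.3), seed = seed)
    expect_equal(neighbourhood_sum(g), brute_ksum(g), tolerance = 1e-12)
    expect_equal(two_hop_neighbourhood_sum(g), brute_k2sum(g), tolerance = 1e-12)
  }
})

test_that("core numbers follow shell-peeling structure", {
  expect_true(all(core_number(fixture("complete", 5)) ==
                    max(core_number(fixture("complete", 5)))))
  bcyc <- largest_scc(read_edge_list(
    write_lines_tmp(c("1 2", "2 3", "3 4", "4 5", "5 6", "6 1")),
    undirected = TRUE))
  expect_equal(length(unique(core_number(bcyc))), 1L)

  # clique plus a pendant: pendant strictly below clique members
  gp <- read_edge_list(write_lines_tmp(
    c("a b", "a c", "b c", "c p")), undirected = TRUE)
  cn <- core_number(gp)
  expect_lt(cn[["p"]], min(cn[c("a", "b", "c")]))
})

test_that("closeness: symmetry cases, error off the SCC, oracle", {
  expect_true(all(abs(closeness(fixture("complete", 4)) - 1) < 1e-12))
  expect_true(all(abs(closeness(fixture("cycle", 5)) - 0.4) < 1e-12))
  expect_error(closeness(read_edge_list(write_lines_tmp("a b"))),
               "largest_scc")
  for (seed in 1:10) {
    g <- largest_scc(random_digraph(30, 0.15, seed = 100 + seed))
    if (igraph::vcount(g) < 3) next
    expect_equal(closeness(g), brute_closeness(g), tolerance = 1e-10)
  }
})

test_that("pagerank: uniform cases, fixed point, oracle", {
  expect_true(all(abs(pagerank(fixture("complete", 5)) - 0.2) < 1e-9))
  expect_true(all(abs(pagerank(fixture("cycle", 5)) - 0.2) < 1e-9))
  g <- read_edge_list(write_lines_tmp(c("a b", "b a", "c a")))
  pr <- pagerank(g)
  expect_equal(sum(pr), 1, tolerance = 1e-9)
  expect_equal(pr, brute_pagerank(g), tolerance = 1e-8)
  for (seed in 1:5) {
    g <- random_digraph(25, 0.15, seed = 200 + seed)
    expect_equal(pagerank(g), brute_pagerank(g), tolerance = 1e-8)
  }
})

test_that("eigenvector: symmetry, star ratio, residual, oracle", {
  ev <- eigenvector(fixture("complete", 6))
  expect_true(all(abs(ev - ev[1]) < 1e-8))
  expect_equal(sum(ev^2), 1, tolerance = 1e-9)

  star <- fixture("star", 10)
  ev <- eigenvector(star)
  expect_equal(unname(ev["n02"] / ev["n01"]), 1 / sqrt(9), tolerance = 1e-6)
  A <- dense_adj(star)
  lam <- as.numeric(t(ev) %*% A %*% ev)
  expect_lt(max(abs(A %*% ev - lam * ev)), 1e-8)

  for (seed in 1:10) {
    g <- largest_scc(random_digraph(30, 0.15, seed = 300 + seed))
    if (igraph::vcount(g) < 3) next
    expect_equal(eigenvector(g), brute_eigenvector(g), tolerance = 1e-6)
  }
})

test_that("orientation options flip the underlying direction", {
  p3 <- largest_scc(read_edge_list(
    write_lines_tmp(c("a b", "b c", "c a", "a c"))))
  expect_false(isTRUE(all.equal(closeness(p3, "out"), closeness(p3, "in"))))
  expect_false(isTRUE(all.equal(eigenvector(p3, "out"), eigenvector(p3, "in"))))
  expect_equal(eigenvector(p3, "in"), brute_eigenvector(reverse_edges(p3)),
               tolerance = 1e-6)
})

test_that("centrality_table is complete, deterministic, constant on vertex-transitive graphs", {
  g <- largest_scc(random_digraph(25, 0.2, seed = 42))
  tab <- centrality_table(g)
  expect_named(tab, c("node", centrality_names()))
  expect_equal(nrow(tab), igraph::vcount(g))
  expect_equal(tab, centrality_table(g))

  for (fx in list(fixture("cycle", 6), fixture("complete", 5))) {
    tab <- centrality_table(fx)
    for (cn in centrality_names()) {
      expect_lt(diff(range(tab[[cn]])), 1e-8)
    }
  }
})
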