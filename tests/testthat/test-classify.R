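toy_table <- function(n, seed) {
  set.seed(seed)
  data.frame(node = sprintf("v%03d", seq_len(n)),
             degree = runif(n), k_sum = runif(n), k_2sum = runif(n),
             core = runif(n), closeness = runif(n), pagerank = runif(n),
             eigenvector = runif(n), stringsAsFactors = FALSE)
}

test_that("build_dataset labels exactly the top-f quota", {
  tab <- toy_table(100, 1)
  infl <- setNames(seq_len(100), tab$node)
  ds <- build_dataset(tab, infl, f = 0.05)
  expect_equal(sum(ds$y), 5L)
  expect_equal(ds$y[match(sprintf("v%03d", 96:100), rownames(ds$X))],
               rep(1L, 5))
  ds1 <- build_dataset(tab, infl, f = 0.05, features = "degree")
  expect_equal(ncol(ds1$X), 1L)
  # tiny f floors at one positive
  expect_equal(sum(build_dataset(tab, infl, f = 0.001)$y), 1L)
})

test_that("build_dataset is invariant to node insertion order", {
  tab <- toy_table(60, 2)
  infl <- setNames(runif(60), tab$node)
  perm <- sample(60)
  ds1 <- build_dataset(tab, infl, f = 0.1)
  ds2 <- build_dataset(tab[perm, ], infl, f = 0.1)
  ord <- match(rownames(ds1$X), rownames(ds2$X))
  expect_equal(ds1$y, ds2$y[ord])
  expect_equal(unname(ds1$X), unname(ds2$X[ord, ]))
})

make_ds <- function(X, y) {
  rownames(X) <- sprintf("v%03d", seq_len(nrow(X)))
  structure(list(X = X, y = y, f = mean(y), features = colnames(X)),
            class = "node_dataset")
}

test_that("SVM separates a noiseless joint-threshold rule", {
  # corner rule with a margin band, so a conic boundary can separate exactly
  set.seed(3)
  X <- cbind(a = runif(150), b = runif(150))
  keep <- pmin(abs(X[, 1] - 0.55), abs(X[, 2] - 0.55)) > 0.08 |
    (X[, 1] < 0.47 | X[, 2] < 0.47)
  X <- X[keep, , drop = FALSE]
  y <- as.integer(X[, 1] > 0.55 & X[, 2] > 0.55)
  ds <- make_ds(X, y)
  m <- train_classifier(ds, classifier_config(), rng_seed = 11)
  expect_equal(superspreadr:::f1_score(y, predict(m, ds)), 1.0)
  expect_true(m$C %in% classifier_config()$C_grid)
})

test_that("training is deterministic given the seed and errors on one class", {
  set.seed(4)
  X <- cbind(a = runif(80), b = runif(80))
  y <- as.integer(X[, 1] + X[, 2] > 1.2)
  ds <- make_ds(X, y)
  m1 <- train_classifier(ds, classifier_config(), rng_seed = 5)
  m2 <- train_classifier(ds, classifier_config(), rng_seed = 5)
  expect_identical(m1$C, m2$C)
  expect_identical(predict(m1, ds), predict(m2, ds))

  expect_error(train_classifier(make_ds(X, rep(0L, 80))), "single class")
})

test_that("permuted labels give near-chance cross-validated F1", {
  set.seed(12)
  X <- cbind(a = runif(200), b = runif(200))
  y <- as.integer(X[, 1] > 0.8)  # 20% positives
  f1_null <- replicate(10, {
    yp <- sample(y)
    ds <- make_ds(X, yp)
    m <- train_classifier(ds, classifier_config(C_grid = 10), rng_seed = NULL)
    superspreadr:::f1_score(yp, predict(m, ds))
  })
  # no-signal F1 cannot approach the separable ceiling
  expect_lt(mean(f1_null), 0.6)
})

test_that("evaluate_classifier scores and degenerate conventions", {
  set.seed(13)
  X <- cbind(a = c(runif(20, 0.7, 1), runif(60, 0, 0.4)))
  y <- c(rep(1L, 20), rep(0L, 60))
  ds <- make_ds(X, y)
  infl <- setNames(as.numeric(X[, 1]), rownames(ds$X))
  m <- train_classifier(ds, classifier_config(C_grid = 10), rng_seed = 2)
  sc <- evaluate_classifier(m, ds, infl)
  expect_equal(unname(sc["f1"]), 1)
  expect_equal(unname(sc["p"]), 1)

  # harmonic mean arithmetic: recall 0.5, precision 1 -> 2/3
  expect_equal(superspreadr:::f1_score(c(1, 1, 0, 0), c(1, 0, 0, 0)), 2 / 3)

  # a model that predicts no positives scores (0, 0)
  m0 <- m
  m0$fit$rho <- 1e9
  expect_equal(unname(evaluate_classifier(m0, ds, infl)), c(0, 0))
})

test_that("repeated holdout: self-feature recovers the labels", {
  tab <- toy_table(120, 14)
  infl <- setNames(tab$degree, tab$node)  # label is a function of the feature
  ev <- repeated_holdout_eval(tab, infl, f = 0.2,
                              classifier_config(repeats = 10, C_grid = c(10, 100)),
                              features = "degree", rng_seed = 3)
  expect_gt(ev$f1_mean, 0.9)
  expect_gt(ev$p_mean, 0.95)
  expect_true(all(ev$f1 >= 0 & ev$f1 <= 1))
  expect_true(all(ev$p >= 0 & ev$p <= 1))

  ev1 <- repeated_holdout_eval(tab, infl, f = 0.2,
                               classifier_config(repeats = 1, C_grid = 10),
                               features = "degree", rng_seed = 4)
  expect_length(ev1$f1, 1L)
})

test_that("feature order does not change predictions", {
  set.seed(15)
  X <- cbind(a = runif(100), b = runif(100))
  y <- as.integer(X[, 1] > 0.6 & X[, 2] > 0.4)
  m1 <- train_classifier(make_ds(X, y), classifier_config(C_grid = 10),
                         rng_seed = 6)
  m2 <- train_classifier(make_ds(X[, c("b", "a")], y),
                         classifier_config(C_grid = 10), rng_seed = 6)
  newX <- cbind(a = runif(30), b = runif(30))
  expect_equal(predict(m1, newX), predict(m2, newX[, c("b", "a")]))
})
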