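#' Classifier configuration
#'
#' Settings for the multi-centrality superspreader classifier: a
#' soft-margin SVM with a polynomial kernel, the regularisation constant C
#' tuned over a grid within `[1, 100]` by k-fold cross-validation.
#'
#' @param kernel_degree Polynomial kernel degree (default 2).
#' @param C_grid Candidate regularisation constants, all within `[1, 100]`
#'   (default `c(1, 3, 10, 30, 100)`, log-spaced).
#' @param cv_folds Cross-validation folds for tuning C (default 5).
#' @param tol Stopping tolerance of the SMO solver (default 5e-4).
#' @param train_fraction Fraction of nodes in the training split
#'   (default 0.5).
#' @param repeats Number of random train/test draws in repeated-holdout
#'   evaluation (default 100).
#' @param standardize Z-score features using training-split statistics
#'   (default `TRUE`; polynomial kernels are scale-sensitive and centrality
#'   magnitudes differ by orders of magnitude).
#' @return A list of class `classifier_config`. No class weights are used.
#' @export
classifier_config <- function(kernel_degree = 2L, C_grid = c(1, 3, 10, 30, 100),
                              cv_folds = 5L, tol = 5e-4,
                              train_fraction = 0.5, repeats = 100L,
                              standardize = TRUE) {
  stopifnot(all(C_grid >= 1), all(C_grid <= 100),
            train_fraction > 0, train_fraction < 1, cv_folds >= 2)
  structure(list(kernel_degree = as.integer(kernel_degree), C_grid = C_grid,
                 cv_folds = as.integer(cv_folds), tol = tol,
                 train_fraction = train_fraction,
                 repeats = as.integer(repeats), standardize = standardize),
            class = "classifier_config")
}

#' Build a node-classification dataset
#'
#' Assembles the feature matrix (chosen centrality columns) and the binary
#' target: label 1 iff the node is among the top fraction `f` of nodes by
#' SIR influence, exactly `round(f * N)` positives (floored at 1), ties at
#' the influence boundary broken deterministically by node label.
#'
#' @param table A [centrality_table()] data frame.
#' @param influence Named numeric per-node influence, or the data frame
#'   returned by [influence_all()].
#' @param f Fraction in (0, 1].
#' @param features Character vector of feature column names
#'   (subset of [centrality_names()]).
#' @return A list of class `node_dataset` with `X` (matrix, rownames =
#'   node labels), `y` (0/1 integer), `f`, `features`.
#' @export
build_dataset <- function(table, influence, f,
                          features = centrality_names()) {
  stopifnot(all(features %in% centrality_names()),
            all(features %in% names(table)))
  if (is.data.frame(influence)) {
    influence <- stats::setNames(influence$mean_spread, influence$node)
  }
  nodes <- table$node
  stopifnot(all(nodes %in% names(influence)))
  n <- length(nodes)
  k <- top_quota(f, n)
  # deterministic: sort by influence desc, node label as tie-break
  ord <- order(-influence[nodes], nodes, method = "radix")
  y <- integer(n)
  y[ord[seq_len(k)]] <- 1L
  X <- as.matrix(table[, features, drop = FALSE])
  rownames(X) <- nodes
  structure(list(X = X, y = y, f = f, features = features),
            class = "node_dataset")
}

poly_kernel <- function(X1, X2, degree) {
  p <- ncol(X1)
  (tcrossprod(X1, X2) / p + 1)^degree
}

f1_score <- function(truth, pred) {
  tp <- sum(truth == 1L & pred == 1L)
  npred <- sum(pred == 1L)
  npos <- sum(truth == 1L)
  if (npred == 0L || tp == 0L) return(0)
  prec <- tp / npred
  rec <- tp / npos
  2 / (1 / rec + 1 / prec)
}

svm_fit <- function(X, y01, C, degree, tol) {
  y <- ifelse(y01 == 1L, 1, -1)
  K <- poly_kernel(X, X, degree)
  sol <- svm_smo_cpp(K, y, C, tol, max_iter = 10000000L)
  sv <- which(sol$alpha > 1e-12)
  list(X_sv = X[sv, , drop = FALSE], coef = (sol$alpha * y)[sv],
       rho = sol$rho, degree = degree, C = C,
       converged = sol$converged)
}

svm_decision <- function(fit, X) {
  if (length(fit$coef) == 0L) return(rep(-fit$rho, nrow(X)))
  as.numeric(poly_kernel(X, fit$X_sv, fit$degree) %*% fit$coef) - fit$rho
}

#' Train the polynomial-kernel SVM superspreader classifier
#'
#' Features are z-scored with training-split statistics (if configured),
#' the regularisation constant C is selected from `cfg$C_grid` by k-fold
#' cross-validation maximizing F1, and the final model is refit on the full
#' training split. Deterministic given the RNG state.
#'
#' @param train A `node_dataset` (see [build_dataset()]) containing both
#'   classes.
#' @param cfg A [classifier_config()].
#' @param rng_seed Optional seed (controls the CV fold assignment).
#' @return An object of class `svm_spreader`; supports [predict()] with
#'   `type = "class"` (0/1) or `"decision"`.
#' @export
train_classifier <- function(train, cfg = classifier_config(),
                             rng_seed = NULL) {
  if (!is.null(rng_seed)) set.seed(rng_seed)
  X <- train$X
  y <- train$y
  if (length(unique(y)) < 2L) {
    stop("training data has a single class; increase f or the training fraction")
  }
  ctr <- rep(0, ncol(X)); scl <- rep(1, ncol(X))
  if (cfg$standardize) {
    ctr <- colMeans(X)
    scl <- apply(X, 2, stats::sd)
    scl[scl == 0 | !is.finite(scl)] <- 1
  }
  Xs <- scale(X, center = ctr, scale = scl)
  n <- nrow(Xs)
  cv_f1 <- rep(NA_real_, length(cfg$C_grid))
  if (length(cfg$C_grid) > 1L) {
    folds <- sample(rep_len(seq_len(cfg$cv_folds), n))
    for (ci in seq_along(cfg$C_grid)) {
      preds <- integer(n)
      ok <- TRUE
      for (fold in seq_len(cfg$cv_folds)) {
        hold <- folds == fold
        if (length(unique(y[!hold])) < 2L) { ok <- FALSE; break }
        fit <- svm_fit(Xs[!hold, , drop = FALSE], y[!hold], cfg$C_grid[ci],
                       cfg$kernel_degree, cfg$tol)
        preds[hold] <- as.integer(svm_decision(fit, Xs[hold, , drop = FALSE]) > 0)
      }
      cv_f1[ci] <- if (ok) f1_score(y, preds) else -Inf
    }
    C_best <- cfg$C_grid[which.max(cv_f1)]
  } else {
    C_best <- cfg$C_grid[1L]
  }
  fit <- svm_fit(Xs, y, C_best, cfg$kernel_degree, cfg$tol)
  structure(list(fit = fit, center = ctr, scale = scl, C = C_best,
                 cv_f1 = cv_f1, features = train$features, cfg = cfg),
            class = "svm_spreader")
}

#' @param object An `svm_spreader` model.
#' @param newdata A `node_dataset` or a numeric feature matrix in the
#'   model's feature order.
#' @param type `"class"` (default) for 0/1 labels, `"decision"` for raw
#'   decision values.
#' @param ... Unused.
#' @rdname train_classifier
#' @export
predict.svm_spreader <- function(object, newdata, type = c("class", "decision"),
                                 ...) {
  type <- match.arg(type)
  X <- if (inherits(newdata, "node_dataset")) newdata$X else as.matrix(newdata)
  Xs <- scale(X, center = object$center, scale = object$scale)
  d <- svm_decision(object$fit, Xs)
  if (type == "decision") d else as.integer(d > 0)
}

#' Evaluate a trained classifier on a test split
#'
#' Scores the predicted-positive set against the test split's true
#' positives: the F1 score (harmonic mean of recall and classification
#' precision) and the precision function p(f) (relative mean influence,
#' capped at 1). If the model predicts no positives both scores are 0.
#'
#' @param model An `svm_spreader`.
#' @param test A `node_dataset` (nonempty).
#' @param influence Named numeric per-node influence covering the test
#'   nodes.
#' @return Named numeric vector `c(f1 = , p = )`.
#' @export
evaluate_classifier <- function(model, test, influence) {
  stopifnot(nrow(test$X) > 0)
  pred <- predict(model, test)
  truth <- test$y
  nodes <- rownames(test$X)
  pred_set <- nodes[pred == 1L]
  true_set <- nodes[truth == 1L]
  if (length(pred_set) == 0L) return(c(f1 = 0, p = 0))
  p <- if (length(true_set) == 0L) 0 else
    precision_function(true_set, pred_set, influence)
  c(f1 = f1_score(truth, pred), p = p)
}

#' Repeated-holdout evaluation of the multi-centrality classifier
#'
#' Repeats `cfg$repeats` times: draw a random training fraction
#' `cfg$train_fraction` of the nodes without replacement, relabel the
#' training and test splits from the network-wide top-f assignment, train
#' the SVM, and evaluate F1 and p(f) on the held-out nodes. Splits whose
#' training part is single-class are redrawn (at most 10 times each).
#'
#' @param table A [centrality_table()] data frame.
#' @param influence Per-node influence (named vector or [influence_all()]
#'   output).
#' @param f Fraction in (0, 1].
#' @param cfg A [classifier_config()].
#' @param features Feature subset (default all seven).
#' @param rng_seed Root seed for the repeated draws.
#' @return A list of class `classify_eval` with `f`, `feature_names`,
#'   `f1_mean`, `p_mean`, and per-repeat `f1` / `p` vectors.
#' @export
repeated_holdout_eval <- function(table, influence, f,
                                  cfg = classifier_config(),
                                  features = centrality_names(),
                                  rng_seed = 1L) {
  ds <- build_dataset(table, influence, f, features)
  if (is.data.frame(influence)) {
    influence <- stats::setNames(influence$mean_spread, influence$node)
  }
  n <- nrow(ds$X)
  n_train <- max(1L, round(cfg$train_fraction * n))
  f1s <- numeric(cfg$repeats)
  ps <- numeric(cfg$repeats)
  set.seed(rng_seed)
  for (rep_i in seq_len(cfg$repeats)) {
    for (attempt in 1:11) {
      if (attempt > 10L) stop("could not draw a two-class training split in 10 attempts")
      tr <- sample.int(n, n_train)
      if (length(unique(ds$y[tr])) == 2L) break
    }
    train <- structure(list(X = ds$X[tr, , drop = FALSE], y = ds$y[tr],
                            f = f, features = features),
                       class = "node_dataset")
    test <- structure(list(X = ds$X[-tr, , drop = FALSE], y = ds$y[-tr],
                           f = f, features = features),
                      class = "node_dataset")
    model <- train_classifier(train, cfg)
    sc <- evaluate_classifier(model, test, influence)
    f1s[rep_i] <- sc["f1"]
    ps[rep_i] <- sc["p"]
  }
  structure(list(f = f, feature_names = features,
                 f1_mean = mean(f1s), p_mean = mean(ps),
                 f1 = f1s, p = ps),
            class = "classify_eval")
}

#' @export
print.classify_eval <- function(x, ...) {
  cat(sprintf("Classifier [%s] at f = %.3f (%d repeats):\n",
              paste(x$feature_names, collapse = "+"), x$f, length(x$f1)))
  cat(sprintf("  F1 = %.3f   p(f) = %.3f\n", x$f1_mean, x$p_mean))
  invisible(x)
}
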