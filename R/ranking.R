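top_quota <- function(f, n) max(1L, as.integer(floor(f * n + 0.5)))

#' Top fraction of nodes by score, with randomized tie handling
#'
#' Returns exactly `round(f * N)` nodes (at least 1): all nodes strictly
#' above the boundary score, plus a uniform-random draw from the nodes tied
#' at the boundary to fill the quota. Discrete-valued centralities (degree,
#' core number) routinely tie at the boundary; the random fill is averaged
#' out by the bootstrap.
#'
#' @param scores Named numeric vector of scores.
#' @param f Fraction in (0, 1].
#' @return Character vector of selected node names.
#' @export
top_fraction <- function(scores, f) {
  stopifnot(f > 0, f <= 1, length(scores) > 0)
  n <- length(scores)
  k <- top_quota(f, n)
  thr <- sort(scores, decreasing = TRUE)[k]
  above <- names(scores)[scores > thr]
  tied <- names(scores)[scores == thr]
  need <- k - length(above)
  if (need >= length(tied)) return(c(above, tied))
  c(above, sample(tied, need))
}

#' Recognition rate (recall) of a superspreader prediction
#'
#' Fraction of the true top spreaders recovered by the prediction:
#' `|I_f intersect C_f| / |I_f|`.
#'
#' @param true_top Character vector of true top-spreader labels (nonempty).
#' @param predicted Character vector of predicted labels.
#' @return A real in `[0, 1]`.
#' @export
recognition_rate <- function(true_top, predicted) {
  stopifnot(length(true_top) > 0)
  length(intersect(true_top, predicted)) / length(true_top)
}

#' Precision function of a superspreader prediction
#'
#' Mean SIR influence of the predicted nodes divided by the mean influence
#' of the true top spreaders; values above 1 (possible when the prediction
#' is a small, high-influence set) are capped at 1. Unlike classification
#' precision, this does not penalise substituting a top spreader with a
#' near-equally influential node.
#'
#' @param true_top Character vector of true top-spreader labels (nonempty).
#' @param predicted Character vector of predicted labels (nonempty).
#' @param influence Named numeric vector of per-node influence.
#' @return A real in `[0, 1]`.
#' @export
precision_function <- function(true_top, predicted, influence) {
  stopifnot(length(true_top) > 0, length(predicted) > 0)
  p <- mean(influence[predicted]) / mean(influence[true_top])
  min(p, 1.0)
}

#' Evaluate a single-centrality ranker with bootstrap confidence intervals
#'
#' Draws `B` bootstrap resamples of the N node labels uniformly with
#' replacement; each resample is reduced to its unique nodes, within which
#' the centrality ranking predicts the top fraction `f` (random tie fill)
#' and the influence ranking defines the true top fraction. Recognition
#' rate and precision function are computed per resample; reported are
#' their means and empirical 2.5/97.5 percentile intervals.
#'
#' @param scores Named numeric centrality values (the ranker).
#' @param influence Named numeric per-node influence (the ground truth).
#' @param f Fraction in (0, 1].
#' @param B Number of bootstrap resamples (default 100).
#' @param centrality_name Label stored in the result.
#' @param rng_seed Optional seed set before resampling.
#' @return A list of class `rank_eval` with fields `f`, `centrality_name`,
#'   `r_mean`, `r_ci95`, `p_mean`, `p_ci95`, `bootstrap_B`.
#' @export
bootstrap_rank_eval <- function(scores, influence, f, B = 100L,
                                centrality_name = "centrality",
                                rng_seed = NULL) {
  stopifnot(B >= 2, f > 0, f <= 1)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  labs <- names(scores)
  stopifnot(!is.null(labs), all(labs %in% names(influence)))
  n <- length(labs)
  rs <- numeric(B)
  ps <- numeric(B)
  for (b in seq_len(B)) {
    smp <- unique(sample(labs, n, replace = TRUE))
    pred <- top_fraction(scores[smp], f)
    truth <- top_fraction(influence[smp], f)
    rs[b] <- recognition_rate(truth, pred)
    ps[b] <- precision_function(truth, pred, influence)
  }
  structure(list(f = f, centrality_name = centrality_name,
                 r_mean = mean(rs),
                 r_ci95 = unname(stats::quantile(rs, c(0.025, 0.975))),
                 p_mean = mean(ps),
                 p_ci95 = unname(stats::quantile(ps, c(0.025, 0.975))),
                 bootstrap_B = as.integer(B)),
            class = "rank_eval")
}

#' Evaluate a single-centrality ranker on the full node set
#'
#' Plain (non-bootstrap) evaluation: the top fraction `f` by centrality is
#' compared against the top fraction by influence on the whole network,
#' averaging the recognition rate and precision function over `n_draws`
#' randomizations of boundary ties.
#'
#' @inheritParams bootstrap_rank_eval
#' @param n_draws Number of tie-randomization draws to average (default 100).
#' @return A list with `r_mean` and `p_mean`.
#' @export
rank_eval <- function(scores, influence, f, n_draws = 100L, rng_seed = NULL) {
  if (!is.null(rng_seed)) set.seed(rng_seed)
  rs <- numeric(n_draws)
  ps <- numeric(n_draws)
  for (b in seq_len(n_draws)) {
    pred <- top_fraction(scores, f)
    truth <- top_fraction(influence, f)
    rs[b] <- recognition_rate(truth, pred)
    ps[b] <- precision_function(truth, pred, influence)
  }
  list(r_mean = mean(rs), p_mean = mean(ps))
}

#' @export
print.rank_eval <- function(x, ...) {
  cat(sprintf("Ranker %s at f = %.3f (B = %d):\n", x$centrality_name, x$f,
              x$bootstrap_B))
  cat(sprintf("  r(f) = %.3f [%.3f, %.3f]\n", x$r_mean, x$r_ci95[1], x$r_ci95[2]))
  cat(sprintf("  p(f) = %.3f [%.3f, %.3f]\n", x$p_mean, x$p_ci95[1], x$p_ci95[2]))
  invisible(x)
}
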