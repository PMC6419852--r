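# Independent oracles used to cross-check the package implementations.
# These deliberately use a different route (lm/t.test/var.test/choose/
# phyper/p.adjust, explicit loops) than the package code.

# Brute-force invariant-causal-prediction over all 2^p subsets.
oracle_icp <- function(X, Y, env, alpha = 0.05) {
  p <- ncol(X)
  env <- droplevels(as.factor(env))
  subsets <- list(integer(0))
  for (k in seq_len(p))
    subsets <- c(subsets, utils::combn(seq_len(p), k, simplify = FALSE))
  accepted <- list()
  for (s in subsets) {
    d <- data.frame(.Y = Y)
    if (length(s)) d <- cbind(d, as.data.frame(X[, s, drop = FALSE]))
    res <- stats::residuals(stats::lm(.Y ~ ., data = d))
    p_env <- vapply(levels(env), function(e) {
      r1 <- res[env == e]
      r2 <- res[env != e]
      p_t <- stats::t.test(r1, r2, var.equal = FALSE)$p.value
      p_f <- stats::var.test(r1, r2)$p.value
      min(1, 2 * min(p_t, p_f))
    }, numeric(1))
    if (min(1, nlevels(env) * min(p_env)) >= alpha)
      accepted[[length(accepted) + 1L]] <- s
  }
  parent <- if (length(accepted)) sort(Reduce(intersect, accepted)) else integer(0)
  list(accepted_sets = accepted, parent_set = parent)
}

# Hypergeometric upper tail by plain choose() summation.
oracle_hyper_tail <- function(N, K, M, n) {
  if (n == 0) return(1)
  x <- n:min(K, M)
  sum(choose(K, x) * choose(N - K, M - x)) / choose(N, M)
}

# Mean-rank Borda by explicit per-pair loops over the input rankings.
oracle_borda_order <- function(rankings) {
  keys <- paste(rankings[[1]]$regulator, rankings[[1]]$target, sep = "|")
  mean_rank <- vapply(seq_along(keys), function(i) {
    reg <- rankings[[1]]$regulator[i]
    tar <- rankings[[1]]$target[i]
    mean(vapply(rankings, function(r)
      r$avg_rank[r$regulator == reg & r$target == tar], numeric(1)))
  }, numeric(1))
  keys[order(mean_rank, rankings[[1]]$regulator, rankings[[1]]$target, method = "radix")]
}

# Small deterministic ranking over a p x t pair grid from a score matrix.
toy_ranking <- function(scores, method = "toy") {
  rank_interactions(structure(scores, method = method))
}

# Jaccard index of two index sets.
jaccard <- function(a, b) {
  if (!length(a) && !length(b)) return(1)
  length(intersect(a, b)) / length(union(a, b))
}
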