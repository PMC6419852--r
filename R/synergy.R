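## miRNA-miRNA synergy: do two regulators share more targets than chance?
##
## For regulators i and j with K = |targets_i|, M = |targets_j| drawn from
## a universe of N genes, the number of shared targets under the null is
## hypergeometric; the synergy p-value is the upper tail
##   p = 1 - sum_{x=0}^{n-1} C(K,x) C(N-K,M-x) / C(N,M) = P(X >= n),
## Benjamini-Hochberg adjusted over all regulator pairs.

#' Hypergeometric overlap p-value
#'
#' Upper-tail probability `P(X >= n)` for a hypergeometric count of shared
#' targets, computed by direct log-gamma summation of the tail terms
#' (numerically stable; no subtraction from 1 except for the empty sum).
#'
#' @param N Universe size (all mRNAs of interest).
#' @param K Number of targets of the first regulator.
#' @param M Number of targets of the second regulator.
#' @param n Number of shared targets; must satisfy
#'   `max(0, K + M - N) <= n <= min(K, M)`.
#' @return p-value in \[0, 1\]; `n = 0` gives exactly 1.
#' @export
#' @examples
#' hypergeom_pvalue(10, 5, 5, 5)  # 1/252
#' hypergeom_pvalue(4, 2, 2, 2)   # 1/6
hypergeom_pvalue <- function(N, K, M, n) {
  N <- check_count(N, "N", min = 0L); K <- check_count(K, "K", min = 0L)
  M <- check_count(M, "M", min = 0L); n <- check_count(n, "n", min = 0L)
  if (K > N || M > N)
    icpmir_stop("icpmir_bad_argument", "need K <= N and M <= N (got N=%d K=%d M=%d)", N, K, M)
  if (n < max(0L, K + M - N) || n > min(K, M))
    icpmir_stop("icpmir_bad_argument",
                "n = %d outside feasible overlap range [%d, %d]",
                n, max(0L, K + M - N), min(K, M))
  if (n == 0L) return(1)
  x <- n:min(K, M)
  log_terms <- lchoose(K, x) + lchoose(N - K, M - x) - lchoose(N, M)
  m <- max(log_terms)
  min(1, exp(m + log(sum(exp(log_terms - m)))))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard step-up rule: sort ascending, multiply `p_(i)` by `m/i`,
#' enforce monotonicity from the largest down, cap at 1; values are
#' returned in the original order.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  if (!is.numeric(pvalues) || anyNA(pvalues) ||
      any(pvalues < 0) || any(pvalues > 1))
    icpmir_stop("icpmir_bad_argument", "p-values must all lie in [0, 1]")
  m <- length(pvalues)
  if (m == 0L) return(numeric(0))
  o <- order(pvalues, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin((m / (m:1)) * pvalues[o]))[ro]
}

#' Pairwise regulator synergy matrix
#'
#' Tests every unordered pair of regulators for significant sharing of
#' targets: raw p-values from [hypergeom_pvalue()] with `N =
#' universe_size`, `K`/`M` the two target-set sizes and `n` the
#' intersection size; BH adjustment over all `choose(r, 2)` pairs as one
#' family; a pair is synergistic when the adjusted p-value is below
#' `cutoff`.
#'
#' @param target_sets Named list: regulator id -> character vector of
#'   target ids (deduplicated internally). Typically the targets from
#'   [top_k_per_regulator()] at k in 50/100/150/200.
#' @param universe_size Number of all mRNAs of interest (N); must be at
#'   least the largest target-set size.
#' @param cutoff Adjusted p-value cutoff, default 0.05.
#' @return List of class `synergy_result`: `regulator_ids`, `raw_p`,
#'   `adj_p`, `synergistic` (symmetric matrices, diagonal NA), `shared`
#'   (pairwise intersection sizes), `set_sizes`, `universe_size`,
#'   `cutoff`.
#' @export
synergy_matrix <- function(target_sets, universe_size, cutoff = 0.05) {
  if (!is.list(target_sets) || is.null(names(target_sets)) || length(target_sets) < 2L)
    icpmir_stop("icpmir_bad_argument", "target_sets must be a named list of >= 2 regulators")
  target_sets <- lapply(target_sets, function(s) unique(as.character(s)))
  sizes <- lengths(target_sets)
  universe_size <- check_count(universe_size, "universe_size", min = 0L)
  if (universe_size < max(sizes))
    icpmir_stop("icpmir_bad_argument",
                "universe_size %d smaller than largest target set (%d)",
                universe_size, max(sizes))
  r <- length(target_sets)
  ids <- names(target_sets)
  raw <- matrix(NA_real_, r, r, dimnames = list(ids, ids))
  shared <- matrix(NA_integer_, r, r, dimnames = list(ids, ids))
  idx <- utils::combn(r, 2L)
  pvec <- numeric(ncol(idx))
  for (c in seq_len(ncol(idx))) {
    i <- idx[1L, c]; j <- idx[2L, c]
    nshared <- length(intersect(target_sets[[i]], target_sets[[j]]))
    shared[i, j] <- shared[j, i] <- nshared
    pvec[c] <- hypergeom_pvalue(universe_size, sizes[i], sizes[j], nshared)
    raw[i, j] <- raw[j, i] <- pvec[c]
  }
  adjvec <- bh_adjust(pvec)
  adj <- matrix(NA_real_, r, r, dimnames = list(ids, ids))
  for (c in seq_len(ncol(idx))) {
    i <- idx[1L, c]; j <- idx[2L, c]
    adj[i, j] <- adj[j, i] <- adjvec[c]
  }
  syn <- adj < cutoff
  structure(list(regulator_ids = ids, raw_p = raw, adj_p = adj,
                 synergistic = syn, shared = shared,
                 set_sizes = sizes, universe_size = universe_size,
                 cutoff = cutoff),
            class = "synergy_result")
}

#' Minimum number of synergistic partners over regulators
#'
#' The smallest, over regulators, count of other regulators it forms a
#' synergistic pair with (e.g. "every miRNA shares targets with at least 9
#' others").
#'
#' @param result `synergy_result` from [synergy_matrix()].
#' @return Single integer.
#' @export
min_synergy_partners <- function(result) {
  if (!inherits(result, "synergy_result"))
    icpmir_stop("icpmir_bad_argument", "expected a synergy_result")
  as.integer(min(rowSums(result$synergistic, na.rm = TRUE)))
}

#' Write synergy results as a long-format CSV
#'
#' Columns `miRNA_i,miRNA_j,shared,raw_p,adj_p,synergistic`, one row per
#' unordered pair.
#'
#' @param result `synergy_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_synergy <- function(result, path) {
  ids <- result$regulator_ids
  idx <- utils::combn(length(ids), 2L)
  df <- data.frame(miRNA_i = ids[idx[1L, ]], miRNA_j = ids[idx[2L, ]],
                   shared = result$shared[t(idx)],
                   raw_p = result$raw_p[t(idx)],
                   adj_p = result$adj_p[t(idx)],
                   synergistic = result$synergistic[t(idx)],
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.synergy_result <- function(x, ...) {
  n_pairs <- sum(x$synergistic[upper.tri(x$synergistic)], na.rm = TRUE)
  cat(sprintf("Synergy analysis of %d regulators (N = %d, BH cutoff %g)\n",
              length(x$regulator_ids), x$universe_size, x$cutoff))
  cat(sprintf("  synergistic pairs: %d of %d; min partners per regulator: %d\n",
              n_pairs, choose(length(x$regulator_ids), 2L), min_synergy_partners(x)))
  invisible(x)
}
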