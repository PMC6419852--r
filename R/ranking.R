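## Interaction rankings and Borda rank aggregation.
##
## A ranking is a data.frame (class `interaction_ranking`) over the full
## regulator x target pair universe with columns regulator, target, score,
## avg_rank, rank, method. `rank` is contiguous 1..n after the
## deterministic tie-break; `avg_rank` assigns tied scores their average
## rank and is what Borda aggregation averages, so the ensemble is
## invariant to the arbitrary ordering inside ties.

#' Turn a score matrix into an interaction ranking
#'
#' Orders all regulator-target pairs by score. By default larger absolute
#' score is better (rank 1 best): miRNA regulation is typically
#' repressive, so strong negative correlations must rank high.
#' `direction = "signed"` ranks by decreasing signed score instead. Exact
#' ties share their average rank in `avg_rank` and are broken
#' lexicographically (regulator id, then target id) for the contiguous
#' `rank` column.
#'
#' @param scores `interaction_scores` matrix (regulators x targets).
#' @param direction `"absolute"` (default) or `"signed"`.
#' @param method Method label; defaults to the matrix's `method` attribute.
#' @return `interaction_ranking` data.frame sorted by rank.
#' @export
rank_interactions <- function(scores, direction = c("absolute", "signed"),
                              method = attr(scores, "method")) {
  direction <- match.arg(direction)
  if (is.null(method)) method <- "scores"
  if (!is.matrix(scores) || !is.numeric(scores) ||
      is.null(rownames(scores)) || is.null(colnames(scores)))
    icpmir_stop("icpmir_bad_argument", "scores must be a named regulators x targets matrix")
  if (any(!is.finite(scores)))
    icpmir_stop("icpmir_bad_argument", "scores must be finite")
  df <- data.frame(regulator = rep(rownames(scores), times = ncol(scores)),
                   target = rep(colnames(scores), each = nrow(scores)),
                   score = as.numeric(scores),
                   stringsAsFactors = FALSE)
  key <- if (direction == "absolute") -abs(df$score) else -df$score
  df$avg_rank <- rank(key, ties.method = "average")
  ord <- order(key, df$regulator, df$target, method = "radix")
  df <- df[ord, , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  df$method <- method
  rownames(df) <- NULL
  class(df) <- c("interaction_ranking", "data.frame")
  df
}

#' Validate an interaction ranking
#' @param ranking Object to check.
#' @return `ranking`, invisibly.
#' @export
validate_ranking <- function(ranking) {
  need <- c("regulator", "target", "score", "avg_rank", "rank", "method")
  if (!is.data.frame(ranking) || !all(need %in% names(ranking)))
    icpmir_stop("icpmir_bad_argument", "ranking must have columns %s",
                paste(need, collapse = ", "))
  if (!identical(sort(ranking$rank), seq_len(nrow(ranking))))
    icpmir_stop("icpmir_bad_argument", "ranks must be contiguous 1..n")
  if (anyDuplicated(paste(ranking$regulator, ranking$target, sep = "\r")))
    icpmir_stop("icpmir_bad_argument", "duplicate regulator-target pairs in ranking")
  invisible(ranking)
}

#' Borda rank aggregation of several rankings
#'
#' Each pair's ensemble score is the arithmetic mean of its (tie-averaged)
#' ranks across the input rankings; pairs are reordered by increasing mean
#' rank, ties broken lexicographically, and contiguous ranks reassigned.
#' All rankings must cover the identical pair universe; a mismatch is an
#' error listing the symmetric difference, never a silent intersection.
#'
#' @param rankings List of >= 2 `interaction_ranking` data.frames.
#' @param method Label for the aggregate, default `"Borda"`.
#' @return `interaction_ranking` with an extra `mean_rank` column and
#'   `score = -mean_rank` (so that larger score still means better).
#' @export
borda_aggregate <- function(rankings, method = "Borda") {
  if (!is.list(rankings) || length(rankings) < 2L)
    icpmir_stop("icpmir_bad_argument", "need at least 2 rankings to aggregate")
  lapply(rankings, validate_ranking)
  keys <- lapply(rankings, function(r) paste(r$regulator, r$target, sep = "\r"))
  ref <- sort(keys[[1L]])
  for (i in seq_along(keys)[-1L]) {
    if (!identical(sort(keys[[i]]), ref)) {
      diff <- c(setdiff(keys[[i]], keys[[1L]]), setdiff(keys[[1L]], keys[[i]]))
      icpmir_stop("icpmir_universe_mismatch",
                  "rankings cover different pair universes; symmetric difference: %s",
                  paste(utils::head(gsub("\r", "/", diff), 10L), collapse = ", "))
    }
  }
  base <- rankings[[1L]][order(keys[[1L]]), c("regulator", "target")]
  mean_rank <- Reduce(`+`, lapply(seq_along(rankings), function(i)
    rankings[[i]]$avg_rank[order(keys[[i]])])) / length(rankings)
  df <- data.frame(base, mean_rank = mean_rank, stringsAsFactors = FALSE)
  df$score <- -df$mean_rank
  df$avg_rank <- rank(df$mean_rank, ties.method = "average")
  ord <- order(df$mean_rank, df$regulator, df$target, method = "radix")
  df <- df[ord, c("regulator", "target", "score", "avg_rank", "mean_rank")]
  df$rank <- seq_len(nrow(df))
  df$method <- method
  rownames(df) <- NULL
  class(df) <- c("interaction_ranking", "data.frame")
  df
}

#' Write a ranking to CSV
#'
#' Long format `miRNA,mRNA,score,rank,method` (plus `mean_rank` for Borda
#' aggregates).
#'
#' @param ranking `interaction_ranking`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ranking <- function(ranking, path) {
  validate_ranking(ranking)
  out <- data.frame(miRNA = ranking$regulator, mRNA = ranking$target,
                    score = ranking$score, rank = ranking$rank,
                    method = ranking$method, stringsAsFactors = FALSE)
  if ("mean_rank" %in% names(ranking)) out$mean_rank <- ranking$mean_rank
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a score matrix as TSV plus long-format CSV
#'
#' @param scores `interaction_scores` matrix.
#' @param tsv_path Path for the regulators x targets TSV.
#' @param csv_path Optional path for the long `miRNA,mRNA,score,method` CSV.
#' @return `tsv_path`, invisibly.
#' @export
write_scores <- function(scores, tsv_path, csv_path = NULL) {
  write_expression_matrix(unclass(scores)[, , drop = FALSE], tsv_path,
                          id_column = "miRNA")
  if (!is.null(csv_path)) {
    long <- data.frame(miRNA = rep(rownames(scores), times = ncol(scores)),
                       mRNA = rep(colnames(scores), each = nrow(scores)),
                       score = as.numeric(scores),
                       method = attr(scores, "method") %||% "scores",
                       stringsAsFactors = FALSE)
    utils::write.csv(long, csv_path, row.names = FALSE, quote = FALSE)
  }
  invisible(tsv_path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
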