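## Validation protocol: top-k selection, confirmation against transfection
## fold-changes and confirmed-interaction databases, the random null
## experiment, and per-method overlap tables.
##
## Identifier matching is case-insensitive throughout (ids are lower-cased
## and trimmed before comparison); mismatched namespaces are the caller's
## responsibility.

#' Read a transfection fold-change table
#'
#' CSV with columns `miRNA,mRNA,log2fc`: the log2 fold-change of each mRNA
#' after transfection (over-expression) of the miRNA.
#'
#' @param path Path to the CSV (optionally `.gz`).
#' @return data.frame with columns `miRNA`, `mRNA`, `log2fc`.
#' @export
read_transfection_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("miRNA", "mRNA", "log2fc")
  if (!all(need %in% names(df)))
    icpmir_stop("icpmir_io", "transfection table needs columns %s", paste(need, collapse = ","))
  if (anyNA(df$log2fc) || any(!is.finite(df$log2fc)))
    icpmir_stop("icpmir_missing_values", "non-finite log2fc values in %s", path)
  df[need]
}

#' Read a confirmed-interaction list
#'
#' CSV with columns `miRNA,mRNA`, e.g. a union of experimentally confirmed
#' target databases. Duplicate pairs are collapsed.
#'
#' @param path Path to the CSV (optionally `.gz`).
#' @return data.frame with columns `miRNA`, `mRNA`, unique pairs.
#' @export
read_ground_truth <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("miRNA", "mRNA") %in% names(df)))
    icpmir_stop("icpmir_io", "ground-truth list needs columns miRNA,mRNA")
  df <- df[c("miRNA", "mRNA")]
  df[!duplicated(pair_key(df$miRNA, df$mRNA)), , drop = FALSE]
}

#' Top k interactions overall
#'
#' @param ranking `interaction_ranking`.
#' @param k Number of pairs (<= nrow(ranking)); typical values 500, 1000,
#'   1500, 2000.
#' @return data.frame of the k best pairs with their scores and ranks.
#' @export
top_k_overall <- function(ranking, k) {
  validate_ranking(ranking)
  k <- check_count(k, "k")
  if (k > nrow(ranking))
    icpmir_stop("icpmir_bad_argument", "k = %d exceeds ranking length %d", k, nrow(ranking))
  ranking[order(ranking$rank)[seq_len(k)], , drop = FALSE]
}

#' Top k interactions per regulator
#'
#' For each regulator, its `k` best-ranked pairs (typical values 50, 100,
#' 150, 200). Regulators with fewer than `k` pairs contribute all of them,
#' with a logged note.
#'
#' @inheritParams top_k_overall
#' @return Named list, one data.frame per regulator.
#' @export
top_k_per_regulator <- function(ranking, k) {
  validate_ranking(ranking)
  k <- check_count(k, "k")
  ranking <- ranking[order(ranking$rank), , drop = FALSE]
  out <- split(ranking, ranking$regulator)
  short <- names(out)[vapply(out, nrow, integer(1)) < k]
  if (length(short))
    icpmir_log("INFO", "top_k_per_regulator",
               sprintf("%d regulator(s) have fewer than %d pairs; truncated", length(short), k))
  lapply(out, function(df) df[seq_len(min(k, nrow(df))), , drop = FALSE])
}

#' Confirm predicted pairs against transfection fold-changes
#'
#' A pair is confirmed when it appears in the transfection table and the
#' absolute log2 fold-change strictly exceeds `threshold` (default 0.3; a
#' pair at exactly the threshold is not confirmed). Pairs absent from the
#' table cannot be checked and are reported separately as uncheckable,
#' excluded from the confirmed count.
#'
#' @param pairs data.frame with columns `regulator`/`miRNA` and
#'   `target`/`mRNA`.
#' @param table Transfection data.frame as from [read_transfection_table()].
#' @param threshold Absolute log2 fold-change cutoff, default 0.3.
#' @return List: `n_confirmed`, `n_uncheckable`, `n_checked`, `confirmed`
#'   (data.frame of confirmed pairs with their log2fc).
#' @export
confirm_by_transfection <- function(pairs, table, threshold = 0.3) {
  if (threshold < 0)
    icpmir_stop("icpmir_bad_argument", "threshold must be >= 0")
  pairs <- normalize_pairs(pairs)
  tab_key <- pair_key(table$miRNA, table$mRNA)
  fc <- table$log2fc[match(pair_key(pairs$regulator, pairs$target), tab_key)]
  uncheckable <- is.na(fc)
  confirmed <- !uncheckable & abs(fc) > threshold
  list(n_confirmed = sum(confirmed),
       n_uncheckable = sum(uncheckable),
       n_checked = sum(!uncheckable),
       confirmed = data.frame(regulator = pairs$regulator[confirmed],
                              target = pairs$target[confirmed],
                              log2fc = fc[confirmed],
                              stringsAsFactors = FALSE))
}

#' Confirm predicted pairs against a confirmed-interaction database
#'
#' @param pairs data.frame with columns `regulator`/`miRNA` and
#'   `target`/`mRNA`.
#' @param db data.frame as from [read_ground_truth()].
#' @return List: `n_confirmed`, `confirmed` (data.frame of pairs found in
#'   the database).
#' @export
confirm_by_database <- function(pairs, db) {
  pairs <- normalize_pairs(pairs)
  hit <- pair_key(pairs$regulator, pairs$target) %in% pair_key(db$miRNA, db$mRNA)
  list(n_confirmed = sum(hit),
       confirmed = data.frame(regulator = pairs$regulator[hit],
                              target = pairs$target[hit],
                              stringsAsFactors = FALSE))
}

#' @noRd
normalize_pairs <- function(pairs) {
  if (is.list(pairs) && !is.data.frame(pairs)) pairs <- do.call(rbind, pairs)
  nm <- names(pairs)
  reg <- if ("regulator" %in% nm) pairs$regulator else pairs$miRNA
  tar <- if ("target" %in% nm) pairs$target else pairs$mRNA
  if (is.null(reg) || is.null(tar))
    icpmir_stop("icpmir_bad_argument", "pairs need regulator/miRNA and target/mRNA columns")
  data.frame(regulator = as.character(reg), target = as.character(tar),
             stringsAsFactors = FALSE)
}

#' Random-selection null experiment
#'
#' Baseline for the per-regulator validation: each repetition draws
#' `n_regulators` regulators uniformly without replacement and, for each,
#' `k` of its targets uniformly without replacement from the pair
#' universe; the validator is applied to the pooled draw and the confirmed
#' counts are averaged over repetitions (defaults mirror the protocol: 30
#' regulators, 100 repetitions).
#'
#' @param pair_universe data.frame of all candidate pairs
#'   (`regulator`/`miRNA`, `target`/`mRNA` columns).
#' @param n_regulators Regulators drawn per repetition, default 30.
#' @param k Targets drawn per regulator.
#' @param reps Repetitions, default 100.
#' @param validator Function mapping a pairs data.frame to a list with an
#'   `n_confirmed` element (e.g. a partially applied
#'   [confirm_by_database()]).
#' @param seed Integer seed; the experiment is deterministic given it.
#' @return List: `mean_confirmed`, `counts` (per repetition).
#' @export
null_experiment <- function(pair_universe, n_regulators = 30L, k, reps = 100L,
                            validator, seed = 1L) {
  universe <- normalize_pairs(pair_universe)
  n_regulators <- check_count(n_regulators, "n_regulators")
  k <- check_count(k, "k")
  reps <- check_count(reps, "reps")
  by_reg <- split(universe$target, universe$regulator)
  if (length(by_reg) < n_regulators)
    icpmir_stop("icpmir_bad_argument", "universe has %d regulators, need %d",
                length(by_reg), n_regulators)
  if (any(lengths(by_reg) < k))
    icpmir_stop("icpmir_bad_argument",
                "some regulators have fewer than k = %d targets in the universe", k)
  counts <- with_seed(seed, {
    vapply(seq_len(reps), function(r) {
      regs <- sample(names(by_reg), n_regulators)
      draw <- do.call(rbind, lapply(regs, function(g)
        data.frame(regulator = g, target = sample(by_reg[[g]], k),
                   stringsAsFactors = FALSE)))
      as.numeric(validator(draw)$n_confirmed)
    }, numeric(1))
  })
  list(mean_confirmed = mean(counts), counts = counts)
}

#' Overlap of confirmed interactions between methods
#'
#' UpSet-style table: per-method confirmed counts plus the count of every
#' non-empty intersection class (pairs confirmed by exactly that set of
#' methods).
#'
#' @param confirmed_lists Named list (>= 2 methods) of pair data.frames.
#' @return List: `per_method` (named counts), `classes` (data.frame
#'   `methods`, `count` with `methods` a `&`-joined label).
#' @export
method_overlap <- function(confirmed_lists) {
  if (!is.list(confirmed_lists) || length(confirmed_lists) < 2L ||
      is.null(names(confirmed_lists)))
    icpmir_stop("icpmir_bad_argument", "need a named list of >= 2 methods")
  keys <- lapply(confirmed_lists, function(df) {
    df <- normalize_pairs(df)
    unique(pair_key(df$regulator, df$target))
  })
  all_keys <- unique(unlist(keys, use.names = FALSE))
  member <- vapply(keys, function(k) all_keys %in% k, logical(length(all_keys)))
  member <- matrix(member, nrow = length(all_keys),
                   dimnames = list(NULL, names(confirmed_lists)))
  class_label <- apply(member, 1L, function(row)
    paste(colnames(member)[row], collapse = "&"))
  tab <- table(class_label)
  list(per_method = vapply(keys, length, integer(1)),
       classes = data.frame(methods = names(tab), count = as.integer(tab),
                            stringsAsFactors = FALSE))
}
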