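## Expression matrices, environment labels, MAD feature selection.
##
## An expression matrix is a plain numeric matrix, features in rows and
## samples in columns, with unique non-empty dimnames and log-scale values.
## An environment assignment is a named factor: names are sample ids, levels
## are environment labels (e.g. Pam50 subtypes Basal/Her2/LumA/LumB/Normal).

#' Validate an expression matrix
#'
#' Checks the container contract used throughout the package: a numeric
#' matrix with unique feature row names and unique sample column names and
#' no missing or non-finite values.
#'
#' @param x Numeric matrix, features x samples.
#' @param what Label used in error messages.
#' @return `x`, invisibly, if valid; otherwise an error.
#' @export
validate_expression_matrix <- function(x, what = "expression matrix") {
  if (!is.matrix(x) || !is.numeric(x))
    icpmir_stop("icpmir_bad_matrix", "%s must be a numeric matrix", what)
  if (is.null(rownames(x)) || is.null(colnames(x)))
    icpmir_stop("icpmir_bad_matrix", "%s must carry feature rownames and sample colnames", what)
  dup_f <- unique(rownames(x)[duplicated(rownames(x))])
  if (length(dup_f))
    icpmir_stop("icpmir_duplicate_id", "duplicated feature id(s) in %s: %s",
                what, paste(dup_f, collapse = ", "))
  dup_s <- unique(colnames(x)[duplicated(colnames(x))])
  if (length(dup_s))
    icpmir_stop("icpmir_duplicate_id", "duplicated sample id(s) in %s: %s",
                what, paste(dup_s, collapse = ", "))
  if (anyNA(x) || any(!is.finite(x)))
    icpmir_stop("icpmir_missing_values", "%s contains missing or non-finite values", what)
  invisible(x)
}

#' Read an expression matrix from a delimited text file
#'
#' Expects a header row of sample ids and a first column of feature ids;
#' the body must be numeric. Gzip-compressed files are handled
#' transparently. Feature order is preserved as in the file.
#'
#' @param path Path to a TSV/CSV file (optionally `.gz`).
#' @param delimiter Field separator, default tab.
#' @param na_action `"error"` (default) fails on any missing value;
#'   `"drop_features"` removes features containing missing values and logs
#'   how many were dropped.
#' @return Numeric matrix, features x samples.
#' @export
read_expression_matrix <- function(path, delimiter = "\t",
                                   na_action = c("error", "drop_features")) {
  na_action <- match.arg(na_action)
  if (!file.exists(path))
    icpmir_stop("icpmir_io", "file not found: %s", path)
  df <- utils::read.table(path, sep = delimiter, header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "", quote = "\"")
  if (ncol(df) < 2L)
    icpmir_stop("icpmir_io", "expected feature-id column plus at least one sample column in %s", path)
  feature_ids <- as.character(df[[1L]])
  dup <- unique(feature_ids[duplicated(feature_ids)])
  if (length(dup))
    icpmir_stop("icpmir_duplicate_id", "duplicated feature id(s): %s", paste(dup, collapse = ", "))
  body <- df[-1L]
  for (j in seq_along(body)) {
    col <- body[[j]]
    if (!is.numeric(col)) {
      suppressWarnings(num <- as.numeric(col))
      bad <- which(is.na(num) & !is.na(col) & trimws(col) != "" &
                     !(toupper(trimws(col)) %in% c("NA", "NAN")))
      if (length(bad))
        icpmir_stop("icpmir_non_numeric",
                    "non-numeric value %s at feature row %d, sample column %s",
                    dQuote(col[bad[1L]]), bad[1L], dQuote(names(body)[j]))
      body[[j]] <- num
    }
  }
  mat <- as.matrix(body)
  storage.mode(mat) <- "double"
  rownames(mat) <- feature_ids
  if (anyNA(mat)) {
    if (na_action == "drop_features") {
      keep <- stats::complete.cases(mat)
      icpmir_log("INFO", "read_expression_matrix",
                 sprintf("dropped %d feature(s) with missing values", sum(!keep)))
      mat <- mat[keep, , drop = FALSE]
    } else {
      icpmir_stop("icpmir_missing_values",
                  "missing values in %s (use na_action = \"drop_features\" to drop)", path)
    }
  }
  validate_expression_matrix(mat)
  mat
}

#' Write an expression matrix to a delimited text file
#'
#' Inverse of [read_expression_matrix()]: header row of sample ids, first
#' column of feature ids. Paths ending in `.gz` are written compressed.
#'
#' @param x Numeric matrix, features x samples, with dimnames.
#' @param path Output path.
#' @param delimiter Field separator, default tab.
#' @param id_column Name of the feature-id column, default `"feature_id"`.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path, delimiter = "\t", id_column = "feature_id") {
  validate_expression_matrix(x)
  df <- data.frame(rownames(x), x, check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1L] <- id_column
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.table(df, con, sep = delimiter, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Median absolute deviation with consistency constant 1
#'
#' `median(|x - median(x)|)`, the robust variability measure used for
#' feature selection. Deliberately unscaled (no 1.4826 normal-consistency
#' factor): scaling is rank-preserving and only the ranks drive selection.
#'
#' @param x Non-empty numeric vector.
#' @return A single non-negative number.
#' @export
#' @examples
#' mad_unscaled(c(1, 2, 3, 4, 100))  # 1
mad_unscaled <- function(x) {
  if (length(x) == 0L || !is.numeric(x))
    icpmir_stop("icpmir_bad_argument", "mad_unscaled() needs a non-empty numeric vector")
  if (anyNA(x))
    icpmir_stop("icpmir_missing_values", "mad_unscaled() input contains NA")
  stats::mad(x, constant = 1)
}

#' Select the most variable features by MAD
#'
#' Keeps the `k` features with largest median absolute deviation, ordered
#' by decreasing MAD. Exact MAD ties keep the original input order, so the
#' selection is deterministic. Typical use mirrors the pipeline defaults:
#' top 30 miRNAs and top 1500 mRNAs.
#'
#' @param x Expression matrix, features x samples.
#' @param k Number of features to keep (`k <= nrow(x)`).
#' @return Submatrix of `x` with `k` rows.
#' @export
select_by_mad <- function(x, k) {
  validate_expression_matrix(x)
  k <- check_count(k, "k")
  if (k > nrow(x))
    icpmir_stop("icpmir_bad_argument", "k = %d exceeds feature count %d", k, nrow(x))
  mads <- apply(x, 1L, mad_unscaled)
  ord <- order(-mads)  # stable: ties stay in input order
  x[ord[seq_len(k)], , drop = FALSE]
}

#' Construct and validate an environment assignment
#'
#' @param labels Character (or factor) vector of environment labels, named
#'   by sample id; or an unnamed vector with `sample_ids` supplied.
#' @param sample_ids Optional sample ids if `labels` is unnamed.
#' @param min_size Minimum samples per environment (default 3, the smallest
#'   group for which the variance test has positive degrees of freedom).
#' @return Named factor with one level per environment.
#' @export
environment_assignment <- function(labels, sample_ids = NULL, min_size = 3L) {
  if (!is.null(sample_ids)) names(labels) <- sample_ids
  if (is.null(names(labels)) || anyNA(names(labels)) || any(names(labels) == ""))
    icpmir_stop("icpmir_bad_argument", "environment labels must be named by sample id")
  dup <- unique(names(labels)[duplicated(names(labels))])
  if (length(dup))
    icpmir_stop("icpmir_duplicate_id", "duplicated sample id(s) in labels: %s",
                paste(dup, collapse = ", "))
  env <- factor(as.character(labels))
  names(env) <- names(labels)
  if (nlevels(env) < 2L)
    icpmir_stop("icpmir_single_environment",
                "need at least 2 distinct environments, got %d (%s)",
                nlevels(env), paste(levels(env), collapse = ", "))
  sizes <- table(env)
  small <- names(sizes)[sizes < min_size]
  if (length(small))
    icpmir_stop("icpmir_small_environment",
                "environment(s) below minimum size %d: %s", min_size,
                paste(sprintf("%s (n=%d)", small, sizes[small]), collapse = ", "))
  env
}

#' Read environment labels from a two-column table
#'
#' First column sample id, second column environment label (header
#' optional, auto-detected; comma-separated by default). These are
#' typically the output of an external subtype classifier such as Pam50.
#'
#' @param path Path to a CSV (optionally `.gz`).
#' @param delimiter Field separator, default comma.
#' @inheritParams environment_assignment
#' @return Named factor as from [environment_assignment()].
#' @export
read_environment_labels <- function(path, delimiter = ",", min_size = 3L) {
  if (!file.exists(path))
    icpmir_stop("icpmir_io", "file not found: %s", path)
  first <- strsplit(readLines(path, n = 1L), delimiter, fixed = TRUE)[[1L]]
  header <- length(first) >= 2L &&
    any(tolower(trimws(first)) %in% c("sample_id", "sample", "environment", "label", "subtype"))
  df <- utils::read.table(path, sep = delimiter, header = header,
                          stringsAsFactors = FALSE, comment.char = "")
  if (ncol(df) < 2L)
    icpmir_stop("icpmir_io", "expected two columns sample_id,environment in %s", path)
  environment_assignment(as.character(df[[2L]]), sample_ids = as.character(df[[1L]]),
                         min_size = min_size)
}

#' Check that every labeled sample exists in an expression matrix
#'
#' @param env Named factor from [environment_assignment()].
#' @param x Expression matrix whose columns must cover the labeled samples.
#' @return `env` restricted and reordered to the columns of `x`.
#' @export
align_environments <- function(env, x) {
  validate_expression_matrix(x)
  missing <- setdiff(names(env), colnames(x))
  if (length(missing))
    icpmir_stop("icpmir_unknown_sample",
                "labeled sample(s) absent from expression matrix: %s",
                paste(utils::head(missing, 5L), collapse = ", "))
  unlabeled <- setdiff(colnames(x), names(env))
  if (length(unlabeled))
    icpmir_stop("icpmir_unknown_sample",
                "expression sample(s) without environment label: %s",
                paste(utils::head(unlabeled, 5L), collapse = ", "))
  env[colnames(x)]
}

#' Randomly split samples into balanced environments
#'
#' Partitions the samples into `n_env` groups whose sizes differ by at most
#' one, as in the random-environment scenario where no subtype labels are
#' used. Deterministic given (`sample_ids` order, `n_env`, `seed`).
#'
#' @param sample_ids Character vector of sample ids.
#' @param n_env Number of environments (>= 2), default 3.
#' @param seed Integer seed.
#' @param min_size Minimum samples per environment.
#' @return Named factor with levels `env1..envn`.
#' @export
random_environment_split <- function(sample_ids, n_env = 3L, seed = 1L, min_size = 3L) {
  n_env <- check_count(n_env, "n_env", min = 2L)
  n <- length(sample_ids)
  if (n < n_env * min_size)
    icpmir_stop("icpmir_bad_argument",
                "%d samples cannot form %d environments of at least %d", n, n_env, min_size)
  sizes <- rep(n %/% n_env, n_env)
  extra <- n %% n_env
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  labels <- rep(sprintf("env%d", seq_len(n_env)), times = sizes)
  perm <- with_seed(seed, sample.int(n))
  out <- character(n)
  out[perm] <- labels
  environment_assignment(out, sample_ids = sample_ids, min_size = min_size)
}

#' Intersect two expression matrices on shared samples
#'
#' Restricts both matrices to their common sample ids (in the first
#' matrix's order) and warns about samples dropped from either side.
#'
#' @param regulators,targets Expression matrices.
#' @return List with elements `regulators` and `targets`.
#' @export
match_samples <- function(regulators, targets) {
  validate_expression_matrix(regulators, "regulator matrix")
  validate_expression_matrix(targets, "target matrix")
  shared <- intersect(colnames(regulators), colnames(targets))
  if (length(shared) == 0L)
    icpmir_stop("icpmir_unknown_sample", "no shared samples between the two matrices")
  dropped <- length(union(colnames(regulators), colnames(targets))) - length(shared)
  if (dropped > 0L)
    warning(sprintf("dropping %d unmatched sample(s); keeping %d shared", dropped, length(shared)),
            call. = FALSE)
  list(regulators = regulators[, shared, drop = FALSE],
       targets = targets[, shared, drop = FALSE])
}
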