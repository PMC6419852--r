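## Correlation and regression baselines producing interaction score
## matrices comparable to the ICP scores.

#' Pearson correlation scores for all regulator-target pairs
#'
#' Entry (i, j) is the Pearson correlation of regulator i and target j
#' across all shared samples. Zero-variance features yield a 0 score with
#' a warning instead of NA.
#'
#' @inheritParams score_all_pairs
#' @return `interaction_scores` matrix, regulators x targets, entries in
#'   \[-1, 1\].
#' @export
pearson_scores <- function(regulators, targets) {
  validate_expression_matrix(regulators, "regulator matrix")
  validate_expression_matrix(targets, "target matrix")
  if (!identical(colnames(regulators), colnames(targets)))
    icpmir_stop("icpmir_unknown_sample",
                "regulator and target matrices must share identical sample columns (use match_samples())")
  suppressWarnings(scores <- stats::cor(t(regulators), t(targets), method = "pearson"))
  if (anyNA(scores)) {
    warning(sprintf("%d zero-variance pair(s) scored 0", sum(is.na(scores))), call. = FALSE)
    scores[is.na(scores)] <- 0
  }
  structure(scores, method = "Pearson",
            class = c("interaction_scores", "matrix", "array"))
}

#' Lasso regression scores for all regulator-target pairs
#'
#' For each target, fits an L1-penalised linear regression of the target
#' on all regulators (standardised internally; coefficients reported on
#' the original scale). The penalty is chosen per target by 10-fold
#' cross-validation at minimum CV error (`lambda_rule = "cv"`, seeded fold
#' assignment for reproducibility) or fixed (`lambda_rule = "fixed"`).
#'
#' @inheritParams score_all_pairs
#' @param lambda_rule `"cv"` (default) or `"fixed"`.
#' @param lambda Penalty value when `lambda_rule = "fixed"`.
#' @param nfolds CV folds, default 10.
#' @param seed Integer seed controlling the CV fold assignment.
#' @return `interaction_scores` matrix, regulators x targets.
#' @export
lasso_scores <- function(regulators, targets, lambda_rule = c("cv", "fixed"),
                         lambda = NULL, nfolds = 10L, seed = 1L) {
  lambda_rule <- match.arg(lambda_rule)
  validate_expression_matrix(regulators, "regulator matrix")
  validate_expression_matrix(targets, "target matrix")
  if (!identical(colnames(regulators), colnames(targets)))
    icpmir_stop("icpmir_unknown_sample",
                "regulator and target matrices must share identical sample columns (use match_samples())")
  if (lambda_rule == "fixed" && is.null(lambda))
    icpmir_stop("icpmir_bad_argument", "lambda_rule = \"fixed\" requires `lambda`")
  X <- t(regulators)
  n <- nrow(X)
  p <- ncol(X)
  scores <- matrix(0, nrow = p, ncol = nrow(targets),
                   dimnames = list(rownames(regulators), rownames(targets)))
  foldid <- if (lambda_rule == "cv")
    with_seed(seed, sample(rep(seq_len(nfolds), length.out = n))) else NULL
  for (j in seq_len(nrow(targets))) {
    y <- targets[j, ]
    if (stats::sd(y) == 0) {
      warning(sprintf("target %s has zero variance; zero column", rownames(targets)[j]),
              call. = FALSE)
      next
    }
    if (lambda_rule == "cv") {
      cvfit <- glmnet::cv.glmnet(X, y, foldid = foldid, standardize = TRUE)
      beta <- stats::coef(cvfit, s = "lambda.min")
    } else {
      # descend the path to the requested penalty for a well-converged fit
      lam_seq <- sort(unique(c(exp(seq(log(max(lambda, 1e-4) * 100), log(max(lambda, 1e-4)),
                                       length.out = 20L)), lambda)), decreasing = TRUE)
      fit <- glmnet::glmnet(X, y, lambda = lam_seq, standardize = TRUE, thresh = 1e-12)
      beta <- stats::coef(fit)[, which.min(abs(fit$lambda - lambda)), drop = FALSE]
    }
    scores[, j] <- as.numeric(beta)[-1L]
  }
  structure(scores, method = "Lasso",
            class = c("interaction_scores", "matrix", "array"))
}
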