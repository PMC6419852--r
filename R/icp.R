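## Invariant causal prediction per target gene.
##
## The model: across environments e, the target satisfies
##   Y^e = mu + X^e gamma* + eps^e,   eps^e ~ F_eps,  eps^e independent of
## the causal predictors, with F_eps identical in every environment. A
## candidate predictor subset S is "plausible" when the residuals of the
## pooled OLS fit on S have the same mean and variance in each environment
## as in the rest of the samples; the parent estimate is the intersection
## of all plausible subsets.

#' Pooled ordinary least squares on a predictor subset
#'
#' Fits one global regression over all samples of all environments (the
#' pooled fit whose residual distribution is then compared between
#' environments). An empty subset gives the intercept-only fit.
#'
#' @param X Numeric matrix, samples x predictors.
#' @param Y Numeric response vector, length `nrow(X)`.
#' @param subset Integer vector of predictor column indices (possibly empty).
#' @param level Confidence level for per-coefficient intervals (default 0.95).
#' @return List of class `icpmir_fit`: `subset`, `intercept`, `coefficients`
#'   (aligned to `subset`), `residuals` (length n), `ci` (|subset| x 2
#'   matrix), `sigma`, `df`.
#' @export
fit_pooled_regression <- function(X, Y, subset = integer(0), level = 0.95) {
  X <- as.matrix(X)
  n <- length(Y)
  if (nrow(X) != n)
    icpmir_stop("icpmir_bad_argument", "nrow(X) (%d) != length(Y) (%d)", nrow(X), n)
  subset <- sort(unique(as.integer(subset)))
  if (length(subset) && (min(subset) < 1L || max(subset) > ncol(X)))
    icpmir_stop("icpmir_bad_argument", "subset indices out of range 1..%d", ncol(X))
  if (length(subset) + 1L >= n)
    icpmir_stop("icpmir_bad_argument", "subset size %d too large for %d samples",
                length(subset), n)
  M <- cbind(`(Intercept)` = 1, X[, subset, drop = FALSE])
  qr_m <- qr(M)
  if (qr_m$rank < ncol(M))
    icpmir_stop("icpmir_collinear",
                "collinear predictor subset {%s}: untestable",
                paste(subset, collapse = ","))
  coefs <- qr.coef(qr_m, Y)
  res <- as.numeric(Y - M %*% coefs)
  df <- n - ncol(M)
  sigma2 <- sum(res^2) / max(df, 1L)
  XtXinv <- chol2inv(qr.R(qr_m))
  se <- sqrt(pmax(diag(XtXinv), 0) * sigma2)
  tq <- stats::qt(1 - (1 - level) / 2, df = max(df, 1L))
  ci <- cbind(lower = coefs - tq * se, upper = coefs + tq * se)
  structure(list(subset = subset,
                 intercept = unname(coefs[1L]),
                 coefficients = unname(coefs[-1L]),
                 residuals = res,
                 ci = ci[-1L, , drop = FALSE],
                 sigma = sqrt(sigma2),
                 df = df),
            class = "icpmir_fit")
}

#' Residual-invariance p-value for one environment
#'
#' Tests whether pooled-fit residuals in environment `e` look like the
#' residuals of all other samples: a Welch two-sample t-test compares the
#' means and a variance-ratio F-test compares the variances. The two
#' p-values are Bonferroni-combined, `min(1, 2 * min(p_t, p_F))`.
#'
#' Both p-values are computed from the closed-form statistics for speed;
#' they agree with [stats::t.test()] (`var.equal = FALSE`) and
#' [stats::var.test()].
#'
#' @param residuals Numeric vector of pooled residuals over all samples.
#' @param env Named or unnamed factor of environment labels aligned to
#'   `residuals`.
#' @param e Environment label to test against the rest.
#' @param min_size Minimum group size on either side (default 3).
#' @return A single p-value in \[0, 1\].
#' @export
invariance_pvalue <- function(residuals, env, e, min_size = 3L) {
  in_e <- env == e
  r1 <- residuals[in_e]
  r2 <- residuals[!in_e]
  n1 <- length(r1); n2 <- length(r2)
  if (n1 < min_size || n2 < min_size)
    icpmir_stop("icpmir_small_environment",
                "environment %s leaves groups of size %d/%d (min %d)", e, n1, n2, min_size)
  m1 <- mean(r1); m2 <- mean(r2)
  v1 <- stats::var(r1); v2 <- stats::var(r2)
  if (v1 == 0 && v2 == 0) {
    # degenerate: exact fit in both groups; invariant iff the means agree
    return(if (isTRUE(all.equal(m1, m2))) 1 else 0)
  }
  # Welch t-test on means
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df_w <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p_t <- 2 * stats::pt(-abs(tstat), df = df_w)
  # two-sided variance-ratio F-test
  fstat <- v1 / v2
  p_low <- stats::pf(fstat, n1 - 1, n2 - 1)
  p_F <- min(1, 2 * min(p_low, 1 - p_low))
  min(1, 2 * min(p_t, p_F))
}

#' Test one predictor subset for residual invariance
#'
#' Fits the pooled regression on `subset`, computes the per-environment
#' invariance p-values, and Bonferroni-combines them over the
#' environments: `p = min(1, |E| * min_e p_e)`. The subset is accepted
#' when `p >= alpha`. Collinear (untestable) subsets are reported as
#' rejected with `p = 0` and a logged reason, never silently accepted.
#'
#' @inheritParams fit_pooled_regression
#' @param env Factor of environment labels aligned to the rows of `X`
#'   (at least two levels).
#' @param alpha Test level, default 0.05.
#' @param min_size Minimum per-group size for the invariance tests.
#' @return List of class `icpmir_subset_test`: `subset`, `p_invariance`,
#'   `accepted`, `fit` (NULL when untestable), `untestable`.
#' @export
test_subset <- function(X, Y, subset, env, alpha = 0.05, min_size = 3L) {
  env <- droplevels(as.factor(env))
  if (nlevels(env) < 2L)
    icpmir_stop("icpmir_single_environment",
                "invariance testing needs at least 2 environments")
  fit <- tryCatch(fit_pooled_regression(X, Y, subset, level = 1 - alpha),
                  icpmir_collinear = function(cnd) cnd)
  if (inherits(fit, "condition")) {
    icpmir_log("WARN", "test_subset", conditionMessage(fit))
    return(structure(list(subset = sort(unique(as.integer(subset))),
                          p_invariance = 0, accepted = FALSE,
                          fit = NULL, untestable = TRUE),
                     class = "icpmir_subset_test"))
  }
  p_env <- vapply(levels(env), function(e)
    invariance_pvalue(fit$residuals, env, e, min_size = min_size), numeric(1))
  p <- min(1, nlevels(env) * min(p_env))
  structure(list(subset = fit$subset, p_invariance = p,
                 accepted = p >= alpha, fit = fit, untestable = FALSE),
            class = "icpmir_subset_test")
}

#' Order predictors by lasso path entry
#'
#' Ranks predictors by the largest penalty at which their lasso
#' coefficient first becomes nonzero (earlier entry = stronger marginal
#' signal). Predictors that never enter the path are placed last in
#' original column order. Used to preselect candidates before exhaustive
#' subset search.
#'
#' @inheritParams fit_pooled_regression
#' @return Integer permutation of `1:ncol(X)`.
#' @export
lasso_entry_order <- function(X, Y) {
  p <- ncol(X)
  if (p == 1L) return(1L)
  fit <- glmnet::glmnet(X, Y, family = "gaussian", standardize = TRUE)
  beta <- as.matrix(fit$beta)  # p x nlambda, lambda decreasing
  entry <- apply(beta != 0, 1L, function(nz) if (any(nz)) which(nz)[1L] else Inf)
  order(entry)  # stable, so never-entered keep input order
}

#' Invariant-causal-prediction parent estimate for one target
#'
#' Enumerates predictor subsets (all subsets of the preselected candidates
#' up to `max_set_size`, always including the empty set), tests each for
#' residual invariance at level `alpha`, and intersects the accepted
#' subsets. If no subset is accepted the invariance model itself is
#' rejected and the parent set is empty; if the empty set is accepted the
#' intersection is empty (no invariant signal).
#'
#' Per-predictor confidence bounds are the envelope (union bound) of the
#' OLS coefficient confidence intervals over accepted subsets containing
#' the predictor, `[0, 0]` for predictors in no accepted subset. The
#' per-predictor score is the signed coefficient of largest magnitude
#' across accepted subsets containing it (0 if in none).
#'
#' @inheritParams test_subset
#' @param max_set_size Largest subset cardinality searched (default 3).
#'   Use `Inf` for the exhaustive search over all `2^p` subsets
#'   (practical for p <= 15).
#' @param preselect Number of candidate predictors kept by lasso path
#'   entry order before enumeration (default 10). Ignored when
#'   `p <= preselect`.
#' @return List of class `icp_result`: `target_id`, `alpha`,
#'   `accepted_sets`, `parent_set`, `coefficient_bounds` (p x 2),
#'   `scores` (length p), `pvalues` (per tested subset), `model_rejected`,
#'   `candidates`.
#' @export
icp_parents <- function(X, Y, env, alpha = 0.05, max_set_size = 3L,
                        preselect = 10L, min_size = 3L, target_id = "Y") {
  X <- as.matrix(X)
  p <- ncol(X)
  if (p < 1L) icpmir_stop("icpmir_bad_argument", "need at least one predictor")
  env <- droplevels(as.factor(env))
  candidates <- seq_len(p)
  if (is.finite(preselect) && p > preselect) {
    candidates <- sort(lasso_entry_order(X, Y)[seq_len(preselect)])
    icpmir_log("INFO", "icp_parents",
               sprintf("preselection truncated %d predictors to %d candidates", p, preselect))
  }
  kmax <- min(length(candidates), if (is.finite(max_set_size)) max_set_size else length(candidates))
  subsets <- list(integer(0))
  for (k in seq_len(kmax))
    subsets <- c(subsets, utils::combn(candidates, k, simplify = FALSE))

  tests <- lapply(subsets, function(s) test_subset(X, Y, s, env, alpha = alpha,
                                                   min_size = min_size))
  accepted <- Filter(function(t) t$accepted, tests)
  accepted_sets <- lapply(accepted, `[[`, "subset")
  model_rejected <- length(accepted_sets) == 0L
  parent_set <- if (model_rejected) integer(0) else
    sort(Reduce(intersect, accepted_sets))

  bounds <- matrix(c(Inf, -Inf), nrow = p, ncol = 2L, byrow = TRUE,
                   dimnames = list(colnames(X), c("lower", "upper")))
  scores <- stats::setNames(numeric(p), colnames(X))
  in_some <- logical(p)
  for (t in accepted) {
    s <- t$subset
    if (!length(s)) next
    for (i in seq_along(s)) {
      j <- s[i]
      in_some[j] <- TRUE
      co <- t$fit$coefficients[i]
      ci <- t$fit$ci[i, ]
      bounds[j, 1L] <- min(bounds[j, 1L], ci[1L])
      bounds[j, 2L] <- max(bounds[j, 2L], ci[2L])
      if (abs(co) > abs(scores[j])) scores[j] <- co
    }
  }
  bounds[!in_some, 1L] <- 0
  bounds[!in_some, 2L] <- 0
  structure(list(target_id = target_id, alpha = alpha,
                 accepted_sets = accepted_sets, parent_set = parent_set,
                 coefficient_bounds = bounds, scores = scores,
                 pvalues = data.frame(
                   subset = vapply(tests, function(t)
                     paste(t$subset, collapse = ","), character(1)),
                   p_invariance = vapply(tests, `[[`, numeric(1), "p_invariance"),
                   accepted = vapply(tests, `[[`, logical(1), "accepted"),
                   stringsAsFactors = FALSE),
                 model_rejected = model_rejected,
                 candidates = candidates),
            class = "icp_result")
}

#' @export
print.icp_result <- function(x, ...) {
  cat(sprintf("Invariant causal prediction for target %s (alpha = %g)\n",
              x$target_id, x$alpha))
  cat(sprintf("  subsets tested: %d, accepted: %d%s\n",
              nrow(x$pvalues), length(x$accepted_sets),
              if (x$model_rejected) " (model rejected)" else ""))
  ps <- if (length(x$parent_set)) {
    nm <- rownames(x$coefficient_bounds)
    if (!is.null(nm)) paste(nm[x$parent_set], collapse = ", ")
    else paste(x$parent_set, collapse = ", ")
  } else "(empty)"
  cat("  parent set:", ps, "\n")
  invisible(x)
}
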