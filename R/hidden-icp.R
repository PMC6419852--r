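## Hidden-confounder invariant causal prediction.
##
## Model: Y^e = X^e gamma* + g(H^e, eps^e) with unobserved H whose joint
## distribution with (X, eps) is the same in every environment while the
## regulator noise is intervened between environments. Differencing
## per-environment second moments against the pooled ones then cancels the
## (invariant) confounding term:
##   (G_e - G) gamma* = (g_e - g),  G_e = X_e'X_e/n_e,  g_e = X_e'Y_e/n_e,
## and gamma* is recovered as the least-squares solution of the system
## stacked over environments.

#' Hidden-confounder ICP coefficient estimate
#'
#' Solves the stacked moment-difference system over environments in least
#' squares and (optionally) attaches percentile bootstrap confidence
#' intervals from resampling samples within each environment.
#'
#' With exactly two environments and an invertible difference matrix the
#' stacked solution coincides with the closed form
#' `solve(G1 - G2, g1 - g2)`.
#'
#' @param X Numeric matrix, samples x predictors.
#' @param Y Numeric response vector.
#' @param env Factor of environment labels aligned to rows of `X` (>= 2
#'   levels).
#' @param B Number of bootstrap replicates for confidence intervals
#'   (default 100); `B = 0` skips the bootstrap.
#' @param level Confidence level for the intervals, default 0.95.
#' @param seed Optional integer seed for the bootstrap.
#' @param ridge Ridge fallback factor applied when the stacked system is
#'   numerically singular (scaled by the largest diagonal of the normal
#'   matrix).
#' @param target_id Label carried into the result.
#' @return List of class `hidden_icp_result`: `target_id`, `coefficients`
#'   (length p), `conf_intervals` (p x 2, NA when `B = 0`), `significant`
#'   (interval excludes 0), `degenerate` (no detectable intervention
#'   signal).
#' @export
hidden_icp_coefficients <- function(X, Y, env, B = 100L, level = 0.95,
                                    seed = NULL, ridge = 1e-8, target_id = "Y") {
  X <- as.matrix(X)
  p <- ncol(X)
  n <- nrow(X)
  if (length(Y) != n)
    icpmir_stop("icpmir_bad_argument", "nrow(X) (%d) != length(Y) (%d)", n, length(Y))
  env <- droplevels(as.factor(env))
  if (nlevels(env) < 2L)
    icpmir_stop("icpmir_single_environment", "hidden ICP needs at least 2 environments")

  solve_stacked <- function(idx_list) {
    rows_all <- unlist(idx_list, use.names = FALSE)
    Xp <- X[rows_all, , drop = FALSE]
    Yp <- Y[rows_all]
    G <- crossprod(Xp) / length(rows_all)
    g <- crossprod(Xp, Yp) / length(rows_all)
    M <- matrix(0, nrow = 0L, ncol = p)
    v <- numeric(0)
    for (idx in idx_list) {
      Xe <- X[idx, , drop = FALSE]
      Ge <- crossprod(Xe) / length(idx)
      ge <- crossprod(Xe, Y[idx]) / length(idx)
      M <- rbind(M, Ge - G)
      v <- c(v, ge - g)
    }
    list(M = M, v = v)
  }

  ls_solve <- function(M, v) {
    qr_m <- qr(M)
    if (qr_m$rank < p) {
      A <- crossprod(M)
      lam <- ridge * max(diag(A), 1)
      icpmir_log("WARN", "hidden_icp",
                 "stacked moment-difference system is singular; ridge-stabilised solve")
      return(as.numeric(solve(A + lam * diag(p), crossprod(M, v))))
    }
    as.numeric(qr.coef(qr_m, v))
  }

  idx_by_env <- split(seq_len(n), env)
  sys0 <- solve_stacked(idx_by_env)
  # no intervention signal when the moment differences are within the
  # O(1/sqrt(n_e)) sampling noise of the pooled second moments
  n_min <- min(lengths(idx_by_env))
  G_max <- max(abs(crossprod(X) / n), .Machine$double.eps)
  degenerate <- max(abs(sys0$M)) < 4 / sqrt(n_min) * G_max
  if (degenerate)
    warning("environments look identically distributed: moment differences ~ 0, ",
            "hidden-ICP coefficients are not identified", call. = FALSE)
  gamma <- ls_solve(sys0$M, sys0$v)

  ci <- matrix(NA_real_, nrow = p, ncol = 2L,
               dimnames = list(colnames(X), c("lower", "upper")))
  significant <- rep(NA, p)
  if (B > 0L) {
    boots <- with_seed(seed, {
      vapply(seq_len(B), function(b) {
        idx_b <- lapply(idx_by_env, function(idx)
          idx[sample.int(length(idx), replace = TRUE)])
        sys_b <- solve_stacked(idx_b)
        ls_solve(sys_b$M, sys_b$v)
      }, numeric(p))
    })
    boots <- matrix(boots, nrow = p)
    a <- (1 - level) / 2
    ci[, 1L] <- apply(boots, 1L, stats::quantile, probs = a, names = FALSE)
    ci[, 2L] <- apply(boots, 1L, stats::quantile, probs = 1 - a, names = FALSE)
    significant <- ci[, 1L] > 0 | ci[, 2L] < 0
  }
  structure(list(target_id = target_id,
                 coefficients = stats::setNames(gamma, colnames(X)),
                 conf_intervals = ci,
                 significant = significant,
                 degenerate = degenerate),
            class = "hidden_icp_result")
}

#' @export
print.hidden_icp_result <- function(x, ...) {
  cat(sprintf("Hidden-ICP coefficients for target %s%s\n", x$target_id,
              if (isTRUE(x$degenerate)) " [degenerate: no intervention signal]" else ""))
  df <- data.frame(coefficient = x$coefficients,
                   lower = x$conf_intervals[, 1L],
                   upper = x$conf_intervals[, 2L],
                   significant = x$significant)
  print(df, ...)
  invisible(x)
}

#' Score all regulator-target pairs with an ICP method
#'
#' Runs [icp_parents()] or [hidden_icp_coefficients()] independently for
#' every target row and assembles a dense regulators x targets score
#' matrix (class `interaction_scores`, `method` attribute attached). A
#' failure on one target yields a zero column and a logged warning rather
#' than aborting the run.
#'
#' @param regulators Expression matrix of regulators (e.g. miRNAs),
#'   features x samples.
#' @param targets Expression matrix of targets (e.g. mRNAs), features x
#'   samples; columns must match `regulators`.
#' @param env Environment assignment (named factor) covering the shared
#'   samples.
#' @param method `"hidden_icp"` (default; coefficients of the
#'   moment-difference estimator) or `"icp"` (plain ICP scores: signed
#'   coefficient over accepted sets, 0 outside).
#' @param ... Passed to the per-target estimator. For `"hidden_icp"` the
#'   bootstrap is skipped (`B = 0`) unless requested, since only point
#'   scores feed the ranking.
#' @return Numeric matrix regulators x targets with class
#'   `interaction_scores` and attribute `method`.
#' @export
score_all_pairs <- function(regulators, targets, env,
                            method = c("hidden_icp", "icp"), ...) {
  method <- match.arg(method)
  validate_expression_matrix(regulators, "regulator matrix")
  validate_expression_matrix(targets, "target matrix")
  if (!identical(colnames(regulators), colnames(targets)))
    icpmir_stop("icpmir_unknown_sample",
                "regulator and target matrices must share identical sample columns (use match_samples())")
  env <- align_environments(env, regulators)
  X <- t(regulators)
  p <- nrow(regulators)
  extra <- list(...)
  scores <- matrix(0, nrow = p, ncol = nrow(targets),
                   dimnames = list(rownames(regulators), rownames(targets)))
  for (j in seq_len(nrow(targets))) {
    tid <- rownames(targets)[j]
    col <- tryCatch({
      if (method == "hidden_icp") {
        args <- c(list(X = X, Y = targets[j, ], env = env, target_id = tid), extra)
        if (is.null(args$B)) args$B <- 0L
        suppressWarnings(do.call(hidden_icp_coefficients, args)$coefficients)
      } else {
        do.call(icp_parents,
                c(list(X = X, Y = targets[j, ], env = env, target_id = tid), extra))$scores
      }
    }, error = function(cnd) {
      icpmir_log("WARN", "score_all_pairs",
                 sprintf("target %s failed (%s); zero column", tid, conditionMessage(cnd)))
      rep(0, p)
    })
    scores[, j] <- col
  }
  structure(scores, method = if (method == "hidden_icp") "hiddenICP" else "ICP",
            class = c("interaction_scores", "matrix", "array"))
}
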