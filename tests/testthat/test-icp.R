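# Invariant causal prediction core: pooled fit, invariance tests,
# subset search and the intersection parent estimator.

test_that("pooled regression matches exact and normal-equation solutions", {
  x1 <- c(1, 2, 3, 4, 5)
  X <- cbind(x1)
  fit <- fit_pooled_regression(X, 2 * x1, 1L)
  expect_equal(fit$coefficients, 2, tolerance = 1e-12)
  expect_equal(fit$residuals, rep(0, 5), tolerance = 1e-12)

  fit0 <- fit_pooled_regression(matrix(0, 3, 1), c(1, 2, 3), integer(0))
  expect_equal(fit0$residuals, c(-1, 0, 1), tolerance = 1e-12)
  expect_equal(fit0$intercept, 2, tolerance = 1e-12)

  set.seed(31)
  Xr <- matrix(rnorm(150), 50, 3)
  Yr <- rnorm(50)
  fitr <- fit_pooled_regression(Xr, Yr, 1:3)
  M <- cbind(1, Xr)
  beta <- solve(crossprod(M), crossprod(M, Yr))  # normal equations
  expect_equal(c(fitr$intercept, fitr$coefficients), as.numeric(beta), tolerance = 1e-8)

  # collinear subset is flagged untestable
  Xc <- cbind(Xr[, 1], 2 * Xr[, 1])
  expect_error(fit_pooled_regression(Xc, Yr, 1:2), class = "icpmir_collinear")
})

test_that("invariance_pvalue agrees with t.test/var.test and handles extremes", {
  env <- factor(rep(c("e1", "e2"), each = 4))

  # identical residual values in both groups: perfect invariance
  r <- c(0.3, -0.1, 0.2, 0.05, 0.3, -0.1, 0.2, 0.05)
  expect_equal(invariance_pvalue(r, env, "e1"), 1)

  # fixed toy vectors against the textbook Welch t / F combination
  r2 <- c(0.1, -0.2, 0.05, 0.0, 1.1, 0.9, 1.2, 0.8)
  expected <- local({
    p_t <- t.test(r2[1:4], r2[5:8], var.equal = FALSE)$p.value
    p_f <- var.test(r2[1:4], r2[5:8])$p.value
    min(1, 2 * min(p_t, p_f))
  })
  expect_equal(invariance_pvalue(r2, env, "e1"), expected, tolerance = 1e-12)

  set.seed(7)
  for (i in 1:20) {
    rr <- rnorm(40)
    ee <- factor(sample(rep(c("a", "b"), each = 20)))
    want <- min(1, 2 * min(t.test(rr[ee == "a"], rr[ee == "b"])$p.value,
                           var.test(rr[ee == "a"], rr[ee == "b"])$p.value))
    expect_equal(invariance_pvalue(rr, ee, "a"), want, tolerance = 1e-10)
  }

  # large mean shift drives p to 0
  big <- c(rnorm(200), rnorm(200) + 50)
  envb <- factor(rep(c("e1", "e2"), each = 200))
  expect_lt(invariance_pvalue(big, envb, "e1"), 1e-10)

  expect_error(invariance_pvalue(rnorm(5), factor(c("a", "a", "b", "b", "b")), "a"),
               class = "icpmir_small_environment")
})

test_that("test_subset applies the Bonferroni combination and rejects shifts", {
  set.seed(12)
  env <- factor(rep(c("e1", "e2", "e3"), each = 30))
  X <- matrix(rnorm(90 * 2), 90, 2)

  expect_error(test_subset(X, rnorm(90), integer(0), factor(rep("only", 90))),
               class = "icpmir_single_environment")

  # strong mean shift between environments, empty subset: rejected
  Y <- rnorm(90) + 10 * (env == "e3")
  res <- test_subset(X, Y, integer(0), env, alpha = 0.05)
  expect_false(res$accepted)
  expect_lt(res$p_invariance, 1e-6)

  # invariant response with its true predictor: accepted
  Y2 <- 1.5 * X[, 1] + rnorm(90)
  res2 <- test_subset(X, Y2, 1L, env, alpha = 0.05)
  expect_equal(res2$p_invariance,
               min(1, 3 * min(vapply(levels(env), function(e)
                 invariance_pvalue(res2$fit$residuals, env, e), numeric(1)))),
               tolerance = 1e-12)

  # collinear subsets are reported rejected, not accepted
  Xc <- cbind(X[, 1], X[, 1])
  resc <- suppressMessages(test_subset(Xc, Y2, 1:2, env))
  expect_false(resc$accepted)
  expect_true(resc$untestable)
})

test_that("true-parent subsets are accepted at roughly the nominal rate", {
  # Y = X gamma + invariant noise; testing the true set should be accepted
  # with probability about 1 - alpha
  reps <- 300
  acc <- logical(reps)
  set.seed(99)
  for (i in 1:reps) {
    env <- factor(rep(c("a", "b"), each = 40))
    X <- matrix(rnorm(80 * 2), 80, 2)
    X[env == "b", 2] <- X[env == "b", 2] * 2   # intervention on non-parent
    Y <- X[, 1] + rnorm(80)
    acc[i] <- test_subset(X, Y, 1L, env, alpha = 0.05)$accepted
  }
  expect_gte(mean(acc), 0.92)   # 1 - alpha, Bonferroni-conservative; MC slack
})

test_that("icp_parents equals the brute-force enumeration oracle", {
  set.seed(17)
  for (i in 1:12) {
    p <- sample(2:4, 1)
    n <- 60
    env <- factor(rep(c("a", "b"), each = n / 2))
    X <- matrix(rnorm(n * p), n, p)
    iv <- sample(p, 1)
    X[env == "b", iv] <- X[env == "b", iv] * 1.8
    Y <- as.numeric(X %*% rbinom(p, 1, 0.5)) + rnorm(n)
    got <- icp_parents(X, Y, env, alpha = 0.05, max_set_size = Inf, preselect = Inf)
    want <- oracle_icp(X, Y, env, alpha = 0.05)
    expect_identical(got$parent_set, want$parent_set)
    expect_identical(got$accepted_sets, want$accepted_sets)
  }
})

test_that("icp_parents recovers planted parents and handles pure noise", {
  set.seed(21)
  hits <- 0L
  for (i in 1:20) {
    st <- simulate_sem(p = 3, t = 1, parents_per_target = 1,
                       env_sizes = c(a = 300, b = 300, c = 300), hidden_dim = 0,
                       intervened = "all", seed = 1000 + i)
    r <- icp_parents(t(st$regulators), st$targets[1, ], st$env,
                     alpha = 0.05, max_set_size = Inf, preselect = Inf)
    truth <- match(st$true_parents[[1]], rownames(st$regulators))
    if (identical(r$parent_set, truth)) hits <- hits + 1L
  }
  expect_gte(hits, 16L)  # planted single parent found in >= 80% of runs

  # response independent of all predictors: empty set accepted, so the
  # intersection is empty without rejecting the model
  set.seed(5)
  env <- factor(rep(c("a", "b"), each = 50))
  X <- matrix(rnorm(200), 100, 2)
  X[env == "b", ] <- X[env == "b", ] * 2
  r0 <- icp_parents(X, rnorm(100), env, max_set_size = Inf, preselect = Inf)
  expect_false(r0$model_rejected)
  expect_identical(r0$parent_set, integer(0))
  expect_true(any(vapply(r0$accepted_sets, length, integer(1)) == 0L))
})

test_that("parent sets and bounds respect the contract as alpha varies", {
  set.seed(33)
  env <- factor(rep(c("a", "b", "c"), each = 60))
  X <- matrix(rnorm(180 * 3), 180, 3)
  X[env != "a", 2:3] <- X[env != "a", 2:3] * 2
  Y <- X[, 1] - rnorm(180)
  alphas <- c(0.2, 0.1, 0.05, 0.01)
  n_accepted <- integer(length(alphas))
  for (i in seq_along(alphas)) {
    r <- icp_parents(X, Y, env, alpha = alphas[i], max_set_size = Inf, preselect = Inf)
    n_accepted[i] <- length(r$accepted_sets)
    # predictors in no accepted set score 0 with a [0,0] bound
    outside <- setdiff(1:3, unique(unlist(r$accepted_sets)))
    expect_true(all(r$scores[outside] == 0))
    expect_true(all(r$coefficient_bounds[outside, ] == 0))
    if (length(r$accepted_sets))
      expect_true(all(r$parent_set %in% Reduce(intersect, r$accepted_sets)))
  }
  # smaller alpha never shrinks the accepted-set collection
  expect_true(all(diff(n_accepted) >= 0))
})

test_that("lasso preselection truncates the search space deterministically", {
  set.seed(44)
  env <- factor(rep(c("a", "b"), each = 100))
  X <- matrix(rnorm(200 * 12), 200, 12)
  X[env == "b", ] <- X[env == "b", ] * 1.5
  Y <- 2 * X[, 4] + rnorm(200)
  ord <- lasso_entry_order(X, Y)
  expect_identical(sort(ord), 1:12)
  expect_identical(ord[1], 4L)  # the strong predictor enters the path first
  r <- suppressMessages(icp_parents(X, Y, env, preselect = 5, max_set_size = 2))
  expect_lte(length(r$candidates), 5L)
  expect_true(4L %in% r$candidates)
})
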