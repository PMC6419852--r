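# Synthetic multi-environment SEM generator and validation fixtures.

test_that("regeneration from the same seed is bit-identical", {
  a <- simulate_sem(p = 5, t = 8, env_sizes = c(x = 20, y = 20), seed = 42)
  b <- simulate_sem(p = 5, t = 8, env_sizes = c(x = 20, y = 20), seed = 42)
  expect_identical(a, b)
  c2 <- simulate_sem(p = 5, t = 8, env_sizes = c(x = 20, y = 20), seed = 43)
  expect_false(identical(a$regulators, c2$regulators))
})

test_that("study dimensions, labels and ground truth are consistent", {
  st <- simulate_sem(p = 6, t = 10, parents_per_target = 2,
                     env_sizes = c(e1 = 30, e2 = 25, e3 = 20), seed = 3)
  expect_identical(dim(st$regulators), c(6L, 75L))
  expect_identical(dim(st$targets), c(10L, 75L))
  expect_identical(colnames(st$regulators), colnames(st$targets))
  expect_identical(names(st$env), colnames(st$regulators))
  expect_identical(unname(as.integer(table(st$env))), c(30L, 25L, 20L))
  tp <- true_pairs(st)
  expect_identical(nrow(tp), 20L)
  expect_true(all(tp$regulator %in% rownames(st$regulators)))
  expect_true(all(lengths(st$gamma) == lengths(st$true_parents)))
  expect_true(all(abs(unlist(st$gamma)) == 1))
})

test_that("gamma_scale 0 and unit intervention give unidentifiable nulls", {
  st0 <- simulate_sem(p = 4, t = 5, gamma_scale = 0,
                      env_sizes = c(a = 20, b = 20), seed = 9)
  expect_true(all(lengths(st0$true_parents) == 0L))
  expect_identical(nrow(true_pairs(st0)), 0L)

  # no intervention, no hidden term: environments identically distributed,
  # so the empty set is accepted in about 1 - alpha of replicates
  acc <- vapply(1:60, function(i) {
    st <- simulate_sem(p = 2, t = 1, parents_per_target = 1,
                       env_sizes = c(a = 40, b = 40), intervention_scale = 1,
                       hidden_dim = 0, seed = 2000 + i)
    test_subset(t(st$regulators), st$targets[1, ], integer(0), st$env,
                alpha = 0.05)$accepted
  }, logical(1))
  expect_gte(mean(acc), 0.85)
})

test_that("interventions shift regulator variance exactly where placed", {
  st <- simulate_sem(p = 8, t = 2, env_sizes = c(ref = 800, shift = 800),
                     intervention_scale = 2, hidden_dim = 0,
                     intervened = c(2L, 5L), seed = 31)
  v_ref <- apply(st$regulators[, st$env == "ref"], 1, var)
  v_shift <- apply(st$regulators[, st$env == "shift"], 1, var)
  ratio <- v_shift / v_ref
  expect_true(all(ratio[c(2, 5)] > 2.5))   # variance x4 at scale 2
  expect_true(all(ratio[-c(2, 5)] < 1.5))
  expect_identical(st$intervened, c("miR-2", "miR-5"))
})

test_that("true-parent residuals stay invariant; invariance p-values are honest", {
  # the p-value of the true parent set must never be anti-conservative:
  # P(p <= a) <= a across replicates, and the underlying Welch t p-value
  # on the raw errors is uniform
  reps <- 400
  pvals <- numeric(reps)
  t_pvals <- numeric(reps)
  set.seed(88)
  for (i in 1:reps) {
    st <- simulate_sem(p = 2, t = 1, parents_per_target = 1,
                       env_sizes = c(a = 50, b = 50), hidden_dim = 0,
                       intervened = "all", seed = 5000 + i)
    X <- t(st$regulators)
    ts <- test_subset(X, st$targets[1, ],
                      match(st$true_parents[[1]], rownames(st$regulators)),
                      st$env, alpha = 0.05)
    pvals[i] <- ts$p_invariance
    t_pvals[i] <- t.test(ts$fit$residuals[st$env == "a"],
                         ts$fit$residuals[st$env == "b"])$p.value
  }
  for (a in c(0.01, 0.05, 0.1, 0.25))
    expect_lte(mean(pvals <= a), a + 3 * sqrt(a * (1 - a) / reps))
  expect_gt(ks.test(t_pvals, "punif")$p.value, 0.01)
})

test_that("validation fixtures encode the ground truth at the stated rates", {
  st <- simulate_sem(p = 6, t = 30, parents_per_target = 2,
                     env_sizes = c(a = 30, b = 30), seed = 12)
  fx0 <- make_validation_fixtures(st, noise_rate = 0)
  truth <- true_pairs(st)
  expect_identical(nrow(fx0$db), nrow(truth))
  expect_identical(confirm_by_database(truth, fx0$db)$n_confirmed, nrow(truth))

  fx1 <- make_validation_fixtures(st, noise_rate = 1)
  expect_identical(nrow(fx1$db), 2L * nrow(truth))

  # transfection table covers the full grid; true pairs almost always pass
  # the 0.3 threshold, null pairs almost always miss it
  fx <- make_validation_fixtures(st, noise_rate = 0.5)
  expect_identical(nrow(fx$transfection), 6L * 30L)
  res_true <- confirm_by_transfection(truth, fx$transfection, 0.3)
  expect_gte(res_true$n_confirmed / nrow(truth), 0.95)  # P(|N(1,.2)| > .3) ~ 0.9998
  null_pairs <- fx$transfection[!(pair_key(fx$transfection$miRNA, fx$transfection$mRNA)
                                  %in% pair_key(truth$regulator, truth$target)), ]
  res_null <- confirm_by_transfection(data.frame(regulator = null_pairs$miRNA,
                                                 target = null_pairs$mRNA),
                                      fx$transfection, 0.3)
  expect_lte(res_null$n_confirmed / nrow(null_pairs), 0.1)  # 2 * P(N(0,.15) > .3) ~ 0.046
})

test_that("study files round-trip through the pipeline input formats", {
  st <- simulate_sem(p = 4, t = 6, env_sizes = c(a = 10, b = 10, c = 10), seed = 77)
  dir <- withr::local_tempdir()
  paths <- write_study_files(st, dir)
  expect_true(all(file.exists(unlist(paths))))
  expect_equal(read_expression_matrix(paths$regulators), st$regulators,
               tolerance = 1e-12)
  env <- read_environment_labels(paths$environments)
  expect_identical(as.character(env[names(st$env)]), as.character(st$env))
  manifest <- jsonlite::read_json(paths$manifest, simplifyVector = TRUE)
  expect_identical(manifest$seed, 77L)
  db <- read_ground_truth(paths$db)
  expect_identical(confirm_by_database(true_pairs(st), db)$n_confirmed,
                   nrow(true_pairs(st)))
})
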