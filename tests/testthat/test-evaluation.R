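# Validation protocol: top-k selection, confirmation, null experiment,
# method overlap.

ranking5 <- local({
  sc <- matrix(c(5, 4, 3, 2, 1, 0.5), nrow = 2,
               dimnames = list(c("mA", "mB"), c("t1", "t2", "t3")))
  rank_interactions(structure(sc, method = "hand"))
})

test_that("top_k selections follow the ranking exactly", {
  expect_identical(nrow(top_k_overall(ranking5, 6)), 6L)
  expect_identical(top_k_overall(ranking5, 1)$regulator, "mA")
  top3 <- top_k_overall(ranking5, 3)
  expect_identical(paste(top3$regulator, top3$target),
                   c("mA t1", "mB t1", "mA t2"))
  expect_error(top_k_overall(ranking5, 7), "exceeds")

  per <- top_k_per_regulator(ranking5, 2)
  expect_identical(names(per), c("mA", "mB"))
  expect_identical(per$mA$target, c("t1", "t2"))
  expect_identical(per$mB$target, c("t1", "t2"))
  # k beyond a regulator's pairs returns everything it has
  per_big <- suppressMessages(top_k_per_regulator(ranking5, 10))
  expect_identical(unname(vapply(per_big, nrow, integer(1))), c(3L, 3L))
  all_pairs <- do.call(rbind, per_big)
  expect_identical(nrow(all_pairs), nrow(ranking5))
})

test_that("transfection confirmation uses |log2fc| strictly above threshold", {
  tab <- data.frame(miRNA = c("mA", "mA", "mB", "mB", "mB", "mC"),
                    mRNA = c("t1", "t2", "t1", "t2", "t3", "t1"),
                    log2fc = c(-0.5, 0.3, 1.2, -0.31, 0.29, 2))
  pairs <- data.frame(regulator = tab$miRNA, target = tab$mRNA)
  res <- confirm_by_transfection(pairs, tab, threshold = 0.3)
  # -0.5, 1.2, -0.31, 2 exceed; 0.3 exactly and 0.29 do not
  expect_identical(res$n_confirmed, 4L)
  expect_identical(res$n_uncheckable, 0L)

  # pairs missing from the table are uncheckable, not unconfirmed
  extra <- rbind(pairs, data.frame(regulator = "mZ", target = "t9"))
  res2 <- confirm_by_transfection(extra, tab, threshold = 0.3)
  expect_identical(res2$n_confirmed, 4L)
  expect_identical(res2$n_uncheckable, 1L)

  # case-insensitive identifier matching
  up <- data.frame(regulator = "MA", target = "T1")
  expect_identical(confirm_by_transfection(up, tab)$n_confirmed, 1L)

  # repeated calls agree and do not mutate inputs
  snapshot <- tab
  invisible(confirm_by_transfection(pairs, tab))
  expect_identical(tab, snapshot)
})

test_that("database confirmation counts membership", {
  db <- data.frame(miRNA = c("mA", "mA", "mB"), mRNA = c("t1", "t2", "t3"))
  pairs <- data.frame(regulator = c("mA", "mA", "mB", "mB"),
                      target = c("t1", "t3", "t3", "t9"))
  expect_identical(confirm_by_database(pairs, db)$n_confirmed, 2L)
  expect_identical(confirm_by_database(pairs, db[0, ])$n_confirmed, 0L)
  expect_identical(confirm_by_database(db, db)$n_confirmed, 3L)
})

test_that("confirmed counts are monotone in k for nested top lists", {
  set.seed(41)
  sc <- matrix(rnorm(60), nrow = 6,
               dimnames = list(sprintf("m%d", 1:6), sprintf("t%d", 1:10)))
  rk <- rank_interactions(structure(sc, method = "x"))
  db <- data.frame(miRNA = sample(sprintf("m%d", 1:6), 20, replace = TRUE),
                   mRNA = sample(sprintf("t%d", 1:10), 20, replace = TRUE))
  counts <- vapply(c(10, 20, 40, 60), function(k)
    confirm_by_database(top_k_overall(rk, k), db)$n_confirmed, integer(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("null experiment matches degenerate validators and the analytic mean", {
  universe <- expand.grid(regulator = sprintf("m%d", 1:10),
                          target = sprintf("t%d", 1:40),
                          stringsAsFactors = FALSE)
  always <- function(p) list(n_confirmed = nrow(p))
  never <- function(p) list(n_confirmed = 0L)
  expect_equal(null_experiment(universe, n_regulators = 5, k = 10, reps = 3,
                               validator = always, seed = 1)$mean_confirmed, 50)
  expect_equal(null_experiment(universe, n_regulators = 5, k = 10, reps = 3,
                               validator = never, seed = 1)$mean_confirmed, 0)

  # db holding 10% of each regulator's targets: expectation 5 x 10 x 0.1 = 5
  db <- subset(universe, target %in% sprintf("t%d", 1:4))
  names(db) <- c("miRNA", "mRNA")
  ne <- null_experiment(universe, n_regulators = 5, k = 10, reps = 500,
                        validator = function(p) confirm_by_database(p, db),
                        seed = 7)
  se <- sqrt(50 * 0.1 * 0.9 / 500)  # binomial s.e. of the mean
  expect_lt(abs(ne$mean_confirmed - 5), 3 * se)

  expect_identical(
    null_experiment(universe, 5, k = 10, reps = 5, validator = always, seed = 3),
    null_experiment(universe, 5, k = 10, reps = 5, validator = always, seed = 3))
  expect_error(null_experiment(universe[1:20, ], n_regulators = 15, k = 2,
                               reps = 2, validator = always, seed = 1))
})

test_that("method overlap counts every intersection class", {
  a <- data.frame(regulator = c("m1", "m2"), target = c("t1", "t2"))
  b <- data.frame(regulator = c("m1", "m3"), target = c("t1", "t3"))
  c3 <- data.frame(regulator = "m9", target = "t9")

  same <- method_overlap(list(x = a, y = a))
  expect_identical(same$classes$methods, "x&y")
  expect_identical(same$classes$count, 2L)

  disj <- method_overlap(list(x = a, y = c3))
  expect_setequal(disj$classes$methods, c("x", "y"))

  three <- method_overlap(list(x = a, y = b, z = c3))
  got <- setNames(three$classes$count, three$classes$methods)
  expect_identical(got[["x&y"]], 1L)  # m1/t1 shared
  expect_identical(got[["x"]], 1L)    # m2/t2 only in x
  expect_identical(got[["y"]], 1L)    # m3/t3 only in y
  expect_identical(got[["z"]], 1L)
  expect_identical(unname(three$per_method), c(2L, 2L, 1L))
})
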