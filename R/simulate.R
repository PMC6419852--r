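## Multi-environment linear-SEM study generator with known ground truth.
##
## Regulators receive environment-specific noise interventions (their
## error scale changes between environments); each target is a linear
## function of its true parent regulators plus an optional hidden
## confounder contribution and an i.i.d. error whose distribution is the
## same in every environment. This is exactly the data-generating regime
## under which invariant causal prediction identifies the parents, so the
## generator provides ground truth for every pipeline stage.

#' Default environment sizes
#'
#' Five environments proportioned like the breast-cancer intrinsic
#' subtypes (Basal/Her2/LumA/LumB/Normal-like, 107/75/147/116/58 of 503)
#' scaled to 500 samples.
#' @return Named integer vector summing to 500.
#' @export
default_env_sizes <- function() {
  c(Basal = 106L, Her2 = 75L, LumA = 146L, LumB = 115L, Normal = 58L)
}

#' Simulate a multi-environment linear-SEM study
#'
#' Generates regulator and target expression matrices over labeled
#' environments. In the reference (first) environment every regulator j
#' has error scale `noise_sd`; in the other environments the intervened
#' regulators' error scale is multiplied by `intervention_scale` (a noise
#' intervention). With `hidden_dim = q > 0`, q standard-normal hidden
#' confounders load on all regulators and targets with fixed coefficients,
#' identically in every environment. Each target is
#' `mu + sum(gamma * parents) + hidden term + eps`, with eps i.i.d. from
#' an environment-invariant distribution. Fully deterministic given
#' `seed`.
#'
#' Defaults mirror the pipeline's study shape at one tenth of the target
#' dimension: 30 regulators, 150 targets, 5 subtype-proportioned
#' environments totalling 500 samples.
#'
#' @param p Number of regulators (miRNAs), default 30.
#' @param t Number of targets (mRNAs), default 150.
#' @param parents_per_target True parents per target, default 2.
#' @param env_sizes Integer vector (>= 2 entries, each >= 3) of samples
#'   per environment; names become environment labels.
#' @param gamma_scale Magnitude of every true causal coefficient (signs
#'   random), default 1. `0` makes all targets parentless.
#' @param intervention_scale Multiplier on intervened regulators' error
#'   scale in non-reference environments, default 2. `1` means no
#'   intervention (environments identically distributed when
#'   `hidden_dim = 0`).
#' @param hidden_dim Number of hidden confounders q, default 2.
#' @param noise_sd Regulator error scale in the reference environment,
#'   default 1.
#' @param target_noise_sd Scale of the targets' invariant error, default 1.
#' @param intervened Which regulators are intervened: `"random_half"`
#'   (default), `"all"`, `"none"`, `"non_parents"`, or an integer vector
#'   of regulator indices.
#' @param parents Optional list (length `t`) of integer vectors fixing
#'   each target's parent regulators; `NULL` draws them uniformly.
#' @param error_dist Targets' error family: `"gaussian"` (default) or
#'   `"t"` (t with 5 df, scaled to `target_noise_sd`).
#' @param seed Integer seed.
#' @return List of class `synthetic_study`: `regulators`, `targets`
#'   (expression matrices), `env` (named factor), `true_parents` (named
#'   list target id -> regulator ids), `gamma` (named list of
#'   coefficients aligned to `true_parents`), `intervened` (regulator
#'   ids), `hidden_dim`, `params`, `seed`.
#' @export
simulate_sem <- function(p = 30L, t = 150L, parents_per_target = 2L,
                         env_sizes = default_env_sizes(),
                         gamma_scale = 1, intervention_scale = 2,
                         hidden_dim = 2L, noise_sd = 1, target_noise_sd = 1,
                         intervened = "random_half", parents = NULL,
                         error_dist = c("gaussian", "t"), seed = 1L) {
  error_dist <- match.arg(error_dist)
  p <- check_count(p, "p"); t <- check_count(t, "t")
  parents_per_target <- check_count(parents_per_target, "parents_per_target", min = 0L)
  hidden_dim <- check_count(hidden_dim, "hidden_dim", min = 0L)
  if (length(env_sizes) < 2L || any(env_sizes < 3L))
    icpmir_stop("icpmir_bad_argument",
                "need >= 2 environments with >= 3 samples each")
  if (parents_per_target > p)
    icpmir_stop("icpmir_bad_argument", "parents_per_target %d > p %d",
                parents_per_target, p)
  if (gamma_scale < 0 || intervention_scale <= 0 || noise_sd <= 0 || target_noise_sd <= 0)
    icpmir_stop("icpmir_bad_argument", "scales must be positive (gamma_scale >= 0)")
  n <- sum(env_sizes)
  E <- length(env_sizes)
  env_labels <- names(env_sizes) %||% sprintf("env%d", seq_len(E))
  reg_ids <- sprintf("miR-%d", seq_len(p))
  tar_ids <- sprintf("mRNA-%d", seq_len(t))
  sample_ids <- sprintf("S%04d", seq_len(n))
  env <- factor(rep(env_labels, times = env_sizes), levels = env_labels)
  names(env) <- sample_ids

  study <- with_seed(seed, {
    # -- structure draws (fixed order for reproducibility) --
    if (is.null(parents)) {
      pa <- lapply(seq_len(t), function(i)
        if (parents_per_target == 0L || gamma_scale == 0) integer(0)
        else sort(sample.int(p, parents_per_target)))
    } else {
      if (length(parents) != t)
        icpmir_stop("icpmir_bad_argument", "parents list must have length t = %d", t)
      pa <- lapply(parents, function(s) {
        s <- sort(unique(as.integer(s)))
        if (length(s) && (min(s) < 1L || max(s) > p))
          icpmir_stop("icpmir_bad_argument", "parent index out of range 1..%d", p)
        if (gamma_scale == 0) integer(0) else s
      })
    }
    gam <- lapply(pa, function(s) gamma_scale * sample(c(-1, 1), length(s), replace = TRUE))
    all_parents <- sort(unique(unlist(pa)))
    iv <- if (is.numeric(intervened)) {
      sort(unique(as.integer(intervened)))
    } else switch(as.character(intervened),
      random_half = sort(sample.int(p, ceiling(p / 2))),
      all = seq_len(p),
      none = integer(0),
      non_parents = setdiff(seq_len(p), all_parents),
      icpmir_stop("icpmir_bad_argument", "unknown `intervened` keyword: %s", intervened))
    if (length(iv) && (min(iv) < 1L || max(iv) > p))
      icpmir_stop("icpmir_bad_argument", "intervened index out of range 1..%d", p)
    A <- if (hidden_dim > 0L)
      matrix(stats::rnorm(hidden_dim * p, sd = 0.5), hidden_dim, p) else NULL
    b <- if (hidden_dim > 0L)
      matrix(stats::rnorm(hidden_dim * t, sd = 0.5), hidden_dim, t) else NULL
    mu <- stats::rnorm(t)

    # -- sample draws --
    H <- if (hidden_dim > 0L) matrix(stats::rnorm(n * hidden_dim), n, hidden_dim) else NULL
    sd_mat <- matrix(noise_sd, n, p)
    if (length(iv))
      sd_mat[env != env_labels[1L], iv] <- noise_sd * intervention_scale
    X <- matrix(stats::rnorm(n * p), n, p) * sd_mat
    if (hidden_dim > 0L) X <- X + H %*% A
    eps <- if (error_dist == "gaussian")
      matrix(stats::rnorm(n * t, sd = target_noise_sd), n, t)
    else matrix(stats::rt(n * t, df = 5) * sqrt(3 / 5) * target_noise_sd, n, t)
    Y <- matrix(rep(mu, each = n), n, t) + eps
    if (hidden_dim > 0L) Y <- Y + H %*% b
    for (i in seq_len(t))
      if (length(pa[[i]]))
        Y[, i] <- Y[, i] + X[, pa[[i]], drop = FALSE] %*% gam[[i]]

    regulators <- base::t(X)  # `t` is the target count here
    dimnames(regulators) <- list(reg_ids, sample_ids)
    targets <- base::t(Y)
    dimnames(targets) <- list(tar_ids, sample_ids)
    list(regulators = regulators, targets = targets, env = env,
         true_parents = stats::setNames(lapply(pa, function(s) reg_ids[s]), tar_ids),
         gamma = stats::setNames(gam, tar_ids),
         intervened = reg_ids[iv], hidden_dim = hidden_dim,
         params = list(p = p, t = t, parents_per_target = parents_per_target,
                       env_sizes = as.list(env_sizes),
                       gamma_scale = gamma_scale,
                       intervention_scale = intervention_scale,
                       noise_sd = noise_sd, target_noise_sd = target_noise_sd,
                       error_dist = error_dist),
         seed = seed)
  })
  structure(study, class = "synthetic_study")
}

#' True regulator-target pairs of a synthetic study
#'
#' @param study `synthetic_study`.
#' @return data.frame with columns `regulator`, `target`.
#' @export
true_pairs <- function(study) {
  if (!inherits(study, "synthetic_study"))
    icpmir_stop("icpmir_bad_argument", "expected a synthetic_study")
  reg <- unlist(study$true_parents, use.names = FALSE)
  tar <- rep(names(study$true_parents), lengths(study$true_parents))
  data.frame(regulator = as.character(reg), target = tar, stringsAsFactors = FALSE)
}

#' Toy validation fixtures for a synthetic study
#'
#' Builds a confirmed-interaction list and a transfection fold-change
#' table consistent with the study's ground truth. The database holds the
#' true pairs plus `noise_rate * |true pairs|` random false pairs
#' (collisions with true pairs or earlier draws are redrawn). The
#' transfection table covers every regulator-target pair: true pairs get
#' `sign * |N(1, 0.2)|` log2 fold-changes (almost always beyond the 0.3
#' confirmation threshold) and null pairs `N(0, 0.15)` (mostly below it).
#'
#' @param study `synthetic_study`.
#' @param noise_rate False-pair fraction added to the database, in
#'   \[0, 1\], default 0.5.
#' @param seed Integer seed, default `study$seed + 1000`.
#' @return List: `transfection` (data.frame `miRNA,mRNA,log2fc`), `db`
#'   (data.frame `miRNA,mRNA`).
#' @export
make_validation_fixtures <- function(study, noise_rate = 0.5, seed = NULL) {
  if (!inherits(study, "synthetic_study"))
    icpmir_stop("icpmir_bad_argument", "expected a synthetic_study")
  if (noise_rate < 0 || noise_rate > 1)
    icpmir_stop("icpmir_bad_argument", "noise_rate must be in [0, 1]")
  seed <- seed %||% (study$seed + 1000L)
  truth <- true_pairs(study)
  reg_ids <- rownames(study$regulators)
  tar_ids <- rownames(study$targets)
  with_seed(seed, {
    true_key <- pair_key(truth$regulator, truth$target)
    n_false <- round(noise_rate * nrow(truth))
    false_pairs <- data.frame(regulator = character(0), target = character(0),
                              stringsAsFactors = FALSE)
    guard <- 0L
    while (nrow(false_pairs) < n_false && guard < 50L) {
      need <- n_false - nrow(false_pairs)
      cand <- data.frame(regulator = sample(reg_ids, need, replace = TRUE),
                         target = sample(tar_ids, need, replace = TRUE),
                         stringsAsFactors = FALSE)
      key <- pair_key(cand$regulator, cand$target)
      keep <- !(key %in% true_key) &
        !(key %in% pair_key(false_pairs$regulator, false_pairs$target)) &
        !duplicated(key)
      false_pairs <- rbind(false_pairs, cand[keep, , drop = FALSE])
      guard <- guard + 1L
    }
    db <- rbind(data.frame(miRNA = truth$regulator, mRNA = truth$target,
                           stringsAsFactors = FALSE),
                data.frame(miRNA = false_pairs$regulator, mRNA = false_pairs$target,
                           stringsAsFactors = FALSE))
    all_pairs <- expand.grid(miRNA = reg_ids, mRNA = tar_ids,
                             KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    is_true <- pair_key(all_pairs$miRNA, all_pairs$mRNA) %in% true_key
    fc <- stats::rnorm(nrow(all_pairs), 0, 0.15)
    n_true <- sum(is_true)
    fc[is_true] <- sample(c(-1, 1), n_true, replace = TRUE) *
      abs(stats::rnorm(n_true, 1, 0.2))
    all_pairs$log2fc <- fc
    list(transfection = all_pairs, db = db)
  })
}

#' Write a synthetic study and its fixtures to pipeline input files
#'
#' Emits the regulator and target expression TSVs, the environment-label
#' CSV, the transfection and confirmed-interaction CSVs, and a JSON
#' manifest recording the generating parameters, seed and true parents.
#'
#' @param study `synthetic_study`.
#' @param dir Output directory (created if needed).
#' @param noise_rate Passed to [make_validation_fixtures()].
#' @return Named list of the file paths written, invisibly.
#' @export
write_study_files <- function(study, dir, noise_rate = 0.5) {
  if (!inherits(study, "synthetic_study"))
    icpmir_stop("icpmir_bad_argument", "expected a synthetic_study")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    regulators = file.path(dir, "mirna_expression.tsv"),
    targets = file.path(dir, "mrna_expression.tsv"),
    environments = file.path(dir, "environments.csv"),
    transfection = file.path(dir, "transfection.csv"),
    db = file.path(dir, "confirmed_interactions.csv"),
    manifest = file.path(dir, "study_manifest.json"))
  write_expression_matrix(study$regulators, paths$regulators, id_column = "miRNA")
  write_expression_matrix(study$targets, paths$targets, id_column = "mRNA")
  utils::write.csv(data.frame(sample_id = names(study$env),
                              environment = as.character(study$env)),
                   paths$environments, row.names = FALSE, quote = FALSE)
  fx <- make_validation_fixtures(study, noise_rate = noise_rate)
  utils::write.csv(fx$transfection, paths$transfection, row.names = FALSE, quote = FALSE)
  utils::write.csv(fx$db, paths$db, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(params = study$params, seed = study$seed,
                            noise_rate = noise_rate,
                            intervened = study$intervened,
                            hidden_dim = study$hidden_dim,
                            true_parents = study$true_parents),
                       paths$manifest, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(paths)
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("Synthetic SEM study: %d regulators x %d targets, %d samples in %d environments\n",
              nrow(x$regulators), nrow(x$targets), ncol(x$regulators), nlevels(x$env)))
  cat(sprintf("  true pairs: %d; intervened regulators: %d; hidden confounders: %d; seed %d\n",
              nrow(true_pairs(x)), length(x$intervened), x$hidden_dim, x$seed))
  invisible(x)
}
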