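## End-to-end orchestration: select -> environments -> score -> ensemble
## -> validate -> synergy, driven by a single config, fully seeded.

#' Resolve and validate a pipeline configuration
#'
#' Fills defaults into a configuration list (or JSON/YAML file) and
#' validates it: referenced paths must exist, counts must be positive and
#' rates in range. The fully resolved config is what [run_pipeline()]
#' persists next to its outputs.
#'
#' Recognised fields (defaults in parentheses): `mirna`, `mrna`
#' (expression TSV paths, required), `delimiter` (tab), `environments`
#' (label CSV path, or NULL for a random split), `n_env` (3, random split
#' only), `k_mirna` (30), `k_mrna` (1500), `alpha` (0.05), `methods`
#' (`pearson`, `lasso`, `hidden_icp`), `ensemble` (same three),
#' `top_k_overall` (500/1000/1500/2000), `top_k_per_mirna`
#' (50/100/150/200), `transfection`, `db` (optional validation file
#' paths), `transfection_threshold` (0.3), `synergy_k` (50),
#' `synergy_cutoff` (0.05), `min_env_size` (3), `seed` (1), `out_dir`
#' (required).
#'
#' @param config Named list, or path to a JSON (or YAML, if the yaml
#'   package is installed) file.
#' @return Resolved config list of class `pipeline_config`.
#' @export
pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config))
      icpmir_stop("icpmir_config", "config file not found: %s", config)
    config <- if (grepl("\\.ya?ml$", config)) {
      if (!requireNamespace("yaml", quietly = TRUE))
        icpmir_stop("icpmir_config", "yaml package required for YAML configs")
      yaml::read_yaml(config)
    } else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!is.list(config))
    icpmir_stop("icpmir_config", "config must be a named list or a config file path")
  defaults <- list(delimiter = "\t", environments = NULL, n_env = 3L,
                   k_mirna = 30L, k_mrna = 1500L, alpha = 0.05,
                   methods = c("pearson", "lasso", "hidden_icp"),
                   ensemble = c("Pearson", "Lasso", "hiddenICP"),
                   top_k_overall = c(500L, 1000L, 1500L, 2000L),
                   top_k_per_mirna = c(50L, 100L, 150L, 200L),
                   transfection = NULL, db = NULL,
                   transfection_threshold = 0.3,
                   synergy_k = 50L, synergy_cutoff = 0.05,
                   min_env_size = 3L, seed = 1L)
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[nm] <- list(defaults[[nm]])
  for (nm in c("mirna", "mrna", "out_dir"))
    if (is.null(config[[nm]]))
      icpmir_stop("icpmir_config", "config field `%s` is required", nm)
  for (nm in c("mirna", "mrna", "environments", "transfection", "db"))
    if (!is.null(config[[nm]]) && !file.exists(config[[nm]]))
      icpmir_stop("icpmir_config", "config path `%s` does not exist: %s", nm, config[[nm]])
  config$k_mirna <- check_count(config$k_mirna, "k_mirna")
  config$k_mrna <- check_count(config$k_mrna, "k_mrna")
  config$seed <- check_count(config$seed, "seed", min = 0L)
  if (config$alpha <= 0 || config$alpha >= 1)
    icpmir_stop("icpmir_config", "alpha must be in (0, 1)")
  if (config$transfection_threshold < 0)
    icpmir_stop("icpmir_config", "transfection_threshold must be >= 0")
  bad <- setdiff(config$methods, c("pearson", "lasso", "hidden_icp", "icp"))
  if (length(bad))
    icpmir_stop("icpmir_config", "unknown method(s): %s", paste(bad, collapse = ", "))
  structure(config, class = c("pipeline_config", "list"))
}

#' Run the full inference pipeline
#'
#' Executes, in order: load expression matrices; MAD feature selection;
#' environment assignment (label file or seeded random split); per-method
#' scoring (Pearson, Lasso, hidden ICP, plain ICP); per-method rankings
#' and the Borda ensemble; validation against the transfection table and
#' confirmed-interaction database when provided; synergy analysis of the
#' per-miRNA top target sets. All artifacts plus the resolved config and
#' a run manifest are written under `config$out_dir`. Any stage failure
#' stops the run with the failing stage named and leaves a `FAILED`
#' marker file.
#'
#' @param config A `pipeline_config`, a config list, or a config file
#'   path (see [pipeline_config()]).
#' @return Named list of artifact paths, invisibly.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "pipeline_config")) config else pipeline_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- "configure"
  timings <- list()
  paths <- list(config = file.path(cfg$out_dir, "resolved_config.json"),
                manifest = file.path(cfg$out_dir, "run_manifest.json"))
  jsonlite::write_json(unclass(cfg), paths$config, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  run_stage <- function(name, expr) {
    stage <<- name
    icpmir_log("INFO", "pipeline", sprintf("stage %s", name))
    t0 <- proc.time()[["elapsed"]]
    out <- force(expr)
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    out
  }
  tryCatch({
    inputs <- run_stage("load", {
      mir <- read_expression_matrix(cfg$mirna, delimiter = cfg$delimiter)
      mrna <- read_expression_matrix(cfg$mrna, delimiter = cfg$delimiter)
      if (cfg$k_mirna > nrow(mir))
        icpmir_stop("icpmir_config", "k_mirna = %d exceeds available miRNAs (%d)",
                    cfg$k_mirna, nrow(mir))
      if (cfg$k_mrna > nrow(mrna))
        icpmir_stop("icpmir_config", "k_mrna = %d exceeds available mRNAs (%d)",
                    cfg$k_mrna, nrow(mrna))
      match_samples(mir, mrna)
    })
    selected <- run_stage("select", {
      list(regulators = select_by_mad(inputs$regulators, cfg$k_mirna),
           targets = select_by_mad(inputs$targets, cfg$k_mrna))
    })
    env <- run_stage("environments", {
      e <- if (is.null(cfg$environments))
        random_environment_split(colnames(selected$regulators), n_env = cfg$n_env,
                                 seed = cfg$seed, min_size = cfg$min_env_size)
      else read_environment_labels(cfg$environments, min_size = cfg$min_env_size)
      align_environments(e, selected$regulators)
    })
    rankings <- run_stage("score", {
      out <- list()
      for (m in cfg$methods) {
        sc <- switch(m,
          pearson = pearson_scores(selected$regulators, selected$targets),
          lasso = lasso_scores(selected$regulators, selected$targets, seed = cfg$seed),
          hidden_icp = score_all_pairs(selected$regulators, selected$targets, env,
                                       method = "hidden_icp"),
          icp = score_all_pairs(selected$regulators, selected$targets, env,
                                method = "icp", alpha = cfg$alpha))
        write_scores(sc, file.path(cfg$out_dir, sprintf("scores_%s.tsv", attr(sc, "method"))),
                     file.path(cfg$out_dir, sprintf("scores_%s_long.csv", attr(sc, "method"))))
        rk <- rank_interactions(sc)
        write_ranking(rk, file.path(cfg$out_dir, sprintf("ranking_%s.csv", attr(sc, "method"))))
        out[[attr(sc, "method")]] <- rk
      }
      out
    })
    rankings <- run_stage("ensemble", {
      members <- intersect(cfg$ensemble, names(rankings))
      if (length(members) >= 2L) {
        rankings$Borda <- borda_aggregate(rankings[members])
        write_ranking(rankings$Borda, file.path(cfg$out_dir, "ranking_Borda.csv"))
      } else icpmir_log("WARN", "pipeline", "fewer than 2 ensemble members; skipping Borda")
      rankings
    })
    run_stage("validate", {
      db <- if (!is.null(cfg$db)) read_ground_truth(cfg$db) else NULL
      tf <- if (!is.null(cfg$transfection)) read_transfection_table(cfg$transfection) else NULL
      if (is.null(db) && is.null(tf)) {
        icpmir_log("INFO", "pipeline", "no validation inputs; skipping")
      } else {
        rows <- list()
        n_pairs <- nrow(rankings[[1L]])
        for (m in names(rankings)) {
          for (k in cfg$top_k_overall) {
            if (k > n_pairs) {
              icpmir_log("WARN", "pipeline",
                         sprintf("top_k_overall %d exceeds %d pairs; skipped", k, n_pairs))
              next
            }
            sel <- top_k_overall(rankings[[m]], k)
            if (!is.null(db))
              rows[[length(rows) + 1L]] <- data.frame(
                method = m, scope = "overall", k = k, source = "database",
                n_selected = k, n_confirmed = confirm_by_database(sel, db)$n_confirmed)
          }
          for (k in cfg$top_k_per_mirna) {
            sel <- do.call(rbind, top_k_per_regulator(rankings[[m]], k))
            if (!is.null(tf)) {
              ct <- confirm_by_transfection(sel, tf, threshold = cfg$transfection_threshold)
              rows[[length(rows) + 1L]] <- data.frame(
                method = m, scope = "per_mirna", k = k, source = "transfection",
                n_selected = nrow(sel), n_confirmed = ct$n_confirmed)
              icpmir_log("INFO", "pipeline",
                         sprintf("%s per-miRNA k=%d: %d uncheckable pair(s)", m, k, ct$n_uncheckable))
            }
            if (!is.null(db))
              rows[[length(rows) + 1L]] <- data.frame(
                method = m, scope = "per_mirna", k = k, source = "database",
                n_selected = nrow(sel), n_confirmed = confirm_by_database(sel, db)$n_confirmed)
          }
        }
        report <- do.call(rbind, rows)
        paths$validation <- file.path(cfg$out_dir, "validation_report.csv")
        utils::write.csv(report, paths$validation, row.names = FALSE, quote = FALSE)
      }
      NULL
    })
    run_stage("synergy", {
      base_m <- if ("hiddenICP" %in% names(rankings)) "hiddenICP" else names(rankings)[1L]
      tops <- top_k_per_regulator(rankings[[base_m]], cfg$synergy_k)
      sets <- lapply(tops, `[[`, "target")
      syn <- synergy_matrix(sets, universe_size = cfg$k_mrna, cutoff = cfg$synergy_cutoff)
      paths$synergy <- file.path(cfg$out_dir, "synergy.csv")
      write_synergy(syn, paths$synergy)
      NULL
    })
    stage <- "manifest"
    jsonlite::write_json(
      list(package_version = as.character(utils::packageVersion("icpmir")),
           seed = cfg$seed, methods = names(rankings),
           stage_seconds = timings),
      paths$manifest, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }, error = function(cnd) {
    writeLines(sprintf("stage %s failed: %s", stage, conditionMessage(cnd)),
               file.path(cfg$out_dir, "FAILED"))
    icpmir_stop("icpmir_stage_failure", "pipeline stage `%s` failed: %s",
                stage, conditionMessage(cnd))
  })
  invisible(paths)
}
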