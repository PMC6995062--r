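# deterministic child seed per pipeline stage, derived from the global
# seed and the stage name so stages can be rerun in isolation
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% .Machine$integer.max)
}

#' Assemble and validate a discovery run configuration
#'
#' @param beta_path,manifest_path Paths to the beta matrix and manifest
#'   TSVs (required).
#' @param expression_path,gmt_path Optional paths to an expression
#'   matrix and a GMT collection; when both are given, every passing
#'   probe gets a stratified enrichment analysis.
#' @param target_cohort,blood_cohort Cohort names for the filter preset.
#' @param chain A `filter_chain`, a path to a YAML chain config, or
#'   `"preset:brca"` (default).
#' @param covariates Manifest columns to summarize per passing probe.
#' @param min_n Minimum evaluable group size for metrics.
#' @param n_perm Permutations for enrichment.
#' @param weight Enrichment weight exponent.
#' @param statistic Ranking statistic for enrichment.
#' @param top_k Size of top/bottom correlated gene lists.
#' @param seed Global seed; per-stage child seeds are derived from it.
#' @param out_dir Output directory.
#' @return A validated `run_config` list.
#' @export
run_config <- function(beta_path, manifest_path, expression_path = NULL,
                       gmt_path = NULL, target_cohort = "BRCA",
                       blood_cohort = "BLOOD", chain = "preset:brca",
                       covariates = c("stage", "subtype", "age", "race",
                                      "ethnicity"),
                       min_n = 5, n_perm = 1000, weight = 1,
                       statistic = "signal_to_noise", top_k = 20,
                       seed = 1, out_dir = "methmark_run") {
  cfg <- list(beta_path = beta_path, manifest_path = manifest_path,
              expression_path = expression_path, gmt_path = gmt_path,
              target_cohort = target_cohort, blood_cohort = blood_cohort,
              chain = chain, covariates = covariates, min_n = min_n,
              n_perm = n_perm, weight = weight, statistic = statistic,
              top_k = top_k, seed = as.integer(seed), out_dir = out_dir)
  for (f in c("beta_path", "manifest_path", "expression_path", "gmt_path")) {
    p <- cfg[[f]]
    if (!is.null(p) && !file.exists(p)) {
      stop(sprintf("config validation: %s does not exist: %s", f, p),
           call. = FALSE)
    }
  }
  if (is.character(cfg$chain) && !startsWith(cfg$chain, "preset:") &&
      !file.exists(cfg$chain)) {
    stop(sprintf("config validation: chain config does not exist: %s",
                 cfg$chain), call. = FALSE)
  }
  structure(cfg, class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Any field of [run_config()] may appear in the file; unspecified
#' fields take the function defaults.
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  obj <- yaml::read_yaml(path)
  do.call(run_config, obj)
}

resolve_chain <- function(cfg) {
  ch <- cfg$chain
  if (inherits(ch, "filter_chain")) return(ch)
  if (identical(ch, "preset:brca")) {
    return(brca_preset(cfg$target_cohort, cfg$blood_cohort))
  }
  read_filter_chain(ch)
}

log_line <- function(con, level, fmt, ...) {
  msg <- sprintf("[%s] %s %s", level,
                 format(Sys.time(), "%Y-%m-%d %H:%M:%S"), sprintf(fmt, ...))
  message(msg)
  if (!is.null(con)) writeLines(msg, con)
}

#' Run the end-to-end marker discovery pipeline
#'
#' Executes the discovery funnel: subset metrics over all (cohort,
#' subset) groups, filter-chain evaluation, then for each passing probe
#' (when expression and gene sets are configured) mean+/-1SD
#' stratification, gene ranking, permutation enrichment, probe-
#' expression correlation, and covariate summaries. All outputs are
#' written under `cfg$out_dir`; a run manifest with the effective
#' config, per-file checksums and funnel counts is written at the end.
#'
#' @param cfg A `run_config`.
#' @return The run manifest (list), invisibly; outputs on disk.
#' @export
run_discovery <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_con <- file(file.path(cfg$out_dir, "run.log"), open = "wt")
  on.exit(close(log_con), add = TRUE)
  t0 <- Sys.time()
  timings <- list()
  failed_sentinel <- file.path(cfg$out_dir, "FAILED")
  ok <- FALSE
  on.exit({
    if (!ok) writeLines("run aborted; partial outputs retained",
                        failed_sentinel)
  }, add = TRUE)

  stage <- function(name, expr) {
    t <- Sys.time()
    res <- tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    timings[[name]] <<- as.numeric(difftime(Sys.time(), t, units = "secs"))
    res
  }

  log_line(log_con, "INFO", "reading inputs")
  beta <- stage("read_beta", read_beta_matrix(cfg$beta_path))
  manifest <- stage("read_manifest", read_manifest(cfg$manifest_path))
  expr <- if (!is.null(cfg$expression_path)) {
    stage("read_expression", read_expression_matrix(cfg$expression_path))
  } else NULL
  gene_sets <- if (!is.null(cfg$gmt_path)) {
    stage("read_gmt", read_gmt(cfg$gmt_path))
  } else NULL

  log_line(log_con, "INFO", "computing subset metrics (%d probes, %d samples)",
           nrow(beta), ncol(beta))
  metrics <- stage("metrics", subset_metrics(beta, manifest, min_n = cfg$min_n))
  write_subset_metrics(metrics, file.path(cfg$out_dir, "subset_metrics.tsv"))

  chain <- resolve_chain(cfg)
  report <- stage("filter", apply_chain(chain, metrics, cfg$target_cohort))
  funnel <- attr(report, "funnel")
  for (j in seq_along(funnel)) {
    log_line(log_con, "INFO", "funnel: %d candidates after criterion %d (%s)",
             funnel[j], j, format(chain$criteria[[j]]))
  }
  write_marker_report(report, file.path(cfg$out_dir, "marker_report.tsv"))
  passing <- report$probe_id[report$pass]
  log_line(log_con, "INFO", "%d probes pass the full chain", length(passing))

  for (probe in passing) {
    if (!is.null(expr) && !is.null(gene_sets)) {
      strat <- tryCatch(
        stratify(beta, manifest, probe, cfg$target_cohort, "PT"),
        error = function(e) {
          log_line(log_con, "INFO", "skipping enrichment at %s: %s",
                   probe, conditionMessage(e)); NULL
        })
      if (!is.null(strat) && length(intersect(strat$H, colnames(expr))) >= 3 &&
          length(intersect(strat$L, colnames(expr))) >= 3) {
        enr <- stage(paste0("enrich_", probe), permutation_test(
          expr, strat, gene_sets, n_perm = cfg$n_perm, p = cfg$weight,
          seed = derive_seed(cfg$seed, paste0("enrich_", probe)),
          statistic = cfg$statistic))
        write_enrichment_result(
          enr, file.path(cfg$out_dir, sprintf("enrichment_%s.tsv", probe)))
      }
      ct <- tryCatch(
        correlate_probe_expression(beta, expr, probe, top_k = cfg$top_k),
        error = function(e) NULL)
      if (!is.null(ct)) {
        write_correlation_table(
          ct, file.path(cfg$out_dir, sprintf("correlation_%s.tsv", probe)))
        writeLines(ct$top, file.path(cfg$out_dir,
                                     sprintf("top_genes_%s.txt", probe)))
        writeLines(ct$bottom, file.path(cfg$out_dir,
                                        sprintf("bottom_genes_%s.txt", probe)))
      }
    }
    for (cov in cfg$covariates) {
      cs <- tryCatch(
        covariate_summary(beta, manifest, probe, cfg$target_cohort, "PT",
                          covariate = cov, min_n = cfg$min_n,
                          seed = derive_seed(cfg$seed,
                                             paste0("assoc_", probe, cov))),
        error = function(e) {
          log_line(log_con, "INFO", "skipping covariate '%s' at %s: %s",
                   cov, probe, conditionMessage(e)); NULL
        })
      if (!is.null(cs)) {
        write_covariate_summary(
          cs, file.path(cfg$out_dir,
                        sprintf("covariate_%s_%s.tsv", probe, cov)))
      }
    }
  }

  outputs <- setdiff(list.files(cfg$out_dir, full.names = TRUE),
                     file.path(cfg$out_dir, c("run.log", "run_manifest.yaml")))
  manifest_obj <- list(
    package_version = as.character(utils::packageVersion("methmark")),
    config = unclass(cfg),
    funnel = as.list(funnel),
    n_passing = length(passing),
    passing_probes = passing,
    checksums = as.list(tools::md5sum(sort(outputs))),
    wall_clock_seconds = timings,
    total_seconds = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  yaml::write_yaml(manifest_obj,
                   file.path(cfg$out_dir, "run_manifest.yaml"))
  ok <- TRUE
  log_line(log_con, "INFO", "run complete in %.1f s", manifest_obj$total_seconds)
  invisible(manifest_obj)
}

#' One-command synthetic demonstration run
#'
#' Generates the default synthetic scenario (multi-cohort beta matrix
#' with planted markers and decoys, linked expression, gene sets),
#' writes the inputs, and runs the full discovery pipeline on them.
#'
#' @param seed Integer seed; drives both generation and analysis.
#' @param out_dir Output directory (inputs under `inputs/`, results
#'   under `results/`).
#' @param n_perm Permutations for enrichment (kept modest so the demo
#'   finishes in seconds to minutes).
#' @return List with the run manifest, the truth table, and recovery
#'   metrics (`sensitivity`, `specificity`) of the pass set against the
#'   planted truth.
#' @export
demo_run <- function(seed = 1, out_dir = tempfile("methmark_demo"),
                     n_perm = 200) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  in_dir <- file.path(out_dir, "inputs")
  dir.create(in_dir, showWarnings = FALSE)
  plant <- plant_spec()
  sim <- generate_cohorts(default_cohort_specs(), plant,
                          n_background_probes = 100,
                          seed = derive_seed(seed, "simulate"))
  expr <- generate_expression(sim$beta, sim$manifest, plant,
                              n_genes = 200,
                              seed = derive_seed(seed, "expression"),
                              probe = "mk_001")
  sets <- generate_gene_sets(expr, attr(expr, "linked_genes"),
                             n_sets = 10, set_size = 10,
                             seed = derive_seed(seed, "gene_sets"))
  write_beta_matrix(sim$beta, file.path(in_dir, "beta.tsv"))
  write_manifest(sim$manifest, file.path(in_dir, "manifest.tsv"))
  write_beta_matrix(expr, file.path(in_dir, "expression.tsv"),
                    id_col = "gene_id")
  write_gmt(sets, file.path(in_dir, "sets.gmt"))
  utils::write.table(sim$truth, file.path(in_dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- run_config(
    beta_path = file.path(in_dir, "beta.tsv"),
    manifest_path = file.path(in_dir, "manifest.tsv"),
    expression_path = file.path(in_dir, "expression.tsv"),
    gmt_path = file.path(in_dir, "sets.gmt"),
    n_perm = n_perm, seed = seed,
    out_dir = file.path(out_dir, "results"))
  rm_manifest <- run_discovery(cfg)
  truth <- sim$truth
  is_marker <- truth$class == "marker"
  pass <- truth$probe_id %in% rm_manifest$passing_probes
  sensitivity <- if (any(is_marker)) mean(pass[is_marker]) else NA_real_
  specificity <- if (any(!is_marker)) mean(!pass[!is_marker]) else NA_real_
  list(run_manifest = rm_manifest, truth = truth,
       sensitivity = sensitivity, specificity = specificity,
       out_dir = out_dir)
}
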