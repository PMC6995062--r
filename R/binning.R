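#' Classify beta values into methylation bins
#'
#' A beta value is the fraction of methylation at a CpG probe in one
#' sample. The four bins partition \[0, 1\]:
#' UnMethylated (UM): beta <= 0.15; Indeterminately Methylated (IM):
#' 0.15 < beta <= 0.3; Lowly Methylated (LM): 0.3 < beta <= 0.6;
#' Highly Methylated (HM): beta > 0.6. Boundary membership follows the
#' printed inequalities exactly; no epsilon slack. Missing values map to
#' `NA`.
#'
#' @param beta Numeric vector of beta values in \[0, 1\]; `NA` allowed.
#' @return A factor with levels `UM`, `IM`, `LM`, `HM` (`NA` preserved).
#' @examples
#' classify_beta(c(0.15, 0.3, 0.536, 0.6, 0.61, NA))
#' @export
classify_beta <- function(beta) {
  beta <- as.numeric(beta)
  if (any(!is.na(beta) & (beta < 0 | beta > 1))) {
    off <- beta[!is.na(beta) & (beta < 0 | beta > 1)][1]
    stop(sprintf("beta value %g outside [0, 1]", off), call. = FALSE)
  }
  bin <- cut(beta, breaks = c(-Inf, 0.15, 0.3, 0.6, Inf),
             labels = c("UM", "IM", "LM", "HM"), right = TRUE)
  bin
}

METRIC_NAMES <- c("%UM", "%IM", "%LM", "%HM", "%UM+%IM", "%LM+%HM")

#' Per-(cohort, subset) bin-percentage metrics
#'
#' For each probe and each requested (cohort, subset) group, computes
#' the percentage of non-missing samples falling in each methylation bin
#' (%UM, %IM, %LM, %HM) and the two sum metrics %UM+%IM and %LM+%HM.
#' Percentages are `100 * count / n_eval` in double precision, where
#' `n_eval` is the number of non-missing samples for that probe in that
#' group; groups with `n_eval < min_n` are unevaluable and their metrics
#' reported as `NA`, never silently as 0.
#'
#' @param beta Numeric beta matrix (probes x samples, rownames/colnames set).
#' @param manifest Sample manifest data.frame (see [read_manifest()]).
#' @param groups Data.frame with columns `cohort`, `subset` naming the
#'   groups to evaluate; defaults to all (cohort, subset) pairs present.
#' @param min_n Minimum non-missing samples for a metric to be evaluable.
#' @return An object of class `subset_metrics`: a list with `metrics`
#'   (3-d array probe x group x metric), `n_eval` (probe x group matrix),
#'   and `groups` (data.frame with `cohort`, `subset`, `label`, `n`).
#' @examples
#' b <- matrix(c(0.05, 0.2, 0.5, 0.9), 1, 4,
#'             dimnames = list("cg01", paste0("s", 1:4)))
#' m <- data.frame(sample_id = paste0("s", 1:4),
#'                 cohort = "BRCA", subset = "PT")
#' subset_metrics(b, m, min_n = 1)
#' @export
subset_metrics <- function(beta, manifest, groups = NULL, min_n = 5) {
  manifest <- validate_manifest(manifest)
  miss <- setdiff(colnames(beta), manifest$sample_id)
  if (length(miss) > 0) {
    stop(sprintf("samples in beta matrix absent from manifest: %s",
                 paste(utils::head(miss, 5), collapse = ", ")), call. = FALSE)
  }
  present <- unique(manifest[, c("cohort", "subset")])
  if (is.null(groups)) {
    groups <- present
  } else {
    key <- paste(groups$cohort, groups$subset)
    have <- paste(present$cohort, present$subset)
    absent <- setdiff(key, have)
    if (length(absent) > 0) {
      stop(sprintf("group(s) absent from manifest: %s",
                   paste(absent, collapse = "; ")), call. = FALSE)
    }
  }
  groups <- data.frame(cohort = groups$cohort, subset = groups$subset,
                       stringsAsFactors = FALSE)
  groups$label <- paste(groups$cohort, groups$subset, sep = ".")
  n_probe <- nrow(beta)
  n_group <- nrow(groups)
  metrics <- array(NA_real_, dim = c(n_probe, n_group, length(METRIC_NAMES)),
                   dimnames = list(rownames(beta), groups$label, METRIC_NAMES))
  n_eval <- matrix(0L, n_probe, n_group,
                   dimnames = list(rownames(beta), groups$label))
  groups$n <- 0L
  for (g in seq_len(n_group)) {
    ids <- manifest$sample_id[manifest$cohort == groups$cohort[g] &
                              manifest$subset == groups$subset[g]]
    ids <- intersect(ids, colnames(beta))
    groups$n[g] <- length(ids)
    if (length(ids) == 0) next
    sub <- beta[, ids, drop = FALSE]
    ne <- rowSums(!is.na(sub))
    n_eval[, g] <- as.integer(ne)
    # counts per bin, vectorized over probes
    c_um <- rowSums(sub <= 0.15, na.rm = TRUE)
    c_im <- rowSums(sub > 0.15 & sub <= 0.3, na.rm = TRUE)
    c_lm <- rowSums(sub > 0.3 & sub <= 0.6, na.rm = TRUE)
    c_hm <- rowSums(sub > 0.6, na.rm = TRUE)
    ok <- ne >= max(min_n, 1L)
    pct <- function(cnt) ifelse(ok, 100 * cnt / ne, NA_real_)
    metrics[, g, "%UM"] <- pct(c_um)
    metrics[, g, "%IM"] <- pct(c_im)
    metrics[, g, "%LM"] <- pct(c_lm)
    metrics[, g, "%HM"] <- pct(c_hm)
    metrics[, g, "%UM+%IM"] <- metrics[, g, "%UM"] + metrics[, g, "%IM"]
    metrics[, g, "%LM+%HM"] <- metrics[, g, "%LM"] + metrics[, g, "%HM"]
  }
  structure(list(metrics = metrics, n_eval = n_eval, groups = groups,
                 min_n = min_n),
            class = "subset_metrics")
}

#' Construct a subset_metrics object from a long-format table
#'
#' Low-level constructor mainly useful for assembling metric tables
#' directly (e.g. from an export or a simulation) without beta values.
#'
#' @param df Data.frame with columns `probe_id`, `cohort`, `subset`,
#'   `metric`, `value`, `n_eval`.
#' @return A `subset_metrics` object.
#' @export
subset_metric_table <- function(df) {
  stopifnot(all(c("probe_id", "cohort", "subset", "metric", "value",
                  "n_eval") %in% names(df)))
  probes <- unique(df$probe_id)
  groups <- unique(data.frame(cohort = df$cohort, subset = df$subset,
                              stringsAsFactors = FALSE))
  groups$label <- paste(groups$cohort, groups$subset, sep = ".")
  metrics <- array(NA_real_,
                   dim = c(length(probes), nrow(groups), length(METRIC_NAMES)),
                   dimnames = list(probes, groups$label, METRIC_NAMES))
  n_eval <- matrix(0L, length(probes), nrow(groups),
                   dimnames = list(probes, groups$label))
  lab <- paste(df$cohort, df$subset, sep = ".")
  idx <- cbind(match(df$probe_id, probes), match(lab, groups$label),
               match(df$metric, METRIC_NAMES))
  metrics[idx] <- df$value
  n_eval[idx[, 1:2]] <- as.integer(df$n_eval)
  groups$n <- apply(n_eval, 2, max)
  structure(list(metrics = metrics, n_eval = n_eval, groups = groups,
                 min_n = NA_integer_),
            class = "subset_metrics")
}

#' @export
as.data.frame.subset_metrics <- function(x, ...) {
  d <- dim(x$metrics)
  dn <- dimnames(x$metrics)
  long <- expand.grid(probe_id = dn[[1]], label = dn[[2]], metric = dn[[3]],
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  long$value <- as.vector(x$metrics)
  gi <- match(long$label, x$groups$label)
  long$cohort <- x$groups$cohort[gi]
  long$subset <- x$groups$subset[gi]
  long$n_eval <- x$n_eval[cbind(match(long$probe_id, dn[[1]]), gi)]
  long[, c("probe_id", "cohort", "subset", "metric", "value", "n_eval")]
}

#' Export a metric table as long-format TSV
#'
#' @param x A `subset_metrics` object.
#' @param path Output path.
#' @export
write_subset_metrics <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' @export
print.subset_metrics <- function(x, ...) {
  cat(sprintf("subset_metrics: %d probes x %d groups (min_n = %s)\n",
              dim(x$metrics)[1], dim(x$metrics)[2], x$min_n))
  cat("groups:\n")
  print(x$groups, row.names = FALSE)
  invisible(x)
}

# fetch one metric value for (probe, cohort, subset); NA if unevaluable
metric_value <- function(metrics, probe, cohort, subset, metric) {
  lab <- paste(cohort, subset, sep = ".")
  gi <- match(lab, metrics$groups$label)
  if (is.na(gi)) {
    stop(sprintf("group %s/%s not present in metric table", cohort, subset),
         call. = FALSE)
  }
  metrics$metrics[probe, gi, metric]
}
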