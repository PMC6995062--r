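#' Correlate a probe's methylation with genome-wide expression
#'
#' Pearson correlation between one probe's beta values and every gene's
#' expression over the shared samples, with pairwise-complete deletion
#' of missing values. Genes are ranked by R descending; the top-k and
#' bottom-k lists are the usual inputs to a marker-centred expression
#' heatmap.
#'
#' @param beta Beta matrix.
#' @param expression Expression matrix.
#' @param probe Probe id.
#' @param samples Optional sample ids to restrict to; defaults to all
#'   samples shared by the two matrices.
#' @param top_k Size of the top/bottom correlated gene lists.
#' @return List of class `correlation_table`: `table` (data.frame gene,
#'   r, n, p_value, q_value ordered by r descending), `top`, `bottom`
#'   (gene id vectors), `probe`.
#' @export
correlate_probe_expression <- function(beta, expression, probe,
                                       samples = NULL, top_k = 20) {
  if (!probe %in% rownames(beta)) {
    stop(sprintf("probe '%s' not in beta matrix", probe), call. = FALSE)
  }
  shared <- intersect(colnames(beta), colnames(expression))
  if (!is.null(samples)) shared <- intersect(shared, samples)
  b <- beta[probe, shared]
  keep <- !is.na(b)
  shared <- shared[keep]
  b <- b[keep]
  if (length(shared) < 3) {
    stop("fewer than 3 shared samples with non-missing beta", call. = FALSE)
  }
  if (stats::sd(b) == 0) {
    stop(sprintf("probe '%s' has zero variance across the shared samples; correlation undefined",
                 probe), call. = FALSE)
  }
  ex <- expression[, shared, drop = FALSE]
  genes <- rownames(ex)
  r <- numeric(length(genes))
  n <- integer(length(genes))
  pv <- numeric(length(genes))
  for (i in seq_along(genes)) {
    y <- ex[i, ]
    ok <- !is.na(y)
    n[i] <- sum(ok)
    if (n[i] < 3 || stats::sd(y[ok]) == 0) {
      r[i] <- NA_real_
      pv[i] <- NA_real_
      next
    }
    r[i] <- stats::cor(b[ok], y[ok])
    # two-sided t-test on the correlation
    tt <- r[i] * sqrt((n[i] - 2) / max(1 - r[i]^2, .Machine$double.eps))
    pv[i] <- 2 * stats::pt(-abs(tt), df = n[i] - 2)
  }
  tab <- data.frame(gene = genes, r = r, n = n, p_value = pv,
                    stringsAsFactors = FALSE)
  tab$q_value <- stats::p.adjust(tab$p_value, method = "BH")
  tab <- tab[order(-tab$r, tab$gene, method = "radix"), ]
  rownames(tab) <- NULL
  ok <- !is.na(tab$r)
  structure(list(table = tab,
                 top = utils::head(tab$gene[ok], top_k),
                 bottom = rev(utils::tail(tab$gene[ok], top_k)),
                 probe = probe, n_samples = length(shared)),
            class = "correlation_table")
}

#' @export
print.correlation_table <- function(x, ...) {
  cat(sprintf("correlation_table at %s: %d genes over %d samples\n",
              x$probe, nrow(x$table), x$n_samples))
  cat("top correlated:", paste(utils::head(x$top, 5), collapse = ", "), "\n")
  cat("bottom correlated:", paste(utils::head(x$bottom, 5), collapse = ", "),
      "\n")
  invisible(x)
}

#' Export a correlation table as TSV
#'
#' @param x A `correlation_table`.
#' @param path Output path.
#' @export
write_correlation_table <- function(x, path) {
  utils::write.table(x$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

# seeded permutation test on the difference of group means
perm_diff_test <- function(x, y, n_perm = 10000) {
  obs <- mean(x) - mean(y)
  pool <- c(x, y)
  nx <- length(x)
  d <- vapply(seq_len(n_perm), function(k) {
    h <- sample.int(length(pool), nx)
    mean(pool[h]) - mean(pool[-h])
  }, numeric(1))
  # add-one correction keeps p > 0 and exact under the null
  p <- (1 + sum(abs(d) >= abs(obs) - 1e-12)) / (n_perm + 1)
  list(diff = obs, p = p)
}

STAGE_LEVELS <- c("I", "II", "III", "IV")
SUBTYPE_LEVELS <- c("Basal", "LumA", "LumB", "HER2")

#' Summarize a probe's methylation against a clinical covariate
#'
#' For categorical covariates (stage, subtype, race, ethnicity): group
#' mean beta, n and sd per level, plus all pairwise two-group
#' comparisons by a seeded permutation test on the difference of means,
#' Benjamini-Hochberg adjusted. Stage and subtype levels are reported in
#' their natural order (I < II < III < IV; Basal, LumA, LumB, HER2).
#' For `age`: simple linear regression of beta on age, reporting R^2
#' and the slope.
#'
#' @param beta Beta matrix.
#' @param manifest Sample manifest carrying the covariate column.
#' @param probe Probe id.
#' @param cohort,subset Group of samples to analyse.
#' @param covariate Covariate column name (`"stage"`, `"subtype"`,
#'   `"age"`, `"race"`, `"ethnicity"`, or any manifest column).
#' @param min_n Levels with fewer samples are reported but flagged
#'   (`evaluable = FALSE`) and excluded from pairwise comparisons.
#' @param n_perm Permutations per pairwise comparison.
#' @param seed Integer seed for the permutation draws.
#' @return Object of class `covariate_summary`. For categorical
#'   covariates: `levels` (data.frame level, n, mean, sd, evaluable) and
#'   `comparisons` (data.frame level_a, level_b, diff, p_value, q_value).
#'   For age: `r_squared`, `slope`, `n`.
#' @export
covariate_summary <- function(beta, manifest, probe, cohort, subset = "PT",
                              covariate = "stage", min_n = 5,
                              n_perm = 10000, seed = 1) {
  if (!covariate %in% names(manifest)) {
    stop(sprintf("covariate '%s' absent from manifest", covariate),
         call. = FALSE)
  }
  sel <- manifest[manifest$cohort == cohort & manifest$subset == subset, ]
  sel <- sel[sel$sample_id %in% colnames(beta), ]
  b <- beta[probe, sel$sample_id]
  cv <- sel[[covariate]]
  ok <- !is.na(b) & !is.na(cv)
  b <- b[ok]
  cv <- cv[ok]
  if (covariate == "age") {
    if (length(b) < 3) stop("need >= 3 samples with age and beta", call. = FALSE)
    fit <- stats::lm(b ~ cv)
    return(structure(list(covariate = "age", probe = probe,
                          cohort = cohort, subset = subset,
                          n = length(b),
                          r_squared = summary(fit)$r.squared,
                          slope = unname(stats::coef(fit)[2])),
                     class = "covariate_summary"))
  }
  lv <- if (covariate == "stage") intersect(STAGE_LEVELS, unique(cv))
        else if (covariate == "subtype") intersect(SUBTYPE_LEVELS, unique(cv))
        else sort(unique(cv))
  levels_df <- data.frame(
    level = lv,
    n = vapply(lv, function(l) sum(cv == l), integer(1)),
    mean = vapply(lv, function(l) mean(b[cv == l]), numeric(1)),
    sd = vapply(lv, function(l) stats::sd(b[cv == l]), numeric(1)),
    stringsAsFactors = FALSE)
  levels_df$evaluable <- levels_df$n >= min_n
  if (sum(levels_df$evaluable) < 2) {
    stop(sprintf("covariate '%s' has fewer than 2 levels with >= %d samples",
                 covariate, min_n), call. = FALSE)
  }
  ev <- levels_df$level[levels_df$evaluable]
  pairs <- utils::combn(ev, 2)
  set.seed(seed)
  comps <- lapply(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1, k]; bb <- pairs[2, k]
    res <- perm_diff_test(b[cv == a], b[cv == bb], n_perm)
    data.frame(level_a = a, level_b = bb, diff = res$diff,
               p_value = res$p, stringsAsFactors = FALSE)
  })
  comps <- do.call(rbind, comps)
  comps$q_value <- stats::p.adjust(comps$p_value, method = "BH")
  structure(list(covariate = covariate, probe = probe, cohort = cohort,
                 subset = subset, levels = levels_df, comparisons = comps,
                 adjustment = "BH", n_perm = n_perm, seed = seed),
            class = "covariate_summary")
}

#' @export
print.covariate_summary <- function(x, ...) {
  cat(sprintf("covariate_summary: %s at %s (%s/%s)\n",
              x$covariate, x$probe, x$cohort, x$subset))
  if (x$covariate == "age") {
    cat(sprintf("  n = %d, R^2 = %.4f, slope = %.5f per year\n",
                x$n, x$r_squared, x$slope))
  } else {
    print(x$levels, row.names = FALSE, digits = 4)
    cat(sprintf("pairwise permutation tests (n_perm = %d, %s-adjusted):\n",
                x$n_perm, x$adjustment))
    print(x$comparisons, row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' Export a covariate summary as TSV
#'
#' @param x A `covariate_summary`.
#' @param path Output path.
#' @export
write_covariate_summary <- function(x, path) {
  if (x$covariate == "age") {
    df <- data.frame(covariate = "age", n = x$n, r_squared = x$r_squared,
                     slope = x$slope)
  } else {
    df <- x$levels
    df$covariate <- x$covariate
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  if (x$covariate != "age") {
    utils::write.table(x$comparisons,
                       sub("\\.tsv$", "_pairwise.tsv", path),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "NA")
  }
  invisible(path)
}
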