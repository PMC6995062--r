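#' Stratify a group into high/low methylation subsets
#'
#' Splits one (cohort, subset) group at a probe into the H subset
#' (samples with beta at least 1 standard deviation above the group
#' mean) and the L subset (at least 1 SD below). Mean and SD are the
#' sample statistics (n - 1 denominator) over non-missing betas;
#' thresholds are inclusive. A zero-variance group yields empty H and L.
#'
#' @param beta Beta matrix.
#' @param manifest Sample manifest.
#' @param probe Probe id.
#' @param cohort,subset The group to stratify.
#' @return List of class `stratified_sets` with `H`, `L` (sample ids),
#'   `mean`, `sd`, `n`, `probe`, `cohort`, `subset`.
#' @export
stratify <- function(beta, manifest, probe, cohort, subset = "PT") {
  if (!probe %in% rownames(beta)) {
    stop(sprintf("probe '%s' not in beta matrix", probe), call. = FALSE)
  }
  ids <- manifest$sample_id[manifest$cohort == cohort &
                            manifest$subset == subset]
  ids <- intersect(ids, colnames(beta))
  b <- beta[probe, ids]
  ids <- ids[!is.na(b)]
  b <- b[!is.na(b)]
  if (length(b) < 3) {
    stop(sprintf("group %s/%s has %d non-missing samples at %s (need >= 3)",
                 cohort, subset, length(b), probe), call. = FALSE)
  }
  m <- mean(b)
  s <- stats::sd(b)
  if (s == 0) {
    H <- character(0)
    L <- character(0)
  } else {
    # tiny absolute tolerance so inclusive boundaries survive the
    # floating-point rounding of m +/- s
    eps <- 1e-10
    H <- ids[b >= m + s - eps]
    L <- ids[b <= m - s + eps]
  }
  structure(list(H = H, L = L, mean = m, sd = s, n = length(b),
                 probe = probe, cohort = cohort, subset = subset),
            class = "stratified_sets")
}

#' @export
print.stratified_sets <- function(x, ...) {
  cat(sprintf(
    "stratified_sets at %s (%s/%s): n = %d, mean = %.4f, sd = %.4f, |H| = %d, |L| = %d\n",
    x$probe, x$cohort, x$subset, x$n, x$mean, x$sd,
    length(x$H), length(x$L)))
  invisible(x)
}

# per-gene differential statistic between two sample-id classes.
# signal-to-noise follows the classic GSEA convention: each class SD is
# floored at 0.2 * |class mean|.
class_statistic <- function(expression, h_ids, l_ids,
                            statistic = c("signal_to_noise", "t_statistic")) {
  statistic <- match.arg(statistic)
  eh <- expression[, h_ids, drop = FALSE]
  el <- expression[, l_ids, drop = FALSE]
  mh <- rowMeans(eh)
  ml <- rowMeans(el)
  vh <- rowSums((eh - mh)^2) / (ncol(eh) - 1)
  vl <- rowSums((el - ml)^2) / (ncol(el) - 1)
  if (statistic == "signal_to_noise") {
    sh <- pmax(sqrt(vh), 0.2 * abs(mh))
    sl <- pmax(sqrt(vl), 0.2 * abs(ml))
    denom <- sh + sl
    num <- mh - ml
    s <- ifelse(denom == 0, 0, num / pmax(denom, .Machine$double.eps))
  } else {
    nh <- ncol(eh); nl <- ncol(el)
    denom <- sqrt(vh / nh + vl / nl)
    num <- mh - ml
    s <- ifelse(denom == 0 & num == 0, 0,
                num / pmax(denom, .Machine$double.eps))
  }
  s
}

#' Rank genes by differential expression between H and L subsets
#'
#' Computes a per-gene differential statistic between the high- and
#' low-methylation subsets and orders genes by it, descending, with
#' ties broken by gene id (lexicographic, C locale) so the ranking is
#' strictly deterministic. Genes with missing expression in more than
#' 20% of the H-union-L samples are dropped before ranking.
#'
#' @param expression Expression matrix (genes x samples).
#' @param sets A `stratified_sets` object (or list with `H`, `L`).
#' @param statistic `"signal_to_noise"` — (mean_H - mean_L)/(sd_H + sd_L)
#'   with each sd floored at 0.2 x |class mean| — or `"t_statistic"`
#'   (Welch-style denominator).
#' @param max_missing Maximum tolerated fraction of missing expression.
#' @return Data.frame of class `ranked_list` with columns `gene`,
#'   `statistic`, ordered.
#' @export
rank_genes <- function(expression, sets,
                       statistic = c("signal_to_noise", "t_statistic"),
                       max_missing = 0.2) {
  statistic <- match.arg(statistic)
  h_ids <- intersect(sets$H, colnames(expression))
  l_ids <- intersect(sets$L, colnames(expression))
  if (length(h_ids) < 3 || length(l_ids) < 3) {
    stop(sprintf("H (%d) and L (%d) must each have >= 3 samples with expression",
                 length(h_ids), length(l_ids)), call. = FALSE)
  }
  if (statistic == "signal_to_noise" &&
      (length(h_ids) < 7 || length(l_ids) < 7)) {
    warning("fewer than 7 samples in a class: the signal-to-noise sd floor dominates; consider statistic = 't_statistic'")
  }
  sub <- expression[, c(h_ids, l_ids), drop = FALSE]
  keep <- rowMeans(is.na(sub)) <= max_missing
  sub <- sub[keep, , drop = FALSE]
  # remaining missing values are mean-imputed per gene within the pool
  if (anyNA(sub)) {
    for (i in which(rowSums(is.na(sub)) > 0)) {
      v <- sub[i, ]
      v[is.na(v)] <- mean(v, na.rm = TRUE)
      sub[i, ] <- v
    }
  }
  s <- class_statistic(sub, h_ids, l_ids, statistic)
  ord <- order(-s, rownames(sub), method = "radix")
  structure(data.frame(gene = rownames(sub)[ord], statistic = s[ord],
                       stringsAsFactors = FALSE),
            class = c("ranked_list", "data.frame"),
            statistic_name = statistic)
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Walks the ranked gene list: genes in the set increment the running
#' sum by |statistic|^p normalized by the sum of |statistic|^p over set
#' members; genes outside decrement by 1/(N - N_hit). The enrichment
#' score is the running sum's maximum deviation from zero, signed.
#' With `p = 0` this is the classic (equal-weight) KS statistic. If all
#' hit statistics are zero at `p > 0`, hits fall back to equal weights.
#'
#' @param ranked A `ranked_list` (or data.frame with `gene`, `statistic`).
#' @param gene_set Character vector of gene ids.
#' @param p Weight exponent, >= 0 (1 by default).
#' @return List with `es` and `running` (the N-step running-sum profile).
#' @export
enrichment_score <- function(ranked, gene_set, p = 1) {
  stopifnot(p >= 0)
  genes <- ranked$gene
  stats_ <- ranked$statistic
  hit <- genes %in% gene_set
  n <- length(genes)
  n_hit <- sum(hit)
  if (n_hit == 0) {
    stop("gene set shares no genes with the ranked list", call. = FALSE)
  }
  if (n_hit == n) {
    stop("gene set covers the whole ranked list; misses undefined",
         call. = FALSE)
  }
  w <- abs(stats_)^p
  nr <- sum(w[hit])
  inc <- if (nr == 0) rep(1 / n_hit, n) else w / nr
  step <- ifelse(hit, inc, -1 / (n - n_hit))
  running <- cumsum(step)
  es <- running[which.max(abs(running))]
  list(es = es, running = running)
}

# all ways to relabel the pooled samples into (H, L) of the observed
# sizes; column k of the result gives the H indices of partition k
all_partitions <- function(n_pool, n_h) {
  utils::combn(n_pool, n_h)
}

#' Gene-set enrichment with a phenotype-permutation null
#'
#' For each gene set: computes the observed enrichment score on the
#' H-vs-L ranking, then permutes the H/L labels within the pooled
#' samples (class sizes preserved), re-ranks and re-scores. The
#' normalized enrichment score is ES divided by the mean |permuted ES|
#' of matching sign; the nominal p-value is the fraction of same-sign
#' permuted ES at least as extreme; the FDR q-value is the sign-
#' stratified ratio of the permuted-NES tail fraction to the observed-
#' NES tail fraction, capped at 1.
#'
#' @param expression Expression matrix.
#' @param sets A `stratified_sets` object.
#' @param gene_sets Named list of gene-id vectors.
#' @param n_perm Number of label permutations (>= 1).
#' @param p Weight exponent for [enrichment_score()].
#' @param seed Integer seed.
#' @param statistic Ranking statistic, see [rank_genes()].
#' @param exhaustive If `TRUE`, enumerate all label partitions instead
#'   of sampling (small pools only); `n_perm` is then ignored.
#' @return Data.frame of class `enrichment_result`: one row per gene
#'   set with `set`, `size`, `es`, `nes`, `p_value`, `fdr_q`,
#'   `n_perm_used`; attribute `seed`.
#' @export
permutation_test <- function(expression, sets, gene_sets, n_perm = 1000,
                             p = 1, seed = 1,
                             statistic = c("signal_to_noise", "t_statistic"),
                             exhaustive = FALSE) {
  statistic <- match.arg(statistic)
  if (!exhaustive && n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  h_ids <- intersect(sets$H, colnames(expression))
  l_ids <- intersect(sets$L, colnames(expression))
  pool <- c(h_ids, l_ids)
  n_h <- length(h_ids)
  ranked <- suppressWarnings(rank_genes(expression, sets, statistic))
  usable <- vapply(gene_sets, function(gs)
    sum(ranked$gene %in% gs) > 0 && sum(!(ranked$gene %in% gs)) > 0,
    logical(1))
  if (!all(usable)) {
    stop(sprintf("gene set(s) with no usable overlap: %s",
                 paste(names(gene_sets)[!usable], collapse = ", ")),
         call. = FALSE)
  }
  es_obs <- vapply(gene_sets, function(gs)
    enrichment_score(ranked, gs, p)$es, numeric(1))

  # permutation ES matrix: sets x permutations
  if (exhaustive) {
    parts <- all_partitions(length(pool), n_h)
    n_used <- ncol(parts)
    perm_h <- lapply(seq_len(n_used), function(k) pool[parts[, k]])
  } else {
    set.seed(seed)
    n_used <- n_perm
    perm_h <- lapply(seq_len(n_perm), function(k) sample(pool, n_h))
  }
  es_perm <- matrix(NA_real_, length(gene_sets), n_used,
                    dimnames = list(names(gene_sets), NULL))
  sub <- expression[, pool, drop = FALSE]
  for (k in seq_len(n_used)) {
    hk <- perm_h[[k]]
    lk <- setdiff(pool, hk)
    fake <- list(H = hk, L = lk)
    rk <- suppressWarnings(rank_genes(sub, fake, statistic))
    es_perm[, k] <- vapply(gene_sets, function(gs)
      enrichment_score(rk, gs, p)$es, numeric(1))
  }

  # NES: ES / mean(|same-sign permuted ES|), sign-stratified per set
  nes_obs <- numeric(length(es_obs))
  nes_perm <- matrix(NA_real_, nrow(es_perm), ncol(es_perm))
  p_nom <- numeric(length(es_obs))
  for (i in seq_along(es_obs)) {
    e <- es_obs[i]
    pe <- es_perm[i, ]
    pos_mean <- mean(pe[pe >= 0])
    neg_mean <- mean(abs(pe[pe < 0]))
    norm_of <- function(v) {
      ifelse(v >= 0,
             if (is.nan(pos_mean) || pos_mean == 0) NA_real_ else v / pos_mean,
             if (is.nan(neg_mean) || neg_mean == 0) NA_real_ else v / neg_mean)
    }
    nes_obs[i] <- norm_of(e)
    nes_perm[i, ] <- norm_of(pe)
    same <- if (e >= 0) pe[pe >= 0] else pe[pe < 0]
    p_nom[i] <- if (length(same) == 0) NA_real_ else
      mean(abs(same) >= abs(e))
  }

  # FDR q: sign-stratified tail-fraction ratio
  q <- numeric(length(es_obs))
  all_perm <- as.vector(nes_perm)
  for (i in seq_along(es_obs)) {
    ne <- nes_obs[i]
    if (is.na(ne)) { q[i] <- NA_real_; next }
    if (ne >= 0) {
      denom_pool <- nes_obs[!is.na(nes_obs) & nes_obs >= 0]
      perm_pool <- all_perm[!is.na(all_perm) & all_perm >= 0]
      num <- mean(perm_pool >= ne)
      den <- mean(denom_pool >= ne)
    } else {
      denom_pool <- nes_obs[!is.na(nes_obs) & nes_obs < 0]
      perm_pool <- all_perm[!is.na(all_perm) & all_perm < 0]
      num <- mean(perm_pool <= ne)
      den <- mean(denom_pool <= ne)
    }
    q[i] <- if (is.nan(num) || is.nan(den) || den == 0) NA_real_ else
      min(1, num / den)
  }

  structure(data.frame(set = names(gene_sets),
                       size = vapply(gene_sets, function(gs)
                         sum(ranked$gene %in% gs), integer(1)),
                       es = es_obs, nes = nes_obs, p_value = p_nom,
                       fdr_q = q, n_perm_used = n_used,
                       row.names = NULL, stringsAsFactors = FALSE),
            class = c("enrichment_result", "data.frame"),
            seed = seed, weight = p, statistic = statistic)
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("enrichment_result: %d gene sets, %d permutations (%s, p = %g)\n",
              nrow(x), x$n_perm_used[1], attr(x, "statistic"),
              attr(x, "weight")))
  print.data.frame(x[order(x$p_value), ], row.names = FALSE, digits = 4)
  invisible(x)
}

#' Export an enrichment result as TSV
#'
#' @param x An `enrichment_result`.
#' @param path Output path.
#' @export
write_enrichment_result <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
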