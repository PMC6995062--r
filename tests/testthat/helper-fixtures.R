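# Small fixture builders and independent brute-force oracles shared by
# the test files. Oracles are deliberately naive (per-sample loops and
# explicit conditionals) and never call the code paths they check.

tiny_beta <- function() {
  matrix(c(0.05, 0.20, 0.50, 0.90,
           0.10, NA,   0.61, 0.30,
           0.15, 0.15, 0.60, 0.60),
         nrow = 3, byrow = TRUE,
         dimnames = list(c("cg01", "cg02", "cg03"), paste0("s", 1:4)))
}

tiny_manifest <- function() {
  data.frame(sample_id = paste0("s", 1:4),
             cohort = c("BRCA", "BRCA", "OV", "OV"),
             subset = c("PT", "SN", "PT", "SN"),
             stringsAsFactors = FALSE)
}

write_tsv_lines <- function(lines) {
  tf <- tempfile(fileext = ".tsv")
  writeLines(lines, tf)
  tf
}

# brute-force bin classifier: explicit conditionals
oracle_bin <- function(b) {
  if (is.na(b)) return(NA_character_)
  if (b <= 0.15) "UM"
  else if (b <= 0.3) "IM"
  else if (b <= 0.6) "LM"
  else "HM"
}

# per-sample counting oracle for subset metrics; returns long data.frame
oracle_metrics <- function(beta, manifest, min_n = 5) {
  groups <- unique(manifest[, c("cohort", "subset")])
  out <- list()
  for (g in seq_len(nrow(groups))) {
    ids <- manifest$sample_id[manifest$cohort == groups$cohort[g] &
                              manifest$subset == groups$subset[g]]
    for (p in rownames(beta)) {
      counts <- c(UM = 0, IM = 0, LM = 0, HM = 0)
      n_eval <- 0
      for (s in ids) {
        bin <- oracle_bin(beta[p, s])
        if (!is.na(bin)) {
          counts[bin] <- counts[bin] + 1
          n_eval <- n_eval + 1
        }
      }
      vals <- if (n_eval >= min_n) {
        pc <- 100 * counts / n_eval
        c(pc, pc[["UM"]] + pc[["IM"]], pc[["LM"]] + pc[["HM"]])
      } else rep(NA_real_, 6)
      out[[length(out) + 1]] <- data.frame(
        probe_id = p, cohort = groups$cohort[g], subset = groups$subset[g],
        metric = c("%UM", "%IM", "%LM", "%HM", "%UM+%IM", "%LM+%HM"),
        value = unname(vals), n_eval = n_eval, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

# naive nested-loop filter evaluator over a long-format metric table
oracle_chain <- function(criteria, long, target, missing_policy) {
  probes <- unique(long$probe_id)
  cohorts_all <- unique(long$cohort)
  res <- matrix(FALSE, length(probes), length(criteria),
                dimnames = list(probes, NULL))
  for (pi in seq_along(probes)) {
    for (ci in seq_along(criteria)) {
      cr <- criteria[[ci]]
      cohorts <- if (identical(cr$cohort, "ALL_EXCEPT")) {
        sort(unique(long$cohort[long$subset == cr$subset &
                                long$cohort != target]))
      } else cr$cohort
      vals <- c()
      any_na <- FALSE
      for (co in cohorts) {
        v <- long$value[long$probe_id == probes[pi] & long$cohort == co &
                        long$subset == cr$subset & long$metric == cr$metric]
        if (length(v) == 0 || is.na(v)) any_na <- TRUE else vals <- c(vals, v)
      }
      if (missing_policy == "fail_probe" && any_na) next
      if (length(vals) == 0) next
      cmp <- function(v) if (cr$comparator == ">=") v >= cr$threshold
                         else v <= cr$threshold
      res[pi, ci] <- if (cr$aggregator == "every_cohort") all(cmp(vals))
                     else cmp(mean(vals))
    }
  }
  data.frame(probe_id = probes, pass = apply(res, 1, all),
             stringsAsFactors = FALSE)
}

# explicit step-by-step running-sum walk for the enrichment score
oracle_es_walk <- function(genes, stats, set, p) {
  hit <- genes %in% set
  w <- abs(stats)^p
  nr <- sum(w[hit])
  running <- numeric(length(genes))
  acc <- 0
  for (i in seq_along(genes)) {
    if (hit[i]) {
      acc <- acc + (if (nr == 0) 1 / sum(hit) else w[i] / nr)
    } else {
      acc <- acc - 1 / (length(genes) - sum(hit))
    }
    running[i] <- acc
  }
  running[which.max(abs(running))]
}

# independent signal-to-noise + ranking for the exhaustive-permutation
# oracle: recomputes everything with its own loops
oracle_s2n_rank <- function(expr, h_ids, l_ids) {
  s <- sapply(rownames(expr), function(g) {
    xh <- expr[g, h_ids]; xl <- expr[g, l_ids]
    sh <- max(sd(xh), 0.2 * abs(mean(xh)))
    sl <- max(sd(xl), 0.2 * abs(mean(xl)))
    (mean(xh) - mean(xl)) / (sh + sl)
  })
  ord <- order(-s, rownames(expr), method = "radix")
  list(genes = rownames(expr)[ord], stats = unname(s[ord]))
}

# fully independent exhaustive-permutation oracle: naive ranking + walk
# over every label partition of the pooled samples
exhaustive_oracle <- function(expr, h_ids, l_ids, gene_set, p = 1) {
  pool <- c(h_ids, l_ids)
  rk <- oracle_s2n_rank(expr[, pool], h_ids, l_ids)
  es_obs <- oracle_es_walk(rk$genes, rk$stats, gene_set, p)
  parts <- combn(length(pool), length(h_ids))
  es_perm <- apply(parts, 2, function(ix) {
    h <- pool[ix]; l <- setdiff(pool, h)
    r <- oracle_s2n_rank(expr[, pool], h, l)
    oracle_es_walk(r$genes, r$stats, gene_set, p)
  })
  same <- if (es_obs >= 0) es_perm[es_perm >= 0] else es_perm[es_perm < 0]
  list(es = es_obs, p = mean(abs(same) >= abs(es_obs)))
}

# random long-format metric table: multinomial bin counts per probe/group,
# a fraction of groups unevaluable (all-NA metrics)
random_metric_long <- function(n_probes, cohorts, subsets = c("PT", "SN"),
                               p_missing = 0.1) {
  out <- list()
  for (co in cohorts) for (su in subsets) {
    for (p in sprintf("p%03d", seq_len(n_probes))) {
      n <- sample(5:30, 1)
      if (runif(1) < p_missing) {
        vals <- rep(NA_real_, 6); n <- sample(0:4, 1)
      } else {
        cnt <- as.vector(rmultinom(1, n, runif(4)))
        pc <- 100 * cnt / n
        vals <- c(pc, pc[1] + pc[2], pc[3] + pc[4])
      }
      out[[length(out) + 1]] <- data.frame(
        probe_id = p, cohort = co, subset = su,
        metric = c("%UM", "%IM", "%LM", "%HM", "%UM+%IM", "%LM+%HM"),
        value = vals, n_eval = n, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

random_criteria <- function(k, cohorts, target) {
  lapply(seq_len(k), function(i) {
    all_except <- runif(1) < 0.5
    filter_criterion(
      metric = sample(c("%UM", "%IM", "%LM", "%HM", "%UM+%IM", "%LM+%HM"), 1),
      cohort = if (all_except) "ALL_EXCEPT" else sample(cohorts, 1),
      subset = sample(c("PT", "SN"), 1),
      comparator = sample(c(">=", "<="), 1),
      threshold = runif(1, 0, 100),
      aggregator = if (all_except)
        sample(c("mean_over_cohorts", "every_cohort"), 1) else "single")
  })
}
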