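strat_fixture <- function(betas, ids = sprintf("s%02d", seq_along(betas)),
                          cohort = "BRCA") {
  b <- matrix(betas, 1, length(betas), dimnames = list("cg01", ids))
  mf <- data.frame(sample_id = ids, cohort = cohort, subset = "PT",
                   stringsAsFactors = FALSE)
  stratify(b, mf, "cg01", cohort, "PT")
}

test_that("mean +/- 1 SD stratification on hand-computed groups", {
  s <- strat_fixture(c(0.1, 0.5, 0.9))
  expect_equal(s$mean, 0.5)
  expect_equal(s$sd, 0.4)
  expect_equal(s$H, "s03")
  expect_equal(s$L, "s01")

  # inclusive thresholds: a sample exactly at mean + sd joins H
  s2 <- strat_fixture(c(0.2, 0.4, 0.6))
  expect_equal(s2$H, "s03")   # 0.6 == 0.4 + 0.2

  const <- strat_fixture(rep(0.5, 5))
  expect_length(const$H, 0)
  expect_length(const$L, 0)

  expect_error(strat_fixture(c(0.5, NA, NA, 0.4)), ">= 3")
})

test_that("H fraction matches the normal-tail oracle at n = 2000", {
  set.seed(8)
  n <- 2000
  b <- pmin(pmax(rnorm(n, 0.5, 0.1), 0), 1)
  s <- strat_fixture(b, ids = sprintf("s%04d", 1:n))
  p0 <- 1 - pnorm(1)
  half <- qnorm(0.995) * sqrt(p0 * (1 - p0) / n)
  expect_gt(length(s$H) / n, p0 - half)
  expect_lt(length(s$H) / n, p0 + half)
  expect_true(length(intersect(s$H, s$L)) == 0)
})

test_that("signal-to-noise ranking with sd floor and deterministic ties", {
  ex <- rbind(
    g1 = c(2, 2.5, 1.5, 2, 1, 1.5, 0.5, 1),       # means 2 vs 1, sd ~ 0.41
    g2 = c(5, 5, 5, 5, 5, 5, 5, 5),                # flat
    g3 = c(0, 0, 0, 0, 0, 0, 0, 0))                # flat at zero
  colnames(ex) <- sprintf("s%02d", 1:8)
  sets <- list(H = sprintf("s%02d", 1:4), L = sprintf("s%02d", 5:8))
  rl <- suppressWarnings(rank_genes(ex, sets))
  expect_equal(rl$gene[1], "g1")
  expect_equal(rl$statistic[rl$gene == "g2"], 0)   # floored sds, zero diff
  expect_equal(rl$statistic[rl$gene == "g3"], 0)
  # zero statistics tie-break lexicographically
  expect_equal(rl$gene[2:3], c("g2", "g3"))

  # plug-in value: means 2 and 1, both sds exactly 0.5 -> (2-1)/(0.5+0.5) = 1
  exact <- rbind(ga = c(1.5, 2, 2.5, 0.5, 1, 1.5))
  colnames(exact) <- sprintf("s%02d", 1:6)
  rl2 <- suppressWarnings(rank_genes(
    exact, list(H = sprintf("s%02d", 1:3), L = sprintf("s%02d", 4:6))))
  expect_equal(rl2$statistic, 1.0)

  expect_error(rank_genes(ex, list(H = c("s01", "s02"), L = sets$L)),
               ">= 3")
})

test_that("identical classes give all-zero statistics in gene-id order", {
  ex <- matrix(rep(c(3, 1, 2, 4), each = 6), 4, 6, byrow = TRUE,
               dimnames = list(c("gb", "ga", "gd", "gc"), sprintf("s%d", 1:6)))
  sets <- list(H = sprintf("s%d", 1:3), L = sprintf("s%d", 4:6))
  rl <- suppressWarnings(rank_genes(ex, sets))
  expect_true(all(rl$statistic == 0))
  expect_equal(rl$gene, c("ga", "gb", "gc", "gd"))
})

test_that("enrichment score matches the hand-walked running sum", {
  ranked <- data.frame(gene = c("g1", "g2", "g3", "g4", "g5"),
                       statistic = c(2, 1.5, 1, 0.5, 0.1),
                       stringsAsFactors = FALSE)
  # p = 0, set = top two: steps +1/2, +1/2, -1/3, -1/3, -1/3
  res <- enrichment_score(ranked, c("g1", "g2"), p = 0)
  expect_equal(res$running, c(0.5, 1, 1 - 1 / 3, 1 - 2 / 3, 0),
               tolerance = 1e-12)
  expect_equal(res$es, 1, tolerance = 1e-12)

  # p = 1, same set: weights 2/3.5 and 1.5/3.5
  res1 <- enrichment_score(ranked, c("g1", "g2"), p = 1)
  walk <- cumsum(c(2 / 3.5, 1.5 / 3.5, -1 / 3, -1 / 3, -1 / 3))
  expect_equal(res1$running, walk, tolerance = 1e-12)
  expect_equal(res1$es, 1, tolerance = 1e-12)

  # bottom-ranked set: negative score at any weight
  resb <- enrichment_score(ranked, c("g4", "g5"), p = 1)
  expect_lt(resb$es, 0)

  # reversing the list negates ES when p = 0
  rev_ranked <- ranked[5:1, ]
  expect_equal(enrichment_score(rev_ranked, c("g1", "g2"), p = 0)$es,
               -res$es, tolerance = 1e-12)

  expect_error(enrichment_score(ranked, c("zz"), p = 0), "no genes")
})

test_that("ES agrees with the brute-force walk on random instances", {
  set.seed(17)
  for (i in 1:20) {
    n <- sample(10:60, 1)
    stats_ <- sort(rnorm(n, sd = 2), decreasing = TRUE)
    genes <- sprintf("g%03d", 1:n)
    ranked <- data.frame(gene = genes, statistic = stats_,
                         stringsAsFactors = FALSE)
    set <- sample(genes, sample(2:(n - 1), 1))
    p <- sample(c(0, 1, 1.5), 1)
    expect_equal(enrichment_score(ranked, set, p)$es,
                 oracle_es_walk(genes, stats_, set, p), tolerance = 1e-12)
  }
})

test_that("appending zero-statistic misses changes ES only via the denominator", {
  ranked <- data.frame(gene = sprintf("g%d", 1:6),
                       statistic = c(3, 2, 1, 0.5, 0.2, 0.1))
  set <- c("g1", "g3")
  ext <- rbind(ranked, data.frame(gene = sprintf("x%d", 1:4), statistic = 0))
  for (p in c(0, 1)) {
    expect_equal(enrichment_score(ext, set, p)$es,
                 oracle_es_walk(ext$gene, ext$statistic, set, p),
                 tolerance = 1e-12)
  }
})

test_that("ES matches fgsea's statistic on a shared random instance", {
  skip_if_not_installed("fgsea")
  set.seed(23)
  n <- 40
  stats_ <- sort(rnorm(n), decreasing = TRUE)
  genes <- sprintf("g%02d", 1:n)
  ranked <- data.frame(gene = genes, statistic = stats_)
  idx <- sort(sample(n, 8))
  mine <- enrichment_score(ranked, genes[idx], p = 1)$es
  theirs <- fgsea::calcGseaStat(stats_, idx, gseaParam = 1)
  expect_equal(mine, theirs, tolerance = 1e-10)
})

test_that("nominal p equals exhaustive enumeration on small pools", {
  set.seed(41)
  for (sizes in list(c(3, 3), c(4, 3), c(4, 4))) {
    n <- sum(sizes)
    ex <- matrix(rnorm(12 * n), 12, n,
                 dimnames = list(sprintf("g%02d", 1:12), sprintf("s%02d", 1:n)))
    h <- sprintf("s%02d", seq_len(sizes[1]))
    l <- sprintf("s%02d", sizes[1] + seq_len(sizes[2]))
    sets <- list(SET = sprintf("g%02d", c(1, 4, 7)))
    strat <- list(H = h, L = l)
    got <- permutation_test(ex, strat, sets, p = 1, exhaustive = TRUE)
    want <- exhaustive_oracle(ex, h, l, sets$SET, p = 1)
    expect_equal(got$es, want$es, tolerance = 1e-12)
    expect_equal(got$p_value, want$p, tolerance = 1e-12)
    expect_equal(got$n_perm_used, choose(n, sizes[1]))
  }
})

test_that("permutation results are seed-deterministic", {
  set.seed(3)
  ex <- matrix(rnorm(30 * 14), 30, 14,
               dimnames = list(sprintf("g%02d", 1:30), sprintf("s%02d", 1:14)))
  strat <- list(H = sprintf("s%02d", 1:7), L = sprintf("s%02d", 8:14))
  sets <- list(A = sprintf("g%02d", 1:5), B = sprintf("g%02d", 10:18))
  r1 <- permutation_test(ex, strat, sets, n_perm = 50, seed = 9)
  r2 <- permutation_test(ex, strat, sets, n_perm = 50, seed = 9)
  expect_identical(r1, r2)
  expect_error(permutation_test(ex, strat, sets, n_perm = 0, seed = 1),
               "n_perm")
  expect_error(permutation_test(ex, strat, list(Z = "nope"), n_perm = 5,
                                seed = 1), "overlap")
})

test_that("linked genes dominate the top ranks of the H-vs-L ranking", {
  wins <- 0
  for (s in 1:10) {
    plant <- plant_spec(rho = 0.8, n_linked_genes = 5)
    specs <- list(cohort_spec("BRCA", n_pt = 80, n_sn = 10),
                  cohort_spec("BLOOD", n_pb = 10))
    sim <- generate_cohorts(specs, plant, n_background_probes = 2, seed = s)
    ex <- generate_expression(sim$beta, sim$manifest, plant, n_genes = 60,
                              seed = s, probe = "mk_001")
    strat <- stratify(sim$beta, sim$manifest, "mk_001", "BRCA", "PT")
    rl <- suppressWarnings(rank_genes(ex, strat))
    linked_rank <- match(attr(ex, "linked_genes"), rl$gene)
    other_rank <- setdiff(seq_len(nrow(rl)), linked_rank)
    # positive-rho linked genes should sit above the median unlinked rank
    wins <- wins + (mean(linked_rank) < mean(other_rank))
  }
  expect_gte(wins, 9)
})
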