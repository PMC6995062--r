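make_metrics <- function(df) subset_metric_table(df)

# metric table with one probe and explicit %HM / %UM values per group
simple_long <- function() {
  rows <- list()
  add <- function(cohort, subset, um, hm) {
    rows[[length(rows) + 1]] <<- data.frame(
      probe_id = "cg01", cohort = cohort, subset = subset,
      metric = c("%UM", "%IM", "%LM", "%HM", "%UM+%IM", "%LM+%HM"),
      value = c(um, 0, 100 - um - hm, hm, um, 100 - um),
      n_eval = 50, stringsAsFactors = FALSE)
  }
  add("BRCA", "PT", um = 10, hm = 35)
  add("BRCA", "SN", um = 45, hm = 5)
  add("OV", "PT", um = 30, hm = 10)
  add("LUAD", "PT", um = 50, hm = 10)
  add("KIRC", "PT", um = 50, hm = 10)
  add("OV", "SN", um = 80, hm = 0)
  add("LUAD", "SN", um = 80, hm = 0)
  add("KIRC", "SN", um = 80, hm = 0)
  add("GSE42861", "PB", um = 99, hm = 0)
  do.call(rbind, rows)
}

test_that("single-cohort criterion compares the one group's metric", {
  sm <- make_metrics(simple_long())
  crit <- filter_criterion("%HM", "BRCA", "PT", ">=", 30)
  res <- evaluate_criterion(crit, sm, "cg01", "BRCA")
  expect_true(res$pass)
  expect_equal(res$value, 35)

  res0 <- evaluate_criterion(filter_criterion("%IM", "BRCA", "PT", ">=", 0),
                             sm, "cg01", "BRCA")
  expect_true(res0$pass)
})

test_that("mean_over_cohorts averages per-cohort metrics unweighted", {
  sm <- make_metrics(simple_long())
  crit <- filter_criterion("%UM", "ALL_EXCEPT", "PT", ">=", 40,
                           "mean_over_cohorts")
  res <- evaluate_criterion(crit, sm, "cg01", "BRCA")
  # hand mean over OV/LUAD/KIRC PTs: (30 + 50 + 50) / 3
  expect_equal(res$value, mean(c(30, 50, 50)))
  expect_equal(res$value, 43 + 1 / 3)
  expect_true(res$pass)

  strict <- filter_criterion("%UM", "ALL_EXCEPT", "PT", ">=", 40,
                             "every_cohort")
  expect_false(evaluate_criterion(strict, sm, "cg01", "BRCA")$pass)
})

test_that("the five-filter preset matches the printed chain", {
  ch <- brca_preset("BRCA", "GSE42861")
  expect_length(ch$criteria, 5)
  expect_equal(vapply(ch$criteria, `[[`, numeric(1), "threshold"),
               c(30, 40, 40, 40, 98))
  a <- ch$criteria[[1]]
  expect_equal(a$metric, "%HM"); expect_equal(a$cohort, "BRCA")
  expect_equal(a$subset, "PT"); expect_equal(a$comparator, ">=")
  e <- ch$criteria[[5]]
  expect_equal(e$metric, "%UM"); expect_equal(e$cohort, "GSE42861")
  expect_equal(e$subset, "PB"); expect_equal(e$threshold, 98)
  expect_equal(ch$criteria[[3]]$aggregator, "mean_over_cohorts")
  expect_equal(ch$criteria[[3]]$cohort, "ALL_EXCEPT")

  sm <- make_metrics(simple_long())
  rep <- apply_chain(ch, sm, "BRCA")
  expect_true(rep$pass[rep$probe_id == "cg01"])
})

test_that("unevaluable groups follow the missing-metric policy", {
  long <- simple_long()
  long$value[long$cohort == "GSE42861"] <- NA
  sm <- make_metrics(long)
  ch <- brca_preset("BRCA", "GSE42861")
  rep_fail <- apply_chain(ch, sm, "BRCA")
  expect_false(rep_fail$pass[1])
  expect_false(rep_fail$pass_5[1])

  # a single-cohort criterion has no group to skip to: fails either way
  ch_skip <- brca_preset("BRCA", "GSE42861", missing_policy = "skip_group")
  expect_false(apply_chain(ch_skip, sm, "BRCA")$pass[1])

  # but a multi-cohort mean drops the unevaluable cohort under skip_group
  long2 <- simple_long()
  long2$value[long2$cohort == "OV" & long2$subset == "PT"] <- NA
  sm2 <- make_metrics(long2)
  crit <- filter_criterion("%UM", "ALL_EXCEPT", "PT", ">=", 45,
                           "mean_over_cohorts")
  expect_false(evaluate_criterion(crit, sm2, "cg01", "BRCA",
                                  "fail_probe")$pass)
  res_skip <- evaluate_criterion(crit, sm2, "cg01", "BRCA", "skip_group")
  expect_true(res_skip$pass)          # mean(50, 50) = 50 >= 45
  expect_equal(res_skip$value, 50)
})

test_that("empty chains and vacuous selectors error", {
  expect_error(filter_chain(), "non-empty")
  sm <- make_metrics(simple_long())
  crit <- filter_criterion("%UM", "NOPE", "PT", ">=", 10)
  expect_error(evaluate_criterion(crit, sm, "cg01", "BRCA"), "no cohort")
  expect_error(filter_criterion("%UM", "BRCA", "PT", ">=", 101), "\\[0, 100\\]")
  expect_error(filter_criterion("%UM", "ALL_EXCEPT", "PT", ">=", 10,
                                aggregator = "single"), "explicit cohort")
})

test_that("raising a >=-threshold never grows the pass set", {
  set.seed(21)
  long <- random_metric_long(40, c("BRCA", "OV", "LUAD"), p_missing = 0)
  sm <- make_metrics(long)
  prev <- NULL
  for (thr in seq(0, 100, by = 10)) {
    ch <- filter_chain(filter_criterion("%LM+%HM", "BRCA", "PT", ">=", thr))
    cur <- apply_chain(ch, sm, "BRCA")
    ids <- cur$probe_id[cur$pass]
    if (!is.null(prev)) expect_true(all(ids %in% prev))
    prev <- ids
  }
})

test_that("apply_chain matches the nested-loop oracle on random tables", {
  set.seed(31)
  cohorts <- sprintf("C%02d", 1:8)
  for (rep_i in 1:3) {
    long <- random_metric_long(60, cohorts, p_missing = 0.15)
    sm <- make_metrics(long)
    crits <- random_criteria(4, cohorts, target = "C01")
    for (pol in c("fail_probe", "skip_group")) {
      ch <- filter_chain(crits, missing_policy = pol)
      got <- apply_chain(ch, sm, "C01")
      want <- oracle_chain(crits, long, "C01", pol)
      expect_equal(got$pass, want$pass[match(got$probe_id, want$probe_id)],
                   info = sprintf("rep %d policy %s", rep_i, pol))
    }
  }
})

test_that("filter chains round-trip through the YAML config", {
  ch <- brca_preset("BRCA", "BLOOD", missing_policy = "skip_group")
  tf <- tempfile(fileext = ".yaml")
  write_filter_chain(ch, tf)
  ch2 <- read_filter_chain(tf)
  expect_equal(ch2$missing_policy, "skip_group")
  expect_equal(lapply(ch2$criteria, unclass), lapply(ch$criteria, unclass))
})

test_that("planted markers pass and decoys each fail one filter", {
  sim <- generate_cohorts(seed = 77)
  sm <- subset_metrics(sim$beta, sim$manifest, min_n = 5)
  rep <- apply_chain(brca_preset("BRCA", "BLOOD"), sm, "BRCA")
  truth <- sim$truth
  pass <- rep$pass[match(truth$probe_id, rep$probe_id)]
  expect_true(all(pass[truth$class == "marker"]))
  expect_true(all(!pass[truth$class != "marker"]))
  # decoys fail the one filter they were planted to violate
  fail_col <- c(decoy_pt_low = "pass_1", decoy_sn_high = "pass_2",
                decoy_pan_pt = "pass_3", decoy_pan_sn = "pass_4",
                decoy_blood_meth = "pass_5")
  for (cl in names(fail_col)) {
    rows <- rep[match(truth$probe_id[truth$class == cl], rep$probe_id), ]
    expect_true(all(!rows[[fail_col[cl]]]), info = cl)
    other <- setdiff(paste0("pass_", 1:5), fail_col[cl])
    for (oc in other) expect_true(all(rows[[oc]]), info = paste(cl, oc))
  }
})
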