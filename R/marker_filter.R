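#' Declarative filter criterion on subset metrics
#'
#' One criterion of the general form V_P(C, S) >= n: a percentage metric
#' for probe P within subset S of cohort C compared against a threshold
#' n in \[0, 100\]. The cohort selector is either an explicit cohort
#' name or `"ALL_EXCEPT"` (every cohort in the table other than the
#' run's target cohort). For multi-cohort selectors the aggregator
#' decides how per-cohort values combine: `mean_over_cohorts` takes the
#' unweighted mean of the per-cohort metric before comparing, while
#' `every_cohort` requires each selected cohort to pass on its own.
#'
#' @param metric One of `%UM`, `%IM`, `%LM`, `%HM`, `%UM+%IM`, `%LM+%HM`.
#' @param cohort Explicit cohort name, or `"ALL_EXCEPT"`.
#' @param subset One of `PT`, `SN`, `PB`, `Met`, `Imm`.
#' @param comparator `">="` or `"<="`.
#' @param threshold Percentage in \[0, 100\].
#' @param aggregator `"single"`, `"mean_over_cohorts"` or `"every_cohort"`;
#'   `"single"` requires an explicit cohort name.
#' @return An object of class `filter_criterion`.
#' @export
filter_criterion <- function(metric, cohort, subset, comparator, threshold,
                             aggregator = if (identical(cohort, "ALL_EXCEPT"))
                               "mean_over_cohorts" else "single") {
  metric <- match.arg(metric, METRIC_NAMES)
  subset <- match.arg(subset, SUBSET_LEVELS)
  comparator <- match.arg(comparator, c(">=", "<="))
  aggregator <- match.arg(aggregator,
                          c("single", "mean_over_cohorts", "every_cohort"))
  if (!is.numeric(threshold) || threshold < 0 || threshold > 100) {
    stop("threshold must be a percentage in [0, 100]", call. = FALSE)
  }
  if (aggregator == "single" && identical(cohort, "ALL_EXCEPT")) {
    stop("aggregator 'single' requires an explicit cohort name", call. = FALSE)
  }
  structure(list(metric = metric, cohort = cohort, subset = subset,
                 comparator = comparator, threshold = threshold,
                 aggregator = aggregator),
            class = "filter_criterion")
}

#' @export
format.filter_criterion <- function(x, ...) {
  coh <- if (x$aggregator == "single") x$cohort else
    sprintf("%s(%s)", if (x$aggregator == "mean_over_cohorts") "Ave" else
              "Every", x$cohort)
  sprintf("%s (%s, %s) %s %g", x$metric, coh, x$subset, x$comparator,
          x$threshold)
}

#' @export
print.filter_criterion <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Conjunctive chain of filter criteria
#'
#' Criteria combine conjunctively: a probe passes the chain only if it
#' passes every criterion. `missing_policy` decides how a criterion
#' treats groups that are unevaluable (metric `NA`): `"fail_probe"`
#' (default, conservative — a probe unevaluable in a referenced group
#' fails that criterion) or `"skip_group"` (unevaluable cohorts are
#' dropped from multi-cohort aggregation; a criterion with no evaluable
#' group left fails).
#'
#' @param ... `filter_criterion` objects (or one list of them).
#' @param missing_policy `"fail_probe"` or `"skip_group"`.
#' @return An object of class `filter_chain`.
#' @export
filter_chain <- function(..., missing_policy = c("fail_probe", "skip_group")) {
  missing_policy <- match.arg(missing_policy)
  crits <- list(...)
  if (length(crits) == 1 && !inherits(crits[[1]], "filter_criterion")) {
    crits <- crits[[1]]
  }
  if (length(crits) == 0) stop("filter chain must be non-empty", call. = FALSE)
  ok <- vapply(crits, inherits, logical(1), "filter_criterion")
  if (!all(ok)) stop("all chain elements must be filter_criterion objects",
                     call. = FALSE)
  structure(list(criteria = crits, missing_policy = missing_policy),
            class = "filter_chain")
}

#' @export
print.filter_chain <- function(x, ...) {
  cat(sprintf("filter_chain of %d criteria (missing policy: %s)\n",
              length(x$criteria), x$missing_policy))
  for (i in seq_along(x$criteria)) {
    cat(sprintf("  %d) %s\n", i, format(x$criteria[[i]])))
  }
  invisible(x)
}

#' The five-filter breast-cancer marker preset
#'
#' The published chain selecting CpG sites highly methylated in target
#' primary tumors yet unmethylated in target solid normals, in other
#' cancer cohorts (both PT and SN, averaged across cohorts), and almost
#' completely unmethylated in peripheral blood:
#' (a) %HM(target, PT) >= 30; (b) %UM(target, SN) >= 40;
#' (c) mean over non-target cohorts of %UM(PT) >= 40;
#' (d) mean over non-target cohorts of %UM(SN) >= 40;
#' (e) %UM(blood cohort, PB) >= 98.
#'
#' @param target Target cohort name (e.g. `"BRCA"`).
#' @param blood_cohort Peripheral-blood cohort name.
#' @param aggregator Aggregator for filters (c) and (d);
#'   `"mean_over_cohorts"` (default, the "Average" reading) or the
#'   stricter `"every_cohort"`.
#' @param missing_policy Passed to [filter_chain()].
#' @return A `filter_chain` of the five criteria.
#' @export
brca_preset <- function(target = "BRCA", blood_cohort = "BLOOD",
                        aggregator = c("mean_over_cohorts", "every_cohort"),
                        missing_policy = c("fail_probe", "skip_group")) {
  aggregator <- match.arg(aggregator)
  filter_chain(
    filter_criterion("%HM", target, "PT", ">=", 30),
    filter_criterion("%UM", target, "SN", ">=", 40),
    filter_criterion("%UM", "ALL_EXCEPT", "PT", ">=", 40, aggregator),
    filter_criterion("%UM", "ALL_EXCEPT", "SN", ">=", 40, aggregator),
    filter_criterion("%UM", blood_cohort, "PB", ">=", 98),
    missing_policy = match.arg(missing_policy)
  )
}

# resolve the cohorts a criterion refers to, given the metric table and
# target cohort; only cohorts that actually carry the criterion's subset
resolve_cohorts <- function(criterion, metrics, target_cohort) {
  groups <- metrics$groups
  if (identical(criterion$cohort, "ALL_EXCEPT")) {
    cohorts <- unique(groups$cohort[groups$subset == criterion$subset &
                                    groups$cohort != target_cohort])
  } else {
    cohorts <- intersect(criterion$cohort,
                         groups$cohort[groups$subset == criterion$subset])
  }
  if (length(cohorts) == 0) {
    stop(sprintf("criterion '%s' selects no cohort with subset %s",
                 format(criterion), criterion$subset), call. = FALSE)
  }
  sort(cohorts)
}

#' Evaluate one criterion for one probe
#'
#' @param criterion A `filter_criterion`.
#' @param metrics A `subset_metrics` table.
#' @param probe Probe id present in `metrics`.
#' @param target_cohort Target cohort name (resolves `"ALL_EXCEPT"`).
#' @param missing_policy `"fail_probe"` or `"skip_group"`.
#' @return List with `pass` (logical) and `value` (the evaluated metric,
#'   `NA` if nothing was evaluable).
#' @export
evaluate_criterion <- function(criterion, metrics, probe, target_cohort,
                               missing_policy = c("fail_probe", "skip_group")) {
  missing_policy <- match.arg(missing_policy)
  if (!probe %in% rownames(metrics$metrics)) {
    stop(sprintf("probe '%s' not in metric table", probe), call. = FALSE)
  }
  cohorts <- resolve_cohorts(criterion, metrics, target_cohort)
  vals <- vapply(cohorts, function(co)
    metric_value(metrics, probe, co, criterion$subset, criterion$metric),
    numeric(1))
  cmp <- function(v) if (criterion$comparator == ">=")
    v >= criterion$threshold else v <= criterion$threshold
  if (any(is.na(vals)) && missing_policy == "fail_probe") {
    return(list(pass = FALSE, value = NA_real_))
  }
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0) return(list(pass = FALSE, value = NA_real_))
  if (criterion$aggregator == "every_cohort") {
    list(pass = all(cmp(vals)), value = if (criterion$comparator == ">=")
      min(vals) else max(vals))
  } else {
    # single cohort is the one-element mean
    v <- mean(vals)
    list(pass = cmp(v), value = v)
  }
}

#' Apply a filter chain to every probe of a metric table
#'
#' Evaluates the chain conjunctively for every probe. All criteria are
#' evaluated for every probe (no short-circuit) so the report carries a
#' full audit trail of per-criterion decisions and backing values.
#'
#' @param chain A `filter_chain`.
#' @param metrics A `subset_metrics` table.
#' @param target_cohort Target cohort name.
#' @return An object of class `marker_report`: a data.frame with one row
#'   per probe, logical `pass_k` and numeric `value_k` columns per
#'   criterion, and an overall `pass` column; attributes `chain`,
#'   `target_cohort` and `funnel` (candidate count after criteria
#'   1..k applied conjunctively).
#' @export
apply_chain <- function(chain, metrics, target_cohort) {
  stopifnot(inherits(chain, "filter_chain"))
  probes <- rownames(metrics$metrics)
  k <- length(chain$criteria)
  pass <- matrix(FALSE, length(probes), k)
  value <- matrix(NA_real_, length(probes), k)
  for (j in seq_len(k)) {
    crit <- chain$criteria[[j]]
    cohorts <- resolve_cohorts(crit, metrics, target_cohort)
    labs <- paste(cohorts, crit$subset, sep = ".")
    gi <- match(labs, metrics$groups$label)
    vals <- metrics$metrics[, gi, crit$metric, drop = FALSE]
    dim(vals) <- c(length(probes), length(gi))
    any_na <- rowSums(is.na(vals)) > 0
    cmp <- function(v) if (crit$comparator == ">=")
      v >= crit$threshold else v <= crit$threshold
    if (crit$aggregator == "every_cohort") {
      pm <- cmp(vals)
      if (chain$missing_policy == "fail_probe") {
        pass[, j] <- !any_na & rowSums(!pm, na.rm = TRUE) == 0 &
          rowSums(!is.na(vals)) > 0
      } else {
        pass[, j] <- rowSums(!pm, na.rm = TRUE) == 0 &
          rowSums(!is.na(vals)) > 0
      }
      ext <- if (crit$comparator == ">=") {
        suppressWarnings(apply(vals, 1, min, na.rm = TRUE))
      } else {
        suppressWarnings(apply(vals, 1, max, na.rm = TRUE))
      }
      ext[!is.finite(ext)] <- NA_real_
      value[, j] <- ext
      if (chain$missing_policy == "fail_probe") value[any_na, j] <- NA_real_
    } else {
      mv <- rowMeans(vals, na.rm = TRUE)
      mv[is.nan(mv)] <- NA_real_
      if (chain$missing_policy == "fail_probe") mv[any_na] <- NA_real_
      value[, j] <- mv
      pass[, j] <- !is.na(mv) & cmp(mv)
    }
  }
  report <- data.frame(probe_id = probes, stringsAsFactors = FALSE)
  for (j in seq_len(k)) {
    report[[paste0("pass_", j)]] <- pass[, j]
    report[[paste0("value_", j)]] <- value[, j]
  }
  report$pass <- rowSums(!pass) == 0
  funnel <- vapply(seq_len(k), function(j)
    sum(rowSums(!pass[, seq_len(j), drop = FALSE]) == 0), integer(1))
  structure(report, class = c("marker_report", "data.frame"),
            chain = chain, target_cohort = target_cohort,
            funnel = stats::setNames(funnel, paste0("after_", seq_len(k))))
}

#' @export
print.marker_report <- function(x, ...) {
  k <- length(attr(x, "chain")$criteria)
  cat(sprintf("marker_report: %d probes, %d criteria, %d passing\n",
              nrow(x), k, sum(x$pass)))
  cat("funnel (candidates after criteria 1..k):",
      paste(attr(x, "funnel"), collapse = " -> "), "\n")
  invisible(x)
}

#' Export a marker report as TSV
#'
#' @param x A `marker_report`.
#' @param path Output path.
#' @export
write_marker_report <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Serialize a filter chain to a YAML config
#'
#' @param chain A `filter_chain`.
#' @param path Output path.
#' @export
write_filter_chain <- function(chain, path) {
  obj <- list(
    missing_policy = chain$missing_policy,
    criteria = lapply(chain$criteria, function(cr)
      list(metric = cr$metric, cohort = cr$cohort, subset = cr$subset,
           aggregator = cr$aggregator, comparator = cr$comparator,
           threshold = cr$threshold))
  )
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' Read a filter chain from a YAML config
#'
#' @param path Path to a YAML file written by [write_filter_chain()] or
#'   hand-authored with the same fields.
#' @return A `filter_chain`.
#' @export
read_filter_chain <- function(path) {
  obj <- yaml::read_yaml(path)
  crits <- lapply(obj$criteria, function(cr)
    filter_criterion(cr$metric, cr$cohort, cr$subset, cr$comparator,
                     cr$threshold, cr$aggregator))
  filter_chain(crits, missing_policy = obj$missing_policy %||% "fail_probe")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
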