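#' Specify one synthetic cohort
#'
#' @param name Cohort code (e.g. `"BRCA"`, `"BLOOD"`).
#' @param n_pt,n_sn,n_pb Sample counts for the primary-tumor, solid-normal
#'   and peripheral-blood subsets (0 omits a subset).
#' @return A `cohort_spec` object.
#' @export
cohort_spec <- function(name, n_pt = 0, n_sn = 0, n_pb = 0) {
  stopifnot(n_pt >= 0, n_sn >= 0, n_pb >= 0)
  structure(list(name = name, n_pt = as.integer(n_pt),
                 n_sn = as.integer(n_sn), n_pb = as.integer(n_pb)),
            class = "cohort_spec")
}

#' Default synthetic cohort roster
#'
#' A target cohort with PT and SN subsets, five other tumor cohorts with
#' PT and SN, and one peripheral-blood cohort — small enough that the
#' full pipeline runs in seconds while percentages stay stable.
#'
#' @return List of `cohort_spec` objects.
#' @export
default_cohort_specs <- function() {
  list(
    cohort_spec("BRCA", n_pt = 60, n_sn = 40),
    cohort_spec("OV", n_pt = 40, n_sn = 30),
    cohort_spec("COADREAD", n_pt = 40, n_sn = 30),
    cohort_spec("LUAD", n_pt = 40, n_sn = 30),
    cohort_spec("PRAD", n_pt = 40, n_sn = 30),
    cohort_spec("KIRC", n_pt = 40, n_sn = 30),
    cohort_spec("BLOOD", n_pb = 100)
  )
}

#' Specify the planted signal structure
#'
#' Describes the probes planted into a synthetic beta matrix: marker
#' probes hypermethylated in the target cohort's primary tumors but
#' unmethylated in target solid normals, in other cohorts and (near
#' zero) in peripheral blood; decoy probe classes that each violate
#' exactly one of the five preset filters; background probes with a
#' cohort-shared baseline. Beta noise is drawn from beta distributions
#' parameterized by (mean, concentration): shape1 = mean * conc,
#' shape2 = (1 - mean) * conc.
#'
#' Covariate effects apply to marker probes in target-cohort primary
#' tumors: the per-sample beta mean is shifted additively by
#' `stage_effect * (stage - 1)` (stages I..IV coded 1..4) and by the
#' subtype effect (Basal lowest), then clipped to \[0.02, 0.98\].
#'
#' @param target_cohort,blood_cohort Cohort names the plant refers to.
#' @param n_markers Number of planted marker probes.
#' @param marker_pt Mean/concentration of marker beta in target PT.
#' @param low Mean/concentration of the unmethylated state (target SN,
#'   other cohorts, decoy low groups).
#' @param blood Mean/concentration of the peripheral-blood state.
#' @param decoy_high Mean/concentration of a decoy's hypermethylated group.
#' @param decoy_blood Mean/concentration of the blood-methylated decoy in
#'   blood.
#' @param decoys_per_class Decoy probes per violated filter (5 classes).
#' @param stage_effect Additive shift of marker PT beta mean per stage
#'   above I.
#' @param subtype_effects Named additive shifts per molecular subtype.
#' @param n_linked_genes Genes with planted correlation to marker 1's
#'   beta across target PT samples.
#' @param rho Planted methylation-expression correlation, in \[-1, 1\].
#' @return A `plant_spec` object.
#' @export
plant_spec <- function(target_cohort = "BRCA", blood_cohort = "BLOOD",
                       n_markers = 5,
                       marker_pt = c(mean = 0.7, conc = 25),
                       low = c(mean = 0.08, conc = 25),
                       blood = c(mean = 0.01, conc = 40),
                       decoy_high = c(mean = 0.7, conc = 25),
                       decoy_blood = c(mean = 0.4, conc = 25),
                       decoys_per_class = 3,
                       stage_effect = 0.04,
                       subtype_effects = c(Basal = -0.08, LumA = 0,
                                           LumB = 0.05, HER2 = 0.05),
                       n_linked_genes = 10, rho = 0.8) {
  for (p in list(marker_pt, low, blood, decoy_high, decoy_blood)) {
    stopifnot(p[["mean"]] > 0, p[["mean"]] < 1, p[["conc"]] > 0)
  }
  if (abs(rho) > 1) stop("rho must lie in [-1, 1]", call. = FALSE)
  structure(list(target_cohort = target_cohort, blood_cohort = blood_cohort,
                 n_markers = as.integer(n_markers), marker_pt = marker_pt,
                 low = low, blood = blood, decoy_high = decoy_high,
                 decoy_blood = decoy_blood,
                 decoys_per_class = as.integer(decoys_per_class),
                 stage_effect = stage_effect,
                 subtype_effects = subtype_effects,
                 n_linked_genes = as.integer(n_linked_genes), rho = rho),
            class = "plant_spec")
}

DECOY_CLASSES <- c("decoy_pt_low",     # fails %HM(target, PT) >= 30
                   "decoy_sn_high",    # fails %UM(target, SN) >= 40
                   "decoy_pan_pt",     # fails mean %UM(other, PT) >= 40
                   "decoy_pan_sn",     # fails mean %UM(other, SN) >= 40
                   "decoy_blood_meth") # fails %UM(blood, PB) >= 98

rbeta_mc <- function(n, mean, conc) {
  stats::rbeta(n, mean * conc, (1 - mean) * conc)
}

# per-probe-class beta mean for a (cohort, subset) group
class_group_mean <- function(class, cohort, subset, plant) {
  tgt <- plant$target_cohort
  bld <- plant$blood_cohort
  is_blood <- cohort == bld
  if (class == "marker") {
    if (is_blood) return(plant$blood)
    if (cohort == tgt && subset == "PT") return(plant$marker_pt)
    return(plant$low)
  }
  if (class == "decoy_pt_low") {
    if (is_blood) return(plant$blood)
    return(plant$low)
  }
  if (class == "decoy_sn_high") {
    if (is_blood) return(plant$blood)
    if (cohort == tgt) return(plant$decoy_high)   # both PT and SN high
    return(plant$low)
  }
  if (class == "decoy_pan_pt") {
    if (is_blood) return(plant$blood)
    if (cohort == tgt && subset == "SN") return(plant$low)
    if (subset == "PT" || cohort == tgt) return(plant$decoy_high)
    return(plant$low)
  }
  if (class == "decoy_pan_sn") {
    if (is_blood) return(plant$blood)
    if (cohort == tgt && subset == "PT") return(plant$marker_pt)
    if (cohort == tgt && subset == "SN") return(plant$low)
    if (subset == "SN") return(plant$decoy_high)
    return(plant$low)
  }
  if (class == "decoy_blood_meth") {
    if (is_blood) return(plant$decoy_blood)
    if (cohort == tgt && subset == "PT") return(plant$marker_pt)
    return(plant$low)
  }
  stop("unknown probe class: ", class)
}

#' Generate a synthetic multi-cohort beta matrix
#'
#' Draws beta values per (probe class, cohort, subset) from beta
#' distributions, plants marker and decoy probes per `plant`, assigns
#' per-sample clinical covariates, and returns a truth table labelling
#' every probe. Identical seeds give bit-identical output.
#'
#' @param specs List of `cohort_spec`s; must include the plant's target
#'   cohort with PT and SN subsets and its blood cohort with PB samples.
#' @param plant A `plant_spec`.
#' @param n_background_probes Background probes with a shared baseline
#'   mean drawn uniformly from \[0.05, 0.95\].
#' @param seed Integer seed.
#' @return List with `beta` (matrix), `manifest` (data.frame with
#'   covariates stage, subtype, age, race, ethnicity), and `truth`
#'   (data.frame probe_id, class: marker / decoy_* / background).
#' @export
generate_cohorts <- function(specs = default_cohort_specs(),
                             plant = plant_spec(),
                             n_background_probes = 100, seed = 1) {
  names_ <- vapply(specs, `[[`, character(1), "name")
  names(specs) <- names_
  has_blood <- any(vapply(specs, function(s) s$n_pb > 0, logical(1)))
  if (!has_blood) {
    stop("no blood cohort (n_pb > 0) in specs: the blood unmethylation filter would be vacuous",
         call. = FALSE)
  }
  tgt <- specs[[plant$target_cohort]]
  if (is.null(tgt) || tgt$n_pt == 0 || tgt$n_sn == 0) {
    stop(sprintf("target cohort '%s' must be present with PT and SN samples",
                 plant$target_cohort), call. = FALSE)
  }
  if (is.null(specs[[plant$blood_cohort]]) ||
      specs[[plant$blood_cohort]]$n_pb == 0) {
    stop(sprintf("blood cohort '%s' must be present with PB samples",
                 plant$blood_cohort), call. = FALSE)
  }
  set.seed(seed)

  # --- manifest with covariates ---
  rows <- list()
  for (s in specs) {
    for (sub in c("PT", "SN", "PB")) {
      n <- switch(sub, PT = s$n_pt, SN = s$n_sn, PB = s$n_pb)
      if (n == 0) next
      ids <- sprintf("%s_%s_%03d", s$name, sub, seq_len(n))
      stage <- if (sub == "PT") {
        sample(c("I", "II", "III", "IV"), n, replace = TRUE,
               prob = c(0.30, 0.40, 0.25, 0.05))
      } else rep(NA_character_, n)
      subtype <- if (sub == "PT" && s$name == plant$target_cohort) {
        sample(names(plant$subtype_effects), n, replace = TRUE,
               prob = c(0.20, 0.40, 0.25, 0.15))
      } else rep(NA_character_, n)
      rows[[length(rows) + 1]] <- data.frame(
        sample_id = ids, cohort = s$name, subset = sub,
        stage = stage, subtype = subtype,
        age = round(stats::runif(n, 30, 85), 1),
        race = sample(c("White", "African American", "Asian"), n,
                      replace = TRUE, prob = c(0.65, 0.18, 0.17)),
        ethnicity = sample(c("non-Hispanic", "Hispanic"), n,
                           replace = TRUE, prob = c(0.9, 0.1)),
        stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)

  # --- probe roster and truth table ---
  probe_ids <- c(
    sprintf("mk_%03d", seq_len(plant$n_markers)),
    unlist(lapply(DECOY_CLASSES, function(cl)
      sprintf("%s_%02d", cl, seq_len(plant$decoys_per_class)))),
    sprintf("bg_%04d", seq_len(n_background_probes))
  )
  truth <- data.frame(
    probe_id = probe_ids,
    class = c(rep("marker", plant$n_markers),
              rep(DECOY_CLASSES, each = plant$decoys_per_class),
              rep("background", n_background_probes)),
    stringsAsFactors = FALSE)

  beta <- matrix(NA_real_, length(probe_ids), nrow(manifest),
                 dimnames = list(probe_ids, manifest$sample_id))
  bg_means <- stats::runif(n_background_probes, 0.05, 0.95)

  group_key <- paste(manifest$cohort, manifest$subset)
  for (i in seq_along(probe_ids)) {
    cl <- truth$class[i]
    if (cl == "background") {
      m <- bg_means[i - (length(probe_ids) - n_background_probes)]
      beta[i, ] <- rbeta_mc(nrow(manifest), m, 10)
      next
    }
    for (gk in unique(group_key)) {
      idx <- which(group_key == gk)
      cohort <- manifest$cohort[idx[1]]
      subset <- manifest$subset[idx[1]]
      par <- class_group_mean(cl, cohort, subset, plant)
      if (cl == "marker" && cohort == plant$target_cohort && subset == "PT") {
        # covariate-shifted per-sample means for the planted markers
        st <- match(manifest$stage[idx], c("I", "II", "III", "IV"))
        sub_eff <- plant$subtype_effects[manifest$subtype[idx]]
        sub_eff[is.na(sub_eff)] <- 0
        m_i <- par[["mean"]] + plant$stage_effect * (st - 1) + sub_eff
        m_i <- pmin(pmax(m_i, 0.02), 0.98)
        beta[i, idx] <- rbeta_mc(length(idx), m_i, par[["conc"]])
      } else {
        beta[i, idx] <- rbeta_mc(length(idx), par[["mean"]], par[["conc"]])
      }
    }
  }
  beta <- pmin(pmax(beta, 0), 1)
  list(beta = beta, manifest = manifest, truth = truth)
}

#' Generate a synthetic expression matrix with planted linkage
#'
#' Expression is generated for the target cohort's primary-tumor samples
#' (the samples a tumor expression study would profile). Linked genes
#' are a linear function of the linked probe's beta plus Gaussian noise
#' calibrated so the population correlation equals `rho`; unlinked genes
#' are independent standard-normal noise.
#'
#' @param beta Beta matrix from [generate_cohorts()].
#' @param manifest Matching manifest.
#' @param plant The `plant_spec` used (provides target cohort and rho).
#' @param n_genes Total genes; the first `plant$n_linked_genes` are
#'   linked (ids `lg_*`), the rest independent (`bgg_*`).
#' @param seed Integer seed.
#' @param probe Probe whose beta the linked genes track; defaults to the
#'   first planted marker.
#' @return Numeric expression matrix (genes x target-PT samples) with a
#'   `linked_genes` attribute.
#' @export
generate_expression <- function(beta, manifest, plant = plant_spec(),
                                n_genes = 200, seed = 1,
                                probe = NULL) {
  if (abs(plant$rho) > 1) stop("rho must lie in [-1, 1]", call. = FALSE)
  if (is.null(probe)) probe <- rownames(beta)[1]
  if (!probe %in% rownames(beta)) {
    stop(sprintf("linked probe '%s' not in beta matrix", probe), call. = FALSE)
  }
  ids <- manifest$sample_id[manifest$cohort == plant$target_cohort &
                            manifest$subset == "PT"]
  ids <- intersect(ids, colnames(beta))
  set.seed(seed)
  n <- length(ids)
  b <- beta[probe, ids]
  z <- (b - mean(b)) / stats::sd(b)
  n_linked <- min(plant$n_linked_genes, n_genes)
  gene_ids <- c(sprintf("lg_%03d", seq_len(n_linked)),
                sprintf("bgg_%04d", seq_len(n_genes - n_linked)))
  expr <- matrix(NA_real_, n_genes, n, dimnames = list(gene_ids, ids))
  rho <- plant$rho
  for (g in seq_len(n_linked)) {
    noise <- if (abs(rho) == 1) 0 else stats::rnorm(n)
    expr[g, ] <- rho * z + sqrt(1 - rho^2) * noise
  }
  if (n_genes > n_linked) {
    expr[(n_linked + 1):n_genes, ] <- stats::rnorm((n_genes - n_linked) * n)
  }
  attr(expr, "linked_genes") <- gene_ids[seq_len(n_linked)]
  expr
}

#' Generate synthetic gene-set collections
#'
#' One "responsive" set is built from the planted methylation-linked
#' genes; the remaining sets are drawn uniformly at random (without
#' replacement within a set) from all genes.
#'
#' @param expression Expression matrix (genes in rows).
#' @param planted_genes Genes forming the responsive set (padded with
#'   random genes if fewer than `set_size`).
#' @param n_sets Total sets including the responsive one.
#' @param set_size Genes per set.
#' @param seed Integer seed.
#' @return Named list of gene-id vectors; the responsive set is named
#'   `"RESPONSIVE"`.
#' @export
generate_gene_sets <- function(expression, planted_genes, n_sets = 10,
                               set_size = 10, seed = 1) {
  genes <- rownames(expression)
  if (set_size > length(genes)) {
    stop("set_size exceeds the number of genes", call. = FALSE)
  }
  if (length(planted_genes) == 0) {
    stop("planted_genes is empty but a responsive set was requested",
         call. = FALSE)
  }
  set.seed(seed)
  resp <- utils::head(planted_genes, set_size)
  if (length(resp) < set_size) {
    resp <- c(resp, sample(setdiff(genes, resp), set_size - length(resp)))
  }
  sets <- list(RESPONSIVE = resp)
  for (k in seq_len(n_sets - 1)) {
    sets[[sprintf("RANDOM_%02d", k)]] <- sample(genes, set_size)
  }
  attr(sets, "description") <- stats::setNames(
    c("planted methylation-linked genes",
      rep("random draw", n_sets - 1)), names(sets))
  sets
}
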