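# Seeded synthetic cohorts with the statistical structure the pipeline
# assumes: a paired tumor/normal design (38 good / 15 poor by default),
# risk genes shifted far outside the reference interval in a subgroup of
# poor samples, decoy genes with small whole-group mean shifts that stay
# inside the interval, risk genes concentrated in designated pathways
# (disjoint between tissues), an at-risk good subgroup carrying attenuated
# poor-type shifts, and exponential survival with elevated hazard for
# altered patients.

#' Simulation configuration
#'
#' Defaults mirror the study design the pipeline targets: 38 good / 15 poor
#' samples per tissue, subgroup outlier shifts of 4 z-units in 40% of poor
#' samples, within-interval decoy shifts of 0.5 z-units in all poor
#' samples, and a hazard ratio of 3 for altered patients.
#'
#' @param n_good,n_poor samples per prognosis group (38 / 15).
#' @param n_genes total genes (2000).
#' @param n_pathways total pathways (50).
#' @param genes_per_pathway members per pathway (20).
#' @param n_risk_pathways risk pathways per tissue (4); tumor and normal
#'   get disjoint sets, and risk-pathway members are disjoint risk genes.
#' @param n_decoy decoy genes (100).
#' @param subgroup_frac fraction of poor samples carrying each risk gene's
#'   shift (0.4).
#' @param shift_z outlier shift magnitude in z-units (4; must exceed 1.96).
#' @param decoy_shift_z whole-group decoy shift (0.5; must stay below 1.96).
#' @param n_at_risk_good good samples carrying 50%-attenuated risk shifts
#'   (5).
#' @param hazard_ratio hazard multiplier for altered patients (3).
#' @param censor_frac administrative censoring: the horizon is set where
#'   this fraction of baseline patients would still be event-free (0.3).
#' @param median_survival baseline median survival in months (60).
#' @param seed integer seed driving every random draw.
#' @return validated list of class \code{SimulationConfig}.
#' @export
sim_config <- function(n_good = 38, n_poor = 15, n_genes = 2000,
                       n_pathways = 50, genes_per_pathway = 20,
                       n_risk_pathways = 4, n_decoy = 100,
                       subgroup_frac = 0.4, shift_z = 4.0,
                       decoy_shift_z = 0.5, n_at_risk_good = 5,
                       hazard_ratio = 3.0, censor_frac = 0.3,
                       median_survival = 60, seed = 1) {
  cfg <- list(n_good = n_good, n_poor = n_poor, n_genes = n_genes,
              n_pathways = n_pathways,
              genes_per_pathway = genes_per_pathway,
              n_risk_pathways = n_risk_pathways, n_decoy = n_decoy,
              subgroup_frac = subgroup_frac, shift_z = shift_z,
              decoy_shift_z = decoy_shift_z,
              n_at_risk_good = n_at_risk_good,
              hazard_ratio = hazard_ratio, censor_frac = censor_frac,
              median_survival = median_survival, seed = seed)
  counts <- cfg[c("n_good", "n_poor", "n_genes", "n_pathways",
                  "genes_per_pathway", "n_risk_pathways")]
  if (any(unlist(counts) <= 0)) stop("all counts must be positive")
  if (round(subgroup_frac * n_poor) < 1)
    stop("subgroup_frac * n_poor must be >= 1")
  if (shift_z != 0 && shift_z <= 1.96)
    stop("shift_z must exceed 1.96 (or be 0 for a null cohort)")
  if (decoy_shift_z >= 1.96) stop("decoy_shift_z must stay below 1.96")
  n_risk_genes <- 2 * n_risk_pathways * genes_per_pathway
  if (n_risk_genes + n_decoy > n_genes)
    stop("n_genes too small for the risk and decoy gene blocks")
  if (2 * n_risk_pathways > n_pathways)
    stop("n_pathways too small for disjoint tumor/normal risk sets")
  if (n_at_risk_good >= n_good)
    stop("n_at_risk_good must be smaller than n_good")
  structure(cfg, class = "SimulationConfig")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Generate a synthetic paired tumor/normal cohort
#'
#' Baseline expression is i.i.d. Normal(0, 1) per gene and sample (the
#' pipeline z-scores everything anyway). Per tissue, each risk gene gets a
#' fixed sign and a shift of \code{shift_z} added to a random
#' \code{subgroup_frac} subset of poor samples; decoy genes get
#' \code{decoy_shift_z} added to every poor sample; the designated at-risk
#' good samples mirror the poor-side subgroup rule, each risk gene being
#' carried at half magnitude by a \code{subgroup_frac} subset of them.
#' Survival times
#' are exponential, with the hazard multiplied by \code{hazard_ratio} for
#' samples carrying at least one risk-gene alteration, and administratively
#' censored at a fixed horizon.
#'
#' @param config \code{\link{sim_config}} object.
#' @return list of class \code{SyntheticCohort}: \code{tumor} and
#'   \code{normal} ExpressionMatrix, \code{survival} (data.frame:
#'   sample_id, time, event, altered), \code{pathways} (GMT-style list),
#'   \code{truth} (risk genes/carriers/pathways, decoys, at-risk good
#'   samples), \code{config}.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  with_seed(config$seed, {
    n <- config$n_good + config$n_poor
    sample_ids <- sprintf("S%03d", seq_len(n))
    good_ids <- sample_ids[seq_len(config$n_good)]
    poor_ids <- sample_ids[-seq_len(config$n_good)]
    gene_ids <- sprintf("G%04d", seq_len(config$n_genes))
    gpp <- config$genes_per_pathway
    nrp <- config$n_risk_pathways
    n_risk <- 2 * nrp * gpp

    # Gene blocks: [tumor risk | normal risk | decoys | background].
    risk_genes_t <- gene_ids[seq_len(nrp * gpp)]
    risk_genes_n <- gene_ids[nrp * gpp + seq_len(nrp * gpp)]
    decoy_genes <- gene_ids[n_risk + seq_len(config$n_decoy)]
    background <- gene_ids[(n_risk + config$n_decoy + 1):config$n_genes]

    pathway_ids <- sprintf("PW%03d", seq_len(config$n_pathways))
    risk_pw_t <- pathway_ids[seq_len(nrp)]
    risk_pw_n <- pathway_ids[nrp + seq_len(nrp)]
    pathways <- vector("list", config$n_pathways)
    names(pathways) <- pathway_ids
    for (i in seq_len(nrp)) {
      pathways[[risk_pw_t[i]]] <- risk_genes_t[(i - 1) * gpp + seq_len(gpp)]
      pathways[[risk_pw_n[i]]] <- risk_genes_n[(i - 1) * gpp + seq_len(gpp)]
    }
    pool <- c(decoy_genes, background)
    for (p in pathway_ids[-(seq_len(2 * nrp))])
      pathways[[p]] <- sample(pool, min(gpp, length(pool)))
    attr(pathways, "description") <- stats::setNames(
      ifelse(pathway_ids %in% c(risk_pw_t, risk_pw_n),
             "synthetic risk pathway", "synthetic background pathway"),
      pathway_ids)

    at_risk_good <- sort(sample(good_ids, config$n_at_risk_good))
    n_carrier <- round(config$subgroup_frac * config$n_poor)
    n_carrier_ar <- max(1L, round(config$subgroup_frac *
                                    config$n_at_risk_good))

    make_tissue <- function(risk_genes) {
      v <- matrix(stats::rnorm(config$n_genes * n), config$n_genes, n,
                  dimnames = list(gene_ids, sample_ids))
      signs <- stats::setNames(sample(c(-1, 1), length(risk_genes),
                                      replace = TRUE), risk_genes)
      carriers <- lapply(risk_genes, function(g) sort(sample(poor_ids,
                                                             n_carrier)))
      names(carriers) <- risk_genes
      for (g in risk_genes) {
        v[g, carriers[[g]]] <- v[g, carriers[[g]]] +
          signs[[g]] * config$shift_z
        # at-risk goods mirror the poor-side subgroup rule: each risk gene
        # is carried (at half magnitude) by a subgroup_frac subset of them
        ar <- sample(at_risk_good, n_carrier_ar)
        v[g, ar] <- v[g, ar] + 0.5 * signs[[g]] * config$shift_z
      }
      dsigns <- stats::setNames(sample(c(-1, 1), length(decoy_genes),
                                       replace = TRUE), decoy_genes)
      for (g in decoy_genes)
        v[g, poor_ids] <- v[g, poor_ids] + dsigns[[g]] * config$decoy_shift_z
      list(values = v, signs = signs, carriers = carriers,
           decoy_signs = dsigns)
    }
    tum <- make_tissue(risk_genes_t)
    nor <- make_tissue(risk_genes_n)

    annot <- function(tissue) data.frame(
      sample_id = sample_ids,
      group = rep(c("good", "poor"), c(config$n_good, config$n_poor)),
      tissue = tissue, stringsAsFactors = FALSE)

    # Survival: a sample is truly altered if it carries >= 1 risk-gene
    # shift in either tissue (all poor carriers plus the at-risk goods).
    carrier_union <- unique(c(unlist(tum$carriers), unlist(nor$carriers),
                              at_risk_good))
    altered <- sample_ids %in% carrier_union
    rate0 <- log(2) / config$median_survival
    rate <- rate0 * ifelse(altered, config$hazard_ratio, 1)
    t_raw <- stats::rexp(n, rate)
    horizon <- stats::qexp(1 - config$censor_frac, rate0)
    surv <- data.frame(sample_id = sample_ids,
                       time = pmin(t_raw, horizon),
                       event = as.integer(t_raw <= horizon),
                       altered = altered, stringsAsFactors = FALSE)

    structure(list(
      tumor = expression_matrix(tum$values, annot("tumor")),
      normal = expression_matrix(nor$values, annot("normal")),
      survival = surv,
      pathways = pathways,
      truth = list(
        risk_genes = list(tumor = risk_genes_t, normal = risk_genes_n),
        risk_signs = list(tumor = tum$signs, normal = nor$signs),
        carriers = list(tumor = tum$carriers, normal = nor$carriers),
        risk_pathways = list(tumor = risk_pw_t, normal = risk_pw_n),
        decoy_genes = decoy_genes,
        at_risk_good = at_risk_good,
        altered = stats::setNames(altered, sample_ids)),
      config = config), class = "SyntheticCohort")
  })
}

#' Write a synthetic cohort to plain-text files
#'
#' Writes per-tissue expression and annotation TSVs, the pathway GMT, a
#' clinical TSV (sample_id, time, event) and the truth tables as JSON, so
#' that \code{\link{read_expression}} / \code{\link{read_gmt}} round-trip
#' the cohort.
#'
#' @param cohort SyntheticCohort.
#' @param dir output directory (created if needed).
#' @return named character vector of written paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create directory: ", dir)
  paths <- c(
    tumor = file.path(dir, "tumor_expression.tsv"),
    normal = file.path(dir, "normal_expression.tsv"),
    annot_tumor = file.path(dir, "tumor_annotation.tsv"),
    annot_normal = file.path(dir, "normal_annotation.tsv"),
    gmt = file.path(dir, "pathways.gmt"),
    clinical = file.path(dir, "clinical.tsv"),
    truth = file.path(dir, "truth.json"))
  write_expression(cohort$tumor, paths["tumor"], paths["annot_tumor"])
  write_expression(cohort$normal, paths["normal"], paths["annot_normal"])
  write_gmt(cohort$pathways, paths["gmt"])
  utils::write.table(cohort$survival[c("sample_id", "time", "event")],
                     paths["clinical"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(cohort$truth, paths["truth"], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}

#' Simulate an independent validation cohort with per-tissue alterations
#'
#' Emulates applying tumor- and normal-tissue risk gene sets to an
#' independent survival cohort: each patient is altered in tumor genes
#' only, normal genes only, both, or neither, and carries elevated hazard
#' if altered in either. A single tissue's gene set misclassifies the
#' patients altered only in the other tissue, which is what integration
#' recovers.
#'
#' @param n patients (default 526, a typical validation-cohort size).
#' @param frac_tumor_only,frac_normal_only,frac_both composition of the
#'   altered population (defaults 0.15 / 0.15 / 0.10).
#' @param hazard_ratio hazard multiplier for altered patients (default 3).
#' @param median_survival baseline median in months (default 60).
#' @param censor_frac administrative censoring fraction of the baseline
#'   group (default 0.3).
#' @param seed integer seed.
#' @return data.frame: sample_id, time, event, altered_tumor,
#'   altered_normal, altered (the union).
#' @export
simulate_validation_cohort <- function(n = 526, frac_tumor_only = 0.15,
                                       frac_normal_only = 0.15,
                                       frac_both = 0.10, hazard_ratio = 3,
                                       median_survival = 60,
                                       censor_frac = 0.3, seed = 1) {
  if (frac_tumor_only + frac_normal_only + frac_both >= 1)
    stop("altered fractions must sum to < 1")
  with_seed(seed, {
    cls <- sample(c("tumor", "normal", "both", "none"), n, replace = TRUE,
                  prob = c(frac_tumor_only, frac_normal_only, frac_both,
                           1 - frac_tumor_only - frac_normal_only -
                             frac_both))
    alt_t <- cls %in% c("tumor", "both")
    alt_n <- cls %in% c("normal", "both")
    altered <- alt_t | alt_n
    rate0 <- log(2) / median_survival
    t_raw <- stats::rexp(n, rate0 * ifelse(altered, hazard_ratio, 1))
    horizon <- if (censor_frac > 0) stats::qexp(1 - censor_frac, rate0)
               else Inf
    data.frame(sample_id = sprintf("V%04d", seq_len(n)),
               time = pmin(t_raw, horizon),
               event = as.integer(t_raw <= horizon),
               altered_tumor = alt_t, altered_normal = alt_n,
               altered = altered, stringsAsFactors = FALSE)
  })
}

#' Simulate a standalone survival table (for power studies)
#'
#' @param n number of patients.
#' @param altered_frac fraction altered (default 0.5).
#' @param hazard_ratio hazard multiplier for altered patients (default 3).
#' @param median_survival baseline median in months (default 60).
#' @param censor_frac administrative censoring fraction of the baseline
#'   group (default 0 = none).
#' @param seed integer seed.
#' @return data.frame: sample_id, time, event, altered.
#' @export
simulate_survival_table <- function(n, altered_frac = 0.5,
                                    hazard_ratio = 3,
                                    median_survival = 60,
                                    censor_frac = 0, seed = 1) {
  with_seed(seed, {
    altered <- seq_len(n) <= round(altered_frac * n)
    rate0 <- log(2) / median_survival
    rate <- rate0 * ifelse(altered, hazard_ratio, 1)
    t_raw <- stats::rexp(n, rate)
    horizon <- if (censor_frac > 0) stats::qexp(1 - censor_frac, rate0)
               else Inf
    data.frame(sample_id = sprintf("P%04d", seq_len(n)),
               time = pmin(t_raw, horizon),
               event = as.integer(t_raw <= horizon),
               altered = altered, stringsAsFactors = FALSE)
  })
}
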