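# End-to-end orchestration: per tissue, normalize -> exceedance DEG test ->
# clustering / at-risk subgroup -> pathway deviation scores -> two-circle
# evaluation and risk-pathway ranking -> cross-validated models -> survival
# screen; the two tissues' risk genes are then integrated for a combined
# survival comparison. Outputs are written as TSV/JSON plus a manifest that
# is byte-identical across reruns with the same inputs and seed.

default_params <- function() {
  list(alpha = 0.05, n_perm = 1000, coverage = 0.8, threshold = 0.65,
       top_k = 4, folds = 5, k_tumor = 3, k_normal = 4, seed = 1)
}

run_tissue <- function(m, pathways, clinical, params, out_dir, tissue) {
  z <- zscore_normalize(m)
  degs <- call_degs(z, alpha = params$alpha, n_perm = params$n_perm,
                    seed = params$seed)
  utils::write.table(degs, file.path(out_dir,
                                     paste0("degs_", tissue, ".tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  k <- if (tissue == "tumor") params$k_tumor else params$k_normal
  clust <- list(assignment = NULL, at_risk = character(0),
                poor_recall = NA_real_)
  if (nrow(degs) >= 2) {
    tree <- cluster_samples(median_center(z), degs$gene_id)
    assignment <- cut_to_clusters(tree, k)
    truth <- stats::setNames(z$annotation$group, z$annotation$sample_id)
    purity <- cluster_purity(assignment, truth)
    at_risk <- suppressWarnings(identify_at_risk(z, assignment,
                                                 degs$gene_id))
    clust <- list(assignment = assignment, at_risk = as.character(at_risk),
                  poor_recall = purity$poor_recall)
    utils::write.table(
      data.frame(sample_id = names(assignment), cluster = assignment,
                 at_risk = names(assignment) %in% at_risk),
      file.path(out_dir, paste0("clusters_", tissue, ".tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }

  scores <- score_matrix(z, pathways, degs)
  evals <- evaluate_pathways(scores, z$annotation,
                             coverage = params$coverage)
  risk <- rank_pathways(evals, threshold = params$threshold,
                        top_k = params$top_k)
  evals$risk_flag <- evals$pathway_id %in% risk$pathway_id
  utils::write.table(evals, file.path(out_dir,
                                      paste0("pathways_", tissue, ".tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  cv <- NULL
  if (nrow(risk) > 0) {
    features <- build_features(scores, risk$pathway_id)
    cv <- cross_validate(features, z$annotation$group,
                         model = "random_forest", folds = params$folds,
                         seed = params$seed)
  }

  screened <- character(0)
  km <- NULL
  if (nrow(risk) > 0 && nrow(degs) > 0) {
    risk_genes <- intersect(unique(unlist(pathways[risk$pathway_id])),
                            degs$gene_id)
    if (length(risk_genes)) {
      screened <- suppressWarnings(
        as.character(screen_genes(risk_genes, z, clinical,
                                  alpha = params$alpha)))
      if (length(screened)) {
        alt <- mark_altered(z, screened)
        surv <- clinical[match(colnames(z$values), clinical$sample_id), ]
        tab <- data.frame(time = surv$time, event = surv$event,
                          altered = alt)
        if (length(unique(tab$altered)) == 2L) km <- km_logrank(tab)
      }
    }
  }

  list(z = z, degs = degs, clust = clust, scores = scores, evals = evals,
       risk = risk, cv = cv, screened = screened, km = km)
}

#' Run the full recurrence-risk pipeline on a cohort
#'
#' Executes each stage per tissue, then integrates the two tissues'
#' screened risk genes for a combined altered-vs-unaltered survival
#' comparison. A JSON manifest of parameters, summary numbers and output
#' file checksums is written; reruns with the same inputs and seed produce
#' a byte-identical manifest.
#'
#' @param cohort a \code{SyntheticCohort} or a list with elements
#'   \code{tumor}, \code{normal} (ExpressionMatrix), \code{pathways}
#'   (gene-set list) and \code{survival} (data.frame sample_id, time,
#'   event).
#' @param out_dir output directory.
#' @param params named list overriding \code{alpha} (0.05), \code{n_perm}
#'   (1000), \code{coverage} (0.8), \code{threshold} (0.65), \code{top_k}
#'   (4), \code{folds} (5), \code{k_tumor} (3), \code{k_normal} (4),
#'   \code{seed} (1).
#' @return the manifest list, invisibly; full stage results in attribute
#'   \code{"stages"}.
#' @export
run_pipeline <- function(cohort, out_dir, params = list()) {
  p <- utils::modifyList(default_params(), params)
  for (el in c("tumor", "normal", "pathways", "survival"))
    if (is.null(cohort[[el]])) stop("cohort is missing element '", el, "'")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  clinical <- cohort$survival

  stages <- list(
    tumor = run_tissue(cohort$tumor, cohort$pathways, clinical, p,
                       out_dir, "tumor"),
    normal = run_tissue(cohort$normal, cohort$pathways, clinical, p,
                        out_dir, "normal"))

  integrated <- integrate_gene_sets(stages$tumor$screened,
                                    stages$normal$screened)
  km_int <- NULL
  if (nrow(integrated)) {
    alt <- rep(FALSE, nrow(clinical))
    names(alt) <- clinical$sample_id
    for (tis in c("tumor", "normal")) {
      g <- integrated$gene_id[integrated$source %in% c(tis, "both")]
      g <- intersect(g, rownames(stages[[tis]]$z$values))
      if (length(g)) {
        a <- mark_altered(stages[[tis]]$z, g)
        alt[names(a)] <- alt[names(a)] | a
      }
    }
    tab <- data.frame(time = clinical$time, event = clinical$event,
                      altered = alt[clinical$sample_id])
    if (length(unique(tab$altered)) == 2L) km_int <- km_logrank(tab)
  }
  utils::write.table(integrated,
                     file.path(out_dir, "integrated_risk_genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  tissue_summary <- function(st) list(
    n_deg = nrow(st$degs),
    n_deg_up = sum(st$degs$direction == "up"),
    n_deg_down = sum(st$degs$direction == "down"),
    poor_cluster_recall = st$clust$poor_recall,
    n_at_risk = length(st$clust$at_risk),
    risk_pathways = st$risk$pathway_id,
    risk_mean_precision = st$risk$mean_precision,
    rf_mean_auc = if (!is.null(st$cv)) st$cv$mean_auc else NULL,
    rf_mean_accuracy = if (!is.null(st$cv)) st$cv$mean_accuracy else NULL,
    n_screened_genes = length(st$screened),
    km_logrank_p = if (!is.null(st$km)) st$km$p_value else NULL)

  files <- sort(setdiff(list.files(out_dir), "manifest.json"))
  manifest <- list(
    package = "riskpath",
    parameters = p,
    tumor = tissue_summary(stages$tumor),
    normal = tissue_summary(stages$normal),
    integrated = list(
      n_genes = nrow(integrated),
      km_logrank_p = if (!is.null(km_int)) km_int$p_value else NULL),
    outputs = as.list(stats::setNames(
      unname(tools::md5sum(file.path(out_dir, files))), files)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  attr(manifest, "stages") <- c(stages, list(integrated = integrated,
                                             km_integrated = km_int))
  invisible(manifest)
}
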