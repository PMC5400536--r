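#!/usr/bin/env Rscript
# Cross-validated classifiers on the risk-pathway (U, D) features: a
# 5-fold random forest and an SVM, with ROC/AUC per fold; then a
# hypergeometric enrichment of the risk genes into a synthetic hallmark
# collection (stand-in for a user-supplied hallmark GMT).

library(riskpath)

seed <- 1
dir.create("results", showWarnings = FALSE)
cohort <- simulate_cohort(sim_config(seed = seed))

cv_out <- list()
risk_genes <- list()
for (tissue in c("tumor", "normal")) {
  z <- zscore_normalize(cohort[[tissue]])
  degs <- call_degs(z, n_perm = 10000, seed = seed)
  scores <- score_matrix(z, cohort$pathways, degs)
  risk <- rank_pathways(evaluate_pathways(scores, z$annotation))
  features <- build_features(scores, risk$pathway_id)
  rf <- cross_validate(features, z$annotation$group, "random_forest",
                       seed = seed)
  sv <- cross_validate(features, z$annotation$group, "svm", seed = seed)
  cat("==", tissue, "tissue (", ncol(features), "features ) ==\n")
  cat(sprintf("  random forest: mean AUC %.3f, mean accuracy %.3f\n",
              rf$mean_auc, rf$mean_accuracy))
  cat(sprintf("  SVM (RBF)    : mean AUC %.3f, mean accuracy %.3f\n",
              sv$mean_auc, sv$mean_accuracy))
  cv_out[[tissue]] <- list(
    random_forest = list(fold_auc = rf$fold_auc, mean_auc = rf$mean_auc,
                         mean_accuracy = rf$mean_accuracy),
    svm = list(fold_auc = sv$fold_auc, mean_auc = sv$mean_auc,
               mean_accuracy = sv$mean_accuracy))
  risk_genes[[tissue]] <- intersect(
    unique(unlist(cohort$pathways[risk$pathway_id])), degs$gene_id)
}

# Synthetic hallmark collection: ten categories drawn over the gene
# universe, half of them seeded with tumor/normal risk genes so that the
# enrichment stage has signal to find.
set.seed(seed)
universe <- rownames(cohort$tumor$values)
halls <- lapply(1:10, function(i) sample(universe, 120))
names(halls) <- sprintf("HALLMARK_%02d", 1:10)
halls[[1]] <- unique(c(risk_genes$tumor, halls[[1]][1:60]))
halls[[2]] <- unique(c(risk_genes$normal, halls[[2]][1:60]))

both <- integrate_gene_sets(risk_genes$tumor, risk_genes$normal)
enr <- hallmark_enrichment(both$gene_id, halls, universe)
cat("\nHallmark enrichment of integrated risk genes (p < 0.05):\n")
print(enr[enr$significant, c("hallmark_id", "overlap", "set_size",
                             "p_value")], row.names = FALSE, digits = 3)

jsonlite::write_json(list(cv = cv_out, enrichment = enr),
                     "results/05_models.json", auto_unbox = TRUE,
                     digits = NA, pretty = TRUE)
cat("Model summary: results/05_models.json\n")
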