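#!/usr/bin/env Rscript
# Reference-interval exceedance DEG test per tissue (B = 10000 label
# permutations, BH at q < 0.05), contrasted with the conventional
# two-sample t-test: subgroup outlier genes are caught by the exceedance
# test and largely missed by the mean test at the matched per-gene alpha,
# while within-interval decoys fool only the mean test.

library(riskpath)

seed <- 1
dir.create("results", showWarnings = FALSE)
cohort <- simulate_cohort(sim_config(seed = seed))

for (tissue in c("tumor", "normal")) {
  z <- zscore_normalize(cohort[[tissue]])
  degs <- call_degs(z, n_perm = 10000, seed = seed)
  full <- attr(degs, "full")
  rg <- cohort$truth$risk_genes[[tissue]]
  dec <- cohort$truth$decoy_genes
  alpha_star <- max(full$p_value[full$q_value < 0.05])
  tt <- mean_difference_test(cohort[[tissue]])

  cat("==", tissue, "tissue ==\n")
  cat("  DEGs (q < 0.05):", nrow(degs),
      sprintf("(%d up, %d down)\n", sum(degs$direction == "up"),
              sum(degs$direction == "down")))
  cat("  planted risk-gene recall      :",
      sprintf("%.1f%%\n", 100 * mean(rg %in% degs$gene_id)))
  cat("  decoys flagged                :",
      sum(dec %in% degs$gene_id), "of", length(dec), "\n")
  cat("  t-test recall at matched alpha:",
      sprintf("%.1f%% (alpha* = %.2g)\n",
              100 * mean(tt$p_value[tt$gene_id %in% rg] < alpha_star),
              alpha_star))
  cat("  t-test decoy rate at p < 0.05 :",
      sprintf("%.1f%%\n", 100 * mean(tt$p_value[tt$gene_id %in% dec] <
                                       0.05)))
  write.table(degs, sprintf("results/02_degs_%s.tsv", tissue),
              sep = "\t", quote = FALSE, row.names = FALSE)
}
cat("DEG tables: results/02_degs_{tumor,normal}.tsv\n")
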