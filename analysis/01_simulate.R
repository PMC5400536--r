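#!/usr/bin/env Rscript
# Generate the default synthetic cohort: paired tumor/normal expression for
# 38 good / 15 poor patients, 2000 genes, 50 pathways of which 4 per tissue
# are planted risk pathways, plus survival data. Writes the cohort files to
# scratch/cohort/ (the downstream drivers regenerate it from the seed) and
# a small design summary to results/.

library(riskpath)

seed <- 1
dir.create("results", showWarnings = FALSE)

cfg <- sim_config(seed = seed)
cohort <- simulate_cohort(cfg)
paths <- write_cohort(cohort, "scratch/cohort")

cat("Synthetic cohort (seed ", seed, "):\n", sep = "")
print(cohort$tumor)
cat("\nPlanted structure:\n")
cat("  risk pathways, tumor :",
    paste(cohort$truth$risk_pathways$tumor, collapse = " "), "\n")
cat("  risk pathways, normal:",
    paste(cohort$truth$risk_pathways$normal, collapse = " "), "\n")
cat("  risk genes per tissue:", length(cohort$truth$risk_genes$tumor), "\n")
cat("  decoy genes          :", length(cohort$truth$decoy_genes), "\n")
cat("  at-risk good samples :",
    paste(cohort$truth$at_risk_good, collapse = " "), "\n")
cat("  truly altered samples:", sum(cohort$truth$altered), "\n")
cat("\nFiles written:\n")
for (p in paths) cat("  ", p, "\n")

summary_tab <- data.frame(
  parameter = c("n_good", "n_poor", "n_genes", "n_pathways",
                "n_risk_pathways_per_tissue", "genes_per_pathway",
                "n_decoy", "subgroup_frac", "shift_z", "decoy_shift_z",
                "n_at_risk_good", "hazard_ratio", "censor_frac", "seed"),
  value = unlist(cfg[c("n_good", "n_poor", "n_genes", "n_pathways",
                       "n_risk_pathways", "genes_per_pathway", "n_decoy",
                       "subgroup_frac", "shift_z", "decoy_shift_z",
                       "n_at_risk_good", "hazard_ratio", "censor_frac",
                       "seed")]))
write.table(summary_tab, "results/01_design.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("\nDesign table: results/01_design.tsv\n")
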