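# riskpath

Recurrence-risk analysis for paired tumor/normal expression cohorts, built
around a heterogeneity-aware alternative to mean-difference testing. The
package is aimed at computational biologists who work with
recurrent-vs-non-recurrent (poor/good prognosis) cancer cohorts in which
the interesting genes are dysregulated in only a *subset* of the poor
patients — exactly the genes a t-test or limma-style moderated test is
weakest on.

## The method in brief

**Exceedance DEG test.** Per gene, a reference ("normal") interval
[x̄ − 1.96 s, x̄ + 1.96 s] is fitted on the good-prognosis group
(population SD). The gene's statistic is the summed absolute distance by
which poor-group samples fall outside that interval,

    score = Σᵢ |dᵢ|,   dᵢ = (xᵢ − xmax)₊ − (xmin − xᵢ)₊ ,

with the signed sum kept for the direction call. Significance comes from
B label permutations in which the interval is recomputed from each
permuted control set; p = (1 + #{random ≥ observed})/(B + 1), BH-corrected
to q-values.

**Pathway deviation scores.** Per sample and pathway, U = Σ(xᵢ − μᵢ)³/N₁
over the pathway's up-regulated DEGs and D likewise over down-regulated
ones (μ = good-group gene mean). In the (U, D) plane each pathway gets a
**two-circle classifier**: per-group geometric centers with the minimal
radius covering 80% of that group; samples inside both circles
(intersection) or neither (isolation) are *fuzzy* and rejected. Pathways
with mean circle precision above 65% (top four) are the risk-associated
pathways.

**Downstream.** Hierarchical clustering on DEGs (1 − centered Pearson,
average linkage) with an at-risk good-prognosis subgroup call; 5-fold
cross-validated random forest / SVM on the risk-pathway features;
hypergeometric hallmark enrichment; Kaplan–Meier + log-rank comparison of
patients with vs without expression alterations in the (survival-screened)
risk genes, with tumor+normal gene-set integration.

Everything runs on seeded synthetic cohorts (38 good / 15 poor per tissue,
planted subgroup outliers, within-interval decoys, at-risk samples,
survival with elevated hazard for carriers) generated by
`simulate_cohort()`, so the whole pipeline is testable offline.

## Worked example

```r
library(riskpath)

cohort <- simulate_cohort(sim_config(seed = 1))
z      <- zscore_normalize(cohort$tumor)
degs   <- call_degs(z, n_perm = 10000, seed = 1)
nrow(degs)
#> [1] 75
scores <- score_matrix(z, cohort$pathways, degs)
risk   <- rank_pathways(evaluate_pathways(scores, z$annotation))
risk$pathway_id
#> [1] "PW001" "PW002" "PW003" "PW004"
cv <- cross_validate(build_features(scores, risk$pathway_id),
                     z$annotation$group, "random_forest", seed = 1)
cv
#> 5-fold CV (random_forest): mean AUC 1.000, mean accuracy 1.000
```

75 genes pass the exceedance test at q < 0.05 — 90% of the 80 planted
subgroup-outlier genes, and 0 of the 100 decoy genes whose mean shifts but
stays inside the interval. A two-sample t-test at the matched per-gene
alpha recovers only 2.5% of the planted genes while flagging 38% of the
decoys: the two tests disagree on exactly the two gene classes they are
supposed to disagree on. All four planted risk pathways are ranked top
with mean precision 1.00, and the random forest on their (U, D) features
separates the groups perfectly in cross-validation.

The numbered drivers under `analysis/` walk the same cohort through every
stage with commentary (`01_simulate.R` … `06_survival.R`); each writes its
summary tables under `results/`.

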