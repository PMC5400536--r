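test_that("configuration is validated before any generation", {
  expect_error(sim_config(subgroup_frac = 0.01), "subgroup_frac")
  expect_error(sim_config(shift_z = 1.5), "shift_z")
  expect_error(sim_config(decoy_shift_z = 2.5), "decoy_shift_z")
  expect_error(sim_config(n_genes = 100), "too small")
  expect_error(sim_config(n_at_risk_good = 40), "n_at_risk_good")
  expect_s3_class(sim_config(shift_z = 0), "SimulationConfig")
})

test_that("the same seed reproduces the cohort bit for bit", {
  a <- simulate_cohort(sim_config(seed = 5))
  b <- simulate_cohort(sim_config(seed = 5))
  expect_identical(a$tumor$values, b$tumor$values)
  expect_identical(a$normal$values, b$normal$values)
  expect_identical(a$survival, b$survival)
  expect_identical(a$truth, b$truth)
  c2 <- simulate_cohort(sim_config(seed = 6))
  expect_false(identical(a$tumor$values, c2$tumor$values))
})

test_that("truth tables are consistent with the planted matrices", {
  cfg <- sim_config(seed = 12)
  co <- simulate_cohort(cfg)
  # fully nested risk pathways: n_risk_pathways * genes_per_pathway genes
  expect_length(co$truth$risk_genes$tumor,
                cfg$n_risk_pathways * cfg$genes_per_pathway)
  expect_setequal(unlist(co$pathways[co$truth$risk_pathways$tumor]),
                  co$truth$risk_genes$tumor)
  expect_length(intersect(co$truth$risk_genes$tumor,
                          co$truth$risk_genes$normal), 0)
  expect_identical(colnames(co$tumor$values), colnames(co$normal$values))

  # every planted shift is recoverable by recomputation: carriers of an
  # up-gene sit shift_z above the same cells of a re-draw without shifts
  g <- co$truth$risk_genes$tumor[1]
  carr <- co$truth$carriers$tumor[[g]]
  sgn <- co$truth$risk_signs$tumor[[g]]
  others <- setdiff(co$tumor$annotation$sample_id[
    co$tumor$annotation$group == "poor"], carr)
  gap <- mean(co$tumor$values[g, carr]) - mean(co$tumor$values[g, others])
  expect_gt(abs(gap), 2)
  expect_identical(sign(gap), sgn)

  # at-risk good samples are good-group members
  expect_true(all(co$truth$at_risk_good %in%
    co$tumor$annotation$sample_id[co$tumor$annotation$group == "good"]))
  # altered = carrier of >= 1 risk shift in either tissue
  expect_true(all(co$truth$altered[unlist(co$truth$carriers$tumor)]))
})

test_that("written fixtures round-trip through the package readers", {
  co <- simulate_cohort(sim_config(seed = 3))
  dir <- withr::local_tempdir()
  paths <- write_cohort(co, dir)
  back <- read_expression(paths[["tumor"]], paths[["annot_tumor"]])
  expect_identical(back$values, co$tumor$values)
  expect_identical(back$annotation$group, co$tumor$annotation$group)
  sets <- expect_no_warning(read_gmt(paths[["gmt"]]))
  expect_identical(sets[], co$pathways[])
  clin <- read.delim(paths[["clinical"]])
  expect_equal(clin$time, co$survival$time, tolerance = 1e-6)
  truth <- jsonlite::read_json(paths[["truth"]], simplifyVector = TRUE)
  expect_identical(truth$decoy_genes, co$truth$decoy_genes)
})

test_that("about 95% of good-group values fall inside fitted intervals", {
  co <- simulate_cohort(sim_config(seed = 21))
  z <- zscore_normalize(co$tumor)
  good <- z$values[, z$annotation$group == "good"]
  bg <- setdiff(rownames(good), c(unlist(co$truth$risk_genes),
                                  co$truth$decoy_genes))
  inside <- vapply(bg, function(g) {
    iv <- compute_reference_interval(good[g, ])
    mean(good[g, ] >= iv$xmin & good[g, ] <= iv$xmax)
  }, numeric(1))
  expect_gt(mean(inside), 0.93)
  expect_lt(mean(inside), 0.985)
})

test_that("decoys move the mean but not the exceedance test (Fig-1 contrast)", {
  co <- simulate_cohort(sim_config(seed = 2))
  z <- zscore_normalize(co$tumor)
  degs <- call_degs(z, n_perm = 2000, seed = 2)
  dec <- co$truth$decoy_genes
  rg <- co$truth$risk_genes$tumor
  # exceedance test: flags subgroup risk genes, nearly no decoys
  expect_gt(mean(rg %in% degs$gene_id), 0.8)
  expect_lte(sum(dec %in% degs$gene_id), 0.05 * length(dec))
  # mean-difference test: detects decoys at a rate far above both the
  # nominal level and the exceedance test's decoy rate
  tt <- mean_difference_test(co$tumor)
  decoy_t_rate <- mean(tt$p_value[tt$gene_id %in% dec] < 0.05)
  expect_gt(decoy_t_rate, 0.2)
  expect_gt(decoy_t_rate, mean(dec %in% degs$gene_id) + 0.1)
})

test_that("risk pathways separate poor samples in the (U, D) plane", {
  co <- simulate_cohort(sim_config(seed = 31))
  z <- zscore_normalize(co$tumor)
  truth_degs <- data.frame(
    gene_id = co$truth$risk_genes$tumor,
    direction = ifelse(unlist(co$truth$risk_signs$tumor) > 0, "up",
                       "down"))
  sm <- score_matrix(z, co$pathways, truth_degs)
  poor <- z$annotation$group == "poor"
  risk_u <- mean(abs(sm$U[poor, co$truth$risk_pathways$tumor]))
  rest <- setdiff(colnames(sm$U), co$truth$risk_pathways$tumor)
  rest_u <- mean(abs(sm$U[poor, rest]))
  expect_gt(risk_u, rest_u + 1)
})
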