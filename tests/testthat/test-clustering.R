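test_that("duplicated samples merge first, at distance zero", {
  set.seed(15)
  v <- matrix(rnorm(40), 10, 4,
              dimnames = list(sprintf("g%02d", 1:10),
                              c("a1", "a2", "b1", "b2")))
  v[, "a2"] <- v[, "a1"]
  m <- expression_matrix(v, make_annotation(
    colnames(v), c("good", "good", "poor", "poor")))
  tree <- cluster_samples(m, rownames(v))
  expect_lt(tree$height[1], 1e-12)
  first <- tree$labels[-tree$merge[1, ]]
  expect_setequal(first, c("a1", "a2"))
  expect_error(cluster_samples(m, character(0)), "empty")
  expect_error(cluster_samples(subset_expression(m, samples = 1:2),
                               rownames(v)), "3 samples")
})

test_that("tree matches hand-computed centered correlations", {
  v <- matrix(c(1, 2, 3,
                2, 4, 6,
                3, 2, 1), 3, 3,
              dimnames = list(c("g1", "g2", "g3"), c("s1", "s2", "s3")))
  # profiles per sample: s1 = (1,2,3), s2 = (2,4,2), s3 = (3,6,1)
  v <- t(v)
  dimnames(v) <- list(c("g1", "g2", "g3"), c("s1", "s2", "s3"))
  m <- expression_matrix(v, make_annotation(
    colnames(v), c("good", "good", "poor")))
  tree <- cluster_samples(m, rownames(v))
  manual_cor <- function(x, y) {
    xc <- x - mean(x); yc <- y - mean(y)
    sum(xc * yc) / sqrt(sum(xc^2) * sum(yc^2))
  }
  d <- c(1 - manual_cor(v[, 1], v[, 2]),
         1 - manual_cor(v[, 1], v[, 3]),
         1 - manual_cor(v[, 2], v[, 3]))
  # closest pair merges first at its 1 - r distance
  expect_equal(tree$height[1], min(d), tolerance = 1e-12)
  # average linkage: second height is the mean of the two remaining
  rest <- setdiff(seq_along(d), which.min(d))
  expect_equal(tree$height[2], mean(d[rest]), tolerance = 1e-12)
})

test_that("tree topology is invariant to sample input order", {
  m <- random_expr(30, 12, seed = 27)
  tree1 <- cluster_samples(m, rownames(m$values))
  set.seed(1)
  perm <- sample(ncol(m$values))
  m2 <- subset_expression(m, samples = perm)
  tree2 <- cluster_samples(m2, rownames(m$values))
  p1 <- cut_to_clusters(tree1, 3)
  p2 <- cut_to_clusters(tree2, 3)[names(p1)]
  # same partition up to relabeling
  expect_equal(length(unique(paste(p1, p2))), 3L)
})

test_that("cutting the tree yields the requested number of clusters", {
  m <- random_expr(20, 8, seed = 2)
  tree <- cluster_samples(m, rownames(m$values))
  expect_identical(length(unique(cut_to_clusters(tree, 1))), 1L)
  expect_identical(length(unique(cut_to_clusters(tree, 8))), 8L)
  expect_error(cut_to_clusters(tree, 9), "k must be")

  # planted 2-cloud structure is recovered at k = 2
  set.seed(44)
  v <- matrix(rnorm(50 * 14), 50, 14,
              dimnames = list(sprintf("g%02d", 1:50),
                              sprintf("s%02d", 1:14)))
  v[1:25, 8:14] <- v[1:25, 8:14] + 6
  v[26:50, 1:7] <- v[26:50, 1:7] + 6
  mc <- expression_matrix(v, make_annotation(
    colnames(v), rep(c("good", "poor"), 7)))
  cl <- cut_to_clusters(cluster_samples(mc, rownames(v)), 2)
  expect_identical(length(unique(cl[1:7])), 1L)
  expect_identical(length(unique(cl[8:14])), 1L)
  expect_false(cl[1] == cl[8])
})

test_that("cluster purity reports majorities and poor-group recall", {
  truth <- setNames(rep(c("good", "poor"), c(38, 15)),
                    sprintf("s%02d", 1:53))
  # one poor sample strays into the good cluster: recall 14/15
  assignment <- setNames(c(rep(1L, 38), 1L, rep(2L, 14)), names(truth))
  pu <- cluster_purity(assignment, truth)
  expect_equal(pu$poor_recall, 14 / 15, tolerance = 1e-12)
  expect_identical(pu$poor_modal_cluster, 2L)
  expect_equal(pu$clusters$fraction[pu$clusters$cluster == 2], 1)

  pure <- setNames(c(rep(1L, 38), rep(2L, 15)), names(truth))
  expect_true(all(cluster_purity(pure, truth)$clusters$fraction == 1))

  set.seed(10)
  rand <- setNames(sample(1:3, 53, TRUE), names(truth))
  pu2 <- cluster_purity(rand, truth)
  for (cl in pu2$clusters$cluster) {
    lab <- truth[names(rand)[rand == cl]]
    tab <- sort(table(lab), decreasing = TRUE)
    expect_identical(pu2$clusters$majority[pu2$clusters$cluster == cl],
                     names(tab)[1])
  }
})

test_that("at-risk subgroup is the good cluster nearest the poor centroid", {
  # good core at 0, at-risk goods at 2, poor at 4 (one informative axis)
  set.seed(55)
  n <- c(core = 20, risk = 6, poor = 10)
  v <- matrix(rnorm(30 * sum(n), sd = 0.5), 30, sum(n))
  v[, 21:26] <- v[, 21:26] + 2
  v[, 27:36] <- v[, 27:36] + 4
  dimnames(v) <- list(sprintf("g%02d", 1:30), sprintf("s%02d", 1:36))
  m <- expression_matrix(v, make_annotation(
    colnames(v), rep(c("good", "poor"), c(26, 10))))
  assignment <- setNames(rep(c(1L, 2L, 3L), n), colnames(v))
  at_risk <- identify_at_risk(m, assignment, rownames(v))
  expect_setequal(as.character(at_risk), sprintf("s%02d", 21:26))
  expect_identical(attr(at_risk, "subgroup"), 2L)

  single <- setNames(rep(c(1L, 3L), c(26, 10)), colnames(v))
  expect_warning(none <- identify_at_risk(m, single, rownames(v)),
                 "subgroups")
  expect_length(none, 0)

  # symmetric tie breaks toward the smaller cluster id
  vt <- matrix(0, 4, 9)
  vt[1, ] <- c(-2, -2, -2, 2, 2, 2, 0, 0, 0)
  dimnames(vt) <- list(sprintf("g%d", 1:4), sprintf("t%d", 1:9))
  mt <- expression_matrix(vt + rnorm(36, sd = 1e-6), make_annotation(
    colnames(vt), rep(c("good", "good", "poor"), each = 3)))
  tie <- setNames(rep(c(1L, 2L, 3L), each = 3), colnames(vt))
  ar <- identify_at_risk(mt, tie, rownames(vt))
  expect_identical(attr(ar, "subgroup"), 1L)
})
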