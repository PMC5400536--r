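test_that("geometric center and minimal radius are order statistics", {
  expect_equal(geometric_center(rbind(c(0, 0), c(2, 2))), c(U = 1, D = 1),
               ignore_attr = TRUE)
  expect_equal(geometric_center(rbind(c(3, -1))), c(3, -1),
               ignore_attr = TRUE)
  set.seed(2)
  pts <- matrix(rnorm(200), 100, 2)
  expect_equal(geometric_center(pts),
               c(sum(pts[, 1]) / 100, sum(pts[, 2]) / 100),
               ignore_attr = TRUE)
  expect_error(geometric_center(pts[0, , drop = FALSE]), "no points")

  # 10 points at distances 1..10: 80% coverage radius is the 8th distance
  ang <- seq(0, 2 * pi, length.out = 11)[1:10]
  ring <- cbind((1:10) * cos(ang), (1:10) * sin(ang))
  expect_equal(minimal_radius(ring, c(0, 0), 0.8), 8)
  expect_equal(minimal_radius(ring, c(0, 0), 1.0), 10)

  # minimality: exactly ceil(0.8 n) points inside, and no candidate radius
  # smaller than R achieves that count
  set.seed(7)
  cloud <- matrix(rnorm(90), 45, 2)
  ctr <- geometric_center(cloud)
  R <- minimal_radius(cloud, ctr, 0.8)
  d <- sqrt(rowSums(sweep(cloud, 2, ctr)^2))
  expect_gte(sum(d <= R), ceiling(0.8 * 45))
  for (cand in sort(d)[sort(d) < R])
    expect_lt(sum(d <= cand), ceiling(0.8 * 45))
})

test_that("fitted circles honor self-coverage and separate planted clouds", {
  set.seed(5)
  good <- cbind(rnorm(38), rnorm(38))
  poor <- cbind(rnorm(15, 10), rnorm(15, 10))   # 10-SD separation
  model <- fit_center_model(good, poor)
  # self-coverage, inclusive boundary
  dg <- sqrt(rowSums(sweep(good, 2, model$center_good)^2))
  dp <- sqrt(rowSums(sweep(poor, 2, model$center_poor)^2))
  expect_gte(sum(dg <= model$radius_good), ceiling(0.8 * 38))
  expect_gte(sum(dp <= model$radius_poor), ceiling(0.8 * 15))
  # disjoint circles at this separation
  ctr_dist <- sqrt(sum((model$center_good - model$center_poor)^2))
  expect_gt(ctr_dist, model$radius_good + model$radius_poor)

  ident <- fit_center_model(good, good + 1e-9)
  expect_lt(sqrt(sum((ident$center_good - ident$center_poor)^2)), 1e-6)
  expect_lt(abs(ident$radius_good - ident$radius_poor), 1e-6)

  degen <- fit_center_model(matrix(1, 3, 2), matrix(9, 3, 2))
  expect_equal(degen$radius_good, 0)
})

test_that("sample calls follow the circle membership definitions", {
  model <- structure(list(center_good = c(0, 0), center_poor = c(4, 0),
                          radius_good = 2.5, radius_poor = 2.5,
                          coverage = 0.8), class = "CenterModel")
  pts <- rbind(only_good = c(0.5, 0), both = c(2, 0),
               neither = c(10, 10), only_poor = c(4.2, 0),
               on_good_boundary = c(-2.5, 0))
  calls <- classify_samples(model, pts)
  expect_identical(calls$call,
                   c("good", "fuzzy_intersection", "fuzzy_isolation",
                     "poor", "good"))
})

test_that("pathway evaluation excludes fuzzy samples from precision", {
  truth <- c(a = "good", b = "good", c = "poor", d = "poor", e = "good")
  calls <- data.frame(sample_id = letters[1:5],
                      call = c("good", "good", "poor", "poor",
                               "fuzzy_isolation"))
  ev <- evaluate_pathway(calls, truth)
  expect_equal(ev[c("precise1", "precise2", "fuzzy_count")],
               list(precise1 = 1, precise2 = 1, fuzzy_count = 1L))

  all_fuzzy <- data.frame(sample_id = letters[1:5],
                          call = "fuzzy_intersection")
  # one warning per empty circle (good and poor)
  expect_warning(expect_warning(
    ev2 <- evaluate_pathway(all_fuzzy, truth), "precision"), "precision")
  expect_equal(ev2$precise1, 0)
  expect_equal(ev2$fuzzy_count, 5L)

  # hand confusion-matrix tally on a seeded mixed case
  set.seed(19)
  calls3 <- data.frame(
    sample_id = sprintf("s%02d", 1:40),
    call = sample(c("good", "poor", "fuzzy_intersection",
                    "fuzzy_isolation"), 40, replace = TRUE))
  truth3 <- setNames(sample(c("good", "poor"), 40, TRUE),
                     calls3$sample_id)
  ev3 <- suppressWarnings(evaluate_pathway(calls3, truth3))
  cg <- calls3$sample_id[calls3$call == "good"]
  cp <- calls3$sample_id[calls3$call == "poor"]
  expect_equal(ev3$precise1, sum(truth3[cg] == "good") / length(cg))
  expect_equal(ev3$precise2, sum(truth3[cp] == "poor") / length(cp))
  expect_equal(ev3$mean_precision, (ev3$precise1 + ev3$precise2) / 2)

  # label swap exchanges the two precisions
  calls_sw <- calls3
  calls_sw$call <- ifelse(calls3$call == "good", "poor",
                   ifelse(calls3$call == "poor", "good", calls3$call))
  truth_sw <- ifelse(truth3 == "good", "poor", "good")
  names(truth_sw) <- names(truth3)
  ev_sw <- suppressWarnings(evaluate_pathway(calls_sw, truth_sw))
  expect_equal(ev_sw$precise1, ev3$precise2)
  expect_equal(ev_sw$precise2, ev3$precise1)
})

test_that("classification is invariant under a rigid rotation", {
  set.seed(11)
  good <- cbind(rnorm(20), rnorm(20))
  poor <- cbind(rnorm(12, 3), rnorm(12, 1))
  pts <- rbind(good, poor)
  rownames(pts) <- sprintf("s%02d", 1:32)
  model <- fit_center_model(good, poor)
  calls <- classify_samples(model, pts)

  th <- 0.83
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  model_r <- fit_center_model(good %*% rot, poor %*% rot)
  pts_r <- pts %*% rot
  rownames(pts_r) <- rownames(pts)
  expect_identical(classify_samples(model_r, pts_r)$call, calls$call)
})

test_that("pathway ranking filters, sorts and breaks ties as documented", {
  evals <- data.frame(pathway_id = c("A", "B", "C"),
                      precise1 = c(0.8, 0.6, 0.7),
                      precise2 = c(0.8, 0.6, 0.7),
                      fuzzy_count = c(1L, 1L, 1L),
                      mean_precision = c(0.8, 0.6, 0.7))
  expect_identical(rank_pathways(evals, top_k = 2)$pathway_id, c("A", "C"))
  expect_warning(none <- rank_pathways(evals, threshold = 0.9), "no pathway")
  expect_identical(nrow(none), 0L)

  set.seed(3)
  big <- data.frame(pathway_id = sprintf("pw%03d", 1:278),
                    precise1 = runif(278), precise2 = runif(278),
                    fuzzy_count = sample(0:20, 278, TRUE))
  big$mean_precision <- (big$precise1 + big$precise2) / 2
  got <- rank_pathways(big, threshold = 0.65, top_k = 4)
  keep <- big[big$mean_precision > 0.65, ]
  ord <- order(-keep$mean_precision, -pmin(keep$precise1, keep$precise2),
               keep$fuzzy_count, keep$pathway_id)
  expect_identical(got$pathway_id, head(keep$pathway_id[ord], 4))
})

test_that("risk overlap is plain set arithmetic", {
  expect_equal(risk_overlap(c("a", "b"), c("a", "b")), 1)
  expect_equal(risk_overlap(c("a", "b"), c("c")), 0)
  expect_warning(z <- risk_overlap(character(0), "a"), "no intersection")
  expect_equal(z, 0)
  set.seed(9)
  fz <- sample(letters, 10)
  ar <- sample(letters, 12)
  expect_equal(risk_overlap(fz, ar),
               length(intersect(fz, ar)) / length(fz))
})

test_that("mean precision degrades as cloud separation shrinks", {
  prec_at <- function(sep) {
    set.seed(41)
    good <- cbind(rnorm(38), rnorm(38))
    poor <- cbind(rnorm(15, sep), rnorm(15, sep))
    pts <- rbind(good, poor)
    rownames(pts) <- sprintf("s%02d", 1:53)
    truth <- setNames(rep(c("good", "poor"), c(38, 15)), rownames(pts))
    model <- fit_center_model(good, poor)
    suppressWarnings(
      evaluate_pathway(classify_samples(model, pts), truth))$mean_precision
  }
  p10 <- prec_at(10); p2 <- prec_at(2); p0 <- prec_at(0.3)
  expect_equal(p10, 1)
  expect_gte(p10, p2)
  expect_gt(p2, p0)
})
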