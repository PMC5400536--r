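# Cross-validated classifiers on risk-pathway features, ROC/AUC reporting,
# and hypergeometric hallmark enrichment.

#' Build a feature table from risk-pathway deviation scores
#'
#' One column pair (U, D) per risk pathway, ordered by pathway rank with U
#' before D.
#'
#' @param scores ScoreMatrix.
#' @param risk_pathways character vector of pathway ids, in rank order.
#' @return samples x (2 * k) numeric matrix, columns \code{<id>.U},
#'   \code{<id>.D}.
#' @export
build_features <- function(scores, risk_pathways) {
  if (length(risk_pathways) == 0L) stop("empty risk-pathway list")
  cols <- lapply(risk_pathways, function(p) pathway_points(scores, p))
  out <- do.call(cbind, cols)
  colnames(out) <- as.vector(t(outer(risk_pathways, c("U", "D"),
                                     paste, sep = ".")))
  out
}

# Empirical ROC as a step function: points sorted by decreasing score,
# ties grouped. Returns FPR/TPR including (0,0) and (1,1).
roc_points <- function(score, label, positive = "poor") {
  is_pos <- label == positive
  ord <- order(score, decreasing = TRUE)
  sc <- score[ord]; pos <- is_pos[ord]
  keep <- c(diff(sc) != 0, TRUE)   # last index of each tie group
  tpr <- cumsum(pos)[keep] / sum(pos)
  fpr <- cumsum(!pos)[keep] / sum(!pos)
  data.frame(fpr = c(0, fpr), tpr = c(0, tpr))
}

# Rank-based (Mann-Whitney) AUC with tie correction.
auc_rank <- function(score, label, positive = "poor") {
  is_pos <- label == positive
  r <- rank(score)
  (sum(r[is_pos]) - sum(is_pos) * (sum(is_pos) + 1) / 2) /
    (sum(is_pos) * sum(!is_pos))
}

# TPR of a step-function ROC at each FPR of a grid (right-continuous).
tpr_at <- function(roc, fpr_grid) {
  vapply(fpr_grid, function(f) max(roc$tpr[roc$fpr <= f]), numeric(1))
}

#' Stratified k-fold cross-validation of a classifier on labeled features
#'
#' Folds are stratified so every training split contains both classes.
#' Decision scores on the held-out fold (class-probability of the poor
#' class) give a per-fold ROC and AUC; the mean ROC is computed by vertical
#' averaging of the fold curves on a 101-point FPR grid. Per-fold
#' classification accuracy (score > 0.5) is reported alongside AUC since
#' "accuracy" is used for both in this literature.
#'
#' @param features samples x features numeric matrix.
#' @param labels character/factor vector of \code{good}/\code{poor}, one
#'   per sample.
#' @param model \code{"random_forest"} (500 trees) or \code{"svm"} (RBF
#'   kernel, probability scores).
#' @param folds number of folds (default 5).
#' @param seed integer RNG seed; the whole procedure is deterministic given
#'   it.
#' @return list of class \code{CvResult}: \code{fold_auc},
#'   \code{mean_auc}, \code{fold_accuracy}, \code{mean_accuracy},
#'   \code{fold_roc} (list of FPR/TPR data.frames), \code{mean_roc}
#'   (101-point grid), \code{model}, \code{seed}.
#' @export
cross_validate <- function(features, labels,
                           model = c("random_forest", "svm"),
                           folds = 5, seed) {
  model <- match.arg(model)
  labels <- factor(as.character(labels), levels = c("good", "poor"))
  if (min(table(labels)) < folds)
    stop("a class has fewer members than folds; reduce 'folds'")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(seed)
  fold_id <- integer(length(labels))
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    fold_id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  grid <- seq(0, 1, length.out = 101)
  fold_auc <- fold_acc <- numeric(folds)
  fold_roc <- vector("list", folds)
  tprs <- matrix(0, folds, length(grid))
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    if (model == "random_forest") {
      fit <- randomForest::randomForest(
        x = features[tr, , drop = FALSE], y = labels[tr], ntree = 500)
      sc <- stats::predict(fit, features[!tr, , drop = FALSE],
                           type = "prob")[, "poor"]
    } else {
      fit <- e1071::svm(x = features[tr, , drop = FALSE], y = labels[tr],
                        kernel = "radial", probability = TRUE)
      pr <- stats::predict(fit, features[!tr, , drop = FALSE],
                           probability = TRUE)
      sc <- attr(pr, "probabilities")[, "poor"]
    }
    te_lab <- as.character(labels[!tr])
    fold_auc[f] <- auc_rank(sc, te_lab)
    fold_acc[f] <- mean(ifelse(sc > 0.5, "poor", "good") == te_lab)
    fold_roc[[f]] <- roc_points(sc, te_lab)
    tprs[f, ] <- tpr_at(fold_roc[[f]], grid)
  }
  structure(list(fold_auc = fold_auc, mean_auc = mean(fold_auc),
                 fold_accuracy = fold_acc, mean_accuracy = mean(fold_acc),
                 fold_roc = fold_roc,
                 mean_roc = data.frame(fpr = grid, tpr = colMeans(tprs)),
                 model = model, folds = folds, seed = seed),
            class = "CvResult")
}

#' @export
print.CvResult <- function(x, ...) {
  cat(sprintf("%d-fold CV (%s): mean AUC %.3f, mean accuracy %.3f\n",
              x$folds, x$model, x$mean_auc, x$mean_accuracy))
  invisible(x)
}

#' Hypergeometric enrichment of a gene set in hallmark categories
#'
#' Upper-tail hypergeometric test of the overlap between a query gene set
#' and each hallmark set, both intersected with the expression universe.
#' Significance at raw p < 0.05 by default; set \code{adjust = TRUE} for BH.
#'
#' @param query_genes character vector (must be a subset of
#'   \code{universe}).
#' @param hallmark_sets named list of hallmark member vectors.
#' @param universe character vector of all assayed genes.
#' @param alpha significance level (default 0.05).
#' @param adjust apply BH correction before thresholding (default FALSE).
#' @return data.frame: \code{hallmark_id}, \code{overlap}, \code{set_size},
#'   \code{query_size}, \code{universe_size}, \code{p_value},
#'   \code{significant}.
#' @export
hallmark_enrichment <- function(query_genes, hallmark_sets, universe,
                                alpha = 0.05, adjust = FALSE) {
  if (length(universe) == 0L) stop("empty universe")
  universe <- unique(universe)
  if (!all(query_genes %in% universe))
    stop("query genes must be a subset of the universe")
  query_genes <- unique(query_genes)
  N <- length(universe); n <- length(query_genes)
  rows <- lapply(names(hallmark_sets), function(h) {
    set <- intersect(hallmark_sets[[h]], universe)
    K <- length(set)
    k <- length(intersect(set, query_genes))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(hallmark_id = h, overlap = k, set_size = K,
               query_size = n, universe_size = N, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  p_eff <- if (adjust) stats::p.adjust(out$p_value, "BH") else out$p_value
  out$significant <- p_eff < alpha
  out
}
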