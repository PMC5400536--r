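# Sample clustering on DEG expression with centered-Pearson similarity
# (distance = 1 - r), average linkage, and identification of the good-group
# subgroup nearest the poor group ("at-risk").

#' Hierarchically cluster samples on DEG rows
#'
#' Distance between samples is 1 - centered Pearson correlation of their
#' DEG expression profiles; agglomeration is average linkage by default.
#'
#' @param m ExpressionMatrix (filtered and median-centered upstream).
#' @param degs character vector of DEG gene ids present in \code{m}.
#' @param linkage hclust method (default \code{"average"}).
#' @return \code{hclust} tree over samples.
#' @export
cluster_samples <- function(m, degs, linkage = "average") {
  if (length(degs) == 0L) stop("empty DEG set")
  if (ncol(m$values) < 3L) stop("need >= 3 samples to cluster")
  miss <- setdiff(degs, rownames(m$values))
  if (length(miss)) stop("DEG not in matrix: ", miss[1L])
  v <- m$values[degs, , drop = FALSE]
  d <- stats::as.dist(1 - stats::cor(v))
  stats::hclust(d, method = linkage)
}

#' Cut a sample tree into k clusters
#'
#' @param tree hclust tree from \code{\link{cluster_samples}}.
#' @param k number of clusters (1 <= k <= n).
#' @return named integer vector: cluster id per sample.
#' @export
cut_to_clusters <- function(tree, k) {
  n <- length(tree$order)
  if (k < 1L || k > n) stop("k must be in [1, n]")
  stats::cutree(tree, k = k)
}

#' Cluster purity against true prognosis groups
#'
#' For each cluster, its majority group label and that label's fraction;
#' also the recall of the poor group's modal cluster (the fraction of all
#' poor samples that land in the cluster holding most of them).
#'
#' @param assignment named cluster vector from
#'   \code{\link{cut_to_clusters}}.
#' @param truth named character vector sample_id -> good/poor.
#' @return list with \code{clusters} (data.frame: cluster, n, majority,
#'   fraction) and \code{poor_recall}.
#' @export
cluster_purity <- function(assignment, truth) {
  if (!all(names(assignment) %in% names(truth)))
    stop("truth must cover all samples")
  tr <- truth[names(assignment)]
  rows <- lapply(sort(unique(assignment)), function(cl) {
    lab <- tr[assignment == cl]
    tab <- sort(table(lab), decreasing = TRUE)
    data.frame(cluster = cl, n = length(lab),
               majority = names(tab)[1L],
               fraction = as.numeric(tab[1L]) / length(lab),
               stringsAsFactors = FALSE)
  })
  poor_by_cluster <- table(assignment[tr == "poor"])
  modal <- names(poor_by_cluster)[which.max(poor_by_cluster)]
  list(clusters = do.call(rbind, rows),
       poor_recall = max(poor_by_cluster) / sum(tr == "poor"),
       poor_modal_cluster = as.integer(modal))
}

#' Identify the at-risk subgroup of good-prognosis samples
#'
#' Good-prognosis samples are split into subgroups by their cluster
#' membership; the subgroup whose centroid (in DEG expression space) lies
#' closest to the poor-group centroid is flagged at risk of recurrence.
#' With fewer than two good subgroups nothing is flagged (warning). Ties
#' break toward the smaller cluster id.
#'
#' @param m ExpressionMatrix the tree was built on.
#' @param assignment named cluster vector.
#' @param degs DEG gene ids defining the expression space.
#' @return character vector of at-risk sample ids (possibly empty);
#'   attribute \code{"subgroup"} gives the flagged cluster id.
#' @export
identify_at_risk <- function(m, assignment, degs) {
  v <- m$values[degs, names(assignment), drop = FALSE]
  grp <- m$annotation$group[match(names(assignment),
                                  m$annotation$sample_id)]
  good_ids <- names(assignment)[grp == "good"]
  poor_ids <- names(assignment)[grp == "poor"]
  subs <- sort(unique(assignment[good_ids]))
  if (length(subs) < 2L) {
    warning("good group not split into >= 2 subgroups; no at-risk call")
    return(structure(character(0), subgroup = NA_integer_))
  }
  poor_centroid <- rowMeans(v[, poor_ids, drop = FALSE])
  dist_to_poor <- vapply(subs, function(cl) {
    ids <- good_ids[assignment[good_ids] == cl]
    sqrt(sum((rowMeans(v[, ids, drop = FALSE]) - poor_centroid)^2))
  }, numeric(1))
  flagged <- subs[which.min(dist_to_poor)]   # which.min: first = smallest id
  structure(good_ids[assignment[good_ids] == flagged],
            subgroup = as.integer(flagged))
}
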