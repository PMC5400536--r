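# Two-circle geometric classifier in the (U, D) plane with a reject option.
# Each group gets a circle: center = coordinate-wise mean of the group's
# training points, radius = smallest value covering at least 80% of them.
# A sample inside exactly one circle takes that circle's label; inside both
# it is fuzzy (intersection), inside neither fuzzy (isolation).

#' Geometric center (coordinate-wise mean) of a point cloud
#'
#' @param points n x 2 numeric matrix of (U, D) points.
#' @return length-2 numeric vector.
#' @export
geometric_center <- function(points) {
  points <- rbind(points)
  if (nrow(points) == 0L) stop("no points")
  colMeans(points)
}

#' Minimal radius covering a fraction of points around a center
#'
#' R is the ceil(coverage * n)-th smallest Euclidean distance from the
#' center; containment is inclusive (distance <= R), so ties at R are
#' inside. Coverage below 100% absorbs within-group heterogeneity and
#' keeps outliers from inflating the circle.
#'
#' @param points n x 2 matrix.
#' @param center length-2 center.
#' @param coverage fraction of points the circle must contain (default 0.8).
#' @return non-negative radius.
#' @export
minimal_radius <- function(points, center, coverage = 0.8) {
  points <- rbind(points)
  if (nrow(points) == 0L) stop("no points")
  if (coverage <= 0 || coverage > 1) stop("coverage must be in (0, 1]")
  d <- sqrt((points[, 1L] - center[1L])^2 + (points[, 2L] - center[2L])^2)
  sort(d)[ceiling(coverage * length(d))]
}

#' Fit the two-circle model for one pathway
#'
#' @param points_good,points_poor (U, D) training points of the two groups
#'   (each >= 2 rows).
#' @param coverage per-circle coverage fraction (default 0.8).
#' @return object of class \code{CenterModel}: centers, radii, coverage.
#' @export
fit_center_model <- function(points_good, points_poor, coverage = 0.8) {
  points_good <- rbind(points_good)
  points_poor <- rbind(points_poor)
  if (nrow(points_good) < 2L || nrow(points_poor) < 2L)
    stop("each group needs >= 2 training points")
  cg <- geometric_center(points_good)
  cp <- geometric_center(points_poor)
  structure(list(center_good = cg, center_poor = cp,
                 radius_good = minimal_radius(points_good, cg, coverage),
                 radius_poor = minimal_radius(points_poor, cp, coverage),
                 coverage = coverage),
            class = "CenterModel")
}

#' Classify samples with a fitted two-circle model
#'
#' @param model CenterModel.
#' @param points n x 2 matrix of (U, D) points, rownames = sample ids.
#' @return data.frame with \code{sample_id} and \code{call} in
#'   \{\code{good}, \code{poor}, \code{fuzzy_intersection},
#'   \code{fuzzy_isolation}\}.
#' @export
classify_samples <- function(model, points) {
  points <- rbind(points)
  dg <- sqrt((points[, 1L] - model$center_good[1L])^2 +
             (points[, 2L] - model$center_good[2L])^2)
  dp <- sqrt((points[, 1L] - model$center_poor[1L])^2 +
             (points[, 2L] - model$center_poor[2L])^2)
  in_g <- dg <= model$radius_good
  in_p <- dp <= model$radius_poor
  call <- ifelse(in_g & in_p, "fuzzy_intersection",
          ifelse(!in_g & !in_p, "fuzzy_isolation",
          ifelse(in_g, "good", "poor")))
  ids <- rownames(points)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(points)))
  data.frame(sample_id = ids, call = call, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Evaluate one pathway's classification against true groups
#'
#' precise1 is the precision of the good circle (fraction of samples called
#' good that are truly good), precise2 that of the poor circle; fuzzy
#' samples are excluded from both denominators. An empty denominator yields
#' precision 0 with a warning.
#'
#' @param calls data.frame from \code{\link{classify_samples}}.
#' @param truth named character vector mapping sample_id to
#'   \code{good}/\code{poor}.
#' @return list with \code{precise1}, \code{precise2}, \code{fuzzy_count},
#'   \code{mean_precision}.
#' @export
evaluate_pathway <- function(calls, truth) {
  if (!all(calls$sample_id %in% names(truth)))
    stop("truth must cover all classified samples")
  tr <- truth[calls$sample_id]
  prec <- function(label) {
    called <- calls$call == label
    if (!any(called)) {
      warning("no samples called '", label, "'; precision reported as 0")
      return(0)
    }
    mean(tr[called] == label)
  }
  p1 <- prec("good")
  p2 <- prec("poor")
  list(precise1 = p1, precise2 = p2,
       fuzzy_count = sum(calls$call %in%
                           c("fuzzy_intersection", "fuzzy_isolation")),
       mean_precision = (p1 + p2) / 2)
}

#' Fit, classify and evaluate every pathway of a ScoreMatrix
#'
#' Training and evaluation use the same cohort (resubstitution), matching
#' how the pathway precision tables are constructed.
#'
#' @param scores ScoreMatrix.
#' @param annotation the cohort annotation (sample_id, group).
#' @param coverage circle coverage (default 0.8).
#' @return data.frame: \code{pathway_id}, \code{precise1}, \code{precise2},
#'   \code{fuzzy_count}, \code{mean_precision}; per-pathway calls in
#'   attribute \code{"calls"}.
#' @export
evaluate_pathways <- function(scores, annotation, coverage = 0.8) {
  truth <- stats::setNames(annotation$group, annotation$sample_id)
  good_ids <- annotation$sample_id[annotation$group == "good"]
  poor_ids <- annotation$sample_id[annotation$group == "poor"]
  all_calls <- list()
  rows <- lapply(scores$pathway_ids, function(p) {
    pts <- pathway_points(scores, p)
    model <- fit_center_model(pts[good_ids, , drop = FALSE],
                              pts[poor_ids, , drop = FALSE], coverage)
    calls <- classify_samples(model, pts)
    all_calls[[p]] <<- calls
    ev <- suppressWarnings(evaluate_pathway(calls, truth))
    data.frame(pathway_id = p, precise1 = ev$precise1,
               precise2 = ev$precise2, fuzzy_count = ev$fuzzy_count,
               mean_precision = ev$mean_precision,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "calls") <- all_calls
  out
}

#' Rank pathways and keep the top risk-associated ones
#'
#' Pathways with mean precision above \code{threshold}, sorted by mean
#' precision (descending), truncated to \code{top_k}. Ties break by higher
#' min(precise1, precise2), then fewer fuzzy samples, then pathway id.
#'
#' @param evals data.frame from \code{\link{evaluate_pathways}}.
#' @param threshold mean-precision cutoff (default 0.65).
#' @param top_k maximum number retained (default 4).
#' @return the qualifying rows, ranked; empty with a warning if none pass.
#' @export
rank_pathways <- function(evals, threshold = 0.65, top_k = 4) {
  keep <- evals[evals$mean_precision > threshold, , drop = FALSE]
  if (nrow(keep) == 0L) {
    warning("no pathway exceeds mean precision ", threshold)
    return(keep)
  }
  ord <- order(-keep$mean_precision,
               -pmin(keep$precise1, keep$precise2),
               keep$fuzzy_count, keep$pathway_id)
  keep <- keep[ord, , drop = FALSE]
  rownames(keep) <- NULL
  utils::head(keep, top_k)
}

#' Overlap of intersection-fuzzy samples with the at-risk subgroup
#'
#' @param fuzzy_intersection_samples sample ids called fuzzy by
#'   intersection.
#' @param at_risk_samples sample ids of the at-risk clustering subgroup.
#' @return fraction of intersection-fuzzy samples that are at-risk; 0 with
#'   a warning when there are no intersection samples.
#' @export
risk_overlap <- function(fuzzy_intersection_samples, at_risk_samples) {
  if (length(fuzzy_intersection_samples) == 0L) {
    warning("no intersection-fuzzy samples; overlap reported as 0")
    return(0)
  }
  length(intersect(fuzzy_intersection_samples, at_risk_samples)) /
    length(fuzzy_intersection_samples)
}
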