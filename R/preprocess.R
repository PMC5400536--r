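# Normalization and clustering pre-filters.
# SD convention: population SD (divide by n) throughout, matching the
# reference-interval statistics.

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

row_pop_sd <- function(v) {
  mu <- rowMeans(v)
  sqrt(rowMeans((v - mu)^2))
}

#' Z-score normalize an expression matrix per gene, within each tissue
#'
#' Each gene row is centered and scaled to population SD 1 across all samples
#' (good and poor pooled) of one tissue; tumor and normal samples are
#' normalized independently. Pooling the groups only affects the scale:
#' the good-group reference-interval statistics are recomputed downstream on
#' the good samples alone.
#'
#' @param m ExpressionMatrix.
#' @return ExpressionMatrix in z-units. Zero-variance genes are retained as
#'   all-zero rows with a warning (they can never exceed any interval).
#' @export
zscore_normalize <- function(m) {
  v <- m$values
  out <- v
  for (tis in unique(m$annotation$tissue)) {
    idx <- m$annotation$tissue == tis
    sub <- v[, idx, drop = FALSE]
    mu <- rowMeans(sub)
    sdv <- row_pop_sd(sub)
    flat <- sdv == 0
    if (any(flat)) {
      warning(sum(flat), " zero-variance gene(s) set to all-zero in tissue ",
              tis)
      sdv[flat] <- 1
    }
    out[, idx] <- (sub - mu) / sdv
  }
  expression_matrix(out, m$annotation)
}

#' Filter genes for clustering by presence and variability
#'
#' Retains genes expressed (strictly above \code{floor}) in at least
#' \code{presence_frac} of samples and with population SD greater than
#' \code{sd_min}. With no missing/floored values the presence criterion is
#' vacuous and the filter reduces to the SD cut.
#'
#' @param m ExpressionMatrix.
#' @param presence_frac minimum fraction of samples in which a gene must be
#'   expressed (default 0.8).
#' @param sd_min minimum population SD (default 1).
#' @param floor values less than or equal to this sentinel count as not
#'   expressed; default \code{-Inf} (no missing-value convention).
#' @return filtered ExpressionMatrix, gene order preserved.
#' @export
filter_for_clustering <- function(m, presence_frac = 0.8, sd_min = 1.0,
                                  floor = -Inf) {
  v <- m$values
  present <- rowMeans(v > floor) >= presence_frac
  keep <- present & row_pop_sd(v) > sd_min
  if (!any(keep))
    stop("no genes pass the clustering filter; relax 'presence_frac' or ",
         "'sd_min'")
  subset_expression(m, genes = which(keep))
}

#' Median-center a matrix by genes, then by samples
#'
#' One pass each (Cluster-3.0-style): gene medians are subtracted first,
#' then sample medians.
#'
#' @param m ExpressionMatrix.
#' @return median-centered ExpressionMatrix.
#' @export
median_center <- function(m) {
  v <- m$values
  v <- v - apply(v, 1L, stats::median)
  v <- sweep(v, 2L, apply(v, 2L, stats::median))
  expression_matrix(v, m$annotation)
}
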