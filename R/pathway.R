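#' Pathway deviation score of one sample (mean cubed deviations)
#'
#' A pathway's deviation in a sample is summarized by two numbers: U, the
#' mean cubed deviation of the sample's expression from the good-group gene
#' means over the pathway's up-regulated DEGs, and D, the same over its
#' down-regulated DEGs. Cubing preserves the deviation sign while amplifying
#' large excursions, so imbalance in a pathway shows up even when individual
#' genes move modestly.
#'
#' @param sample_values named numeric vector, the sample's expression by gene.
#' @param up_genes,down_genes character vectors: the pathway's members that
#'   are up-/down-regulated DEGs (an empty set contributes 0).
#' @param good_means named numeric vector of per-gene means over the
#'   good-prognosis samples of the same tissue.
#' @return list with \code{U} and \code{D}.
#' @export
deviation_vector <- function(sample_values, up_genes, down_genes,
                             good_means) {
  one <- function(genes) {
    if (length(genes) == 0L) return(0)
    miss <- genes[!(genes %in% names(sample_values))]
    if (length(miss)) stop("gene missing from sample values: ", miss[1L])
    miss <- genes[!(genes %in% names(good_means))]
    if (length(miss)) stop("gene missing from good-group means: ", miss[1L])
    sum((sample_values[genes] - good_means[genes])^3) / length(genes)
  }
  list(U = one(up_genes), D = one(down_genes))
}

#' Per-sample, per-pathway deviation score matrices
#'
#' Scores every sample (good and poor) on every pathway. Up/down membership
#' comes from the DEG table's \code{direction} column intersected with the
#' pathway members present in the matrix; per-gene means are computed over
#' the good-prognosis samples only.
#'
#' @param m z-normalized ExpressionMatrix, one tissue.
#' @param sets named list of pathway member vectors (see
#'   \code{\link{read_gmt}}).
#' @param degs data.frame with \code{gene_id} and \code{direction}
#'   (\code{up}/\code{down}) as returned by \code{\link{call_degs}}.
#' @return object of class \code{ScoreMatrix}: list with \code{U} and
#'   \code{D} (samples x pathways matrices), \code{sample_ids},
#'   \code{pathway_ids}.
#' @export
score_matrix <- function(m, sets, degs) {
  v <- m$values
  good_means <- rowMeans(v[, m$annotation$group == "good", drop = FALSE])
  up <- degs$gene_id[degs$direction == "up"]
  down <- degs$gene_id[degs$direction == "down"]
  dev3 <- (v - good_means)^3   # genes x samples
  n_s <- ncol(v)
  U <- D <- matrix(0, n_s, length(sets),
                   dimnames = list(colnames(v), names(sets)))
  absent <- character(0)
  for (p in names(sets)) {
    members <- sets[[p]]
    expressed <- intersect(members, rownames(v))
    if (length(expressed) == 0L) absent <- c(absent, p)
    pu <- intersect(expressed, up)
    pd <- intersect(expressed, down)
    if (length(pu))
      U[, p] <- colSums(dev3[pu, , drop = FALSE]) / length(pu)
    if (length(pd))
      D[, p] <- colSums(dev3[pd, , drop = FALSE]) / length(pd)
  }
  if (length(absent))
    warning(length(absent), " pathway(s) with no expressed members ",
            "scored 0: ", paste(utils::head(absent, 3), collapse = ", "))
  structure(list(U = U, D = D, sample_ids = colnames(v),
                 pathway_ids = names(sets)),
            class = "ScoreMatrix")
}

#' @export
print.ScoreMatrix <- function(x, ...) {
  cat(sprintf("ScoreMatrix: %d samples x %d pathways (U, D)\n",
              length(x$sample_ids), length(x$pathway_ids)))
  invisible(x)
}

#' Extract the (U, D) points of one pathway
#'
#' @param scores ScoreMatrix.
#' @param pathway_id pathway identifier.
#' @return samples x 2 matrix with columns \code{U}, \code{D}.
#' @export
pathway_points <- function(scores, pathway_id) {
  if (!pathway_id %in% scores$pathway_ids)
    stop("unknown pathway id: ", pathway_id)
  cbind(U = scores$U[, pathway_id], D = scores$D[, pathway_id])
}
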