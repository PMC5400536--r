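#' Reference interval of a gene from good-prognosis samples
#'
#' The "normal" expression range of a gene is mean +/- k * SD of its values
#' in the good-prognosis (non-recurrent) group, with k = 1.96 covering ~95%
#' of a Gaussian. Population SD, matching \code{\link{zscore_normalize}}.
#'
#' @param good_values numeric vector of the gene's values in the good group
#'   (length >= 2).
#' @param k half-width in SD units (default 1.96).
#' @return list with \code{mean}, \code{sd}, \code{xmin}, \code{xmax}.
#' @export
compute_reference_interval <- function(good_values, k = 1.96) {
  if (length(good_values) < 2L)
    stop("need at least 2 good-group values to fit a reference interval")
  mu <- mean(good_values)
  sdv <- pop_sd(good_values)
  list(mean = mu, sd = sdv, xmin = mu - k * sdv, xmax = mu + k * sdv)
}

#' Summed exceedance of case samples beyond a reference interval
#'
#' For each case sample the deviation is the distance by which its value
#' falls outside the interval (0 if inside). The score sums absolute
#' deviations so that above- and below-interval excursions cannot cancel;
#' the signed sum is kept separately to call the direction.
#'
#' @param case_values numeric vector of case (poor-group) values.
#' @param interval list with \code{xmin}, \code{xmax} (see
#'   \code{\link{compute_reference_interval}}).
#' @return list with \code{score} (sum of |deviations|, >= 0) and
#'   \code{signed_score} (sum of signed deviations).
#' @export
exceedance_score <- function(case_values, interval) {
  up <- pmax(case_values - interval$xmax, 0)
  dn <- pmax(interval$xmin - case_values, 0)
  list(score = sum(up) + sum(dn), signed_score = sum(up) - sum(dn))
}

# Vectorized observed scores for a genes x samples matrix split into
# good (reference) and case columns. Returns score/signed per gene.
exceedance_scores_matrix <- function(values, good_idx, case_idx, k = 1.96) {
  g <- values[, good_idx, drop = FALSE]
  mu <- rowMeans(g)
  sdv <- row_pop_sd(g)
  xmax <- mu + k * sdv
  xmin <- mu - k * sdv
  x <- values[, case_idx, drop = FALSE]
  up <- pmax(x - xmax, 0)
  dn <- pmax(xmin - x, 0)
  list(score = rowSums(up) + rowSums(dn),
       signed_score = rowSums(up) - rowSums(dn))
}

#' Permutation p-values for per-gene exceedance scores
#'
#' The null keeps the cohort fixed and randomizes only the good/poor labels:
#' in each iteration n1 samples are drawn as a random "good" set, the
#' reference interval is recomputed from them, and the remaining n2 samples
#' are scored. p = (1 + #\{random score >= observed\}) / (B + 1) (add-one
#' estimator, so p >= 1/(B+1) and ties count against significance). One
#' label shuffle scores all genes, which is valid because the null permutes
#' samples, not genes.
#'
#' @param m z-normalized ExpressionMatrix restricted to one tissue.
#' @param n_perm number of label permutations B (default 10000).
#' @param seed integer RNG seed.
#' @param k interval half-width in SD units (default 1.96).
#' @return data.frame with \code{gene_id}, \code{score},
#'   \code{signed_score}, \code{p_value}.
#' @export
permutation_pvalues <- function(m, n_perm = 10000, seed, k = 1.96) {
  tis <- unique(m$annotation$tissue)
  if (length(tis) != 1L)
    stop("permutation test runs on one tissue at a time; subset first")
  good_idx <- which(m$annotation$group == "good")
  case_idx <- which(m$annotation$group == "poor")
  if (length(case_idx) == 0L) stop("no poor-group samples")
  if (length(good_idx) < 2L) stop("need >= 2 good-group samples")
  if (n_perm < 1L) stop("n_perm must be >= 1")
  v <- m$values
  obs <- exceedance_scores_matrix(v, good_idx, case_idx, k = k)
  n <- ncol(v)
  n1 <- length(good_idx)
  hits <- numeric(nrow(v))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(seed)
  for (b in seq_len(n_perm)) {
    perm <- sample.int(n)
    sc <- exceedance_scores_matrix(v, perm[seq_len(n1)], perm[-seq_len(n1)],
                                   k = k)
    hits <- hits + (sc$score >= obs$score)
  }
  data.frame(gene_id = rownames(v),
             score = obs$score,
             signed_score = obs$signed_score,
             p_value = (1 + hits) / (n_perm + 1),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg q-values
#'
#' @param p_values numeric vector of p-values in (0, 1].
#' @return step-up q-values, each capped at 1.
#' @export
fdr_correct <- function(p_values) {
  if (any(p_values <= 0 | p_values > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Call differentially expressed genes by exceedance permutation test
#'
#' Runs \code{\link{permutation_pvalues}}, applies BH correction, and
#' returns the genes significant at \code{q < alpha} with a direction call
#' from the sign of the signed score (\code{up}, \code{down}, or \code{none}
#' for an exact tie, which is warned about). The full per-gene table is
#' attached as attribute \code{"full"}.
#'
#' @param m z-normalized ExpressionMatrix, one tissue.
#' @param alpha FDR threshold (default 0.05).
#' @param n_perm permutations (default 10000).
#' @param seed integer RNG seed.
#' @return data.frame of significant genes: \code{gene_id}, \code{score},
#'   \code{signed_score}, \code{p_value}, \code{q_value}, \code{direction}.
#' @export
call_degs <- function(m, alpha = 0.05, n_perm = 10000, seed) {
  tab <- permutation_pvalues(m, n_perm = n_perm, seed = seed)
  tab$q_value <- fdr_correct(tab$p_value)
  tab$direction <- ifelse(tab$signed_score > 0, "up",
                          ifelse(tab$signed_score < 0, "down", "none"))
  sig <- tab[tab$q_value < alpha, , drop = FALSE]
  if (any(sig$direction == "none") && nrow(sig))
    warning(sum(sig$direction == "none"),
            " significant gene(s) with exactly tied up/down exceedance; ",
            "direction set to 'none'")
  rownames(sig) <- NULL
  attr(sig, "full") <- tab
  sig
}

#' Per-gene two-sample t-test (mean-difference comparator)
#'
#' The conventional mean-shift test used as a comparator for the exceedance
#' test: a gene whose expression is shifted in only a small subgroup of case
#' samples moves the group mean little, while a uniform within-interval
#' shift moves it a lot. Welch t-test per gene, good vs poor.
#'
#' @param m ExpressionMatrix, one tissue.
#' @param var_equal pooled-variance t-test instead of Welch (default
#'   FALSE).
#' @return data.frame with \code{gene_id}, \code{t}, \code{p_value}.
#' @export
mean_difference_test <- function(m, var_equal = FALSE) {
  good <- m$values[, m$annotation$group == "good", drop = FALSE]
  poor <- m$values[, m$annotation$group == "poor", drop = FALSE]
  res <- vapply(seq_len(nrow(m$values)), function(i) {
    ht <- stats::t.test(poor[i, ], good[i, ], var.equal = var_equal)
    c(ht$statistic, ht$p.value)
  }, numeric(2))
  data.frame(gene_id = rownames(m$values), t = res[1L, ],
             p_value = res[2L, ], row.names = NULL,
             stringsAsFactors = FALSE)
}
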