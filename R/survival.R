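# Survival comparison of patients with vs without expression alterations in
# risk-associated genes. "Altered" means expression outside the gene's
# good-group reference interval in at least one listed gene.

#' Flag samples altered in at least one gene of a set
#'
#' @param m ExpressionMatrix (z-normalized, one tissue).
#' @param genes character vector of gene ids.
#' @param intervals named list of reference intervals (per gene, from
#'   \code{\link{compute_reference_interval}}); computed from \code{m}'s
#'   good group if omitted.
#' @return named logical vector per sample: TRUE iff >= 1 listed gene lies
#'   outside its interval.
#' @export
mark_altered <- function(m, genes, intervals = NULL) {
  miss <- setdiff(genes, rownames(m$values))
  if (length(miss)) stop("gene missing from matrix: ", miss[1L])
  if (is.null(intervals)) {
    good <- m$values[, m$annotation$group == "good", drop = FALSE]
    intervals <- lapply(genes, function(g)
      compute_reference_interval(good[g, ]))
    names(intervals) <- genes
  }
  miss <- setdiff(genes, names(intervals))
  if (length(miss)) stop("no interval for gene: ", miss[1L])
  altered <- rep(FALSE, ncol(m$values))
  names(altered) <- colnames(m$values)
  for (g in genes) {
    iv <- intervals[[g]]
    altered <- altered | m$values[g, ] > iv$xmax | m$values[g, ] < iv$xmin
  }
  altered
}

#' Kaplan-Meier curves and log-rank test, altered vs unaltered
#'
#' Product-limit estimator per group and the two-group log-rank test
#' (chi-square, 1 df; hypergeometric variance handles tied event times).
#'
#' @param table data.frame with \code{time} (months), \code{event}
#'   (0 censored / 1 event) and logical \code{altered}.
#' @return list of class \code{KmResult}: \code{curves} (data.frame of
#'   time, surv, group), \code{chisq}, \code{p_value}, \code{n}.
#' @export
km_logrank <- function(table) {
  if (!all(c("time", "event", "altered") %in% names(table)))
    stop("table needs columns time, event, altered")
  if (length(unique(table$altered)) < 2L)
    stop("both altered and unaltered groups must be non-empty")
  sd <- survival::survdiff(survival::Surv(time, event) ~ altered,
                           data = table)
  fit <- survival::survfit(survival::Surv(time, event) ~ altered,
                           data = table)
  grp <- rep(sub("^altered=", "", names(fit$strata)),
             times = fit$strata)
  structure(list(curves = data.frame(time = fit$time, surv = fit$surv,
                                     group = grp),
                 chisq = sd$chisq,
                 p_value = stats::pchisq(sd$chisq, df = 1,
                                         lower.tail = FALSE),
                 n = nrow(table)),
            class = "KmResult")
}

#' @export
print.KmResult <- function(x, ...) {
  cat(sprintf("Log-rank: chisq = %.3f, p = %.4g (n = %d)\n",
              x$chisq, x$p_value, x$n))
  invisible(x)
}

#' Screen genes by single-gene survival association
#'
#' Retains genes whose altered-vs-unaltered log-rank p-value is below
#' \code{alpha}; genes altered in no sample (or in all) are untestable and
#' excluded with a warning.
#'
#' @param genes character vector of candidate gene ids.
#' @param m ExpressionMatrix.
#' @param surv data.frame with \code{sample_id}, \code{time}, \code{event}.
#' @param intervals optional named interval list (see
#'   \code{\link{mark_altered}}).
#' @param alpha retention threshold (default 0.05).
#' @return retained gene ids; per-gene p-values in attribute
#'   \code{"p_values"}.
#' @export
screen_genes <- function(genes, m, surv, intervals = NULL, alpha = 0.05) {
  if (length(genes) == 0L) stop("empty gene set")
  surv <- surv[match(colnames(m$values), surv$sample_id), , drop = FALSE]
  pvals <- stats::setNames(rep(NA_real_, length(genes)), genes)
  untestable <- character(0)
  for (g in genes) {
    alt <- mark_altered(m, g, intervals)
    if (length(unique(alt)) < 2L) {
      untestable <- c(untestable, g)
      next
    }
    pvals[g] <- km_logrank(data.frame(time = surv$time,
                                      event = surv$event,
                                      altered = alt))$p_value
  }
  if (length(untestable))
    warning(length(untestable), " gene(s) altered in no (or every) sample",
            " excluded as untestable: ",
            paste(utils::head(untestable, 3), collapse = ", "))
  kept <- genes[!is.na(pvals) & pvals < alpha]
  if (length(kept) == 0L) warning("no gene passes the survival screen")
  structure(kept, p_values = pvals)
}

#' Merge tumor- and normal-tissue risk gene sets with provenance
#'
#' @param tumor_genes,normal_genes character vectors.
#' @return data.frame with \code{gene_id} and \code{source} in
#'   \{\code{tumor}, \code{normal}, \code{both}\}.
#' @export
integrate_gene_sets <- function(tumor_genes, normal_genes) {
  all_g <- union(tumor_genes, normal_genes)
  src <- ifelse(all_g %in% tumor_genes & all_g %in% normal_genes, "both",
                ifelse(all_g %in% tumor_genes, "tumor", "normal"))
  data.frame(gene_id = all_g, source = src, stringsAsFactors = FALSE)
}
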