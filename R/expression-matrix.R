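#' Expression matrix with sample annotation
#'
#' The container used throughout the pipeline: a genes x samples numeric
#' matrix together with a per-sample annotation table giving the prognosis
#' group (\code{good} = non-recurrent, \code{poor} = recurrent) and the
#' tissue of origin (\code{tumor} or \code{normal}).
#'
#' @param values numeric matrix, genes as rows, samples as columns; both
#'   dimensions must be named.
#' @param annotation data.frame with columns \code{sample_id}, \code{group}
#'   (\code{good}/\code{poor}) and \code{tissue} (\code{tumor}/\code{normal});
#'   optional \code{time} and \code{event} columns carry survival data.
#' @return An object of class \code{ExpressionMatrix}: a list with elements
#'   \code{values} and \code{annotation} (rows ordered to match the columns
#'   of \code{values}).
#' @export
expression_matrix <- function(values, annotation) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene id: ",
         rownames(values)[duplicated(rownames(values))][1L])
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample id: ",
         colnames(values)[duplicated(colnames(values))][1L])
  if (!all(is.finite(values)))
    stop("non-finite expression values; missing entries must be removed or ",
         "imputed before constructing an ExpressionMatrix")
  req <- c("sample_id", "group", "tissue")
  if (!all(req %in% names(annotation)))
    stop("annotation must have columns: ", paste(req, collapse = ", "))
  missing <- setdiff(colnames(values), annotation$sample_id)
  if (length(missing))
    stop("no annotation for sample: ", missing[1L])
  annotation <- annotation[match(colnames(values), annotation$sample_id), ,
                           drop = FALSE]
  rownames(annotation) <- NULL
  if (!all(annotation$group %in% c("good", "poor")))
    stop("annotation 'group' must be 'good' or 'poor'")
  if (!all(annotation$tissue %in% c("tumor", "normal")))
    stop("annotation 'tissue' must be 'tumor' or 'normal'")
  structure(list(values = values, annotation = annotation),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  tab <- table(x$annotation$tissue, x$annotation$group)
  print(tab)
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Subset an ExpressionMatrix by genes and/or samples
#'
#' @param x ExpressionMatrix.
#' @param genes,samples character, logical or integer index vectors; omit to
#'   keep all.
#' @return ExpressionMatrix restricted to the selection.
#' @export
subset_expression <- function(x, genes = NULL, samples = NULL) {
  v <- x$values
  if (!is.null(genes)) v <- v[genes, , drop = FALSE]
  if (!is.null(samples)) v <- v[, samples, drop = FALSE]
  expression_matrix(v, x$annotation)
}

#' Read an expression matrix and its annotation from TSV files
#'
#' The expression file has a header row of sample ids, first column
#' \code{gene_id}; the annotation file maps every sample id to a group and
#' tissue (optional \code{time}/\code{event} columns).
#'
#' @param path path to the expression TSV.
#' @param annotation_path path to the annotation TSV.
#' @return ExpressionMatrix; row and column order as in the file.
#' @export
read_expression <- function(path, annotation_path) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           colClasses = "character")
  if (names(tab)[1L] != "gene_id")
    stop("expression file must have 'gene_id' as its first column")
  gene_ids <- tab[[1L]]
  if (anyDuplicated(gene_ids))
    stop("duplicate gene id: ", gene_ids[duplicated(gene_ids)][1L])
  num <- suppressWarnings(
    vapply(tab[-1L], as.numeric, numeric(nrow(tab))))
  if (nrow(tab) == 1L) num <- matrix(num, nrow = 1L,
                                     dimnames = list(NULL, names(tab)[-1L]))
  bad <- which(is.na(num) & tab[-1L] != "NA", arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-numeric value at gene '%s', sample '%s'",
                 gene_ids[bad[1L, 1L]], colnames(num)[bad[1L, 2L]]))
  rownames(num) <- gene_ids
  annot <- utils::read.delim(annotation_path, check.names = FALSE,
                             stringsAsFactors = FALSE)
  expression_matrix(num, annot)
}

#' Write an expression matrix (and optionally its annotation) to TSV
#'
#' Values are written with 17 significant digits so that a write/read
#' round trip reproduces doubles bit for bit.
#'
#' @param m ExpressionMatrix.
#' @param path output path for the expression TSV.
#' @param annotation_path optional output path for the annotation TSV.
#' @return \code{path}, invisibly.
#' @export
write_expression <- function(m, path, annotation_path = NULL) {
  v <- m$values
  txt <- cbind(gene_id = rownames(v),
               matrix(formatC(v, digits = 17, format = "g"),
                      nrow = nrow(v), dimnames = dimnames(v)))
  utils::write.table(txt, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(annotation_path))
    utils::write.table(m$annotation, annotation_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(path)
}
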