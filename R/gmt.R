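# GMT (Broad dialect) gene-set I/O: one set per line,
# <id> \t <description> \t <gene> \t <gene> ...

#' Read a gene-set collection from a GMT file
#'
#' @param path path to the GMT file.
#' @return named list of character vectors (members, deduplicated), one per
#'   pathway; descriptions kept in attribute \code{"description"}.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 3L)
  if (length(short))
    stop("malformed GMT line ", short[1L], ": fewer than 3 fields")
  ids <- vapply(parts, `[[`, character(1), 1L)
  if (anyDuplicated(ids))
    stop("duplicate pathway id: ", ids[duplicated(ids)][1L])
  sets <- lapply(parts, function(p) {
    genes <- p[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      warning("duplicate member gene(s) in pathway '", p[[1L]],
              "'; deduplicated")
      genes <- unique(genes)
    }
    genes
  })
  names(sets) <- ids
  attr(sets, "description") <- stats::setNames(
    vapply(parts, `[[`, character(1), 2L), ids)
  sets
}

#' Write a gene-set collection to a GMT file
#'
#' @param sets named list of character vectors; optional
#'   \code{"description"} attribute as produced by \code{\link{read_gmt}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "description")
  if (is.null(desc)) desc <- stats::setNames(names(sets), names(sets))
  lines <- vapply(names(sets), function(id) {
    paste(c(id, desc[[id]], sets[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
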