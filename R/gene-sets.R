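#' Read gene sets from a GMT file
#'
#' GMT is the tab-separated gene-set format used by MSigDB: one set per line,
#' `name TAB description TAB gene1 TAB gene2 ...`.
#'
#' @param path GMT file path.
#' @return A named list of character vectors (one per set, file order
#'   preserved); each element carries a `description` attribute. Duplicate
#'   genes within a set are dropped with a warning.
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(stats::setNames(list(), character()))
  sets <- vector("list", length(lines))
  nms <- character(length(lines))
  for (k in seq_along(lines)) {
    fields <- strsplit(lines[k], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3)
      stop(sprintf("line %d of '%s': GMT lines need at least 3 tab-separated fields",
                   k, path), call. = FALSE)
    genes <- fields[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      warning(sprintf("gene set '%s': duplicate genes dropped", fields[1]),
              call. = FALSE)
      genes <- unique(genes)
    }
    nms[k] <- fields[1]
    sets[[k]] <- structure(genes, description = fields[2])
  }
  stats::setNames(sets, nms)
}

#' Write gene sets to a GMT file
#'
#' @param sets named list of character vectors; an optional `description`
#'   attribute per element is written to the second column.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_sets <- function(sets, path) {
  lines <- vapply(seq_along(sets), function(k) {
    desc <- attr(sets[[k]], "description")
    if (is.null(desc)) desc <- ""
    paste(c(names(sets)[k], desc, as.character(sets[[k]])), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
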