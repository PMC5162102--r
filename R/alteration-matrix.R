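#' Binary gene-by-tumor alteration matrix
#'
#' The central data container: a binary matrix with genes in the rows and
#' tumors in the columns, where entry `x[i, j] = 1` records a somatic
#' alteration of gene `i` in tumor `j`. An optional stratum assignment
#' (e.g. cancer type) per tumor supports stratified background estimation.
#'
#' @param values integer or numeric matrix of 0/1 entries with unique
#'   rownames (gene labels) and colnames (tumor labels).
#' @param strata optional named character vector or factor mapping every
#'   tumor label to a stratum id. Names must cover all tumors exactly once.
#' @return An object of class `alteration_matrix`: the validated integer
#'   matrix with an optional `strata` attribute.
#' @examples
#' x <- matrix(c(1L, 0L, 0L, 1L), 2, dimnames = list(c("g1", "g2"), c("t1", "t2")))
#' alteration_matrix(x)
#' @export
alteration_matrix <- function(values, strata = NULL) {
  if (!is.matrix(values)) stop("`values` must be a matrix", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must carry gene rownames and tumor colnames", call. = FALSE)
  bad <- which(!(values %in% c(0, 1)))
  if (length(bad)) {
    i <- ((bad[1] - 1) %% nrow(values)) + 1
    j <- ((bad[1] - 1) %/% nrow(values)) + 1
    stop(sprintf("non-binary entry '%s' at gene '%s', tumor '%s'",
                 format(values[bad[1]]), rownames(values)[i], colnames(values)[j]),
         call. = FALSE)
  }
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene labels: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(colnames(values)))
    stop("duplicate tumor labels: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "),
         call. = FALSE)
  storage.mode(values) <- "integer"
  if (!is.null(strata)) {
    strata <- vapply(strata, as.character, character(1))
    if (is.null(names(strata)) || !setequal(names(strata), colnames(values)) ||
        anyDuplicated(names(strata)))
      stop("`strata` must assign exactly one stratum to every tumor", call. = FALSE)
    strata <- strata[colnames(values)]
  }
  structure(values, strata = strata, class = c("alteration_matrix", "matrix", "array"))
}

#' @export
print.alteration_matrix <- function(x, ...) {
  st <- attr(x, "strata")
  cat(sprintf("<alteration_matrix> %d genes x %d tumors, %d alterations%s\n",
              nrow(x), ncol(x), sum(x),
              if (is.null(st)) "" else sprintf(", %d strata", length(unique(st)))))
  invisible(x)
}

#' Stratum assignments of an alteration matrix
#'
#' @param x an [alteration_matrix()].
#' @return Named character vector (tumor -> stratum), or `NULL`.
#' @export
strata <- function(x) attr(x, "strata")

#' Read a binary alteration matrix from a delimited text file
#'
#' Expects genes in rows and tumors in columns: the first row holds tumor
#' labels and the first column gene labels. Every cell must be 0 or 1.
#'
#' @param path file path.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @param strata optional path to a two-column file (tumor, stratum) with a
#'   header line, same dialect.
#' @param transpose set `TRUE` if the file stores tumors in rows.
#' @return An [alteration_matrix()] with row/column order as in the file.
#' @export
read_alteration_matrix <- function(path, dialect = c("tsv", "csv"),
                                   strata = NULL, transpose = FALSE) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tsv") "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE, row.names = 1,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df)
  if (transpose) m <- t(m)
  if (!is.numeric(m)) {
    nonnum <- which(is.na(suppressWarnings(as.numeric(m))) & !is.na(m))
    i <- ((nonnum[1] - 1) %% nrow(m)) + 1; j <- ((nonnum[1] - 1) %/% nrow(m)) + 1
    stop(sprintf("cell '%s' (gene '%s', tumor '%s') does not parse as 0/1",
                 m[nonnum[1]], rownames(m)[i], colnames(m)[j]), call. = FALSE)
  }
  st <- if (!is.null(strata)) read_strata(strata, dialect) else NULL
  alteration_matrix(m, strata = st)
}

#' Read a tumor-to-stratum assignment table
#'
#' @param path two-column delimited file (tumor label, stratum id) with header.
#' @param dialect `"tsv"` or `"csv"`.
#' @return Named character vector mapping tumor to stratum.
#' @export
read_strata <- function(path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tsv") "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 2) stop("strata file needs two columns (tumor, stratum)", call. = FALSE)
  stats::setNames(as.character(df[[2]]), as.character(df[[1]]))
}

#' Write an alteration matrix to a delimited text file
#'
#' @param x an [alteration_matrix()] (or plain labelled 0/1 matrix).
#' @param path output file path.
#' @param dialect `"tsv"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_alteration_matrix <- function(x, path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tsv") "\t" else ","
  df <- data.frame(gene = rownames(x), unclass(x)[, , drop = FALSE],
                   check.names = FALSE)
  colnames(df)[1] <- ""
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Drop genes altered in fewer than a minimum number of tumors
#'
#' Frequency filtering is applied after background estimation: rarely altered
#' genes contribute to the per-tumor alteration load and so to the background,
#' but are typically too infrequent to test individually.
#'
#' @param x an [alteration_matrix()].
#' @param min_alterations keep genes with at least this many altered tumors.
#' @return A new [alteration_matrix()] with the same tumors.
#' @export
filter_genes <- function(x, min_alterations) {
  stopifnot(min_alterations >= 0)
  keep <- rowSums(x) >= min_alterations
  if (!any(keep))
    stop("no genes remain after filtering at min_alterations = ", min_alterations,
         call. = FALSE)
  alteration_matrix(unclass(x)[keep, , drop = FALSE], strata = attr(x, "strata"))
}

#' Summarise an alteration matrix as tibbles
#'
#' @param x an [alteration_matrix()].
#' @param ... unused.
#' @return `tidy()`: one row per gene with its alteration count and frequency.
#' @export
tidy.alteration_matrix <- function(x, ...) {
  tibble::tibble(gene = rownames(x),
                 altered_tumors = as.integer(unname(rowSums(x))),
                 frequency = unname(rowSums(x)) / ncol(x))
}

#' @rdname tidy.alteration_matrix
#' @return `glance()`: a one-row tibble with matrix dimensions and density.
#' @export
glance.alteration_matrix <- function(x, ...) {
  tibble::tibble(n_genes = nrow(x), n_tumors = ncol(x),
                 n_alterations = sum(x),
                 density = mean(x),
                 n_strata = if (is.null(attr(x, "strata"))) 1L
                            else length(unique(attr(x, "strata"))))
}
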