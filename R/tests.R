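#' Observed and expected alteration overlap of a gene pair
#'
#' `pair_overlap()` counts the tumors altered in both genes;
#' `expected_overlap()` is the overlap expected under independence given a
#' background matrix, `sum_j p[a, j] * p[b, j]`.
#'
#' @param x an [alteration_matrix()].
#' @param bg a `background_matrix` aligned with `x`.
#' @param a,b gene labels.
#' @return An integer count / a real expectation.
#' @export
pair_overlap <- function(x, a, b) {
  xm <- unclass(x)
  check_genes(rownames(xm), c(a, b))
  sum(xm[a, ] * xm[b, ])
}

#' @rdname pair_overlap
#' @export
expected_overlap <- function(bg, a, b) {
  check_genes(rownames(bg$probs), c(a, b))
  sum(bg$probs[a, ] * bg$probs[b, ])
}

check_genes <- function(known, genes) {
  missing <- setdiff(genes, known)
  if (length(missing))
    stop("unknown gene label(s): ", paste(missing, collapse = ", "), call. = FALSE)
  invisible(TRUE)
}

check_aligned <- function(x, bg) {
  if (!identical(dim(unclass(x)), dim(bg$probs)) ||
      !identical(rownames(x), rownames(bg$probs)) ||
      !identical(colnames(x), colnames(bg$probs)))
    stop("alteration matrix and background matrix are not aligned", call. = FALSE)
  invisible(TRUE)
}

# joint per-tumor probabilities, clamped away from exact 0/1 for use in
# products (the stored background itself is never clamped)
joint_probs <- function(bg, a, b) {
  pa <- pmin(pmax(bg$probs[a, ], 1e-12), 1 - 1e-12)
  pb <- pmin(pmax(bg$probs[b, ], 1e-12), 1 - 1e-12)
  pa * pb
}

#' Poisson-binomial independence test for a gene pair
#'
#' Tests whether the number of tumors altered in both genes deviates from
#' independence. Under the background model the overlap count is
#' Poisson-binomial with per-tumor parameters `p[a, j] * p[b, j]`; the
#' p-value is the upper tail (overlap at least as high) for co-occurrence or
#' the lower tail (at most as low) for mutual exclusivity, observed count
#' included. Stratification is inherited from the background matrix.
#'
#' @inheritParams pair_overlap
#' @param direction `"cooccurrence"` or `"exclusivity"`.
#' @return A one-row tibble: `gene_a`, `gene_b`, `direction`, `observed`,
#'   `expected`, `p_value`, `support_size` (number of attainable outcomes).
#' @examples
#' x <- simulate_null_matrix(simulation_config(n_genes = 30, n_tumors = 40, seed = 7))
#' bg <- estimate_background(x)
#' test_pair(x, bg, rownames(x)[1], rownames(x)[2], "exclusivity")
#' @export
test_pair <- function(x, bg, a, b, direction = c("cooccurrence", "exclusivity")) {
  direction <- match.arg(direction)
  check_aligned(x, bg)
  xm <- unclass(x)
  check_genes(rownames(xm), c(a, b))
  jp <- joint_probs(bg, a, b)
  obs <- sum(xm[a, ] * xm[b, ])
  pv <- ppoibin(jp, obs, if (direction == "cooccurrence") "upper" else "lower")
  tibble::tibble(gene_a = a, gene_b = b, direction = direction,
                 observed = as.integer(obs), expected = sum(jp),
                 p_value = max(pv, .Machine$double.xmin),
                 support_size = length(jp) + 1L)
}

#' Test all gene pairs for co-occurrence or mutual exclusivity
#'
#' Runs [test_pair()] on every unordered pair (in deterministic lexicographic
#' order) and optionally appends multiple-testing-corrected q-values.
#'
#' @inheritParams test_pair
#' @param pair_filter optional predicate `function(gene_a, gene_b)`; pairs for
#'   which it returns `FALSE` are skipped (e.g. pairs on the same chromosome,
#'   via a user-supplied gene-to-chromosome map).
#' @param fdr `"discrete"` (step-up procedure using each test's attainable
#'   p-value support), `"bh"` (plain Benjamini-Hochberg), or `"none"`.
#' @return A tibble with one row per tested pair; with `fdr != "none"` a
#'   `q_value` column is appended and the procedure is recorded in the
#'   `fdr_method` attribute.
#' @export
test_all_pairs <- function(x, bg, direction = c("cooccurrence", "exclusivity"),
                           pair_filter = NULL,
                           fdr = c("none", "bh", "discrete")) {
  direction <- match.arg(direction)
  fdr <- match.arg(fdr)
  check_aligned(x, bg)
  xm <- unclass(x)
  genes <- sort(rownames(xm))
  if (length(genes) < 2) stop("need at least 2 genes", call. = FALSE)
  pairs <- utils::combn(genes, 2)
  if (!is.null(pair_filter)) {
    keep <- vapply(seq_len(ncol(pairs)),
                   function(k) isTRUE(pair_filter(pairs[1, k], pairs[2, k])),
                   logical(1))
    pairs <- pairs[, keep, drop = FALSE]
  }
  np <- ncol(pairs)
  overlap <- tcrossprod(xm)  # observed overlaps for all pairs at once
  tail_dir <- if (direction == "cooccurrence") "upper" else "lower"
  out <- vector("list", np)
  supports <- if (fdr == "discrete") vector("list", np) else NULL
  for (k in seq_len(np)) {
    a <- pairs[1, k]; b <- pairs[2, k]
    jp <- joint_probs(bg, a, b)
    obs <- overlap[a, b]
    pv <- ppoibin(jp, obs, tail_dir)
    out[[k]] <- tibble::tibble(gene_a = a, gene_b = b, direction = direction,
                               observed = as.integer(obs), expected = sum(jp),
                               p_value = max(pv, .Machine$double.xmin),
                               support_size = length(jp) + 1L)
    if (fdr == "discrete") supports[[k]] <- attainable_pvalues(jp, tail_dir)
  }
  res <- dplyr::bind_rows(out)
  if (fdr == "bh") res$q_value <- bh_fdr(res$p_value)
  if (fdr == "discrete") res$q_value <- discrete_fdr(res$p_value, supports)
  attr(res, "fdr_method") <- fdr
  res
}

#' Per-tumor event probabilities for the group statistics
#'
#' For a gene set with background probabilities `p[i, j]`, the three group
#' statistics count tumors altered in at least one gene (*coverage*), exactly
#' one gene (*exclusivity*), or more than one gene (*impurity*). Each count is
#' Poisson-binomial; this returns its per-tumor parameters:
#' coverage `1 - prod_i(1 - p_ij)`; exclusivity
#' `sum_i p_ij prod_{k != i}(1 - p_kj)`; impurity is one minus both. For a
#' two-gene set the impurity parameter reduces to `p_1j * p_2j`, the pairwise
#' parameterization.
#'
#' @inheritParams pair_overlap
#' @param genes character vector of gene labels (length >= 1).
#' @param statistic `"coverage"`, `"exclusivity"`, or `"impurity"`.
#' @return Numeric vector of per-tumor event probabilities.
#' @export
group_event_probabilities <- function(bg, genes,
                                      statistic = c("impurity", "coverage", "exclusivity")) {
  statistic <- match.arg(statistic)
  if (!length(genes)) stop("empty gene set", call. = FALSE)
  check_genes(rownames(bg$probs), genes)
  pm <- pmin(pmax(bg$probs[genes, , drop = FALSE], 1e-12), 1 - 1e-12)
  code <- match(statistic, c("coverage", "exclusivity", "impurity")) - 1L
  .group_probs_cpp(pm, code)
}

#' Group-based mutual exclusivity test
#'
#' Tests a gene set for groupwise mutual exclusivity with one of three
#' statistics (see [group_event_probabilities()]). Impurity — the number of
#' tumors altered in more than one of the genes — is the default: exclusivity
#' corresponds to *low* impurity, so its p-value is the lower tail; coverage
#' and exclusivity use the upper tail.
#'
#' @inheritParams group_event_probabilities
#' @param name optional set name for the output.
#' @return A one-row tibble: `set`, `genes` (list-column), `statistic`,
#'   `observed`, `expected`, `p_value`, `support_size`.
#' @export
test_group <- function(x, bg, genes,
                       statistic = c("impurity", "coverage", "exclusivity"),
                       name = NULL) {
  statistic <- match.arg(statistic)
  check_aligned(x, bg)
  xm <- unclass(x)
  check_genes(rownames(xm), genes)
  hits <- colSums(xm[genes, , drop = FALSE])
  obs <- switch(statistic,
                coverage = sum(hits >= 1),
                exclusivity = sum(hits == 1),
                impurity = sum(hits > 1))
  pj <- group_event_probabilities(bg, genes, statistic)
  dirn <- if (statistic == "impurity") "lower" else "upper"
  pv <- ppoibin(pj, obs, dirn)
  tibble::tibble(set = name %||% paste(genes, collapse = ","),
                 genes = list(genes), statistic = statistic,
                 observed = as.integer(obs), expected = sum(pj),
                 p_value = max(pv, .Machine$double.xmin),
                 support_size = length(pj) + 1L)
}

#' Test a collection of gene sets for groupwise mutual exclusivity
#'
#' @inheritParams test_group
#' @param sets named list of character vectors (e.g. from [read_gene_sets()]).
#' @param fdr `"discrete"`, `"bh"`, or `"none"`.
#' @return A tibble with one row per set, plus `q_value` unless `fdr = "none"`.
#' @export
test_groups <- function(x, bg, sets,
                        statistic = c("impurity", "coverage", "exclusivity"),
                        fdr = c("discrete", "bh", "none")) {
  statistic <- match.arg(statistic)
  fdr <- match.arg(fdr)
  if (is.null(names(sets))) names(sets) <- paste0("set", seq_along(sets))
  res <- purrr::map2(sets, names(sets),
                     ~ test_group(x, bg, .x, statistic, name = .y))
  res <- dplyr::bind_rows(res)
  if (fdr == "bh") res$q_value <- bh_fdr(res$p_value)
  if (fdr == "discrete") {
    dirn <- if (statistic == "impurity") "lower" else "upper"
    supports <- purrr::map(sets, ~ attainable_pvalues(
      group_event_probabilities(bg, .x, statistic), dirn))
    res$q_value <- discrete_fdr(res$p_value, unname(supports))
  }
  attr(res, "fdr_method") <- fdr
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a
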