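#' Mutual exclusivity graph
#'
#' Builds the gene graph consumed by de novo gene-set detection: nodes are
#' genes, edges connect pairs whose alterations were found mutually exclusive
#' at a permissive FDR (default 10%). Optional must-link groups designate
#' genes that always share cluster assignments (e.g. genes on one copy-number
#' segment, or the mutation and copy-number rows of the same gene).
#'
#' @param results pairwise exclusivity results with a `q_value` column
#'   (e.g. `test_all_pairs(..., direction = "exclusivity", fdr = "discrete")`).
#' @param max_fdr edge inclusion threshold on the q-value.
#' @param must_link optional list of character vectors of gene labels; each
#'   vector moves through clustering as one unit. Groups must be disjoint.
#' @return An object of class `me_graph`: list with `nodes`, `edges` (tibble
#'   `gene_a`, `gene_b`, `q_value`, `weight`) and `must_link`.
#' @export
build_me_graph <- function(results, max_fdr = 0.1, must_link = NULL) {
  if (!"q_value" %in% names(results))
    stop("`results` must carry a q_value column", call. = FALSE)
  sig <- results[results$q_value <= max_fdr, , drop = FALSE]
  edges <- tibble::tibble(gene_a = sig$gene_a, gene_b = sig$gene_b,
                          q_value = sig$q_value, weight = NA_real_)
  nodes <- sort(unique(c(edges$gene_a, edges$gene_b)))
  if (!is.null(must_link)) {
    ml <- lapply(must_link, function(g) intersect(g, nodes))
    ml <- ml[lengths(ml) >= 2]
    if (length(ml) && anyDuplicated(unlist(ml)))
      stop("must-link groups must be disjoint", call. = FALSE)
    must_link <- ml
  }
  structure(list(nodes = nodes, edges = edges, must_link = must_link %||% list()),
            class = "me_graph")
}

#' @export
print.me_graph <- function(x, ...) {
  cat(sprintf("<me_graph> %d genes, %d exclusivity edges, %d must-link groups\n",
              length(x$nodes), nrow(x$edges), length(x$must_link)))
  invisible(x)
}

#' Degree-conditional edge weights for the mutual exclusivity graph
#'
#' Genes mutually exclusive with many partners (hubs) produce edges that are
#' expected even in random graphs with the same degree sequence, so they are
#' weak evidence of joint gene-set membership. Each edge is weighted by its
#' modularity-style centered value `1 - d_u * d_v / (2 |E|)` (degree product
#' relative to the expected number under a degree-preserving random graph),
#' clipped below at `floor`.
#'
#' @param g an `me_graph`.
#' @param floor lower clip for edge weights.
#' @return The graph with filled `weight` column.
#' @export
weight_edges <- function(g, floor = 0.05) {
  if (!nrow(g$edges)) stop("graph has no edges", call. = FALSE)
  deg <- table(c(g$edges$gene_a, g$edges$gene_b))
  ne <- nrow(g$edges)
  w <- 1 - as.numeric(deg[g$edges$gene_a]) * as.numeric(deg[g$edges$gene_b]) / (2 * ne)
  g$edges$weight <- pmax(w, floor)
  g
}

#' Overlapping correlation clustering of the mutual exclusivity graph
#'
#' Detects candidate mutually exclusive gene sets as clusters of the weighted
#' graph. Node pairs joined by an edge score their (positive) weight when
#' co-clustered; non-adjacent pairs pay `penalty` when co-clustered. Seeded
#' local search maximizes the total score of co-clustered pairs: starting
#' from a random assignment, atoms (must-link groups move as units) are
#' toggled in and out of clusters while the objective improves, with random
#' restarts; nodes may end up in several clusters or in none. The objective
#' is non-decreasing across local-search iterations by construction.
#' Clusters that are subsets of other clusters are dropped from the output.
#'
#' @param g a weighted `me_graph` (see [weight_edges()]).
#' @param max_clusters cap on the number of clusters explored.
#' @param penalty cost of co-clustering a non-adjacent pair.
#' @param restarts number of random restarts (best objective wins).
#' @param max_sweeps local-search sweep cap per restart.
#' @param seed integer seed.
#' @return Named list of candidate gene sets (character vectors, >= 2 genes),
#'   with the winning objective value and per-sweep trace in attributes
#'   `objective` and `objective_trace`.
#' @export
cluster_me_graph <- function(g, max_clusters = 20L, penalty = 0.5,
                             restarts = 10L, max_sweeps = 100L, seed = 1L) {
  if (!length(g$nodes)) return(structure(list(), objective = 0))
  if (anyNA(g$edges$weight)) g <- weight_edges(g)
  nodes <- g$nodes
  nn <- length(nodes)

  # gene-level score matrix: weight for edges, -penalty for non-edges
  Wg <- matrix(-penalty, nn, nn, dimnames = list(nodes, nodes))
  diag(Wg) <- 0
  for (k in seq_len(nrow(g$edges))) {
    a <- g$edges$gene_a[k]; b <- g$edges$gene_b[k]
    Wg[a, b] <- Wg[b, a] <- g$edges$weight[k]
  }

  # atoms: must-link groups as units, remaining genes as singletons
  atoms <- c(g$must_link, as.list(setdiff(nodes, unlist(g$must_link))))
  na <- length(atoms)
  Z <- matrix(0, nn, na)
  for (k in seq_len(na)) Z[match(atoms[[k]], nodes), k] <- 1
  S <- t(Z) %*% Wg %*% Z  # atom-pair scores (diagonal unused)
  diag(S) <- 0

  objective <- function(M) {
    share <- tcrossprod(M) > 0   # atoms sharing >= 1 cluster
    diag(share) <- FALSE
    sum(S[share]) / 2
  }

  best <- NULL; best_obj <- -Inf; best_trace <- NULL
  K <- max(2L, min(na, as.integer(max_clusters)))
  with_seed(seed, {
    for (r in seq_len(restarts)) {
      M <- matrix(FALSE, na, K)
      M[cbind(seq_len(na), sample.int(K, na, replace = TRUE))] <- TRUE
      trace <- objective(M)
      for (sweep in seq_len(max_sweeps)) {
        improved <- FALSE
        for (a in seq_len(na)) {
          share_a <- (M[-a, , drop = FALSE] %*% M[a, ]) > 0
          for (cl in seq_len(K)) {
            Mnew_a <- M[a, ]; Mnew_a[cl] <- !Mnew_a[cl]
            share_new <- (M[-a, , drop = FALSE] %*% Mnew_a) > 0
            delta <- sum(S[-a, a] * (share_new - share_a))
            if (delta > 1e-12) {
              M[a, ] <- Mnew_a
              share_a <- share_new
              improved <- TRUE
            }
          }
        }
        trace <- c(trace, objective(M))
        if (!improved) break
      }
      obj <- objective(M)
      if (obj > best_obj) { best_obj <- obj; best <- M; best_trace <- trace }
    }
  })

  sets <- lapply(seq_len(ncol(best)), function(cl) {
    members <- which(best[, cl])
    sort(unique(unlist(atoms[members])))
  })
  sets <- sets[vapply(sets, length, integer(1)) >= 2]
  sets <- sets[!duplicated(lapply(sets, paste, collapse = "\r"))]
  # keep only maximal sets: a cluster fully contained in another is redundant
  if (length(sets) > 1) {
    maximal <- vapply(seq_along(sets), function(i) {
      !any(vapply(seq_along(sets), function(j)
        j != i && all(sets[[i]] %in% sets[[j]]), logical(1)))
    }, logical(1))
    sets <- sets[maximal]
  }
  if (length(sets)) names(sets) <- paste0("candidate", seq_along(sets))
  structure(sets, objective = best_obj, objective_trace = best_trace)
}

#' Validate candidate gene sets with the groupwise test
#'
#' Runs the impurity group test on every candidate set, corrects across
#' candidates with the discrete FDR procedure, and keeps sets significant at
#' `max_fdr`.
#'
#' @param candidates list of gene sets (e.g. from [cluster_me_graph()]).
#' @param x an [alteration_matrix()].
#' @param bg aligned `background_matrix`.
#' @param max_fdr retention threshold on the q-value (default 1%).
#' @return Tibble of retained sets (columns as in [test_groups()]).
#' @export
validate_groups <- function(candidates, x, bg, max_fdr = 0.01) {
  if (!length(candidates))
    return(tibble::tibble(set = character(), genes = list(),
                          statistic = character(), observed = integer(),
                          expected = double(), p_value = double(),
                          support_size = integer(), q_value = double()))
  res <- test_groups(x, bg, candidates, statistic = "impurity", fdr = "discrete")
  res[res$q_value <= max_fdr, , drop = FALSE]
}

#' De novo detection of mutually exclusive gene sets
#'
#' End-to-end pipeline: pairwise exclusivity tests with discrete FDR, graph
#' construction at a permissive edge FDR, degree-conditional edge weighting,
#' overlapping correlation clustering, and groupwise validation at a strict
#' FDR.
#'
#' @inheritParams validate_groups
#' @param max_fdr_edges FDR for including a pairwise exclusivity edge
#'   (default 10%).
#' @param max_fdr_groups FDR for retaining a validated group (default 1%).
#' @param must_link optional must-link gene groups (see [build_me_graph()]).
#' @param min_set_size smallest candidate set forwarded to validation
#'   (default 3: two-gene sets duplicate the pairwise analysis, so de novo
#'   detection targets proper groups).
#' @param min_alterations genes below this alteration count are excluded from
#'   pairwise testing (the background should already have been estimated on
#'   the full matrix).
#' @param seed integer seed for the clustering restarts.
#' @return Tibble of validated gene sets; the candidate list is attached as
#'   attribute `candidates`.
#' @export
denovo_gene_sets <- function(x, bg, max_fdr_edges = 0.1, max_fdr_groups = 0.01,
                             must_link = NULL, min_set_size = 3L,
                             min_alterations = 0L, seed = 1L) {
  xt <- if (min_alterations > 0) filter_genes(x, min_alterations) else x
  bgt <- bg
  if (min_alterations > 0) {
    keep <- rownames(xt)
    bgt$probs <- bg$probs[keep, , drop = FALSE]
    if (is.matrix(bg$mu)) bgt$mu <- bg$mu[keep, , drop = FALSE]
    else if (!is.null(bg$mu)) bgt$mu <- bg$mu[keep]
  }
  pw <- test_all_pairs(xt, bgt, direction = "exclusivity", fdr = "discrete")
  graph <- build_me_graph(pw, max_fdr = max_fdr_edges, must_link = must_link)
  if (!length(graph$nodes)) {
    out <- validate_groups(list(), xt, bgt, max_fdr_groups)
    attr(out, "candidates") <- list()
    return(out)
  }
  graph <- weight_edges(graph)
  candidates <- cluster_me_graph(graph, seed = seed)
  candidates <- candidates[lengths(candidates) >= min_set_size]
  out <- validate_groups(candidates, xt, bgt, max_fdr = max_fdr_groups)
  attr(out, "candidates") <- candidates
  out
}

#' Permutation test for edge overlap between two gene graphs
#'
#' Measures how many edges two graphs share (e.g. a mutual exclusivity graph
#' and a functional interaction network) and assesses enrichment by shuffling
#' the gene labels of the first graph `n_perm` times. The p-value uses the
#' add-one estimator, so it is never exactly zero.
#'
#' @param edges_a,edges_b two-column data frames / matrices of undirected
#'   edges (gene labels).
#' @param universe label universe for the shuffle; defaults to the union of
#'   labels seen in either graph.
#' @param n_perm number of label permutations.
#' @param seed integer seed.
#' @return A one-row tibble: `overlap`, `expected` (mean permuted overlap),
#'   `p_value`.
#' @export
edge_overlap_permutation_test <- function(edges_a, edges_b, universe = NULL,
                                          n_perm = 10000L, seed = 1L) {
  if (n_perm < 1) stop("`n_perm` must be at least 1", call. = FALSE)
  ea <- as.matrix(edges_a)[, 1:2, drop = FALSE]
  eb <- as.matrix(edges_b)[, 1:2, drop = FALSE]
  if (is.null(universe)) universe <- sort(unique(c(ea, eb)))
  key <- function(e) paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]), sep = "\r")
  set_b <- unique(key(eb))
  obs <- sum(unique(key(ea)) %in% set_b)
  perm_overlaps <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      relabel <- stats::setNames(sample(universe), universe)
      ep <- cbind(relabel[ea[, 1]], relabel[ea[, 2]])
      sum(unique(key(ep)) %in% set_b)
    }, numeric(1))
  })
  tibble::tibble(overlap = obs, expected = mean(perm_overlaps),
                 p_value = (1 + sum(perm_overlaps >= obs)) / (n_perm + 1))
}
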