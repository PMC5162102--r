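# lean inner loop shared by the benchmark drivers: p-values for a set of
# gene pairs given a probability matrix, without per-pair tibble overhead
pair_pvalues <- function(xm, probs, pairs, direction) {
  tail_dir <- if (direction == "cooccurrence") "upper" else "lower"
  ov <- tcrossprod(xm[unique(c(pairs)), , drop = FALSE])
  out <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    a <- pairs[1, k]; b <- pairs[2, k]
    pa <- pmin(pmax(probs[a, ], 1e-12), 1 - 1e-12)
    pb <- pmin(pmax(probs[b, ], 1e-12), 1 - 1e-12)
    out[k] <- ppoibin(pa * pb, ov[a, b], tail_dir)
  }
  pmax(out, .Machine$double.xmin)
}

#' Calibration and sensitivity benchmark on simulated data
#'
#' Reproduces the simulation benchmark design: degree-exact null matrices
#' with realistic marginal heterogeneity, planted mutually exclusive /
#' co-occurring pairs (`level = "pair"`) or planted mutually exclusive groups
#' with frequency-matched independent control groups (`level = "group"`),
#' each tested under both the entropy ("discover") and the homogeneous
#' ("binomial") background. Null/negative cases measure calibration (false
#' positive rate versus significance level); planted cases measure
#' sensitivity.
#'
#' @param cfg a [simulation_config()]; its seed drives everything.
#' @param n_datasets independent replicate data sets.
#' @param n_pos planted (positive) pairs or groups per data set.
#' @param n_neg null (negative) pairs or groups per data set.
#' @param level `"group"` (impurity group test) or `"pair"` (pairwise test).
#' @return A tibble with one row per test:
#'   `dataset`, `case` (`"positive"`/`"negative"`), `direction` or
#'   `statistic`, `method` (`"discover"`/`"binomial"`), `p_value`, and for
#'   `level = "pair"` the null pairs are tested in both directions.
#' @seealso [benchmark_curves()], [autoplot.altex_benchmark()]
#' @export
run_benchmark <- function(cfg, n_datasets = 3L, n_pos = 30L, n_neg = 30L,
                          level = c("group", "pair")) {
  level <- match.arg(level)
  res <- purrr::map(seq_len(n_datasets), function(d) {
    if (level == "group") benchmark_groups_one(cfg, d, n_pos, n_neg)
    else benchmark_pairs_one(cfg, d, n_pos, n_neg)
  })
  out <- dplyr::bind_rows(res)
  class(out) <- c("altex_benchmark", class(out))
  attr(out, "level") <- level
  out
}

benchmark_pairs_one <- function(cfg, d, n_pos, n_neg) {
  seed0 <- cfg$seed + 1000L * d
  cfg_d <- simulation_config(
    n_genes = cfg$n_genes, n_tumors = cfg$n_tumors,
    gene_exponent = cfg$gene_exponent, gene_freq_range = cfg$gene_freq_range,
    tumor_dispersion = cfg$tumor_dispersion,
    min_alterations_tested = cfg$min_alterations_tested,
    gene_degrees = cfg$gene_degrees, tumor_degrees = cfg$tumor_degrees,
    seed = seed0)
  x0 <- simulate_null_matrix(cfg_d)
  m <- ncol(x0)

  q_me <- fit_impurity_quantile(x0, 0.01, "impurity",
                                min_alterations = cfg$min_alterations_tested)
  q_co <- fit_impurity_quantile(x0, 0.99, "overlap",
                                min_alterations = cfg$min_alterations_tested)

  # coverages of planted pairs drawn from the empirical coverages of
  # independent tested pairs
  tested0 <- rownames(x0)[rowSums(unclass(x0)) >= cfg$min_alterations_tested]
  cov_pool <- with_seed(seed0 + 1L, {
    idx <- sample(tested0, min(length(tested0), 60L))
    sub <- unclass(x0)[idx, , drop = FALSE]
    pr <- utils::combn(seq_len(nrow(sub)), 2)
    rs <- rowSums(sub); ov <- tcrossprod(sub)
    rs[pr[1, ]] + rs[pr[2, ]] - ov[cbind(pr[1, ], pr[2, ])]
  })

  x <- x0
  me_genes <- co_genes <- list()
  for (k in seq_len(n_pos)) {
    cov_k <- with_seed(seed0 + 10L * k, sample(cov_pool, 1))
    inj <- inject_pair(x, "me", cov_k, q_me, seed = seed0 + 10L * k + 1L,
                       prefix = paste0("me", k))
    x <- inj$matrix; me_genes[[k]] <- inj$genes
    cov_k2 <- with_seed(seed0 + 10L * k + 2L, sample(cov_pool, 1))
    inj2 <- inject_pair(x, "co", cov_k2, q_co, seed = seed0 + 10L * k + 3L,
                        prefix = paste0("co", k))
    x <- inj2$matrix; co_genes[[k]] <- inj2$genes
  }

  # background estimated on the complete matrix, planted pairs included
  bg_e <- estimate_background(x)
  bg_b <- estimate_binomial_background(x)
  xm <- unclass(x)

  null_pairs <- with_seed(seed0 + 2L, {
    pr <- utils::combn(sort(tested0), 2)
    if (ncol(pr) > n_neg) pr <- pr[, sort(sample.int(ncol(pr), n_neg)), drop = FALSE]
    pr
  })
  me_pairs <- do.call(cbind, lapply(me_genes, matrix, ncol = 1))
  co_pairs <- do.call(cbind, lapply(co_genes, matrix, ncol = 1))

  piece <- function(pairs, case, direction, method, probs) {
    pv <- pair_pvalues(xm, probs, pairs, direction)
    tibble::tibble(dataset = d, case = case, direction = direction,
                   method = method,
                   gene_a = pairs[1, ], gene_b = pairs[2, ],
                   p_value = pv)
  }
  dplyr::bind_rows(
    piece(null_pairs, "negative", "cooccurrence", "discover", bg_e$probs),
    piece(null_pairs, "negative", "exclusivity", "discover", bg_e$probs),
    piece(null_pairs, "negative", "cooccurrence", "binomial", bg_b$probs),
    piece(null_pairs, "negative", "exclusivity", "binomial", bg_b$probs),
    piece(me_pairs, "positive", "exclusivity", "discover", bg_e$probs),
    piece(me_pairs, "positive", "exclusivity", "binomial", bg_b$probs),
    piece(co_pairs, "positive", "cooccurrence", "discover", bg_e$probs),
    piece(co_pairs, "positive", "cooccurrence", "binomial", bg_b$probs)
  )
}

benchmark_groups_one <- function(cfg, d, n_pos, n_neg) {
  seed0 <- cfg$seed + 1000L * d + 500L
  cfg_d <- simulation_config(
    n_genes = cfg$n_genes, n_tumors = cfg$n_tumors,
    gene_exponent = cfg$gene_exponent, gene_freq_range = cfg$gene_freq_range,
    tumor_dispersion = cfg$tumor_dispersion,
    min_alterations_tested = cfg$min_alterations_tested,
    gene_degrees = cfg$gene_degrees, tumor_degrees = cfg$tumor_degrees,
    seed = seed0)
  x <- simulate_null_matrix(cfg_d)
  x0 <- x

  pos_sets <- list()
  for (k in seq_len(n_pos)) {
    spec <- sample_group_spec(seed = seed0 + 20L * k)
    grp <- generate_me_group(x, spec, seed = seed0 + 20L * k + 1L,
                             prefix = paste0("d", d, "_grp", k))
    x <- grp$matrix
    pos_sets[[paste0("pos", k)]] <- grp$genes
  }

  # negatives: independent null genes matched within +/-10% alteration frequency
  counts0 <- rowSums(unclass(x0))
  neg_sets <- with_seed(seed0 + 3L, {
    out <- list()
    for (k in seq_len(n_neg)) {
      ref <- pos_sets[[((k - 1L) %% n_pos) + 1L]]
      ref_counts <- rowSums(unclass(x)[ref, , drop = FALSE])
      chosen <- character(0)
      for (rc in ref_counts) {
        cand <- names(counts0)[abs(counts0 - rc) <= pmax(1, 0.1 * rc)]
        cand <- setdiff(cand, chosen)
        if (!length(cand))
          cand <- setdiff(names(counts0)[order(abs(counts0 - rc))][1:5], chosen)
        chosen <- c(chosen, sample(cand, 1))
      }
      out[[paste0("neg", k)]] <- chosen
    }
    out
  })

  bg_e <- estimate_background(x)
  bg_b <- estimate_binomial_background(x)

  run <- function(sets, case, method, bg) {
    res <- test_groups(x, bg, sets, statistic = "impurity", fdr = "none")
    tibble::tibble(dataset = d, case = case, statistic = "impurity",
                   method = method, set = res$set, size = lengths(sets),
                   p_value = res$p_value)
  }
  dplyr::bind_rows(
    run(pos_sets, "positive", "discover", bg_e),
    run(neg_sets, "negative", "discover", bg_e),
    run(pos_sets, "positive", "binomial", bg_b),
    run(neg_sets, "negative", "binomial", bg_b)
  )
}

#' False/true positive rate curves from a benchmark run
#'
#' @param bench output of [run_benchmark()].
#' @param alphas significance levels at which to evaluate the rates.
#' @return A tibble with `method`, `direction`/`statistic`, `alpha`, `fpr`
#'   (fraction of negative cases with `p <= alpha`, averaged over data sets)
#'   and `tpr` (same for positive cases).
#' @export
benchmark_curves <- function(bench, alphas = c(0.01, 0.02, 0.05, 0.1, 0.2, 0.3, 0.5)) {
  side <- if ("direction" %in% names(bench)) "direction" else "statistic"
  rates <- dplyr::group_by(bench, .data$method, side = .data[[side]],
                           .data$case, .data$dataset)
  out <- purrr::map_dfr(alphas, function(a) {
    dplyr::summarise(rates, alpha = a, rate = mean(.data$p_value <= a),
                     .groups = "drop")
  })
  out <- dplyr::group_by(out, .data$method, .data$side, .data$case, .data$alpha)
  out <- dplyr::summarise(out, rate = mean(.data$rate), .groups = "drop")
  out <- tidyr::pivot_wider(out, names_from = "case", values_from = "rate")
  dplyr::rename(out, tpr = "positive", fpr = "negative")
}
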