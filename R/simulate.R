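#' Simulation configuration
#'
#' Parameters of the synthetic alteration-matrix generator. The generator
#' emulates the marginal structure of tumor copy-number data: gene alteration
#' counts follow a truncated discrete power law (few frequently altered
#' genes, many rare ones) and per-tumor alteration loads follow a log-normal
#' distribution (strong overdispersion across tumors — the heterogeneity
#' that breaks i.i.d. tests). Alterations are otherwise independent between
#' genes, so matrices drawn from this model are genuine nulls for
#' co-occurrence and mutual exclusivity.
#'
#' @param n_genes,n_tumors matrix dimensions.
#' @param gene_exponent tail exponent of the gene alteration-count power law
#'   (larger = lighter tail).
#' @param gene_freq_range range of gene alteration *frequencies* (fractions
#'   of tumors) spanned by the power law.
#' @param tumor_dispersion log-scale standard deviation of per-tumor
#'   alteration loads; `0` gives near-constant loads (the homogeneous regime
#'   where binomial and entropy backgrounds agree).
#' @param min_alterations_tested genes with fewer alterations are excluded
#'   from testing (but not from background estimation).
#' @param gene_degrees,tumor_degrees optional explicit integer degree
#'   sequences (e.g. margins of a real data set); when supplied they override
#'   the parametric model and must have equal sums.
#' @param seed integer seed making every downstream generator call
#'   deterministic.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_genes = 1200L, n_tumors = 800L,
                              gene_exponent = 1.5,
                              gene_freq_range = c(0.005, 0.35),
                              tumor_dispersion = 0.8,
                              min_alterations_tested = 50L,
                              gene_degrees = NULL, tumor_degrees = NULL,
                              seed = 1L) {
  if (!is.null(gene_degrees) || !is.null(tumor_degrees)) {
    if (is.null(gene_degrees) || is.null(tumor_degrees))
      stop("supply both degree sequences or neither", call. = FALSE)
    if (sum(gene_degrees) != sum(tumor_degrees))
      stop("degree sequences must have equal sums", call. = FALSE)
    if (any(gene_degrees < 0) || any(tumor_degrees < 0) ||
        any(gene_degrees > length(tumor_degrees)) ||
        any(tumor_degrees > length(gene_degrees)))
      stop("degrees must be >= 0 and bounded by the opposite dimension", call. = FALSE)
    n_genes <- length(gene_degrees); n_tumors <- length(tumor_degrees)
  }
  structure(list(n_genes = as.integer(n_genes), n_tumors = as.integer(n_tumors),
                 gene_exponent = gene_exponent, gene_freq_range = gene_freq_range,
                 tumor_dispersion = tumor_dispersion,
                 min_alterations_tested = as.integer(min_alterations_tested),
                 gene_degrees = gene_degrees, tumor_degrees = tumor_degrees,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# draw `target` of `m` units with inclusion probability proportional to `w`
# (capped at 1): solve the proportionality constant so the expected sample
# size is `target`, draw independent Bernoulli indicators, then repair the
# small count discrepancy. Unlike sequential weighted sampling without
# replacement, inclusion stays proportional to the weights even when a large
# fraction of the population is drawn.
sample_by_inclusion <- function(m, target, w) {
  if (target >= m) return(seq_len(m))
  f <- function(cc) sum(pmin(1, cc * w)) - target
  hi <- 1 / max(w)
  while (f(hi) < 0) hi <- hi * 2
  cc <- stats::uniroot(f, c(0, hi), tol = 1e-12)$root
  pi <- pmin(1, cc * w)
  sel <- which(stats::runif(m) < pi)
  while (length(sel) > target) sel <- sel[-sample.int(length(sel), 1)]
  while (length(sel) < target) {
    pool <- setdiff(seq_len(m), sel)
    sel <- c(sel, pool[sample.int(length(pool), 1, prob = pi[pool] + 1e-9)])
  }
  sel
}

# evaluate `code` under `seed`, restoring the caller's RNG state afterwards
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

#' Sample gene and tumor degree sequences
#'
#' Draws the two marginal count sequences used by the degree-preserving null
#' generator: heavy-tailed gene alteration counts and overdispersed tumor
#' loads, adjusted so both sequences sum to the same total.
#'
#' @param cfg a [simulation_config()].
#' @return List with integer vectors `gene_degrees` and `tumor_degrees`
#'   (equal sums).
#' @export
sample_marginals <- function(cfg) {
  if (!is.null(cfg$gene_degrees))
    return(list(gene_degrees = as.integer(cfg$gene_degrees),
                tumor_degrees = as.integer(cfg$tumor_degrees)))
  with_seed(cfg$seed, {
    n <- cfg$n_genes; m <- cfg$n_tumors
    dmin <- max(1, round(cfg$gene_freq_range[1] * m))
    dmax <- min(m, round(cfg$gene_freq_range[2] * m))
    a <- cfg$gene_exponent
    # inverse-CDF draw from a continuous power law on [dmin, dmax], rounded
    u <- stats::runif(n)
    g <- (dmin^(1 - a) + u * (dmax^(1 - a) - dmin^(1 - a)))^(1 / (1 - a))
    gene_deg <- as.integer(pmin(pmax(round(g), dmin), dmax))
    total <- sum(gene_deg)

    raw <- if (cfg$tumor_dispersion > 0)
      stats::rlnorm(m, meanlog = 0, sdlog = cfg$tumor_dispersion)
    else rep(1, m)
    tum <- as.integer(round(raw * total / sum(raw)))
    tum <- pmin(pmax(tum, 0L), n)
    # repair the rounding remainder one unit at a time, respecting caps
    diff <- total - sum(tum)
    while (diff != 0) {
      j <- sample.int(m, 1)
      if (diff > 0 && tum[j] < n) { tum[j] <- tum[j] + 1L; diff <- diff - 1 }
      else if (diff < 0 && tum[j] > 0) { tum[j] <- tum[j] - 1L; diff <- diff + 1 }
    }
    list(gene_degrees = gene_deg, tumor_degrees = tum)
  })
}

#' Generate a degree-exact null alteration matrix
#'
#' Builds a random bipartite graph with the requested degree sequences by
#' configuration-model stub pairing, then repairs multi-edges with
#' degree-preserving checkerboard swaps until the adjacency matrix is binary.
#' Row and column sums of the result equal the requested degrees exactly, and
#' there is no dependence between genes beyond what the margins impose.
#'
#' @param gene_degrees,tumor_degrees integer sequences with equal sums.
#' @param seed integer seed.
#' @return An [alteration_matrix()] with genes `g1..gn`, tumors `t1..tm`.
#' @export
generate_null_matrix <- function(gene_degrees, tumor_degrees, seed = 1L) {
  if (sum(gene_degrees) != sum(tumor_degrees))
    stop("degree sequences must have equal sums", call. = FALSE)
  if (any(gene_degrees > length(tumor_degrees)) ||
      any(tumor_degrees > length(gene_degrees)))
    stop("a degree exceeds the opposite dimension", call. = FALSE)
  n <- length(gene_degrees); m <- length(tumor_degrees)
  with_seed(seed, {
    gi <- rep.int(seq_len(n), gene_degrees)
    tj <- rep.int(seq_len(m), tumor_degrees)
    tj <- tj[sample.int(length(tj))]
    M <- matrix(0L, n, m)
    for (e in seq_along(gi)) M[gi[e], tj[e]] <- M[gi[e], tj[e]] + 1L
    E <- cbind(gi, tj)
    max_attempts <- 1e4 * nrow(E)
    attempts <- 0
    repeat {
      dup <- which(M > 1L)
      if (!length(dup)) break
      for (cell in dup) {
        i <- ((cell - 1L) %% n) + 1L
        j <- ((cell - 1L) %/% n) + 1L
        idx_ij <- which(E[, 1] == i & E[, 2] == j)
        ptr <- 1L
        while (M[i, j] > 1L) {
          attempts <- attempts + 1
          if (attempts > max_attempts)
            stop("degree sequence could not be realized as a simple bipartite graph",
                 call. = FALSE)
          e <- sample.int(nrow(E), 1)
          k <- E[e, 1]; l <- E[e, 2]
          if (k == i || l == j || M[i, l] > 0L || M[k, j] > 0L) next
          # checkerboard swap: (i,j),(k,l) -> (i,l),(k,j)
          M[i, j] <- M[i, j] - 1L; M[k, l] <- M[k, l] - 1L
          M[i, l] <- M[i, l] + 1L; M[k, j] <- M[k, j] + 1L
          E[e, ] <- c(i, l)
          E[idx_ij[ptr], ] <- c(k, j)
          ptr <- ptr + 1L
        }
      }
    }
    dimnames(M) <- list(paste0("g", seq_len(n)), paste0("t", seq_len(m)))
    alteration_matrix(M)
  })
}

#' @rdname generate_null_matrix
#' @param cfg a [simulation_config()]; margins are drawn with
#'   [sample_marginals()] and the matrix generated under `cfg$seed`.
#' @export
simulate_null_matrix <- function(cfg) {
  deg <- sample_marginals(cfg)
  generate_null_matrix(deg$gene_degrees, deg$tumor_degrees, seed = cfg$seed + 1L)
}

#' Quantile model of pair impurity (or overlap) as a function of coverage
#'
#' Fits a linear quantile regression (pinball loss, solved numerically) of a
#' pair statistic on pair coverage across independent gene pairs of a null
#' matrix. The percentile bounds it predicts are what the pair injectors use:
#' mutually exclusive pairs must fall below the low quantile of impurity,
#' co-occurring pairs above the high quantile of overlap.
#'
#' @param x_null a null [alteration_matrix()].
#' @param tau quantile level in (0, 1).
#' @param mode `"impurity"` (overlap / coverage proportion) or `"overlap"`
#'   (tumors altered in both, a count).
#' @param min_alterations restrict to genes with at least this many
#'   alterations.
#' @param max_pairs cap on the number of pairs used for the fit
#'   (deterministically thinned).
#' @return A `quantile_model` with a [predict()] method mapping coverage to
#'   the fitted (nonnegative) quantile.
#' @export
fit_impurity_quantile <- function(x_null, tau, mode = c("impurity", "overlap"),
                                  min_alterations = 50L, max_pairs = 10000L) {
  mode <- match.arg(mode)
  stopifnot(tau > 0, tau < 1)
  xm <- unclass(x_null)
  xm <- xm[rowSums(xm) >= min_alterations, , drop = FALSE]
  ng <- nrow(xm)
  if (ng < 15 || choose(ng, 2) < 100)
    stop("need at least 100 testable gene pairs to fit the quantile model",
         call. = FALSE)
  pairs <- utils::combn(seq_len(ng), 2)
  if (ncol(pairs) > max_pairs)  # deterministic thinning
    pairs <- pairs[, round(seq(1, ncol(pairs), length.out = max_pairs))]
  ov <- tcrossprod(xm)
  rs <- rowSums(xm)
  o <- ov[cbind(pairs[1, ], pairs[2, ])]
  coverage <- rs[pairs[1, ]] + rs[pairs[2, ]] - o
  y <- if (mode == "impurity") o / coverage else o
  if (diff(range(coverage)) == 0)
    stop("degenerate coverage range; cannot fit a quantile model", call. = FALSE)

  pinball <- function(beta) {
    r <- y - beta[1] - beta[2] * coverage
    sum(r * (tau - (r < 0)))
  }
  start <- stats::coef(stats::lm(y ~ coverage))
  fit <- stats::optim(start, pinball, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-12))
  fit <- stats::optim(fit$par, pinball, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-12))
  structure(list(tau = tau, mode = mode, coef = unname(fit$par),
                 n_pairs = ncol(pairs)),
            class = "quantile_model")
}

#' @export
predict.quantile_model <- function(object, coverage, ...) {
  pmax(0, object$coef[1] + object$coef[2] * coverage)
}

#' @export
print.quantile_model <- function(x, ...) {
  cat(sprintf("<quantile_model> tau = %.3g, mode = %s, fit on %d pairs\n",
              x$tau, x$mode, x$n_pairs))
  cat(sprintf("  %s ~ %.4g + %.4g * coverage\n", x$mode, x$coef[1], x$coef[2]))
  invisible(x)
}

#' Inject a mutually exclusive or co-occurring gene pair
#'
#' Appends two synthetic gene rows to an alteration matrix. For a mutually
#' exclusive pair (`kind = "me"`) the pair's impurity is forced below the
#' quantile bound predicted at its coverage (usually overlap 0); for a
#' co-occurring pair (`kind = "co"`) the overlap is forced above the bound.
#' Per-gene frequencies split the coverage at a random ratio, and altered
#' tumors are drawn with probability proportional to their overall alteration
#' load (so injected genes share the cohort's rate heterogeneity).
#'
#' @param x an [alteration_matrix()].
#' @param kind `"me"` or `"co"`.
#' @param coverage number of tumors altered in at least one of the two genes.
#' @param qmodel a `quantile_model` of matching `mode` (`"impurity"` for me,
#'   `"overlap"` for co).
#' @param seed integer seed.
#' @param prefix label prefix for the two new rows.
#' @return List: `matrix` (the enlarged [alteration_matrix()]) and `genes`
#'   (the two new labels).
#' @export
inject_pair <- function(x, kind = c("me", "co"), coverage, qmodel, seed = 1L,
                        prefix = paste0(kind, "_pair")) {
  kind <- match.arg(kind)
  xm <- unclass(x)
  m <- ncol(xm)
  if (coverage > m) stop("coverage exceeds the number of tumors", call. = FALSE)
  expected_mode <- if (kind == "me") "impurity" else "overlap"
  if (qmodel$mode != expected_mode)
    stop(sprintf("kind '%s' needs a quantile model of mode '%s'", kind, expected_mode),
         call. = FALSE)
  with_seed(seed, {
    bound <- predict(qmodel, coverage)
    if (kind == "me") {
      o_max <- ceiling(bound * coverage) - 1L  # impurity strictly below the bound
      o <- if (o_max < 1) 0L else sample.int(o_max + 1L, 1) - 1L
    } else {
      o_min <- floor(bound) + 1L               # overlap strictly above the bound
      if (o_min > coverage)
        stop(sprintf(paste0("overlap bound %.1f is unsatisfiable at coverage %d; ",
                            "try a larger coverage"), bound, coverage), call. = FALSE)
      o <- min(coverage, o_min + sample.int(3L, 1) - 1L)
    }
    excl <- coverage - o
    u <- stats::runif(1, 0.3, 0.7)
    ea <- round(u * excl); eb <- excl - ea
    load <- colSums(xm)
    covered <- sample_by_inclusion(m, coverage, load + 1)
    covered <- covered[sample.int(length(covered))]
    both <- covered[seq_len(o)]
    rest <- setdiff(covered, both)
    only_a <- rest[seq_len(ea)]
    only_b <- setdiff(rest, only_a)
    ra <- rb <- integer(m)
    ra[c(both, only_a)] <- 1L
    rb[c(both, only_b)] <- 1L
    new <- rbind(ra, rb)
    rownames(new) <- paste0(prefix, c("_a", "_b"))
    colnames(new) <- colnames(xm)
    out <- alteration_matrix(rbind(unclass(xm), new), strata = attr(x, "strata"))
    list(matrix = out, genes = rownames(new), overlap = o)
  })
}

#' Sample a mutually exclusive group specification
#'
#' Coverage fraction is drawn from a normal distribution with mean 0.4 and
#' standard deviation 0.2 truncated to `[0.2, 0.8]`; impurity is drawn from
#' `{0.02, 0.05, 0.08}`; group size is bounded to 3-6 genes.
#'
#' @param seed integer seed.
#' @return A `group_spec` list: `coverage_fraction`, `impurity`,
#'   `size_range`.
#' @export
sample_group_spec <- function(seed = 1L) {
  with_seed(seed, {
    repeat {
      cf <- stats::rnorm(1, 0.4, 0.2)
      if (cf >= 0.2 && cf <= 0.8) break
    }
    structure(list(coverage_fraction = cf,
                   impurity = sample(c(0.02, 0.05, 0.08), 1),
                   size_range = c(3L, 6L)),
              class = "group_spec")
  })
}

#' Inject a mutually exclusive gene group
#'
#' Appends 3-6 synthetic gene rows forming a mutually exclusive pattern.
#' Individual gene alteration counts are sampled from the empirical
#' distribution of alteration counts in `x` until their sum reaches the
#' requested coverage (the last count is trimmed to hit it exactly; the draw
#' is retried until the group size lands in the allowed range). Covered
#' tumors are drawn with probability proportional to their overall alteration
#' load (so the planted genes share the cohort's rate heterogeneity, like any
#' real gene) and partitioned among the genes; impure alterations — second
#' alterations in already covered tumors — are then added, again
#' load-proportionally, until the requested impurity fraction of covered
#' tumors is reached.
#'
#' @param x an [alteration_matrix()].
#' @param spec a `group_spec` from [sample_group_spec()] (or a list with the
#'   same fields).
#' @param seed integer seed.
#' @param prefix label prefix for the new rows.
#' @return List: `matrix`, `genes`, `coverage` (tumors covered) and
#'   `n_impure` (tumors altered in more than one group gene).
#' @export
generate_me_group <- function(x, spec = sample_group_spec(seed), seed = 1L,
                              prefix = "me_grp") {
  xm <- unclass(x)
  m <- ncol(xm)
  target <- as.integer(round(spec$coverage_fraction * m))
  counts <- rowSums(xm)
  counts <- counts[counts > 0]
  lo <- spec$size_range[1]; hi <- spec$size_range[2]
  with_seed(seed, {
    freqs <- NULL
    for (attempt in 1:10000) {
      f <- integer(0); tot <- 0
      while (tot < target && length(f) <= hi) {
        d <- sample(counts, 1)
        f <- c(f, d); tot <- tot + d
      }
      f[length(f)] <- f[length(f)] - (tot - target)  # trim to hit coverage
      if (length(f) >= lo && length(f) <= hi && all(f >= 1)) { freqs <- f; break }
    }
    if (is.null(freqs))
      stop("could not realize a group of 3-6 genes at the requested coverage",
           call. = FALSE)
    g <- length(freqs)
    load <- colSums(xm)
    covered <- sample_by_inclusion(m, target, load + 1)
    covered <- covered[sample.int(length(covered))]  # random partition order
    assign_to <- rep.int(seq_len(g), freqs)
    rows <- matrix(0L, g, m)
    rows[cbind(assign_to, covered)] <- 1L

    n_impure <- round(spec$impurity * target)
    if (n_impure > 0) {
      w <- load[covered] + 1
      impure_tumors <- covered[sample.int(target, n_impure, prob = w)]
      for (j in impure_tumors) {
        open <- which(rows[, j] == 0L)
        rows[open[sample.int(length(open), 1)], j] <- 1L
      }
    }
    rownames(rows) <- paste0(prefix, "_", seq_len(g))
    colnames(rows) <- colnames(xm)
    out <- alteration_matrix(rbind(xm, rows), strata = attr(x, "strata"))
    list(matrix = out, genes = rownames(rows), coverage = target,
         n_impure = n_impure)
  })
}
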