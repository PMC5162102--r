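test_that("marginal sampling is deterministic with equal sums and overdispersed loads", {
  cfg <- simulation_config(n_genes = 300, n_tumors = 200, seed = 5)
  d1 <- sample_marginals(cfg)
  d2 <- sample_marginals(cfg)
  expect_identical(d1, d2)
  expect_identical(sum(d1$gene_degrees), sum(d1$tumor_degrees))
  expect_gte(sd(d1$tumor_degrees) / mean(d1$tumor_degrees), 0.5)
  expect_true(all(d1$gene_degrees >= 0 & d1$gene_degrees <= 200))

  # explicit degree sequences pass through untouched
  cfg2 <- simulation_config(gene_degrees = c(2L, 1L, 1L), tumor_degrees = c(2L, 1L, 1L, 0L))
  expect_identical(sample_marginals(cfg2)$gene_degrees, c(2L, 1L, 1L))
  expect_error(simulation_config(gene_degrees = c(5L, 1L), tumor_degrees = c(1L, 1L)),
               "equal sums")
})

test_that("null matrices realize the requested degrees exactly", {
  x <- generate_null_matrix(c(1L, 1L), c(1L, 1L), seed = 3)
  expect_identical(sort(unname(rowSums(x))), c(1, 1))
  expect_identical(unname(colSums(x)), c(1, 1))
  expect_identical(sum(unclass(x)), 2L)  # a 2x2 permutation matrix

  cfg <- simulation_config(n_genes = 250, n_tumors = 150, seed = 8,
                           gene_freq_range = c(0.02, 0.4))
  deg <- sample_marginals(cfg)
  xa <- generate_null_matrix(deg$gene_degrees, deg$tumor_degrees, seed = 1)
  xb <- generate_null_matrix(deg$gene_degrees, deg$tumor_degrees, seed = 2)
  for (x in list(xa, xb)) {
    expect_true(all(unclass(x) %in% c(0L, 1L)))
    expect_identical(as.integer(rowSums(x)), deg$gene_degrees)
    expect_identical(as.integer(colSums(x)), deg$tumor_degrees)
  }
  expect_false(identical(unclass(xa), unclass(xb)))  # same margins, different draws
  expect_identical(unclass(generate_null_matrix(deg$gene_degrees, deg$tumor_degrees, seed = 1)),
                   unclass(xa))
  expect_error(generate_null_matrix(c(4L, 1L), c(2L, 2L, 1L)), "exceeds")
})

test_that("zero tumor dispersion makes binomial and entropy backgrounds agree", {
  cfg <- simulation_config(n_genes = 150, n_tumors = 120, tumor_dispersion = 0,
                           gene_freq_range = c(0.05, 0.4), seed = 6)
  x <- simulate_null_matrix(cfg)
  expect_lte(diff(range(colSums(unclass(x)))), 2)  # near-constant loads
  bg_e <- estimate_background(x)
  bg_b <- estimate_binomial_background(x)
  expect_lt(max(abs(bg_e$probs - bg_b$probs)), 0.02)
})

test_that("quantile models track empirical quantiles and order correctly", {
  cfg <- simulation_config(n_genes = 500, n_tumors = 300, seed = 9,
                           gene_freq_range = c(0.05, 0.4),
                           min_alterations_tested = 20L)
  x <- simulate_null_matrix(cfg)
  qm <- fit_impurity_quantile(x, 0.5, "impurity", min_alterations = 20)
  # binned empirical medians as the independent reference
  xm <- unclass(x)[rowSums(unclass(x)) >= 20, ]
  pr <- utils::combn(seq_len(nrow(xm)), 2)
  ov <- tcrossprod(xm); rs <- rowSums(xm)
  o <- ov[cbind(pr[1, ], pr[2, ])]
  coverage <- rs[pr[1, ]] + rs[pr[2, ]] - o
  y <- o / coverage
  bins <- cut(coverage, quantile(coverage, seq(0, 1, 0.25)), include.lowest = TRUE)
  emp <- tapply(y, bins, median)
  mid <- tapply(coverage, bins, median)
  fit <- predict(qm, mid)
  expect_lt(max(abs(fit - emp)), 0.05)

  q01 <- fit_impurity_quantile(x, 0.01, "impurity", min_alterations = 20)
  q99 <- fit_impurity_quantile(x, 0.99, "impurity", min_alterations = 20)
  at <- seq(min(coverage), max(coverage), length.out = 20)
  expect_true(all(predict(q01, at) <= predict(q99, at)))
  expect_true(all(predict(q01, at) >= 0))
})

test_that("injected pairs respect the quantile bound and their drawn frequencies", {
  cfg <- simulation_config(n_genes = 400, n_tumors = 300, seed = 13,
                           gene_freq_range = c(0.03, 0.4),
                           min_alterations_tested = 20L)
  x <- simulate_null_matrix(cfg)
  q_me <- fit_impurity_quantile(x, 0.01, "impurity", min_alterations = 20)
  q_co <- fit_impurity_quantile(x, 0.99, "overlap", min_alterations = 20)

  inj <- inject_pair(x, "me", coverage = 80, qmodel = q_me, seed = 2)
  rows <- unclass(inj$matrix)[inj$genes, ]
  expect_identical(nrow(inj$matrix), nrow(x) + 2L)
  overlap <- sum(rows[1, ] * rows[2, ])
  expect_lt(overlap / 80, max(predict(q_me, 80), 1 / 80))
  expect_identical(sum(colSums(rows) > 0), 80L)

  inj_co <- inject_pair(x, "co", coverage = 80, qmodel = q_co, seed = 3)
  rows_co <- unclass(inj_co$matrix)[inj_co$genes, ]
  expect_gt(sum(rows_co[1, ] * rows_co[2, ]), predict(q_co, 80))

  # a bound of ~0 forces overlap 0
  q0 <- structure(list(tau = 0.01, mode = "impurity", coef = c(0, 0), n_pairs = 0L),
                  class = "quantile_model")
  inj0 <- inject_pair(x, "me", coverage = 50, qmodel = q0, seed = 4)
  r0 <- unclass(inj0$matrix)[inj0$genes, ]
  expect_identical(sum(r0[1, ] * r0[2, ]), 0L)
  expect_error(inject_pair(x, "me", 50, q_co), "mode")
})

test_that("planted mutually exclusive pairs are detectable at alpha = 0.05", {
  cfg <- simulation_config(n_genes = 400, n_tumors = 400, seed = 17,
                           gene_freq_range = c(0.03, 0.4))
  x <- simulate_null_matrix(cfg)
  q_me <- fit_impurity_quantile(x, 0.01, "impurity", min_alterations = 50)
  genes <- list()
  for (k in 1:10) {
    inj <- inject_pair(x, "me", coverage = 160, qmodel = q_me, seed = 100 + k,
                       prefix = paste0("me", k))
    x <- inj$matrix; genes[[k]] <- inj$genes
  }
  bg <- estimate_background(x)
  hits <- vapply(genes, function(g)
    test_pair(x, bg, g[1], g[2], "exclusivity")$p_value <= 0.05, logical(1))
  expect_gte(mean(hits), 0.5)
})

test_that("generated groups obey size, coverage, and impurity specifications", {
  cfg <- simulation_config(n_genes = 300, n_tumors = 400, seed = 23,
                           gene_freq_range = c(0.02, 0.35))
  x <- simulate_null_matrix(cfg)
  for (k in 1:5) {
    spec <- sample_group_spec(seed = 40 + k)
    expect_true(spec$coverage_fraction >= 0.2 && spec$coverage_fraction <= 0.8)
    expect_true(spec$impurity %in% c(0.02, 0.05, 0.08))
    grp <- generate_me_group(x, spec, seed = 50 + k)
    g <- length(grp$genes)
    expect_true(g >= 3 && g <= 6)
    sub <- unclass(grp$matrix)[grp$genes, ]
    hits <- colSums(sub)
    expect_identical(sum(hits > 0), grp$coverage)
    target_impure <- round(spec$impurity * grp$coverage)
    expect_lte(abs(sum(hits > 1) - target_impure), 1)
  }
  # zero-impurity variant: every covered tumor altered in exactly one gene
  spec0 <- sample_group_spec(seed = 61)
  spec0$impurity <- 0
  grp0 <- generate_me_group(x, spec0, seed = 62)
  hits0 <- colSums(unclass(grp0$matrix)[grp0$genes, ])
  expect_true(all(hits0[hits0 > 0] == 1))
})

test_that("every generator is a pure function of its seed", {
  cfg <- simulation_config(n_genes = 120, n_tumors = 100, seed = 3,
                           gene_freq_range = c(0.05, 0.4))
  x <- simulate_null_matrix(cfg)
  expect_identical(unclass(simulate_null_matrix(cfg)), unclass(x))
  g1 <- generate_me_group(x, sample_group_spec(7), seed = 8)
  g2 <- generate_me_group(x, sample_group_spec(7), seed = 8)
  expect_identical(unclass(g1$matrix), unclass(g2$matrix))
})

test_that("null p-value distributions are conservative (stochastically >= uniform)", {
  cfg <- simulation_config(n_genes = 500, n_tumors = 300, seed = 29,
                           gene_freq_range = c(0.03, 0.4))
  x <- simulate_null_matrix(cfg)
  bg <- estimate_background(x)
  tested <- sort(rownames(x)[rowSums(unclass(x)) >= 50])
  # disjoint pairs: the one-sided KS test assumes independent observations,
  # which pairs sharing a gene would violate
  tested <- withr::with_seed(2, sample(tested))
  pairs <- matrix(tested[seq_len(2 * (length(tested) %/% 2))], nrow = 2)
  for (dir in c("cooccurrence", "exclusivity")) {
    pv <- altex:::pair_pvalues(unclass(x), bg$probs, pairs, dir)
    ks <- suppressWarnings(ks.test(pv, "punif", alternative = "greater"))
    expect_gt(ks$p.value, 0.01)
  }
})
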