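test_that("pair overlap counts tumors altered in both genes", {
  x <- matrix(0L, 3, 6, dimnames = list(c("a", "b", "c"), paste0("t", 1:6)))
  x[1, 1:4] <- 1L; x[2, 1:4] <- 1L; x[3, 5:6] <- 1L
  am <- alteration_matrix(x)
  expect_identical(pair_overlap(am, "a", "b"), 4L)   # identical rows
  expect_identical(pair_overlap(am, "a", "c"), 0L)   # disjoint rows
  expect_error(pair_overlap(am, "a", "nope"), "unknown gene")

  am2 <- rand_alteration_matrix(6, 30, seed = 2)
  xm <- unclass(am2)
  brute <- sum(xm["g2", ] == 1 & xm["g5", ] == 1)
  expect_identical(pair_overlap(am2, "g2", "g5"), brute)
})

test_that("the five-tumor worked example gives 0.16 per tumor and 0.8 expected", {
  am <- fig1_matrix()
  bg <- estimate_binomial_background(am)
  joint <- bg$probs["gene3", ] * bg$probs["gene5", ]
  expect_equal(unname(joint), rep(0.16, 5))
  expect_equal(expected_overlap(bg, "gene3", "gene5"), 0.8)
  # a gene altered everywhere contributes the partner's probability sum
  x <- unclass(am); x[1, ] <- 1L
  bg2 <- estimate_binomial_background(alteration_matrix(x))
  expect_equal(expected_overlap(bg2, "gene3", "gene5"),
               sum(bg2$probs["gene5", ]))
})

test_that("pairwise test matches the closed-form binomial tail under a flat background", {
  am <- fig1_matrix()
  bg <- estimate_binomial_background(am)
  res <- test_pair(am, bg, "gene3", "gene5", "cooccurrence")
  expect_identical(res$observed, 1L)
  # under p = 0.16 in each of 5 tumors the count is Bin(5, 0.16)
  expect_equal(res$p_value, sum(dbinom(1:5, 5, 0.16)), tolerance = 1e-9)
  # observed = 2 upper tail equals P(Bin(5, 0.16) >= 2) ~ 0.18349
  x <- unclass(am); x[2, ] <- c(1L, 1L, 0L, 0L, 0L)  # overlap now 2
  am2 <- alteration_matrix(x)
  bg2 <- estimate_binomial_background(am2)
  res2 <- test_pair(am2, bg2, "gene3", "gene5", "cooccurrence")
  expect_identical(res2$observed, 2L)
  expect_equal(res2$p_value, sum(dbinom(2:5, 5, 0.16)), tolerance = 1e-9)
  expect_equal(res2$p_value, 0.18349, tolerance = 1e-4)

  # exclusivity + cooccurrence = 1 + P(X = observed)
  pe <- test_pair(am2, bg2, "gene3", "gene5", "exclusivity")$p_value
  expect_equal(res2$p_value + pe, 1 + dbinom(2, 5, 0.16), tolerance = 1e-9)
})

test_that("exclusivity p-value is 1 when nothing can overlap", {
  x <- matrix(0L, 2, 4, dimnames = list(c("a", "b"), paste0("t", 1:4)))
  x[1, 1:2] <- 1L  # b all-zero: joint probabilities all ~0
  am <- alteration_matrix(x)
  bg <- estimate_binomial_background(am)
  res <- test_pair(am, bg, "a", "b", "exclusivity")
  expect_identical(res$observed, 0L)
  expect_equal(res$p_value, 1, tolerance = 1e-8)
})

test_that("test_all_pairs enumerates pairs deterministically and honors filters", {
  am <- rand_alteration_matrix(4, 20, seed = 4)
  bg <- estimate_background(am)
  res <- test_all_pairs(am, bg, "exclusivity")
  expect_identical(nrow(res), 6L)
  expect_true(all(res$gene_a < res$gene_b))
  # spot-check equivalence with single calls
  for (k in c(1, 4)) {
    single <- test_pair(am, bg, res$gene_a[k], res$gene_b[k], "exclusivity")
    expect_equal(res$p_value[k], single$p_value)
    expect_equal(res$expected[k], single$expected)
  }
  skip_one <- function(a, b) !(a == "g1" & b == "g2")
  expect_identical(nrow(test_all_pairs(am, bg, "exclusivity", pair_filter = skip_one)), 5L)
  # q-values appear when requested; the discrete procedure never exceeds BH
  res_q <- test_all_pairs(am, bg, "exclusivity", fdr = "discrete")
  res_b <- test_all_pairs(am, bg, "exclusivity", fdr = "bh")
  expect_true(all(res_q$q_value <= res_b$q_value + 1e-9))
  expect_true(all(res_q$q_value > 0 & res_q$q_value <= 1))
})

test_that("group event probabilities follow the three parameterizations", {
  x <- matrix(0L, 2, 3, dimnames = list(c("a", "b"), paste0("t", 1:3)))
  x[1, 1] <- 1L; x[2, 2] <- 1L  # not used beyond alignment
  am <- alteration_matrix(x)
  bg <- estimate_binomial_background(am)
  bg$probs[] <- 0.5
  expect_equal(group_event_probabilities(bg, c("a", "b"), "coverage"), rep(0.75, 3))
  expect_equal(group_event_probabilities(bg, c("a", "b"), "exclusivity"), rep(0.5, 3))
  expect_equal(group_event_probabilities(bg, c("a", "b"), "impurity"), rep(0.25, 3))
  # singleton group
  expect_equal(group_event_probabilities(bg, "a", "coverage"), rep(0.5, 3))
  expect_equal(group_event_probabilities(bg, "a", "impurity"), rep(0, 3))
  expect_error(group_event_probabilities(bg, character(0)), "empty")
})

test_that("two-gene impurity parameters reduce to the pairwise product", {
  am <- rand_alteration_matrix(5, 15, seed = 9)
  bg <- estimate_background(am)
  imp <- group_event_probabilities(bg, c("g1", "g4"), "impurity")
  expect_equal(imp, unname(bg$probs["g1", ] * bg$probs["g4", ]), tolerance = 1e-12)
})

test_that("coverage = exclusivity + impurity per tumor", {
  am <- rand_alteration_matrix(7, 25, seed = 12)
  bg <- estimate_background(am)
  genes <- c("g1", "g3", "g5", "g7")
  cov <- group_event_probabilities(bg, genes, "coverage")
  exc <- group_event_probabilities(bg, genes, "exclusivity")
  imp <- group_event_probabilities(bg, genes, "impurity")
  expect_lt(max(abs(cov - (exc + imp))), 1e-12)
})

test_that("group test counts the right events and reduces to the pairwise test", {
  # three genes altering disjoint tumors: impurity 0, p = P(X <= 0)
  x <- matrix(0L, 3, 9, dimnames = list(c("a", "b", "c"), paste0("t", 1:9)))
  x[1, 1:3] <- 1L; x[2, 4:6] <- 1L; x[3, 7:9] <- 1L
  am <- alteration_matrix(x)
  bg <- estimate_binomial_background(am)
  res <- test_group(am, bg, c("a", "b", "c"), "impurity")
  expect_identical(res$observed, 0L)
  pj <- group_event_probabilities(bg, c("a", "b", "c"), "impurity")
  expect_equal(res$p_value, prod(1 - pj), tolerance = 1e-12)

  # coverage / exclusivity observations
  expect_identical(test_group(am, bg, c("a", "b"), "coverage")$observed, 6L)
  expect_identical(test_group(am, bg, c("a", "b"), "exclusivity")$observed, 6L)

  # a group of two equals the pairwise exclusivity test
  am2 <- rand_alteration_matrix(6, 18, seed = 14)
  bg2 <- estimate_background(am2)
  grp <- test_group(am2, bg2, c("g2", "g6"), "impurity")
  pair <- test_pair(am2, bg2, "g2", "g6", "exclusivity")
  expect_identical(grp$observed, pair$observed)
  expect_equal(grp$p_value, pair$p_value, tolerance = 1e-9)
})

test_that("pairwise p-values agree with Monte-Carlo sampling from the background", {
  am <- rand_alteration_matrix(6, 10, density = 0.4, seed = 16)
  bg <- estimate_background(am)
  jp <- bg$probs["g1", ] * bg$probs["g2", ]
  obs <- pair_overlap(am, "g1", "g2")
  n_draws <- 1e6
  draws <- withr::with_seed(99, {
    tot <- integer(n_draws)
    for (j in seq_along(jp)) tot <- tot + (runif(n_draws) < jp[j])
    tot
  })
  for (dir in c("upper", "lower")) {
    p_hat <- if (dir == "upper") mean(draws >= obs) else mean(draws <= obs)
    se <- sqrt(p_hat * (1 - p_hat) / n_draws)
    expect_lt(abs(ppoibin(jp, obs, dir) - p_hat), 3 * se + 1e-9)
  }
})

test_that("stratified backgrounds flow through the tests unchanged in form", {
  withr::with_seed(20, {
    x <- cbind(matrix(rbinom(5 * 12, 1, 0.5), 5, 12),
               matrix(rbinom(5 * 12, 1, 0.1), 5, 12))
  })
  dimnames(x) <- list(paste0("g", 1:5), paste0("t", 1:24))
  st <- setNames(rep(c("A", "B"), each = 12), colnames(x))
  am <- alteration_matrix(x, strata = st)
  bg <- estimate_stratified_background(am)
  res <- test_pair(am, bg, "g1", "g2", "exclusivity")
  expect_true(res$p_value > 0 && res$p_value <= 1)
  expect_equal(res$expected, sum(pmin(pmax(bg$probs["g1", ], 1e-12), 1 - 1e-12) *
                                 pmin(pmax(bg$probs["g2", ], 1e-12), 1 - 1e-12)))
})
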