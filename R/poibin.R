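#' Poisson-binomial distribution
#'
#' Distribution of the sum of independent Bernoulli trials with unequal
#' success probabilities — the null distribution of every overlap statistic
#' in this package. Mass and tail probabilities are computed exactly by
#' dynamic-programming convolution (no normal approximation); tail queries
#' truncate the recursion at the queried count, so a tail at small `k` costs
#' O(n k) rather than O(n^2).
#'
#' @param probs vector of per-trial success probabilities in `[0, 1]`.
#' @return `dpoibin()` returns the full probability mass vector
#'   `P(X = 0), ..., P(X = n)`.
#' @examples
#' dpoibin(c(0.1, 0.2, 0.3))
#' ppoibin(c(0.1, 0.2, 0.3), 2, "upper")
#' @export
dpoibin <- function(probs) {
  .poibin_pmf_cpp(as.numeric(probs))
}

#' @rdname dpoibin
#' @param k integer count, `0 <= k <= length(probs)`.
#' @param direction `"upper"` for `P(X >= k)` or `"lower"` for `P(X <= k)`;
#'   both tails include the observed count.
#' @return `ppoibin()` returns the tail probability.
#' @export
ppoibin <- function(probs, k, direction = c("upper", "lower")) {
  direction <- match.arg(direction)
  probs <- as.numeric(probs)
  k <- as.integer(k)
  if (is.na(k) || k < 0 || k > length(probs))
    stop("`k` must lie in 0..", length(probs), call. = FALSE)
  if (direction == "upper") .poibin_upper_cpp(probs, k)
  else .poibin_lower_cpp(probs, k)
}

#' Attainable p-values of a discrete Poisson-binomial test
#'
#' A tail test on a discrete statistic can only realize finitely many
#' p-values: one per attainable count. The sorted set of these values (its
#' "support") is what the discrete false discovery rate procedure consumes.
#'
#' @inheritParams dpoibin
#' @param direction tail direction of the test.
#' @return Sorted numeric vector of distinct attainable p-values; the largest
#'   is 1.
#' @export
attainable_pvalues <- function(probs, direction = c("upper", "lower")) {
  direction <- match.arg(direction)
  pmf <- dpoibin(probs)
  tails <- if (direction == "lower") cumsum(pmf) else rev(cumsum(rev(pmf)))
  tails <- pmin(pmax(tails, 0), 1)
  if (direction == "lower") tails[length(tails)] <- 1 else tails[1] <- 1
  out <- sort(unique(tails))
  out[out > 0]
}
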