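#' Benjamini-Hochberg q-values
#'
#' Plain step-up false discovery rate control (wraps
#' `stats::p.adjust(method = "BH")`). Valid but conservative for discrete
#' tests, whose null p-values are non-uniform; see [discrete_fdr()].
#'
#' @param pvalues numeric vector of p-values in `(0, 1]`.
#' @return Vector of q-values, same order as the input.
#' @export
bh_fdr <- function(pvalues) {
  if (!length(pvalues)) return(numeric(0))
  stats::p.adjust(pvalues, method = "BH")
}

#' False discovery rate control for discrete test statistics
#'
#' Step-up FDR procedure that exploits the discreteness of the tests. A
#' discrete test can only attain finitely many p-values; at a rejection
#' threshold `t`, the null mass contributed by test `i` is not `t` (as plain
#' Benjamini-Hochberg assumes) but the largest attainable p-value of test `i`
#' that is `<= t` — zero if the test cannot reach `t` at all. Summing these
#' per-test masses gives the estimated number of false discoveries at `t`,
#' and q-values follow by the usual step-up minimization over thresholds (the
#' observed p-values). Because each per-test mass is at most `t`, the
#' resulting q-values never exceed the plain BH q-values.
#'
#' @param pvalues numeric vector of observed p-values.
#' @param supports list (same length) of sorted attainable p-value vectors,
#'   one per test, e.g. from [attainable_pvalues()].
#' @return Vector of q-values, same order as the input.
#' @examples
#' sup <- list(c(0.02, 0.5, 1), c(1))  # the second test can never be significant
#' discrete_fdr(c(0.02, 1), sup)
#' @export
discrete_fdr <- function(pvalues, supports) {
  n <- length(pvalues)
  if (!n) return(numeric(0))
  if (length(supports) != n)
    stop("`pvalues` and `supports` must have the same length", call. = FALSE)

  ord <- order(pvalues)
  ps <- pvalues[ord]

  # E0(t) = sum_i max{s in support_i : s <= t} is a step function; encode each
  # support as increments at its attainable values and accumulate once.
  vals <- unlist(supports, use.names = FALSE)
  incs <- unlist(lapply(supports, function(s) diff(c(0, s))), use.names = FALSE)
  o <- order(vals)
  vals <- vals[o]; cum <- cumsum(incs[o])
  # tiny relative nudge so an observed p equal to an attainable value (up to
  # roundoff between the truncated and full tail recursions) is counted
  idx <- findInterval(ps * (1 + 1e-9), vals)  # last attainable value <= threshold
  e0 <- ifelse(idx == 0, 0, cum[pmax(idx, 1)])

  qs <- e0 / seq_len(n)
  qs <- rev(cummin(rev(qs)))          # step-up
  qs <- pmin(qs, 1)
  out <- numeric(n)
  out[ord] <- qs
  out
}
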