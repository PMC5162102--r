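# brute-force Poisson-binomial pmf by enumerating all 2^n outcomes;
# the independent oracle for the DP kernel
pb_enum_pmf <- function(p) {
  n <- length(p)
  pmf <- numeric(n + 1)
  for (s in 0:(2^n - 1)) {
    bits <- as.integer(intToBits(s))[seq_len(n)]
    pmf[sum(bits) + 1] <- pmf[sum(bits) + 1] +
      prod(ifelse(bits == 1, p, 1 - p))
  }
  pmf
}

# small labelled binary matrix
rand_alteration_matrix <- function(n, m, density = 0.3, seed = 1) {
  withr::with_seed(seed, {
    x <- matrix(rbinom(n * m, 1, density), n, m,
                dimnames = list(paste0("g", seq_len(n)), paste0("t", seq_len(m))))
    alteration_matrix(x)
  })
}

# the worked five-tumor example: two genes, each altered in 2 of 5 tumors
fig1_matrix <- function() {
  x <- matrix(0L, 2, 5,
              dimnames = list(c("gene3", "gene5"), paste0("t", 1:5)))
  x[1, c(1, 2)] <- 1L
  x[2, c(2, 3)] <- 1L
  alteration_matrix(x)
}
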