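#' Background alteration probability matrices
#'
#' The null model for every test in this package is a matrix of per-gene,
#' per-tumor alteration probabilities `p[i, j]`. Two estimators are provided:
#'
#' * **binomial** — assumes identically distributed alterations across
#'   tumors: `p[i, j] = x_i. / m`, the gene's altered-tumor fraction. The
#'   expected alteration count per gene matches the observed count, but the
#'   per-tumor expectation does not.
#' * **entropy** — maximizes the information entropy of the probability
#'   matrix subject to *both* marginal constraints: expected alterations per
#'   gene and per tumor each match the observed counts. The optimum has the
#'   logistic form `p[i, j] = 1 / (1 + exp(mu_i + lambda_j))` with one
#'   parameter per gene and one per tumor; genes with equal alteration counts
#'   share a `mu`, tumors with equal alteration loads share a `lambda`, and
#'   the fit is performed over these shared parameters with L-BFGS on the
#'   convex dual (whose gradient components are exactly the marginal
#'   residuals, so convergence is declared when the largest absolute residual
#'   drops below `tol`).
#'
#' All-zero and all-one rows/columns are peeled off before optimization
#' (their probabilities are exactly 0 or 1 and their dual parameters
#' diverge); the stored `mu`/`lambda` are `+Inf`/`-Inf` for them.
#'
#' @param x an [alteration_matrix()].
#' @param tol convergence tolerance on the maximum absolute marginal
#'   residual, in units of expected alteration counts (default `1e-4`).
#' @param max_iter maximum L-BFGS iterations per stratum.
#' @return An object of class `background_matrix`: a list with elements
#'   `probs` (matrix aligned with `x`), `method`, `strata`, `mu`, `lambda`
#'   (per-gene / per-tumor dual parameters; for stratified fits `mu` is a
#'   genes x strata matrix), and `fit` (per-stratum tibble of residuals and
#'   iteration counts).
#' @seealso [estimate_binomial_background()], [estimate_stratified_background()]
#' @examples
#' x <- simulate_null_matrix(simulation_config(n_genes = 40, n_tumors = 60, seed = 1))
#' bg <- estimate_background(x)
#' glance(bg)
#' @export
estimate_background <- function(x, tol = 1e-4, max_iter = 2000L) {
  stopifnot(nrow(x) >= 1, ncol(x) >= 1)
  fit <- fit_entropy_block(unclass(x), tol = tol, max_iter = max_iter)
  new_background(
    probs = fit$probs, method = "entropy", strata = NULL,
    mu = fit$mu, lambda = fit$lambda,
    fit = tibble::tibble(stratum = NA_character_, n_tumors = ncol(x),
                         max_residual = fit$residual,
                         iterations = fit$iterations, converged = TRUE)
  )
}

#' Binomial (homogeneous-rate) background
#'
#' @inheritParams estimate_background
#' @param stratified if `TRUE` (default when `x` carries strata), the
#'   per-gene fraction is computed within each stratum.
#' @return A `background_matrix` with `method = "binomial"`.
#' @export
estimate_binomial_background <- function(x, stratified = !is.null(strata(x))) {
  xm <- unclass(x)
  st <- strata(x)
  probs <- matrix(0, nrow(xm), ncol(xm), dimnames = dimnames(xm))
  if (stratified && !is.null(st)) {
    for (s in unique(st)) {
      cols <- which(st == s)
      probs[, cols] <- rowSums(xm[, cols, drop = FALSE]) / length(cols)
    }
  } else {
    probs[] <- rowSums(xm) / ncol(xm)
    st <- NULL
  }
  new_background(probs, method = "binomial", strata = st,
                 mu = NULL, lambda = NULL,
                 fit = tibble::tibble(stratum = NA_character_,
                                      n_tumors = ncol(xm),
                                      max_residual = 0, iterations = 0L,
                                      converged = TRUE))
}

#' Stratified entropy background
#'
#' Solves the margin-constrained entropy problem separately within each
#' tumor stratum (e.g. cancer type) and concatenates the per-stratum
#' probability matrices, so that expected per-gene and per-tumor alteration
#' counts match the observed counts *within every stratum*. Tests downstream
#' are unchanged: stratification lives entirely in the background matrix.
#'
#' @inheritParams estimate_background
#' @return A `background_matrix` with per-stratum fit report; `mu` is a
#'   genes x strata matrix, `lambda` a per-tumor vector.
#' @export
estimate_stratified_background <- function(x, tol = 1e-4, max_iter = 2000L) {
  st <- strata(x)
  if (is.null(st)) stop("`x` carries no strata; use estimate_background()", call. = FALSE)
  xm <- unclass(x)
  groups <- unique(st)
  probs <- matrix(NA_real_, nrow(xm), ncol(xm), dimnames = dimnames(xm))
  mu <- matrix(NA_real_, nrow(xm), length(groups),
               dimnames = list(rownames(xm), groups))
  lambda <- stats::setNames(rep(NA_real_, ncol(xm)), colnames(xm))
  reports <- vector("list", length(groups))
  for (g in seq_along(groups)) {
    cols <- which(st == groups[g])
    if (!length(cols)) stop("empty stratum '", groups[g], "'", call. = FALSE)
    fit <- fit_entropy_block(xm[, cols, drop = FALSE], tol = tol, max_iter = max_iter)
    probs[, cols] <- fit$probs
    mu[, g] <- fit$mu
    lambda[cols] <- fit$lambda
    reports[[g]] <- tibble::tibble(stratum = groups[g], n_tumors = length(cols),
                                   max_residual = fit$residual,
                                   iterations = fit$iterations, converged = TRUE)
  }
  new_background(probs, method = "entropy", strata = st,
                 mu = mu, lambda = lambda, fit = dplyr::bind_rows(reports))
}

new_background <- function(probs, method, strata, mu, lambda, fit) {
  structure(list(probs = probs, method = method, strata = strata,
                 mu = mu, lambda = lambda, fit = fit),
            class = "background_matrix")
}

#' @export
print.background_matrix <- function(x, ...) {
  cat(sprintf("<background_matrix> %d genes x %d tumors, method = %s%s\n",
              nrow(x$probs), ncol(x$probs), x$method,
              if (is.null(x$strata)) "" else
                sprintf(", %d strata", length(unique(x$strata)))))
  cat(sprintf("  max marginal residual: %.3g\n", max(x$fit$max_residual)))
  invisible(x)
}

#' @export
tidy.background_matrix <- function(x, ...) x$fit

#' @export
glance.background_matrix <- function(x, ...) {
  tibble::tibble(method = x$method,
                 n_genes = nrow(x$probs), n_tumors = ncol(x$probs),
                 n_strata = if (is.null(x$strata)) 1L else length(unique(x$strata)),
                 max_residual = max(x$fit$max_residual),
                 converged = all(x$fit$converged))
}

#' Reconstruct probabilities from the stored dual parameters
#'
#' For the entropy method the fitted probabilities have the closed form
#' `p = 1 / (1 + exp(mu_i + lambda_j))`; this recomputes the matrix from the
#' stored `mu` and `lambda` (degenerate entries with infinite parameters
#' reproduce their exact 0/1 values where the signs are unambiguous).
#'
#' @param bg an entropy-method `background_matrix`.
#' @return Probability matrix of the same shape as `bg$probs`.
#' @export
background_from_duals <- function(bg) {
  if (bg$method != "entropy") stop("dual parameters only exist for the entropy method",
                                   call. = FALSE)
  out <- matrix(NA_real_, nrow(bg$probs), ncol(bg$probs), dimnames = dimnames(bg$probs))
  if (is.matrix(bg$mu)) {
    for (g in colnames(bg$mu)) {
      cols <- which(bg$strata == g)
      out[, cols] <- 1 / (1 + exp(outer(bg$mu[, g], bg$lambda[cols], "+")))
    }
  } else {
    out[] <- 1 / (1 + exp(outer(bg$mu, bg$lambda, "+")))
  }
  out
}

# --- single-block entropy fit -------------------------------------------------

# Peels degenerate (all-0 / all-1) rows and columns iteratively, then solves
# the dual program over one parameter per distinct row sum and one per
# distinct column sum.
fit_entropy_block <- function(xm, tol, max_iter) {
  n <- nrow(xm); m <- ncol(xm)
  probs <- matrix(NA_real_, n, m, dimnames = dimnames(xm))
  mu <- stats::setNames(rep(NA_real_, n), rownames(xm))
  lambda <- stats::setNames(rep(NA_real_, m), colnames(xm))
  activeR <- rep(TRUE, n); activeC <- rep(TRUE, m)

  repeat {
    changed <- FALSE
    rs <- rowSums(xm[, activeC, drop = FALSE])
    nC <- sum(activeC)
    zero_r <- activeR & rs == 0
    full_r <- activeR & rs == nC & nC > 0
    if (any(zero_r)) { probs[zero_r, activeC] <- 0; mu[zero_r] <- Inf
                       activeR[zero_r] <- FALSE; changed <- TRUE }
    if (any(full_r)) { probs[full_r, activeC] <- 1; mu[full_r] <- -Inf
                       activeR[full_r] <- FALSE; changed <- TRUE }
    cs <- colSums(xm[activeR, , drop = FALSE])
    nR <- sum(activeR)
    zero_c <- activeC & cs == 0
    full_c <- activeC & cs == nR & nR > 0
    if (any(zero_c)) { probs[activeR, zero_c] <- 0; lambda[zero_c] <- Inf
                       activeC[zero_c] <- FALSE; changed <- TRUE }
    if (any(full_c)) { probs[activeR, full_c] <- 1; lambda[full_c] <- -Inf
                       activeC[full_c] <- FALSE; changed <- TRUE }
    if (!changed || !any(activeR) || !any(activeC)) break
  }

  if (!any(activeR) || !any(activeC))
    return(list(probs = probs, mu = mu, lambda = lambda,
                residual = 0, iterations = 0L))

  core <- xm[activeR, activeC, drop = FALSE]
  r <- rowSums(core); cc <- colSums(core)
  ur <- sort(unique(r)); uc <- sort(unique(cc))
  rmap <- match(r, ur);  cmap <- match(cc, uc)
  w <- as.numeric(tabulate(rmap, length(ur)))
  z <- as.numeric(tabulate(cmap, length(uc)))
  mc <- ncol(core)

  # dual objective over theta = (alpha_u, beta_v), p = plogis(alpha + beta)
  nu <- length(ur); nv <- length(uc)
  log1pexp <- function(t) ifelse(t > 0, t + log1p(exp(-t)), log1p(exp(t)))
  fn <- function(theta) {
    a <- theta[seq_len(nu)]; b <- theta[nu + seq_len(nv)]
    s <- outer(a, b, "+")
    sum((w %o% z) * log1pexp(s)) - sum(w * a * ur) - sum(z * b * uc)
  }
  gr <- function(theta) {
    a <- theta[seq_len(nu)]; b <- theta[nu + seq_len(nv)]
    p <- stats::plogis(outer(a, b, "+"))
    ga <- w * (as.numeric(p %*% z) - ur)
    gb <- z * (as.numeric(w %*% p) - uc)
    c(ga, gb)
  }
  residual_of <- function(theta) {
    a <- theta[seq_len(nu)]; b <- theta[nu + seq_len(nv)]
    p <- stats::plogis(outer(a, b, "+"))
    max(abs(as.numeric(p %*% z) - ur), abs(as.numeric(w %*% p) - uc))
  }

  theta <- c(stats::qlogis(ur / mc), rep(0, nv))
  opt <- stats::optim(theta, fn, gr, method = "L-BFGS-B",
                      control = list(maxit = max_iter, factr = 10))
  theta <- opt$par
  iters <- opt$counts[["function"]]

  # polish with alternating coordinate-Newton sweeps: each shared parameter
  # solves a 1-D monotone margin equation, so the sweeps push the residuals
  # to the tolerance even when L-BFGS stalls on its relative-change criterion
  a <- theta[seq_len(nu)]; b <- theta[nu + seq_len(nv)]
  for (sweep in seq_len(500L)) {
    p <- stats::plogis(outer(a, b, "+"))
    fa <- as.numeric(p %*% z); da <- as.numeric((p * (1 - p)) %*% z)
    a <- a + (ur - fa) / pmax(da, 1e-12)
    p <- stats::plogis(outer(a, b, "+"))
    fb <- as.numeric(w %*% p); db <- as.numeric(w %*% (p * (1 - p)))
    b <- b + (uc - fb) / pmax(db, 1e-12)
    iters <- iters + 1L
    theta <- c(a, b)
    if (residual_of(theta) <= tol) break
  }
  res <- residual_of(theta)
  if (res > tol)
    stop(sprintf(paste0("background estimation did not converge: max marginal ",
                        "residual %.3g > tol %.3g after %d evaluations"),
                 res, tol, iters), call. = FALSE)

  a <- theta[seq_len(nu)]; b <- theta[nu + seq_len(nv)]
  pcore <- stats::plogis(outer(a[rmap], b[cmap], "+"))
  probs[activeR, activeC] <- pcore
  # paper parameterization: p = 1 / (1 + exp(mu + lambda)) => mu = -alpha, lambda = -beta
  mu[activeR] <- -a[rmap]
  lambda[activeC] <- -b[cmap]
  list(probs = probs, mu = mu, lambda = lambda, residual = res,
       iterations = as.integer(iters))
}
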