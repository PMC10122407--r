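# Independent numerical oracles used across the suite. These deliberately
# avoid the code paths of the package kernels they check.

# upper-tail bivariate normal probability by adaptive quadrature of the
# density: the inner (conditional) integral is available in closed form,
# the outer integral is done by stats::integrate
quad_up2 <- function(t1, t2, r) {
  s <- sqrt(1 - r^2)
  stats::integrate(function(x)
    stats::dnorm(x) * stats::pnorm((t2 - r * x) / s, lower.tail = FALSE),
    t1, Inf, rel.tol = 1e-12, abs.tol = 1e-13)$value
}

# upper-tail liability threshold by bisection on pnorm (high-accuracy CDF)
bisect_threshold <- function(K, tol = 1e-13) {
  lo <- -10; hi <- 10
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (stats::pnorm(mid, lower.tail = FALSE) > K) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# upper orthant of an exchangeable d-dim normal (pairwise correlation rho
# >= 0) via the one-factor reduction: X_i = sqrt(rho) U + sqrt(1-rho) Z_i
exch_orthant <- function(t, rho, d) {
  stats::integrate(function(u) {
    stats::dnorm(u) *
      stats::pnorm((sqrt(rho) * u - t) / sqrt(1 - rho))^d
  }, -Inf, Inf, rel.tol = 1e-11)$value
}

# explicit 4x4 per-pair liability correlation for two traits (matrix
# assembly oracle, independent of the package's constructors)
oracle_biv_corr <- function(a1, c1, a2, c2, ra, rc, re, g) {
  e1 <- sqrt(1 - a1^2 - c1^2); e2 <- sqrt(1 - a2^2 - c2^2)
  comp <- function(rr) matrix(c(1, rr, rr, 1), 2)
  # covariance of (L1, L2) within and between twins, component by component
  A <- diag(c(a1, a2)) %*% comp(ra) %*% diag(c(a1, a2))
  C <- diag(c(c1, c2)) %*% comp(rc) %*% diag(c(c1, c2))
  E <- diag(c(e1, e2)) %*% comp(re) %*% diag(c(e1, e2))
  W <- A + C + E
  B <- g * A + C
  R <- rbind(cbind(W, B), cbind(B, W))
  diag(R) <- 1
  R
}

# expected counts helper for a pair of identical margins
sym_table <- function(K, r, N) implied_table(K, K, r, N)

# build a tiny cohort data frame by hand from per-pair phenotype vectors
toy_cohort <- function(y1, y2, zygosity = "MZ", trait = "x") {
  n <- length(y1)
  d <- data.frame(
    pair_id = rep(seq_len(n), each = 2),
    twin_index = rep(c(1L, 2L), n),
    zygosity = zygosity, sex = "F", age = 9L)
  d[[trait]] <- as.vector(rbind(y1, y2))
  d
}
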