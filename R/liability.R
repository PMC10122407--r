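#' Liability threshold from prevalence
#'
#' Under the liability-threshold model a binary diagnosis corresponds to a
#' latent standard-normal liability exceeding a cut-point. This returns the
#' cut-point whose upper-tail area equals the prevalence.
#'
#' @param K prevalence (proportion affected), strictly inside (0, 1).
#' @return A list of class `"liability_threshold"` with elements `t` (the
#'   standard-normal cut-point) and `K` (the prevalence).
#' @examples
#' threshold_from_prevalence(0.134)  # t about 1.107
#' @export
threshold_from_prevalence <- function(K) {
  if (!is.numeric(K) || length(K) != 1L || is.na(K) || K <= 0 || K >= 1)
    stop("prevalence K must lie strictly in (0, 1); got ", format(K))
  structure(list(t = stats::qnorm(K, lower.tail = FALSE), K = K),
            class = "liability_threshold")
}

#' @export
print.liability_threshold <- function(x, ...) {
  cat(sprintf("Liability threshold: t = %.6f (prevalence K = %.4g)\n", x$t, x$K))
  invisible(x)
}

.check_corr <- function(corr, d) {
  if (!is.matrix(corr) || nrow(corr) != d || ncol(corr) != d)
    stop("corr must be a ", d, "x", d, " matrix")
  if (max(abs(corr - t(corr))) > 1e-10) stop("corr must be symmetric")
  if (max(abs(diag(corr) - 1)) > 1e-10) stop("corr must have unit diagonal")
  ev <- min(eigen(corr, symmetric = TRUE, only.values = TRUE)$values)
  if (ev < -1e-8)
    stop("corr is not positive semi-definite (smallest eigenvalue ",
         format(ev), ")")
  ev
}

#' Multivariate-normal rectangle probability
#'
#' Probability that a standard multivariate normal vector with the given
#' correlation matrix falls in the rectangle `[lower, upper]`, for 2 to 4
#' dimensions. This is the computational kernel of every liability-model
#' likelihood in the package. Two-dimensional rectangles are evaluated with
#' a deterministic double-precision algorithm (absolute error below 1e-13);
#' three- and four-dimensional ones with a deterministic product-rule
#' method, falling back to quasi-Monte Carlo integration with an internally
#' fixed seed when the correlation matrix is nearly singular, so repeated
#' calls are bit-for-bit reproducible.
#'
#' @param lower,upper numeric bound vectors of equal length (2-4); `-Inf`
#'   and `Inf` are allowed. `upper` defaults to all `Inf` (an upper orthant).
#' @param corr correlation matrix (symmetric, unit diagonal, positive
#'   semi-definite).
#' @return A single probability in [0, 1].
#' @examples
#' t1 <- threshold_from_prevalence(0.134)$t
#' mvn_rectangle(c(t1, t1), corr = matrix(c(1, 0.83, 0.83, 1), 2))
#' @export
mvn_rectangle <- function(lower, corr, upper = rep(Inf, length(lower))) {
  d <- length(lower)
  if (d < 2 || d > 4) stop("rectangle dimension must be 2-4, got ", d)
  if (length(upper) != d) stop("lower and upper must have equal length")
  if (any(upper < lower)) return(0)
  ev <- .check_corr(corr, d)

  # drop dimensions with unbounded support on both sides
  free <- is.infinite(lower) & lower < 0 & is.infinite(upper)
  if (any(free)) {
    keep <- which(!free)
    if (length(keep) == 0L) return(1)
    if (length(keep) == 1L)
      return(stats::pnorm(upper[keep]) - stats::pnorm(lower[keep]))
    return(mvn_rectangle(lower[keep], corr[keep, keep, drop = FALSE],
                         upper[keep]))
  }

  if (d == 2L && abs(abs(corr[1, 2]) - 1) < 1e-12) {
    # degenerate perfect correlation: X2 = +/- X1
    r <- sign(corr[1, 2])
    if (r > 0) {
      lo <- max(lower); up <- min(upper)
      return(max(0, stats::pnorm(up) - stats::pnorm(lo)))
    }
    lo <- max(lower[1], -upper[2]); up <- min(upper[1], -lower[2])
    return(max(0, stats::pnorm(up) - stats::pnorm(lo)))
  }

  p <- if (d == 2L) {
    # the orthant kernel handles upper tails; general rectangles by
    # inclusion-exclusion over the four corners
    r <- corr[1, 2]
    U <- function(s, t) {
      if (s == Inf || t == Inf) return(0)
      if (s == -Inf && t == -Inf) return(1)
      if (s == -Inf) return(stats::pnorm(t, lower.tail = FALSE))
      if (t == -Inf) return(stats::pnorm(s, lower.tail = FALSE))
      .pbvu(s, t, r)
    }
    U(lower[1], lower[2]) - U(lower[1], upper[2]) -
      U(upper[1], lower[2]) + U(upper[1], upper[2])
  } else if (ev > 1e-7) {
    mvtnorm::pmvnorm(lower = lower, upper = upper, corr = corr,
                     algorithm = mvtnorm::Miwa(steps = 128))
  } else {
    .qmc_rectangle(lower, upper, corr)
  }
  min(max(as.numeric(p[1]), 0), 1)
}

# quasi-Monte Carlo fallback for (near-)singular 3-4D correlation matrices;
# RNG state is saved and restored so callers see a pure function
.qmc_rectangle <- function(lower, upper, corr) {
  has_seed <- exists(".Random.seed", envir = globalenv())
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(285714L)
  p <- mvtnorm::pmvnorm(lower = lower, upper = upper, corr = corr,
                        algorithm = mvtnorm::GenzBretz(maxpts = 100000L,
                                                       abseps = 1e-7))
  as.numeric(p[1])
}

# upper-tail bivariate probability P(X1 > t1, X2 > t2) under correlation r
.up2 <- function(t1, t2, r) .pbvu(t1, t2, r)

#' Expected cross-twin 2x2 table implied by a bivariate liability model
#'
#' Reconstructs the expected (possibly fractional) cell counts of a 2x2
#' cross-twin (or cross-trait) contingency table from the two marginal
#' prevalences, the latent liability correlation, and the number of pairs.
#' This turns published summary statistics (prevalence + tetrachoric
#' correlation + pair counts) back into sufficient statistics for the
#' liability models.
#'
#' @param K_row,K_col marginal prevalences in (0, 1).
#' @param r latent liability correlation, in [-1, 1].
#' @param N number of pairs (positive).
#' @return A 2x2 matrix of expected counts (rows: row trait absent/present;
#'   columns: column trait absent/present), summing to `N` exactly.
#' @examples
#' implied_table(0.134, 0.134, r = 0.83, N = 4767)  # asthma-like MZ table
#' @export
implied_table <- function(K_row, K_col, r, N) {
  for (K in c(K_row, K_col))
    if (!is.numeric(K) || K <= 0 || K >= 1)
      stop("prevalences must lie in (0, 1); got ", format(K))
  if (abs(r) > 1) stop("|r| must not exceed 1; got ", format(r))
  if (N <= 0) stop("N must be positive")
  t_row <- stats::qnorm(K_row, lower.tail = FALSE)
  t_col <- stats::qnorm(K_col, lower.tail = FALSE)
  p11 <- .up2(t_row, t_col, r)
  p10 <- K_row - p11
  p01 <- K_col - p11
  p00 <- 1 - p11 - p10 - p01
  tab <- N * matrix(pmax(c(p00, p01, p10, p11), 0), 2, byrow = TRUE,
                    dimnames = list(row = c("0", "1"), col = c("0", "1")))
  tab * (N / sum(tab))
}
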