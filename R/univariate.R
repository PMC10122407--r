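# cell vector (n00, n01, n10, n11) from a 2x2 table
.tab_vec <- function(tab) c(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])

# cell probabilities for a cross-twin table at threshold t, correlation r
.cell_probs <- function(t, r) {
  K <- stats::pnorm(t, lower.tail = FALSE)
  p11 <- .up2(t, t, r)
  p10 <- K - p11
  p00 <- 1 - 2 * K + p11
  pmax(c(p00, p10, p10, p11), 1e-320)
}

# negative log-likelihood of (t, a, c) over both zygosity tables
.uni_nll <- function(par, mz, dz) {
  if (any(!is.finite(par))) return(1e10)
  t <- par[1]; a <- par[2]; cc <- par[3]
  if (a * a + cc * cc > 1) return(1e10)
  ll <- sum(mz * log(.cell_probs(t, a * a + cc * cc))) +
        sum(dz * log(.cell_probs(t, 0.5 * a * a + cc * cc)))
  -ll
}

.uni_optim <- function(mz, dz, model, start = NULL) {
  Ktot <- (mz[4] + mz[3] + dz[4] + dz[3] + mz[2] + dz[2]) / 2 /
    (sum(mz) + sum(dz))
  t0 <- stats::qnorm(min(max(Ktot, 1e-6), 1 - 1e-6), lower.tail = FALSE)
  lower <- c(-6, 0, 0); upper <- c(6, 0.99999, 0.99999)
  if (is.null(start)) start <- c(t0, 0.6, 0.3)
  if (model %in% c("AE", "E")) { lower[3] <- upper[3] <- 0; start[3] <- 0 }
  if (model == "E") { lower[2] <- upper[2] <- 0; start[2] <- 0 }
  stats::nlminb(start, .uni_nll, mz = mz, dz = dz, lower = lower,
                upper = upper,
                control = list(rel.tol = 1e-12, x.tol = 1e-12))
}

#' Univariate liability-threshold twin model (ACE / AE / E)
#'
#' Fits the classical twin model to binary trait data by maximizing the
#' joint multinomial likelihood over the MZ and DZ cross-twin 2x2 tables,
#' with a single threshold shared across twins and zygosity groups and
#' cross-twin liability correlations `a2 + c2` (MZ) and `a2/2 + c2` (DZ).
#' Nonnegativity of the variance components is enforced by estimating path
#' coefficients and reporting their squares. If the ACE solution lands on
#' the `c2 = 0` boundary (within 1e-6) the model is re-solved as AE and
#' reported with `c2 = 0` and the boundary flag set.
#'
#' @param mz either a 2x2 MZ cross-twin count table (counts may be
#'   fractional, e.g. from [implied_table()]) or a cohort data frame, in
#'   which case `trait` must name the binary column and the tables are
#'   built from single-entered complete pairs.
#' @param dz 2x2 DZ table (ignored when `mz` is a cohort).
#' @param model `"ACE"`, `"AE"` or `"E"`.
#' @param trait trait column name (cohort interface only).
#' @param ci `"profile"` for profile-likelihood intervals on a2/c2/e2, or
#'   `"none"`.
#' @param conf_level confidence level for the intervals.
#' @return An object of class `"twin_ace"`: list with `a2`, `c2`, `e2`,
#'   `threshold`, `K`, `ci` (matrix when requested), `minus2LL`, `AIC`,
#'   `df` (free parameters), `model`, `boundary_c`, `convergence`, and the
#'   input tables. Supports `print`, `summary`, `coef`, `logLik`,
#'   `confint`, `fitted`, `residuals` and `simulate` methods.
#' @examples
#' mz <- implied_table(0.134, 0.134, 0.83, 4767)
#' dz <- implied_table(0.134, 0.134, 0.49, 5580)
#' twin_ace(mz, dz)  # a2 ~ 0.68, c2 ~ 0.15 (asthma-like)
#' @export
twin_ace <- function(mz, dz = NULL, model = c("ACE", "AE", "E"),
                     trait = NULL, ci = c("none", "profile"),
                     conf_level = 0.95) {
  model <- match.arg(model)
  ci <- match.arg(ci)
  if (is.data.frame(mz)) {
    if (is.null(trait)) stop("the cohort interface needs a trait name")
    cohort <- mz
    mz <- cross_twin_table(cohort, trait, zygosity = "MZ", double_entry = FALSE)
    dz <- cross_twin_table(cohort, trait, zygosity = "DZ", double_entry = FALSE)
  }
  mzv <- .tab_vec(as.matrix(mz)); dzv <- .tab_vec(as.matrix(dz))
  if (sum(mzv) <= 0 || sum(dzv) <= 0) stop("both zygosity tables must be non-empty")
  for (v in list(MZ = mzv, DZ = dzv))
    if (any(v < 0)) stop("negative cell counts in a zygosity table")
  if (sum(mzv[2:4]) == 0 || sum(dzv[2:4]) == 0)
    stop("degenerate table: trait never present in a zygosity stratum")

  fit <- .uni_optim(mzv, dzv, model)
  boundary_c <- FALSE
  if (model == "ACE" && fit$par[3]^2 < 1e-6) {
    # boundary solution: the AE refit is the ACE maximum with c pinned at 0
    fit <- .uni_optim(mzv, dzv, "AE", start = c(fit$par[1], fit$par[2], 0))
    boundary_c <- TRUE
  }
  a2 <- fit$par[2]^2; c2 <- fit$par[3]^2
  npar <- switch(model, ACE = 3L, AE = 2L, E = 1L)
  out <- list(a2 = a2, c2 = c2, e2 = 1 - a2 - c2,
              threshold = fit$par[1],
              K = stats::pnorm(fit$par[1], lower.tail = FALSE),
              minus2LL = 2 * fit$objective,
              AIC = 2 * fit$objective + 2 * npar,
              df = npar, model = model, boundary_c = boundary_c,
              convergence = fit$convergence, par = fit$par,
              mz = mzv, dz = dzv, trait = trait, conf_level = conf_level,
              ci_method = ci)
  class(out) <- "twin_ace"
  if (ci == "profile") out$ci <- confint(out, level = conf_level)
  out
}

#' Falconer moment estimators of twin variance components
#'
#' The classical arithmetic solution `a2 = 2 (rMZ - rDZ)`,
#' `c2 = 2 rDZ - rMZ`, `e2 = 1 - rMZ`, returned raw (no bounding), used
#' as an independent moment oracle for the likelihood fits.
#'
#' @param r_mz,r_dz cross-twin correlations in [-1, 1].
#' @return Named numeric vector `c(a2, c2, e2)`.
#' @examples
#' falconer(0.83, 0.49)  # c(0.68, 0.15, 0.17)
#' @export
falconer <- function(r_mz, r_dz) {
  r_mz <- unname(r_mz); r_dz <- unname(r_dz)
  stopifnot(abs(r_mz) <= 1, abs(r_dz) <= 1)
  c(a2 = 2 * (r_mz - r_dz), c2 = 2 * r_dz - r_mz, e2 = 1 - r_mz)
}

#' Likelihood-ratio comparison of nested twin models
#'
#' @param full,nested fitted [twin_ace()] (or [twin_biv()]) objects on the
#'   same data; `nested`'s parameters must be a subset of `full`'s.
#' @return A list of class `"twin_lrt"` with `statistic`
#'   (`nested$minus2LL - full$minus2LL`), `df` and `p_value` from the
#'   chi-square reference (conservative when the constrained parameter
#'   sits on a boundary).
#' @examples
#' mz <- implied_table(0.134, 0.134, 0.83, 4767)
#' dz <- implied_table(0.134, 0.134, 0.49, 5580)
#' compare_models(twin_ace(mz, dz, model = "ACE"),
#'                twin_ace(mz, dz, model = "AE"))
#' @export
compare_models <- function(full, nested) {
  stat <- nested$minus2LL - full$minus2LL
  if (stat < -1e-6)
    stop("nested model fits better than the full model (difference ",
         format(stat), "): optimizer failure")
  stat <- max(stat, 0)
  df <- full$df - nested$df
  if (df < 1) stop("models have the same number of parameters")
  out <- list(statistic = stat, df = df,
              p_value = stats::pchisq(stat, df, lower.tail = FALSE),
              full = full$model, nested = nested$model)
  class(out) <- "twin_lrt"
  out
}

#' @export
print.twin_lrt <- function(x, ...) {
  cat(sprintf("LRT %s vs %s: chi2 = %.4f, df = %d, p = %s\n", x$nested,
              x$full, x$statistic, x$df, stats::format.pval(x$p_value, digits = 4)))
  invisible(x)
}

# profile deviance of one component fixed at value v
.uni_profile_dev <- function(obj, comp, v) {
  mz <- obj$mz; dz <- obj$dz
  if (comp == "a2") {
    f <- function(par) .uni_nll(c(par[1], sqrt(v), par[2]), mz, dz)
    up <- sqrt(max(1 - v, 0))
    o <- stats::nlminb(c(obj$par[1], min(sqrt(obj$c2), up)), f,
                       lower = c(-6, 0), upper = c(6, up),
                       control = list(rel.tol = 1e-11))
  } else if (comp == "c2") {
    f <- function(par) .uni_nll(c(par[1], par[2], sqrt(v)), mz, dz)
    up <- sqrt(max(1 - v, 0))
    o <- stats::nlminb(c(obj$par[1], min(sqrt(obj$a2), up)), f,
                       lower = c(-6, 0), upper = c(6, up),
                       control = list(rel.tol = 1e-11))
  } else {  # e2 fixed: a^2 + c^2 = 1 - v, parameterized by an angle
    R <- sqrt(max(1 - v, 0))
    f <- function(par) .uni_nll(c(par[1], R * cos(par[2]), R * sin(par[2])),
                                mz, dz)
    th0 <- atan2(sqrt(obj$c2), sqrt(obj$a2))
    o <- stats::nlminb(c(obj$par[1], th0), f, lower = c(-6, 0),
                       upper = c(6, pi / 2),
                       control = list(rel.tol = 1e-11))
  }
  2 * o$objective - obj$minus2LL
}

#' @export
confint.twin_ace <- function(object, parm = c("a2", "c2", "e2"),
                             level = 0.95, ...) {
  parm <- match.arg(parm, c("a2", "c2", "e2"), several.ok = TRUE)
  # components absent from the model are not profiled
  if (object$model %in% c("AE", "E")) parm <- setdiff(parm, "c2")
  if (object$model == "E") parm <- setdiff(parm, "a2")
  crit <- stats::qchisq(level, 1)
  out <- matrix(NA_real_, length(parm), 2,
                dimnames = list(parm, c("lower", "upper")))
  for (p in parm) {
    hat <- object[[p]]
    dev <- function(v) .uni_profile_dev(object, p, v) - crit
    lo <- if (hat < 1e-8) 0 else {
      if (dev(1e-9) < 0) 0
      else stats::uniroot(dev, c(1e-9, hat), tol = 1e-6)$root
    }
    hi <- if (hat > 1 - 1e-8) 1 else {
      if (dev(1 - 1e-9) < 0) 1
      else stats::uniroot(dev, c(hat, 1 - 1e-9), tol = 1e-6)$root
    }
    out[p, ] <- c(lo, hi)
  }
  out
}

#' @export
coef.twin_ace <- function(object, ...) {
  c(a2 = object$a2, c2 = object$c2, e2 = object$e2)
}

#' @export
logLik.twin_ace <- function(object, ...) {
  structure(-object$minus2LL / 2, df = object$df, class = "logLik")
}

#' @export
fitted.twin_ace <- function(object, ...) {
  r_mz <- object$a2 + object$c2
  r_dz <- 0.5 * object$a2 + object$c2
  list(MZ = matrix(.cell_probs(object$threshold, r_mz), 2, byrow = TRUE,
                   dimnames = list(c("0", "1"), c("0", "1"))),
       DZ = matrix(.cell_probs(object$threshold, r_dz), 2, byrow = TRUE,
                   dimnames = list(c("0", "1"), c("0", "1"))))
}

#' @export
residuals.twin_ace <- function(object, ...) {
  f <- fitted(object)
  list(MZ = (matrix(object$mz, 2, byrow = TRUE) - sum(object$mz) * f$MZ) /
         sqrt(sum(object$mz) * f$MZ),
       DZ = (matrix(object$dz, 2, byrow = TRUE) - sum(object$dz) * f$DZ) /
         sqrt(sum(object$dz) * f$DZ))
}

#' @export
simulate.twin_ace <- function(object, nsim = 1, seed = NULL,
                              n_mz = sum(object$mz), n_dz = sum(object$dz),
                              ...) {
  if (!is.null(seed)) set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, nsim)
  name <- if (is.null(object$trait)) "trait" else object$trait
  spec <- function(s) cohort_spec(
    n_mz = round(n_mz), n_dz = round(n_dz),
    traits = list(trait_spec(name, object$a2, object$c2, object$K)),
    seed = s)
  out <- lapply(seeds, function(s) simulate_cohort(spec(s)))
  if (nsim == 1) out[[1]] else out
}

#' @export
print.twin_ace <- function(x, digits = 3, ...) {
  cat(sprintf("Univariate %s liability model%s\n", x$model,
              if (x$boundary_c) " (c2 at boundary, AE solution reported)"
              else ""))
  cat(sprintf("  a2 = %.*f  c2 = %.*f  e2 = %.*f\n", digits, x$a2,
              digits, x$c2, digits, x$e2))
  cat(sprintf("  threshold = %.*f (K = %.4f)  -2LL = %.3f  AIC = %.3f\n",
              digits, x$threshold, x$K, x$minus2LL, x$AIC))
  invisible(x)
}

#' @export
summary.twin_ace <- function(object, ...) {
  print(object)
  if (!is.null(object$ci)) {
    cat(sprintf("  %.0f%% profile-likelihood intervals:\n",
                100 * object$conf_level))
    print(round(object$ci, 4))
  }
  r_mz <- object$a2 + object$c2; r_dz <- 0.5 * object$a2 + object$c2
  cat(sprintf("  implied cross-twin correlations: rMZ = %.3f, rDZ = %.3f\n",
              r_mz, r_dz))
  invisible(object)
}
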