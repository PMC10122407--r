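#' Cluster-robust logistic association between two binary phenotypes
#'
#' Population-averaged logistic regression of a binary outcome on a binary
#' exposure with optional covariate adjustment (sex and age group by
#' default), with the variance estimated by a cluster-robust sandwich over
#' twin pairs (a GEE with independence working correlation). Reported as an
#' odds ratio with Wald 95% confidence interval and two-sided p value.
#'
#' @param cohort cohort data frame (one row per individual) containing the
#'   exposure, outcome, covariate and cluster columns.
#' @param exposure,outcome names of binary 0/1 columns.
#' @param covariates covariate column names entered as factors
#'   (default `c("sex", "age")`).
#' @param cluster clustering column (default `"pair_id"`).
#' @param conf_level confidence level for the interval.
#' @return An object of class `"twin_assoc"`: list with `exposure`,
#'   `outcome`, `odds_ratio`, `ci_low`, `ci_high`, `p_value`, `log_or`,
#'   `se` (robust), `se_naive`, `n_used`, and `separation` (TRUE when the
#'   exposure separates the outcome, in which case the interval is
#'   infinite rather than silently wrong).
#' @examples
#' spec <- cohort_spec(300, 300,
#'   traits = list(trait_spec("x", 0.5, 0, 0.2), trait_spec("y", 0.5, 0, 0.2)),
#'   cross = list("x:y" = cross_trait_spec(ra = 0.5)), seed = 1)
#' fit_clustered_logistic(simulate_cohort(spec), "x", "y")
#' @export
fit_clustered_logistic <- function(cohort, exposure, outcome,
                                   covariates = c("sex", "age"),
                                   cluster = "pair_id", conf_level = 0.95) {
  for (v in c(exposure, outcome, covariates, cluster))
    if (!v %in% names(cohort)) stop("column '", v, "' not found in cohort")
  dat <- cohort[, c(outcome, exposure, covariates, cluster)]
  dat <- dat[stats::complete.cases(dat), ]
  if (sum(dat[[exposure]] == 1) == 0 || sum(dat[[exposure]] == 0) == 0)
    stop("exposure '", exposure, "' has an empty group")
  if (length(unique(dat[[outcome]])) < 2)
    stop("outcome '", outcome, "' has no discordant observations")
  for (v in covariates)
    if (length(unique(dat[[v]])) < 2) covariates <- setdiff(covariates, v)

  rhs <- paste(c(exposure, sprintf("factor(%s)", covariates)), collapse = " + ")
  fml <- stats::as.formula(paste(outcome, "~", rhs))
  fit <- stats::glm(fml, family = stats::binomial(), data = dat)

  b <- stats::coef(fit)[exposure]
  V <- sandwich::vcovCL(fit, cluster = dat[[cluster]])
  se <- sqrt(V[exposure, exposure])
  se_naive <- sqrt(stats::vcov(fit)[exposure, exposure])
  separation <- !fit$converged || abs(b) > 15 || se > 50
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  res <- list(exposure = exposure, outcome = outcome,
              odds_ratio = exp(unname(b)), log_or = unname(b),
              se = unname(se), se_naive = unname(se_naive),
              ci_low = if (separation) 0 else exp(unname(b - z * se)),
              ci_high = if (separation) Inf else exp(unname(b + z * se)),
              p_value = if (separation) NA_real_
                        else 2 * stats::pnorm(-abs(unname(b) / unname(se))),
              n_used = nrow(dat), separation = separation,
              conf_level = conf_level)
  class(res) <- "twin_assoc"
  res
}

#' @export
print.twin_assoc <- function(x, digits = 3, ...) {
  cat(sprintf("%s ~ %s: OR = %.*f (%.0f%% CI %.*f, %.*f), p = %s, n = %d%s\n",
              x$outcome, x$exposure, digits, x$odds_ratio,
              100 * x$conf_level, digits, x$ci_low, digits, x$ci_high,
              stats::format.pval(x$p_value, digits = 3), x$n_used,
              if (x$separation) " [separation]" else ""))
  invisible(x)
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha family-wise level in (0, 1).
#' @param m number of tests (>= 1).
#' @return `alpha / m`. With `alpha = 0.05` and `m = 13` outcome
#'   conditions this is the 0.0038 threshold used for the association
#'   tables.
#' @examples
#' round(bonferroni_threshold(0.05, 13), 4)
#' @export
bonferroni_threshold <- function(alpha, m) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (m < 1) stop("m must be >= 1")
  alpha / m
}

#' Exclusive phenotype groups
#'
#' Partitions individuals into mutually exclusive autism-only, adhd-only,
#' overlap and neither groups from two binary flags.
#'
#' @param autism,adhd binary 0/1 vectors of equal length.
#' @return A factor with levels `neither`, `autism_only`, `adhd_only`,
#'   `autism_adhd`.
#' @export
exclusive_groups <- function(autism, adhd) {
  stopifnot(length(autism) == length(adhd))
  g <- ifelse(autism == 1 & adhd == 1, "autism_adhd",
              ifelse(autism == 1, "autism_only",
                     ifelse(adhd == 1, "adhd_only", "neither")))
  factor(g, levels = c("neither", "autism_only", "adhd_only", "autism_adhd"))
}

#' Association table across exposures and outcomes
#'
#' Fits [fit_clustered_logistic()] for every exposure x outcome
#' combination and flags Bonferroni-significant results (the layout of a
#' published association table: one row per outcome, one OR/CI/p block per
#' exposure).
#'
#' @inheritParams fit_clustered_logistic
#' @param exposures,outcomes character vectors of binary column names.
#' @param alpha family-wise alpha (default 0.05).
#' @param m Bonferroni divisor; defaults to the number of outcomes.
#' @return A data frame with columns `exposure`, `outcome`, `odds_ratio`,
#'   `ci_low`, `ci_high`, `p_value`, `significant`, `n_used`; the
#'   per-test threshold is in the `threshold` attribute.
#' @export
association_table <- function(cohort, exposures, outcomes,
                              covariates = c("sex", "age"),
                              cluster = "pair_id", alpha = 0.05, m = NULL) {
  if (is.null(m)) m <- length(outcomes)
  thr <- bonferroni_threshold(alpha, m)
  rows <- list()
  for (out in outcomes) for (exp_ in exposures) {
    a <- fit_clustered_logistic(cohort, exp_, out, covariates, cluster)
    rows[[length(rows) + 1L]] <- data.frame(
      exposure = exp_, outcome = out, odds_ratio = a$odds_ratio,
      ci_low = a$ci_low, ci_high = a$ci_high, p_value = a$p_value,
      significant = !is.na(a$p_value) & a$p_value < thr,
      n_used = a$n_used, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  attr(res, "threshold") <- thr
  res
}
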