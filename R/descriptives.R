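# Wilson score interval for a binomial proportion
.wilson_ci <- function(x, n, conf_level = 0.95) {
  if (n == 0) return(c(NA_real_, NA_real_))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  p <- x / n
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(max(0, ctr - hw), min(1, ctr + hw))
}

#' Stratified prevalence with Wilson confidence intervals
#'
#' @param cohort cohort data frame (one row per individual).
#' @param trait binary 0/1 column name.
#' @param by optional character vector of stratifying columns (e.g.
#'   `c("zygosity", "sex")`); `NULL` gives the overall prevalence.
#' @param conf_level confidence level (Wilson score interval, which stays
#'   inside [0, 1] at the small counts typical of rare conditions).
#' @return A data frame with the stratum columns and `n_affected`, `n`,
#'   `prevalence`, `ci_low`, `ci_high`.
#' @export
prevalence <- function(cohort, trait, by = NULL, conf_level = 0.95) {
  if (!trait %in% names(cohort)) stop("column '", trait, "' not found")
  y <- cohort[[trait]]
  strata <- if (is.null(by)) list(rep("all", nrow(cohort)))
            else as.list(cohort[, by, drop = FALSE])
  agg_n <- stats::aggregate(y, strata, length)
  agg_x <- stats::aggregate(y, strata, function(v) sum(v, na.rm = TRUE))
  out <- agg_n
  names(out) <- c(if (is.null(by)) "stratum" else by, "n")
  out$n_affected <- agg_x$x
  out$prevalence <- out$n_affected / out$n
  ci <- t(mapply(.wilson_ci, out$n_affected, out$n,
                 MoreArgs = list(conf_level = conf_level)))
  out$ci_low <- ci[, 1]; out$ci_high <- ci[, 2]
  out[, c(setdiff(names(out), c("n", "n_affected", "prevalence", "ci_low",
                                "ci_high")),
          "n_affected", "n", "prevalence", "ci_low", "ci_high")]
}

# pairwise wide layout: one row per complete pair with both twins' traits
.pair_wide <- function(cohort, cols, zygosity = NULL) {
  d <- cohort
  if (!is.null(zygosity)) d <- d[d$zygosity %in% zygosity, ]
  t1 <- d[d$twin_index == 1, c("pair_id", cols)]
  t2 <- d[d$twin_index == 2, c("pair_id", cols)]
  m <- merge(t1, t2, by = "pair_id", suffixes = c(".1", ".2"))
  m[stats::complete.cases(m), ]
}

#' Cross-twin (cross-trait) count table
#'
#' Builds the 2x2 table pairing one twin's `trait_a` with the co-twin's
#' `trait_b` in a zygosity group. With `double_entry = TRUE` (the default,
#' and standard practice) both orderings of each pair are counted, making
#' the table symmetric; the correlation estimate is then invariant to
#' within-pair twin ordering.
#'
#' @param cohort cohort data frame.
#' @param trait_a,trait_b binary column names; equal names give the
#'   within-trait cross-twin table.
#' @param zygosity `"MZ"` or `"DZ"` (or a vector of groups to pool).
#' @param double_entry count each pair in both twin orders.
#' @return A 2x2 count matrix (rows: twin's `trait_a` 0/1; columns:
#'   co-twin's `trait_b` 0/1) with attribute `n_pairs`.
#' @export
cross_twin_table <- function(cohort, trait_a, trait_b = trait_a, zygosity,
                             double_entry = TRUE) {
  w <- .pair_wide(cohort, unique(c(trait_a, trait_b)), zygosity)
  if (nrow(w) == 0) stop("no complete pairs in zygosity group ",
                         paste(zygosity, collapse = "/"))
  a1 <- w[[paste0(trait_a, ".1")]]; a2 <- w[[paste0(trait_a, ".2")]]
  b1 <- w[[paste0(trait_b, ".1")]]; b2 <- w[[paste0(trait_b, ".2")]]
  tab <- matrix(0, 2, 2, dimnames = list(a = c("0", "1"), b = c("0", "1")))
  add <- function(x, yy) {
    for (i in 0:1) for (j in 0:1)
      tab[i + 1, j + 1] <<- tab[i + 1, j + 1] + sum(x == i & yy == j)
  }
  add(a1, b2)
  if (double_entry) add(a2, b1)
  attr(tab, "n_pairs") <- nrow(w)
  tab
}

#' Cross-twin (cross-trait) tetrachoric correlation
#'
#' Tetrachoric correlation of one twin's `trait_a` with the co-twin's
#' `trait_b`, from the double-entered cross-twin table. With
#' `trait_a == trait_b` this is the within-trait cross-twin correlation
#' whose MZ/DZ contrast identifies the variance components; with different
#' traits it is the cross-twin cross-trait correlation whose MZ/DZ
#' contrast identifies shared etiology. Standard errors account for double
#' entry by using the pair count as the effective sample size.
#'
#' @inheritParams cross_twin_table
#' @return A [tetrachoric()] object.
#' @export
cross_twin_correlation <- function(cohort, trait_a, trait_b = trait_a,
                                   zygosity, double_entry = TRUE) {
  tab <- cross_twin_table(cohort, trait_a, trait_b, zygosity, double_entry)
  n_eff <- if (double_entry) sum(tab) / 2 else sum(tab)
  tetrachoric(tab, n_eff = n_eff)
}

#' Proband-wise cross-concordance
#'
#' Probability that the co-twin of a proband affected by `proband_trait`
#' is affected by `target_trait`. Every affected individual counts as a
#' proband, so pairs concordant for the proband trait contribute twice
#' (the standard proband-wise rule).
#'
#' @inheritParams cross_twin_table
#' @param proband_trait,target_trait binary column names.
#' @param conf_level confidence level for the Wilson interval.
#' @return A list of class `"concordance"` with `proband_trait`,
#'   `target_trait`, `zygosity`, `n_probands`, `n_affected_cotwins`,
#'   `concordance`, `ci_low`, `ci_high`, and `degenerate` (TRUE with zero
#'   probands, in which case the estimate is `NA`).
#' @export
proband_cross_concordance <- function(cohort, proband_trait, target_trait,
                                      zygosity, conf_level = 0.95) {
  w <- .pair_wide(cohort, unique(c(proband_trait, target_trait)), zygosity)
  p1 <- w[[paste0(proband_trait, ".1")]]; p2 <- w[[paste0(proband_trait, ".2")]]
  t1 <- w[[paste0(target_trait, ".1")]]; t2 <- w[[paste0(target_trait, ".2")]]
  n_prob <- sum(p1 == 1) + sum(p2 == 1)
  n_hit <- sum(p1 == 1 & t2 == 1) + sum(p2 == 1 & t1 == 1)
  out <- list(proband_trait = proband_trait, target_trait = target_trait,
              zygosity = paste(zygosity, collapse = "/"),
              n_probands = n_prob, n_affected_cotwins = n_hit,
              degenerate = n_prob == 0)
  if (n_prob == 0) {
    out$concordance <- NA_real_; out$ci_low <- NA_real_; out$ci_high <- NA_real_
  } else {
    out$concordance <- n_hit / n_prob
    ci <- .wilson_ci(n_hit, n_prob, conf_level)
    out$ci_low <- ci[1]; out$ci_high <- ci[2]
  }
  class(out) <- "concordance"
  out
}

#' @export
print.concordance <- function(x, digits = 3, ...) {
  if (x$degenerate) {
    cat(sprintf("Cross-concordance %s -> %s (%s): undefined (no probands)\n",
                x$proband_trait, x$target_trait, x$zygosity))
  } else {
    cat(sprintf(
      "Cross-concordance %s -> %s (%s): %.*f (CI %.*f, %.*f), %d/%d probands\n",
      x$proband_trait, x$target_trait, x$zygosity, digits, x$concordance,
      digits, x$ci_low, digits, x$ci_high, x$n_affected_cotwins, x$n_probands))
  }
  invisible(x)
}
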