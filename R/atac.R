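#' @name atac
#' @title A-TAC item emission and subclinical phenotyping
#'
#' @description
#' The Autism--Tics, ADHD and Other Comorbidities inventory (A-TAC) is a
#' standardized parent interview whose items are scored 0 ("No"),
#' 0.5 ("Yes, to some extent") or 1 ("Yes"). The autism module has 17 items
#' and the ADHD module 19. Subclinical autism is a module total of 4.5 or
#' more; subclinical ADHD a total of at least 6.0 (the validated low
#' screening cutoffs, screening positive in about 3.6% and 10.5% of the
#' general population respectively).
#'
#' For simulation, each item is modeled as a graded (3-level)
#' discretization of the module's source liability plus item-specific
#' normal noise: item latent `u = loading * L + sqrt(1-loading^2) * eps`,
#' scored 0.5 above `tau1` and 1 above `tau1 + gap`. The lower threshold is
#' calibrated deterministically (dynamic-programming convolution of the
#' item-score distribution integrated over the population liability) so the
#' population screen-positive rate matches a target.
NULL

.atac_items <- c(autism = 17L, adhd = 19L)
.atac_cutoffs <- c(autism = 4.5, adhd = 6.0)

# P(score = 0 / 0.5 / 1 | liability L) for one item
.atac_item_probs <- function(L, loading, tau1, gap) {
  s <- sqrt(1 - loading^2)
  p0 <- stats::pnorm((tau1 - loading * L) / s)
  p01 <- stats::pnorm((tau1 + gap - loading * L) / s)
  cbind(p0 = p0, p05 = p01 - p0, p1 = 1 - p01)
}

# exact P(total >= cutoff) by convolution over items + quadrature over L
.atac_positive_rate <- function(n_items, cutoff, loading, tau1, gap) {
  Ls <- seq(-6, 6, by = 0.02)
  w <- stats::dnorm(Ls) * 0.02
  pr <- .atac_item_probs(Ls, loading, tau1, gap)
  # totals in half-point units: support 0..2*n_items
  rate <- numeric(length(Ls))
  for (i in seq_along(Ls)) {
    f <- 1
    for (j in seq_len(n_items))
      f <- c(f * pr[i, 1], 0, 0) + c(0, f * pr[i, 2], 0) + c(0, 0, f * pr[i, 3])
    rate[i] <- sum(f[seq(2 * cutoff + 1, 2 * n_items + 1)])
  }
  sum(rate * w) / sum(w)
}

#' A-TAC emission settings
#'
#' Builds calibrated item-emission settings for one A-TAC module: the lower
#' item threshold `tau1` is solved so the population screen-positive rate
#' at the module cutoff equals `target_rate` under a standard-normal source
#' liability.
#'
#' @param module `"autism"` (17 items, cutoff 4.5) or `"adhd"` (19 items,
#'   cutoff 6.0).
#' @param source_trait name of the simulated trait whose liability drives
#'   the items.
#' @param loading correlation between the source liability and each item
#'   latent (default 0.7).
#' @param gap distance between the 0/0.5 and 0.5/1 item thresholds
#'   (default 0.8).
#' @param target_rate population screen-positive probability at the module
#'   cutoff (defaults: 0.036 autism, 0.105 adhd).
#' @return A list of class `"atac_settings"`.
#' @examples
#' st <- atac_settings("autism", source_trait = "autism_liab")
#' st$tau1
#' @export
atac_settings <- function(module = c("autism", "adhd"), source_trait,
                          loading = 0.7, gap = 0.8, target_rate = NULL) {
  module <- match.arg(module)
  if (is.null(target_rate))
    target_rate <- c(autism = 0.036, adhd = 0.105)[[module]]
  if (loading <= 0 || loading >= 1) stop("loading must lie in (0, 1)")
  n_items <- .atac_items[[module]]
  cutoff <- .atac_cutoffs[[module]]
  f <- function(tau1)
    .atac_positive_rate(n_items, cutoff, loading, tau1, gap) - target_rate
  tau1 <- stats::uniroot(f, c(-2, 6), tol = 1e-8)$root
  structure(list(module = module, source_trait = source_trait,
                 n_items = n_items, cutoff = cutoff, loading = loading,
                 gap = gap, tau1 = tau1, target_rate = target_rate),
            class = "atac_settings")
}

#' Emit A-TAC item scores from liabilities
#'
#' Draws one row of item scores (0 / 0.5 / 1) per liability value using the
#' graded item model in the current RNG stream. Higher liability gives
#' stochastically higher totals.
#'
#' @param liability numeric vector of source liabilities.
#' @param module `"autism"` or `"adhd"`; must match `settings$module`.
#' @param settings an [atac_settings()] object.
#' @return A numeric matrix, rows = individuals, columns = items.
#' @export
emit_atac_items <- function(liability, module, settings) {
  if (!module %in% names(.atac_items)) stop("unknown A-TAC module: ", module)
  stopifnot(inherits(settings, "atac_settings"))
  if (settings$module != module)
    stop("settings are for module '", settings$module, "', not '", module, "'")
  n <- length(liability)
  k <- settings$n_items
  s <- sqrt(1 - settings$loading^2)
  u <- settings$loading * liability + s * matrix(stats::rnorm(n * k), n, k)
  (u > settings$tau1) * 0.5 + (u > settings$tau1 + settings$gap) * 0.5
}

#' Score an A-TAC module
#'
#' Totals item scores, validating that every item is 0, 0.5 or 1 and the
#' item count matches a module (17 or 19). Rows with any missing item get
#' a missing total (listwise exclusion downstream).
#'
#' @param items numeric vector (one individual) or matrix/data frame
#'   (rows = individuals) of item scores.
#' @return Numeric vector of totals.
#' @examples
#' score_atac(c(rep(0.5, 9), rep(0, 8)))  # 4.5
#' @export
score_atac <- function(items) {
  m <- if (is.null(dim(items))) matrix(as.numeric(items), nrow = 1)
       else as.matrix(items)
  if (!ncol(m) %in% .atac_items)
    stop("item count ", ncol(m), " matches no A-TAC module (17 or 19)")
  ok <- is.na(m) | m %in% c(0, 0.5, 1)
  if (!all(ok)) {
    bad <- which(!ok, arr.ind = TRUE)[1, ]
    stop("invalid item score ", m[bad[1], bad[2]], " in row ", bad[1],
         ", item ", bad[2], " (must be 0, 0.5 or 1)")
  }
  rowSums(m)
}

#' Classify a subclinical phenotype from an A-TAC total
#'
#' Inclusive cutoffs: autism positive at a total of 4.5 or more, ADHD at
#' 6.0 or more. Missing totals give missing flags.
#'
#' @param total numeric vector of module totals.
#' @param module `"autism"` or `"adhd"`.
#' @return Integer vector of 0/1 flags (NA where total is missing).
#' @export
classify_subclinical <- function(total, module = c("autism", "adhd")) {
  module <- match.arg(module)
  rng <- c(0, .atac_items[[module]])
  if (any(total < rng[1] | total > rng[2], na.rm = TRUE))
    stop("totals outside the ", module, " module range [0, ", rng[2], "]")
  as.integer(total >= .atac_cutoffs[[module]])
}

#' Resolve clinical and subclinical phenotype assignments
#'
#' Combines clinical diagnosis columns with A-TAC-derived subclinical flags
#' into one assignment table. By default subclinical groups include
#' individuals who also carry the clinical diagnosis; the sensitivity
#' variant removes them (see [apply_sensitivity_exclusion()]).
#'
#' @param cohort cohort data frame (see [simulate_cohort()] for the layout).
#' @param clinical named character vector mapping phenotypes to clinical
#'   diagnosis columns, e.g. `c(autism = "clinical_autism")`.
#' @param exclude_clinical if TRUE, apply the sensitivity exclusion.
#' @return A data frame keyed by `pair_id` + `twin_index` with columns
#'   `clinical_autism`, `clinical_adhd`, `subclinical_autism`,
#'   `subclinical_adhd` (as available) and `group` (the exclusive
#'   autism-only / adhd-only / autism+adhd / neither partition of clinical
#'   diagnoses). Rows with missing A-TAC items are counted in the
#'   `n_excluded_missing` attribute.
#' @export
assign_phenotypes <- function(cohort,
                              clinical = c(autism = "clinical_autism",
                                           adhd = "clinical_adhd"),
                              exclude_clinical = FALSE) {
  out <- cohort[, c("pair_id", "twin_index")]
  n_missing <- 0L
  for (ph in c("autism", "adhd")) {
    col <- clinical[[ph]]
    if (!is.null(col) && col %in% names(cohort))
      out[[paste0("clinical_", ph)]] <- as.integer(cohort[[col]])
    tot_col <- paste0("atac_", ph, "_total")
    item_cols <- grep(paste0("^atac_", ph, "_[0-9]+$"), names(cohort),
                      value = TRUE)
    if (length(item_cols) > 0) {
      tot <- score_atac(cohort[, item_cols])
    } else if (tot_col %in% names(cohort)) {
      tot <- cohort[[tot_col]]
    } else next
    n_missing <- n_missing + sum(is.na(tot))
    out[[paste0("subclinical_", ph)]] <- classify_subclinical(tot, ph)
  }
  if (all(c("clinical_autism", "clinical_adhd") %in% names(out)))
    out$group <- exclusive_groups(out$clinical_autism, out$clinical_adhd)
  if (exclude_clinical) out <- apply_sensitivity_exclusion(out)
  attr(out, "n_excluded_missing") <- n_missing
  out
}

#' Sensitivity exclusion of clinical cases from subclinical groups
#'
#' Sets each subclinical flag to 0 for individuals carrying the
#' corresponding clinical diagnosis, leaving everything else unchanged.
#' Used to check that subclinical associations are not driven by clinical
#' cases.
#'
#' @param assignments data frame from [assign_phenotypes()].
#' @return The modified assignments.
#' @export
apply_sensitivity_exclusion <- function(assignments) {
  for (ph in c("autism", "adhd")) {
    cl <- paste0("clinical_", ph); sub <- paste0("subclinical_", ph)
    if (all(c(cl, sub) %in% names(assignments))) {
      hit <- !is.na(assignments[[cl]]) & assignments[[cl]] == 1 &
        !is.na(assignments[[sub]])
      assignments[[sub]][hit] <- 0L
    }
  }
  assignments
}
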