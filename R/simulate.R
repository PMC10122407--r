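#' Trait specification for cohort simulation
#'
#' Defines one binary trait by its standardized liability variance
#' decomposition and its population prevalence.
#'
#' @param name column name of the trait in the simulated cohort.
#' @param a2,c2 additive-genetic and shared-environmental proportions of
#'   liability variance; the nonshared proportion is `e2 = 1 - a2 - c2`.
#' @param K prevalence in (0, 1); the liability threshold is
#'   `threshold_from_prevalence(K)`.
#' @return A list of class `"trait_spec"`.
#' @export
trait_spec <- function(name, a2, c2 = 0, K = 0.05) {
  e2 <- 1 - a2 - c2
  if (a2 < 0 || c2 < 0 || e2 < -1e-12)
    stop("a2, c2, e2 must be nonnegative and sum to 1 for trait ", name)
  e2 <- max(e2, 0)
  if (K <= 0 || K >= 1) stop("prevalence must lie in (0,1) for trait ", name)
  structure(list(name = name, a2 = a2, c2 = c2, e2 = e2, K = K,
                 threshold = stats::qnorm(K, lower.tail = FALSE)),
            class = "trait_spec")
}

#' Cross-trait etiologic correlations
#'
#' Correlations between the additive-genetic (`ra`), shared-environmental
#' (`rc`) and nonshared-environmental (`re`) influences on two traits.
#'
#' @param ra,rc,re correlations in [-1, 1].
#' @return A list of class `"cross_trait_spec"`.
#' @export
cross_trait_spec <- function(ra = 0, rc = 0, re = 0) {
  for (r in c(ra, rc, re))
    if (abs(r) > 1) stop("etiologic correlations must lie in [-1, 1]")
  structure(list(ra = ra, rc = rc, re = re), class = "cross_trait_spec")
}

# component correlation matrices (k x k) from the cross map
.component_corrs <- function(traits, cross) {
  k <- length(traits)
  nm <- vapply(traits, `[[`, "", "name")
  Ra <- Rc <- Re <- diag(k)
  dimnames(Ra) <- dimnames(Rc) <- dimnames(Re) <- list(nm, nm)
  for (key in names(cross)) {
    pair <- strsplit(key, ":", fixed = TRUE)[[1]]
    if (length(pair) != 2L || !all(pair %in% nm))
      stop("cross-trait key '", key, "' must name two traits as 'a:b'")
    i <- match(pair[1], nm); j <- match(pair[2], nm)
    cs <- cross[[key]]
    Ra[i, j] <- Ra[j, i] <- cs$ra
    Rc[i, j] <- Rc[j, i] <- cs$rc
    Re[i, j] <- Re[j, i] <- cs$re
  }
  list(Ra = Ra, Rc = Rc, Re = Re)
}

# implied 2k x 2k per-pair liability correlation matrix for one zygosity
.pair_corr <- function(traits, comp, zygosity) {
  k <- length(traits)
  a <- sqrt(vapply(traits, `[[`, 0, "a2"))
  cc <- sqrt(vapply(traits, `[[`, 0, "c2"))
  e <- sqrt(vapply(traits, `[[`, 0, "e2"))
  g <- if (zygosity == "MZ") 1 else 0.5
  Da <- diag(a, k); Dc <- diag(cc, k); De <- diag(e, k)
  within <- Da %*% comp$Ra %*% Da + Dc %*% comp$Rc %*% Dc + De %*% comp$Re %*% De
  between <- g * Da %*% comp$Ra %*% Da + Dc %*% comp$Rc %*% Dc
  R <- rbind(cbind(within, between), cbind(between, within))
  diag(R) <- 1
  R
}

#' Cohort specification
#'
#' Describes a simulated classical-twin cohort: pair counts by zygosity,
#' traits with their variance components and prevalences, cross-trait
#' etiologic correlations, demographics, optional A-TAC item emission, and
#' the random seed. The implied per-pair liability correlation matrices for
#' both zygosities are checked for positive semi-definiteness at
#' construction, before any sampling.
#'
#' @param n_mz,n_dz numbers of monozygotic and same-sex dizygotic pairs.
#' @param traits list of [trait_spec()] objects.
#' @param cross named list of [cross_trait_spec()] objects; names are
#'   `"traitA:traitB"`.
#' @param sex_ratio proportion of female pairs.
#' @param age_levels named numeric vector of age-group proportions
#'   (default the 9- vs 12-year mix 8125:2222 of the reference cohort).
#' @param atac optional list of [atac_settings()] keyed by module
#'   (`autism`, `adhd`); each must name its `source_trait`.
#' @param n_dzos number of opposite-sex DZ pairs (descriptives only; not
#'   part of the twin-model design, default 0).
#' @param seed integer random seed recorded in the spec.
#' @return A list of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n_mz = 4767, n_dz = 5580, traits, cross = list(),
                        sex_ratio = 0.5,
                        age_levels = c("9" = 8125 / 10347, "12" = 2222 / 10347),
                        atac = NULL, n_dzos = 0, seed = 1L) {
  if (n_mz < 0 || n_dz < 0 || n_dzos < 0) stop("pair counts must be >= 0")
  if (inherits(traits, "trait_spec")) traits <- list(traits)
  stopifnot(length(traits) >= 1, all(vapply(traits, inherits, TRUE, "trait_spec")))
  if (abs(sum(age_levels) - 1) > 1e-8)
    stop("age_levels proportions must sum to 1")
  comp <- .component_corrs(traits, cross)
  for (z in c("MZ", "DZ")) {
    R <- .pair_corr(traits, comp, z)
    ev <- min(eigen(R, symmetric = TRUE, only.values = TRUE)$values)
    if (ev < -1e-8)
      stop("implied ", z, " liability correlation matrix is not positive ",
           "semi-definite (smallest eigenvalue ", format(ev), ")")
  }
  if (!is.null(atac)) {
    nm <- vapply(traits, `[[`, "", "name")
    for (m in names(atac))
      if (!atac[[m]]$source_trait %in% nm)
        stop("atac module '", m, "' references unknown trait '",
             atac[[m]]$source_trait, "'")
  }
  structure(list(n_mz = n_mz, n_dz = n_dz, n_dzos = n_dzos, traits = traits,
                 cross = cross, comp = comp, sex_ratio = sex_ratio,
                 age_levels = age_levels, atac = atac, seed = as.integer(seed)),
            class = "cohort_spec")
}

# k-dim correlated normals: n x k matrix with correlation R
.rmvn <- function(n, R) {
  k <- ncol(R)
  L <- tryCatch(chol(R), error = function(e) {
    ed <- eigen(R, symmetric = TRUE)
    t(ed$vectors %*% diag(sqrt(pmax(ed$values, 0)), k) %*% t(ed$vectors))
  })
  matrix(stats::rnorm(n * k), n, k) %*% L
}

# liabilities for n pairs of one zygosity: list(t1 = n x k, t2 = n x k)
.pair_liabilities <- function(n, traits, comp, zygosity) {
  k <- length(traits)
  a <- sqrt(vapply(traits, `[[`, 0, "a2"))
  cc <- sqrt(vapply(traits, `[[`, 0, "c2"))
  e <- sqrt(vapply(traits, `[[`, 0, "e2"))
  if (zygosity == "MZ") {
    A <- .rmvn(n, comp$Ra); A1 <- A2 <- A
  } else {
    As <- .rmvn(n, comp$Ra)
    A1 <- sqrt(0.5) * As + sqrt(0.5) * .rmvn(n, comp$Ra)
    A2 <- sqrt(0.5) * As + sqrt(0.5) * .rmvn(n, comp$Ra)
  }
  C <- .rmvn(n, comp$Rc)
  sc <- function(M, w) sweep(M, 2, w, `*`)
  list(t1 = sc(A1, a) + sc(C, cc) + sc(.rmvn(n, comp$Re), e),
       t2 = sc(A2, a) + sc(C, cc) + sc(.rmvn(n, comp$Re), e))
}

#' Simulate a classical-twin cohort
#'
#' Draws per-pair latent liabilities from the multivariate normal implied
#' by the correlated-factors model (additive-genetic factors shared with
#' coefficient 1 between MZ and 0.5 between DZ co-twins, shared environment
#' fully shared, nonshared environment twin-specific; cross-trait
#' correlations `ra`/`rc`/`re` applied within each component), dichotomizes
#' each trait at its prevalence threshold, assigns sex and age group, and
#' optionally emits A-TAC item scores from the configured source
#' liabilities. Fully reproducible from the seed.
#'
#' @param spec a [cohort_spec()].
#' @param seed overrides `spec$seed` when given.
#' @param keep_liability if TRUE, latent liability columns
#'   (`liab_<trait>`) are retained for diagnostics.
#' @return A data frame with one row per individual: `pair_id`,
#'   `twin_index` (1/2), `zygosity` (MZ/DZ/DZOS), `sex`, `age`, one 0/1
#'   column per trait, and (when configured) A-TAC item and total columns
#'   `atac_<module>_<i>` / `atac_<module>_total`.
#' @examples
#' spec <- cohort_spec(n_mz = 500, n_dz = 500,
#'                     traits = list(trait_spec("asthma", 0.68, 0.15, 0.134)),
#'                     seed = 7)
#' head(simulate_cohort(spec))
#' @export
simulate_cohort <- function(spec, seed = NULL, keep_liability = FALSE) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (is.null(seed)) seed <- spec$seed
  has_seed <- exists(".Random.seed", envir = globalenv())
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_seed) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)

  traits <- spec$traits
  k <- length(traits)
  nm <- vapply(traits, `[[`, "", "name")
  thr <- vapply(traits, `[[`, 0, "threshold")

  blocks <- list()
  pair_offset <- 0L
  for (z in c("MZ", "DZ", "DZOS")) {
    n <- switch(z, MZ = spec$n_mz, DZ = spec$n_dz, DZOS = spec$n_dzos)
    if (n == 0) next
    lab <- .pair_liabilities(n, traits, spec$comp,
                             if (z == "MZ") "MZ" else "DZ")
    if (z == "DZOS") {
      sex1 <- rep("M", n); sex2 <- rep("F", n)
    } else {
      s <- ifelse(stats::runif(n) < spec$sex_ratio, "F", "M")
      sex1 <- sex2 <- s
    }
    age <- sample(names(spec$age_levels), n, replace = TRUE,
                  prob = spec$age_levels)
    pid <- pair_offset + seq_len(n)
    pair_offset <- pair_offset + n
    mk <- function(idx, liab, sex) {
      d <- data.frame(pair_id = pid, twin_index = idx, zygosity = z,
                      sex = sex, age = as.integer(age),
                      stringsAsFactors = FALSE)
      y <- sweep(liab, 2, thr, `>`) + 0L
      colnames(y) <- nm
      d <- cbind(d, as.data.frame(y))
      if (keep_liability) {
        l <- as.data.frame(liab); colnames(l) <- paste0("liab_", nm)
        d <- cbind(d, l)
      }
      if (!is.null(spec$atac)) {
        for (m in names(spec$atac)) {
          st <- spec$atac[[m]]
          items <- emit_atac_items(liab[, st$source_trait], m, st)
          colnames(items) <- paste0("atac_", m, "_", seq_len(ncol(items)))
          d <- cbind(d, as.data.frame(items))
          d[[paste0("atac_", m, "_total")]] <- rowSums(items)
        }
      }
      d
    }
    blocks[[length(blocks) + 1L]] <- mk(1L, lab$t1, sex1)
    blocks[[length(blocks) + 1L]] <- mk(2L, lab$t2, sex2)
  }
  out <- do.call(rbind, blocks)
  out <- out[order(out$pair_id, out$twin_index), ]
  rownames(out) <- NULL
  attr(out, "seed") <- seed
  out
}

#' Write / read a cohort CSV
#'
#' Plain comma-separated UTF-8 files with a header row and `.` decimal,
#' one row per individual, as produced by [simulate_cohort()].
#'
#' @param cohort a cohort data frame.
#' @param path file path.
#' @return `read_cohort()` returns the cohort data frame;
#'   `write_cohort()` returns `path` invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}
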