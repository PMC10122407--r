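#' Univariate components from published summary statistics (two-stage)
#'
#' Reconstructs the expected MZ/DZ cross-twin tables from a condition's
#' prevalence, cross-twin correlations and pair counts via
#' [implied_table()], then fits the ACE model ([twin_ace()]; the AE
#' solution is reported automatically on the `c2 = 0` boundary). This is
#' the route by which published variance components can be reproduced
#' when only summary statistics are available.
#'
#' @param K prevalence; `r_mz`, `r_dz` cross-twin correlations;
#'   `n_mz`, `n_dz` pair counts.
#' @param r_mz,r_dz cross-twin tetrachoric correlations.
#' @param n_mz,n_dz pair counts by zygosity.
#' @param ... passed to [twin_ace()].
#' @return A [twin_ace()] fit.
#' @examples
#' fit_from_summary(K = 0.134, r_mz = 0.83, r_dz = 0.49)  # asthma-like
#' @export
fit_from_summary <- function(K, r_mz, r_dz, n_mz = 4767, n_dz = 5580, ...) {
  twin_ace(implied_table(K, K, r_mz, n_mz),
           implied_table(K, K, r_dz, n_dz), ...)
}

.log_stage <- function(stage, ...) {
  message(sprintf("[%s] %s %s", format(Sys.time(), "%H:%M:%S"), stage,
                  paste(..., collapse = " ")))
}

# build a cohort_spec from a plain (YAML/JSON-parsed) list
.spec_from_list <- function(x) {
  traits <- lapply(x$traits, function(tr)
    trait_spec(tr$name, tr$a2, tr$c2 %||% 0, tr$K))
  cross <- lapply(x$cross %||% list(), function(cr)
    cross_trait_spec(cr$ra %||% 0, cr$rc %||% 0, cr$re %||% 0))
  atac <- if (!is.null(x$atac)) {
    stats::setNames(lapply(names(x$atac), function(m) {
      a <- x$atac[[m]]
      atac_settings(m, source_trait = a$source_trait,
                    loading = a$loading %||% 0.7, gap = a$gap %||% 0.8,
                    target_rate = a$target_rate)
    }), names(x$atac))
  } else NULL
  cohort_spec(n_mz = x$n_mz %||% 4767, n_dz = x$n_dz %||% 5580,
              traits = traits, cross = cross,
              sex_ratio = x$sex_ratio %||% 0.5,
              age_levels = if (!is.null(x$age_levels))
                unlist(x$age_levels) else c("9" = 8125 / 10347,
                                            "12" = 2222 / 10347),
              atac = atac, n_dzos = x$n_dzos %||% 0,
              seed = x$seed %||% 1L)
}

#' Read a pipeline configuration
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON configuration file.
#' @return The configuration as a list.
#' @export
read_config <- function(path) {
  if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Run the full twin-comorbidity analysis pipeline
#'
#' Orchestrates the analysis end-to-end on a cohort CSV or a simulated
#' cohort: prevalence descriptives, cluster-robust association table with
#' Bonferroni gating, univariate variance components and proband-wise
#' cross-concordances for the gated conditions, and bivariate twin models
#' for every Bonferroni-significant exposure-outcome pair. Twin-model
#' stages use MZ and same-sex DZ pairs only; the association stage uses
#' all rows. Structured per-stage log lines go to stderr (via
#' `message()`); results never do.
#'
#' @param config configuration list or path (see [read_config()]):
#'   `cohort` (CSV path) or `spec` (simulation settings), `exposures`,
#'   `outcomes`, `alpha` (default 0.05), `bonferroni_m` (default: number
#'   of outcomes), `models`, `exclude_clinical`, `bivariate_method`
#'   (`"ml"` or `"two_stage"`), `seed`.
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list with the four tables, the bivariate fits and
#'   the manifest; files `table1.tsv` ... `table4.tsv`,
#'   `bivariate/<pair>.json`, `fig1_contributions.tsv` and
#'   `manifest.json` are written under `out_dir`.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_config(config)
  t_start <- Sys.time()
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "bivariate"), showWarnings = FALSE)
  seed <- config$seed %||% 1L

  # --- cohort -------------------------------------------------------------
  if (!is.null(config$cohort)) {
    .log_stage("cohort", "reading", config$cohort)
    cohort <- read_cohort(config$cohort)
  } else if (!is.null(config$spec)) {
    spec <- if (inherits(config$spec, "cohort_spec")) config$spec
            else .spec_from_list(c(config$spec, list(seed = seed)))
    .log_stage("cohort", "simulating", spec$n_mz, "MZ +", spec$n_dz,
               "DZ pairs, seed", seed)
    cohort <- simulate_cohort(spec, seed = seed)
  } else stop("config must provide either 'cohort' or 'spec'")

  # subclinical phenotyping when A-TAC columns are present
  if (any(grepl("^atac_", names(cohort)))) {
    .log_stage("phenotyping", "A-TAC subclinical classification")
    asg <- assign_phenotypes(cohort,
                             exclude_clinical = isTRUE(config$exclude_clinical))
    for (v in setdiff(names(asg), c("pair_id", "twin_index", "group",
                                    names(cohort))))
      cohort[[v]] <- asg[[v]]
  }

  exposures <- config$exposures
  outcomes <- config$outcomes
  for (v in c(exposures, outcomes))
    if (!v %in% names(cohort))
      stop("configured column '", v, "' not present in cohort")
  alpha <- config$alpha %||% 0.05
  m <- config$bonferroni_m %||% length(outcomes)
  twin_rows <- cohort$zygosity %in% c("MZ", "DZ")

  # --- table 1: prevalence ------------------------------------------------
  .log_stage("table1", "prevalence for", length(c(exposures, outcomes)),
             "phenotypes")
  tab1 <- do.call(rbind, lapply(c(exposures, outcomes), function(tr) {
    p <- prevalence(cohort, tr, by = "zygosity")
    p$trait <- tr
    p[, c("trait", setdiff(names(p), "trait"))]
  }))
  utils::write.table(tab1, file.path(out_dir, "table1.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)

  # --- table 2: associations ----------------------------------------------
  .log_stage("table2", "associations:", length(exposures), "exposures x",
             length(outcomes), "outcomes, Bonferroni m =", m)
  tab2 <- association_table(cohort, exposures, outcomes, alpha = alpha, m = m)
  utils::write.table(tab2, file.path(out_dir, "table2.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  gated <- tab2[tab2$significant, c("exposure", "outcome")]

  # --- table 3: univariate components for outcome conditions --------------
  .log_stage("table3", "univariate models for", length(outcomes), "traits")
  tab3 <- do.call(rbind, lapply(outcomes, function(tr) {
    fit <- tryCatch(twin_ace(cohort[twin_rows, ], trait = tr),
                    error = function(e) NULL)
    if (is.null(fit))
      return(data.frame(trait = tr, a2 = NA, c2 = NA, e2 = NA, r_mz = NA,
                        r_dz = NA, minus2LL = NA, AIC = NA,
                        boundary_c = NA))
    data.frame(trait = tr, a2 = fit$a2, c2 = fit$c2, e2 = fit$e2,
               r_mz = cross_twin_correlation(cohort, tr, zygosity = "MZ")$r,
               r_dz = cross_twin_correlation(cohort, tr, zygosity = "DZ")$r,
               minus2LL = fit$minus2LL, AIC = fit$AIC,
               boundary_c = fit$boundary_c)
  }))
  utils::write.table(tab3, file.path(out_dir, "table3.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)

  # --- table 4: proband-wise cross-concordances for gated pairs -----------
  .log_stage("table4", "cross-concordances for", nrow(gated), "gated pairs")
  tab4 <- if (nrow(gated) == 0) {
    data.frame(proband = character(), target = character(),
               zygosity = character(), concordance = numeric(),
               ci_low = numeric(), ci_high = numeric(),
               n_probands = integer())
  } else do.call(rbind, lapply(seq_len(nrow(gated)), function(i) {
    do.call(rbind, lapply(c("MZ", "DZ"), function(z) {
      cc <- proband_cross_concordance(cohort[twin_rows, ],
                                      gated$exposure[i], gated$outcome[i], z)
      data.frame(proband = gated$exposure[i], target = gated$outcome[i],
                 zygosity = z, concordance = cc$concordance,
                 ci_low = cc$ci_low, ci_high = cc$ci_high,
                 n_probands = cc$n_probands)
    }))
  }))
  utils::write.table(tab4, file.path(out_dir, "table4.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)

  # --- bivariate models for gated pairs -----------------------------------
  biv_method <- config$bivariate_method %||% "ml"
  fits <- list()
  contrib_rows <- list()
  for (i in seq_len(nrow(gated))) {
    ex <- gated$exposure[i]; ou <- gated$outcome[i]
    .log_stage("bivariate", ex, "x", ou, paste0("(", biv_method, ")"))
    fit <- tryCatch(
      twin_biv(cohort[twin_rows, ], trait_a = ex, trait_b = ou,
               method = biv_method),
      error = function(e) stop("bivariate stage failed for ", ex, " x ", ou,
                               ": ", conditionMessage(e)))
    key <- paste0(ex, "__", ou)
    fits[[key]] <- fit
    dec <- decompose_rph(fit)
    jsonlite::write_json(
      list(traits = fit$traits, paths = as.list(fit$paths),
           a2 = fit$a2, c2 = fit$c2, e2 = fit$e2,
           ra = fit$ra, rc = fit$rc, re = fit$re, rph = fit$rph,
           contributions = as.list(fit$contributions),
           bivariate_heritability = fit$bivariate_heritability,
           thresholds = fit$thresholds, minus2LL = fit$minus2LL,
           AIC = fit$AIC, method = fit$method, converged = fit$converged,
           seed = seed),
      file.path(out_dir, "bivariate", paste0(key, ".json")),
      auto_unbox = TRUE, digits = NA)
    contrib_rows[[key]] <- data.frame(
      exposure = ex, outcome = ou, rph = fit$rph,
      genetic = fit$contributions["genetic"],
      shared = fit$contributions["shared"],
      nonshared = fit$contributions["nonshared"],
      bivariate_heritability = fit$bivariate_heritability)
  }
  contrib <- if (length(contrib_rows)) do.call(rbind, contrib_rows) else
    data.frame(exposure = character(), outcome = character(),
               rph = numeric(), genetic = numeric(), shared = numeric(),
               nonshared = numeric(), bivariate_heritability = numeric())
  utils::write.table(contrib, file.path(out_dir, "fig1_contributions.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)

  manifest <- list(
    seed = seed,
    package_version = as.character(utils::packageVersion("twinliab")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    alpha = alpha, bonferroni_m = m,
    bonferroni_threshold = bonferroni_threshold(alpha, m),
    n_individuals = nrow(cohort),
    n_pairs = length(unique(cohort$pair_id)),
    n_pairs_by_zygosity = as.list(table(
      cohort$zygosity[cohort$twin_index == 1])),
    exposures = exposures, outcomes = outcomes,
    n_gated_pairs = nrow(gated),
    exclude_clinical = isTRUE(config$exclude_clinical),
    runtime_seconds = as.numeric(difftime(Sys.time(), t_start,
                                          units = "secs")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  .log_stage("done", sprintf("%.1f s", manifest$runtime_seconds))
  invisible(list(table1 = tab1, table2 = tab2, table3 = tab3, table4 = tab4,
                 bivariate = fits, contributions = contrib,
                 manifest = manifest))
}
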