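#' Published summary statistics for the CATSS physical-health conditions
#'
#' Cohort-level summary statistics for 13 physical health conditions in the
#' Child and Adolescent Twin Study in Sweden (CATSS; 4,767 monozygotic and
#' 5,580 same-sex dizygotic twin pairs aged 9 and 12): prevalence in the
#' twin-model sample, MZ and DZ cross-twin tetrachoric correlations, and the
#' published univariate variance-component estimates (A/V, C/V, E/V). The
#' individual-level registry data are access-restricted, so these printed
#' summaries are the reference inputs for the package's two-stage
#' reproduction workflow and for calibrating synthetic cohorts.
#'
#' @return A data frame with one row per condition and columns `condition`,
#'   `group` (neurological/immunological/gastrointestinal), `prevalence`,
#'   `r_mz`, `r_dz`, `A`, `C`, `E` (published variance proportions), and
#'   pair counts `n_mz`, `n_dz`.
#' @examples
#' ref <- catss_reference()
#' falconer(ref$r_mz[ref$condition == "asthma"],
#'          ref$r_dz[ref$condition == "asthma"])
#' @export
catss_reference <- function() {
  data.frame(
    condition = c("epilepsy", "migraine", "other_headache", "mixed_headache",
                  "allergic_rhinitis", "asthma", "atopic_dermatitis",
                  "specific_allergy", "coeliac_disease", "constipation",
                  "functional_diarrhea", "irritable_bowel_syndrome",
                  "mixed_fgids"),
    group = rep(c("neurological", "immunological", "gastrointestinal"),
                c(4L, 5L, 4L)),
    prevalence = c(0.012, 0.017, 0.008, 0.023, 0.059, 0.134, 0.051, 0.019,
                   0.011, 0.062, 0.006, 0.004, 0.069),
    r_mz = c(0.62, 0.45, 0.54, 0.49, 0.76, 0.83, 0.79, 0.90, 0.96, 0.51,
             0.93, 0.69, 0.55),
    r_dz = c(0.25, 0.13, 0.18, 0.12, 0.40, 0.49, 0.43, 0.54, 0.71, 0.25,
             0.54, 0.57, 0.27),
    A = c(0.61, 0.41, 0.53, 0.45, 0.73, 0.68, 0.73, 0.71, 0.49, 0.51,
          0.77, 0.26, 0.56),
    C = c(0, 0, 0, 0, 0.04, 0.15, 0.06, 0.19, 0.47, 0, 0.16, 0.43, 0),
    E = c(0.39, 0.59, 0.47, 0.55, 0.24, 0.17, 0.21, 0.10, 0.04, 0.49,
          0.07, 0.31, 0.44),
    n_mz = 4767L,
    n_dz = 5580L,
    stringsAsFactors = FALSE
  )
}
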