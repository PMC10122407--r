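# expected (fractional) 16-cell tables at a known parameter set
expected_tables <- function(par, n_mz = 20000, n_dz = 20000) {
  list(
    mz = n_mz * twinliab:::.biv_cell_probs(par[1], par[2],
      twinliab:::.biv_corr_cf(par[3], par[4], par[5], par[6], par[7],
                              par[8], par[9], 1)),
    dz = n_dz * twinliab:::.biv_cell_probs(par[1], par[2],
      twinliab:::.biv_corr_cf(par[3], par[4], par[5], par[6], par[7],
                              par[8], par[9], 0.5)))
}

test_that("implied correlation assembly matches the explicit matrix oracle", {
  for (g in c(1, 0.5)) {
    R_pkg <- twinliab:::.biv_corr_cf(0.8, 0.3, 0.7, 0.2, 0.5, 0.4, 0.1, g)
    R_or <- oracle_biv_corr(0.8, 0.3, 0.7, 0.2, 0.5, 0.4, 0.1, g)
    expect_equal(R_pkg, R_or, tolerance = 1e-12)
  }
})

test_that("CTCT expectations follow the g-attenuated path product", {
  par <- c(0, 0, 0.8, 0, 0.8, 0, 0.5, 0, 0)
  tabs <- expected_tables(par, 500, 500)
  fit <- twin_biv(tabs$mz, tabs$dz, method = "two_stage")
  expect_equal(ctct_expected(fit, "MZ"), 0.32, tolerance = 0.01)
  expect_equal(ctct_expected(fit, "DZ"), 0.16, tolerance = 0.005)
  expect_gte(ctct_expected(fit, "MZ"), ctct_expected(fit, "DZ"))
  # no shared etiology: zero for both zygosities
  fit0 <- list(paths = c(aa = 0.8, ca = 0.4, ea = sqrt(1 - 0.8), ab = 0.7,
                         cb = 0.3, eb = sqrt(1 - 0.58)), ra = 0, rc = 0)
  class(fit0) <- "twin_biv"
  expect_equal(ctct_expected(fit0, "MZ"), 0)
  expect_equal(ctct_expected(fit0, "DZ"), 0)
})

test_that("rPH decomposition sums to rPH and matches the matrix entries", {
  par <- c(1.5, 2.0, 0.85, 0.25, 0.7, 0.3, 0.5, 0.2, 0.1)
  tabs <- expected_tables(par)
  fit <- twin_biv(tabs$mz, tabs$dz, method = "ml")
  d <- decompose_rph(fit)
  expect_equal(sum(d$contributions), d$rph, tolerance = 1e-10)
  expect_equal(sum(d$proportions), 1, tolerance = 1e-8)
  # path products against the implied-matrix entries (two routes)
  p <- fit$par
  R_mz <- twinliab:::.biv_corr_cf(p[3], p[4], p[5], p[6], p[7], p[8], p[9], 1)
  expect_equal(fit$rph, R_mz[1, 2], tolerance = 1e-10)
  expect_equal(ctct_expected(fit, "MZ"), R_mz[1, 4], tolerance = 1e-10)
  # purely genetic covariance: proportion exactly one
  par2 <- c(1.5, 2.0, 0.85, 0, 0.7, 0, 0.5, 0, 0)
  tabs2 <- expected_tables(par2)
  fit2 <- twin_biv(tabs2$mz, tabs2$dz, method = "ml")
  expect_equal(unname(decompose_rph(fit2)$proportions["genetic"]), 1,
               tolerance = 0.02)
})

test_that("full ML recovers parameters from the model's expected tables", {
  par <- c(2.144, 2.257, sqrt(0.90), 0, sqrt(0.61), 0, 0.5, 0, 0.149)
  tabs <- expected_tables(par, 50000, 50000)
  fit <- twin_biv(tabs$mz, tabs$dz, method = "ml")
  expect_equal(fit$par[1:2], par[1:2], tolerance = 1e-3)
  expect_equal(fit$a2[1], 0.90, tolerance = 1e-3)
  expect_equal(fit$a2[2], 0.61, tolerance = 1e-3)
  expect_equal(fit$ra, 0.5, tolerance = 2e-3)
  expect_equal(fit$re, 0.149, tolerance = 5e-3)
  expect_true(fit$converged)
})

test_that("independent traits yield null etiologic correlations", {
  par <- c(1.0, 1.3, 0.8, 0.2, 0.75, 0.3, 0, 0, 0)
  tabs <- expected_tables(par)
  fit <- twin_biv(tabs$mz, tabs$dz, method = "ml")
  expect_lt(abs(fit$ra), 0.01)
  expect_lt(abs(fit$rph), 0.01)
  d <- decompose_rph(fit)
  expect_true(d$undefined)
  expect_true(all(is.na(d$proportions)))
})

test_that("Cholesky and correlated-factors parameterizations are equivalent", {
  # random Cholesky path sets mapped to the correlated-factors solution
  # must give identical likelihood under the independent matrix assembly
  par_data <- c(1.2, 1.5, 0.8, 0.2, 0.7, 0.25, 0.4, 0.1, 0.05)
  tabs <- expected_tables(par_data, 3000, 3000)
  nll_from_R <- function(R_mz, R_dz, ta, tb) {
    -sum(tabs$mz * log(twinliab:::.biv_cell_probs(ta, tb, R_mz))) -
      sum(tabs$dz * log(twinliab:::.biv_cell_probs(ta, tb, R_dz)))
  }
  set.seed(77)
  for (i in 1:10) {
    # draw a valid Cholesky parameter set with unit variances
    repeat {
      a <- runif(3, 0.1, 0.7); cc <- runif(3, 0.05, 0.5)
      e11 <- 1 - a[1]^2 - cc[1]^2
      e21 <- runif(1, -0.3, 0.3)
      e22sq <- 1 - a[2]^2 - a[3]^2 - cc[2]^2 - cc[3]^2 - e21^2
      if (e11 > 0.05 && e22sq > 0.05) break
    }
    chol_par <- list(a11 = a[1], a21 = a[2], a22 = a[3], c11 = cc[1],
                     c21 = cc[2], c22 = cc[3], e11 = sqrt(e11), e21 = e21,
                     e22 = sqrt(e22sq))
    cf <- do.call(twinliab:::.cf_from_chol, chol_par)
    ta <- 1.1; tb <- 1.6
    nll_chol <- nll_from_R(
      do.call(twinliab:::.biv_corr_chol, c(chol_par, g = 1)),
      do.call(twinliab:::.biv_corr_chol, c(chol_par, g = 0.5)), ta, tb)
    nll_cf <- twinliab:::.biv_nll(
      c(ta, tb, cf$aa, cf$ca, cf$ab, cf$cb, cf$ra, cf$rc, cf$re),
      tabs$mz, tabs$dz)
    expect_lt(abs(nll_chol - nll_cf), 1e-6)
  }
})

test_that("two-stage and full-ML solutions agree on clean expected tables", {
  par <- c(1.3, 1.8, 0.8, 0.2, 0.7, 0.3, 0.5, 0.2, 0.1)
  tabs <- expected_tables(par, 50000, 50000)
  ml <- twin_biv(tabs$mz, tabs$dz, method = "ml")
  ts <- twin_biv(tabs$mz, tabs$dz, method = "two_stage")
  expect_equal(ml$ra, ts$ra, tolerance = 0.05)
  expect_equal(ml$rph, ts$rph, tolerance = 0.02)
  expect_lte(ml$minus2LL, ts$minus2LL + 1e-6)
})

test_that("profile intervals for ra tighten with more pairs", {
  par <- c(1.3, 1.5, 0.8, 0, 0.7, 0, 0.5, 0, 0.1)
  small <- expected_tables(par, 2000, 2000)
  big <- expected_tables(par, 8000, 8000)
  ci_small <- confint(twin_biv(small$mz, small$dz, method = "ml"),
                      parm = "ra")
  ci_big <- confint(twin_biv(big$mz, big$dz, method = "ml"), parm = "ra")
  expect_lt(diff(ci_big[1, ]), diff(ci_small[1, ]))
  expect_true(ci_big[1, 1] < 0.5 && 0.5 < ci_big[1, 2])
})

test_that("16-cell tables count pair patterns and feed the cohort interface", {
  spec <- cohort_spec(1500, 1500,
    traits = list(trait_spec("x", 0.8, 0, 0.1), trait_spec("y", 0.6, 0, 0.1)),
    cross = list("x:y" = cross_trait_spec(ra = 0.5)), seed = 61)
  co <- simulate_cohort(spec)
  tab <- pair_trait_table(co, "x", "y", "MZ")
  expect_equal(sum(tab), 1500)
  expect_equal(length(tab), 16)
  fit <- twin_biv(co, trait_a = "x", trait_b = "y", method = "two_stage")
  expect_true(abs(fit$ra) <= 1)
  expect_error(twin_biv(co, trait_a = "x"), "trait_a and trait_b")
})
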