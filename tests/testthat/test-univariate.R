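test_that("Falconer moment arithmetic is exact", {
  expect_equal(falconer(0.83, 0.49), c(a2 = 0.68, c2 = 0.15, e2 = 0.17),
               tolerance = 1e-12)
  for (r in c(0.2, 0.5, 0.8))
    expect_equal(falconer(r, r), c(a2 = 0, c2 = r, e2 = 1 - r),
                 tolerance = 1e-12)
  # coeliac-like correlations: the moment solution sits within 0.01 of
  # the published likelihood estimates 0.49 / 0.47
  f <- falconer(0.96, 0.71)
  expect_equal(unname(f), c(0.50, 0.46, 0.04), tolerance = 1e-12)
})

test_that("no familial resemblance collapses to the E model", {
  mz <- implied_table(0.2, 0.2, 0, 3000)
  dz <- implied_table(0.2, 0.2, 0, 3000)
  fit <- twin_ace(mz, dz)
  expect_lt(fit$a2, 0.01)
  expect_lt(fit$c2, 0.01)
  expect_gt(fit$e2, 0.98)
})

test_that("expected tables from published summary rows recover printed components", {
  # asthma: ACE with both A and C identified
  fit <- fit_from_summary(K = 0.134, r_mz = 0.83, r_dz = 0.49)
  expect_equal(fit$a2, 0.68, tolerance = 0.01)
  expect_equal(fit$c2, 0.15, tolerance = 0.01)
  expect_false(fit$boundary_c)
  # epilepsy: ACE hits the c2 = 0 boundary, AE refit reported
  fit2 <- fit_from_summary(K = 0.012, r_mz = 0.62, r_dz = 0.25)
  expect_true(fit2$boundary_c)
  expect_equal(fit2$c2, 0)
  expect_equal(fit2$a2, 0.61, tolerance = 0.03)
})

test_that("likelihood fit agrees with the Falconer oracle on consistent tables", {
  for (par in list(c(0.6, 0.1), c(0.3, 0.3), c(0.8, 0), c(0.2, 0.4))) {
    for (K in c(0.05, 0.13)) {
      r_mz <- par[1] + par[2]; r_dz <- par[1] / 2 + par[2]
      fit <- fit_from_summary(K, r_mz, r_dz, n_mz = 4767, n_dz = 5580)
      oracle <- falconer(r_mz, r_dz)
      expect_equal(fit$a2, unname(oracle["a2"]), tolerance = 0.02)
      expect_equal(fit$c2, unname(oracle["c2"]), tolerance = 0.02)
    }
  }
})

test_that("deviance is monotone across nested models", {
  spec <- cohort_spec(3000, 3000, traits = list(trait_spec("x", 0.5, 0.2,
                                                           0.15)),
                      seed = 51)
  co <- simulate_cohort(spec)
  ace <- twin_ace(co, trait = "x", model = "ACE")
  ae <- twin_ace(co, trait = "x", model = "AE")
  e <- twin_ace(co, trait = "x", model = "E")
  expect_lte(ace$minus2LL, ae$minus2LL + 1e-6)
  expect_lte(ae$minus2LL, e$minus2LL + 1e-6)
  lrt <- compare_models(ace, e)
  expect_equal(lrt$df, 2)
  expect_gte(lrt$statistic, 0)
})

test_that("model comparison handles identical fits and flags inversions", {
  mz <- implied_table(0.134, 0.134, 0.83, 4767)
  dz <- implied_table(0.134, 0.134, 0.49, 5580)
  ace <- twin_ace(mz, dz, model = "ACE")
  ace2 <- ace; ace2$df <- 2L  # same -2LL, fewer parameters
  lrt <- compare_models(ace, ace2)
  expect_equal(lrt$statistic, 0, tolerance = 1e-8)
  expect_equal(lrt$p_value, 1, tolerance = 1e-6)
  ae <- twin_ace(mz, dz, model = "AE")
  expect_error(compare_models(ae, ace), "optimizer failure|same number")
})

test_that("strong additive variance is detected with high power", {
  # AE-vs-E likelihood-ratio test at a2 = 0.6, 5000 pairs per zygosity
  rejections <- 0L
  for (s in 1:10) {
    spec <- cohort_spec(5000, 5000, traits = list(trait_spec("x", 0.6, 0,
                                                             0.1)),
                        seed = 500 + s)
    co <- simulate_cohort(spec)
    ae <- twin_ace(co, trait = "x", model = "AE")
    e <- twin_ace(co, trait = "x", model = "E")
    if (compare_models(ae, e)$p_value < 0.05) rejections <- rejections + 1L
  }
  expect_gte(rejections, 9L)
})

test_that("profile intervals bracket the estimate and cover the truth", {
  fit <- fit_from_summary(K = 0.134, r_mz = 0.83, r_dz = 0.49,
                          ci = "profile")
  expect_lt(fit$ci["a2", "lower"], fit$a2)
  expect_gt(fit$ci["a2", "upper"], fit$a2)
  expect_lt(fit$ci["c2", "lower"], fit$c2)
  expect_true(all(fit$ci >= 0 & fit$ci <= 1))
  # reduced-replicate coverage check at nominal 95%
  hits <- 0L
  for (s in 1:25) {
    spec <- cohort_spec(5000, 5000,
                        traits = list(trait_spec("x", 0.6, 0.2, 0.1)),
                        seed = 600 + s)
    co <- simulate_cohort(spec)
    fit <- twin_ace(co, trait = "x")
    ci <- confint(fit, parm = "a2")
    if (ci[1] <= 0.6 && 0.6 <= ci[2]) hits <- hits + 1L
  }
  expect_gte(hits, 20L)  # binomial 0.005 quantile at p = 0.95, n = 25
})

test_that("fitted probabilities, residuals and simulation are coherent", {
  mz <- implied_table(0.134, 0.134, 0.83, 4767)
  dz <- implied_table(0.134, 0.134, 0.49, 5580)
  fit <- twin_ace(mz, dz)
  f <- fitted(fit)
  expect_equal(sum(f$MZ), 1, tolerance = 1e-8)
  expect_equal(sum(f$DZ), 1, tolerance = 1e-8)
  # residuals on the generating tables are essentially zero
  expect_lt(max(abs(unlist(residuals(fit)))), 0.05)
  co <- simulate(fit, seed = 1, n_mz = 800, n_dz = 700)
  expect_equal(nrow(co), 2 * 1500)
  expect_true("trait" %in% names(co))
  expect_equal(coef(fit), c(a2 = fit$a2, c2 = fit$c2, e2 = fit$e2))
  expect_equal(AIC(fit), fit$AIC, tolerance = 1e-9)
})

test_that("degenerate tables raise errors naming the problem", {
  empty <- matrix(c(100, 0, 0, 0), 2)
  expect_error(twin_ace(empty, implied_table(0.1, 0.1, 0.3, 100)),
               "degenerate")
  expect_error(twin_ace(matrix(c(-1, 2, 2, 2), 2),
                        implied_table(0.1, 0.1, 0.3, 100)), "negative")
})
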