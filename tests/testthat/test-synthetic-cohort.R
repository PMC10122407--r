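make_spec <- function(a2, c2, K, n = 5000, seed = 1, name = "x") {
  cohort_spec(n_mz = n, n_dz = n, traits = list(trait_spec(name, a2, c2, K)),
              seed = seed)
}

test_that("cohorts are bit-identical for equal seeds and differ otherwise", {
  s <- make_spec(0.6, 0.1, 0.1, n = 500)
  a <- simulate_cohort(s, seed = 7)
  b <- simulate_cohort(s, seed = 7)
  c <- simulate_cohort(s, seed = 8)
  expect_identical(a, b)
  expect_false(identical(a$x, c$x))
  # simulating does not disturb the caller's RNG stream
  set.seed(123); before <- rnorm(1)
  set.seed(123); invisible(simulate_cohort(s, seed = 9)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("empirical prevalence converges to the configured K", {
  co <- simulate_cohort(make_spec(0.68, 0.15, 0.134, n = 50000, seed = 3))
  p <- mean(co$x)
  n <- nrow(co)
  expect_lt(abs(p - 0.134), 4 * sqrt(0.134 * 0.866 / n) + 0.002)
  # constipation-like rare trait
  co <- simulate_cohort(make_spec(0.51, 0, 0.062, n = 50000, seed = 4))
  expect_lt(abs(mean(co$x) - 0.062), 0.004)
})

test_that("no familial variance gives null cross-twin correlations", {
  co <- simulate_cohort(make_spec(0, 0, 0.2, n = 20000, seed = 5))
  for (z in c("MZ", "DZ")) {
    est <- cross_twin_correlation(co, "x", zygosity = z)
    expect_lt(abs(est$r), 3 * est$se + 1e-3)
  }
})

test_that("additive-only traits show rMZ close to twice rDZ", {
  co <- simulate_cohort(make_spec(0.6, 0, 0.134, n = 50000, seed = 6))
  r_mz <- cross_twin_correlation(co, "x", zygosity = "MZ")
  r_dz <- cross_twin_correlation(co, "x", zygosity = "DZ")
  expect_equal(r_mz$r, 0.6, tolerance = 0.05)
  expect_equal(r_mz$r / r_dz$r, 2, tolerance = 0.2)
})

test_that("asthma-like generating values reproduce the published correlations", {
  co <- simulate_cohort(make_spec(0.68, 0.15, 0.134, n = 50000, seed = 9))
  expect_equal(cross_twin_correlation(co, "x", zygosity = "MZ")$r, 0.83,
               tolerance = 0.02)
  expect_equal(cross_twin_correlation(co, "x", zygosity = "DZ")$r, 0.49,
               tolerance = 0.03)
})

test_that("cross-trait structure matches the explicit matrix-assembly oracle", {
  # two traits, a-paths 0.8, ra = 0.5, no C: MZ CTCT 0.32, DZ CTCT 0.16
  spec <- cohort_spec(50000, 50000,
    traits = list(trait_spec("u", 0.64, 0, 0.2),
                  trait_spec("v", 0.64, 0, 0.2)),
    cross = list("u:v" = cross_trait_spec(ra = 0.5)), seed = 10)
  R_or <- oracle_biv_corr(0.8, 0, 0.8, 0, 0.5, 0, 0, g = 1)
  expect_equal(R_or[1, 4], 0.32, tolerance = 1e-12)
  expect_equal(oracle_biv_corr(0.8, 0, 0.8, 0, 0.5, 0, 0, g = 0.5)[1, 4],
               0.16, tolerance = 1e-12)
  # the generator's internal assembly agrees with the oracle
  comp <- twinliab:::.component_corrs(spec$traits, spec$cross)
  for (g in c("MZ", "DZ"))
    expect_equal(twinliab:::.pair_corr(spec$traits, comp, g),
                 oracle_biv_corr(0.8, 0, 0.8, 0, 0.5, 0, 0,
                                 g = if (g == "MZ") 1 else 0.5),
                 tolerance = 1e-12)
  # and the sampled cohort reproduces the implied CTCT pattern
  co <- simulate_cohort(spec)
  ct_mz <- cross_twin_correlation(co, "u", "v", "MZ")
  ct_dz <- cross_twin_correlation(co, "u", "v", "DZ")
  expect_equal(ct_mz$r, 0.32, tolerance = 0.03)
  expect_equal(ct_dz$r, 0.16, tolerance = 0.03)
  expect_gt(ct_mz$r, ct_dz$r)
})

test_that("invalid cross-trait structure is rejected before sampling", {
  expect_error(cohort_spec(100, 100,
    traits = list(trait_spec("a", 1, 0, 0.1), trait_spec("b", 1, 0, 0.1),
                  trait_spec("c", 1, 0, 0.1)),
    cross = list("a:b" = cross_trait_spec(ra = 0.9),
                 "a:c" = cross_trait_spec(ra = -0.9),
                 "b:c" = cross_trait_spec(ra = 0.9))),
    "positive semi-definite")
  expect_error(trait_spec("x", 0.8, 0.4, 0.1), "sum to 1")
  expect_error(cross_trait_spec(ra = 1.2), "\\[-1, 1\\]")
})

test_that("demographics follow the configured design", {
  spec <- cohort_spec(2000, 3000, traits = list(trait_spec("x", 0.5, 0, 0.1)),
                      n_dzos = 500, seed = 11)
  co <- simulate_cohort(spec)
  expect_equal(nrow(co), 2 * 5500)
  tw1 <- co[co$twin_index == 1, ]
  expect_equal(as.vector(table(tw1$zygosity)[c("MZ", "DZ", "DZOS")]),
               c(2000L, 3000L, 500L))
  # same-sex design: co-twins share sex except in the DZOS block
  w <- merge(co[co$twin_index == 1, c("pair_id", "sex", "zygosity")],
             co[co$twin_index == 2, c("pair_id", "sex")], by = "pair_id")
  expect_true(all(w$sex.x == w$sex.y | w$zygosity == "DZOS"))
  expect_true(all(w$sex.x != w$sex.y | w$zygosity != "DZOS"))
  # age mix close to the 9:12 reference proportions
  expect_equal(mean(tw1$age == 9), 8125 / 10347, tolerance = 0.03)
})

test_that("cohort CSV round trips through write/read", {
  co <- simulate_cohort(make_spec(0.5, 0, 0.1, n = 50))
  path <- tempfile(fileext = ".csv")
  write_cohort(co, path)
  back <- read_cohort(path)
  expect_equal(back$x, co$x)
  expect_equal(back$pair_id, co$pair_id)
  unlink(path)
})
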