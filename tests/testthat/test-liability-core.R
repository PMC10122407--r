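test_that("liability thresholds match a bisection oracle and reject bad input", {
  expect_equal(threshold_from_prevalence(0.5)$t, 0)
  for (K in c(0.134, 0.012, 0.062, 0.004, 0.9)) {
    th <- threshold_from_prevalence(K)
    expect_equal(th$t, bisect_threshold(K), tolerance = 1e-10)
    # round trip: upper-tail area beyond t equals K
    expect_equal(pnorm(th$t, lower.tail = FALSE), K, tolerance = 1e-12)
  }
  # the published asthma and epilepsy prevalences pin known cut-points
  expect_equal(threshold_from_prevalence(0.134)$t, 1.107, tolerance = 1e-3)
  expect_equal(threshold_from_prevalence(0.012)$t, 2.257, tolerance = 1e-3)
  expect_error(threshold_from_prevalence(0), "\\(0, 1\\)")
  expect_error(threshold_from_prevalence(1.2), "1.2")
})

test_that("2-D rectangles factorize under independence and collapse at r = 1", {
  for (t1 in c(-1, 0.5, 2)) for (t2 in c(-0.3, 1.1)) {
    expect_equal(mvn_rectangle(c(t1, t2), diag(2)),
                 pnorm(t1, lower.tail = FALSE) * pnorm(t2, lower.tail = FALSE),
                 tolerance = 1e-12)
  }
  r1 <- matrix(c(1, 1, 1, 1), 2)
  expect_equal(mvn_rectangle(c(1.3, 1.3), r1),
               pnorm(1.3, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(mvn_rectangle(c(0.4, 0.4), r1),
               pnorm(0.4, lower.tail = FALSE), tolerance = 1e-12)
})

test_that("2-D rectangles agree with the adaptive-quadrature oracle", {
  set.seed(11)
  for (i in 1:25) {
    r <- runif(1, -0.95, 0.95)
    t1 <- runif(1, -2.5, 2.5); t2 <- runif(1, -2.5, 2.5)
    expect_lt(abs(mvn_rectangle(c(t1, t2), matrix(c(1, r, r, 1), 2)) -
                    quad_up2(t1, t2, r)), 1e-8)
  }
})

test_that("quadrant probabilities sum to one and grow with r", {
  for (r in c(-0.8, 0, 0.62, 0.95)) {
    R <- matrix(c(1, r, r, 1), 2)
    t1 <- 1.1; t2 <- -0.4
    q <- mvn_rectangle(c(t1, t2), R) +
      mvn_rectangle(c(t1, -Inf), R, upper = c(Inf, t2)) +
      mvn_rectangle(c(-Inf, t2), R, upper = c(t1, Inf)) +
      mvn_rectangle(c(-Inf, -Inf), R, upper = c(t1, t2))
    expect_equal(q, 1, tolerance = 1e-10)
  }
  rs <- seq(-0.95, 0.95, by = 0.1)
  p <- vapply(rs, function(r)
    mvn_rectangle(c(1, 1), matrix(c(1, r, r, 1), 2)), 0)
  expect_true(all(diff(p) >= -1e-12))
})

test_that("3-4D rectangles match closed-form reductions", {
  # block-diagonal correlation factorizes into two 2-D problems
  R <- diag(4)
  R[1, 2] <- R[2, 1] <- 0.7
  R[3, 4] <- R[4, 3] <- -0.3
  t <- c(0.5, 1.2, -0.4, 0.9)
  expect_equal(mvn_rectangle(t, R),
               mvn_rectangle(t[1:2], R[1:2, 1:2]) *
                 mvn_rectangle(t[3:4], R[3:4, 3:4]),
               tolerance = 1e-6)
  # exchangeable correlation reduces to a one-factor integral
  for (d in 3:4) for (rho in c(0.3, 0.6)) {
    Re <- matrix(rho, d, d); diag(Re) <- 1
    expect_equal(mvn_rectangle(rep(0.8, d), Re), exch_orthant(0.8, rho, d),
                 tolerance = 1e-6)
  }
})

test_that("non-PSD correlation matrices are rejected with the eigenvalue", {
  R <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0.9, -0.9, 0.9, 1), 3)
  expect_error(mvn_rectangle(c(0, 0, 0), R), "eigenvalue")
})

test_that("implied tables reproduce closed forms and the quadrature oracle", {
  expect_equal(unname(implied_table(0.5, 0.5, 0, 100)),
               matrix(25, 2, 2), tolerance = 1e-9, ignore_attr = TRUE)
  tab <- implied_table(0.1, 0.1, 1, 500)
  expect_equal(tab[2, 2], 50, tolerance = 1e-9)
  expect_equal(tab[1, 2] + tab[2, 1], 0, tolerance = 1e-9)
  # asthma-like MZ row: cells against the independent quadrature oracle
  tab <- implied_table(0.134, 0.134, 0.83, 4767)
  p11 <- quad_up2(qnorm(0.866), qnorm(0.866), 0.83)
  expect_equal(tab[2, 2], 4767 * p11, tolerance = 1e-6)
  expect_equal(sum(tab), 4767, tolerance = 1e-9)
})

test_that("tetrachoric ML recovers r from implied tables (round trip)", {
  for (r in c(-0.9, -0.4, 0, 0.3, 0.62, 0.95)) {
    for (K in c(0.012, 0.05, 0.134, 0.5)) {
      tab <- implied_table(K, K, r, 4767)
      # a cell whose expected count underflows to zero erases the
      # information that identifies r: the MLE is then a boundary point
      if (min(tab) < 1e-9) next
      est <- tetrachoric(tab)
      expect_lt(abs(est$r - r), 1e-4)
      expect_lt(abs(pnorm(est$t_row, lower.tail = FALSE) - K), 1e-4)
    }
  }
  # asymmetric margins round trip too
  est <- tetrachoric(implied_table(0.02, 0.3, 0.45, 10000))
  expect_lt(abs(est$r - 0.45), 1e-4)
})

test_that("tetrachoric flags independence, boundaries and degeneracy", {
  est <- tetrachoric(matrix(c(25, 25, 25, 25), 2))
  expect_lt(abs(est$r), 1e-6)
  est <- tetrachoric(matrix(c(40, 0, 0, 10), 2))
  expect_true(est$at_boundary)
  expect_gt(est$r, 1 - 1e-5)
  est <- tetrachoric(matrix(c(50, 10, 0, 0), 2))
  expect_true(est$degenerate)
  expect_true(is.na(est$r))
})

test_that("tetrachoric standard errors shrink like 1/sqrt(N)", {
  se1 <- tetrachoric(implied_table(0.134, 0.134, 0.5, 2000))$se
  se2 <- tetrachoric(implied_table(0.134, 0.134, 0.5, 4000))$se
  expect_gt(se2 / se1, 0.65)
  expect_lt(se2 / se1, 0.75)
})
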