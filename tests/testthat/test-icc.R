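test_that("worked example: perfect correlation but consistency 0.60", {
  m <- worked_matrix()
  est <- icc(m, "icc_3")
  expect_equal(est$estimate, 0.6)
  expect_equal(pearson_r(m[, 1], m[, 2]), 1.0)
})

test_that("identical occasions give ICC(3,1) = 1 with degenerate-free CI", {
  a <- c(1, 3, 6, 9, 12)
  est <- icc(cbind(a, a), "icc_3")
  expect_equal(est$estimate, 1.0)
  expect_equal(est$lower, 1.0)
  expect_equal(est$upper, 1.0)
  expect_true(est$perfect)
})

test_that("icc_2 and icc_1 estimates follow the Shrout-Fleiss forms", {
  m <- worked_matrix()
  # plug mean squares (157.6, 384.4, 39.4; MSW 108.4) into the formulas
  expect_equal(icc(m, "icc_2")$estimate,
               118.2 / (157.6 + 39.4 + 2 * (384.4 - 39.4) / 5))
  expect_equal(icc(m, "icc_1")$estimate, (157.6 - 108.4) / (157.6 + 108.4))
})

test_that("variance components compose the icc_3 estimate", {
  for (seed in 1:10) {
    m <- random_matrix(sample(4:20, 1), sample(2:4, 1), seed = 200 + seed)
    est <- icc(m, "icc_3")
    s2 <- est$components
    k <- ncol(m)
    # sigma_r^2 / (sigma_r^2 + sigma_v^2) only equals the MS form for k = 2;
    # the general identity is (MSBS - MSE)/(MSBS + (k-1) MSE)
    with_ms <- (est$anova$ms_between_subject - est$anova$ms_error) /
      (est$anova$ms_between_subject + (k - 1) * est$anova$ms_error)
    expect_equal(est$estimate, with_ms, tolerance = 1e-12)
    if (k == 2) {
      expect_equal(est$estimate, s2$sigma2_between /
                     (s2$sigma2_between + s2$sigma2_within),
                   tolerance = 1e-12)
    }
    expect_equal(s2$sigma2_within, est$anova$ms_error)
    expect_equal(s2$sigma2_between,
                 (est$anova$ms_between_subject - est$anova$ms_error) / k)
  }
})

test_that("icc_3 ignores additive occasion bias while icc_2 is penalised", {
  # matrices carry real subject signal: the shift-penalty direction is only
  # guaranteed for positive reliabilities (a bias shrinks negative ICCs
  # toward zero instead)
  for (seed in 1:8) {
    m <- random_icc_matrix(10, 3, seed = 300 + seed)
    shift <- m
    shift[, 2] <- shift[, 2] + 5  # constant added to one occasion
    expect_equal(icc(shift, "icc_3")$estimate, icc(m, "icc_3")$estimate,
                 tolerance = 1e-9)
    expect_lt(icc(shift, "icc_2")$estimate, icc(m, "icc_2")$estimate)
  }
})

test_that("negative estimates are not truncated", {
  # anti-correlated occasions: between-subject MS below residual MS
  m <- cbind(c(1, 2, 3, 4), c(4, 3, 2, 1.5))
  est <- icc(m, "icc_3")
  expect_lt(est$estimate, 0)
  expect_gte(est$estimate, -1)
})

test_that("zero-variance input yields a flagged NA, not a crash", {
  est <- icc(matrix(5, 6, 2), "icc_3")
  expect_true(est$degenerate)
  expect_true(is.na(est$estimate))
  expect_true(is.na(est$lower))
})

test_that("F-based bounds match an independent quantile oracle (icc_3/icc_1)", {
  m <- worked_matrix()
  tw <- decompose_twoway(m)
  ci <- icc_confidence_interval(tw, "icc_3", alpha = 0.05)
  # oracle: F = 157.6/39.4 = 4.0 on (4, 4) df, transformed to the ICC scale
  fobs <- 157.6 / 39.4
  fl <- fobs / qf(0.975, 4, 4)
  fu <- fobs * qf(0.975, 4, 4)
  expect_equal(fobs, 4.0)
  expect_equal(unname(ci), c((fl - 1) / (fl + 1), (fu - 1) / (fu + 1)))

  ow <- decompose_oneway(m)
  ci1 <- icc_confidence_interval(ow, "icc_1", alpha = 0.05)
  f1 <- ow$ms_between_subject / ow$ms_within
  fl1 <- f1 / qf(0.975, 4, 5)
  fu1 <- f1 * qf(0.975, 5, 4)
  expect_equal(unname(ci1), c((fl1 - 1) / (fl1 + 1), (fu1 - 1) / (fu1 + 1)))
})

test_that("icc_2 bounds reproduce the McGraw-Wong Satterthwaite interval", {
  # frozen from the agreement-ICC interval of the worked example, computed
  # independently with the published formula (Satterthwaite df v = 4.0479
  # for these mean squares)
  est <- icc(worked_matrix(), "icc_2")
  expect_equal(est$lower, -0.1557, tolerance = 1e-3)
  expect_equal(est$upper, 0.8763, tolerance = 1e-3)
})

test_that("bounds bracket the estimate and collapse as alpha -> 1", {
  for (seed in 1:8) {
    m <- random_matrix(10, 2, seed = 400 + seed)
    for (ty in c("icc_1", "icc_2", "icc_3")) {
      est <- icc(m, ty)
      expect_lte(est$lower, est$estimate)
      expect_gte(est$upper, est$estimate)
      wide <- icc(m, ty, alpha = 0.9999)
      expect_lt(wide$upper - wide$lower, 0.05)
      expect_lt(abs(wide$upper - est$estimate), 0.05)
    }
  }
})
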