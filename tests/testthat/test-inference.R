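test_that("inverse normal combination behaves as a weighted z combination", {
  w <- combination_weights(100, 300)
  expect_equal(w$w1, 0.5)
  expect_equal(w$w2, sqrt(0.75))
  # median inputs give z = 0, p = 0.5 for any valid weights
  out <- inverse_normal_combine(0.5, 0.5, w)
  expect_equal(out$z, 0)
  expect_equal(out$p, 0.5)
  # equal weights, both stages at 0.025
  weq <- combination_weights(weight = 0.5)
  out <- inverse_normal_combine(0.025, 0.025, weq)
  expect_equal(out$z, sqrt(2) * qnorm(0.975), tolerance = 1e-10)
  expect_equal(out$p, 0.00279, tolerance = 1e-2)
  # decreasing in each p
  expect_gt(inverse_normal_combine(0.01, 0.5, w)$z,
            inverse_normal_combine(0.02, 0.5, w)$z)
  # degenerate p in {0, 1} stays finite (quantile capping)
  expect_true(is.finite(inverse_normal_combine(0, 1, w)$z))
  expect_error(inverse_normal_combine(1.5, 0.5, w), "\\[0, 1\\]")
})

test_that("fisher combination uses the chi-squared(4) critical product", {
  # two independent oracles: the chi-squared quantile and the root of
  # c (1 - log c) = alpha
  for (alpha in c(0.025, 0.05)) {
    crit <- fisher_combine(0.5, 0.5, alpha)$critical
    expect_equal(crit, exp(-qchisq(1 - alpha, 4) / 2), tolerance = 1e-12)
    root <- uniroot(function(c) c * (1 - log(c)) - alpha,
                    c(1e-10, 0.5), tol = 1e-12)$root
    expect_equal(crit, root, tolerance = 1e-8)
  }
  expect_equal(fisher_combine(0.5, 0.5, 0.025)$critical, 0.00380,
               tolerance = 1e-2)
  expect_true(fisher_combine(0, 0.9, 0.025)$reject)
  expect_error(fisher_combine(0.5, 0.5, 0), "alpha")
})

test_that("Dunnett p-values agree with the multivariate normal oracle", {
  skip_if_not_installed("mvtnorm")
  expect_equal(dunnett_pvalue(qnorm(0.975)), 0.025, tolerance = 1e-10)
  # frozen from the mvtnorm Miwa oracle: 1 - Phi_2(1.95996, 1.95996; 0.5)
  expect_equal(dunnett_pvalue(c(qnorm(0.975), 0), lambda = 1), 0.045378,
               tolerance = 1e-4)
  # oracle agreement to 1e-5 across dimensions and z values
  for (m in 1:4)
    for (z in c(-1, 0, 1, 1.95996, 3))
      expect_equal(dunnett_pvalue(c(rep(-5, m - 1), z)),
                   oracle_dunnett(z, m), tolerance = 1e-5)
  # increasing in the number of comparisons at fixed maximum
  p <- vapply(1:5, function(m) dunnett_pvalue(rep(2, m)), numeric(1))
  expect_true(all(diff(p) > 0))
  expect_equal(dunnett_pvalue(rep(50, 4)), 0, tolerance = 1e-10)
  expect_error(dunnett_pvalue(numeric(0)), "at least one")
})

test_that("Simes and Bonferroni intersection p-values follow their formulas", {
  expect_equal(simes_pvalue(c(0.01, 0.04)), 0.02)
  expect_equal(simes_pvalue(c(0.03, 0.04)), 0.04)
  expect_equal(simes_pvalue(0.2), 0.2)
  expect_equal(bonferroni_pvalue(c(0.01, 0.04)), 0.02)
  expect_equal(bonferroni_pvalue(0.2), 0.2)
  expect_equal(bonferroni_pvalue(c(0.6, 0.7)), 1)
  # Simes is never larger than Bonferroni
  set.seed(1)
  for (i in 1:50) {
    p <- runif(sample(1:5, 1))
    expect_lte(simes_pvalue(p), bonferroni_pvalue(p))
  }
})

test_that("Spiessens-Debois p-values match the bivariate normal oracle", {
  skip_if_not_installed("mvtnorm")
  z <- qnorm(0.975)
  expect_equal(spiessens_debois_pvalue(z, 0, info_ratio = 1), 0.025,
               tolerance = 1e-10)
  expect_equal(spiessens_debois_pvalue(z, z, info_ratio = 1e-12),
               1 - pnorm(z)^2, tolerance = 1e-4)
  for (ratio in c(0.1, 0.3, 0.7))
    for (zz in c(0.5, 1.96, 2.8))
      expect_equal(spiessens_debois_pvalue(zz, zz - 0.3, ratio),
                   oracle_sd(zz, zz - 0.3, ratio), tolerance = 1e-5)
  expect_error(spiessens_debois_pvalue(1, 1, 1.5), "info_ratio")
})

test_that("the closed test reproduces a hand-computed two-arm example", {
  skip_if_not_installed("mvtnorm")
  # two arms, arm 1 selected, equal weights, alpha 0.025
  z1 <- c(2.5, 1.0)
  z2 <- c(2.5, NA)
  w <- combination_weights(weight = 0.5)
  res <- closed_test(z1, z2, selected = 1, method = "invnorm", weights = w)
  # hand computation with the MVN oracle
  p1_12 <- oracle_dunnett(2.5, 2)
  p1_1 <- 1 - pnorm(2.5)
  p2 <- 1 - pnorm(2.5)   # stage-2 set {1,2} n selected = {1}
  z_12 <- sqrt(0.5) * (qnorm(1 - p1_12) + qnorm(1 - p2))
  z_1 <- sqrt(0.5) * (qnorm(1 - p1_1) + qnorm(1 - p2))
  expect_equal(res$intersections$p1[res$intersections$subset == "1,2"], p1_12,
               tolerance = 1e-6)
  expect_equal(res$intersections$statistic[res$intersections$subset == "1"],
               z_1, tolerance = 1e-6)
  expect_identical(res$elementary[1],
                   unname(min(z_12, z_1) >= qnorm(0.975)))
  # the dropped arm can never be rejected
  expect_false(res$elementary[2])
})

test_that("closed-test coherence holds on exhaustive enumeration", {
  w <- combination_weights(weight = 0.4)
  set.seed(42)
  for (K in 2:4) {
    for (rep in 1:25) {
      z1 <- rnorm(K, mean = 1)
      sel <- which(runif(K) < 0.6)
      z2 <- ifelse(seq_len(K) %in% sel, rnorm(K, mean = 1.5), NA)
      res <- closed_test(z1, z2, sel, weights = w)
      subs <- strsplit(res$intersections$subset, ",")
      rej <- res$intersections$reject
      # subset monotonicity: if K' contains a rejected elementary k, K' rejected
      for (k in which(res$elementary)) {
        containing <- vapply(subs, function(s) as.character(k) %in% s, logical(1))
        expect_true(all(rej[containing]))
        expect_true(k %in% sel)
      }
      expect_true(all(res$intersections$p1 >= 0 & res$intersections$p1 <= 1))
      expect_true(all(res$intersections$p2 >= 0 & res$intersections$p2 <= 1))
    }
  }
  # futility: nothing rejected
  res <- closed_test(c(3, 3), c(NA, NA), integer(0), weights = w)
  expect_false(any(res$elementary))
  # all-zero p-values: every selected hypothesis rejected
  res <- closed_test(c(50, 50), c(50, 50), 1:2, weights = w)
  expect_true(all(res$elementary))
})

test_that("inverse-normal and Fisher agree in the single-stage degenerate case", {
  # with w1 = 1, stage 2 carries no weight: the decision is the stage-1 test
  w <- combination_weights(weight = 1 - 1e-12)
  alpha <- 0.025
  for (p1 in c(0.01, 0.024, 0.026, 0.2)) {
    inv <- inverse_normal_combine(p1, 0.5, w)$p <= alpha + 1e-9
    expect_identical(inv, p1 <= alpha)
  }
})
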