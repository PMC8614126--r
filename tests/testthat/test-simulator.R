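test_that("treatment-selection summaries keep consistent books", {
  d <- copd_design(seed = 11)
  s <- simulate_treatsel(d, nsim = 2000)
  expect_identical(sum(s$count_total) + s$futility, 2000L)
  expect_true(all(s$select_total <= 2000))
  # an arm can only be rejected when it was selected
  expect_true(all(s$reject_total <= s$select_total))
  # combined ptest rejections dominate each member, bounded by their sum
  expect_gte(s$sim_reject, max(s$reject_total[c(3, 4)]))
  expect_lte(s$sim_reject, sum(s$reject_total[c(3, 4)]))
  # best-2 always continues with exactly two arms
  expect_identical(s$count_total, c(0L, 2000L, 0L, 0L))
  expect_identical(s$futility, 0L)
})

test_that("simulations are reproducible given a seed", {
  d <- copd_design(seed = 21)
  a <- simulate_treatsel(d, nsim = 500)
  b <- simulate_treatsel(d, nsim = 500)
  expect_identical(a$reject_total, b$reject_total)
  expect_identical(a$select_total, b$select_total)
  ds <- oncology_design(seed = 22)
  a <- simulate_subpop(ds, nsim = 500)
  b <- simulate_subpop(ds, nsim = 500)
  expect_identical(a$table, b$table)
})

test_that("expected sample size has the stated closed forms", {
  base <- list(n = list(stage1 = 40, stage2 = 400),
               effect = list(early = c(0, 0.68, 0.82, 0.95, 0.91),
                             final = c(0, 0.13, 0.17, 0.23, 0.20)),
               corr = 0.4, seed = 3)
  d_all <- do.call(treatsel_design, c(base, list(select = 0)))
  s <- simulate_treatsel(d_all, nsim = 200)
  expect_equal(expected_sample_size(s), 5 * 40 + 5 * 400)
  d_one <- do.call(treatsel_design, c(base, list(select = 1)))
  s <- simulate_treatsel(d_one, nsim = 200)
  expect_equal(expected_sample_size(s), 5 * 40 + 2 * 400)
  # futility stops contribute stage-1 patients only
  d_none <- do.call(treatsel_design, c(base, list(select = 6, thresh = 50)))
  s <- simulate_treatsel(d_none, nsim = 200)
  expect_equal(expected_sample_size(s), 5 * 40)
  expect_identical(s$futility, 200L)
  expect_identical(s$sim_reject, 0L)
})

test_that("power is monotone in the final effect size and the stage-2 size", {
  rejections <- vapply(c(0.6, 1, 1.4), function(scale) {
    d <- treatsel_design(n = list(stage1 = 100, stage2 = 300),
                         effect = list(early = c(0, 0.68, 0.82, 0.95, 0.91),
                                       final = scale * c(0, 0.13, 0.17, 0.23, 0.20)),
                         corr = 0.4, select = 2, ptest = c(3, 4), seed = 77)
    simulate_treatsel(d, nsim = 4000)$sim_reject
  }, numeric(1))
  expect_true(all(diff(rejections) > 0))
  rejections_n2 <- vapply(c(100, 300, 600), function(n2) {
    d <- treatsel_design(n = list(stage1 = 100, stage2 = n2),
                         effect = list(early = c(0, 0.68, 0.82, 0.95, 0.91),
                                       final = c(0, 0.13, 0.17, 0.23, 0.20)),
                         corr = 0.4, select = 2, ptest = c(3, 4), seed = 78)
    simulate_treatsel(d, nsim = 4000)$sim_reject
  }, numeric(1))
  expect_true(all(diff(rejections_n2) > 0))
})

test_that("perfectly correlated equal outcomes make early selection equal final selection", {
  eff <- effect_spec(early = c(0.3, 0.5, 0.2), final = c(0.3, 0.5, 0.2),
                     corr = 1 - 1e-9)
  mod <- build_model_treatsel(eff, sample_size_plan(80, 80))
  set.seed(12)
  d <- draw_statistics(mod, 5000)
  E <- d[, 1:3]
  F1 <- d[, 4:6]
  expect_equal(E, F1, tolerance = 1e-3, ignore_attr = TRUE)
  rule <- selection_rule("best1")
  set.seed(1)
  sel_e <- apply(E, 1, function(z) select_treatments(z, rule))
  set.seed(1)
  sel_f <- apply(F1, 1, function(z) select_treatments(z, rule))
  expect_identical(sel_e, sel_f)
})

test_that("subgroup summaries keep consistent books", {
  d <- oncology_design(seed = 14)
  s <- simulate_subpop(d, nsim = 4000)
  expect_identical(sum(s$table[, "n"]) + s$futility, 4000)
  # the subgroup-only branch can never reject the full-population null
  expect_identical(s$table["sub", "Hf"], 0)
  expect_identical(s$table["full", "Hs"], 0)
  # union bounds and closed-test coherence of the accumulated counts
  expect_gte(s$sim_reject, max(s$reject_hs, s$reject_hf))
  expect_gte(s$reject_intersection, s$sim_reject)
  expect_identical(s$sim_reject, s$reject_hs + s$reject_hf - s$reject_both)
  # interim branch frequencies agree with the exact bivariate probabilities
  # (means -1.456/-0.583, information-ratio correlation 0.515)
  expect_equal(s$table["sub", "n"] / 4000, 0.231, tolerance = 0.1)
  expect_equal(s$futility / 4000, 0.049, tolerance = 0.35)
})

test_that("subgroup expected sample size follows the continuation branches", {
  d <- oncology_design(seed = 15)
  s <- simulate_subpop(d, nsim = 4000)
  tab <- s$table[, "n"]
  manual <- 2 * 100 +
    (2 * 200 * tab[["sub"]] + 2 * 300 * (tab[["full"]] + tab[["both"]])) / 4000
  expect_equal(expected_sample_size(s), manual)
})

test_that("wide threshold limits always keep both populations", {
  d <- subpop_design(n = list(stage1 = 50, stage2 = 100),
                     effect = list(early = c(0.3, 0.2), final = c(0.3, 0.2)),
                     sprev = 0.4, corr = 0.5, select = "thresh",
                     selim = c(-10, 10), method = "CT-Simes", seed = 8)
  s <- simulate_subpop(d, nsim = 1000)
  expect_identical(unname(s$table[, "n"]), c(0, 0, 1000))
  expect_identical(s$futility, 0)
  # selim = c(0, 0) keeps exactly one population
  d0 <- subpop_design(n = list(stage1 = 50, stage2 = 100),
                      effect = list(early = c(0.3, 0.2), final = c(0.3, 0.2)),
                      sprev = 0.4, corr = 0.5, select = "thresh",
                      selim = c(0, 0), method = "CT-Simes", seed = 8)
  s0 <- simulate_subpop(d0, nsim = 1000)
  expect_identical(unname(s0$table["both", "n"]), 0)
})

test_that("varying prevalence draws one binomial realization per trial", {
  d <- subpop_design(n = list(stage1 = 50, stage2 = 100),
                     effect = list(early = c(0.3, 0.1), final = c(0.3, 0.1)),
                     sprev = 0.3, sprev_fixed = FALSE, corr = 0.4,
                     select = "futility", selim = c(0, 0), seed = 9)
  s <- simulate_subpop(d, nsim = 1000)
  expect_identical(sum(s$table[, "n"]) + s$futility, 1000)
})

test_that("complete follow-up keeps stage-2 data for dropped arms", {
  d <- copd_design(seed = 33, fu = TRUE)
  s <- simulate_treatsel(d, nsim = 2000)
  expect_identical(sum(s$count_total), 2000L)
  # the dropped-arm data change the decisions relative to discontinued
  # follow-up (full-dimension intersection tests at stage 2)
  d0 <- copd_design(seed = 33, fu = FALSE)
  s0 <- simulate_treatsel(d0, nsim = 2000)
  expect_false(identical(s$reject_total, s0$reject_total))
  expect_gt(s$sim_reject, 0)
})

test_that("the Fisher combination driver runs and controls the null", {
  d <- treatsel_design(n = list(stage1 = 50, stage2 = 50),
                       effect = list(early = c(0, 0, 0), final = c(0, 0, 0)),
                       select = 1, method = "fisher", seed = 10)
  s <- simulate_treatsel(d, nsim = 20000)
  fwer <- s$sim_reject / 20000
  expect_lte(fwer, 0.025 + 3 * sqrt(0.025 * 0.975 / 20000))
})

test_that("invalid design combinations are rejected", {
  expect_error(treatsel_design(n = list(stage1 = 10, stage2 = 10),
                               effect = list(early = rep(0, 9), final = rep(0, 9))),
               "eight or more")
  expect_error(treatsel_design(n = list(stage1 = 10, stage2 = 10),
                               effect = list(early = c(0, 1), final = c(0, 1)),
                               ptest = 5), "ptest")
  expect_error(subpop_design(n = list(stage1 = 10, stage2 = 10),
                             effect = list(early = c(1, 2, 3), final = c(1, 2, 3)),
                             sprev = 0.5), "length-2")
  expect_error(subpop_design(n = list(stage1 = 10, stage2 = 10),
                             effect = list(early = c(0.3, 0.2), final = c(0.3, 0.2)),
                             sprev = 0.5, outcome = list(early = "B", final = "N")),
               "control")
})
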