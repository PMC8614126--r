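# Independent numerical oracles used across the test files.

# Equicorrelated one-sided Dunnett p-value via mvtnorm (deterministic Miwa
# quadrature), independent of the package's Gauss-Legendre reduction.
oracle_dunnett <- function(zmax, m, r = 0.5) {
  if (m == 1) return(1 - stats::pnorm(zmax))
  S <- matrix(r, m, m)
  diag(S) <- 1
  1 - mvtnorm::pmvnorm(upper = rep(zmax, m), sigma = S,
                       algorithm = mvtnorm::Miwa(steps = 512))[1]
}

# Bivariate-normal Spiessens-Debois p-value via mvtnorm.
oracle_sd <- function(z_s, z_f, info_ratio) {
  zmax <- max(z_s, z_f)
  r <- sqrt(info_ratio)
  S <- matrix(c(1, r, r, 1), 2)
  1 - mvtnorm::pmvnorm(upper = rep(zmax, 2), sigma = S,
                       algorithm = mvtnorm::Miwa(steps = 512))[1]
}

# Patient-level Monte Carlo oracle for the treatment-selection model: K arms
# plus a shared control, n1/n2 patients per arm and stage, unit-variance
# normal early and final outcomes with within-patient correlation rho.
# Returns the empirical covariance of (E_1..E_K, F1_1..F1_K, F2_1..F2_K).
patient_level_treatsel <- function(nrep, K, n1, n2, rho,
                                   theta_early = rep(0, K),
                                   theta_final = rep(0, K)) {
  arm_means <- function(n, shift_e, shift_f) {
    e <- matrix(stats::rnorm(nrep * n), nrep)
    f <- rho * e + sqrt(1 - rho^2) * matrix(stats::rnorm(nrep * n), nrep)
    cbind(rowMeans(e) + shift_e, rowMeans(f) + shift_f)
  }
  ctl1 <- arm_means(n1, 0, 0)
  ctl2 <- arm_means(n2, 0, 0)
  E <- F1 <- F2 <- matrix(NA_real_, nrep, K)
  for (k in seq_len(K)) {
    a1 <- arm_means(n1, theta_early[k], theta_final[k])
    a2 <- arm_means(n2, theta_early[k], theta_final[k])
    E[, k] <- sqrt(n1 / 2) * (a1[, 1] - ctl1[, 1])
    F1[, k] <- sqrt(n1 / 2) * (a1[, 2] - ctl1[, 2])
    F2[, k] <- sqrt(n2 / 2) * (a2[, 2] - ctl2[, 2])
  }
  stats::cov(cbind(E, F1, F2))
}

# Patient-level oracle for the subgroup model with normal outcomes: nested
# subgroup of n_s patients inside n_f per arm, two outcomes with correlation
# rho, null effects. Returns the empirical covariance of
# (E_S, E_F, F1_S, F1_F, F2_S, F2_F).
patient_level_subpop <- function(nrep, n_s1, n_f1, n_s2, n_f2, rho) {
  stage <- function(n_s, n_f) {
    outc <- function() {
      e <- matrix(stats::rnorm(nrep * n_f), nrep)
      f <- rho * e + sqrt(1 - rho^2) * matrix(stats::rnorm(nrep * n_f), nrep)
      list(e = e, f = f)
    }
    trt <- outc()
    ctl <- outc()
    sub_idx <- seq_len(n_s)
    zs <- function(y_t, y_c, n)
      sqrt(n / 2) * (rowMeans(y_t) - rowMeans(y_c))
    cbind(zs(trt$e[, sub_idx, drop = FALSE], ctl$e[, sub_idx, drop = FALSE], n_s),
          zs(trt$e, ctl$e, n_f),
          zs(trt$f[, sub_idx, drop = FALSE], ctl$f[, sub_idx, drop = FALSE], n_s),
          zs(trt$f, ctl$f, n_f))
  }
  s1 <- stage(n_s1, n_f1)
  s2 <- stage(n_s2, n_f2)
  stats::cov(cbind(s1, s2[, 3:4]))
}

# The worked multi-arm dose-selection example (normal early and final
# outcomes) used throughout the tests.
copd_design <- function(...) {
  treatsel_design(n = list(stage1 = 100, stage2 = 300),
                  effect = list(early = c(0, 0.68, 0.82, 0.95, 0.91),
                                final = c(0, 0.13, 0.17, 0.23, 0.20)),
                  outcome = list(early = "N", final = "N"),
                  corr = 0.4, select = 2, ptest = c(3, 4),
                  nsim = 10000, ...)
}

# The oncology enrichment example with time-to-event outcomes.
oncology_design <- function(...) {
  subpop_design(n = list(stage1 = 100, enrich = 200, stage2 = 300),
                effect = list(early = c(0.6, 0.9), final = c(0.6, 0.9)),
                sprev = 0.3, outcome = list(early = "T", final = "T"),
                corr = 0.5, select = "futility", selim = c(0, 0),
                method = "CT-SD", nsim = 10000, ...)
}
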