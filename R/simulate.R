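# --- design constructors -----------------------------------------------------

select_codes <- c("all", "best1", "best2", "best3", "epsilon", "random1",
                  "threshold")

resolve_rule <- function(select, epsilon, thresh) {
  if (is.numeric(select)) {
    if (!select %in% 0:6) stop("numeric `select` must be one of 0..6")
    select <- select_codes[select + 1]
  }
  selection_rule(select, epsilon = epsilon, thresh = thresh)
}

#' Specify a two-stage treatment-selection design
#'
#' Mirrors the interface of multi-arm seamless design simulators: sample sizes
#' and effects are given as lists, the effect vectors contain the control
#' group first, and the interim selection rule is chosen by name or by the
#' numeric codes 0--6 (0 all, 1--3 best one/two/three, 4 epsilon rule,
#' 5 random, 6 threshold).
#'
#' @param n List with per-arm sample sizes `stage1` and `stage2`.
#' @param effect List with numeric vectors `early` and `final`; the first
#'   element of each is the control group. Interpretation depends on
#'   `outcome`: standardized means (N), minus log hazard rates (T) or event
#'   rates (B).
#' @param outcome List with outcome types `early` and `final` ("N", "T", "B").
#' @param corr Correlation between early and final statistics of the same arm.
#' @param select Selection rule (name or code 0--6).
#' @param epsilon,thresh Parameters of the epsilon and threshold rules.
#' @param ptest Arms whose combined rejection ("reject any of") is counted;
#'   default all arms.
#' @param method Combination test, `"invnorm"` or `"fisher"`.
#' @param fu Complete follow-up of dropped arms (`TRUE`) or discontinued
#'   (`FALSE`, default).
#' @param weight Optional squared stage-1 combination weight; default
#'   `n1 / (n1 + n2)`.
#' @param level One-sided test level.
#' @param nsim Default number of simulated trials.
#' @param seed Default RNG seed.
#' @return An object of class `treatsel_design`.
#' @examples
#' d <- treatsel_design(n = list(stage1 = 100, stage2 = 300),
#'                      effect = list(early = c(0, 0.68, 0.82, 0.95, 0.91),
#'                                    final = c(0, 0.13, 0.17, 0.23, 0.20)),
#'                      corr = 0.4, select = 2, ptest = c(3, 4))
#' @export
treatsel_design <- function(n, effect,
                            outcome = list(early = "N", final = "N"),
                            corr = 0, select = 0, epsilon = 1, thresh = 1,
                            ptest = NULL, method = c("invnorm", "fisher"),
                            fu = FALSE, weight = NULL, level = 0.025,
                            nsim = 1000, seed = NULL) {
  method <- match.arg(method)
  if (is.null(n$stage1) || is.null(n$stage2))
    stop("`n` must be a list with `stage1` and `stage2` per-arm sample sizes")
  K <- length(effect$early) - 1
  if (K < 1) stop("`effect` vectors must contain the control plus >= 1 arm")
  if (K >= 8) stop("designs with eight or more treatment groups are not supported (K <= 7)")
  if (length(effect$final) != K + 1)
    stop("`effect$early` and `effect$final` must have equal length")
  if (level <= 0 || level >= 1) stop("`level` must lie in (0, 1)")
  if (nsim < 1 || nsim > 1e7) stop("`nsim` must lie in 1..1e7")
  if (is.null(ptest)) ptest <- seq_len(K)
  ptest <- as.integer(ptest)
  if (any(ptest < 1 | ptest > K)) stop("`ptest` must index arms 1..K")
  rule <- resolve_rule(select, epsilon, thresh)
  if (rule$kind == "futility")
    stop("the futility rule is a subgroup-selection rule")
  effects <- effect_spec(early = effect$early[-1], final = effect$final[-1],
                         control_early = effect$early[1],
                         control_final = effect$final[1],
                         outcome_early = outcome$early,
                         outcome_final = outcome$final,
                         corr = corr, tte_dialect = "minus-log-hazard")
  plan <- sample_size_plan(n$stage1, n$stage2)
  weights <- combination_weights(n$stage1, n$stage2, weight = weight)
  structure(list(design = "treatment", effects = effects, plan = plan,
                 rule = rule, ptest = ptest, method = method, fu = fu,
                 weights = weights, level = level, nsim = nsim, seed = seed),
            class = c("treatsel_design", "design_spec"))
}

#' Specify a two-stage subgroup-selection (adaptive enrichment) design
#'
#' One experimental treatment versus control, with a pre-defined subgroup of
#' prevalence `sprev` nested in the full population. Effects are given as
#' length-2 vectors (subgroup, full population); for time-to-event outcomes
#' they are hazard ratios against a unit control hazard, for binary outcomes
#' event rates, for normal outcomes standardized mean differences.
#'
#' @param n List with `stage1`, `stage2` and optionally `enrich` (per-arm
#'   subgroup sample size when continuing in the subgroup only).
#' @param effect List of length-2 vectors `early` and `final`:
#'   (subgroup, full population).
#' @param control Optional list with control-group values `early`, `final`
#'   (needed for binary outcomes; defaults to 0 for normal outcomes).
#' @param sprev Subgroup prevalence in (0, 1).
#' @param sprev_fixed If `FALSE`, the realized prevalence is redrawn once per
#'   simulated trial from `Binomial(n1, sprev) / n1`.
#' @param outcome List with outcome types `early` and `final`.
#' @param corr Correlation between early and final statistics.
#' @param select `"thresh"` (threshold rule on the difference of statistics)
#'   or `"futility"` (four-branch futility rule).
#' @param selim Length-2 selection limits `(l1, l2)`.
#' @param method Intersection test: `"CT-SD"`, `"CT-Simes"` or
#'   `"CT-Bonferroni"` (all combined across stages by the inverse normal
#'   combination test).
#' @inheritParams treatsel_design
#' @return An object of class `subpop_design`.
#' @examples
#' d <- subpop_design(n = list(stage1 = 100, enrich = 200, stage2 = 300),
#'                    effect = list(early = c(0.6, 0.9), final = c(0.6, 0.9)),
#'                    sprev = 0.3, outcome = list(early = "T", final = "T"),
#'                    corr = 0.5, select = "futility", selim = c(0, 0),
#'                    method = "CT-SD")
#' @export
subpop_design <- function(n, effect, control = list(early = NULL, final = NULL),
                          sprev, sprev_fixed = TRUE,
                          outcome = list(early = "N", final = "N"),
                          corr = 0, select = c("futility", "thresh"),
                          selim = c(0, 0),
                          method = c("CT-SD", "CT-Simes", "CT-Bonferroni"),
                          weight = NULL, level = 0.025, nsim = 1000,
                          seed = NULL) {
  method <- match.arg(method)
  select <- match.arg(select)
  if (is.null(n$stage1) || is.null(n$stage2))
    stop("`n` must be a list with `stage1` and `stage2` per-arm sample sizes")
  if (length(effect$early) != 2 || length(effect$final) != 2)
    stop("subgroup designs take length-2 effect vectors (subgroup, full)")
  if (missing(sprev)) stop("the subgroup prevalence `sprev` is required")
  if (level <= 0 || level >= 1) stop("`level` must lie in (0, 1)")
  if (nsim < 1 || nsim > 1e7) stop("`nsim` must lie in 1..1e7")
  ctl <- function(x, out) {
    if (!is.null(x)) return(x)
    if (out == "B") stop("binary outcomes need an explicit control event rate")
    if (out == "T") 1 else 0  # unit control hazard for hazard ratios
  }
  effects <- effect_spec(early = effect$early, final = effect$final,
                         control_early = ctl(control$early, outcome$early),
                         control_final = ctl(control$final, outcome$final),
                         outcome_early = outcome$early,
                         outcome_final = outcome$final,
                         corr = corr, tte_dialect = "hazard-ratio")
  plan <- sample_size_plan(n$stage1, n$stage2, enrich = n$enrich,
                           prevalence = sprev, prevalence_fixed = sprev_fixed)
  rule <- selection_rule(if (select == "thresh") "threshold" else "futility",
                         selim = selim)
  weights <- combination_weights(n$stage1, n$stage2, weight = weight)
  structure(list(design = "subgroup", effects = effects, plan = plan,
                 rule = rule, method = method, weights = weights,
                 level = level, nsim = nsim, seed = seed),
            class = c("subpop_design", "design_spec"))
}

#' @export
print.design_spec <- function(x, ...) {
  cat("Two-stage adaptive seamless design (", x$design, " selection)\n", sep = "")
  print(x$effects)
  print(x$plan)
  cat("selection rule:", x$rule$kind)
  if (x$rule$kind == "epsilon") cat(" (epsilon =", x$rule$epsilon, ")")
  if (x$rule$kind == "threshold" && x$design == "treatment")
    cat(" (thresh =", x$rule$thresh, ")")
  if (x$design == "subgroup")
    cat(" (selim =", paste(x$rule$selim, collapse = ", "), ")")
  cat("\nmethod:", x$method, "; level:", x$level, "\n")
  invisible(x)
}

# --- vectorised helpers ------------------------------------------------------

row_max <- function(m) {
  out <- m[, 1]
  for (j in seq_len(ncol(m))[-1]) out <- pmax(out, m[, j])
  out
}

row_any <- function(m) rowSums(m) > 0

all_subsets <- function(K) {
  lapply(seq_len(2^K - 1),
         function(i) which(bitwAnd(i, 2^(seq_len(K) - 1)) > 0))
}

# selection matrix (nsim x K logical) for a block of early statistics
select_matrix <- function(zE, rule) {
  nsim <- nrow(zE)
  K <- ncol(zE)
  switch(rule$kind,
         all = matrix(TRUE, nsim, K),
         best1 = ,
         best2 = ,
         best3 = {
           m <- as.integer(substring(rule$kind, 5))
           if (m > K) stop("cannot select more arms than exist")
           S <- matrix(FALSE, nsim, K)
           tmp <- zE
           rows <- seq_len(nsim)
           for (i in seq_len(m)) {
             j <- max.col(tmp, ties.method = "random")
             S[cbind(rows, j)] <- TRUE
             tmp[cbind(rows, j)] <- -Inf
           }
           S
         },
         epsilon = zE >= row_max(zE) - rule$epsilon,
         random1 = {
           S <- matrix(FALSE, nsim, K)
           S[cbind(seq_len(nsim), sample.int(K, nsim, replace = TRUE))] <- TRUE
           S
         },
         threshold = zE >= rule$thresh,
         stop("rule `", rule$kind, "` is not a treatment-selection rule"))
}

# closed Dunnett + combination test over all replicates at once;
# returns the nsim x K elementary rejection matrix
treatsel_closed_engine <- function(F1, F2, S, r, method, weights, alpha,
                                   followup) {
  nsim <- nrow(F1)
  crit <- stats::qnorm(1 - alpha)
  cfish <- exp(-stats::qchisq(1 - alpha, df = 4) / 2)
  elem <- S
  for (s in all_subsets(ncol(F1))) {
    p1 <- dunnett_p_vec(row_max(F1[, s, drop = FALSE]), length(s), r)
    if (followup == "complete") {
      p2 <- dunnett_p_vec(row_max(F2[, s, drop = FALSE]), length(s), r)
    } else {
      Zm <- F2[, s, drop = FALSE]
      Zm[!S[, s, drop = FALSE]] <- -Inf
      zmax2 <- row_max(Zm)
      m2 <- rowSums(S[, s, drop = FALSE])
      p2 <- rep(1, nsim)
      for (m in seq_along(s)) {
        idx <- which(m2 == m)
        if (length(idx)) p2[idx] <- dunnett_p_vec(zmax2[idx], m, r)
      }
    }
    rej <- if (method == "invnorm")
      (weights$w1 * qnorm_upper(p1) + weights$w2 * qnorm_upper(p2)) >= crit
    else (p1 * p2) <= cfish
    elem[, s] <- elem[, s, drop = FALSE] & rej
  }
  elem
}

# --- treatment-selection driver ----------------------------------------------

#' Simulate a treatment-selection design
#'
#' Monte Carlo evaluation of the operating characteristics of a
#' [treatsel_design()]: per replicate, stage-1 early and final statistics are
#' drawn from the joint normal model, the selection rule is applied to the
#' early statistics, stage-2 increments are drawn for the continuing arms, and
#' the closed Dunnett/combination test decides the elementary hypotheses.
#'
#' @param design A [treatsel_design()].
#' @param nsim,seed Optional overrides of the design defaults.
#' @return A `treatsel_summary` with selection counts, per-hypothesis
#'   rejection counts, the combined `ptest` rejection count, the futility rate
#'   and the expected total sample size. Its print method reproduces the full
#'   simulation report.
#' @export
simulate_treatsel <- function(design, nsim = NULL, seed = NULL) {
  stopifnot(inherits(design, "treatsel_design"))
  if (is.null(nsim)) nsim <- design$nsim
  if (is.null(seed)) seed <- design$seed
  if (!is.null(seed)) set.seed(seed)
  model <- build_model_treatsel(design$effects, design$plan)
  K <- model$K
  r <- 1 / (1 + model$lambda)
  iE <- seq_len(K)
  iF1 <- K + seq_len(K)
  iF2 <- 2 * K + seq_len(K)

  L1 <- chol_psd(model$cov[c(iE, iF1), c(iE, iF1)])
  Z1 <- matrix(stats::rnorm(nsim * 2 * K), nsim) %*% L1
  Z1 <- sweep(Z1, 2, model$mean[c(iE, iF1)], "+")
  E <- Z1[, seq_len(K), drop = FALSE]
  F1 <- Z1[, K + seq_len(K), drop = FALSE]

  S <- select_matrix(E, design$rule)

  L2 <- chol(equicorr(K, r))
  F2 <- matrix(stats::rnorm(nsim * K), nsim) %*% L2
  if (design$fu) {
    # dropped arms carry stage-1-information statistics at stage 2
    m_dropped <- effect_statistic_info(design$effects$outcome_final,
                                       design$plan$stage1,
                                       design$effects$final,
                                       design$effects$control_final,
                                       design$effects$tte_dialect)
    md <- if (m_dropped$flip) -m_dropped$z else m_dropped$z
    mu2 <- matrix(model$mean[iF2], nsim, K, byrow = TRUE)
    mu2[!S] <- matrix(md, nsim, K, byrow = TRUE)[!S]
    F2 <- F2 + mu2
  } else {
    F2 <- sweep(F2, 2, model$mean[iF2], "+")
  }

  elem <- treatsel_closed_engine(F1, F2, S, r, design$method, design$weights,
                                 design$level,
                                 if (design$fu) "complete" else "discontinued")

  m <- rowSums(S)
  n1 <- design$plan$stage1
  n2 <- design$plan$stage2
  summary <- structure(list(
    design = design, model = model, weights = design$weights,
    nsim = nsim, seed = seed,
    count_total = tabulate(m, nbins = K),
    futility = sum(m == 0),
    select_total = colSums(S),
    reject_total = colSums(elem),
    sim_reject = sum(row_any(elem[, design$ptest, drop = FALSE])),
    expected_n = (K + 1) * n1 + mean((m + 1) * n2 * (m >= 1))),
    class = c("treatsel_summary", "simulation_summary"))
  summary
}

#' Expected total sample size implied by a simulation summary
#'
#' For treatment-selection designs, `(K+1) n1` stage-1 patients plus
#' `(m+1) n2` stage-2 patients when `m >= 1` arms continue (none on a futility
#' stop). For subgroup designs, `2 n1` plus `2 n2` when the full population is
#' still recruited and `2 enrich` (or `2 n2` without planned enrichment) when
#' continuing in the subgroup only.
#'
#' @param summary A simulation summary.
#' @return Expected total number of patients.
#' @export
expected_sample_size <- function(summary) {
  stopifnot(inherits(summary, "simulation_summary"))
  summary$expected_n
}

# --- subgroup-selection driver -----------------------------------------------

subpop_intersection_p <- function(z_s, z_f, info_ratio, method) {
  switch(method,
         "CT-SD" = sd_p_vec(z_s, z_f, info_ratio),
         "CT-Simes" = simes2(stats::pnorm(z_s, lower.tail = FALSE),
                             stats::pnorm(z_f, lower.tail = FALSE)),
         "CT-Bonferroni" = bonf2(stats::pnorm(z_s, lower.tail = FALSE),
                                 stats::pnorm(z_f, lower.tail = FALSE)))
}

#' Simulate a subgroup-selection (adaptive enrichment) design
#'
#' Monte Carlo evaluation of a [subpop_design()]: per replicate, the realized
#' prevalence is (optionally) drawn, stage-1 statistics for the subgroup and
#' the full population are drawn on both outcomes, the interim rule picks the
#' continuation branch (both populations, subgroup only, full population only,
#' or a futility stop), branch-specific stage-2 increments are drawn, and the
#' closed combination test decides the subgroup and full-population
#' hypotheses. Dropped populations are never rejected.
#'
#' @param design A [subpop_design()].
#' @param nsim,seed Optional overrides of the design defaults.
#' @return A `subpop_summary`; its print method reproduces the
#'   selection-by-rejection table.
#' @export
simulate_subpop <- function(design, nsim = NULL, seed = NULL) {
  stopifnot(inherits(design, "subpop_design"))
  if (is.null(nsim)) nsim <- design$nsim
  if (is.null(seed)) seed <- design$seed
  if (!is.null(seed)) set.seed(seed)
  plan <- design$plan
  effects <- design$effects
  weights <- design$weights
  crit <- stats::qnorm(1 - design$level)
  n1 <- plan$stage1

  if (plan$prevalence_fixed) {
    tau_all <- rep(plan$prevalence, nsim)
  } else {
    k <- stats::rbinom(nsim, n1, plan$prevalence)
    k <- pmin(pmax(k, 1), n1 - 1)  # keep the realized prevalence in (0, 1)
    tau_all <- k / n1
  }

  # accumulators: rows sub / full / both
  tab <- matrix(0, nrow = 3, ncol = 5,
                dimnames = list(c("sub", "full", "both"),
                                c("Hs", "Hf", "HsHf", "Hsf", "n")))
  futility <- 0
  total_n2 <- 0
  n_sub2_planned <- if (is.null(plan$enrich)) plan$stage2 else plan$enrich

  for (tau in unique(tau_all)) {
    nc <- sum(tau_all == tau)
    mod_b <- build_model_subpop(effects, plan, "both", tau = tau)
    mod_s <- build_model_subpop(effects, plan, "subgroup-only", tau = tau)
    mod_f <- build_model_subpop(effects, plan, "full-only", tau = tau)

    L1 <- chol_psd(mod_b$cov[1:4, 1:4])
    Z1 <- matrix(stats::rnorm(nc * 4), nc) %*% L1
    Z1 <- sweep(Z1, 2, mod_b$mean[1:4], "+")
    z1S <- Z1[, 3]
    z1F <- Z1[, 4]

    # interim branch: 1 subgroup-only, 2 full-only, 3 both, 0 futility
    if (design$rule$kind == "futility") {
      # natural smaller-is-better scale for the printed inequalities
      okS <- -Z1[, 1] < design$rule$selim[1]
      okF <- -Z1[, 2] < design$rule$selim[2]
      branch <- ifelse(okS & okF, 3L, ifelse(okS, 1L, ifelse(okF, 2L, 0L)))
    } else {
      delta <- Z1[, 2] - Z1[, 1]
      branch <- ifelse(delta <= design$rule$selim[1], 1L,
                       ifelse(delta > design$rule$selim[2], 2L, 3L))
    }

    # stage-2 increments per branch
    z2S <- z2F <- rep(NA_real_, nc)
    iB <- which(branch == 3L)
    if (length(iB)) {
      r2 <- sqrt(mod_b$info[5] / mod_b$info[6])
      Lb <- chol(equicorr(2, r2))
      Zb <- matrix(stats::rnorm(2 * length(iB)), ncol = 2) %*% Lb
      z2S[iB] <- Zb[, 1] + mod_b$mean[5]
      z2F[iB] <- Zb[, 2] + mod_b$mean[6]
    }
    iS <- which(branch == 1L)
    if (length(iS)) z2S[iS] <- stats::rnorm(length(iS)) + mod_s$mean[5]
    iF <- which(branch == 2L)
    if (length(iF)) z2F[iF] <- stats::rnorm(length(iF)) + mod_f$mean[6]

    # stage-1 p-values (always over both populations: both have stage-1 data)
    p1S <- stats::pnorm(z1S, lower.tail = FALSE)
    p1F <- stats::pnorm(z1F, lower.tail = FALSE)
    p1SF <- subpop_intersection_p(z1S, z1F, mod_b$info[3] / mod_b$info[4],
                                  design$method)

    # stage-2 p-values, restricted to the continuing population(s)
    p2S <- p2F <- p2SF <- rep(1, nc)
    if (length(iB)) {
      p2S[iB] <- stats::pnorm(z2S[iB], lower.tail = FALSE)
      p2F[iB] <- stats::pnorm(z2F[iB], lower.tail = FALSE)
      p2SF[iB] <- subpop_intersection_p(z2S[iB], z2F[iB],
                                        mod_b$info[5] / mod_b$info[6],
                                        design$method)
    }
    if (length(iS)) {
      p2S[iS] <- stats::pnorm(z2S[iS], lower.tail = FALSE)
      p2SF[iS] <- p2S[iS]
    }
    if (length(iF)) {
      p2F[iF] <- stats::pnorm(z2F[iF], lower.tail = FALSE)
      p2SF[iF] <- p2F[iF]
    }

    comb <- function(p1, p2)
      weights$w1 * qnorm_upper(p1) + weights$w2 * qnorm_upper(p2)
    rejS <- comb(p1S, p2S) >= crit
    rejF <- comb(p1F, p2F) >= crit
    rejSF <- comb(p1SF, p2SF) >= crit

    Hs <- branch %in% c(1L, 3L) & rejS & rejSF
    Hf <- branch %in% c(2L, 3L) & rejF & rejSF
    Hsf <- branch != 0L & rejSF
    for (b in 1:3) {
      idx <- branch == b
      tab[b, ] <- tab[b, ] + c(sum(Hs[idx]), sum(Hf[idx]),
                               sum(Hs[idx] & Hf[idx]), sum(Hsf[idx]),
                               sum(idx))
    }
    futility <- futility + sum(branch == 0L)
    total_n2 <- total_n2 +
      2 * n_sub2_planned * sum(branch == 1L) +
      2 * plan$stage2 * sum(branch %in% c(2L, 3L))
  }

  structure(list(
    design = design, weights = weights, nsim = nsim, seed = seed,
    table = tab, futility = futility,
    reject_hs = sum(tab[, "Hs"]), reject_hf = sum(tab[, "Hf"]),
    reject_both = sum(tab[, "HsHf"]), reject_intersection = sum(tab[, "Hsf"]),
    sim_reject = sum(tab[, "Hs"]) + sum(tab[, "Hf"]) - sum(tab[, "HsHf"]),
    expected_n = 2 * n1 + total_n2 / nsim,
    header = subpop_header(design)),
    class = c("subpop_summary", "simulation_summary"))
}

# expected-statistic lines (natural scale) for the printed model summary,
# at the planned prevalence
subpop_header <- function(design) {
  eff <- design$effects
  plan <- design$plan
  mb <- build_model_subpop(eff, plan, "both")
  ms <- build_model_subpop(eff, plan, "subgroup-only")
  mf <- build_model_subpop(eff, plan, "full-only")
  list(early = mb$mean_natural[1:2],
       final1 = mb$mean_natural[3:4],
       final2_only = c(ms$mean_natural[5], mf$mean_natural[6]),
       final2_both = mb$mean_natural[5:6])
}
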