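# K x K compound-symmetric correlation matrix with off-diagonal r
equicorr <- function(K, r) {
  m <- matrix(r, K, K)
  diag(m) <- 1
  m
}

new_covariance_model <- function(labels, mean, mean_natural, cov, info,
                                 design, extra = list()) {
  if (!isSymmetric(unname(cov), tol = 1e-10))
    stop("covariance matrix is not symmetric")
  ev <- eigen(cov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev)))
    stop("covariance matrix is not positive semi-definite; ",
         "check the correlation/allocation settings")
  dimnames(cov) <- list(labels, labels)
  names(mean) <- names(mean_natural) <- names(info) <- labels
  structure(c(list(labels = labels, mean = mean, mean_natural = mean_natural,
                   cov = cov, info = info, design = design), extra),
            class = "covariance_model")
}

#' Joint distribution of stage-wise statistics for a treatment-selection design
#'
#' Builds the mean vector and covariance matrix of the standardized statistics
#' of a two-stage multi-arm design with a common control: for each of the K
#' experimental arms, the stage-1 early-outcome statistic `E_k`, the stage-1
#' final-outcome statistic `F1_k`, and the stage-2 final-outcome increment
#' `F2_k` (computed from stage-2 patients only, hence independent of stage 1).
#'
#' Within each block, statistics sharing the control group have correlation
#' `1/(1 + lambda)`; early and final stage-1 statistics of the same arm have
#' correlation `corr` (same patients); stage-2 increments are independent of
#' all stage-1 statistics. All statistics are canonically oriented so that
#' larger values favour the experimental arm.
#'
#' @param effects An [effect_spec()].
#' @param plan A [sample_size_plan()].
#' @return A `covariance_model` with `3 * K` slots.
#' @export
build_model_treatsel <- function(effects, plan) {
  stopifnot(inherits(effects, "effect_spec"), inherits(plan, "sample_size_plan"))
  K <- effects$K
  n1 <- plan$stage1
  n2 <- plan$stage2
  r <- 1 / (1 + plan$allocation)
  e1 <- effect_statistic_info(effects$outcome_early, n1, effects$early,
                              effects$control_early, effects$tte_dialect)
  f1 <- effect_statistic_info(effects$outcome_final, n1, effects$final,
                              effects$control_final, effects$tte_dialect)
  f2 <- effect_statistic_info(effects$outcome_final, n2, effects$final,
                              effects$control_final, effects$tte_dialect)
  sgn <- function(x, flip) if (flip) -x else x
  mean_nat <- c(e1$z, f1$z, f2$z)
  mean_can <- c(sgn(e1$z, e1$flip), sgn(f1$z, f1$flip), sgn(f2$z, f2$flip))
  C <- equicorr(K, r)
  Z <- matrix(0, K, K)
  rho <- effects$corr
  cov <- rbind(cbind(C, rho * C, Z),
               cbind(rho * C, C, Z),
               cbind(Z, Z, C))
  labels <- c(paste0("E_", seq_len(K)), paste0("F1_", seq_len(K)),
              paste0("F2_", seq_len(K)))
  info <- c(e1$info + 0 * effects$early, f1$info + 0 * effects$final,
            f2$info + 0 * effects$final)
  new_covariance_model(labels, mean_can, mean_nat, cov, info,
                       design = "treatment",
                       extra = list(K = K, lambda = plan$allocation, corr = rho,
                                    flip_early = e1$flip, flip_final = f1$flip,
                                    n1 = n1, n2 = n2))
}

#' Joint distribution of stage-wise statistics for a subgroup-selection design
#'
#' Builds the joint normal model for a design with one subgroup (prevalence
#' `tau`) nested in the full population: stage-1 early statistics `(E_S, E_F)`,
#' stage-1 final statistics `(F1_S, F1_F)` and stage-2 final increments
#' `(F2_S, F2_F)`. Within a stage and outcome, the subgroup and full-population
#' statistics have correlation `sqrt(I_S / I_F)` (the nesting-induced
#' correlation, equal to `sqrt(tau)` when per-patient information is equal);
#' early and final statistics of the same population have correlation `corr`;
#' the remaining cross terms are `corr * sqrt(r_early * r_final)`.
#'
#' @inheritParams build_model_treatsel
#' @param continuation Which population(s) stage 2 recruits: `"both"` (stage-2
#'   subgroup information from `stage2 * tau` patients per arm),
#'   `"subgroup-only"` (from `enrich`, or `stage2 * tau` when no enrichment is
#'   planned) or `"full-only"`.
#' @param tau Optional prevalence override (used internally when prevalence
#'   varies between simulated trials); defaults to `plan$prevalence`.
#' @return A `covariance_model` with 6 slots.
#' @export
build_model_subpop <- function(effects, plan,
                               continuation = c("both", "subgroup-only", "full-only"),
                               tau = NULL) {
  stopifnot(inherits(effects, "effect_spec"), inherits(plan, "sample_size_plan"))
  continuation <- match.arg(continuation)
  if (effects$K != 2)
    stop("subgroup models need exactly two effect entries: (subgroup, full)")
  if (is.null(tau)) tau <- plan$prevalence
  if (is.null(tau)) stop("a subgroup prevalence is required")
  n1 <- plan$stage1
  n2 <- plan$stage2
  n_sub2 <- switch(continuation,
                   "both" = n2 * tau,
                   "subgroup-only" = if (is.null(plan$enrich)) n2 * tau else plan$enrich,
                   "full-only" = n2 * tau)
  e1 <- effect_statistic_info(effects$outcome_early, c(n1 * tau, n1),
                              effects$early, effects$control_early,
                              effects$tte_dialect)
  f1 <- effect_statistic_info(effects$outcome_final, c(n1 * tau, n1),
                              effects$final, effects$control_final,
                              effects$tte_dialect)
  f2 <- effect_statistic_info(effects$outcome_final, c(n_sub2, n2),
                              effects$final, effects$control_final,
                              effects$tte_dialect)
  sgn <- function(x, flip) if (flip) -x else x
  mean_nat <- c(e1$z, f1$z, f2$z)
  mean_can <- c(sgn(e1$z, e1$flip), sgn(f1$z, f1$flip), sgn(f2$z, f2$flip))
  r_e1 <- sqrt(e1$info[1] / e1$info[2])
  r_f1 <- sqrt(f1$info[1] / f1$info[2])
  # stage-2 populations are disjoint under subgroup-only enrichment, so the
  # cross term is only meaningful when the full population is still recruited
  r_f2 <- if (continuation == "subgroup-only" && !is.null(plan$enrich)) 0
          else sqrt(f2$info[1] / f2$info[2])
  rho <- effects$corr
  pop <- function(r) equicorr(2, r)
  cross <- rho * sqrt(r_e1 * r_f1)
  blk12 <- matrix(c(rho, cross, cross, rho), 2, 2)
  Z <- matrix(0, 2, 2)
  cov <- rbind(cbind(pop(r_e1), blk12, Z),
               cbind(t(blk12), pop(r_f1), Z),
               cbind(Z, Z, pop(r_f2)))
  labels <- c("E_S", "E_F", "F1_S", "F1_F", "F2_S", "F2_F")
  info <- c(e1$info, f1$info, f2$info)
  new_covariance_model(labels, mean_can, mean_nat, cov, info,
                       design = "subgroup",
                       extra = list(K = 2, corr = rho, tau = tau,
                                    continuation = continuation,
                                    flip_early = e1$flip, flip_final = f1$flip,
                                    n1 = n1, n2 = n2, n_sub2 = n_sub2))
}

#' Draw stage-wise statistics from a covariance model
#'
#' One (or several) multivariate normal draws of all slots of the model, on
#' the canonical (larger-is-better) scale. Deterministic given the R random
#' number generator state.
#'
#' @param model A `covariance_model`.
#' @param n Number of draws.
#' @return An `n` by `length(model$labels)` matrix with labelled columns.
#' @export
draw_statistics <- function(model, n = 1) {
  stopifnot(inherits(model, "covariance_model"))
  L <- chol_psd(model$cov)
  d <- length(model$mean)
  z <- matrix(stats::rnorm(n * d), n, d) %*% L
  out <- sweep(z, 2, model$mean, "+")
  colnames(out) <- model$labels
  out
}

# upper-triangular factor, tolerating semi-definite matrices
chol_psd <- function(S) {
  out <- tryCatch(chol(S), error = function(e) NULL)
  if (!is.null(out)) return(out)
  ee <- eigen(S, symmetric = TRUE)
  vals <- pmax(ee$values, 0)
  if (min(ee$values) < -1e-8 * max(vals))
    stop("covariance matrix is not positive semi-definite")
  t(ee$vectors %*% (t(ee$vectors) * sqrt(vals)))
}

#' Cumulative final-outcome statistic from stage-wise increments
#'
#' Combines the stage-1 statistic and the independent stage-2 increment by
#' information weighting, `(sqrt(I1) z1 + sqrt(I2) z2) / sqrt(I1 + I2)`, the
#' statistic that would have been computed from the pooled data.
#'
#' @param z1,z2 Stage-wise statistics.
#' @param info1,info2 Stage-wise information levels.
#' @return The cumulative statistic.
#' @export
cumulative_final_statistic <- function(z1, z2, info1, info2) {
  (sqrt(info1) * z1 + sqrt(info2) * z2) / sqrt(info1 + info2)
}

#' @export
print.covariance_model <- function(x, ...) {
  cat("Covariance model (", x$design, " selection, ",
      length(x$labels), " statistic slots)\n", sep = "")
  cat("  expected statistics (natural scale):\n")
  m <- x$mean_natural
  names(m) <- x$labels
  print(round(m, 3))
  cat("  information per slot:\n")
  i <- round(x$info, 2)
  names(i) <- x$labels
  print(i)
  invisible(x)
}
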