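#' Expected z statistic for a normally distributed outcome
#'
#' For a two-arm comparison with equal per-arm sample size `n`, unit variance
#' and 1:1 allocation, the standardized test statistic for a mean difference
#' `theta` has expectation `sqrt(n/2) * theta`.
#'
#' @param n Per-arm sample size (>= 1).
#' @param theta Standardized mean difference(s) versus control.
#' @return Expected z statistic(s), same length as `theta`.
#' @examples
#' normal_effect_statistic(100, 0.95) # approx 6.7
#' @export
normal_effect_statistic <- function(n, theta) {
  stopifnot(is.numeric(n), is.numeric(theta))
  if (any(n < 1)) stop("per-arm sample size `n` must be >= 1")
  sqrt(n / 2) * theta
}

#' Expected total number of events for a time-to-event comparison
#'
#' Under an exponential survival model with unit follow-up, the probability
#' that a patient has an event is `1 - exp(-hazard)`. Two effect dialects are
#' supported: with `"minus-log-hazard"` the parameters `mu0`, `muk` are minus
#' log hazard rates (hazard `exp(-mu)`); with `"hazard-ratio"` the control
#' hazard is fixed at 1 and `muk` is the hazard ratio of the experimental arm.
#'
#' @param n Per-arm sample size.
#' @param mu0 Control-arm parameter (minus log hazard; ignored under the
#'   hazard-ratio dialect, where the control hazard is 1).
#' @param muk Experimental-arm parameter(s): minus log hazard, or hazard
#'   ratio(s) under the `"hazard-ratio"` dialect.
#' @param dialect Effect dialect, `"minus-log-hazard"` or `"hazard-ratio"`.
#' @return Expected total events (control + experimental arm), a real number.
#' @examples
#' tte_expected_events(30, muk = 0.6, dialect = "hazard-ratio") # approx 32.5
#' @export
tte_expected_events <- function(n, mu0 = 0, muk,
                                dialect = c("minus-log-hazard", "hazard-ratio")) {
  dialect <- match.arg(dialect)
  if (any(n < 1)) stop("per-arm sample size `n` must be >= 1")
  if (dialect == "minus-log-hazard") {
    n * (1 - exp(-exp(-mu0))) + n * (1 - exp(-exp(-muk)))
  } else {
    if (any(muk <= 0)) stop("hazard ratios must be positive")
    n * (1 - exp(-1)) + n * (1 - exp(-muk))
  }
}

#' Expected z statistic for a time-to-event outcome
#'
#' Log-rank-type statistic with expectation `sqrt(o/4) * delta`, where `o` is
#' the expected total number of events ([tte_expected_events()]) and `delta`
#' the log hazard-rate contrast: `muk - mu0` under the minus-log-hazard
#' dialect (positive when the experimental hazard is lower), or `log(HR)`
#' under the hazard-ratio dialect (negative when treatment reduces hazard).
#'
#' @inheritParams tte_expected_events
#' @return Expected z statistic(s) on the natural scale of the dialect.
#' @examples
#' tte_effect_statistic(30, muk = 0.6, dialect = "hazard-ratio") # approx -1.46
#' @export
tte_effect_statistic <- function(n, mu0 = 0, muk,
                                 dialect = c("minus-log-hazard", "hazard-ratio")) {
  dialect <- match.arg(dialect)
  o <- tte_expected_events(n, mu0, muk, dialect)
  delta <- if (dialect == "minus-log-hazard") muk - mu0 else log(muk)
  sqrt(o / 4) * delta
}

#' Expected z statistic for a binary outcome
#'
#' Effects are event (failure) rates; lower rates are better. Internally the
#' rates are converted to minus log odds, `mu = log((1 - r) / r)`, and the
#' statistic is the log odds ratio divided by its standard error from the
#' expected 2x2 cell counts: `(muk - mu0) / sqrt(1/ok + 1/(n-ok) + 1/o0 +
#' 1/(n-o0))` with `ok = n * rk` expected events. Positive when `rk < r0`.
#'
#' @param n Per-arm sample size.
#' @param r0 Control event rate, in (0, 1).
#' @param rk Experimental event rate(s), in (0, 1).
#' @return Expected z statistic(s).
#' @examples
#' binary_effect_statistic(300, 0.50, 0.40) # approx 2.46
#' @export
binary_effect_statistic <- function(n, r0, rk) {
  if (any(r0 <= 0 | r0 >= 1) || any(rk <= 0 | rk >= 1))
    stop("event rates must lie strictly in (0, 1)")
  if (any(n < 1)) stop("per-arm sample size `n` must be >= 1")
  mu0 <- log((1 - r0) / r0)
  muk <- log((1 - rk) / rk)
  o0 <- n * r0
  ok <- n * rk
  if (any(c(o0, n - o0, ok, n - ok) <= 0))
    stop("expected 2x2 cell counts must all be positive")
  (muk - mu0) / sqrt(1 / ok + 1 / (n - ok) + 1 / o0 + 1 / (n - o0))
}

# Expected statistic, Fisher information and orientation for one outcome.
# Returns the statistic on its natural scale plus `flip`: TRUE when smaller
# natural values are better (only the hazard-ratio dialect), so that
# canonical (larger-is-better) statistics are -z_natural.
# Vectorised over `effect` and `n`.
effect_statistic_info <- function(outcome, n, effect, control = 0,
                                  tte_dialect = "minus-log-hazard") {
  outcome <- match.arg(outcome, c("N", "T", "B"))
  if (outcome == "N") {
    list(z = normal_effect_statistic(n, effect - control), info = n / 2, flip = FALSE)
  } else if (outcome == "T") {
    o <- tte_expected_events(n, control, effect, tte_dialect)
    list(z = tte_effect_statistic(n, control, effect, tte_dialect),
         info = o / 4, flip = identical(tte_dialect, "hazard-ratio"))
  } else {
    mu0 <- log((1 - control) / control)
    muk <- log((1 - effect) / effect)
    o0 <- n * control
    ok <- n * effect
    v <- 1 / ok + 1 / (n - ok) + 1 / o0 + 1 / (n - o0)
    list(z = binary_effect_statistic(n, control, effect), info = 1 / v, flip = FALSE)
  }
}

#' Specify treatment effects on the early and final outcomes
#'
#' Bundles the per-arm (or per-population) effects on the early and final
#' outcomes, the outcome types, the within-patient correlation between the
#' two outcomes, and the time-to-event dialect in force.
#'
#' Effect dialects by outcome type: normal (`"N"`) effects are standardized
#' mean differences on the raw scale (higher better); time-to-event (`"T"`)
#' effects are minus log hazard rates under the `"minus-log-hazard"` dialect
#' (used by treatment-selection designs) or hazard ratios against a unit
#' control hazard under `"hazard-ratio"` (used by subgroup designs); binary
#' (`"B"`) effects are event rates in (0, 1), lower better.
#'
#' @param early,final Numeric vectors of arm (or subgroup/full-population)
#'   effects, equal length, one entry per experimental arm; for subgroup
#'   designs length 2: (subgroup, full population).
#' @param control_early,control_final Control-group effect on each outcome.
#' @param outcome_early,outcome_final Outcome types, one of "N", "T", "B".
#' @param corr Within-patient correlation between early and final outcomes,
#'   in (-1, 1).
#' @param tte_dialect Interpretation of "T" effects (see Details).
#' @return An object of class `effect_spec`.
#' @export
effect_spec <- function(early, final, control_early = 0, control_final = 0,
                        outcome_early = "N", outcome_final = "N", corr = 0,
                        tte_dialect = c("minus-log-hazard", "hazard-ratio")) {
  tte_dialect <- match.arg(tte_dialect)
  outcome_early <- match.arg(outcome_early, c("N", "T", "B"))
  outcome_final <- match.arg(outcome_final, c("N", "T", "B"))
  if (length(early) != length(final))
    stop("`early` and `final` effect vectors must have equal length")
  if (length(early) < 1) stop("at least one experimental arm is required")
  if (!is.numeric(corr) || length(corr) != 1 || corr <= -1 || corr >= 1)
    stop("`corr` must be a single number in (-1, 1)")
  for (side in list(c(outcome_early, "early"), c(outcome_final, "final"))) {
    vals <- if (side[2] == "early") c(control_early, early) else c(control_final, final)
    if (side[1] == "B" && any(vals <= 0 | vals >= 1))
      stop("binary effects are event rates and must lie in (0, 1)")
    if (side[1] == "T" && tte_dialect == "hazard-ratio" && any(vals[-1] <= 0))
      stop("hazard ratios must be positive")
  }
  structure(list(early = early, final = final,
                 control_early = control_early, control_final = control_final,
                 outcome_early = outcome_early, outcome_final = outcome_final,
                 corr = corr, tte_dialect = tte_dialect,
                 K = length(early)),
            class = "effect_spec")
}

#' @export
print.effect_spec <- function(x, ...) {
  cat("Effect specification (", x$K, " comparison",
      if (x$K > 1) "s", ")\n", sep = "")
  cat("  early  [", x$outcome_early, "]: control =", x$control_early,
      "; arms =", paste(x$early, collapse = " "), "\n")
  cat("  final  [", x$outcome_final, "]: control =", x$control_final,
      "; arms =", paste(x$final, collapse = " "), "\n")
  cat("  early-final correlation:", x$corr,
      "; T dialect:", x$tte_dialect, "\n")
  invisible(x)
}

#' Per-stage sample size plan
#'
#' @param stage1,stage2 Patients per arm recruited in stage 1 and stage 2.
#' @param enrich Optional patients per arm in stage 2 when continuing in the
#'   subgroup only (enrichment); when absent the subgroup stage-2 size
#'   defaults to `stage2 * prevalence`.
#' @param allocation Control:experimental allocation ratio lambda (default 1),
#'   which sets the between-comparison correlation `1/(1+lambda)`.
#' @param prevalence Subgroup prevalence tau in (0, 1); subgroup designs only.
#' @param prevalence_fixed Logical; if `FALSE` the realized prevalence is
#'   redrawn binomially once per simulated trial.
#' @return An object of class `sample_size_plan`.
#' @export
sample_size_plan <- function(stage1, stage2, enrich = NULL, allocation = 1,
                             prevalence = NULL, prevalence_fixed = TRUE) {
  if (stage1 < 1 || stage2 < 1) stop("stage sample sizes must be >= 1")
  if (!is.null(enrich) && enrich < 1) stop("`enrich` must be >= 1 when present")
  if (allocation <= 0) stop("`allocation` must be positive")
  if (!is.null(prevalence) &&
      (prevalence <= 0 || prevalence >= 1))
    stop("`prevalence` must lie strictly in (0, 1)")
  structure(list(stage1 = stage1, stage2 = stage2, enrich = enrich,
                 allocation = allocation, prevalence = prevalence,
                 prevalence_fixed = prevalence_fixed),
            class = "sample_size_plan")
}

#' @export
print.sample_size_plan <- function(x, ...) {
  cat("Sample size plan: stage 1 =", x$stage1, "per arm; stage 2 =",
      x$stage2, "per arm\n")
  if (!is.null(x$enrich))
    cat("  enrichment (subgroup-only continuation):", x$enrich, "per arm\n")
  if (!is.null(x$prevalence))
    cat("  subgroup prevalence:", x$prevalence,
        if (x$prevalence_fixed) "(fixed)" else "(binomially varying)", "\n")
  invisible(x)
}
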