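# normal quantile of 1 - p, clipped to +/- 8.2 so that degenerate p in {0, 1}
# (e.g. the p = 1 assigned to dropped hypotheses) stays finite; the cap is
# irrelevant for any test level above ~1e-15
QCAP <- 8.2
qnorm_upper <- function(p) pmin(pmax(stats::qnorm(1 - p), -QCAP), QCAP)

#' Stage weights for the inverse normal combination test
#'
#' Pre-specified weights with `w1^2 + w2^2 = 1`. By default the squared
#' weights are the planned stage sample-size fractions, `w1^2 = n1/(n1+n2)`.
#' Alternatively the squared stage-1 weight can be given directly.
#'
#' @param n1,n2 Planned (full-population) per-arm sample sizes by stage.
#' @param weight Optional squared stage-1 weight in (0, 1); overrides `n1`,
#'   `n2` when supplied.
#' @return An object of class `combination_weights` with fields `w1`, `w2`.
#' @export
combination_weights <- function(n1 = NULL, n2 = NULL, weight = NULL) {
  if (!is.null(weight)) {
    if (weight <= 0 || weight >= 1) stop("`weight` must lie in (0, 1)")
    w1 <- sqrt(weight)
  } else {
    if (is.null(n1) || is.null(n2))
      stop("supply either both stage sample sizes or `weight`")
    w1 <- sqrt(n1 / (n1 + n2))
  }
  structure(list(w1 = w1, w2 = sqrt(1 - w1^2)), class = "combination_weights")
}

#' @export
print.combination_weights <- function(x, ...) {
  cat("weights: stage 1 =", fmt_num(x$w1, 2), "and stage 2 =",
      fmt_num(x$w2, 2), "\n")
  invisible(x)
}

#' Inverse normal combination of two stage-wise p-values
#'
#' Combined statistic `z = w1 * qnorm(1 - p1) + w2 * qnorm(1 - p2)`; under the
#' null with independent (p-clud) stage-wise p-values, `z` is standard normal
#' whatever adaptation occurred between the stages. Quantiles at p of 0 or 1
#' are capped at +/- 8.2.
#'
#' @param p1,p2 Stage-wise p-values in [0, 1] (vectorised).
#' @param weights A [combination_weights()] object.
#' @return List with the combined statistic `z` and combined p-value `p`.
#' @export
inverse_normal_combine <- function(p1, p2, weights) {
  stopifnot(inherits(weights, "combination_weights"))
  if (abs(weights$w1^2 + weights$w2^2 - 1) > 1e-12)
    stop("squared combination weights must sum to 1")
  if (any(p1 < 0 | p1 > 1, na.rm = TRUE) || any(p2 < 0 | p2 > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  z <- weights$w1 * qnorm_upper(p1) + weights$w2 * qnorm_upper(p2)
  list(z = z, p = stats::pnorm(z, lower.tail = FALSE))
}

#' Fisher product combination of two stage-wise p-values
#'
#' Rejects when `p1 * p2 <= c_alpha` with `c_alpha = exp(-q/2)` and `q` the
#' upper-alpha quantile of the chi-squared distribution with 4 df (the null
#' distribution of `-2 log(p1 p2)` for independent uniforms).
#'
#' @param p1,p2 Stage-wise p-values (vectorised).
#' @param alpha One-sided test level in (0, 1).
#' @return List with the rejection decision(s) `reject` and the critical
#'   product value `critical`.
#' @export
fisher_combine <- function(p1, p2, alpha = 0.025) {
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must lie in (0, 1)")
  crit <- exp(-stats::qchisq(1 - alpha, df = 4) / 2)
  list(reject = (p1 * p2) <= crit, critical = crit)
}

# P(Z_1 <= z, ..., Z_m <= z) for equicorrelated standard normals with common
# correlation r in [0, 1), via the one-factor reduction
#   Phi_m(z; r) = int phi(x) Phi((z - sqrt(r) x) / sqrt(1 - r))^m dx
# computed with fixed Gauss-Legendre quadrature: deterministic, vectorised
# over z, absolute error well below 1e-8 for m <= 8.
gauss_legendre_cache <- new.env(parent = emptyenv())
gl_nodes <- function(nq = 128L, lim = 8.5) {
  key <- paste0("q", nq)
  if (!is.null(gauss_legendre_cache[[key]])) return(gauss_legendre_cache[[key]])
  # Golub-Welsch on [-1, 1], rescaled to [-lim, lim]
  i <- seq_len(nq - 1)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, nq, nq)
  J[cbind(i, i + 1)] <- b
  J[cbind(i + 1, i)] <- b
  ee <- eigen(J, symmetric = TRUE)
  x <- ee$values * lim
  w <- 2 * ee$vectors[1, ]^2 * lim
  out <- list(x = x, wphi = w * stats::dnorm(x))
  gauss_legendre_cache[[key]] <- out
  out
}

# vectorised over z; scalar m >= 1, scalar r in [0, 1)
pnorm_equicorr <- function(z, m, r) {
  if (m == 1) return(stats::pnorm(z))
  if (r < 0 || r >= 1) stop("common correlation must lie in [0, 1)")
  g <- gl_nodes()
  s <- sqrt(1 - r)
  out <- numeric(length(z))
  # process in blocks to bound the nodes x values working matrix
  blk <- 8192L
  for (i0 in seq(1L, length(z), by = blk)) {
    i1 <- min(i0 + blk - 1L, length(z))
    u <- outer(-sqrt(r) * g$x, z[i0:i1], "+") / s
    out[i0:i1] <- as.numeric(crossprod(g$wphi, stats::pnorm(u)^m))
  }
  out
}

#' Dunnett p-value for an intersection hypothesis
#'
#' One-sided multiplicity-adjusted p-value for the intersection of `m`
#' comparisons with a common control: `p = 1 - P(Z_1 <= zmax, ..., Z_m <=
#' zmax)` under an `m`-variate standard normal with common correlation
#' `1/(1 + lambda)`, where `zmax` is the largest observed statistic. Reduces
#' to `1 - pnorm(z)` for `m = 1`.
#'
#' @param z_values Statistics of the comparisons in the intersection.
#' @param lambda Control:experimental allocation ratio (default 1).
#' @return The intersection p-value.
#' @export
dunnett_pvalue <- function(z_values, lambda = 1) {
  if (length(z_values) < 1) stop("at least one statistic is required")
  if (lambda <= 0) stop("`lambda` must be positive")
  zmax <- max(z_values)
  1 - pnorm_equicorr(zmax, length(z_values), 1 / (1 + lambda))
}

#' Simes intersection p-value
#'
#' `p = min_j m * p_(j) / j` over the ordered p-values; never larger than the
#' Bonferroni p-value.
#'
#' @param p_values Elementary one-sided p-values.
#' @return The intersection p-value.
#' @export
simes_pvalue <- function(p_values) {
  m <- length(p_values)
  if (m < 1) stop("at least one p-value is required")
  ps <- sort(p_values)
  min(m * ps / seq_len(m))
}

#' Bonferroni intersection p-value
#'
#' @param p_values Elementary one-sided p-values.
#' @return `min(1, m * min(p))`.
#' @export
bonferroni_pvalue <- function(p_values) {
  m <- length(p_values)
  if (m < 1) stop("at least one p-value is required")
  min(1, m * min(p_values))
}

#' Spiessens-Debois p-value for the subgroup/full-population intersection
#'
#' Dunnett-type test exploiting the correlation `sqrt(I_S / I_F)` induced by
#' nesting the subgroup in the full population: `p = 1 - Phi_2(zmax, zmax;
#' sqrt(info_ratio))`. At `info_ratio = 1` it equals the univariate
#' `1 - pnorm(zmax)`; as `info_ratio -> 0` it approaches `1 - pnorm(zmax)^2`.
#'
#' @param z_s,z_f Subgroup and full-population statistics (canonical
#'   orientation, larger is better).
#' @param info_ratio Information fraction `I_S / I_F` in (0, 1].
#' @return The intersection p-value.
#' @export
spiessens_debois_pvalue <- function(z_s, z_f, info_ratio) {
  if (any(info_ratio <= 0 | info_ratio > 1))
    stop("`info_ratio` must lie in (0, 1]")
  sd_p_vec(z_s, z_f, info_ratio[1])
}

# vectorised engines used by the simulator -----------------------------------

# Dunnett intersection p for a vector of per-replicate maxima
dunnett_p_vec <- function(zmax, m, r) {
  if (m == 0) return(rep(1, length(zmax)))
  1 - pnorm_equicorr(zmax, m, r)
}

# Spiessens-Debois intersection p for vectors, scalar correlation sqrt(ratio)
sd_p_vec <- function(z_s, z_f, info_ratio) {
  zmax <- pmax(z_s, z_f)
  r <- sqrt(info_ratio)
  if (r > 1 - 1e-12) return(1 - stats::pnorm(zmax))
  1 - pnorm_equicorr(zmax, 2, r)
}

simes2 <- function(pa, pb) pmin(2 * pmin(pa, pb), pmax(pa, pb))
bonf2 <- function(pa, pb) pmin(1, 2 * pmin(pa, pb))

#' Closed testing procedure for a two-stage treatment-selection design
#'
#' Tests every intersection hypothesis over the K experimental arms with a
#' Dunnett test at each stage, combines the stage-wise p-values with the
#' inverse normal (or Fisher) combination function, and rejects an elementary
#' hypothesis `H_k` if and only if every intersection containing `k` is
#' rejected. Following the rule of Posch et al., the stage-1 p-value of an
#' intersection `K` always uses all arms of `K` (all have stage-1 data) while
#' the stage-2 p-value is computed over `K` intersected with the selected set;
#' when that intersection is empty and follow-up is discontinued, the stage-2
#' p-value is 1. Dropped hypotheses are never rejected.
#'
#' @param z1 Stage-1 final-outcome statistics, one per arm.
#' @param z2 Stage-2 final-outcome increment statistics, one per arm (entries
#'   for dropped arms are ignored under `followup = "discontinued"`, and must
#'   be present under `"complete"`).
#' @param selected Integer vector of arms carried into stage 2 (possibly
#'   empty, meaning a futility stop: nothing is rejected).
#' @param method Combination function: `"invnorm"` or `"fisher"`.
#' @param weights A [combination_weights()] object.
#' @param alpha One-sided test level.
#' @param followup `"discontinued"` (dropped arms contribute no stage-2 data)
#'   or `"complete"` (stage-2 statistics exist for all arms).
#' @param lambda Allocation ratio for the Dunnett correlation `1/(1+lambda)`.
#' @return An object of class `closed_test_result`: a data frame of
#'   intersections (`subset`, `p1`, `p2`, statistic, rejection) plus the
#'   elementary rejection indicator per arm.
#' @export
closed_test <- function(z1, z2, selected,
                        method = c("invnorm", "fisher"),
                        weights, alpha = 0.025,
                        followup = c("discontinued", "complete"),
                        lambda = 1) {
  method <- match.arg(method)
  followup <- match.arg(followup)
  K <- length(z1)
  if (K < 1) stop("at least one arm is required")
  selected <- as.integer(selected)
  if (length(selected) && (min(selected) < 1 || max(selected) > K))
    stop("`selected` must index arms 1..K")
  if (followup == "complete" && any(!is.finite(z2)))
    stop("complete follow-up requires stage-2 statistics for every arm")
  if (any(!is.finite(z2[selected])))
    stop("missing stage-2 statistics for a selected arm")
  r <- 1 / (1 + lambda)
  subsets <- lapply(seq_len(2^K - 1), function(i) which(bitwAnd(i, 2^(seq_len(K) - 1)) > 0))
  p1 <- p2 <- cz <- numeric(length(subsets))
  rej <- logical(length(subsets))
  crit <- stats::qnorm(1 - alpha)
  for (i in seq_along(subsets)) {
    s <- subsets[[i]]
    p1[i] <- 1 - pnorm_equicorr(max(z1[s]), length(s), r)
    s2 <- if (followup == "complete") s else intersect(s, selected)
    p2[i] <- if (length(s2) == 0) 1 else 1 - pnorm_equicorr(max(z2[s2]), length(s2), r)
    if (method == "invnorm") {
      cz[i] <- inverse_normal_combine(p1[i], p2[i], weights)$z
      rej[i] <- cz[i] >= crit
    } else {
      cz[i] <- p1[i] * p2[i]
      rej[i] <- fisher_combine(p1[i], p2[i], alpha)$reject
    }
  }
  elementary <- vapply(seq_len(K), function(k) {
    k %in% selected &&
      all(rej[vapply(subsets, function(s) k %in% s, logical(1))])
  }, logical(1))
  structure(list(
    intersections = data.frame(
      subset = vapply(subsets, function(s) paste(s, collapse = ","), character(1)),
      p1 = p1, p2 = p2, statistic = cz, reject = rej),
    elementary = elementary,
    selected = selected, method = method, alpha = alpha),
    class = "closed_test_result")
}

#' @export
print.closed_test_result <- function(x, ...) {
  cat("Closed test (", x$method, ", alpha = ", x$alpha, ")\n", sep = "")
  print(x$intersections, row.names = FALSE, digits = 4)
  cat("selected arms:", if (length(x$selected)) paste(x$selected, collapse = " ")
      else "none (futility)", "\n")
  cat("elementary hypotheses rejected:",
      if (any(x$elementary)) paste(which(x$elementary), collapse = " ") else "none",
      "\n")
  invisible(x)
}
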