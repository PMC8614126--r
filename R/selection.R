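#' Interim selection rule
#'
#' For treatment-selection designs the rule maps the stage-1 early-outcome
#' statistics to the set of arms carried into stage 2: `"all"`, `"best1"`,
#' `"best2"`, `"best3"`, the epsilon rule (all arms within `epsilon` of the
#' maximum), `"random1"` (one arm uniformly at random) or `"threshold"` (all
#' arms at or above `thresh`; an empty set is a futility stop). For subgroup
#' designs the rule is `"threshold"` (on the difference of the full and
#' subgroup statistics, limits `selim`) or `"futility"` (four-branch rule with
#' per-population limits `selim`).
#'
#' @param kind Rule name (see Description).
#' @param epsilon Nonnegative margin for the epsilon rule. `epsilon = 0`
#'   reduces to `"best1"`; a very large value to `"all"`.
#' @param thresh Threshold for the treatment-selection threshold rule.
#' @param selim Length-2 limits `(l1, l2)` for the subgroup rules.
#' @return An object of class `selection_rule`.
#' @export
selection_rule <- function(kind = c("all", "best1", "best2", "best3",
                                    "epsilon", "random1", "threshold",
                                    "futility"),
                           epsilon = 1, thresh = 1, selim = c(0, 0)) {
  kind <- match.arg(kind)
  if (!is.finite(epsilon) || epsilon < 0) stop("`epsilon` must be finite and >= 0")
  if (kind %in% c("threshold", "futility") && length(selim) != 2)
    stop("`selim` must supply both limits (l1, l2)")
  structure(list(kind = kind, epsilon = epsilon, thresh = thresh,
                 selim = selim), class = "selection_rule")
}

#' Select treatment arms at the interim analysis
#'
#' Applies a [selection_rule()] to the stage-1 early-outcome statistics
#' (canonical orientation, larger is better). Ties in the best-M rules and in
#' the maximum are broken uniformly at random using the current RNG state.
#'
#' @param z_early Stage-1 early statistics, one per arm.
#' @param rule A [selection_rule()].
#' @return Integer vector of selected arms; empty means a futility stop.
#' @examples
#' select_treatments(c(1.0, 2.0, 1.9), selection_rule("epsilon", epsilon = 0.2))
#' @export
select_treatments <- function(z_early, rule) {
  stopifnot(inherits(rule, "selection_rule"))
  K <- length(z_early)
  if (K < 1) stop("at least one arm is required")
  pick_best <- function(m) {
    if (m > K) stop("cannot select more arms than exist")
    # random tie-break: secondary sort key is uniform noise
    sort(order(-z_early, stats::runif(K))[seq_len(m)])
  }
  switch(rule$kind,
         all = seq_len(K),
         best1 = pick_best(1),
         best2 = pick_best(2),
         best3 = pick_best(3),
         epsilon = which(z_early >= max(z_early) - rule$epsilon),
         random1 = sample.int(K, 1),
         threshold = which(z_early >= rule$thresh),
         stop("rule `", rule$kind, "` is not a treatment-selection rule"))
}

#' Population selection by the threshold rule (subgroup designs)
#'
#' For the difference `Delta = z_f - z_s` of the full-population and subgroup
#' statistics (canonical orientation): continue in the subgroup only when
#' `Delta <= l1`, in the full population only when `Delta > l2`, otherwise in
#' both. Wide limits such as `(-10, 10)` always keep both; `(0, 0)` keeps only
#' the population with the larger interim statistic (ties go to the subgroup).
#'
#' @param z_s,z_f Subgroup and full-population interim statistics.
#' @param selim Limits `(l1, l2)` with `l1 <= l2`, in standard-deviation units.
#' @return One of `"subgroup-only"`, `"full-only"`, `"both"`.
#' @export
select_populations_threshold <- function(z_s, z_f, selim) {
  if (length(selim) != 2 || selim[1] > selim[2])
    stop("`selim` must be (l1, l2) with l1 <= l2")
  delta <- z_f - z_s
  if (delta <= selim[1]) "subgroup-only"
  else if (delta > selim[2]) "full-only"
  else "both"
}

#' Population selection by the futility rule (subgroup designs)
#'
#' Operates on statistics on the natural time-to-event scale, where smaller
#' values favour the treatment: continue with a co-primary analysis when
#' `s_s < l1` and `s_f < l2`; in the subgroup alone when only `s_s < l1`; in
#' the full population alone when only `s_f < l2`; otherwise stop for
#' futility.
#'
#' @param s_s,s_f Subgroup and full-population interim statistics on the
#'   natural (smaller-is-better) scale.
#' @param selim Limits `(l1, l2)` on the same scale.
#' @return One of `"both"`, `"subgroup-only"`, `"full-only"`, `"futility"`.
#' @export
select_populations_futility <- function(s_s, s_f, selim) {
  if (length(selim) != 2) stop("`selim` must supply both limits")
  ok_s <- s_s < selim[1]
  ok_f <- s_f < selim[2]
  if (ok_s && ok_f) "both"
  else if (ok_s) "subgroup-only"
  else if (ok_f) "full-only"
  else "futility"
}
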