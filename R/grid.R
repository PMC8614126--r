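# apply a single sweep value to a design field; selim values are length-2
update_design_field <- function(design, key, value) {
  if (key %in% c("thresh", "epsilon")) {
    design$rule[[key]] <- value
  } else if (key == "selim") {
    design$rule$selim <- value
  } else if (key %in% c("n.stage1", "n.stage2", "n.enrich")) {
    p <- design$plan
    p[[sub("^n\\.", "", key)]] <- value
    design$plan <- sample_size_plan(p$stage1, p$stage2, enrich = p$enrich,
                                    allocation = p$allocation,
                                    prevalence = p$prevalence,
                                    prevalence_fixed = p$prevalence_fixed)
    design$weights <- combination_weights(design$plan$stage1,
                                          design$plan$stage2)
  } else if (key %in% c("level", "nsim")) {
    design[[key]] <- value
  } else {
    stop("cannot sweep over `", key, "`")
  }
  design
}

#' Evaluate a design over a parameter grid
#'
#' Runs one simulation per grid point (the cross product of the sweep values)
#' with a shared root seed, so points differ only through the swept
#' parameters. Sweepable keys: `thresh`, `epsilon`, `selim` (a list of
#' length-2 limit pairs), `n.stage1`, `n.stage2`, `n.enrich`, `level`,
#' `nsim`. Infeasible points are reported in the `error` column rather than
#' aborting the sweep.
#'
#' @param design A design object.
#' @param sweep Named list of value vectors (for `selim`, a list of pairs).
#' @param nsim,seed Optional overrides applied to every grid point.
#' @return A data frame with one row per grid point: the swept values, the
#'   selection/futility percentages, the power (probability of rejecting at
#'   least one elementary hypothesis counted by `ptest`, or the subgroup/full
#'   union), and the expected sample size.
#' @export
run_grid <- function(design, sweep, nsim = NULL, seed = NULL) {
  stopifnot(inherits(design, "design_spec"), is.list(sweep),
            !is.null(names(sweep)))
  idx <- expand.grid(lapply(sweep, seq_along))
  extra_names <- if (inherits(design, "treatsel_design"))
    c("continue", "futility") else c("subgroup", "full", "both", "futility")
  na_extra <- stats::setNames(rep(list(NA_real_), length(extra_names)),
                              extra_names)
  rows <- lapply(seq_len(nrow(idx)), function(i) {
    d <- design
    label <- list()
    for (key in names(sweep)) {
      value <- sweep[[key]][[idx[i, key]]]
      label[[key]] <- paste(value, collapse = ",")
      d <- tryCatch(update_design_field(d, key, value),
                    error = function(e) e)
      if (inherits(d, "error")) break
    }
    s <- if (inherits(d, "error")) d
         else tryCatch(simulate_design(d, nsim = nsim, seed = seed),
                       error = function(e) e)
    if (inherits(s, "error"))
      return(c(label, na_extra,
               list(power = NA_real_, expected_n = NA_real_,
                    error = conditionMessage(s))))
    extra <- if (inherits(s, "treatsel_summary")) {
      list(continue = 100 * sum(s$count_total) / s$nsim,
           futility = 100 * s$futility / s$nsim)
    } else {
      list(subgroup = 100 * s$table["sub", "n"] / s$nsim,
           full = 100 * s$table["full", "n"] / s$nsim,
           both = 100 * s$table["both", "n"] / s$nsim,
           futility = 100 * s$futility / s$nsim)
    }
    c(label, extra,
      list(power = 100 * s$sim_reject / s$nsim, expected_n = s$expected_n,
           error = NA_character_))
  })
  do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
}
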