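# flat config keys understood by parse_config, mirroring the simulator
# argument names
CONFIG_KEYS <- c("design", "n.stage1", "n.stage2", "n.enrich",
                 "effect.early", "effect.final", "control.early",
                 "control.final", "outcome.early", "outcome.final", "corr",
                 "sprev", "sprev.fixed", "select", "epsilon", "thresh",
                 "selim", "ptest", "method", "fu", "weight", "level",
                 "nsim", "seed")

#' Parse a design configuration from a YAML file or a named list
#'
#' Flat key/value configuration with the usual simulator argument names
#' (`n.stage1`, `effect.early`, `outcome.final`, `corr`, `sprev`, `select`,
#' `selim`, `epsilon`, `thresh`, `ptest`, `method`, `fu`, `weight`, `level`,
#' `nsim`, `seed`) plus `design: treatsel` or `design: subpop`. Defaults
#' (level 0.025, nsim 1000, weights from the sample-size plan, fixed
#' prevalence) are applied and reported via messages.
#'
#' @param config Path to a YAML file, or a named list of the same keys.
#' @param quiet Suppress the applied-defaults messages.
#' @return A [treatsel_design()] or [subpop_design()].
#' @export
parse_config <- function(config, quiet = FALSE) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config) || length(config) == 0)
    stop("empty configuration; required keys: design, n.stage1, n.stage2, ",
         "effect.early, effect.final (plus sprev for subgroup designs)")
  unknown <- setdiff(names(config), CONFIG_KEYS)
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  required <- c("design", "n.stage1", "n.stage2", "effect.early", "effect.final")
  missing_keys <- setdiff(required, names(config))
  if (length(missing_keys))
    stop("missing required configuration keys: ",
         paste(missing_keys, collapse = ", "))
  design_kind <- match.arg(config$design, c("treatsel", "subpop"))
  note <- function(key, value) {
    if (!quiet)
      message("config default applied: ", key, " = ",
              paste(value, collapse = " "))
  }
  get_or <- function(key, default) {
    if (is.null(config[[key]])) { note(key, default); default }
    else config[[key]]
  }
  n <- list(stage1 = config$n.stage1, stage2 = config$n.stage2,
            enrich = config$n.enrich)
  effect <- list(early = as.numeric(config$effect.early),
                 final = as.numeric(config$effect.final))
  outcome <- list(early = get_or("outcome.early", "N"),
                  final = get_or("outcome.final", "N"))
  corr <- get_or("corr", 0)
  level <- get_or("level", 0.025)
  nsim <- get_or("nsim", 1000)
  seed <- config$seed
  if (is.null(config$weight)) note("weight", "n1/(n1+n2)")
  if (design_kind == "treatsel") {
    if (!is.null(config$sprev))
      stop("`sprev` applies to subgroup designs only")
    if (outcome$early == "T" || outcome$final == "T") {
      # minus-log-hazard dialect: a control entry of 1 with ratios below it is
      # the signature of hazard ratios fed to the wrong driver
      if (effect$early[1] == 1 || effect$final[1] == 1)
        stop("treatment-selection T effects are minus log hazard rates, ",
             "not hazard ratios; use design: subpop for hazard ratios")
    }
    treatsel_design(n = n[c("stage1", "stage2")], effect = effect,
                    outcome = outcome, corr = corr,
                    select = get_or("select", 0),
                    epsilon = get_or("epsilon", 1),
                    thresh = get_or("thresh", 1),
                    ptest = get_or("ptest", seq_len(length(effect$early) - 1)),
                    method = get_or("method", "invnorm"),
                    fu = get_or("fu", FALSE), weight = config$weight,
                    level = level, nsim = nsim, seed = seed)
  } else {
    if (is.null(config$sprev))
      stop("subgroup designs require the subgroup prevalence `sprev`")
    subpop_design(n = n, effect = effect,
                  control = list(early = config$control.early,
                                 final = config$control.final),
                  sprev = config$sprev,
                  sprev_fixed = get_or("sprev.fixed", TRUE),
                  outcome = outcome, corr = corr,
                  select = get_or("select", "futility"),
                  selim = get_or("selim", c(0, 0)),
                  method = get_or("method", "CT-SD"),
                  weight = config$weight, level = level, nsim = nsim,
                  seed = seed)
  }
}

#' List the shipped example design configurations
#'
#' @return Character vector of fixture names usable with [load_fixture()].
#' @export
list_fixtures <- function() {
  files <- list.files(system.file("extdata", package = "seamsim"),
                      pattern = "\\.yaml$")
  sub("\\.yaml$", "", files)
}

#' Load a shipped example design configuration
#'
#' The registry contains the worked examples: a multi-arm COPD dose-selection
#' trial (always-best-two, threshold selection, and a binary-final variant)
#' and an oncology time-to-event enrichment trial.
#'
#' @param name Fixture name, one of [list_fixtures()].
#' @param quiet Suppress applied-default messages.
#' @return A design object.
#' @export
load_fixture <- function(name, quiet = TRUE) {
  path <- system.file("extdata", paste0(name, ".yaml"), package = "seamsim")
  if (path == "")
    stop("unknown fixture `", name, "`; available: ",
         paste(list_fixtures(), collapse = ", "))
  parse_config(path, quiet = quiet)
}

#' Simulate a design (generic driver)
#'
#' Dispatches to [simulate_treatsel()] or [simulate_subpop()].
#'
#' @param design A design object from [treatsel_design()], [subpop_design()]
#'   or [parse_config()].
#' @param nsim,seed Optional overrides.
#' @return A simulation summary.
#' @export
simulate_design <- function(design, nsim = NULL, seed = NULL) {
  if (inherits(design, "treatsel_design")) simulate_treatsel(design, nsim, seed)
  else if (inherits(design, "subpop_design")) simulate_subpop(design, nsim, seed)
  else stop("`design` must be a treatsel_design or subpop_design")
}
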