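# round to d decimals and drop trailing zeros, matching the 1-dp/2-dp style
# of the simulation reports (e.g. "3", "3.7", "0.87")
fmt_num <- function(x, d = 1) {
  vapply(x, function(v) format(round(v, d), trim = TRUE, scientific = FALSE),
         character(1))
}

pct <- function(n, nsim, d = 2) fmt_num(100 * n / nsim, d)

#' @export
print.treatsel_summary <- function(x, ...) {
  K <- x$model$K
  cat("simulation of test statistics:\n")
  mn <- x$model$mean_natural
  cat("expectation early =", paste(fmt_num(mn[seq_len(K)]), collapse = " "), "\n")
  cat("expectation final stage 1 =",
      paste(fmt_num(mn[K + seq_len(K)]), collapse = " "),
      "and stage 2 =", paste(fmt_num(mn[2 * K + seq_len(K)]), collapse = " "),
      "\n")
  cat("weights: stage 1 =", fmt_num(x$weights$w1, 2),
      "and stage 2 =", fmt_num(x$weights$w2, 2), "\n\n")

  cat("number of treatments selected at stage 1:\n")
  cnt <- x$count_total
  df <- data.frame(n = cnt, `%` = pct(cnt, x$nsim), check.names = FALSE,
                   row.names = seq_len(K))
  df <- rbind(df, Total = data.frame(n = sum(cnt), `%` = pct(sum(cnt), x$nsim),
                                     check.names = FALSE))
  print(df)
  cat("\ntreatment selection at stage 1:\n")
  print(data.frame(n = x$select_total, `%` = pct(x$select_total, x$nsim),
                   check.names = FALSE, row.names = seq_len(K)))
  cat("\nhypothesis rejection at study endpoint:\n")
  print(data.frame(n = x$reject_total, `%` = pct(x$reject_total, x$nsim),
                   check.names = FALSE,
                   row.names = paste0("H", seq_len(K))))
  cat("\nreject ", paste0("H", x$design$ptest, collapse = " and/or "), " = ",
      x$sim_reject, " : ", pct(x$sim_reject, x$nsim), "%\n", sep = "")
  cat("expected total sample size =", fmt_num(x$expected_n, 1), "\n")
  invisible(x)
}

#' @export
print.subpop_summary <- function(x, ...) {
  h <- x$header
  cat("simulation of test statistics:\n")
  cat("expectation early: sub-pop =", fmt_num(h$early[1], 2),
      ": full-pop =", fmt_num(h$early[2], 2), "\n")
  cat("expectation final stage 1: sub-pop =", fmt_num(h$final1[1], 2),
      ": full-pop =", fmt_num(h$final1[2], 2), "\n")
  cat("expectation final stage 2: sub-pop only =", fmt_num(h$final2_only[1], 2),
      ": full-pop only =", fmt_num(h$final2_only[2], 2), "\n")
  cat("expectation final stage 2, both groups selected: sub-pop =",
      fmt_num(h$final2_both[1], 2), ": full-pop =",
      fmt_num(h$final2_both[2], 2), "\n")
  cat("weights: stage 1 =", fmt_num(x$weights$w1, 2),
      "and stage 2 =", fmt_num(x$weights$w2, 2), "\n\n")

  cat("hypotheses rejected and group selection options at stage 1 (n):\n")
  tab <- x$table
  counts <- rbind(tab, total = colSums(tab))
  printm <- cbind(apply(counts, 2, function(col) format(as.integer(col))),
                  `n%` = c(fmt_num(100 * tab[, "n"] / x$nsim, 2), "-"))
  pct_row <- c(fmt_num(100 * colSums(tab)[1:4] / x$nsim, 2),
               fmt_num(100 * sum(tab[, "n"]) / x$nsim, 2), "-")
  printm <- rbind(printm, `%` = pct_row)
  dimnames(printm) <- list(c("sub", "full", "both", "total", "%"),
                           c("Hs", "Hf", "Hs+Hf", "Hs+f", "n", "n%"))
  print(printm, quote = FALSE)
  cat("reject Hs and/or Hf = ", pct(x$sim_reject, x$nsim), "%\n", sep = "")
  invisible(x)
}

summary_to_list <- function(x) {
  if (inherits(x, "treatsel_summary")) {
    list(design = "treatment", nsim = x$nsim,
         expectation_early = unname(x$model$mean_natural[seq_len(x$model$K)]),
         expectation_final_stage1 =
           unname(x$model$mean_natural[x$model$K + seq_len(x$model$K)]),
         expectation_final_stage2 =
           unname(x$model$mean_natural[2 * x$model$K + seq_len(x$model$K)]),
         weights = c(x$weights$w1, x$weights$w2),
         count_total = x$count_total, futility = x$futility,
         select_total = unname(x$select_total),
         reject_total = unname(x$reject_total),
         ptest = x$design$ptest, sim_reject = x$sim_reject,
         expected_n = x$expected_n)
  } else {
    list(design = "subgroup", nsim = x$nsim,
         expectation_early = unname(x$header$early),
         expectation_final_stage1 = unname(x$header$final1),
         expectation_final_stage2_only = unname(x$header$final2_only),
         expectation_final_stage2_both = unname(x$header$final2_both),
         weights = c(x$weights$w1, x$weights$w2),
         table = as.data.frame(x$table), futility = x$futility,
         reject_hs = x$reject_hs, reject_hf = x$reject_hf,
         reject_both = x$reject_both,
         reject_intersection = x$reject_intersection,
         sim_reject = x$sim_reject, expected_n = x$expected_n)
  }
}

#' Render a simulation summary as text, JSON or CSV
#'
#' The text format reproduces the console report (model expectations, weights,
#' selection and rejection tables); JSON and CSV are lossless renderings of
#' the accumulated counts.
#'
#' @param summary A simulation summary.
#' @param format One of `"text"`, `"json"`, `"csv"`.
#' @return A character vector (text lines), a JSON string, or a data frame of
#'   key/value rows (csv); use [write_report()] to write to a file.
#' @export
render_report <- function(summary, format = c("text", "json", "csv")) {
  format <- match.arg(format)
  stopifnot(inherits(summary, "simulation_summary"))
  if (format == "text") return(utils::capture.output(print(summary)))
  lst <- summary_to_list(summary)
  if (format == "json")
    return(jsonlite::toJSON(lst, auto_unbox = TRUE, digits = NA))
  flat <- unlist(lst)
  data.frame(key = names(flat), value = unname(as.character(flat)),
             stringsAsFactors = FALSE)
}

#' Write a rendered report to a file
#'
#' @inheritParams render_report
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_report <- function(summary, path, format = c("text", "json", "csv")) {
  format <- match.arg(format)
  out <- render_report(summary, format)
  if (format == "csv") utils::write.csv(out, path, row.names = FALSE)
  else writeLines(as.character(out), path)
  invisible(path)
}
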