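# End-to-end analysis pipeline mirroring the standard joint-segregation
# workflow: descriptive summary -> fit the model set -> rank by AIC ->
# goodness-of-fit on the two lowest-AIC candidates -> select the winner ->
# report first- and second-order genetic parameters of the winner.

#' Run the full joint segregation analysis
#'
#' Steps: (1) descriptive summary per generation; (2) likelihood/AIC table
#' over the requested model set; (3) the two lowest-AIC models advance to
#' the goodness-of-fit suitability tests; (4) the winner is the candidate
#' with the fewest significant adequacy statistics at `alpha`, ties broken
#' by lower AIC, then by fewer free parameters; (5) first- and second-order
#' genetic parameter report for the winner.
#'
#' @param dataset A [six_gen_dataset()] or a path to a CSV readable by
#'   [read_dataset()].
#' @param models Character vector of model codes (default: all 24).
#' @param config A [fit_config()].
#' @param alpha Significance level for the adequacy statistics.
#' @param out_dir If non-`NULL`, the summary, AIC table, adequacy table and
#'   parameter reports are written there as CSV files plus a plain-text
#'   report, all derived deterministically from `config$seed`.
#' @return List of class `seg_analysis`: `summary`, `aic_table`,
#'   `gof_table`, `candidates`, `winner` (model code), `fit` (the winning
#'   `segfit`), `first_order`, `second_order`, `alpha`, `config`.
#' @export
run_analysis <- function(dataset, models = model_registry()$name,
                         config = fit_config(), alpha = 0.05,
                         out_dir = NULL) {
  if (is.character(dataset)) dataset <- read_dataset(dataset)
  stopifnot(inherits(dataset, "six_gen_dataset"))
  summary_tab <- summarize_dataset(dataset)
  ranked <- fit_models(dataset, models = models, config = config)
  if (!any(ranked$table$converged)) {
    stop("no model fit converged; see the AIC table for diagnostics",
         call. = FALSE)
  }
  candidates <- utils::head(ranked$table$model, 2)
  gof_tab <- do.call(rbind, lapply(candidates, function(mn) {
    gof_test(ranked$fits[[mn]], dataset)
  }))
  n_sig <- vapply(candidates, function(mn) {
    sum(gof_tab$p_value[gof_tab$model == mn] < alpha)
  }, numeric(1))
  aic <- ranked$table$aic[match(candidates, ranked$table$model)]
  k <- ranked$table$k[match(candidates, ranked$table$model)]
  winner <- candidates[order(n_sig, aic, k)][1]
  wfit <- ranked$fits[[winner]]
  fo <- first_order(wfit)
  so <- second_order(wfit, dataset)
  res <- structure(list(
    summary = summary_tab, aic_table = ranked$table, gof_table = gof_tab,
    candidates = data.frame(model = candidates, n_significant = n_sig,
                            aic = aic, k = k, stringsAsFactors = FALSE),
    winner = winner, fit = wfit, first_order = fo, second_order = so,
    alpha = alpha, config = config), class = "seg_analysis")
  if (!is.null(out_dir)) write_analysis(res, out_dir)
  res
}

#' Write the report bundle of a pipeline run
#'
#' @param analysis A [run_analysis()] result.
#' @param out_dir Output directory (created if absent).
#' @return `out_dir`, invisibly.
#' @export
write_analysis <- function(analysis, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(analysis$summary, file.path(out_dir, "summary.csv"),
                   row.names = FALSE)
  utils::write.csv(analysis$aic_table, file.path(out_dir, "aic_table.csv"),
                   row.names = FALSE)
  utils::write.csv(analysis$gof_table, file.path(out_dir, "gof_table.csv"),
                   row.names = FALSE)
  fo <- analysis$first_order
  utils::write.csv(
    data.frame(parameter = c(names(fo$effects), "dominance_degree"),
               estimate = c(unname(fo$effects), fo$dominance_degree)),
    file.path(out_dir, "first_order.csv"), row.names = FALSE)
  utils::write.csv(analysis$second_order,
                   file.path(out_dir, "second_order.csv"), row.names = FALSE)
  txt <- utils::capture.output(print(analysis))
  writeLines(txt, file.path(out_dir, "report.txt"))
  invisible(out_dir)
}

#' @export
print.seg_analysis <- function(x, ...) {
  cat("Joint segregation analysis\n")
  cat("  seed:", x$config$seed, " starts:", x$config$n_starts,
      " tol:", format(x$config$tol), " alpha:", x$alpha, "\n")
  cat("  models fitted:", nrow(x$aic_table), "\n\n")
  cat("Descriptive summary:\n")
  print(cbind(x$summary[1], round(x$summary[-1], 2)))
  cat("\nTop of the AIC ranking:\n")
  tab <- utils::head(x$aic_table, 5)
  tab[c("loglik", "aic")] <- round(tab[c("loglik", "aic")], 2)
  print(tab)
  cat("\nCandidate adequacy (significant statistics at alpha):\n")
  print(x$candidates)
  cat("\nSelected model:", x$winner, "\n\n")
  print(x$first_order)
  cat("\nSecond-order parameters:\n")
  so <- x$second_order
  so[-1] <- round(so[-1], 2)
  print(so)
  invisible(x)
}
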