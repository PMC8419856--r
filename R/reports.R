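# Report writers. Every number written here is produced by evaluate() /
# the probability engine; the writers only format. Probabilities and other
# reals are printed to 6 decimals in the csv files; the returned data
# frames keep full precision.

.pr_write_csv <- function(df, path) {
  ok <- tryCatch({
    utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    .pr_stop("pr_io_error", "cannot write '%s': %s", path, conditionMessage(ok))
  }
  invisible(path)
}

#' Write per-run solution tables
#'
#' One two-column table (`id`, `selected`) per repetition, named
#' `output_rNNNN.csv`, plus `output_best.csv`, a copy of the repetition
#' with the lowest objective.  Rows are ordered by planning-unit id.
#'
#' @param run_result a `pr_run_result` from [run_batch()].
#' @param directory destination directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_solution_outputs <- function(run_result, directory) {
  stopifnot(inherits(run_result, "pr_run_result"))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (i in seq_len(run_result$repetitions)) {
    df <- data.frame(id = run_result$pu_ids, selected = run_result$solutions[[i]])
    paths <- c(paths, .pr_write_csv(df, file.path(directory, sprintf("output_r%04d.csv", i))))
  }
  best <- data.frame(id = run_result$pu_ids,
                     selected = run_result$solutions[[run_result$best_index]])
  paths <- c(paths, .pr_write_csv(best, file.path(directory, "output_best.csv")))
  invisible(paths)
}

#' Read a solution table back into a selection vector
#'
#' @param path a file written by [write_solution_outputs()].
#' @return integer 0/1 vector ordered by planning-unit id.
#' @export
read_solution_output <- function(path) {
  df <- utils::read.csv(path)
  for (col in c("id", "selected")) {
    if (!col %in% names(df)) {
      .pr_stop("pr_format_error", "file '%s' lacks column '%s'", path, col)
    }
  }
  as.integer(df$selected[order(df$id)])
}

#' Write the summed solution (selection frequency)
#'
#' @param run_result a `pr_run_result`.
#' @param directory destination directory.
#' @return invisibly, the path of `output_ssoln.csv` (`id`, `count`).
#' @export
summed_solution <- function(run_result, directory) {
  stopifnot(inherits(run_result, "pr_run_result"))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  df <- data.frame(id = run_result$pu_ids,
                   count = as.integer(run_result$selection_frequency))
  .pr_write_csv(df, file.path(directory, "output_ssoln.csv"))
}

#' Extended missing-values report
#'
#' One row per feature describing how the given solution serves it: target
#' and held amount, representation shortfall and met flag, and the
#' probability diagnostics (mode, probability target, capture probability,
#' expected amount, variance, z-score, probability shortfall, met flag).
#' Values are those computed by [evaluate()] with the engine in `config`.
#'
#' @param problem a `pr_problem`.
#' @param solution 0/1 selection vector.
#' @param config a [run_config()].
#' @param directory destination directory, or `NULL` to skip writing.
#' @return the report data frame (invisibly when written to disk).
#' @export
missing_values_report <- function(problem, solution, config = run_config(),
                                  directory = NULL) {
  b <- evaluate(problem, solution, config)
  pf <- b$per_feature
  df <- data.frame(
    id = pf$feature_id,
    name = problem$features$name,
    target = pf$target,
    held = pf$held,
    shortfall = pf$shortfall,
    target_met = pf$held >= pf$target - .PR_TIE_EPS,
    mode = problem$mode,
    ptarget = pf$ptarget,
    prob = pf$capture_probability,
    expected_amount = pf$expected_amount,
    variance = pf$amount_variance,
    zscore = pf$z,
    prob_shortfall = pf$probability_shortfall,
    prob_target_met = pf$ptarget == 0 |
      pf$capture_probability >= pf$ptarget - .PR_TIE_EPS
  )
  if (is.null(directory)) return(df)
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  out <- df
  for (col in c("target", "held", "shortfall", "ptarget", "prob",
                "expected_amount", "variance", "zscore", "prob_shortfall")) {
    out[[col]] <- sprintf("%.6f", out[[col]])
  }
  out$zscore[is.na(df$zscore)] <- "NA"
  .pr_write_csv(out, file.path(directory, "output_mv.csv"))
  invisible(df)
}
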