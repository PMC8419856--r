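# Reading and writing the plain-text table dialect: pu.dat, spec.dat,
# puvspr.dat, bound.dat (comma-separated, lower-case headers) plus the
# input.dat key-value file handled in config.R.
#
# Probability columns are optional; which ones are present determines the
# problem mode. Numbers are printed with just enough digits to round-trip
# exactly, so write_problem followed by read_problem is the identity.

.pr_fmt_num <- function(x) {
  s <- sprintf("%.15g", x)
  for (digits in c("%.16g", "%.17g")) {
    bad <- as.numeric(s) != x
    if (!any(bad)) break
    s[bad] <- sprintf(digits, x[bad])
  }
  s
}

.pr_read_table <- function(path, file_label, required, optional = character()) {
  if (!file.exists(path)) {
    .pr_stop("pr_format_error", "required file '%s' (%s) not found", path, file_label)
  }
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(tab) <- tolower(names(tab))
  for (col in required) {
    if (!col %in% names(tab)) {
      .pr_stop("pr_format_error", "file '%s' lacks required column '%s'",
               file_label, col)
    }
  }
  tab[, intersect(c(required, optional), names(tab)), drop = FALSE]
}

.pr_check_prob_col <- function(tab, col, file_label) {
  if (!col %in% names(tab)) return(invisible())
  bad <- which(!is.finite(tab[[col]]) | tab[[col]] < 0 | tab[[col]] > 1)
  if (length(bad)) {
    .pr_stop("pr_validation_error",
             "file '%s' row %d: column '%s' value %s outside [0,1]",
             file_label, bad[1], col, tab[[col]][bad[1]])
  }
}

#' Read a problem from a directory of tables
#'
#' Loads `pu.dat`, `spec.dat`, `puvspr.dat` and (optionally) `bound.dat`
#' (names configurable through `config`) and assembles a validated problem.
#' The mode is inferred from the probability columns present: a `prob`
#' column in the occurrence table gives species mode (per-occurrence
#' existence probabilities), a `prob` column in the planning-unit table
#' gives threat mode (per-site loss probabilities), neither gives a
#' deterministic problem.  Populating both with non-default values is a
#' mode conflict and an error.
#'
#' @param directory_path directory containing the tables.
#' @param config a [run_config()] supplying file names.
#' @param check stop on validation violations (default); `check = FALSE`
#'   returns the problem unvalidated so violations can be listed with
#'   [validate()].
#' @return a `pr_problem`.
#' @export
read_problem <- function(directory_path, config = run_config(), check = TRUE) {
  pu <- .pr_read_table(file.path(directory_path, config$puname), config$puname,
                       c("id", "cost", "status"), "prob")
  sp <- .pr_read_table(file.path(directory_path, config$specname), config$specname,
                       c("id", "target", "spf"),
                       c("ptarget1d", "ptarget2d", "name"))
  oc <- .pr_read_table(file.path(directory_path, config$puvsprname), config$puvsprname,
                       c("species", "pu", "amount"), "prob")
  bpath <- file.path(directory_path, config$boundname)
  bd <- if (file.exists(bpath)) {
    .pr_read_table(bpath, config$boundname, c("id1", "id2", "boundary"))
  } else {
    NULL
  }

  .pr_check_prob_col(pu, "prob", config$puname)
  .pr_check_prob_col(oc, "prob", config$puvsprname)
  .pr_check_prob_col(sp, "ptarget1d", config$specname)
  .pr_check_prob_col(sp, "ptarget2d", config$specname)

  has1d <- "prob" %in% names(pu)
  has2d <- "prob" %in% names(oc)
  nd1d <- has1d && any(pu$prob != 0)
  nd2d <- has2d && any(oc$prob != 1)
  if (nd1d && nd2d) {
    .pr_stop("pr_mode_conflict_error", paste(
      "both site loss probabilities (pu 'prob') and occurrence existence",
      "probabilities (puvspr 'prob') carry non-default values;",
      "a problem must be in one probability mode"))
  }
  mode <- if (nd2d || (has2d && !nd1d)) {
    "species_2d"
  } else if (has1d) {
    "threat_1d"
  } else {
    "deterministic"
  }

  sp$ptarget <- switch(mode,
    threat_1d = if ("ptarget1d" %in% names(sp)) sp$ptarget1d else 0,
    species_2d = if ("ptarget2d" %in% names(sp)) sp$ptarget2d else 0,
    deterministic =
      if ("ptarget2d" %in% names(sp)) sp$ptarget2d
      else if ("ptarget1d" %in% names(sp)) sp$ptarget1d
      else 0
  )
  if (mode != "threat_1d") pu$prob <- NULL
  if (mode != "species_2d") oc$prob <- NULL

  new_problem(pu = pu, features = sp, occ = oc, bound = bd,
              mode = mode, check = check)
}

#' Write a problem as a directory of tables
#'
#' Emits the comma-separated dialect read by [read_problem()]; the
#' probability column matching the problem mode is written, others are
#' omitted.  `read_problem()` inverts the result exactly (numbers are
#' printed at full round-trip precision).
#'
#' @param problem a `pr_problem`.
#' @param directory_path destination directory (created if needed).
#' @param config a [run_config()] supplying file names.
#' @return invisibly, the paths written.
#' @export
write_problem <- function(problem, directory_path, config = run_config()) {
  stopifnot(inherits(problem, "pr_problem"))
  dir.create(directory_path, showWarnings = FALSE, recursive = TRUE)

  wtab <- function(df, path, quote_cols = integer()) {
    ok <- tryCatch({
      utils::write.table(df, path, sep = ",", row.names = FALSE,
                         quote = if (length(quote_cols)) quote_cols else FALSE,
                         col.names = TRUE)
      TRUE
    }, error = function(e) e)
    if (!isTRUE(ok)) {
      .pr_stop("pr_io_error", "cannot write '%s': %s", path, conditionMessage(ok))
    }
    path
  }

  pu <- data.frame(id = problem$pu$id,
                   cost = .pr_fmt_num(problem$pu$cost),
                   status = problem$pu$status)
  if (problem$mode == "threat_1d") pu$prob <- .pr_fmt_num(problem$pu$prob)

  sp <- data.frame(id = problem$features$id,
                   target = .pr_fmt_num(problem$features$target),
                   spf = .pr_fmt_num(problem$features$spf))
  ptcol <- switch(problem$mode,
                  threat_1d = "ptarget1d",
                  species_2d = "ptarget2d",
                  deterministic = if (any(problem$features$ptarget != 0)) "ptarget2d" else NULL)
  if (!is.null(ptcol)) sp[[ptcol]] <- .pr_fmt_num(problem$features$ptarget)
  sp$name <- problem$features$name

  oc <- data.frame(species = problem$occ$species,
                   pu = problem$occ$pu,
                   amount = .pr_fmt_num(problem$occ$amount))
  if (problem$mode == "species_2d") oc$prob <- .pr_fmt_num(problem$occ$prob)

  bd <- data.frame(id1 = problem$bound$id1,
                   id2 = problem$bound$id2,
                   boundary = .pr_fmt_num(problem$bound$boundary))

  paths <- c(
    wtab(pu, file.path(directory_path, config$puname)),
    wtab(sp, file.path(directory_path, config$specname),
         quote_cols = match("name", names(sp))),
    wtab(oc, file.path(directory_path, config$puvsprname)),
    wtab(bd, file.path(directory_path, config$boundname))
  )
  invisible(paths)
}

#' Write a run-parameter file
#'
#' @param config a [run_config()].
#' @param path destination file.
#' @return invisibly, `path`.
#' @export
write_input_dat <- function(config, path) {
  stopifnot(inherits(config, "pr_config"))
  lines <- c(
    sprintf("BLM %s", .pr_fmt_num(config$blm)),
    sprintf("PROP %s", .pr_fmt_num(config$prop)),
    sprintf("NUMREPS %d", config$repetitions),
    sprintf("NUMITNS %d", config$schedule$iterations),
    sprintf("NUMTEMP %d", config$schedule$temperature_steps),
    sprintf("PROBABILITYWEIGHT %s", .pr_fmt_num(config$prob_weight)),
    sprintf("MISSLEVEL %s", .pr_fmt_num(config$misslevel)),
    sprintf("RANDSEED %s", if (is.null(config$seed)) "-1" else config$seed),
    sprintf("SHORTFALLSTYLE %s", config$shortfall_style),
    sprintf("REPPENALTYSTYLE %s", config$rep_penalty_style),
    sprintf("INPUTDIR %s", config$inputdir),
    sprintf("OUTPUTDIR %s", config$outputdir),
    sprintf("PUNAME %s", config$puname),
    sprintf("SPECNAME %s", config$specname),
    sprintf("PUVSPRNAME %s", config$puvsprname),
    sprintf("BOUNDNAME %s", config$boundname)
  )
  writeLines(lines, path)
  invisible(path)
}
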