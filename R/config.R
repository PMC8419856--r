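# Run configuration: objective weights, penalty styles, annealing schedule,
# file locations. Mirrors the classic input.dat key-value parameter file.

#' Annealing schedule
#'
#' @param iterations total number of candidate flips (`NUMITNS`).
#' @param temperature_steps number of geometric temperature decreases
#'   (`NUMTEMP`); must not exceed `iterations`.
#' @param initial_temperature positive number, or `"auto"` to calibrate from
#'   the 90th percentile of |objective delta| over 100 random flips sampled
#'   from the initial solution.
#' @param final_temperature_ratio the final temperature as a fraction of the
#'   initial one; the per-step decay factor is derived from it.
#' @return an object of class `pr_schedule`.
#' @export
anneal_schedule <- function(iterations = 100000L, temperature_steps = 1000L,
                            initial_temperature = "auto",
                            final_temperature_ratio = 1e-4) {
  iterations <- as.integer(iterations)
  temperature_steps <- as.integer(temperature_steps)
  if (is.na(iterations) || iterations < 1L ||
      is.na(temperature_steps) || temperature_steps < 1L ||
      iterations < temperature_steps) {
    .pr_stop("pr_config_error",
             "schedule requires iterations >= temperature_steps >= 1")
  }
  if (!identical(initial_temperature, "auto") &&
      (!is.numeric(initial_temperature) || initial_temperature <= 0)) {
    .pr_stop("pr_config_error", "initial_temperature must be positive or 'auto'")
  }
  if (final_temperature_ratio <= 0 || final_temperature_ratio >= 1) {
    .pr_stop("pr_config_error", "final_temperature_ratio must be in (0,1)")
  }
  structure(list(iterations = iterations,
                 temperature_steps = temperature_steps,
                 initial_temperature = initial_temperature,
                 final_temperature_ratio = final_temperature_ratio),
            class = "pr_schedule")
}

#' Run configuration
#'
#' Collects every tunable of a run: the boundary multiplier `b`, the
#' representation-penalty weight `y`, the probability-penalty weight `w`,
#' penalty styles, annealing schedule, repetitions, seed, and the file names
#' used by [read_problem()] / [write_problem()].
#'
#' @param blm boundary length multiplier `b` (>= 0); trades compactness
#'   against cost.
#' @param rep_weight weight `y` on the representation-shortfall penalty.
#' @param prob_weight weight `w` on the probability-shortfall penalty.
#' @param shortfall_style `"normalized"` divides the probability shortfall
#'   `P_j - p_j` by `P_j`; `"raw"` uses the difference itself.
#' @param rep_penalty_style `"step"` charges the full penalty while a target
#'   is unmet; `"proportional"` scales it by the remaining fraction of the
#'   target.
#' @param repetitions number of independent annealing runs (`NUMREPS`).
#' @param schedule an [anneal_schedule()].
#' @param prop fraction of available units selected in the initial random
#'   solution (`PROP`).
#' @param seed integer master seed, or `NULL` to use the session RNG state.
#' @param engine probability engine used inside the objective:
#'   `"normal_approx"` (normal upper-tail approximation; fast, default) or
#'   `"exact"` (Poisson-binomial; small instances only).
#' @param misslevel fraction of its target a feature must reach before the
#'   run summary stops counting it as missing (`MISSLEVEL`).
#' @param inputdir,outputdir,puname,specname,puvsprname,boundname file
#'   locations for the table dialect.
#' @return an object of class `pr_config`.
#' @export
run_config <- function(blm = 0, rep_weight = 1, prob_weight = 1,
                       shortfall_style = c("normalized", "raw"),
                       rep_penalty_style = c("step", "proportional"),
                       repetitions = 10L,
                       schedule = anneal_schedule(),
                       prop = 0.25, seed = NULL,
                       engine = c("normal_approx", "exact"),
                       misslevel = 1,
                       inputdir = ".", outputdir = "output",
                       puname = "pu.dat", specname = "spec.dat",
                       puvsprname = "puvspr.dat", boundname = "bound.dat") {
  shortfall_style <- match.arg(shortfall_style)
  rep_penalty_style <- match.arg(rep_penalty_style)
  engine <- match.arg(engine)
  if (blm < 0 || rep_weight < 0 || prob_weight < 0) {
    .pr_stop("pr_config_error", "weights must be non-negative")
  }
  if (prop < 0 || prop > 1) {
    .pr_stop("pr_config_error", "prop must be in [0,1]")
  }
  repetitions <- as.integer(repetitions)
  if (is.na(repetitions) || repetitions < 1L) {
    .pr_stop("pr_config_error", "repetitions must be a positive integer")
  }
  stopifnot(inherits(schedule, "pr_schedule"))
  structure(list(blm = blm, rep_weight = rep_weight, prob_weight = prob_weight,
                 shortfall_style = shortfall_style,
                 rep_penalty_style = rep_penalty_style,
                 repetitions = repetitions, schedule = schedule,
                 prop = prop, seed = seed, engine = engine,
                 misslevel = misslevel,
                 inputdir = inputdir, outputdir = outputdir,
                 puname = puname, specname = specname,
                 puvsprname = puvsprname, boundname = boundname),
            class = "pr_config")
}

#' Read a key-value run-parameter file
#'
#' Parses the classic `input.dat` dialect (`KEY value`, one per line) into a
#' [run_config()].  Recognized keys: BLM, PROP, NUMREPS, NUMITNS, NUMTEMP,
#' PROBABILITYWEIGHT, MISSLEVEL, RANDSEED, INPUTDIR, OUTPUTDIR, PUNAME,
#' SPECNAME, PUVSPRNAME, BOUNDNAME, SHORTFALLSTYLE, REPPENALTYSTYLE.
#' Unrecognized keys are ignored with a message.
#'
#' @param path path to the parameter file.
#' @return a `pr_config`.
#' @export
read_input_dat <- function(path) {
  if (!file.exists(path)) {
    .pr_stop("pr_format_error", "parameter file '%s' not found", path)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- regmatches(lines, regexec("^(\\S+)\\s+(.*)$", lines))
  keys <- toupper(vapply(kv, function(m) if (length(m) == 3) m[2] else "", ""))
  vals <- vapply(kv, function(m) if (length(m) == 3) trimws(m[3]) else "", "")
  get <- function(key, default) if (key %in% keys) vals[match(key, keys)] else default
  num <- function(key, default) as.numeric(get(key, default))

  iterations <- as.integer(num("NUMITNS", 100000))
  tsteps <- as.integer(num("NUMTEMP", min(1000, iterations)))
  seed <- get("RANDSEED", NA)
  seed <- if (is.na(seed) || as.numeric(seed) < 0) NULL else as.integer(as.numeric(seed))

  known <- c("BLM", "PROP", "NUMREPS", "NUMITNS", "NUMTEMP",
             "PROBABILITYWEIGHT", "MISSLEVEL", "RANDSEED", "INPUTDIR",
             "OUTPUTDIR", "PUNAME", "SPECNAME", "PUVSPRNAME", "BOUNDNAME",
             "SHORTFALLSTYLE", "REPPENALTYSTYLE")
  unknown <- setdiff(keys, known)
  if (length(unknown)) {
    message("ignoring unrecognized parameter keys: ", paste(unknown, collapse = ", "))
  }

  run_config(
    blm = num("BLM", 0),
    prob_weight = num("PROBABILITYWEIGHT", 1),
    shortfall_style = tolower(get("SHORTFALLSTYLE", "normalized")),
    rep_penalty_style = tolower(get("REPPENALTYSTYLE", "step")),
    repetitions = as.integer(num("NUMREPS", 10)),
    schedule = anneal_schedule(iterations = iterations, temperature_steps = tsteps),
    prop = num("PROP", 0.25),
    seed = seed,
    misslevel = num("MISSLEVEL", 1),
    inputdir = get("INPUTDIR", "."),
    outputdir = get("OUTPUTDIR", "output"),
    puname = get("PUNAME", "pu.dat"),
    specname = get("SPECNAME", "spec.dat"),
    puvsprname = get("PUVSPRNAME", "puvspr.dat"),
    boundname = get("BOUNDNAME", "bound.dat")
  )
}
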