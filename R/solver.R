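# Solvers: seeded random initial solutions, simulated annealing (compiled
# inner loop for the normal-approximation engine, R loop for the exact
# engine), steepest-descent improvement, exhaustive optimum for small
# instances, and batch runs with selection frequencies.

#' Random initial solution
#'
#' Selects each available (status 0) unit independently with probability
#' `inclusion_fraction`; status-1 units start selected, locked-in units are
#' always selected and locked-out units never.
#'
#' @param problem a `pr_problem`.
#' @param inclusion_fraction probability in \[0, 1\] (`PROP`).
#' @return a 0/1 selection vector.
#' @export
initial_solution <- function(problem, inclusion_fraction = 0.25) {
  if (inclusion_fraction < 0 || inclusion_fraction > 1) {
    .pr_stop("pr_config_error", "inclusion_fraction must be in [0,1]")
  }
  st <- problem$pu$status
  x <- integer(nrow(problem$pu))
  x[st == 1L | st == 2L] <- 1L
  avail <- which(st == 0L)
  if (length(avail)) {
    x[avail] <- as.integer(stats::runif(length(avail)) < inclusion_fraction)
  }
  x
}

.pr_free_rows <- function(problem) {
  which(!problem$pu$status %in% c(2L, 3L))
}

# Calibrate the starting temperature from the 90th percentile of |delta|
# over up to 100 random flips sampled from the initial solution.
.pr_auto_t0 <- function(problem, x, config) {
  free <- .pr_free_rows(problem)
  if (!length(free)) return(1)
  b <- evaluate(problem, x, config)
  us <- sample(free, 100, replace = TRUE)
  deltas <- vapply(us, function(u) {
    delta_evaluate(problem, x, b, problem$pu$id[u], config)$delta
  }, numeric(1))
  t0 <- stats::quantile(abs(deltas), 0.9, names = FALSE)
  if (!is.finite(t0) || t0 <= 0) 1 else t0
}

.pr_resolve_schedule <- function(problem, x, config) {
  sch <- config$schedule
  t0 <- if (identical(sch$initial_temperature, "auto")) {
    .pr_auto_t0(problem, x, config)
  } else {
    sch$initial_temperature
  }
  decay <- sch$final_temperature_ratio^(1 / max(1L, sch$temperature_steps - 1L))
  list(iterations = sch$iterations, temperature_steps = sch$temperature_steps,
       t0 = t0, decay = decay)
}

# Marshal the problem into the flat arrays consumed by the compiled loop.
.pr_cpp_arrays <- function(problem) {
  idx <- problem$index
  n <- idx$n
  deg <- lengths(idx$adj_nb)
  uo <- lengths(idx$unit_rows)
  occ_rows <- unlist(idx$unit_rows, use.names = FALSE)
  list(
    cost = problem$pu$cost,
    status = as.integer(problem$pu$status),
    selfv = idx$selfv,
    adj_ptr = as.integer(c(0, cumsum(deg))),
    adj_idx = as.integer(unlist(idx$adj_nb, use.names = FALSE) - 1L),
    adj_len = as.numeric(unlist(idx$adj_v, use.names = FALSE)),
    uo_ptr = as.integer(c(0, cumsum(uo))),
    uo_feat = as.integer(idx$occ_f[occ_rows] - 1L),
    uo_r = problem$occ$amount[occ_rows],
    uo_q = idx$q[occ_rows],
    target = problem$features$target,
    frw = problem$features$spf * problem$features$repcost,
    ptarget = problem$features$ptarget
  )
}

#' Simulated annealing
#'
#' Iterative single-unit flips: a candidate unit is drawn uniformly among
#' the non-locked units, and the flip is accepted when it lowers the
#' objective or with probability `exp(-delta / temperature)` otherwise.
#' The temperature decays geometrically at each of the schedule's steps.
#' The best state seen is returned.  With the default normal-approximation
#' engine the loop runs compiled; the exact engine uses an R loop and is
#' intended for small instances.
#'
#' @param problem a `pr_problem`.
#' @param config a [run_config()].
#' @param initial starting solution; defaults to
#'   [initial_solution()] with `config$prop`.
#' @return list with `solution` and its `breakdown` (a `pr_breakdown`).
#' @export
anneal <- function(problem, config = run_config(), initial = NULL) {
  if (is.null(initial)) initial <- initial_solution(problem, config$prop)
  x <- .pr_check_solution(problem, initial)
  sch <- .pr_resolve_schedule(problem, x, config)

  if (!length(.pr_free_rows(problem))) {
    return(list(solution = x, breakdown = evaluate(problem, x, config)))
  }

  if (config$engine == "normal_approx") {
    a <- .pr_cpp_arrays(problem)
    res <- .anneal_core(a$cost, a$status, a$selfv,
                        a$adj_ptr, a$adj_idx, a$adj_len,
                        a$uo_ptr, a$uo_feat, a$uo_r, a$uo_q,
                        a$target, a$frw, a$ptarget,
                        config$blm, config$rep_weight, config$prob_weight,
                        config$shortfall_style == "normalized",
                        config$rep_penalty_style == "step",
                        x, sch$iterations, sch$temperature_steps,
                        sch$t0, sch$decay)
    best <- res$x
  } else {
    best <- .pr_anneal_r(problem, x, config, sch)
  }
  list(solution = best, breakdown = evaluate(problem, best, config))
}

# Reference annealing loop in R, used with the exact probability engine.
.pr_anneal_r <- function(problem, x, config, sch) {
  free <- .pr_free_rows(problem)
  ids <- problem$pu$id
  b <- evaluate(problem, x, config)
  best_x <- x
  best <- b$total
  temp <- sch$t0
  step_len <- max(1L, sch$iterations %/% sch$temperature_steps)
  for (it in seq_len(sch$iterations)) {
    if (it > 1L && (it - 1L) %% step_len == 0L) temp <- temp * sch$decay
    u <- free[sample.int(length(free), 1L)]
    d <- delta_evaluate(problem, x, b, ids[u], config)
    accept <- d$delta < 0 ||
      (temp > 0 && stats::runif(1) < exp(-d$delta / temp))
    if (accept) {
      x <- d$solution
      b <- d$breakdown
      if (b$total < best - 1e-12) {
        best <- b$total
        best_x <- x
      }
    }
  }
  best_x
}

#' Steepest-descent improvement
#'
#' Repeated passes over the non-locked units, applying the single flip that
#' most reduces the objective until no flip improves it.  The returned
#' solution's objective never exceeds the input's.
#'
#' @inheritParams anneal
#' @param solution starting 0/1 selection vector.
#' @return an improved 0/1 selection vector (a local optimum under single
#'   flips).
#' @export
improve <- function(problem, solution, config = run_config()) {
  x <- .pr_check_solution(problem, solution)
  free <- .pr_free_rows(problem)
  if (!length(free)) return(x)
  ids <- problem$pu$id
  b <- evaluate(problem, x, config)
  repeat {
    best_delta <- -1e-12
    best_move <- NULL
    for (u in free) {
      d <- delta_evaluate(problem, x, b, ids[u], config)
      if (d$delta < best_delta) {
        best_delta <- d$delta
        best_move <- d
      }
    }
    if (is.null(best_move)) break
    x <- best_move$solution
    b <- best_move$breakdown
  }
  x
}

# Objective total without the per-feature report frame (hot path for
# exhaustive search).
.pr_total <- function(problem, x, config, engine = config$engine) {
  idx <- problem$index
  fe <- problem$features
  total <- sum(problem$pu$cost * x) + config$blm * boundary_term(problem, x)
  frw <- fe$spf * fe$repcost
  for (f in seq_len(idx$m)) {
    rows <- idx$feat_rows[[f]]
    held <- 0; mu <- 0; va <- 0
    if (length(rows)) {
      r <- problem$occ$amount[rows]
      q <- idx$q[rows]
      xr <- x[idx$occ_u[rows]]
      held <- sum(r * xr)
      mu <- sum(r * xr * (1 - q))
      va <- sum(r * r * xr * q * (1 - q))
    }
    total <- total + .pr_rep_pen(fe$target[f], held, frw[f], config)
    if (fe$ptarget[f] > 0) {
      p <- if (engine == "exact") {
        exact_capture_probability(problem, x, fe$id[f])
      } else if (va <= .PR_VAR_EPS) {
        as.numeric(mu >= fe$target[f] - .PR_TIE_EPS)
      } else {
        stats::pnorm((fe$target[f] - mu) / sqrt(va), lower.tail = FALSE)
      }
      total <- total +
        config$prob_weight * frw[f] * .pr_prob_shortfall(fe$ptarget[f], p, config)
    }
  }
  total
}

#' Exhaustive optimum for small instances
#'
#' Enumerates every selection of the non-locked units (at most `max_free`
#' of them) and returns the minimum-objective solution.  Ties are broken
#' toward fewer selected units, then toward the lexicographically smallest
#' set of selected ids.
#'
#' @inheritParams anneal
#' @param max_free largest number of free units enumerated (2^k states).
#' @return list with `solution` and `breakdown`.
#' @export
solve_exact <- function(problem, config = run_config(), max_free = 20L) {
  free <- .pr_free_rows(problem)
  k <- length(free)
  if (k > max_free) {
    .pr_stop("pr_capability_error",
             "exhaustive search over %d free units (2^%d states) exceeds the limit of %d",
             k, k, max_free)
  }
  base <- integer(nrow(problem$pu))
  base[problem$pu$status == 2L] <- 1L
  ids <- problem$pu$id

  best_x <- NULL
  best_total <- Inf
  for (code in 0:(2^k - 1)) {
    x <- base
    if (k > 0) {
      bits <- as.integer(bitwAnd(code %/% 2^(seq_len(k) - 1L), 1L))
      x[free] <- bits
    }
    tot <- .pr_total(problem, x, config)
    take <- FALSE
    if (tot < best_total - 1e-9) {
      take <- TRUE
    } else if (abs(tot - best_total) <= 1e-9) {
      ns <- sum(x); nb <- sum(best_x)
      if (ns < nb) {
        take <- TRUE
      } else if (ns == nb) {
        sa <- ids[x == 1L]; sb <- ids[best_x == 1L]
        diff <- which(sa != sb)
        if (length(diff) && sa[diff[1]] < sb[diff[1]]) take <- TRUE
      }
    }
    if (take) {
      best_x <- x
      best_total <- tot
    }
  }
  list(solution = best_x, breakdown = evaluate(problem, best_x, config))
}

#' Batch of annealing runs with selection frequencies
#'
#' Runs `config$repetitions` independent annealing runs (each followed by
#' steepest-descent improvement) with per-repetition seeds derived from the
#' master seed, and aggregates how often each unit is selected.
#'
#' @inheritParams anneal
#' @return an object of class `pr_run_result`: per-repetition solutions and
#'   breakdowns, their totals, `best_index`, and `selection_frequency`
#'   (named by planning-unit id).
#' @export
run_batch <- function(problem, config = run_config()) {
  if (!is.null(config$seed)) set.seed(config$seed)
  reps <- config$repetitions
  rep_seeds <- sample.int(.Machine$integer.max, reps)
  solutions <- vector("list", reps)
  breakdowns <- vector("list", reps)
  totals <- numeric(reps)
  for (i in seq_len(reps)) {
    set.seed(rep_seeds[i])
    a <- anneal(problem, config)
    x <- improve(problem, a$solution, config)
    b <- evaluate(problem, x, config)
    solutions[[i]] <- x
    breakdowns[[i]] <- b
    totals[i] <- b$total
  }
  freq <- Reduce(`+`, solutions)
  names(freq) <- problem$pu$id
  structure(list(solutions = solutions, breakdowns = breakdowns,
                 totals = totals, best_index = which.min(totals),
                 selection_frequency = freq, repetitions = reps,
                 pu_ids = problem$pu$id),
            class = "pr_run_result")
}

#' @export
print.pr_run_result <- function(x, ...) {
  cat(sprintf("%d annealing runs; best objective %.6g (run %d)\n",
              x$repetitions, x$totals[x$best_index], x$best_index))
  cat(sprintf("objective range: [%.6g, %.6g]\n", min(x$totals), max(x$totals)))
  invisible(x)
}
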