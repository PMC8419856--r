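# The four-term objective:
#
#   sum_i c_i x_i                       site cost
#   + b * boundary length               exposed boundary of the selected set
#   + y * sum_j F_j R_j * rep shortfall penalty
#   + w * sum_j F_j R_j * H(P_j - p_j) * probability shortfall
#
# R_j is the representation cost of meeting feature j's target on its own
# (greedy cheapest-per-amount accumulation), cached on the feature table.
# Incremental single-flip deltas keep the annealer O(degree + carried
# features) per move.

#' Total cost of the selected planning units
#'
#' @inheritParams expected_amount
#' @return `sum_i c_i x_i`.
#' @export
cost_term <- function(problem, solution) {
  x <- .pr_check_solution(problem, solution)
  sum(problem$pu$cost * x)
}

#' Exposed boundary length of a selection
#'
#' Each stored segment between a selected and an unselected unit contributes
#' its length once; a self-segment (outer edge) contributes whenever its
#' unit is selected.  The returned value is unweighted; the objective
#' multiplies it by the boundary multiplier `b`.
#'
#' @inheritParams expected_amount
#' @return total boundary length.
#' @export
boundary_term <- function(problem, solution) {
  x <- .pr_check_solution(problem, solution)
  idx <- problem$index
  if (nrow(problem$bound) == 0) return(0)
  v <- problem$bound$boundary
  self <- idx$bnd_self
  out <- 0
  if (any(self)) out <- out + sum(v[self] * x[idx$bnd_a[self]])
  if (any(!self)) {
    out <- out + sum(v[!self] * (x[idx$bnd_a[!self]] != x[idx$bnd_b[!self]]))
  }
  out
}

#' Amount of each feature held by a selection
#'
#' @inheritParams expected_amount
#' @return named numeric vector (`sum_i r_ij x_i` per feature, names are
#'   feature ids).
#' @export
representation_amounts <- function(problem, solution) {
  x <- .pr_check_solution(problem, solution)
  idx <- problem$index
  held <- vapply(seq_len(idx$m), function(f) {
    rows <- idx$feat_rows[[f]]
    if (!length(rows)) return(0)
    sum(problem$occ$amount[rows] * x[idx$occ_u[rows]])
  }, numeric(1))
  names(held) <- problem$features$id
  held
}

# Greedy representation cost: cheapest cost-per-amount carriers first
# (unit id ascending on ties) until the target is reached.
.pr_repcost <- function(problem, feature_id) {
  fr <- .pr_feature_row(problem, feature_id)
  target <- problem$features$target[fr]
  if (target <= 0) return(0)
  idx <- problem$index
  rows <- idx$feat_rows[[fr]]
  if (!length(rows)) {
    warning(sprintf("feature %s has target %g but no occurrences; representation cost is 0",
                    feature_id, target))
    return(0)
  }
  units <- idx$occ_u[rows]
  amount <- problem$occ$amount[rows]
  cost <- problem$pu$cost[units]
  ord <- order(cost / amount, problem$pu$id[units])
  cum <- cumsum(amount[ord])
  k <- match(TRUE, cum >= target - .PR_TIE_EPS)
  if (is.na(k)) {
    warning(sprintf("feature %s: available amount %g cannot reach target %g; representation cost uses all carriers",
                    feature_id, cum[length(cum)], target))
    k <- length(ord)
  }
  sum(cost[ord][seq_len(k)])
}

#' Representation cost of a feature
#'
#' The cost of the greedy set of planning units (ascending cost-per-amount,
#' id-ascending tie-break) needed to meet the feature's target on its own.
#' This is the `R_j` scale factor of both penalty terms; it is computed once
#' at problem construction and cached in `problem$features$repcost`.
#'
#' @inheritParams expected_amount
#' @return a non-negative cost.
#' @export
estimate_representation_cost <- function(problem, feature_id) {
  .pr_repcost(problem, feature_id)
}

# Per-feature penalty components from a held/probability state.
.pr_rep_pen <- function(target, held, frw, config) {
  met <- held >= target - .PR_TIE_EPS
  base <- config$rep_weight * frw
  if (config$rep_penalty_style == "step") {
    ifelse(met, 0, base)
  } else {
    ifelse(met | target <= 0, 0, base * pmax(0, 1 - held / target))
  }
}

.pr_prob_shortfall <- function(ptarget, p, config) {
  s <- ifelse(ptarget > 0 & (ptarget - p) > .PR_TIE_EPS, ptarget - p, 0)
  if (config$shortfall_style == "normalized") {
    ifelse(s > 0, s / ptarget, 0)
  } else {
    s
  }
}

#' Representation-shortfall penalty term
#'
#' `y * sum_j F_j R_j * pen_j`, where `pen_j` is 1 while feature j's target
#' is unmet (`"step"` style) or the unmet fraction of the target
#' (`"proportional"` style); a target held exactly counts as met.
#'
#' @inheritParams expected_amount
#' @param config a [run_config()] (supplies `y` and the penalty style).
#' @return a non-negative penalty.
#' @export
representation_penalty_term <- function(problem, solution, config = run_config()) {
  held <- representation_amounts(problem, solution)
  frw <- problem$features$spf * problem$features$repcost
  sum(.pr_rep_pen(problem$features$target, held, frw, config))
}

#' Probability-shortfall penalty term
#'
#' `w * sum_j F_j R_j * H(P_j - p_j) * s_j`: features whose capture
#' probability `p_j` falls short of their probability target `P_j` are
#' charged in proportion to the shortfall, normalized by `P_j`
#' (`"normalized"` style) or raw (`"raw"` style).  Features with `P_j = 0`
#' never contribute.
#'
#' @inheritParams representation_penalty_term
#' @param engine `"normal_approx"` or `"exact"`; defaults to the engine in
#'   `config`.
#' @return a non-negative penalty.
#' @export
probability_penalty_term <- function(problem, solution, config = run_config(),
                                     engine = config$engine) {
  p <- vapply(problem$features$id, function(fid) {
    .pr_capture_probability(problem, solution, fid, engine)
  }, numeric(1))
  frw <- problem$features$spf * problem$features$repcost
  s <- .pr_prob_shortfall(problem$features$ptarget, p, config)
  sum(config$prob_weight * frw * s)
}

#' Evaluate the full objective
#'
#' @inheritParams representation_penalty_term
#' @param engine probability engine, defaulting to `config$engine`.
#' @return an object of class `pr_breakdown`: the four terms, their total,
#'   the engine used, and a `per_feature` data frame with held amounts,
#'   shortfalls, the probability state (`mu`, `variance`, `z`, `p`) and the
#'   per-feature penalty contributions.
#' @export
evaluate <- function(problem, solution, config = run_config(),
                     engine = config$engine) {
  x <- .pr_check_solution(problem, solution)
  idx <- problem$index
  fe <- problem$features
  m <- idx$m

  held <- numeric(m); mu <- numeric(m); va <- numeric(m)
  for (f in seq_len(m)) {
    rows <- idx$feat_rows[[f]]
    if (length(rows)) {
      r <- problem$occ$amount[rows]
      q <- idx$q[rows]
      xr <- x[idx$occ_u[rows]]
      held[f] <- sum(r * xr)
      mu[f] <- sum(r * xr * (1 - q))
      va[f] <- sum(r * r * xr * q * (1 - q))
    }
  }

  z <- ifelse(va <= .PR_VAR_EPS, NA_real_, (fe$target - mu) / sqrt(pmax(va, 0)))
  if (engine == "exact") {
    p <- vapply(seq_len(m), function(f) {
      exact_capture_probability(problem, x, fe$id[f])
    }, numeric(1))
  } else {
    p <- ifelse(is.na(z), as.numeric(mu >= fe$target - .PR_TIE_EPS),
                stats::pnorm(z, lower.tail = FALSE))
  }

  frw <- fe$spf * fe$repcost
  rep_pen <- .pr_rep_pen(fe$target, held, frw, config)
  prob_short <- .pr_prob_shortfall(fe$ptarget, p, config)
  prob_pen <- config$prob_weight * frw * prob_short

  cost <- sum(problem$pu$cost * x)
  blen <- boundary_term(problem, x)
  total <- cost + config$blm * blen + sum(rep_pen) + sum(prob_pen)

  structure(list(
    cost_term = cost,
    boundary_length = blen,
    boundary_term = config$blm * blen,
    representation_penalty_term = sum(rep_pen),
    probability_penalty_term = sum(prob_pen),
    total = total,
    engine = engine,
    per_feature = data.frame(
      feature_id = fe$id, target = fe$target, held = held,
      shortfall = pmax(0, fe$target - held),
      expected_amount = mu, amount_variance = va, z = z,
      capture_probability = p, ptarget = fe$ptarget,
      probability_shortfall = prob_short,
      representation_penalty = rep_pen,
      probability_penalty = prob_pen
    )
  ), class = "pr_breakdown")
}

#' @export
print.pr_breakdown <- function(x, ...) {
  cat(sprintf(paste0("objective total %.6g = cost %.6g + boundary %.6g",
                     " + representation penalty %.6g + probability penalty %.6g",
                     " [engine %s]\n"),
              x$total, x$cost_term, x$boundary_term,
              x$representation_penalty_term, x$probability_penalty_term,
              x$engine))
  invisible(x)
}

#' Incremental objective change for a single-unit flip
#'
#' Updates an existing breakdown for flipping one planning unit in or out.
#' Cost and boundary updates touch only the unit's incident segments;
#' probability states are recomputed only for the features the unit
#' carries.  The returned delta equals `evaluate(after) - evaluate(before)`
#' up to accumulated rounding.
#'
#' @inheritParams representation_penalty_term
#' @param breakdown the `pr_breakdown` for `solution` (same config/engine).
#' @param flip_unit_id id of the planning unit to flip; flipping a locked
#'   unit is a contract error.
#' @return list with elements `solution` (flipped vector), `breakdown`
#'   (updated) and `delta` (change in total).
#' @export
delta_evaluate <- function(problem, solution, breakdown, flip_unit_id,
                           config = run_config()) {
  x <- .pr_check_solution(problem, solution)
  stopifnot(inherits(breakdown, "pr_breakdown"))
  idx <- problem$index
  u <- .pr_unit_row(problem, flip_unit_id)
  if (problem$pu$status[u] %in% c(2L, 3L)) {
    .pr_stop("pr_contract_error", "planning unit %s is locked and cannot be flipped",
             flip_unit_id)
  }
  s <- 1L - 2L * x[u]  # +1 when adding, -1 when removing
  newx <- x
  newx[u] <- x[u] + s

  b <- breakdown
  b$cost_term <- b$cost_term + s * problem$pu$cost[u]

  dlen <- s * idx$selfv[u]
  nb <- idx$adj_nb[[u]]
  if (length(nb)) {
    v <- idx$adj_v[[u]]
    dlen <- dlen + sum(v * ((newx[u] != x[nb]) - (x[u] != x[nb])))
  }
  b$boundary_length <- b$boundary_length + dlen
  b$boundary_term <- config$blm * b$boundary_length

  rows <- idx$unit_rows[[u]]
  if (length(rows)) {
    pf <- b$per_feature
    frows <- idx$occ_f[rows]
    r <- problem$occ$amount[rows]
    q <- idx$q[rows]
    for (k in seq_along(rows)) {
      f <- frows[k]
      pf$held[f] <- pf$held[f] + s * r[k]
      pf$expected_amount[f] <- pf$expected_amount[f] + s * r[k] * (1 - q[k])
      pf$amount_variance[f] <- max(0, pf$amount_variance[f] + s * r[k]^2 * q[k] * (1 - q[k]))
    }
    touched <- unique(frows)
    fe <- problem$features
    for (f in touched) {
      va <- pf$amount_variance[f]
      mu <- pf$expected_amount[f]
      pf$z[f] <- if (va <= .PR_VAR_EPS) NA_real_ else (fe$target[f] - mu) / sqrt(va)
      pf$capture_probability[f] <- if (breakdown$engine == "exact") {
        exact_capture_probability(problem, newx, fe$id[f])
      } else if (is.na(pf$z[f])) {
        as.numeric(mu >= fe$target[f] - .PR_TIE_EPS)
      } else {
        stats::pnorm(pf$z[f], lower.tail = FALSE)
      }
      pf$shortfall[f] <- max(0, fe$target[f] - pf$held[f])
      frw <- fe$spf[f] * fe$repcost[f]
      pf$representation_penalty[f] <- .pr_rep_pen(fe$target[f], pf$held[f], frw, config)
      pf$probability_shortfall[f] <-
        .pr_prob_shortfall(fe$ptarget[f], pf$capture_probability[f], config)
      pf$probability_penalty[f] <-
        config$prob_weight * frw * pf$probability_shortfall[f]
    }
    b$representation_penalty_term <- sum(pf$representation_penalty)
    b$probability_penalty_term <- sum(pf$probability_penalty)
    b$per_feature <- pf
  }

  b$total <- b$cost_term + b$boundary_term +
    b$representation_penalty_term + b$probability_penalty_term
  list(solution = newx, breakdown = b, delta = b$total - breakdown$total)
}
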