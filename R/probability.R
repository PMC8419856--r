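# Capture-probability engines.
#
# For a selection x, the amount of feature j retained at the end of the
# planning horizon is a sum of independent scaled Bernoulli variables:
# each selected occurrence survives with probability 1 - q_ij, where q_ij
# is the site loss probability (threat mode) or one minus the occurrence
# existence probability (species mode). The capture probability
# p_j(x, T_j) = Pr(sum >= T_j) is computed either exactly (Poisson-binomial
# tail, by dynamic programming on a common amount grid or by enumeration of
# the 2^k outcomes) or by the normal upper-tail approximation driven by the
# mean and variance of the retained amount.

.PR_VAR_EPS <- 1e-12  # below this the amount distribution is treated as degenerate
.PR_TIE_EPS <- 1e-9   # amounts within this of the target count as meeting it

#' Expected retained amount of a feature
#'
#' `mu_j = sum_i r_ij x_i (1 - q_ij)`: the mean amount of feature
#' `feature_id` surviving in the selected set.
#'
#' @param problem a `pr_problem`.
#' @param solution 0/1 selection vector over planning units (sorted by id).
#' @param feature_id feature id.
#' @return a number (same units as the occurrence amounts).
#' @export
expected_amount <- function(problem, solution, feature_id) {
  x <- .pr_check_solution(problem, solution)
  idx <- problem$index
  rows <- idx$feat_rows[[.pr_feature_row(problem, feature_id)]]
  if (!length(rows)) return(0)
  sum(problem$occ$amount[rows] * x[idx$occ_u[rows]] * (1 - idx$q[rows]))
}

#' Variance of the retained amount of a feature
#'
#' `sigma2_j = sum_i r_ij^2 x_i q_ij (1 - q_ij)`; zero when every selected
#' occurrence is certain (probability 0 or 1).
#'
#' @inheritParams expected_amount
#' @return a non-negative number.
#' @export
amount_variance <- function(problem, solution, feature_id) {
  x <- .pr_check_solution(problem, solution)
  idx <- problem$index
  rows <- idx$feat_rows[[.pr_feature_row(problem, feature_id)]]
  if (!length(rows)) return(0)
  r <- problem$occ$amount[rows]
  q <- idx$q[rows]
  sum(r * r * x[idx$occ_u[rows]] * q * (1 - q))
}

#' Standard score of a target against the retained-amount distribution
#'
#' `z_j = (T_j - mu_j) / sigma_j`.  When the variance vanishes the score is
#' undefined and `NA` is returned; consumers treat that state as a
#' degenerate (point-mass) distribution.
#'
#' @param target representation target `T_j`.
#' @param expected_amount mean retained amount `mu_j`.
#' @param amount_variance variance of the retained amount (>= 0).
#' @return a number, or `NA` when `amount_variance` is (numerically) zero.
#' @export
z_score <- function(target, expected_amount, amount_variance) {
  if (amount_variance < 0) {
    .pr_stop("pr_contract_error", "amount_variance must be >= 0")
  }
  if (amount_variance <= .PR_VAR_EPS) return(NA_real_)
  (target - expected_amount) / sqrt(amount_variance)
}

#' Upper tail of the standard normal distribution
#'
#' `Pr(Z >= z)` for standard normal `Z`, evaluated through the
#' complementary normal CDF.  This is the percentile-rank step of the
#' normal approximation to the capture probability.
#'
#' @param z finite standard score.
#' @return a probability in (0, 1).
#' @export
normal_upper_tail <- function(z) {
  if (!is.numeric(z) || anyNA(z) || any(!is.finite(z))) {
    .pr_stop("pr_domain_error", "z must be finite")
  }
  stats::pnorm(z, lower.tail = FALSE)
}

#' Capture probability by the normal approximation
#'
#' Composes [expected_amount()], [amount_variance()], [z_score()] and
#' [normal_upper_tail()].  With zero variance the retained amount is a
#' point mass at the mean, so the probability degenerates to 1 when the
#' mean reaches the target and to 0 otherwise.
#'
#' @inheritParams expected_amount
#' @return an object of class `pr_prob_state` with fields `feature_id`,
#'   `expected_amount`, `amount_variance`, `z`, `capture_probability`,
#'   `engine`.
#' @export
approx_capture_probability <- function(problem, solution, feature_id) {
  fr <- .pr_feature_row(problem, feature_id)
  target <- problem$features$target[fr]
  mu <- expected_amount(problem, solution, feature_id)
  v <- amount_variance(problem, solution, feature_id)
  z <- z_score(target, mu, v)
  p <- if (is.na(z)) {
    as.numeric(mu >= target - .PR_TIE_EPS)
  } else {
    normal_upper_tail(z)
  }
  structure(list(feature_id = feature_id, expected_amount = mu,
                 amount_variance = v, z = z, capture_probability = p,
                 engine = "normal_approx"),
            class = "pr_prob_state")
}

#' @export
print.pr_prob_state <- function(x, ...) {
  cat(sprintf("feature %s [%s]: mu = %.6g, var = %.6g, z = %s, p = %.6g\n",
              x$feature_id, x$engine, x$expected_amount, x$amount_variance,
              if (is.na(x$z)) "undef" else sprintf("%.6g", x$z),
              x$capture_probability))
  invisible(x)
}

# Poisson-binomial tail Pr(sum r_i B_i >= target) for survival
# probabilities pres_i.  Occurrences with pres 1 contribute deterministically
# and are folded into a base amount; pres 0 occurrences are dropped.  On a
# common amount grid the distribution is built by convolution; otherwise the
# outcome space of the k random carriers is enumerated (k <= limit).
.pr_poisbin_tail <- function(amount, pres, target, enumeration_limit = 20L) {
  stopifnot(length(amount) == length(pres))
  base <- sum(amount[pres >= 1])
  keep <- pres > 0 & pres < 1
  r <- amount[keep]
  p <- pres[keep]
  thr <- target - base
  k <- length(r)
  if (k == 0L) return(as.numeric(0 >= thr - .PR_TIE_EPS))
  if (thr <= .PR_TIE_EPS) return(1)

  scale <- min(r)
  mult <- r / scale
  on_grid <- all(abs(mult - round(mult)) < 1e-9) &&
    sum(round(mult)) <= 2^22  # keep the convolution table bounded
  if (on_grid) {
    w <- as.integer(round(mult))
    total <- sum(w)
    f <- numeric(total + 1L)
    f[1L] <- 1
    top <- 0L
    for (i in seq_len(k)) {
      g <- f * (1 - p[i])
      sl <- seq_len(top + 1L)
      g[sl + w[i]] <- g[sl + w[i]] + f[sl] * p[i]
      top <- top + w[i]
      f <- g
    }
    smin <- ceiling(thr / scale - .PR_TIE_EPS)
    if (smin > total) return(0)
    if (smin <= 0) return(1)
    return(sum(f[(smin + 1L):(total + 1L)]))
  }

  if (k > enumeration_limit) {
    .pr_stop("pr_capability_error", paste(
      "exact capture probability needs enumeration of 2^%d outcomes",
      "(amounts are not on a common grid); use the normal approximation"), k)
  }
  sums <- 0
  probs <- 1
  for (i in seq_len(k)) {
    sums <- c(sums, sums + r[i])
    probs <- c(probs * (1 - p[i]), probs * p[i])
  }
  sum(probs[sums >= thr - .PR_TIE_EPS])
}

#' Exact capture probability
#'
#' `Pr(sum_i r_ij B_i >= T_j)` where the `B_i` are independent Bernoulli
#' survival indicators of the selected occurrences of the feature
#' (Poisson-binomial tail).  Amounts on a common grid (e.g. all equal) are
#' handled by dynamic programming at any size; otherwise the 2^k outcome
#' space of the k uncertain carriers is enumerated, for k up to
#' `enumeration_limit`.
#'
#' @inheritParams expected_amount
#' @param enumeration_limit largest number of uncertain carriers enumerated
#'   when amounts are not on a common grid.
#' @return a probability.
#' @export
exact_capture_probability <- function(problem, solution, feature_id,
                                      enumeration_limit = 20L) {
  x <- .pr_check_solution(problem, solution)
  idx <- problem$index
  fr <- .pr_feature_row(problem, feature_id)
  rows <- idx$feat_rows[[fr]]
  rows <- rows[x[idx$occ_u[rows]] == 1L]
  .pr_poisbin_tail(problem$occ$amount[rows], 1 - idx$q[rows],
                   problem$features$target[fr], enumeration_limit)
}

# Internal: capture probability by the configured engine.
.pr_capture_probability <- function(problem, solution, feature_id, engine) {
  if (engine == "exact") {
    exact_capture_probability(problem, solution, feature_id)
  } else {
    approx_capture_probability(problem, solution, feature_id)$capture_probability
  }
}
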