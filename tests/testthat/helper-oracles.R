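# Independent oracles and small fixture builders shared across tests.

# Brute-force Poisson-binomial tail: enumerate all 2^k survival outcomes
# of k carriers and add up the probability mass meeting the target.
# Deliberately independent of the package's dynamic program.
oracle_capture <- function(amount, pres, target) {
  k <- length(amount)
  if (k == 0) return(as.numeric(0 >= target - 1e-9))
  M <- as.matrix(expand.grid(rep(list(c(0, 1)), k)))
  pw <- t(t(M) * pres + t(1 - M) * (1 - pres))
  pr <- apply(pw, 1, prod)
  sums <- as.numeric(M %*% amount)
  sum(pr[sums >= target - 1e-9])
}

# One feature spread over k unit-cost planning units.
single_feature_problem <- function(amount, pres, target, ptarget = 0.9) {
  k <- length(amount)
  # targets above the available amount are legitimate here (tail = 0);
  # silence the unreachable-target advisory
  suppressWarnings(new_problem(
    pu = data.frame(id = seq_len(k), cost = 1, status = 0L),
    features = data.frame(id = 1L, target = target, spf = 1, ptarget = ptarget),
    occ = data.frame(species = 1L, pu = seq_len(k), amount = amount, prob = pres),
    mode = "species_2d"
  ))
}

# Small random species-mode grid problem for solver tests.
small_grid_problem <- function(seed, rows = 2, cols = 5, n_features = 2) {
  random_problem(landscape_spec(rows, cols, n_features,
                                occupancy_fraction = 0.5,
                                target_fraction = 0.5,
                                spf = 5, probability_target = 0.9,
                                mode = "species_2d", seed = seed))
}
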