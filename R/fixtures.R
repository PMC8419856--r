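# Built-in test landscapes: the three worked 4-unit examples and seeded
# random grid landscapes. Every generated problem passes validate().

#' The three worked 4-unit example problems
#'
#' Four planning units (p1..p4, ids 1..4), unit costs, no boundary
#' segments, species mode.  Example 1: one species in p2 with occurrence
#' probability 1 and probability target 1.  Example 2: one species in p2
#' and p3 with probability 0.5 each, probability target 0.8.  Example 3:
#' two species — one in p2 (0.9) and p3 (0.3) with probability target 0.8,
#' the other in p2 (0.6), p3 (0.8) and p4 (0.1) with probability target
#' 0.9.  Every representation target is 1 occurrence and every penalty
#' factor 1, so the probability arithmetic is the only active math.
#'
#' @param example_id 1, 2 or 3.
#' @return a `pr_problem` in species mode.
#' @export
figure1_problem <- function(example_id) {
  if (!example_id %in% 1:3) {
    .pr_stop("pr_lookup_error", "unknown example id %s (must be 1, 2 or 3)",
             example_id)
  }
  pu <- data.frame(id = 1:4, cost = 1, status = 0L)
  tabs <- switch(example_id,
    list(
      features = data.frame(id = 1L, name = "species_1", target = 1,
                            spf = 1, ptarget = 1.0),
      occ = data.frame(species = 1L, pu = 2L, amount = 1, prob = 1)
    ),
    list(
      features = data.frame(id = 2L, name = "species_2", target = 1,
                            spf = 1, ptarget = 0.8),
      occ = data.frame(species = 2L, pu = c(2L, 3L), amount = 1, prob = 0.5)
    ),
    list(
      features = data.frame(id = 3:4, name = c("species_3", "species_4"),
                            target = 1, spf = 1, ptarget = c(0.8, 0.9)),
      occ = data.frame(species = c(3L, 3L, 4L, 4L, 4L),
                       pu = c(2L, 3L, 2L, 3L, 4L),
                       amount = 1,
                       prob = c(0.9, 0.3, 0.6, 0.8, 0.1))
    )
  )
  new_problem(pu = pu, features = tabs$features, occ = tabs$occ,
              mode = "species_2d")
}

#' Specification of a random grid landscape
#'
#' @param grid_rows,grid_cols grid dimensions; planning units are grid
#'   cells with rook adjacency, unit-length shared edges, and exposed
#'   perimeter edges recorded as self-segments.
#' @param n_features number of conservation features.
#' @param cost_meanlog,cost_sdlog lognormal parameters for unit costs.
#' @param presence_alpha,presence_beta beta parameters for occurrence
#'   existence probabilities (species mode) or site loss probabilities
#'   (threat mode).
#' @param occupancy_fraction fraction of units each feature occupies
#'   (amount 1 per occupied unit).
#' @param target_fraction each feature's target as a fraction of its total
#'   occupied amount.
#' @param spf feature penalty factor applied to every feature.
#' @param probability_target probability target for every feature (ignored
#'   in deterministic mode).
#' @param mode problem mode.
#' @param seed integer seed; the same spec always generates the same
#'   problem.
#' @return an object of class `pr_landscape_spec`.
#' @export
landscape_spec <- function(grid_rows, grid_cols, n_features,
                           cost_meanlog = 0, cost_sdlog = 0.3,
                           presence_alpha = 2, presence_beta = 2,
                           occupancy_fraction = 0.3,
                           target_fraction = 0.5,
                           spf = 5, probability_target = 0.9,
                           mode = c("species_2d", "threat_1d", "deterministic"),
                           seed = 1L) {
  mode <- match.arg(mode)
  if (grid_rows < 1 || grid_cols < 1 || n_features < 1) {
    .pr_stop("pr_config_error", "grid dimensions and feature count must be positive")
  }
  if (cost_sdlog <= 0 || presence_alpha <= 0 || presence_beta <= 0) {
    .pr_stop("pr_config_error", "distribution parameters must be positive")
  }
  if (occupancy_fraction <= 0 || occupancy_fraction > 1) {
    .pr_stop("pr_config_error", "occupancy_fraction must be in (0,1]")
  }
  structure(list(grid_rows = as.integer(grid_rows),
                 grid_cols = as.integer(grid_cols),
                 n_features = as.integer(n_features),
                 cost_meanlog = cost_meanlog, cost_sdlog = cost_sdlog,
                 presence_alpha = presence_alpha, presence_beta = presence_beta,
                 occupancy_fraction = occupancy_fraction,
                 target_fraction = target_fraction,
                 spf = spf, probability_target = probability_target,
                 mode = mode, seed = as.integer(seed)),
            class = "pr_landscape_spec")
}

#' Generate a seeded random grid landscape
#'
#' Planning units are the cells of a `grid_rows` x `grid_cols` grid, ids in
#' row-major order, with lognormal costs.  Boundary segments are the
#' unit-length rook edges between neighbouring cells plus, for each
#' perimeter cell, a self-segment whose length is its number of exposed
#' unit edges (2 at corners).  Each feature occupies a random
#' `occupancy_fraction` of units with amount 1; existence probabilities
#' (species mode) or site loss probabilities (threat mode) are drawn from
#' the beta distribution of the spec.
#'
#' @param spec a [landscape_spec()].
#' @return a validated `pr_problem`.
#' @export
random_problem <- function(spec) {
  stopifnot(inherits(spec, "pr_landscape_spec"))
  set.seed(spec$seed)
  nr <- spec$grid_rows; nc <- spec$grid_cols
  n <- nr * nc
  cell <- function(r, c) (r - 1L) * nc + c  # row-major ids

  pu <- data.frame(
    id = seq_len(n),
    cost = stats::rlnorm(n, spec$cost_meanlog, spec$cost_sdlog),
    status = 0L,
    prob = if (spec$mode == "threat_1d") {
      stats::rbeta(n, spec$presence_alpha, spec$presence_beta)
    } else {
      0
    }
  )

  b1 <- integer(); b2 <- integer()
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      if (c < nc) { b1 <- c(b1, cell(r, c)); b2 <- c(b2, cell(r, c + 1L)) }
      if (r < nr) { b1 <- c(b1, cell(r, c)); b2 <- c(b2, cell(r + 1L, c)) }
    }
  }
  exposed <- integer(n)
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      exposed[cell(r, c)] <- (r == 1L) + (r == nr) + (c == 1L) + (c == nc)
    }
  }
  edge_cells <- which(exposed > 0L)
  bound <- rbind(
    data.frame(id1 = b1, id2 = b2, boundary = 1),
    data.frame(id1 = edge_cells, id2 = edge_cells, boundary = exposed[edge_cells])
  )

  n_occ <- max(1L, ceiling(spec$occupancy_fraction * n))
  occ <- do.call(rbind, lapply(seq_len(spec$n_features), function(f) {
    units <- sort(sample.int(n, n_occ))
    data.frame(species = f, pu = units, amount = 1,
               prob = if (spec$mode == "species_2d") {
                 stats::rbeta(n_occ, spec$presence_alpha, spec$presence_beta)
               } else {
                 1
               })
  }))

  features <- data.frame(
    id = seq_len(spec$n_features),
    name = paste0("feature_", seq_len(spec$n_features)),
    target = max(1, round(spec$target_fraction * n_occ)),
    spf = spec$spf,
    ptarget = if (spec$mode == "deterministic") 0 else spec$probability_target
  )

  new_problem(pu = pu, features = features, occ = occ, bound = bound,
              mode = spec$mode)
}
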