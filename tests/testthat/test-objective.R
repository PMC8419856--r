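grid3 <- function() {
  # 3x3 unit grid with rook edges and exposed perimeter self-segments
  random_problem(landscape_spec(3, 3, 1, occupancy_fraction = 1,
                                mode = "deterministic", seed = 11))
}

test_that("cost term is the sum of selected unit costs", {
  p <- new_problem(
    pu = data.frame(id = 1:3, cost = c(1, 2, 3), status = 0L),
    features = data.frame(id = 1, target = 0, spf = 1),
    occ = data.frame(species = 1, pu = 1, amount = 1),
    mode = "deterministic"
  )
  expect_equal(cost_term(p, integer(3)), 0)
  expect_equal(cost_term(p, rep(1L, 3)), 6)

  set.seed(1)
  pr <- random_problem(landscape_spec(10, 10, 2, seed = 2))
  x <- as.integer(stats::runif(100) < 0.5)
  expect_equal(cost_term(pr, x), sum(pr$pu$cost[x == 1]))
})

test_that("boundary term counts cut and exposed segments once", {
  p <- grid3()
  # interior edge vanishes when both sides are in
  pair <- solution_from_ids(p, c(4, 5))  # middle-row neighbours
  single <- solution_from_ids(p, 5)      # centre cell only
  expect_equal(boundary_term(p, single), 4)  # 4 incident unit edges
  # two adjacent interior-ish cells: shared edge not counted
  expect_equal(boundary_term(p, pair),
               boundary_term(p, solution_from_ids(p, 4)) +
                 boundary_term(p, single) - 2)
  expect_equal(boundary_term(p, integer(9)), 0)
  # everything selected: only the perimeter remains
  expect_equal(boundary_term(p, rep(1L, 9)), 12)
})

test_that("held amounts equal the sparse sums", {
  p2 <- figure1_problem(2)
  expect_equal(unname(representation_amounts(p2, solution_from_ids(p2, c(2, 3)))), 2)
  expect_equal(unname(representation_amounts(p2, integer(4))), 0)

  pr <- random_problem(landscape_spec(6, 6, 3, seed = 9))
  set.seed(4)
  x <- as.integer(stats::runif(36) < 0.5)
  held <- representation_amounts(pr, x)
  for (f in pr$features$id) {
    rows <- pr$occ$species == f
    expect_equal(unname(held[as.character(f)]),
                 sum(pr$occ$amount[rows] * x[match(pr$occ$pu[rows], pr$pu$id)]))
  }
})

test_that("representation cost is the greedy cheapest-per-amount accumulation", {
  single <- new_problem(
    pu = data.frame(id = 1, cost = 5, status = 0L),
    features = data.frame(id = 1, target = 1, spf = 1),
    occ = data.frame(species = 1, pu = 1, amount = 1),
    mode = "deterministic"
  )
  expect_equal(estimate_representation_cost(single, 1), 5)

  two <- new_problem(
    pu = data.frame(id = 1:2, cost = c(1, 10), status = 0L),
    features = data.frame(id = 1, target = 1, spf = 1),
    occ = data.frame(species = 1, pu = 1:2, amount = 1),
    mode = "deterministic"
  )
  expect_equal(estimate_representation_cost(two, 1), 1)

  two$features$target <- 2
  expect_equal(estimate_representation_cost(two, 1), 11)

  unreachable <- suppressWarnings(new_problem(
    pu = data.frame(id = 1, cost = 2, status = 0L),
    features = data.frame(id = 1, target = 5, spf = 1),
    occ = data.frame(species = 1, pu = 1, amount = 1),
    mode = "deterministic", check = FALSE
  ))
  expect_warning(estimate_representation_cost(unreachable, 1), "cannot reach")
})

test_that("representation penalty styles behave as indicator and linear shortfall", {
  p <- new_problem(
    pu = data.frame(id = 1:2, cost = c(1, 1), status = 0L),
    features = data.frame(id = 1, target = 2, spf = 1),
    occ = data.frame(species = 1, pu = 1:2, amount = 1),
    mode = "deterministic"
  )
  half <- solution_from_ids(p, 1)
  full <- rep(1L, 2)
  frw <- p$features$spf * p$features$repcost  # = 2 here
  cfg_step <- run_config(rep_penalty_style = "step")
  cfg_prop <- run_config(rep_penalty_style = "proportional")
  expect_equal(representation_penalty_term(p, full, cfg_step), 0)
  expect_equal(representation_penalty_term(p, half, cfg_step), frw)
  expect_equal(representation_penalty_term(p, half, cfg_prop), frw * 0.5)
})

test_that("probability penalty reproduces the worked example in both styles", {
  p3 <- figure1_problem(3)
  only_p2 <- solution_from_ids(p3, 2)
  raw <- run_config(shortfall_style = "raw")
  norm <- run_config(shortfall_style = "normalized")
  expect_equal(probability_penalty_term(p3, only_p2, raw, engine = "exact"), 0.3)
  expect_equal(probability_penalty_term(p3, only_p2, norm, engine = "exact"),
               0.3 / 0.9, tolerance = 1e-9)
  both <- solution_from_ids(p3, c(2, 3))
  expect_equal(probability_penalty_term(p3, both, raw, engine = "exact"), 0)
})

test_that("evaluate composes the terms and satisfies the decomposition identity", {
  p3 <- figure1_problem(3)
  b <- evaluate(p3, solution_from_ids(p3, c(2, 3)), run_config(), engine = "exact")
  expect_equal(b$total, 2)  # both unit costs, no penalties

  empty <- new_problem(
    pu = data.frame(id = 1, cost = 1, status = 0L),
    features = data.frame(id = 1, target = 0, spf = 1),
    occ = data.frame(species = 1, pu = 1, amount = 1),
    mode = "deterministic"
  )
  expect_equal(evaluate(empty, 0L)$total, 0)

  pr <- random_problem(landscape_spec(5, 5, 3, seed = 21))
  cfg <- run_config(blm = 0.4, rep_penalty_style = "proportional")
  set.seed(31)
  for (trial in 1:10) {
    x <- as.integer(stats::runif(25) < stats::runif(1))
    b <- evaluate(pr, x, cfg)
    expect_equal(b$total,
                 b$cost_term + cfg$blm * b$boundary_length +
                   b$representation_penalty_term + b$probability_penalty_term,
                 tolerance = 1e-9)
    expect_equal(b$cost_term, cost_term(pr, x))
    expect_equal(b$boundary_length, boundary_term(pr, x))
    expect_equal(b$representation_penalty_term,
                 representation_penalty_term(pr, x, cfg))
    expect_equal(b$probability_penalty_term,
                 probability_penalty_term(pr, x, cfg))
    expect_true(all(c(b$representation_penalty_term,
                      b$probability_penalty_term) >= 0))
  }
})

test_that("single-flip deltas match full re-evaluation and invert", {
  pr <- random_problem(landscape_spec(4, 5, 3, seed = 13))
  cfg <- run_config(blm = 0.3)
  set.seed(17)
  x <- initial_solution(pr, 0.5)
  b <- evaluate(pr, x, cfg)
  for (trial in 1:50) {
    u <- sample(pr$pu$id, 1)
    d <- delta_evaluate(pr, x, b, u, cfg)
    full <- evaluate(pr, d$solution, cfg)
    expect_equal(d$breakdown$total, full$total, tolerance = 1e-9)
    expect_equal(d$delta, full$total - b$total, tolerance = 1e-9)
    back <- delta_evaluate(pr, d$solution, d$breakdown, u, cfg)
    expect_equal(back$breakdown$total, b$total, tolerance = 1e-9)
    x <- d$solution
    b <- d$breakdown
  }
})

test_that("flipping a locked unit is a contract error", {
  p <- new_problem(
    pu = data.frame(id = 1:2, cost = 1, status = c(2L, 3L)),
    features = data.frame(id = 1, target = 1, spf = 1),
    occ = data.frame(species = 1, pu = 1, amount = 1),
    mode = "deterministic"
  )
  x <- c(1L, 0L)
  b <- evaluate(p, x)
  expect_error(delta_evaluate(p, x, b, 1), class = "pr_contract_error")
  expect_error(delta_evaluate(p, x, b, 2), class = "pr_contract_error")
})

test_that("with certain occurrences the objective reduces to the classic form", {
  spec <- landscape_spec(5, 5, 3, mode = "deterministic", seed = 77)
  pr <- random_problem(spec)
  cfg <- run_config(blm = 0.6)
  set.seed(41)
  for (trial in 1:10) {
    x <- as.integer(stats::runif(25) < 0.5)
    b <- evaluate(pr, x, cfg)
    classic <- cost_term(pr, x) + cfg$blm * boundary_term(pr, x) +
      representation_penalty_term(pr, x, cfg)
    expect_equal(b$total, classic, tolerance = 1e-12)
    expect_equal(b$probability_penalty_term, 0)
  }

  # species mode, all probabilities 1: no probability penalty once targets met
  pr2 <- random_problem(landscape_spec(4, 4, 2, mode = "species_2d",
                                       occupancy_fraction = 0.6, seed = 78))
  pr2$occ$prob[] <- 1
  pr2 <- new_problem(pr2$pu, pr2$features, pr2$occ, pr2$bound, mode = "species_2d")
  full <- rep(1L, 16)
  b <- evaluate(pr2, full, cfg)
  expect_equal(b$probability_penalty_term, 0)
  expect_equal(b$total, cost_term(pr2, full) + cfg$blm * boundary_term(pr2, full),
               tolerance = 1e-12)
})
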