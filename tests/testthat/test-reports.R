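batch_fixture <- function() {
  pr <- small_grid_problem(404)
  cfg <- run_config(repetitions = 3, seed = 2,
                    schedule = anneal_schedule(3000, 30))
  list(problem = pr, config = cfg, result = run_batch(pr, cfg))
}

test_that("per-run solution files round-trip and the best copy is the minimum", {
  fx <- batch_fixture()
  dir <- withr::local_tempdir()
  write_solution_outputs(fx$result, dir)
  files <- list.files(dir, pattern = "^output_r")
  expect_equal(length(files), 3)
  for (i in 1:3) {
    got <- read_solution_output(file.path(dir, sprintf("output_r%04d.csv", i)))
    expect_identical(got, fx$result$solutions[[i]])
  }
  best <- read_solution_output(file.path(dir, "output_best.csv"))
  expect_identical(best, fx$result$solutions[[fx$result$best_index]])
  df <- utils::read.csv(file.path(dir, "output_r0001.csv"))
  expect_equal(nrow(df), 10)
})

test_that("summed solution matches selection frequencies and respects locks", {
  pr <- small_grid_problem(505)
  pr$pu$status[2] <- 2L
  pr$pu$status[3] <- 3L
  pr <- new_problem(pr$pu, pr$features, pr$occ, pr$bound, mode = pr$mode)
  cfg <- run_config(repetitions = 4, seed = 3,
                    schedule = anneal_schedule(2000, 20))
  res <- run_batch(pr, cfg)
  dir <- withr::local_tempdir()
  summed_solution(res, dir)
  df <- utils::read.csv(file.path(dir, "output_ssoln.csv"))
  expect_equal(df$count, unname(res$selection_frequency[as.character(df$id)]))
  expect_true(all(df$count >= 0 & df$count <= 4))
  expect_equal(df$count[df$id == pr$pu$id[2]], 4)  # locked in
  expect_equal(df$count[df$id == pr$pu$id[3]], 0)  # locked out
})

test_that("the missing-values report mirrors the objective diagnostics", {
  p3 <- figure1_problem(3)
  cfg <- run_config(shortfall_style = "raw", engine = "exact")
  mv <- missing_values_report(p3, solution_from_ids(p3, 2), cfg)
  sp4 <- mv[mv$id == 4, ]
  expect_equal(sp4$prob, 0.6)
  expect_equal(sp4$prob_shortfall, 0.3)
  expect_false(sp4$prob_target_met)
  sp3 <- mv[mv$id == 3, ]
  expect_equal(sp3$prob_shortfall, 0)
  expect_true(sp3$prob_target_met)

  # values agree with the module operations they summarize
  b <- evaluate(p3, solution_from_ids(p3, 2), cfg)
  expect_equal(mv$held, b$per_feature$held, tolerance = 1e-9)
  expect_equal(mv$prob, b$per_feature$capture_probability, tolerance = 1e-9)
  expect_equal(mv$expected_amount, b$per_feature$expected_amount, tolerance = 1e-9)

  # all targets met: both flags true everywhere
  mv_ok <- missing_values_report(p3, solution_from_ids(p3, c(2, 3)), cfg)
  expect_true(all(mv_ok$target_met))
  expect_true(all(mv_ok$prob_target_met))

  # a feature without probability target is never short
  pd <- random_problem(landscape_spec(3, 3, 2, mode = "deterministic", seed = 9))
  mv0 <- missing_values_report(pd, rep(1L, 9), run_config())
  expect_true(all(mv0$prob_target_met))
  expect_true(all(mv0$prob_shortfall == 0))
})

test_that("report files parse back to the printed precision", {
  fx <- batch_fixture()
  dir <- withr::local_tempdir()
  best <- fx$result$solutions[[fx$result$best_index]]
  mv <- missing_values_report(fx$problem, best, fx$config, dir)
  disk <- utils::read.csv(file.path(dir, "output_mv.csv"))
  expect_equal(disk$prob, mv$prob, tolerance = 1e-6)
  expect_equal(disk$held, mv$held, tolerance = 1e-6)
  expect_equal(disk$target_met, mv$target_met)
})

test_that("the solve command runs end to end and writes its outputs", {
  base <- withr::local_tempdir()
  pr <- small_grid_problem(606)
  write_problem(pr, base)
  cfg <- run_config(repetitions = 2, seed = 4,
                    schedule = anneal_schedule(2000, 20))
  write_input_dat(cfg, file.path(base, "input.dat"))

  out <- capture.output(
    code <- run_cli(c("solve", "--input", file.path(base, "input.dat"),
                      "--reps", "2", "--seed", "11"))
  )
  expect_equal(code, 0L)
  expect_true(any(grepl("best: run", out)))
  outdir <- file.path(base, "output")
  expect_true(file.exists(file.path(outdir, "output_best.csv")))
  expect_true(file.exists(file.path(outdir, "output_ssoln.csv")))
  expect_true(file.exists(file.path(outdir, "output_mv.csv")))
})

test_that("the cli reports malformed input as exit code 2", {
  base <- withr::local_tempdir()
  pr <- small_grid_problem(707)
  write_problem(pr, base)
  sp <- utils::read.csv(file.path(base, "spec.dat"))
  utils::write.csv(sp[, setdiff(names(sp), "target")],
                   file.path(base, "spec.dat"), row.names = FALSE)
  write_input_dat(run_config(repetitions = 1), file.path(base, "input.dat"))
  expect_message(
    code <- run_cli(c("solve", "--input", file.path(base, "input.dat"))),
    "target")
  expect_equal(code, 2L)
})

test_that("the exact engine refuses oversized instances through the cli", {
  base <- withr::local_tempdir()
  set.seed(1)
  p <- single_feature_problem(stats::runif(30, 0.5, 2), stats::runif(30),
                              target = 3)
  write_problem(p, base)
  write_input_dat(run_config(repetitions = 1, prop = 1,
                             schedule = anneal_schedule(10, 1)),
                  file.path(base, "input.dat"))
  expect_message(
    code <- run_cli(c("solve", "--input", file.path(base, "input.dat"),
                      "--engine", "exact")),
    "enumeration")
  expect_equal(code, 1L)
})

test_that("the validate and generate commands work on directories", {
  base <- withr::local_tempdir()
  write_problem(figure1_problem(2), base)
  out <- capture.output(code <- run_cli(c("validate", "--input", base)))
  expect_equal(code, 0L)
  expect_match(out, "valid", all = FALSE)

  gen <- withr::local_tempdir()
  spec_json <- withr::local_tempfile(fileext = ".json")
  writeLines('{"grid_rows": 3, "grid_cols": 3, "n_features": 2, "seed": 5}',
             spec_json)
  out2 <- capture.output(
    code2 <- run_cli(c("generate", "--spec", spec_json, "--out", gen)))
  expect_equal(code2, 0L)
  p <- read_problem(gen)
  expect_equal(nrow(p$pu), 9)
  expect_equal(nrow(validate(p)), 0)
})
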