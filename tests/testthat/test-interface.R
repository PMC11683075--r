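test_that("the default configuration validates and round-trips through YAML", {
  cfg <- default_config()
  expect_true(validate_config(cfg))
  path <- withr::local_tempfile(fileext = ".yaml")
  write_config(cfg, path)
  back <- read_config(path)
  expect_equal(unclass(back), unclass(cfg))
})

test_that("unknown or invalid configuration keys are rejected by name", {
  cfg <- default_config()
  cfg$homeostat$typo <- 1
  expect_error(validate_config(cfg), "homeostat.typo")
  cfg <- default_config()
  cfg$agent$intake$gamma <- 1.5
  expect_error(validate_config(cfg), "gamma")
  cfg <- default_config()
  cfg$homeostat$tau <- 0.5
  expect_error(validate_config(cfg), "tau")
  cfg <- default_config()
  cfg$tasks$intake <- NULL
  expect_error(validate_config(cfg), "intake")
  expect_error(resolve_config(default_config(), list(nope = 1)), "nope")
  over <- resolve_config(default_config(), list(homeostat = list(eta = 1.7)))
  expect_identical(over$homeostat$eta, 1.7)
})

test_that("result writers emit re-parseable tables and summaries", {
  dir <- withr::local_tempdir()
  cond <- condition("control", n_replicates = 3, base_seed = 50)
  res <- run_condition(cond, "intake", default_config())
  csv <- file.path(dir, "m.csv")
  write_metrics_csv(res, csv)
  back <- utils::read.csv(csv)
  expect_equal(back$total_intake, res$total_intake)
  js <- file.path(dir, "s.json")
  write_summary_json(res, js)
  parsed <- jsonlite::read_json(js)
  expect_identical(parsed$condition, "control")
  expect_equal(parsed$metrics$total_intake$mean, mean(res$total_intake))
  tj <- file.path(dir, "task.json")
  write_task_json(build_intake_task(), tj)
  expect_identical(jsonlite::read_json(tj)$name, "intake_after_food_restriction")
  set.seed(1)
  tr <- run_episode(build_intake_task(), space_1d(tau = 25),
                    agent_params())$trajectory
  tcsv <- file.path(dir, "traj.csv")
  write_trajectory_csv(tr, tcsv, trial = 1L)
  tback <- utils::read.csv(tcsv)
  expect_identical(nrow(tback), 100L)
  expect_true(all(c("trial", "episode", "t", "state", "action", "H_before",
                    "H_after", "reward", "p_action1", "q_action1") %in%
                    names(tback)))
})

test_that("the CLI demo is deterministic and exits cleanly", {
  out1 <- capture.output(status <- cli_main(c("demo", "--seed", "3")))
  out2 <- capture.output(cli_main(c("demo", "--seed", "3")))
  expect_identical(status, 0L)
  expect_identical(out1, out2)
  expect_true(any(grepl("total intakes", out1)))
  expect_output(cli_main(character(0)), "usage")
})

test_that("the CLI validates inputs and reports missing results", {
  expect_identical(suppressMessages(cli_main(c("frobnicate"))), 1L)
  expect_identical(suppressMessages(cli_main(c("demo", "--seed", "abc"))), 1L)
  dir <- withr::local_tempdir()
  expect_identical(
    suppressMessages(cli_main(c("compare", "control", "low_eta",
                                "--out", dir))), 1L)
})

test_that("run-intake writes metrics, summary, config echo and task dump", {
  dir <- withr::local_tempdir()
  status <- suppressMessages(
    cli_main(c("run-intake", "--n-replicates", "2", "--seed", "5",
               "--out", dir)))
  expect_identical(status, 0L)
  expect_true(file.exists(file.path(dir, "intake_control_metrics.csv")))
  expect_true(file.exists(file.path(dir, "intake_control_summary.json")))
  expect_true(file.exists(file.path(dir, "config_resolved.yaml")))
  expect_true(file.exists(file.path(dir, "intake_task.json")))
  echoed <- read_config(file.path(dir, "config_resolved.yaml"))
  expect_identical(echoed$experiment$base_seed, 5L)
  m <- utils::read.csv(file.path(dir, "intake_control_metrics.csv"))
  expect_identical(nrow(m), 2L)
})

test_that("a CLI eta override propagates into the condition", {
  dir <- withr::local_tempdir()
  status <- suppressMessages(
    cli_main(c("run-intake", "--condition", "low_eta", "--eta", "1.0",
               "--n-replicates", "2", "--seed", "11", "--out", dir)))
  expect_identical(status, 0L)
  m <- utils::read.csv(file.path(dir, "intake_low_eta_metrics.csv"))
  # with eta forced to 1 the run must reproduce control dynamics seed-for-seed
  cfg <- default_config()
  cfg$experiment$base_seed <- 11L
  conds <- default_conditions(cfg, "intake")
  ctl <- condition("ctl", n_replicates = 2,
                   base_seed = conds$low_eta$base_seed)
  ref <- run_condition(ctl, "intake", cfg)
  expect_equal(m$total_intake, ref$total_intake)
  expect_equal(m$sum_drive, ref$sum_drive)
})
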