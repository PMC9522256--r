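test_that("table experiments honour the shape contract and reproduce exactly", {
  cfg <- experiment_config(
    charts = list(study_spec("MA", 2.882), study_spec("MMEM", 5.118)),
    distributions = "normal",
    shifts = c(0.5, 1, 2),
    n_reps = 500, seed = 123
  )
  tab <- run_table_experiment(cfg)
  expect_equal(nrow(tab), 6)
  expect_named(tab, c("chart", "distribution", "delta", "C", "w", "lambda",
                      "k", "arl", "se_arl", "sdrl", "mrl", "n_reps",
                      "n_censored", "seed"))
  tab2 <- run_table_experiment(cfg)
  expect_identical(tab, tab2)

  # written table re-parses to equal values
  path <- withr::local_tempfile(fileext = ".csv")
  cfg$output <- path
  tab3 <- run_table_experiment(cfg)
  back <- read.csv(path, stringsAsFactors = FALSE)
  expect_equal(back$arl, tab3$arl, tolerance = 1e-12)
  expect_equal(back$mrl, tab3$mrl)
})

test_that("a one-cell experiment produces exactly one row", {
  cfg <- experiment_config(charts = study_spec("TCC", 2), distributions = "normal",
                           shifts = 0, n_reps = 100, seed = 1)
  expect_equal(nrow(run_table_experiment(cfg)), 1)
})

test_that("YAML configs map one-to-one onto experiment settings", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "charts:",
    "  - kind: MA",
    "    C: 2.882",
    "  - kind: MMEM_TCC",
    "    C: 5.320",
    "    w: 5",
    "    lambda: 0.25",
    "    k: -0.125",
    "distributions: [normal, exponential]",
    "shifts: [0, 0.5]",
    "n_reps: 200",
    "seed: 7",
    "counting: pre-signal"
  ), path)
  cfg <- read_experiment_config(path)
  expect_length(cfg$charts, 2)
  expect_equal(cfg$charts[[2]]$C, 5.320)
  expect_equal(cfg$counting, "pre-signal")
  expect_equal(vapply(cfg$distributions, `[[`, "", "family"),
               c("normal", "exponential"))

  writeLines(c("charts:", "  - kind: MA", "    C: 2"), path)
  expect_error(read_experiment_config(path), "missing required key")
})

test_that("monitoring flags no alarms under wide limits and finds big changepoints", {
  x <- make_pm_series("pm25", 200, seed = 10)
  wide <- chart_spec("MA", C = 60, w = 5)
  rep <- monitor_series(x, wide, phase1 = 50)
  expect_equal(sum(rep$out_of_control), 0)
  expect_true(is.na(attr(rep, "first_signal")))
  expect_equal(nrow(rep), 150)

  # a delta = 3 shift starting with Phase II is caught, and caught quickly,
  # in >= 95% of runs
  spec <- study_spec("MMEM_TCC", 5.320)
  phase1 <- 200; cp <- phase1 + 1
  hits <- vapply(1:100, function(s) {
    x <- make_pm_series("pm25", 320, changepoint = cp, delta = 3, seed = s)
    fs <- attr(monitor_series(x, spec, phase1 = phase1), "first_signal")
    !is.na(fs) && fs <= 30
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("degenerate Phase I input is rejected for Tukey charts", {
  x <- c(rep(5, 30), rnorm(20, 5))
  expect_error(monitor_series(x, study_spec("TCC", 2), phase1 = 30),
               "constant Phase I|degenerate")
  expect_error(monitor_series(rnorm(20), study_spec("MA", 3), phase1 = 25),
               "shorter")
})
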