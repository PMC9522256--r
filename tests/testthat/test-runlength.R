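shewhart_spec <- chart_spec("MA", C = 3, w = 1)

test_that("Shewhart reduction reproduces the geometric run-length law", {
  p <- 2 * pnorm(-3)                      # two-sided 3-sigma exceedance
  s <- estimate_rl_summary(shewhart_spec, std_normal, 0,
                           n_reps = 1e5, seed = 123, max_horizon = 20000)
  expect_lt(abs(s$arl - 1 / p), 4 * s$se_arl)
  expect_lt(abs(s$sdrl / s$arl - sqrt(1 - p)), 0.05)
  expect_lt(abs(s$mrl - ceiling(log(0.5) / log(1 - p))), 2.5)
  expect_lt(s$n_censored / s$n_reps, 1e-3)
})

test_that("run lengths are deterministic in the seed and censored at the horizon", {
  r1 <- simulate_run_length(shewhart_spec, std_normal, 0, seed = 9)
  r2 <- simulate_run_length(shewhart_spec, std_normal, 0, seed = 9)
  expect_identical(as.integer(r1), as.integer(r2))

  wide <- chart_spec("MA", C = 50, w = 1)
  r <- simulate_run_length(wide, std_normal, 0, seed = 1, max_horizon = 200)
  expect_identical(as.integer(r), 200L)
  expect_true(attr(r, "censored"))
  s <- estimate_rl_summary(wide, std_normal, 0, n_reps = 50, seed = 1,
                           max_horizon = 200)
  expect_equal(s$arl, 200)
  expect_equal(s$sdrl, 0)
  expect_equal(s$n_censored, 50)
})

test_that("a huge shift forces an almost immediate signal", {
  s <- estimate_rl_summary(shewhart_spec, std_normal, 6, n_reps = 2000,
                           seed = 2)
  expect_lt(s$arl, 1.01)
})

test_that("ARL decreases in |delta| and is symmetric under symmetric models", {
  spec <- study_spec("MMEM", 5.118)
  for (m in list(std_normal, std_laplace)) {
    arls <- vapply(c(0, 0.5, 1, 2), function(d) {
      estimate_rl_summary(spec, m, d, n_reps = 4000, seed = 31)$arl
    }, numeric(1))
    expect_true(all(diff(arls) < 0))
    for (d in c(0.5, 1, 2)) {
      up <- estimate_rl_summary(spec, m, d, n_reps = 8000, seed = 77)
      dn <- estimate_rl_summary(spec, m, -d, n_reps = 8000, seed = 78)
      expect_lt(abs(up$arl - dn$arl),
                4 * sqrt(up$se_arl^2 + dn$se_arl^2))
    }
  }
})

test_that("pre-signal counting subtracts one and floors at one", {
  set.seed(40)
  a <- estimate_rl_summary(shewhart_spec, std_normal, 0.5, n_reps = 5000,
                           seed = 40)
  b <- estimate_rl_summary(shewhart_spec, std_normal, 0.5, n_reps = 5000,
                           seed = 40, counting = "pre-signal")
  expect_true(b$arl >= a$arl - 1 - 1e-9)
  expect_true(b$arl < a$arl)
  # at a massive shift the floor keeps the pre-signal ARL at 1
  s <- estimate_rl_summary(shewhart_spec, std_normal, 8, n_reps = 1000,
                           seed = 41, counting = "pre-signal")
  expect_equal(s$arl, 1)
})

test_that("the SDRL identity and summary invariants hold", {
  s <- estimate_rl_summary(study_spec("MA", 2.882), std_normal, 0.5,
                           n_reps = 5000, seed = 50)
  expect_gte(s$arl, 1)
  expect_gte(s$mrl, 1)
  # sdrl is the population-form second-moment SD, se_arl the sample-SD / sqrt(n)
  expect_equal(s$se_arl, s$sdrl / sqrt(s$n_reps - 1), tolerance = 1e-10)
  expect_lte(s$n_censored, s$n_reps)
  expect_error(estimate_rl_summary(study_spec("MA", 3), std_normal, 0,
                                   n_reps = 1, seed = 1), "n_reps")
})
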