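test_that("moving-average statistic follows the windowed-mean definition", {
  expect_equal(ma_statistic(c(1, 2, 3, 4, 5, 6), 3), c(1, 1.5, 2, 3, 4, 5))
  expect_equal(ma_statistic(rep(2.5, 8), 4), rep(2.5, 8))
  x <- rnorm(20)
  expect_equal(ma_statistic(x, 1), x)
  expect_error(ma_statistic(numeric(0), 3), "empty")
})

test_that("MEWMA recursion matches hand evaluation and collapses correctly", {
  expect_equal(mewma_statistic(c(1, 2), 0.25, -0.125, m0 = 0, x0 = 0),
               c(0.125, 0.46875))
  x <- rnorm(50)
  expect_equal(mewma_statistic(x, 1, 0), x)
  # k = 0 must agree with an independently coded classical EWMA, bitwise
  expect_identical(mewma_statistic(x, 0.3, 0, m0 = 0.2, x0 = 0.2),
                   ewma_reference(x, 0.3, z0 = 0.2))
  expect_error(mewma_statistic(x, 1.2, 0), "lambda")
})

test_that("variance factor has the stated closed form and limits", {
  expect_equal(variance_factor(0.25, -0.125), 0.125)
  expect_equal(variance_factor(0.4, 0), 0.4 / 1.6)
  expect_equal(variance_factor(1, 0), 1)
  expect_error(variance_factor(2, 0))
})

test_that("mixed statistics compose their stages and reduce under collapsing parameters", {
  x <- c(1, 2, 3)
  # hand evaluation: MEWMA = (0.125, 0.46875, 0.9765625), then w = 2 averages
  s <- chart_spec("MMME", C = 1, w = 2, lambda = 0.25, k = -0.125)
  expect_equal(mmme_statistic(x, s, mu0 = 0), c(0.125, 0.296875, 0.72265625))
  s <- chart_spec("MMEM", C = 1, w = 2, lambda = 0.25, k = -0.125)
  expect_equal(mmem_statistic(x, s, mu0 = 0), c(0.125, 0.40625, 0.8046875))

  set.seed(1)
  for (i in 1:5) {
    x <- rnorm(60, 2)
    expect_equal(
      mmme_statistic(x, chart_spec("MMME", 1, w = 4, lambda = 1, k = 0), 2),
      ma_statistic(x, 4))
    expect_equal(
      mmem_statistic(x, chart_spec("MMEM", 1, w = 4, lambda = 1, k = 0), 2),
      ma_statistic(x, 4))
    expect_equal(
      mmme_statistic(x, chart_spec("MMME", 1, w = 1, lambda = 0.2, k = 0.1), 2),
      mewma_statistic(x, 0.2, 0.1, m0 = 2, x0 = 2))
    expect_equal(
      mmem_statistic(x, chart_spec("MMEM", 1, w = 1, lambda = 0.2, k = 0.1), 2),
      mewma_statistic(x, 0.2, 0.1, m0 = 2, x0 = 2))
  }
})

test_that("parametric limit schedules match their closed forms", {
  n <- 8
  lim <- parametric_limits(study_spec("MA", 2.882), std_normal, n)
  expect_equal(lim$ucl[5:n], rep(2.882 / sqrt(5), n - 4), tolerance = 1e-12)
  expect_equal(lim$ucl[n], 1.28887, tolerance = 1e-4)
  expect_equal(lim$ucl[1], 2.882)

  lim <- parametric_limits(study_spec("MEWMA", 2.199), std_normal, n)
  expect_equal(unique(lim$ucl), 2.199 * sqrt(0.125))
  expect_equal(lim$ucl[1], 0.77747, tolerance = 1e-4)

  lim <- parametric_limits(study_spec("MMEM", 5.118), std_normal, n)
  expect_equal(unique(lim$ucl), 5.118 * sqrt(0.125 / 5))
  expect_equal(lim$ucl[1], 0.80921, tolerance = 1e-4)

  lim <- parametric_limits(study_spec("MMME", 5.086), std_normal, n)
  expect_equal(lim$ucl, 5.086 * sqrt(0.125 / pmin(1:n, 5)))

  expect_error(parametric_limits(study_spec("TCC", 1), std_normal, n),
               "tukey_limits")
})

test_that("limit symmetry and monotonicity invariants hold", {
  n <- 12
  for (kind in c("MA", "MEWMA", "MMME", "MMEM")) {
    lim <- parametric_limits(study_spec(kind, 3), std_gamma, n)
    expect_equal((lim$ucl + lim$lcl) / 2, rep(std_gamma$mu0, n))
    expect_true(all(diff(lim$ucl) <= 1e-12))
    expect_equal(lim$ucl[5:n], rep(lim$ucl[5], n - 4))
  }
  for (kind in c("TCC", "MMME_TCC", "MMEM_TCC")) {
    lim <- tukey_limits(study_spec(kind, 2), q1 = 0.3, q3 = 1.1, n = n)
    expect_equal(lim$ucl - 1.1, 0.3 - lim$lcl)   # symmetric IQR offsets
    expect_true(all(diff(lim$ucl) <= 1e-12))
  }
})

test_that("Tukey limit schedules match their closed forms", {
  q <- qnorm(0.75)
  lim <- tukey_limits(chart_spec("TCC", C = 1), -q, q, n = 3)
  expect_equal(lim$ucl, rep(2.023470, 3), tolerance = 1e-6)
  expect_equal(lim$lcl, rep(-2.023470, 3), tolerance = 1e-6)

  # with observation quartiles the constant MMEM-TCC offset is C*IQR*sqrt(vf/w)
  lim <- tukey_limits(study_spec("MMEM_TCC", 5.320), -q, q, n = 6)
  expect_equal(lim$ucl[1], q + 5.320 * 2 * q * sqrt(0.125 / 5))
  expect_equal(lim$ucl[1], 1.809195, tolerance = 1e-5)

  # MMME-TCC narrows like 1/min(t, w)
  lim <- tukey_limits(study_spec("MMME_TCC", 16.610), -q, q, n = 7)
  off <- 16.610 * 2 * q * sqrt(0.125) / pmin(1:7, 5)
  expect_equal(lim$ucl, q + off)

  # limits collapse onto the quartiles as C -> 0
  lim <- tukey_limits(study_spec("MMEM_TCC", 1e-9), -q, q, n = 2)
  expect_equal(lim$ucl, rep(q, 2), tolerance = 1e-6)

  expect_error(tukey_limits(study_spec("TCC", 1), 1, 1, n = 3), "degenerate")
  expect_error(tukey_limits(study_spec("MA", 1), 0, 1, n = 3), "parametric")
})

test_that("default quartile convention uses the smoothing-stage statistic", {
  # MMEM-TCC: quartiles of the span-w moving average
  q <- chart_quartiles(study_spec("MMEM_TCC", 5.32), std_normal)
  expect_equal(unname(q), qnorm(c(0.25, 0.75), 0, 1 / sqrt(5)))
  q <- chart_quartiles(study_spec("MMEM_TCC", 7.174), std_exponential)
  expect_equal(unname(q), qgamma(c(0.25, 0.75), 5, rate = 5))
  q <- chart_quartiles(study_spec("MMEM_TCC", 12.474), std_gamma)
  expect_equal(unname(q), qgamma(c(0.25, 0.75), 20, scale = 1 / 5))

  # MMME-TCC: quartiles of the asymptotic MEWMA statistic (normal closed form)
  q <- chart_quartiles(study_spec("MMME_TCC", 16.61), std_normal)
  expect_equal(unname(q), qnorm(c(0.25, 0.75), 0, sqrt(0.125)))

  # simulated fallback agrees with a closed form where one exists
  q_sim <- mixtcc:::stage_quartiles(std_exponential, study_spec("MMEM_TCC", 1),
                                    "ma", n_sim = 4e5)
  q_th <- qgamma(c(0.25, 0.75), 5, rate = 5)
  expect_lt(max(abs(q_sim - q_th)), 0.01)

  # observation quartiles on request
  q <- chart_quartiles(study_spec("MMEM_TCC", 1), std_normal,
                       source = "observations")
  expect_equal(unname(q), qnorm(c(0.25, 0.75)))
})

test_that("empirical Phase I quartiles use linear interpolation", {
  expect_equal(phase1_quartiles(1:5), c(q1 = 2, q3 = 4))
  expect_equal(unname(phase1_quartiles(rep(3, 4))), c(3, 3))
  expect_error(phase1_quartiles(1:3), "at least 4")
  set.seed(5)
  q <- phase1_quartiles(rnorm(2e5))
  expect_lt(max(abs(q - c(-0.67449, 0.67449))), 0.01)
  # degenerate quartiles are rejected downstream
  expect_error(tukey_limits(study_spec("TCC", 1), 3, 3, n = 2), "degenerate")
})

test_that("first_signal uses strict exceedance and validates horizons", {
  lim <- tukey_limits(chart_spec("TCC", C = 0.25), -0.5, 0.5, n = 3)  # +/- 0.75
  expect_identical(first_signal(c(0, 0, 0), lim), NA_integer_)
  expect_identical(first_signal(c(0, 0, 9), lim), 3L)
  expect_identical(first_signal(c(0.75, 0.75, 0.75), lim), NA_integer_)
  expect_identical(first_signal(c(-0.76, 0, 0), lim), 1L)
  expect_error(first_signal(c(0, 0), lim), "horizons differ")
})
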