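#' Chart specification
#'
#' Bundles a chart kind with its tuning parameters and control-limit
#' coefficient. Supported kinds:
#'
#' * `"MA"` - span-`w` moving average of the observations;
#' * `"MEWMA"` - modified EWMA recursion
#'   `M_t = lambda*x_t + (1-lambda)*M_{t-1} + k*(x_t - x_{t-1})`;
#' * `"MMME"` - moving average applied to the MEWMA statistic;
#' * `"MMEM"` - MEWMA recursion applied to the moving average;
#' * `"TCC"` - Tukey's individuals chart (limits `Q3 + C*IQR`, `Q1 - C*IQR`);
#' * `"MMME_TCC"`, `"MMEM_TCC"` - the two mixed statistics monitored against
#'   Tukey-style quartile limits.
#'
#' Parameters a kind does not use are ignored (`MA` ignores `lambda` and `k`,
#' `MEWMA` ignores `w`).
#'
#' @param kind Chart kind, one of the seven names above.
#' @param C Control-limit coefficient (> 0).
#' @param w Moving-average span (integer >= 1).
#' @param lambda EWMA smoothing constant in (0, 1].
#' @param k Additional MEWMA weight on the last increment (may be negative).
#'
#' @return An object of class `chart_spec`.
#' @examples
#' chart_spec("MMEM_TCC", C = 5.320, w = 5, lambda = 0.25, k = -0.125)
#' @export
chart_spec <- function(kind = c("MA", "MEWMA", "MMME", "MMEM",
                                "TCC", "MMME_TCC", "MMEM_TCC"),
                       C, w = 5L, lambda = 0.25, k = -0.125) {
  kind <- match.arg(kind)
  if (!is.numeric(C) || length(C) != 1 || is.na(C) || C <= 0) {
    stop("C must be a single positive number")
  }
  w <- as.integer(w)
  if (w < 1) stop("w must be >= 1")
  if (lambda <= 0 || lambda > 1) stop("lambda must lie in (0, 1]")
  structure(list(kind = kind, C = C, w = w, lambda = lambda, k = k),
            class = "chart_spec")
}

#' @export
print.chart_spec <- function(x, ...) {
  cat(sprintf("%s chart: C = %g", x$kind, x$C))
  if (uses_window(x$kind)) cat(sprintf(", w = %d", x$w))
  if (uses_smoothing(x$kind)) cat(sprintf(", lambda = %g, k = %g", x$lambda, x$k))
  cat("\n")
  invisible(x)
}

uses_window <- function(kind) kind %in% c("MA", "MMME", "MMEM", "MMME_TCC", "MMEM_TCC")
uses_smoothing <- function(kind) kind %in% c("MEWMA", "MMME", "MMEM", "MMME_TCC", "MMEM_TCC")
is_tukey_kind <- function(kind) kind %in% c("TCC", "MMME_TCC", "MMEM_TCC")

# engine statistic code shared with src/rl_engine.cpp
stat_code <- function(kind) {
  switch(kind, TCC = 0L, MA = 1L, MEWMA = 2L,
         MMME = 3L, MMME_TCC = 3L, MMEM = 4L, MMEM_TCC = 4L)
}

#' Moving-average statistic
#'
#' `MA_t` is the mean of the last `w` observations, or of all observations so
#' far while fewer than `w` have accrued.
#'
#' @param x Numeric observation series.
#' @param w Span (integer >= 1).
#' @return Numeric vector of the same length as `x`.
#' @examples
#' ma_statistic(1:6, w = 3)
#' @export
ma_statistic <- function(x, w) {
  n <- length(x)
  if (n < 1) stop("empty series")
  w <- as.integer(w)
  if (w < 1) stop("w must be >= 1")
  cs <- cumsum(x)
  t <- seq_len(n)
  out <- cs / t
  if (n > w) {
    i <- (w + 1L):n
    out[i] <- (cs[i] - cs[i - w]) / w
  }
  out
}

#' Modified EWMA statistic
#'
#' Runs the recursion
#' `M_t = lambda*x_t + (1-lambda)*M_{t-1} + k*(x_t - x_{t-1})`, with the
#' starting values `M_0 = m0` and the pre-sample observation `x_0 = x0`.
#' Both default to the in-control target in chart use; `k = 0` reduces the
#' recursion to the classical EWMA.
#'
#' @param x Numeric observation series.
#' @param lambda Smoothing constant in (0, 1].
#' @param k Increment weight.
#' @param m0 Initial statistic value.
#' @param x0 Pre-sample observation used by the increment term at `t = 1`.
#' @return Numeric vector of the same length as `x`.
#' @examples
#' mewma_statistic(c(1, 2), lambda = 0.25, k = -0.125, m0 = 0, x0 = 0)
#' @export
mewma_statistic <- function(x, lambda, k, m0 = 0, x0 = m0) {
  if (length(x) < 1) stop("empty series")
  if (lambda <= 0 || lambda > 1) stop("lambda must lie in (0, 1]")
  # M_t - (1-lambda) M_{t-1} = (lambda+k) x_t - k x_{t-1}: a linear recursive
  # filter with one autoregressive coefficient.
  drive <- (lambda + k) * x - k * c(x0, x[-length(x)])
  as.numeric(stats::filter(drive, 1 - lambda, method = "recursive",
                           init = m0))
}

#' Asymptotic variance factor of the modified EWMA
#'
#' Ratio of the asymptotic variance of the MEWMA statistic to the observation
#' variance: `(lambda + 2*lambda*k + 2*k^2) / (2 - lambda)`. With `k = 0`
#' this is the classical EWMA factor `lambda / (2 - lambda)`.
#'
#' @param lambda Smoothing constant (0 < lambda < 2 for a finite variance).
#' @param k Increment weight.
#' @return A single number.
#' @examples
#' variance_factor(0.25, -0.125)  # 0.125
#' @export
variance_factor <- function(lambda, k) {
  if (lambda <= 0 || lambda >= 2) stop("lambda must lie in (0, 2)")
  (lambda + 2 * lambda * k + 2 * k^2) / (2 - lambda)
}

#' Mixed MA-of-MEWMA (MMME) statistic
#'
#' The MEWMA statistic of the observations is smoothed again by a span-`w`
#' moving average.
#'
#' @param x Numeric observation series.
#' @param spec A [chart_spec()] of kind `"MMME"` or `"MMME_TCC"`.
#' @param mu0 In-control mean used to initialize the MEWMA recursion.
#' @return Numeric vector of the same length as `x`.
#' @export
mmme_statistic <- function(x, spec, mu0 = 0) {
  stopifnot(inherits(spec, "chart_spec"))
  ma_statistic(mewma_statistic(x, spec$lambda, spec$k, m0 = mu0, x0 = mu0),
               spec$w)
}

#' Mixed MEWMA-of-MA (MMEM) statistic
#'
#' The span-`w` moving average of the observations is fed through the MEWMA
#' recursion, with both the recursion start and the pre-sample moving average
#' set to `mu0`.
#'
#' @inheritParams mmme_statistic
#' @param spec A [chart_spec()] of kind `"MMEM"` or `"MMEM_TCC"`.
#' @return Numeric vector of the same length as `x`.
#' @export
mmem_statistic <- function(x, spec, mu0 = 0) {
  stopifnot(inherits(spec, "chart_spec"))
  mewma_statistic(ma_statistic(x, spec$w), spec$lambda, spec$k,
                  m0 = mu0, x0 = mu0)
}

#' Monitoring statistic of any chart kind
#'
#' Dispatches to the statistic matching `spec$kind`; `"TCC"` monitors the raw
#' observations.
#'
#' @inheritParams mmme_statistic
#' @param spec A [chart_spec()].
#' @return Numeric vector of the same length as `x`.
#' @export
chart_statistic <- function(x, spec, mu0 = 0) {
  stopifnot(inherits(spec, "chart_spec"))
  switch(spec$kind,
    TCC = as.numeric(x),
    MA = ma_statistic(x, spec$w),
    MEWMA = mewma_statistic(x, spec$lambda, spec$k, m0 = mu0, x0 = mu0),
    MMME = , MMME_TCC = mmme_statistic(x, spec, mu0),
    MMEM = , MMEM_TCC = mmem_statistic(x, spec, mu0)
  )
}

limit_schedule <- function(ucl, lcl) {
  if (length(ucl) != length(lcl)) stop("ucl and lcl lengths differ")
  if (any(lcl >= ucl)) stop("lcl must be strictly below ucl at every t")
  structure(list(ucl = as.numeric(ucl), lcl = as.numeric(lcl)),
            class = "limit_schedule")
}

#' @export
print.limit_schedule <- function(x, ...) {
  n <- length(x$ucl)
  cat(sprintf("Limit schedule over %d point(s); asymptotic UCL = %.6g, LCL = %.6g\n",
              n, x$ucl[n], x$lcl[n]))
  invisible(x)
}

# length-w "profile" of limits: entry min(t, w) applies at time t. All chart
# kinds here have limits constant from t = w onward.
limit_profile <- function(spec, model, quartile_source = "stage", ...) {
  w <- spec$w
  mu0 <- model$mu0; sig <- model$sigma
  if (is_tukey_kind(spec$kind)) {
    q <- chart_quartiles(spec, model, source = quartile_source, ...)
    return(tukey_profile(spec, q[1], q[2]))
  }
  half <- switch(spec$kind,
    MA = spec$C * sig / sqrt(pmin(seq_len(w), w)),
    MEWMA = rep(spec$C * sig * sqrt(variance_factor(spec$lambda, spec$k)), w),
    MMME = spec$C * sig *
      sqrt(variance_factor(spec$lambda, spec$k) / pmin(seq_len(w), w)),
    MMEM = rep(spec$C * sig *
                 sqrt(variance_factor(spec$lambda, spec$k) / w), w)
  )
  list(ucl = mu0 + half, lcl = mu0 - half)
}

tukey_profile <- function(spec, q1, q3) {
  if (q1 >= q3) stop("degenerate quartiles: q1 must be strictly below q3")
  iqr <- q3 - q1
  vf <- if (uses_smoothing(spec$kind)) variance_factor(spec$lambda, spec$k) else NA
  off <- switch(spec$kind,
    TCC = rep(spec$C * iqr, spec$w),
    # time-varying early widening, settling at sqrt(vf)/w from t = w
    MMME_TCC = spec$C * iqr * sqrt(vf) / pmin(seq_len(spec$w), spec$w),
    MMEM_TCC = rep(spec$C * iqr * sqrt(vf / spec$w), spec$w)
  )
  list(ucl = q3 + off, lcl = q1 - off)
}

#' Parametric control-limit schedule
#'
#' Limits of the MA, MEWMA, MMME and MMEM charts around the in-control mean.
#' MA and MMME limits are wider for `t < w` (the moving average has variance
#' `sigma^2/t` there) and constant from `t = w` on; MEWMA and MMEM limits use
#' the asymptotic variance throughout:
#'
#' * MA: `mu0 +/- C * sigma / sqrt(min(t, w))`
#' * MEWMA: `mu0 +/- C * sigma * sqrt(vf)`
#' * MMME: `mu0 +/- C * sigma * sqrt(vf / min(t, w))`
#' * MMEM: `mu0 +/- C * sigma * sqrt(vf / w)`
#'
#' where `vf = variance_factor(lambda, k)`.
#'
#' @param spec A [chart_spec()] of a parametric kind.
#' @param model A [process_model()].
#' @param n Horizon (number of time points).
#' @return A `limit_schedule` with `ucl` and `lcl` of length `n`.
#' @export
parametric_limits <- function(spec, model, n) {
  stopifnot(inherits(spec, "chart_spec"), is_process_model(model))
  if (is_tukey_kind(spec$kind)) {
    stop("use tukey_limits() for Tukey chart kinds")
  }
  expand_profile(limit_profile(spec, model), n, spec$w)
}

#' Tukey-style control-limit schedule from given quartiles
#'
#' Builds nonparametric limits from a first and third quartile. For `"TCC"`
#' the limits are the classical `Q3 + C*IQR` and `Q1 - C*IQR`, constant in
#' time. For the mixed kinds the IQR offset is scaled by the smoothing of the
#' monitored statistic: `sqrt(vf/w)` for `"MMEM_TCC"` (constant in time) and
#' `sqrt(vf)/min(t, w)` for `"MMME_TCC"` (time-varying until `t = w`). Which
#' quartiles to use is the caller's choice; [chart_quartiles()] implements the
#' package default (the quartiles of the smoothing-stage input statistic) and
#' [phase1_quartiles()] the empirical Phase I route.
#'
#' @param spec A [chart_spec()] of kind `"TCC"`, `"MMME_TCC"` or `"MMEM_TCC"`.
#' @param q1,q3 First and third quartile (`q1 < q3`).
#' @param n Horizon (number of time points).
#' @return A `limit_schedule` with `ucl` and `lcl` of length `n`.
#' @examples
#' spec <- chart_spec("TCC", C = 1)
#' tukey_limits(spec, qnorm(0.25), qnorm(0.75), n = 3)
#' @export
tukey_limits <- function(spec, q1, q3, n) {
  stopifnot(inherits(spec, "chart_spec"))
  if (!is_tukey_kind(spec$kind)) {
    stop("use parametric_limits() for parametric chart kinds")
  }
  expand_profile(tukey_profile(spec, q1, q3), n, spec$w)
}

expand_profile <- function(prof, n, w) {
  idx <- pmin(seq_len(n), length(prof$ucl))
  limit_schedule(prof$ucl[idx], prof$lcl[idx])
}

#' Quartiles used by the Tukey chart kinds
#'
#' The package's default quartile convention for the mixed Tukey charts is the
#' theoretical quartiles of the *smoothing-stage input statistic*: the span-w
#' moving average for `"MMEM_TCC"` (whose distribution is known in closed form
#' for normal, exponential and gamma models) and the asymptotic MEWMA
#' statistic for `"MMME_TCC"` (closed form under the normal model). Where no
#' closed form exists the quartiles are estimated once from a long simulated
#' in-control stream of the stage statistic. `"TCC"` uses the observation
#' quartiles, and `source = "observations"` forces them for any kind.
#'
#' @param spec A [chart_spec()] of a Tukey kind.
#' @param model A [process_model()].
#' @param source `"stage"` (default) or `"observations"`.
#' @param n_sim Stream length for the simulated fallback.
#' @param sim_seed Seed for the simulated fallback (fixed so that limits are
#'   reproducible).
#' @return Numeric vector `c(q1, q3)`.
#' @export
chart_quartiles <- function(spec, model, source = c("stage", "observations"),
                            n_sim = 1e6, sim_seed = 20220929) {
  stopifnot(inherits(spec, "chart_spec"), is_process_model(model))
  source <- match.arg(source)
  if (source == "observations" || spec$kind == "TCC") {
    return(c(q1 = model$q1, q3 = model$q3))
  }
  stage <- if (spec$kind == "MMEM_TCC") "ma" else "mewma"
  stage_quartiles(model, spec, stage, n_sim = n_sim, sim_seed = sim_seed)
}

stage_quartiles <- function(model, spec, stage = c("ma", "mewma"),
                            n_sim = 1e6, sim_seed = 20220929) {
  stage <- match.arg(stage)
  p <- c(0.25, 0.75)
  if (stage == "ma") {
    w <- spec$w
    q <- switch(model$family,
      normal = stats::qnorm(p, model$params[1], sqrt(model$params[2] / w)),
      exponential = stats::qgamma(p, w, rate = w * model$params[1]),
      gamma = stats::qgamma(p, w * model$params[1],
                            scale = model$params[2] / w),
      NULL)
    if (!is.null(q)) return(c(q1 = q[1], q3 = q[2]))
  } else if (model$family == "normal") {
    s <- model$sigma * sqrt(variance_factor(spec$lambda, spec$k))
    return(c(q1 = stats::qnorm(0.25, model$mu0, s),
             q3 = stats::qnorm(0.75, model$mu0, s)))
  }
  # no closed form: estimate from a long simulated in-control stream
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(sim_seed)
  x <- sample_shifted(model, 0, n_sim)
  s <- if (stage == "ma") {
    ma_statistic(x, spec$w)
  } else {
    mewma_statistic(x, spec$lambda, spec$k, m0 = model$mu0, x0 = model$mu0)
  }
  burn <- min(1000L, n_sim %/% 10L)
  q <- stats::quantile(s[-seq_len(burn)], p, names = FALSE, type = 7)
  c(q1 = q[1], q3 = q[2])
}

#' Control limits for any chart kind
#'
#' High-level wrapper dispatching to [parametric_limits()] or
#' [tukey_limits()] with the package's default quartile convention.
#'
#' @inheritParams parametric_limits
#' @param quartile_source Passed to [chart_quartiles()] for Tukey kinds.
#' @param ... Further arguments to [chart_quartiles()].
#' @return A `limit_schedule`.
#' @export
chart_limits <- function(spec, model, n, quartile_source = "stage", ...) {
  stopifnot(inherits(spec, "chart_spec"), is_process_model(model))
  expand_profile(limit_profile(spec, model, quartile_source, ...), n, spec$w)
}

#' Empirical Phase I quartiles
#'
#' First and third sample quartiles using linear interpolation between order
#' statistics (the "type 7" quantile rule), for Phase I estimation of Tukey
#' limits from data.
#'
#' @param x Numeric vector with at least 4 observations.
#' @return Numeric vector `c(q1, q3)`.
#' @examples
#' phase1_quartiles(1:5)  # c(2, 4)
#' @export
phase1_quartiles <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 4) stop("need at least 4 observations")
  q <- stats::quantile(x, c(0.25, 0.75), names = FALSE, type = 7)
  c(q1 = q[1], q3 = q[2])
}

#' First out-of-control signal
#'
#' Index of the first statistic value strictly outside the limits; values
#' exactly on a limit are in control.
#'
#' @param stats Numeric statistic series.
#' @param limits A `limit_schedule` covering the same horizon.
#' @return The first signal index, or `NA_integer_` if none.
#' @examples
#' lim <- tukey_limits(chart_spec("TCC", C = 1), q1 = -1, q3 = 1, n = 3)
#' first_signal(c(0, 0, 9), lim)
#' @export
first_signal <- function(stats, limits) {
  if (!inherits(limits, "limit_schedule")) stop("limits must be a limit_schedule")
  if (length(stats) != length(limits$ucl)) {
    stop("statistic and limit horizons differ")
  }
  out <- which(stats > limits$ucl | stats < limits$lcl)
  if (length(out)) out[1] else NA_integer_
}
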