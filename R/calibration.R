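#' Calibrate a control-limit coefficient to a target in-control ARL
#'
#' Finds the coefficient `C` at which the chart's in-control ARL equals
#' `target_arl0`, by geometric bracketing followed by bisection. All probes
#' reuse the same random numbers (the probe seed is reset before each ARL
#' evaluation) so the ARL-versus-C response is monotone up to the statistic's
#' evaluation noise; the achieved ARL at the returned coefficient is then
#' re-estimated with an independent seed to avoid optimization bias.
#'
#' @param spec A [chart_spec()] whose `C` serves as the starting probe.
#' @param model A [process_model()].
#' @param target_arl0 Target in-control ARL (> 1).
#' @param n_reps Replications per probe.
#' @param seed Integer seed (probes use `seed`; the confirmation run uses
#'   `seed + 1`).
#' @param tol Acceptance half-width in ARL units; the search stops when the
#'   common-random-number probe ARL is within `tol` of the target (or the
#'   bracket is numerically exhausted).
#' @param c_max Upper bound of the admissible coefficient range.
#' @param max_iter Bisection iteration cap.
#' @param counting,quartile_source,max_horizon Passed to
#'   [estimate_rl_summary()].
#'
#' @return An object of class `calibration_result`: `c_star`,
#'   `achieved_arl0`, `se` (both from the fresh-seed confirmation run),
#'   `trace` (data frame of probed `C` and ARL), `target` and `tol`.
#' @examples
#' \donttest{
#' spec <- chart_spec("MA", C = 3, w = 1)
#' calibrate_coefficient(spec, process_model("normal", c(0, 1)),
#'                       target_arl0 = 370.4, n_reps = 5000, seed = 1)
#' }
#' @export
calibrate_coefficient <- function(spec, model, target_arl0 = 370,
                                  n_reps = 20000L, seed = 1L, tol = 1,
                                  c_max = 100, max_iter = 60L,
                                  counting = "signal",
                                  quartile_source = "stage",
                                  max_horizon = 20000L) {
  stopifnot(inherits(spec, "chart_spec"), is_process_model(model))
  if (target_arl0 <= 1) stop("target_arl0 must be > 1")
  trace_C <- numeric(0)
  trace_arl <- numeric(0)
  trace_se <- numeric(0)
  probe <- function(C) {
    s <- estimate_rl_summary(modify_C(spec, C), model, delta = 0,
                             n_reps = n_reps, seed = seed,
                             max_horizon = max_horizon, counting = counting,
                             quartile_source = quartile_source)
    trace_C <<- c(trace_C, C)
    trace_arl <<- c(trace_arl, s$arl)
    trace_se <<- c(trace_se, s$se_arl)
    s
  }

  # bracket: expand geometrically from the starting C
  lo <- hi <- spec$C
  s <- probe(spec$C)
  if (s$arl < target_arl0) {
    repeat {
      hi <- hi * 1.5
      if (hi > c_max) stop("no bracket found: ARL below target for all C <= c_max")
      if (probe(hi)$arl >= target_arl0) break
      lo <- hi
    }
  } else {
    repeat {
      lo <- lo / 1.5
      if (lo < 1e-6) stop("no bracket found: ARL above target for all probed C")
      if (probe(lo)$arl <= target_arl0) break
      hi <- lo
    }
  }

  # With common random numbers the ARL-versus-C response is smooth, so the
  # bisection is pushed to `tol` directly rather than stopping at the Monte
  # Carlo noise level.
  c_star <- (lo + hi) / 2
  for (i in seq_len(max_iter)) {
    c_star <- (lo + hi) / 2
    s <- probe(c_star)
    if (abs(s$arl - target_arl0) <= tol) break
    if (s$arl < target_arl0) lo <- c_star else hi <- c_star
    if ((hi - lo) < 1e-7 * max(1, c_star)) break
  }

  trace <- data.frame(C = trace_C, arl = trace_arl, se = trace_se)
  o <- order(trace$C)
  non_mono <- diff(trace$arl[o]) < -4 * sqrt(trace_se[o][-1]^2 +
                                               trace_se[o][-nrow(trace)]^2)
  if (any(non_mono)) {
    warning("ARL-versus-C probe trace decreases beyond Monte Carlo noise; ",
            "inspect the trace")
  }

  conf <- estimate_rl_summary(modify_C(spec, c_star), model, delta = 0,
                              n_reps = n_reps, seed = seed + 1L,
                              max_horizon = max_horizon, counting = counting,
                              quartile_source = quartile_source)
  structure(list(c_star = c_star, achieved_arl0 = conf$arl, se = conf$se_arl,
                 trace = trace, target = target_arl0, tol = tol,
                 spec = modify_C(spec, c_star)),
            class = "calibration_result")
}

modify_C <- function(spec, C) {
  spec$C <- C
  spec
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("Calibrated %s coefficient: C = %.4f\n", x$spec$kind, x$c_star))
  cat(sprintf("  achieved in-control ARL %.2f (se %.3f) against target %.1f\n",
              x$achieved_arl0, x$se, x$target))
  cat(sprintf("  %d probe(s); tolerance %.2f ARL units\n", nrow(x$trace), x$tol))
  invisible(x)
}

#' Expected ARL over a shift interval
#'
#' Averages the out-of-control ARL over shifts in `[delta_lo, delta_hi]`:
#' the integral `EARL = 1/(d2 - d1) * int ARL(delta) d delta` approximated by
#' the trapezoidal rule on an equally spaced grid (exact for ARL linear in
#' the shift).
#'
#' @inheritParams estimate_rl_summary
#' @param delta_lo,delta_hi Interval bounds (`delta_lo < delta_hi`).
#' @param n_grid Number of grid points including both ends (>= 2).
#'
#' @return An object of class `earl_result`: `earl`, `delta_lo`, `delta_hi`,
#'   `grid`, `arls`, `se_arls`.
#' @export
expected_arl <- function(spec, model, delta_lo, delta_hi, n_grid = 9L,
                         n_reps = 10000L, seed = 1L, max_horizon = 20000L,
                         counting = "signal", shift_type = "location",
                         quartile_source = "stage") {
  stopifnot(inherits(spec, "chart_spec"), is_process_model(model))
  if (delta_lo >= delta_hi) stop("delta_lo must be below delta_hi")
  if (n_grid < 2) stop("n_grid must be >= 2")
  grid <- seq(delta_lo, delta_hi, length.out = n_grid)
  res <- lapply(seq_along(grid), function(i) {
    estimate_rl_summary(spec, model, grid[i], n_reps = n_reps,
                        seed = seed + i - 1L, max_horizon = max_horizon,
                        counting = counting, shift_type = shift_type,
                        quartile_source = quartile_source)
  })
  arls <- vapply(res, `[[`, numeric(1), "arl")
  ses <- vapply(res, `[[`, numeric(1), "se_arl")
  tw <- c(0.5, rep(1, n_grid - 2), 0.5) / (n_grid - 1)   # trapezoid weights
  structure(list(earl = sum(tw * arls), delta_lo = delta_lo,
                 delta_hi = delta_hi, grid = grid, arls = arls,
                 se_arls = ses),
            class = "earl_result")
}

#' @export
print.earl_result <- function(x, ...) {
  cat(sprintf("EARL over [%g, %g] (%d-point trapezoid): %.2f\n",
              x$delta_lo, x$delta_hi, length(x$grid), x$earl))
  invisible(x)
}
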