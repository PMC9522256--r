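rl_engine <- function(spec, model, delta, n_reps, max_horizon,
                      shift_type = "location", quartile_source = "stage", ...) {
  prof <- limit_profile(spec, model, quartile_source, ...)
  a <- engine_dist_args(model, delta, shift_type)
  .rl_sim_cpp(as.integer(n_reps), as.integer(max_horizon),
              stat_code(spec$kind), spec$w, spec$lambda, spec$k,
              model$mu0, prof$ucl, prof$lcl,
              a$dist, a$p1, a$p2, a$shift)
}

#' Simulate a single run length
#'
#' Streams shifted observations through the chart statistic and returns the
#' index of the first out-of-control signal (zero-state: the shift is present
#' from `t = 1`). If no signal occurs within `max_horizon` the run is censored
#' at the horizon.
#'
#' @param spec A [chart_spec()].
#' @param model A [process_model()].
#' @param delta Mean shift in in-control standard deviations.
#' @param seed Integer seed.
#' @param max_horizon Truncation bound.
#' @param shift_type `"location"` or `"scale"` (see [sample_shifted()]).
#' @param quartile_source Quartile convention for Tukey kinds
#'   (see [chart_quartiles()]).
#'
#' @return An integer run length with attribute `censored`.
#' @export
simulate_run_length <- function(spec, model, delta, seed,
                                max_horizon = 20000L,
                                shift_type = "location",
                                quartile_source = "stage") {
  if (max_horizon < 1) stop("max_horizon must be >= 1")
  set.seed(seed)
  r <- rl_engine(spec, model, delta, 1L, max_horizon, shift_type, quartile_source)
  structure(r$rl[1], censored = r$censored[1])
}

#' Monte Carlo run-length summary
#'
#' Estimates the run-length distribution of a chart/model/shift combination by
#' independent zero-state replications and summarizes it as the average run
#' length (ARL), the standard deviation of run length (SDRL, from the second
#' moment), and the median run length (MRL, lower median for even replicate
#' counts), together with the Monte Carlo standard error of the ARL and the
#' number of replicates censored at the truncation horizon.
#'
#' `counting` selects the run-length convention: `"signal"` (default) counts
#' the first-signal index `T` itself; `"pre-signal"` counts the in-control
#' points preceding the alarm, `max(T - 1, 1)`, which is the convention of the
#' published benchmark tables this package reproduces (see the package
#' vignette for how it was identified).
#'
#' @inheritParams simulate_run_length
#' @param n_reps Number of replications (>= 2).
#' @param counting `"signal"` or `"pre-signal"`.
#'
#' @return An object of class `rl_summary`: a list with `arl`, `sdrl`, `mrl`,
#'   `n_reps`, `se_arl`, `max_horizon`, `n_censored`, `counting`, plus the
#'   `spec`, `delta` and `shift_type` that produced it.
#' @examples
#' \donttest{
#' spec <- chart_spec("MA", C = 3, w = 1)
#' estimate_rl_summary(spec, process_model("normal", c(0, 1)),
#'                     delta = 0, n_reps = 2000, seed = 1)
#' }
#' @export
estimate_rl_summary <- function(spec, model, delta, n_reps, seed,
                                max_horizon = 20000L,
                                counting = c("signal", "pre-signal"),
                                shift_type = "location",
                                quartile_source = "stage") {
  counting <- match.arg(counting)
  if (n_reps < 2) stop("n_reps must be >= 2")
  set.seed(seed)
  r <- rl_engine(spec, model, delta, n_reps, max_horizon,
                 shift_type, quartile_source)
  rl <- r$rl
  if (counting == "pre-signal") rl <- pmax(rl - 1L, 1L)
  summarize_rl(rl, sum(r$censored), max_horizon, counting, spec, delta,
               shift_type)
}

summarize_rl <- function(rl, n_censored, max_horizon, counting, spec, delta,
                         shift_type) {
  n <- length(rl)
  arl <- mean(rl)
  sdrl <- sqrt(max(mean(rl^2) - arl^2, 0))
  structure(list(
    arl = arl,
    sdrl = sdrl,
    mrl = sort.int(rl, method = "quick")[ceiling(n / 2)],
    n_reps = n,
    se_arl = stats::sd(rl) / sqrt(n),
    max_horizon = max_horizon,
    n_censored = n_censored,
    counting = counting,
    spec = spec,
    delta = delta,
    shift_type = shift_type
  ), class = "rl_summary")
}

#' @export
print.rl_summary <- function(x, ...) {
  cat(sprintf("%s chart run-length summary (delta = %g, %s shift, %s counting)\n",
              x$spec$kind, x$delta, x$shift_type, x$counting))
  cat(sprintf("  ARL  = %.2f  (MC se %.3f, %d replications)\n",
              x$arl, x$se_arl, x$n_reps))
  cat(sprintf("  SDRL = %.2f   MRL = %d\n", x$sdrl, x$mrl))
  if (x$n_censored > 0) {
    cat(sprintf("  %d replication(s) censored at horizon %d\n",
                x$n_censored, x$max_horizon))
  }
  invisible(x)
}
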