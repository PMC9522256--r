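# Independent run-length calculations used as correctness oracles for the
# Monte Carlo engine: exact geometric run lengths for memoryless (Shewhart)
# charts, and the classical Fredholm integral-equation ARL for the EWMA.

#' Closed-form ARL of a memoryless (Shewhart-type) chart
#'
#' For a chart that signals whenever a single observation leaves
#' `mu0 +/- C * sigma`, the run length is geometric and the ARL is `1/p` with
#' `p` the per-observation exceedance probability under the shifted law. The
#' MA chart with `w = 1` reduces to this case.
#'
#' @param C Limit coefficient.
#' @param delta Mean shift in in-control standard deviations.
#' @param model A [process_model()].
#' @param shift_type `"location"` or `"scale"`.
#' @return The exact ARL (1/p).
#' @examples
#' shewhart_arl_closed_form(3, 0, process_model("normal", c(0, 1)))  # 370.4
#' @export
shewhart_arl_closed_form <- function(C, delta, model,
                                     shift_type = "location") {
  stopifnot(is_process_model(model))
  ucl <- model$mu0 + C * model$sigma
  lcl <- model$mu0 - C * model$sigma
  p <- model_cdf(model, lcl, delta, shift_type) +
    1 - model_cdf(model, ucl, delta, shift_type)
  if (p <= .Machine$double.xmin) stop("exceedance probability is numerically zero")
  1 / p
}

#' EWMA ARL by the integral-equation (Nystrom) method
#'
#' Solves the standard Fredholm integral equation for the zero-state ARL of
#' the classical EWMA chart (`Z_t = (1-lambda) Z_{t-1} + lambda X_t`, standard
#' normal observations shifted by `delta`, asymptotic limits
#' `+/- L * sqrt(lambda/(2-lambda))`) by Gauss-Legendre discretization:
#'
#' `ARL(u) = 1 + (1/lambda) * int_{-h}^{h} ARL(z) phi((z-(1-lambda)u)/lambda - delta) dz`
#'
#' This is the `k = 0` special case of the MEWMA recursion and serves as a
#' Monte-Carlo-free cross-check of the simulation engine.
#'
#' @param lambda Smoothing constant in (0, 1].
#' @param L Limit width in asymptotic standard deviations of the statistic.
#' @param delta Mean shift in standard deviations.
#' @param resolution Number of quadrature nodes (>= 15).
#' @return The ARL started from the in-control target (0).
#' @examples
#' ewma_arl_integral_equation(0.25, 2.898)  # about 370
#' @export
ewma_arl_integral_equation <- function(lambda, L, delta = 0, resolution = 61L) {
  if (lambda <= 0 || lambda > 1) stop("lambda must lie in (0, 1]")
  if (resolution < 15) stop("resolution must be >= 15")
  h <- L * sqrt(lambda / (2 - lambda))
  gl <- pracma::gaussLegendre(as.integer(resolution), -h, h)
  z <- gl$x; wgt <- gl$w
  # kernel K[i, j] = w_j * f(z_j | current state z_i)
  K <- outer(z, z, function(u, v) {
    stats::dnorm((v - (1 - lambda) * u) / lambda - delta) / lambda
  })
  K <- sweep(K, 2, wgt, `*`)
  a <- tryCatch(solve(diag(resolution) - K, rep(1, resolution)),
                error = function(e) stop("singular Nystrom system: ", conditionMessage(e)))
  # ARL at the in-control start u = 0
  k0 <- stats::dnorm(z / lambda - delta) / lambda
  1 + sum(wgt * k0 * a)
}
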