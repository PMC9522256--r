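#' In-control process models
#'
#' Construct the in-control observation model used throughout the simulation
#' study: one of four distributional families with closed-form mean, standard
#' deviation and quartiles. Parameter conventions: `normal` takes mean and
#' variance, `laplace` takes location and scale (variance `2 * b^2`),
#' `exponential` takes the rate (mean `1/rate`), `gamma` takes shape and scale
#' (mean `shape * scale`, variance `shape * scale^2`).
#'
#' @param family One of `"normal"`, `"laplace"`, `"exponential"`, `"gamma"`.
#' @param params Numeric vector of family parameters in the order above
#'   (length 1 for `exponential`, length 2 otherwise).
#'
#' @return An object of class `process_model` with elements `family`,
#'   `params`, `mu0`, `sigma`, `q1`, `q3`.
#'
#' @examples
#' process_model("normal", c(0, 1))
#' process_model("gamma", c(4, 1))
#' @export
process_model <- function(family = c("normal", "laplace", "exponential", "gamma"),
                          params) {
  family <- match.arg(family)
  params <- as.numeric(params)
  n_par <- if (family == "exponential") 1L else 2L
  if (length(params) != n_par) {
    stop(sprintf("family '%s' needs %d parameter(s)", family, n_par))
  }
  m <- switch(family,
    normal = {
      if (params[2] <= 0) stop("normal variance must be > 0")
      mu <- params[1]; s <- sqrt(params[2])
      list(mu0 = mu, sigma = s,
           q1 = stats::qnorm(0.25, mu, s), q3 = stats::qnorm(0.75, mu, s))
    },
    laplace = {
      if (params[2] <= 0) stop("laplace scale must be > 0")
      mu <- params[1]; b <- params[2]
      # quartiles of Laplace(mu, b): mu -/+ b*log(2)
      list(mu0 = mu, sigma = b * sqrt(2),
           q1 = mu - b * log(2), q3 = mu + b * log(2))
    },
    exponential = {
      if (params[1] <= 0) stop("exponential rate must be > 0")
      r <- params[1]
      list(mu0 = 1 / r, sigma = 1 / r,
           q1 = stats::qexp(0.25, r), q3 = stats::qexp(0.75, r))
    },
    gamma = {
      if (any(params <= 0)) stop("gamma shape and scale must be > 0")
      a <- params[1]; b <- params[2]
      list(mu0 = a * b, sigma = sqrt(a) * b,
           q1 = stats::qgamma(0.25, a, scale = b),
           q3 = stats::qgamma(0.75, a, scale = b))
    }
  )
  structure(c(list(family = family, params = params), m),
            class = "process_model")
}

#' @export
print.process_model <- function(x, ...) {
  cat(sprintf("In-control process model: %s(%s)\n",
              x$family, paste(format(x$params), collapse = ", ")))
  cat(sprintf("  mu0 = %.6g  sigma = %.6g  Q1 = %.6g  Q3 = %.6g\n",
              x$mu0, x$sigma, x$q1, x$q3))
  invisible(x)
}

is_process_model <- function(x) inherits(x, "process_model")

# Engine distribution code and parameters for a model after injecting a mean
# shift of delta in-control standard deviations. Location shifts add
# delta*sigma to every draw; scale shifts multiply the observation by
# (1 + delta*sigma/mu0), which moves the mean by the same delta*sigma but
# inflates the spread proportionally (only defined for positive-mean models).
engine_dist_args <- function(model, delta, type = c("location", "scale")) {
  type <- match.arg(type)
  code <- match(model$family, c("normal", "laplace", "exponential", "gamma"))
  p <- model$params
  if (type == "location") {
    p1 <- p[1]
    p2 <- if (model$family == "exponential") 1 else p[2]
    if (model$family == "normal") p2 <- sqrt(p[2])
    return(list(dist = code, p1 = p1, p2 = p2, shift = delta * model$sigma))
  }
  if (model$mu0 <= 0) {
    stop("scale shifts require a positive in-control mean")
  }
  fac <- 1 + delta * model$sigma / model$mu0
  if (fac <= 0) stop("scale shift factor must be positive")
  args <- switch(model$family,
    normal = list(p1 = p[1] * fac, p2 = sqrt(p[2]) * fac),
    laplace = list(p1 = p[1] * fac, p2 = p[2] * fac),
    exponential = list(p1 = p[1] / fac, p2 = 1),
    gamma = list(p1 = p[1], p2 = p[2] * fac)
  )
  list(dist = code, p1 = args$p1, p2 = args$p2, shift = 0)
}

#' Draw a shifted sample from a process model
#'
#' Generates `n` independent observations whose mean is displaced from the
#' in-control mean by `delta` in-control standard deviations. With
#' `type = "location"` (the default) the shift is purely additive,
#' `X = Y + delta * sigma`; with `type = "scale"` the observation is rescaled
#' multiplicatively so that the mean moves by the same amount but the spread
#' grows with it (only available for positive-mean models). Scale shifts are
#' how skewed, positive-valued series such as particulate-matter loads tend to
#' drift in practice, and they are the convention behind the exponential
#' benchmark table this package reproduces.
#'
#' @param model A [process_model()].
#' @param delta Shift size in units of the in-control standard deviation.
#' @param n Number of observations (>= 1).
#' @param seed Optional integer seed (uses the current RNG state if `NULL`).
#' @param type `"location"` or `"scale"`.
#'
#' @return An object of class `shifted_sample`: a numeric vector with
#'   attributes `delta`, `type` and `seed`.
#' @examples
#' x <- sample_shifted(process_model("exponential", 1), delta = 0.5, n = 5, seed = 1)
#' @export
sample_shifted <- function(model, delta, n, seed = NULL,
                           type = c("location", "scale")) {
  stopifnot(is_process_model(model))
  type <- match.arg(type)
  if (n < 1) stop("n must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  a <- engine_dist_args(model, delta, type)
  y <- switch(a$dist,
    stats::rnorm(n, a$p1, a$p2),
    a$p1 + a$p2 * (stats::rexp(n) - stats::rexp(n)),
    stats::rexp(n, a$p1),
    stats::rgamma(n, a$p1, scale = a$p2)
  )
  structure(y + a$shift, delta = delta, type = type, seed = seed,
            class = c("shifted_sample", "numeric"))
}

# Theoretical CDF of a (possibly shifted) observation, used by the closed-form
# run-length oracles.
model_cdf <- function(model, q, delta = 0, type = c("location", "scale")) {
  a <- engine_dist_args(model, delta, match.arg(type))
  q <- q - a$shift
  switch(a$dist,
    stats::pnorm(q, a$p1, a$p2),
    { z <- (q - a$p1) / a$p2
      ifelse(z < 0, 0.5 * exp(z), 1 - 0.5 * exp(-z)) },
    stats::pexp(q, a$p1),
    stats::pgamma(q, a$p1, scale = a$p2)
  )
}
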