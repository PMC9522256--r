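# Shared fixtures: the four study models and the common chart settings
# (w = 5, lambda = 0.25, k = -0.125).

std_normal <- process_model("normal", c(0, 1))
std_laplace <- process_model("laplace", c(0, 1))
std_exponential <- process_model("exponential", 1)
std_gamma <- process_model("gamma", c(4, 1))

study_models <- list(normal = std_normal, laplace = std_laplace,
                     exponential = std_exponential, gamma = std_gamma)

study_spec <- function(kind, C) chart_spec(kind, C = C, w = 5, lambda = 0.25,
                                           k = -0.125)

# plain-R reference EWMA recursion, kept independent of mewma_statistic()
ewma_reference <- function(x, lambda, z0 = 0) {
  z <- numeric(length(x))
  prev <- z0
  for (i in seq_along(x)) {
    prev <- lambda * x[i] + (1 - lambda) * prev
    z[i] <- prev
  }
  z
}
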