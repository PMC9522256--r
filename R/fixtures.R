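# Synthetic particulate-matter-like demonstration series. The defaults mimic
# hourly PM2.5 / PM10 load distributions reported for an urban monitoring
# station: PM2.5 exponential with rate 0.0396 (mean ~25.3 ug/m3), PM10 gamma
# with shape 11.5527 and scale 3.2963 (mean ~38.1 ug/m3).

pm_model <- function(kind = c("pm25", "pm10")) {
  switch(match.arg(kind),
         pm25 = process_model("exponential", 0.0396),
         pm10 = process_model("gamma", c(11.5527, 3.2963)))
}

#' Generate a PM-like surveillance series
#'
#' Draws an in-control series from the PM2.5 or PM10 model and, if a
#' changepoint is given, adds a sustained mean shift of `delta` in-control
#' standard deviations from that index onward. The pre-changepoint segment is
#' in control by construction.
#'
#' @param kind `"pm25"` (exponential) or `"pm10"` (gamma).
#' @param n Series length (>= 1).
#' @param changepoint Index at which the shift begins (1 to `n`), or `NULL`
#'   for a fully in-control series.
#' @param delta Post-changepoint shift in in-control standard deviations.
#' @param seed Integer seed.
#'
#' @return An object of class `pm_series`: a numeric vector with attributes
#'   `model`, `changepoint`, `delta` and `seed`.
#' @examples
#' x <- make_pm_series("pm25", n = 100, changepoint = 51, delta = 1, seed = 1)
#' @export
make_pm_series <- function(kind = c("pm25", "pm10"), n, changepoint = NULL,
                           delta = 0, seed = 1L) {
  kind <- match.arg(kind)
  if (n < 1) stop("n must be >= 1")
  if (!is.null(changepoint) &&
      (changepoint < 1 || changepoint > n)) {
    stop("changepoint must lie between 1 and n")
  }
  model <- pm_model(kind)
  set.seed(seed)
  x <- as.numeric(sample_shifted(model, 0, n))
  if (!is.null(changepoint) && delta != 0) {
    idx <- changepoint:n
    x[idx] <- x[idx] + delta * model$sigma
  }
  structure(x, model = model, changepoint = changepoint, delta = delta,
            seed = seed, class = c("pm_series", "numeric"))
}

#' Write / read a single-column series
#'
#' The on-disk format is one numeric observation per line with a one-line
#' header, the same format the monitoring front end reads.
#'
#' @param x Numeric series.
#' @param path File path.
#' @param header Column name written on the first line.
#' @return `write_series` returns `path` invisibly; `read_series` returns a
#'   numeric vector.
#' @export
write_series <- function(x, path, header = "value") {
  writeLines(c(header, format(as.numeric(x), digits = 15, trim = TRUE,
                              scientific = FALSE)), path)
  invisible(path)
}

#' @rdname write_series
#' @export
read_series <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty series file: ", path)
  first <- suppressWarnings(as.numeric(lines[1]))
  if (is.na(first)) lines <- lines[-1]          # optional header
  x <- suppressWarnings(as.numeric(lines))
  if (anyNA(x)) {
    stop("non-numeric rows in ", path, " at line(s) ",
         paste(utils::head(which(is.na(x)), 5), collapse = ", "))
  }
  x
}
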