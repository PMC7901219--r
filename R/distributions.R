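#' Method-of-moments beta distribution from a mean and range
#'
#' Treats `(lo, hi)` as a central 95% interval, so `sd = (hi - lo) / 3.92`,
#' and solves the beta moment equations:
#' `alpha = mean * (mean (1 - mean) / sd^2 - 1)`, `beta` likewise.  A zero
#' width interval collapses to a point mass.
#'
#' @param mean Mean in (0, 1).
#' @param lo,hi Central 95% interval bounds within \[0, 1\].
#' @return A `param_dist` list: `dist` (`"beta"` or `"point"`) plus its
#'   parameters and the target `mean`.
#' @examples
#' fit_beta(0.5, 0.4, 0.6) # alpha = beta = 47.52
#' @export
fit_beta <- function(mean, lo, hi) {
  stopifnot(mean > 0, mean < 1, lo <= hi, lo >= 0, hi <= 1)
  sd <- (hi - lo) / 3.92
  if (sd == 0) {
    return(structure(list(dist = "point", value = mean, mean = mean),
                     class = "param_dist"))
  }
  v <- sd^2
  if (v >= mean * (1 - mean)) {
    abort(sprintf("implied variance %.4g is not attainable for a beta with mean %.4g.",
                  v, mean),
          class = "markovcea_invalid_spread")
  }
  k <- mean * (1 - mean) / v - 1
  structure(list(dist = "beta", shape1 = mean * k, shape2 = (1 - mean) * k,
                 mean = mean),
            class = "param_dist")
}

#' Method-of-moments gamma distribution from a mean and range
#'
#' As [fit_beta()] but for non-negative cost parameters:
#' `sd = (hi - lo) / 3.92`, `shape = (mean / sd)^2`,
#' `scale = sd^2 / mean`.
#'
#' @param mean Mean (> 0).
#' @param lo,hi Central 95% interval bounds.
#' @return A `param_dist` list (`dist` `"gamma"` or `"point"`).
#' @examples
#' fit_gamma(100, 80, 120) # shape 96.04, scale 1.0412
#' @export
fit_gamma <- function(mean, lo, hi) {
  stopifnot(mean > 0, lo <= hi)
  sd <- (hi - lo) / 3.92
  if (sd == 0) {
    return(structure(list(dist = "point", value = mean, mean = mean),
                     class = "param_dist"))
  }
  structure(list(dist = "gamma", shape = (mean / sd)^2, scale = sd^2 / mean,
                 mean = mean),
            class = "param_dist")
}

#' Sample from a fitted parameter distribution
#'
#' @param d A `param_dist` from [fit_beta()] or [fit_gamma()].
#' @param n Number of draws.
#' @return Numeric vector of length `n`.
#' @export
sample_dist <- function(d, n) {
  stopifnot(inherits(d, "param_dist"))
  switch(d$dist,
         point = rep(d$value, n),
         beta = rbeta(n, d$shape1, d$shape2),
         gamma = rgamma(n, shape = d$shape, scale = d$scale),
         abort(sprintf("unknown distribution '%s'.", d$dist)))
}

#' @export
print.param_dist <- function(x, ...) {
  cat(switch(x$dist,
             point = sprintf("<param_dist> point mass at %.6g\n", x$value),
             beta = sprintf("<param_dist> beta(%.4g, %.4g), mean %.4g\n",
                            x$shape1, x$shape2, x$mean),
             gamma = sprintf("<param_dist> gamma(shape %.4g, scale %.4g), mean %.4g\n",
                             x$shape, x$scale, x$mean)))
  invisible(x)
}
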