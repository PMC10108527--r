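#' Wrap angles into (-pi, pi]
#'
#' Course reversals map to +pi (half-open interval convention).
#'
#' @param a numeric vector of angles in radians.
#' @return angles wrapped into `(-pi, pi]`.
#' @export
#' @examples
#' wrap_angle(c(0, pi, -pi, 3 * pi / 2))
wrap_angle <- function(a) {
  w <- a %% (2 * pi)
  ifelse(is.finite(w) & w > pi, w - 2 * pi, w)
}

.check_zigamma_pars <- function(mean, sd, zeromass) {
  if (any(!is.finite(mean)) || any(mean <= 0)) stop("'mean' must be finite and > 0")
  if (any(!is.finite(sd)) || any(sd <= 0)) stop("'sd' must be finite and > 0")
  if (any(zeromass < 0) || any(zeromass >= 1)) stop("'zeromass' must be in [0, 1)")
  invisible(TRUE)
}

#' Zero-inflated gamma distribution
#'
#' Mixture of a point mass at zero (probability `zeromass`) and a gamma
#' distribution parameterized by its mean and standard deviation
#' (shape = (mean/sd)^2, rate = mean/sd^2). Used for step lengths and RMS
#' acceleration, which are non-negative with exact zeros when an animal does
#' not move.
#'
#' @param x,q vector of non-negative quantiles.
#' @param n number of draws.
#' @param mean,sd mean and standard deviation of the gamma component (> 0).
#' @param zeromass probability of an exact zero, in `[0, 1)`.
#' @param log logical; return log-density?
#' @return `dzigamma` the (log-)density, `pzigamma` the CDF, `rzigamma` draws.
#' @export
#' @examples
#' dzigamma(0, mean = 0.75, sd = 0.93, zeromass = 0.014, log = TRUE) # log(0.014)
dzigamma <- function(x, mean, sd, zeromass = 0, log = FALSE) {
  .check_zigamma_pars(mean, sd, zeromass)
  if (any(x < 0, na.rm = TRUE)) stop("zero-inflated gamma is defined on x >= 0")
  n <- max(length(x), length(mean), length(sd), length(zeromass))
  x <- rep_len(x, n)
  mean <- rep_len(mean, n)
  sd <- rep_len(sd, n)
  zeromass <- rep_len(zeromass, n)
  ld <- ifelse(x == 0,
    log(zeromass),
    log1p(-zeromass) +
      dgamma(x, shape = (mean / sd)^2, rate = mean / sd^2, log = TRUE)
  )
  if (log) ld else exp(ld)
}

#' @rdname dzigamma
#' @export
pzigamma <- function(q, mean, sd, zeromass = 0) {
  .check_zigamma_pars(mean, sd, zeromass)
  if (any(q < 0, na.rm = TRUE)) stop("zero-inflated gamma is defined on x >= 0")
  shape <- (mean / sd)^2
  rate <- mean / sd^2
  zeromass + (1 - zeromass) * pgamma(q, shape = shape, rate = rate)
}

#' @rdname dzigamma
#' @export
rzigamma <- function(n, mean, sd, zeromass = 0) {
  .check_zigamma_pars(mean, sd, zeromass)
  shape <- (mean / sd)^2
  rate <- mean / sd^2
  x <- rgamma(n, shape = shape, rate = rate)
  x[runif(n) < zeromass] <- 0
  x
}

.check_rho <- function(rho) {
  if (any(rho < 0) || any(rho >= 1)) stop("concentration 'rho' must be in [0, 1)")
  invisible(TRUE)
}

#' Wrapped Cauchy distribution
#'
#' Circular distribution obtained by wrapping a Cauchy distribution around
#' the unit circle; density
#' \deqn{f(\theta) = \frac{1 - \rho^2}{2\pi(1 + \rho^2 - 2\rho\cos(\theta - \mu))}}
#' with concentration `rho` in `[0, 1)` (`rho = 0` is the circular uniform).
#' Used for turning angles with the mean direction fixed at 0 (straight-line
#' movement).
#'
#' @param theta,q angles in radians.
#' @param n number of draws.
#' @param mu mean direction (radians).
#' @param rho concentration in `[0, 1)`.
#' @param log logical; return log-density?
#' @return `dwrpcauchy` the (log-)density; `pwrpcauchy` the CDF on
#'   `(-pi, pi]` (mass accumulated from `-pi`); `rwrpcauchy` draws in
#'   `(-pi, pi]`.
#' @export
#' @examples
#' dwrpcauchy(0.3, rho = 0)  # 1 / (2 * pi)
dwrpcauchy <- function(theta, mu = 0, rho, log = FALSE) {
  .check_rho(rho)
  ld <- log1p(-rho^2) - log(2 * pi) - log(1 + rho^2 - 2 * rho * cos(theta - mu))
  if (log) ld else exp(ld)
}

#' @rdname dwrpcauchy
#' @export
pwrpcauchy <- function(q, mu = 0, rho) {
  .check_rho(rho)
  z <- wrap_angle(q - mu)
  out <- ifelse(rho == 0,
    (z + pi) / (2 * pi),
    0.5 + atan(((1 + rho) / (1 - rho)) * tan(z / 2)) / pi
  )
  # tan(pi/2) is finite in floating point; pin the endpoint exactly
  out[z == pi] <- 1
  pmin(pmax(out, 0), 1)
}

#' @rdname dwrpcauchy
#' @export
rwrpcauchy <- function(n, mu = 0, rho) {
  .check_rho(rho)
  if (rho == 0) {
    # uniform on (-pi, pi]
    return(wrap_angle(runif(n, -pi, pi)))
  }
  gamma_scale <- -log(rho)
  wrap_angle(mu + gamma_scale * tan(pi * (runif(n) - 0.5)))
}
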