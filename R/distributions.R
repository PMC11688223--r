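# Interspike-interval candidate densities (Group 1 and Group 3 members with
# simple closed forms).  All time arguments and time-dimensioned parameters
# are in milliseconds; densities have units 1/ms.  Every density is evaluated
# in log space and returns exactly 0 outside its support.

.check_pos <- function(...) {
  vals <- list(...)
  nm <- names(vals)
  for (i in seq_along(vals)) {
    v <- vals[[i]]
    if (length(v) != 1L || !is.finite(v) || v <= 0) {
      stop(sprintf("parameter '%s' must be a single positive finite number", nm[i]))
    }
  }
  invisible(TRUE)
}

.finish_density <- function(logf, log) {
  if (log) logf else exp(logf)
}

#' Wald (inverse Gaussian) interspike-interval density
#'
#' First-passage-time density of a drift-diffusion process with drift
#' \eqn{1/\mu}, diffusion variance \eqn{1/\lambda} and absorbing barrier at 1:
#' \deqn{f(t) = \sqrt{\lambda/(2\pi t^3)}\, e^{-\lambda (t-\mu)^2 / (2\mu^2 t)}, \quad t > 0.}
#' The mean is \eqn{\mu} and the variance \eqn{\mu^3/\lambda}; the
#' coefficient of variation is \eqn{\sqrt{\mu/\lambda}}.  This is the
#' refractory (integrate-and-fire) component of the Exwald model.
#'
#' @param x time since the previous spike (ms); any numeric vector.
#' @param mu mean first-passage time (ms, > 0).
#' @param lambda shape parameter (ms, > 0).
#' @param log return the log density?
#' @return density values (0 for `x <= 0`).
#' @seealso [dexwald()], [rwald()]
#' @export
dwald <- function(x, mu, lambda, log = FALSE) {
  .check_pos(mu = mu, lambda = lambda)
  logf <- rep(-Inf, length(x))
  ok <- is.finite(x) & x > 0
  t <- x[ok]
  logf[ok] <- 0.5 * (base::log(lambda) - base::log(2 * pi) - 3 * base::log(t)) -
    lambda * (t - mu)^2 / (2 * mu^2 * t)
  .finish_density(logf, log)
}

#' Sample from a Wald (inverse Gaussian) distribution
#'
#' Uses the Michael-Schucany-Haas transformation-with-rejection method: a
#' chi-square deviate is mapped through the quadratic first-passage identity
#' and one of the two roots is selected with the appropriate probability.
#'
#' @param n number of draws.
#' @inheritParams dwald
#' @return numeric vector of `n` positive draws (ms).
#' @export
rwald <- function(n, mu, lambda) {
  .check_pos(mu = mu, lambda = lambda)
  y <- stats::rnorm(n)^2
  x1 <- mu + mu^2 * y / (2 * lambda) -
    mu / (2 * lambda) * sqrt(4 * mu * lambda * y + mu^2 * y^2)
  u <- stats::runif(n)
  ifelse(u <= mu / (mu + x1), x1, mu^2 / x1)
}

#' Birnbaum-Saunders (cumulative damage) interspike-interval density
#'
#' Waiting time for a sum of Gaussian-amplitude increments arriving at random
#' times to reach a threshold; a classical model for a neuron accumulating
#' EPSPs to a firing threshold.
#'
#' @inheritParams dwald
#' @param beta scale parameter (ms, > 0).
#' @param gamma shape parameter (dimensionless, > 0).
#' @export
ddamage <- function(x, beta, gamma, log = FALSE) {
  .check_pos(beta = beta, gamma = gamma)
  logf <- rep(-Inf, length(x))
  ok <- is.finite(x) & x > 0
  t <- x[ok]
  rt <- sqrt(t / beta)
  logf[ok] <- base::log(rt + 1 / rt) - base::log(2 * gamma * t) -
    0.5 * base::log(2 * pi) - (rt - 1 / rt)^2 / (2 * gamma^2)
  .finish_density(logf, log)
}

#' Erlang (integer-shape gamma) interspike-interval density
#'
#' Waiting time for `kappa` events of a Poisson process with mean inter-event
#' time `mu`; the distribution mean is `kappa * mu`.  A quantal-accumulation
#' model of spike generation.
#'
#' @inheritParams dwald
#' @param kappa positive integer shape.
#' @param mu scale (ms, > 0), the mean of each exponential stage.
#' @export
derlang <- function(x, kappa, mu, log = FALSE) {
  .check_kappa(kappa)
  .check_pos(mu = mu)
  logf <- rep(-Inf, length(x))
  ok <- is.finite(x) & x >= 0
  logf[ok] <- stats::dgamma(x[ok], shape = kappa, scale = mu, log = TRUE)
  .finish_density(logf, log)
}

.check_kappa <- function(kappa) {
  if (length(kappa) != 1L || !is.finite(kappa) || kappa < 1 ||
      abs(kappa - round(kappa)) > 1e-8) {
    stop("parameter 'kappa' must be a positive integer")
  }
  invisible(TRUE)
}

#' Exponentially modified Gaussian (exGaussian) density
#'
#' Convolution of a Gaussian \eqn{N(\mu, \sigma^2)} with an Exponential of
#' mean \eqn{\tau}:
#' \deqn{f(t) = \frac{1}{2\tau} e^{(\mu - t)/\tau + \sigma^2/(2\tau^2)}
#'   \,\mathrm{erfc}\!\left(\frac{\mu - t + \sigma^2/\tau}{\sigma\sqrt 2}\right).}
#' Evaluated through `erfcx` in the Gaussian-dominated tail so that neither
#' factor overflows.  Mean \eqn{\mu + \tau}, variance \eqn{\sigma^2 + \tau^2}.
#'
#' @inheritParams dwald
#' @param mu Gaussian mean (ms).
#' @param sigma Gaussian standard deviation (ms, > 0).
#' @param tau Exponential mean (ms, > 0).
#' @export
dexgauss <- function(x, mu, sigma, tau, log = FALSE) {
  .check_pos(sigma = sigma, tau = tau)
  if (length(mu) != 1L || !is.finite(mu)) stop("parameter 'mu' must be a finite number")
  xs <- ifelse(is.finite(x), x, mu) # placeholder, overwritten below
  z <- (mu - xs + sigma^2 / tau) / (sigma * sqrt(2))
  logf <- numeric(length(x))
  neg <- z < 0
  # Exponential-dominated region
  logf[neg] <- -base::log(2 * tau) + (mu - xs[neg]) / tau + sigma^2 / (2 * tau^2) +
    .log_erfc(z[neg])
  # Gaussian-dominated region: exponents combined analytically
  logf[!neg] <- -base::log(2 * tau) - (xs[!neg] - mu)^2 / (2 * sigma^2) +
    base::log(.erfcx(z[!neg]))
  logf[!is.finite(x)] <- -Inf
  .finish_density(logf, log)
}

# Evaluate any registered model density at (t - tau0); tau0 may be negative.
# Used by the Group-2 (fixed offset) candidates.
.offset_logdensity <- function(logdens, t, tau0, ...) {
  logdens(t - tau0, ...)
}
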