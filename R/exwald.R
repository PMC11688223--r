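# The Exwald distribution: convolution of a Wald (inverse Gaussian) first
# passage time with an Exponential waiting time.  Physically: a Poisson
# trigger process left-censored by an integrate-and-fire refractory period.

#' Exwald interspike-interval density
#'
#' Density of the sum of a Wald(\eqn{\mu}, \eqn{\lambda}) first-passage time
#' and an Exponential(\eqn{\tau}) waiting time.  Writing
#' \eqn{a = \lambda/(2\mu^2) - 1/\tau} and \eqn{b = \sqrt{\lambda/(2t)}}, the
#' closed form has two branches selected by the sign of \eqn{a}.  With
#' \eqn{c = \sqrt{a t}} (real for \eqn{a \ge 0}):
#' \deqn{f(t) = \frac{1}{2\tau} e^{-\lambda (t-\mu)^2/(2\mu^2 t)}
#'   \left[\mathrm{erfcx}(b - c) + \mathrm{erfcx}(b + c)\right], \quad a \ge 0,}
#' \deqn{f(t) = \frac{1}{\tau} e^{-\lambda (t-\mu)^2/(2\mu^2 t)}
#'   \,\mathrm{Re}\, w\!\left(-\sqrt{-a t} + i b\right), \quad a < 0,}
#' where \eqn{w} is the Faddeeva function ([faddeeva_w()]).  Both forms share
#' the Wald-like Gaussian exponent, so the evaluation never overflows; they
#' agree in the limit \eqn{a \to 0}.
#'
#' Two approximations guard the extreme corners of parameter space where the
#' closed form degenerates numerically during unconstrained search:
#' when the diffusion variance is negligible
#' (\eqn{\mu^3/\lambda < 10^{-6} (\mu+\tau)^2}) the density is replaced by an
#' Exponential with a fixed offset \eqn{\mu}, and when the Exponential
#' component is negligible (\eqn{\tau < 10^{-6}\mu}) by the pure Wald
#' density.  The thresholds trigger only where the neglected component
#' contributes less than \eqn{10^{-6}} of the total variance.
#'
#' @inheritParams dwald
#' @param mu Wald mean first-passage time (ms, > 0).
#' @param lambda Wald shape (ms, > 0).
#' @param tau Exponential mean (ms, > 0).
#' @return density values (0 for `x <= 0`).
#' @seealso [rexwald()], [exwald_moments()], [convolve_with_exp()]
#' @examples
#' dexwald(12.7, mu = 12.7, lambda = 1000, tau = 10)
#' @export
dexwald <- function(x, mu, lambda, tau, log = FALSE) {
  .check_pos(mu = mu, lambda = lambda, tau = tau)
  # degenerate corners: delegate to the limiting forms
  if (tau < 1e-6 * mu) {
    return(dwald(x, mu, lambda, log = log))
  }
  if (mu^3 / lambda < 1e-6 * (mu + tau)^2) {
    logf <- rep(-Inf, length(x))
    ok <- is.finite(x) & x > mu
    logf[ok] <- -base::log(tau) - (x[ok] - mu) / tau
    return(.finish_density(logf, log))
  }
  logf <- rep(-Inf, length(x))
  ok <- is.finite(x) & x > 0
  t <- x[ok]
  a <- lambda / (2 * mu^2) - 1 / tau
  b <- sqrt(lambda / (2 * t))
  gauss <- -lambda * (t - mu)^2 / (2 * mu^2 * t)
  if (a >= 0) {
    cc <- sqrt(a * t)
    # log of each erfc term, sharing the common Gaussian exponent
    l1 <- (b - cc)^2 + .log_erfc(b - cc)
    l2 <- (b + cc)^2 + .log_erfc(b + cc)
    # (b -+ c)^2 + gauss reproduces lam/mu - t/tau -+ 2bc exactly
    logf[ok] <- -base::log(2 * tau) + gauss + .logaddexp(l1, l2)
  } else {
    cp <- sqrt(-a * t)
    rw <- Re(faddeeva_w(complex(real = -cp, imaginary = b)))
    lw <- rep(-Inf, length(rw))
    pos <- rw > 0 # Re w > 0 throughout the upper half plane; guard roundoff
    lw[pos] <- base::log(rw[pos])
    logf[ok] <- -base::log(tau) + gauss + lw
  }
  .finish_density(logf, log)
}

#' Sample Exwald-distributed interspike intervals
#'
#' Each draw is the sum of a Wald(\eqn{\mu}, \eqn{\lambda}) draw (the
#' refractory blocking time) and an Exponential(\eqn{\tau}) draw (the Poisson
#' wait), mirroring the censored-Poisson reading of the model.
#'
#' @inheritParams dexwald
#' @param n number of intervals.
#' @return numeric vector of `n` intervals (ms).
#' @export
rexwald <- function(n, mu, lambda, tau) {
  .check_pos(mu = mu, lambda = lambda, tau = tau)
  rwald(n, mu, lambda) + stats::rexp(n, rate = 1 / tau)
}

#' Closed-form moments of the Exwald distribution
#'
#' @inheritParams dexwald
#' @return named vector with `mean` (\eqn{\mu + \tau}, ms), `variance`
#'   (\eqn{\mu^3/\lambda + \tau^2}, ms^2) and `cv`
#'   (\eqn{\sqrt{\mathrm{variance}}/\mathrm{mean}}, dimensionless).
#' @examples
#' exwald_moments(mu = 12.7, lambda = 1000, tau = 10)
#' @export
exwald_moments <- function(mu, lambda, tau) {
  .check_pos(mu = mu, lambda = lambda, tau = tau)
  m <- mu + tau
  v <- mu^3 / lambda + tau^2
  c(mean = m, variance = v, cv = sqrt(v) / m)
}
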