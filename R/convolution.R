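# Exerlang density and the quadrature convolution oracle used to verify all
# three Exponential-convolution (Group 3) closed forms.

# 64-node Gauss-Legendre rule on [0, 1]; used for the incomplete-gamma
# integral with negative rate argument, where pgamma() is unavailable.
.gl64 <- local({
  g <- pracma::gaussLegendre(64L, 0, 1)
  list(x = g$x, w = g$w)
})

#' Exerlang interspike-interval density
#'
#' Convolution of an Erlang(`kappa`, `mu`) waiting time with an Exponential
#' of mean `tau`.  For rate difference \eqn{r = 1/\mu - 1/\tau > 0},
#' \deqn{f(t) = \frac{1}{\tau}\,(1 - \mu/\tau)^{-\kappa} e^{-t/\tau} P(\kappa, r t),}
#' with \eqn{P} the regularized lower incomplete gamma function.  For
#' \eqn{r < 0} (where the incomplete gamma argument would be negative) the
#' same integral
#' \eqn{\int_0^t s^{\kappa-1} e^{-r s}\,ds} is evaluated exactly in log space
#' with a Gauss-Legendre rule, and for \eqn{\mu = \tau} the density is the
#' Erlang(\eqn{\kappa + 1}, \eqn{\mu}) limit.  All branches were validated
#' against [convolve_with_exp()].
#'
#' @inheritParams dwald
#' @param kappa positive integer Erlang shape.
#' @param mu Erlang scale (ms, > 0); the Erlang component mean is `kappa * mu`.
#' @param tau Exponential mean (ms, > 0).
#' @export
dexerlang <- function(x, kappa, mu, tau, log = FALSE) {
  .check_kappa(kappa)
  .check_pos(mu = mu, tau = tau)
  r <- 1 / mu - 1 / tau
  if (abs(r) < 1e-12) {
    return(derlang(x, kappa + 1, mu, log = log))
  }
  logf <- rep(-Inf, length(x))
  ok <- is.finite(x) & x > 0
  t <- x[ok]
  if (r > 0) {
    logf[ok] <- -base::log(tau) - t / tau - kappa * log1p(-mu / tau) +
      stats::pgamma(r * t, shape = kappa, log.p = TRUE)
  } else {
    # f = e^{-t/mu} (t/mu)^kappa / (t Gamma(kappa) tau) * J,
    # J = int_0^1 (1-v)^{kappa-1} e^{-x v} dv with x = -r t > 0.
    xx <- -r * t
    scale <- pmax(xx + kappa - 1, 1)
    vc <- pmin(1, 40 / scale)
    nodes <- outer(.gl64$x, vc) # 64 x n
    wts <- outer(.gl64$w, vc)
    integ <- (kappa - 1) * log1p(-nodes) - rep(xx, each = 64L) * nodes
    J <- colSums(wts * exp(integ))
    logf[ok] <- -t / mu + kappa * base::log(t / mu) -
      lgamma(kappa) - base::log(tau) + base::log(J)
  }
  .finish_density(logf, log)
}

#' Numerically convolve a density with an Exponential
#'
#' Adaptive-quadrature evaluation of
#' \eqn{\int_{L}^{t} f(s) \frac{1}{\tau} e^{-(t-s)/\tau}\, ds}, the density
#' of the sum of a draw from `base_density` and an independent
#' Exponential(\eqn{\tau}) draw.  This is the independent oracle against
#' which the Exwald, Exerlang and exGaussian closed forms are verified; it is
#' deliberately kept free of any code shared with them.
#'
#' @param base_density function of one vector argument returning a density.
#' @param tau Exponential mean (ms, > 0).
#' @param t evaluation times (ms); vectorized.
#' @param lower lower limit of the component support (default 0; use `-Inf`
#'   for a Gaussian component).
#' @param rel.tol quadrature relative tolerance.
#' @param panels number of sub-intervals integrated separately; panel edges
#'   are placed at equal-mass quantiles of a presampled integrand so that
#'   sharply peaked components (e.g. a near-point-mass Wald) are not stepped
#'   over by the adaptive rule.
#' @param focus optional extra break points (ms) inserted into the panel
#'   edges, e.g. the known location of a narrow component.
#' @return numeric vector of densities at `t`.
#' @examples
#' # Exp(mu) convolved with Exp(mu) is Erlang(2, mu)
#' convolve_with_exp(function(s) dexp(s, 1 / 10), tau = 10, t = 25)
#' derlang(25, kappa = 2, mu = 10)
#' @export
convolve_with_exp <- function(base_density, tau, t, lower = 0,
                              rel.tol = 1e-9, panels = 12L, focus = NULL) {
  .check_pos(tau = tau)
  vapply(t, function(ti) {
    if (!is.finite(ti) || ti <= lower) return(0)
    lo <- if (is.finite(lower)) lower else ti - 50 * tau - 10 * abs(ti)
    # presample the integrand on mixed linear/log grids and place panel
    # edges at equal-mass quantiles, so sharply concentrated components are
    # straddled by panel boundaries rather than stepped over
    g <- seq(lo, ti, length.out = 2000L)
    if (ti > 0) {
      glog <- exp(seq(log(max(ti * 1e-7, 1e-12)), log(ti), length.out = 2000L))
      g <- sort(unique(c(g, glog[glog > lo])))
    }
    fg <- base_density(g) * exp(-(ti - g) / tau)
    fg[!is.finite(fg)] <- 0
    cuts <- numeric(0)
    cm <- cumsum(fg)
    if (cm[length(cm)] > 0) {
      qs <- cm[length(cm)] * seq_len(panels - 1L) / panels
      cuts <- g[pmin(findInterval(qs, cm) + 1L, length(g))]
    }
    if (!is.null(focus)) {
      cuts <- c(cuts, focus[focus > lo & focus < ti])
    }
    edges <- sort(unique(c(lo, cuts, seq(lo, ti, length.out = panels + 1L), ti)))
    if (!is.finite(lower)) edges[1] <- -Inf
    total <- 0
    shaky <- 0 # largest contribution from a panel that did not converge
    for (j in seq_len(length(edges) - 1L)) {
      ans <- tryCatch(
        stats::integrate(function(s) base_density(s) * exp(-(ti - s) / tau) / tau,
                         lower = edges[j], upper = edges[j + 1L],
                         rel.tol = rel.tol, abs.tol = 1e-300,
                         subdivisions = 400L, stop.on.error = FALSE),
        error = function(e) {
          stop(sprintf("convolution quadrature failed at t = %g: %s",
                       ti, conditionMessage(e)))
        })
      if (!identical(ans$message, "OK")) shaky <- max(shaky, abs(ans$value))
      total <- total + ans$value
    }
    # a non-converged panel is tolerable only if its contribution is dwarfed
    # by the total (flat, numerically void stretches trip the extrapolation)
    if (shaky > 1e-6 * abs(total)) {
      stop(sprintf("convolution quadrature failed at t = %g: non-convergent panel contributes %.3g of %.3g",
                   ti, shaky, total))
    }
    total
  }, numeric(1))
}
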