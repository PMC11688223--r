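# Faddeeva function and stable erfc variants.
#
# The Exwald density needs erfcx(x) = exp(x^2) erfc(x) for large real x and
# Re w(z) for complex z in the upper half plane.  Both are evaluated through
# Weideman's rational expansion of w(z) (SIAM J. Numer. Anal. 31(5), 1994),
# which with N = 64 terms is accurate to ~1e-15 on the closed upper half
# plane.  Coefficients are computed once at load time.

.weideman <- local({
  N <- 64L
  M <- 2L * N
  M2 <- 2L * M
  k <- seq(-M + 1L, M - 1L)
  L <- sqrt(N / sqrt(2))
  t <- L * tan(k * pi / (2 * M))
  f <- c(0, exp(-t^2) * (L^2 + t^2))
  fs <- c(f[(M + 1L):M2], f[1:M]) # fftshift
  a <- Re(stats::fft(fs)) / M2
  list(a = rev(a[2:(N + 1L)]), L = L)
})

#' Faddeeva scaled complex complementary error function
#'
#' Computes \eqn{w(z) = e^{-z^2} \mathrm{erfc}(-iz)} for arguments in the
#' closed upper half plane (\eqn{\mathrm{Im}(z) \ge 0}), where \eqn{w} is
#' bounded and the expansion used here is uniformly accurate.  This is the
#' kernel of the oscillatory branch of the Exwald density.
#'
#' @param z complex (or real) vector with `Im(z) >= 0`.
#' @return complex vector of the same length.
#' @examples
#' faddeeva_w(0)            # 1
#' faddeeva_w(1i * 2)       # erfcx(2)
#' @export
faddeeva_w <- function(z) {
  z <- as.complex(z)
  if (any(Im(z) < 0)) {
    stop("faddeeva_w() is defined here for Im(z) >= 0 only")
  }
  L <- .weideman$L
  iz <- 1i * z
  r <- L - iz
  Z <- (L + iz) / r
  p <- rep(0 + 0i, length(z))
  for (ak in .weideman$a) p <- p * Z + ak
  2 * p / r^2 + (1 / sqrt(pi)) / r
}

# exp(x^2) * erfc(x) without overflow; accurate for all real x that do not
# overflow the x < 0 reflection 2 exp(x^2).
.erfcx <- function(x) {
  out <- numeric(length(x))
  pos <- x >= 0
  if (any(pos)) {
    out[pos] <- Re(faddeeva_w(complex(real = 0, imaginary = x[pos])))
  }
  if (any(!pos)) {
    xn <- x[!pos]
    out[!pos] <- 2 * exp(xn^2) - Re(faddeeva_w(complex(real = 0, imaginary = -xn)))
  }
  out
}

# erfc(x) = 2 pnorm(-sqrt(2) x), kept for readability at moderate arguments
.erfc <- function(x) 2 * stats::pnorm(-sqrt(2) * x)

# log erfc(x), stable in both tails
.log_erfc <- function(x) {
  out <- numeric(length(x))
  pos <- x >= 0
  if (any(pos)) out[pos] <- -x[pos]^2 + log(.erfcx(x[pos]))
  if (any(!pos)) out[!pos] <- log(2 - .erfc(-x[!pos]))
  out
}

# log(exp(a) + exp(b)) elementwise
.logaddexp <- function(a, b) {
  m <- pmax(a, b)
  r <- m + log1p(exp(pmin(a, b) - m))
  # if both are -Inf, m is -Inf and the sum is -Inf
  r[is.infinite(m) & m < 0] <- -Inf
  r
}
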