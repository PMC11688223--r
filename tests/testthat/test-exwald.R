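# The Exwald kernel and its relatives: Faddeeva function, convolution
# closed forms vs the quadrature oracle, branch continuity, fallbacks and
# moments.

test_that("Faddeeva function matches independent special-function values", {
  expect_equal(Re(faddeeva_w(0)), 1, tolerance = 1e-14)
  expect_equal(Im(faddeeva_w(0)), 0, tolerance = 1e-14)
  # on the imaginary axis w(ix) = erfcx(x); compare against an independent
  # implementation in its reliable range
  x <- c(0.1, 0.5, 1, 2, 5, 10, 20)
  expect_equal(Re(faddeeva_w(1i * x)), pracma::erfcx(x), tolerance = 1e-12)
  # large-argument asymptote w(z) ~ i/(z sqrt(pi))
  z <- 4000 + 300i
  expect_equal(faddeeva_w(z), 1i / (z * sqrt(pi)), tolerance = 1e-5)
  expect_error(faddeeva_w(1 - 1i), "Im")
})

test_that("convolution oracle reproduces known convolutions", {
  # Exp(mu) * Exp(mu) = Erlang(2, mu)
  mu <- 10
  t <- c(2, 9, 30, 80)
  expect_equal(convolve_with_exp(function(s) stats::dexp(s, 1 / mu), mu, t),
               derlang(t, 2, mu), tolerance = 1e-8)
  # convolution with a near-point-mass Wald shifts the Exponential
  expect_equal(convolve_with_exp(function(s) dwald(s, 1, 1e4), 1, 2),
               exp(-1), tolerance = 1e-3)
  # order of Exponential components is immaterial
  expect_equal(convolve_with_exp(function(s) stats::dexp(s, 1 / 3), 11, t),
               convolve_with_exp(function(s) stats::dexp(s, 1 / 11), 3, t),
               tolerance = 1e-8)
})

test_that("Exwald closed form agrees with the quadrature convolution", {
  # spanning both evaluation branches (a >= 0 and a < 0)
  cases <- list(c(12.7, 1000, 10),   # a < 0
                c(12.7, 1000, 0.2),  # a > 0
                c(5, 50, 80),        # irregular, strongly exponential
                c(25, 8000, 1))
  for (p in cases) {
    tm <- exwald_moments(p[1], p[2], p[3])[["mean"]]
    t <- c(5, 12.7, 50, tm, 2 * tm)
    got <- dexwald(t, p[1], p[2], p[3])
    want <- convolve_with_exp(function(s) dwald(s, p[1], p[2]), p[3], t)
    expect_equal(got, want, tolerance = 1e-6,
                 label = sprintf("exwald(%g, %g, %g)", p[1], p[2], p[3]))
  }
})

test_that("Exwald branches join continuously at a = 0", {
  mu <- 12.7; lam <- 1000
  tau0 <- 2 * mu^2 / lam # a = 0 exactly
  t <- c(3, 8, 12.7, 20, 60)
  for (eps in c(1e-8, 1e-10)) {
    lo <- dexwald(t, mu, lam, tau0 * (1 - eps))
    hi <- dexwald(t, mu, lam, tau0 * (1 + eps))
    expect_lt(max(abs(hi - lo) / lo), 1e-6)
  }
})

test_that("Exwald limiting forms take over in degenerate corners", {
  # tau negligible: pure Wald
  expect_equal(dexwald(1, 1, 1, 1e-9), dwald(1, 1, 1), tolerance = 1e-4)
  # diffusion negligible: Exponential shifted by mu
  f <- dexwald(c(9, 15, 30), 10, 1e12, 10)
  expect_equal(f, c(0, exp(-c(5, 20) / 10) / 10), tolerance = 1e-4)
})

test_that("Exerlang matches the oracle on both rate orderings", {
  t <- c(1, 5, 20, 100)
  # tau > mu (regularized incomplete gamma form)
  expect_equal(dexerlang(t, 3, 4, 10),
               convolve_with_exp(function(s) derlang(s, 3, 4), 10, t),
               tolerance = 1e-6)
  # tau < mu (log-space quadrature form, where gammainc takes a negative
  # argument)
  expect_equal(dexerlang(t, 3, 10, 4),
               convolve_with_exp(function(s) derlang(s, 3, 10), 4, t),
               tolerance = 1e-6)
  # two-exponential case has a hand-derived hypoexponential value
  expect_equal(dexerlang(3, 1, 2, 5), (exp(-3 / 5) - exp(-3 / 2)) / 3,
               tolerance = 1e-10)
  expect_equal(dexerlang(c(-1, 0), 2, 3, 4), c(0, 0))
  # equal rates collapse to the Erlang(kappa + 1) limit
  expect_equal(dexerlang(t, 4, 2, 2), derlang(t, 5, 2), tolerance = 1e-9)
})

test_that("exGaussian matches the oracle and its degenerate limit", {
  t <- c(5, 15, 60)
  expect_equal(dexgauss(t, 12.7, 2, 10),
               convolve_with_exp(function(s) stats::dnorm(s, 12.7, 2), 10, t,
                                 lower = -Inf),
               tolerance = 1e-6)
  # sigma -> 0: Exponential shifted by mu
  expect_equal(dexgauss(1, 0, 1e-6, 1), exp(-1), tolerance = 1e-6)
})

test_that("Exwald moments match arithmetic and Monte-Carlo estimates", {
  m <- exwald_moments(10, 1e12, 10)
  expect_equal(m[["mean"]], 20)
  expect_equal(m[["variance"]], 100, tolerance = 1e-9)
  expect_equal(m[["cv"]], 0.5, tolerance = 1e-9)
  m2 <- exwald_moments(12.7, 1000, 10)
  expect_equal(m2[["mean"]], 22.7)
  expect_equal(m2[["variance"]], 12.7^3 / 1000 + 100)
  expect_equal(m2[["cv"]], sqrt(12.7^3 / 1000 + 100) / 22.7)
  # sample moments from the sampler, 3 MC standard errors
  n <- 1e6
  x <- sample_exwald_intervals(12.7, 1000, 10, n, seed = 99)
  expect_lt(abs(mean(x) - m2[["mean"]]), 3 * sqrt(m2[["variance"]] / n))
  se_var <- sqrt(2 * m2[["variance"]]^2 / n) * 2 # skewed; generous factor
  expect_lt(abs(stats::var(x) - m2[["variance"]]), 3 * se_var)
})

test_that("group-3 closed forms track the oracle across random draws", {
  for (m in c("exwald", "exerlang", "exgaussian")) {
    for (k in 1:3) {
      p <- random_params(m, seed = 50 + k)
      while (m == "exwald" && in_exwald_fallback(p)) {
        p <- random_params(m, seed = 50 + 100 * k + p[["lam"]])
      }
      mean_t <- switch(m,
        exwald = p[["mu"]] + p[["tau"]],
        exerlang = p[["kappa"]] * p[["mu"]] + p[["tau"]],
        exgaussian = p[["mu"]] + p[["tau"]])
      t <- seq(0.1 * mean_t, 5 * mean_t, length.out = 12)
      got <- exp(model_logdensity(m, t, p))
      base <- switch(m,
        exwald = function(s) dwald(s, p[["mu"]], p[["lam"]]),
        exerlang = function(s) derlang(s, p[["kappa"]], p[["mu"]]),
        exgaussian = function(s) stats::dnorm(s, p[["mu"]], p[["sigma"]]))
      lower <- if (m == "exgaussian") -Inf else 0
      want <- convolve_with_exp(base, p[["tau"]], t, lower = lower)
      keep <- want > 1e-12
      expect_lt(max(abs(got[keep] - want[keep]) / want[keep]), 1e-4)
    }
  }
})
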