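# shared fixtures and small independent oracles for the suite

# numeric CDF of a density on (0, Inf): cumulative trapezoid on a fine grid,
# returned as an interpolating function (independent of any sampler)
numeric_cdf <- function(density, upper, n = 20000) {
  g <- seq(0, upper, length.out = n)
  f <- density(g)
  cdf <- c(0, cumsum((f[-1] + f[-n]) / 2 * diff(g)))
  cdf <- cdf / cdf[n]
  stats::approxfun(g, cdf, yleft = 0, yright = 1)
}

# brute-force convex hull membership: a point is interior if it is inside
# (or on) some triangle of other points; O(n^3) witness used to validate the
# hull vertices
point_in_triangle <- function(p, a, b, c) {
  s1 <- (b[1] - a[1]) * (p[2] - a[2]) - (b[2] - a[2]) * (p[1] - a[1])
  s2 <- (c[1] - b[1]) * (p[2] - b[2]) - (c[2] - b[2]) * (p[1] - b[1])
  s3 <- (a[1] - c[1]) * (p[2] - c[2]) - (a[2] - c[2]) * (p[1] - c[1])
  (s1 >= -1e-12 & s2 >= -1e-12 & s3 >= -1e-12) |
    (s1 <= 1e-12 & s2 <= 1e-12 & s3 <= 1e-12)
}

brute_force_hull_index <- function(pts) {
  n <- nrow(pts)
  interior <- rep(FALSE, n)
  for (i in seq_len(n)) {
    others <- setdiff(seq_len(n), i)
    combs <- utils::combn(others, 3)
    for (k in seq_len(ncol(combs))) {
      tri <- combs[, k]
      if (point_in_triangle(pts[i, ], pts[tri[1], ], pts[tri[2], ], pts[tri[3], ])) {
        # strictly inside only (not a vertex of a degenerate triangle)
        a <- pts[tri[1], ]; b <- pts[tri[2], ]; c <- pts[tri[3], ]
        area <- abs((b[1] - a[1]) * (c[2] - a[2]) - (c[1] - a[1]) * (b[2] - a[2]))
        if (area > 1e-12 && !any(apply(pts[tri, , drop = FALSE], 1,
                                       function(q) all(abs(q - pts[i, ]) < 1e-15)))) {
          interior[i] <- TRUE
          break
        }
      }
    }
  }
  which(!interior)
}

# a stationary synthetic record wrapped as an isi_sequence
make_isi <- function(n = 200, mu = 12.7, lam = 1000, tau = 10, seed = 1,
                     id = "fix") {
  structure(list(record_id = id,
                 intervals = sample_exwald_intervals(mu, lam, tau, n, seed = seed),
                 n = n),
            class = "isi_sequence")
}

# TRUE when an Exwald parameter triple lies in a guarded degenerate corner,
# where dexwald() intentionally switches to a limiting approximation and
# oracle comparisons do not apply
in_exwald_fallback <- function(p) {
  p[["tau"]] < 1e-6 * p[["mu"]] ||
    p[["mu"]]^3 / p[["lam"]] < 1e-6 * (p[["mu"]] + p[["tau"]])^2
}

# random valid parameter draws per family, for property-style loops
random_params <- function(model, seed) {
  set.seed(seed)
  r <- function(lo, hi) 10^stats::runif(1, log10(lo), log10(hi))
  switch(model,
    weibull = c(lam = r(1, 100), kappa = r(0.5, 8)),
    lognormal = c(mu = stats::runif(1, 0, 4), sigma = r(0.1, 1.5)),
    erlang = c(kappa = sample(1:40, 1), mu = r(0.1, 20)),
    damage = c(beta = r(1, 100), gamma = r(0.1, 2)),
    wald = c(mu = r(1, 100), lam = r(10, 1e4)),
    offset_erlang = c(kappa = sample(1:40, 1), mu = r(0.1, 20),
                      tau0 = stats::runif(1, -5, 20)),
    offset_wald = c(mu = r(1, 100), lam = r(10, 1e4),
                    tau0 = stats::runif(1, -5, 20)),
    offset_damage = c(beta = r(1, 100), gamma = r(0.1, 2),
                      tau0 = stats::runif(1, -5, 20)),
    exerlang = c(kappa = sample(1:40, 1), mu = r(0.1, 20), tau = r(0.05, 200)),
    exwald = c(mu = r(2, 50), lam = r(20, 2e4), tau = r(0.05, 300)),
    exgaussian = c(mu = r(2, 50), sigma = r(0.3, 10), tau = r(0.05, 300)))
}
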