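# Divergence computation and bounded-simplex fitting.

test_that("particle divergence follows the defining arithmetic", {
  # two observations with model density 1/2 each: 1 + 1 = 2 bits
  ed <- empirical_distribution(c(1e-9, 2e-9))
  expect_equal(dkl_particle(ed, "erlang", c(kappa = 1, mu = 2)), 2,
               tolerance = 1e-6)
  # an observation outside the support makes the divergence infinite
  ed2 <- empirical_distribution(c(1, 2, 3))
  expect_identical(dkl_particle(ed2, "offset_wald",
                                c(mu = 1, lam = 1, tau0 = 2.5)), Inf)
})

test_that("histogram divergence is nonnegative and vanishes for good fits", {
  set.seed(20)
  x <- sample_exwald_intervals(12.7, 1000, 10, 5000, seed = 20)
  ed <- empirical_distribution(x, histogram = TRUE)
  self <- dkl_histogram(ed, "exwald", c(mu = 12.7, lam = 1000, tau = 10))
  expect_gte(self, 0)
  expect_lt(self, 0.05)
  # Gibbs inequality across deliberately wrong parameter draws
  for (k in 1:20) {
    p <- random_params("exwald", seed = 300 + k)
    d <- dkl_histogram(ed, "exwald", p)
    expect_gte(d, -1e-12)
    expect_gte(d, self - 1e-9)
  }
  # a populated bin with no model mass is infinitely surprising
  expect_identical(dkl_histogram(ed, "offset_wald",
                                 c(mu = 1, lam = 1, tau0 = max(x) + 1)), Inf)
})

test_that("divergence and likelihood identity holds exactly for all fits", {
  set.seed(21)
  samples <- list(make_isi(n = 120, seed = 1),
                  make_isi(n = 80, mu = 10, lam = 200, tau = 50, seed = 2))
  for (s in samples) {
    for (m in c("wald", "erlang", "exwald")) {
      f <- fit_model(s, m, seed = 5, n_restarts = 1)
      expect_identical(f$dkl_bits, f$nll_bits / s$n + log2(s$n))
      expect_true(f$converged)
    }
  }
})

test_that("divergence and likelihood rank parameter values identically", {
  # D_KL differs from -loglik/N only by constants, so orderings coincide
  for (k in 1:5) {
    s <- make_isi(n = 150, seed = 40 + k)
    ed <- empirical_distribution(s)
    draws <- lapply(1:20, function(j) random_params("exwald", seed = 900 + 20 * k + j))
    dkl <- vapply(draws, function(p) dkl_particle(ed, "exwald", p), numeric(1))
    nll <- vapply(draws, function(p) {
      -sum(model_logdensity("exwald", ed$intervals, p)) / log(2)
    }, numeric(1))
    fin <- is.finite(dkl)
    expect_identical(order(dkl[fin]), order(nll[fin]))
  }
})

test_that("moment initialization is in-bounds and near the truth", {
  x <- sample_exwald_intervals(12.7, 1000, 10, 4000, seed = 33)
  st <- init_params(x, "exwald")
  truth <- c(mu = 12.7, lam = 1000, tau = 10)
  expect_true(all(st / truth < 3 & st / truth > 1 / 3))
  # bounds respected across families and random samples
  set.seed(34)
  for (k in 1:100) {
    m <- sample(list_models(), 1)[[1]]
    spec <- model_spec(m)
    p <- random_params(if (grepl("offset", m)) sub("offset_", "", m) else
                       if (m %in% c("weibull", "lognormal")) "wald" else m,
                       seed = 500 + k)
    y <- if (k %% 2) stats::rgamma(60, 4, 1 / 4) else
      sample_exwald_intervals(12.7, 1000, 10^stats::runif(1, -1, 2), 60)
    st <- init_params(y, m)
    expect_true(all(st >= spec$lower & st <= spec$upper),
                label = sprintf("start in bounds for %s (draw %d)", m, k))
  }
  # degenerate near-constant sample pushes tau low and lam high
  z <- rep(10, 50) + stats::rnorm(50, 0, 1e-5)
  stz <- init_params(z, "exwald")
  expect_lt(stz[["tau"]], 1e-2)
  expect_gt(stz[["lam"]], 1e4)
  expect_error(init_params(c(1, 2, 3), "exwald"), "at least 10")
})

test_that("fitting recovers known Exwald parameters from a single record", {
  x <- sample_exwald_intervals(12.7, 1000, 10, 2000, seed = 17)
  f <- fit_model(x, "exwald", seed = 17)
  expect_true(f$converged)
  expect_lt(abs(f$params[["mu"]] / 12.7 - 1), 0.10)
  expect_lt(abs(f$params[["tau"]] / 10 - 1), 0.10)
  expect_lt(abs(f$params[["lam"]] / 1000 - 1), 0.35)
  expect_error(fit_model(x[1:5], "exwald"), "at least 10")
})

test_that("fitting is invariant to interval order", {
  x <- sample_exwald_intervals(12.7, 1000, 10, 400, seed = 18)
  f1 <- fit_model(x, "exwald", seed = 3)
  f2 <- fit_model(rev(x), "exwald", seed = 3)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$dkl_bits, f2$dkl_bits)
})

test_that("the Exwald extension degrades gracefully to a pure Wald", {
  set.seed(19)
  x <- rwald(1500, 12.7, 1000)
  fw <- fit_model(x, "wald", seed = 4)
  fx <- fit_model(x, "exwald", seed = 4)
  # the Exponential component shrinks toward nothing and the fit quality
  # matches the two-parameter truth
  expect_lt(fx$params[["tau"]], 0.1 * fx$params[["mu"]])
  expect_lt(abs(fx$dkl_bits - fw$dkl_bits), 0.01)
})

test_that("model ranking identifies the generating family", {
  # records along the population axis, fitted by nested and rival families
  pop <- generate_population(population_config(n_records = 8, seed = 77,
                                               log_tau_range = c(-1, 2)))
  scr <- screen_records(pop$records)
  fits <- fit_records(scr$kept, c("wald", "exwald"), seed = 6, n_restarts = 2)
  tab <- rank_models(fits)
  expect_equal(tab$model[1], "exwald")
  expect_equal(tab$mean_delta_dkl_bits[1], 0)
  expect_true(all(tab$n_records == length(scr$kept)))
  # nested three-parameter family never loses to its base by more than the
  # simplex tolerance, record by record
  wide <- merge(fits[fits$model == "wald", c("record_id", "dkl_bits")],
                fits[fits$model == "exwald", c("record_id", "dkl_bits")],
                by = "record_id", suffixes = c("_wald", "_exwald"))
  expect_true(all(wide$dkl_bits_exwald <= wide$dkl_bits_wald + 0.01))
  # a single-model comparison is its own baseline
  tab1 <- rank_models(fits[fits$model == "exwald", ])
  expect_equal(tab1$mean_delta_dkl_bits, 0)
  # missing pairs are reported
  expect_error(rank_models(fits[-1, ]), "missing")
})
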