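# Synthetic data: direct sampler, physical mechanism, record emission and
# population generation.

test_that("the direct sampler matches its own density and the Wald limit", {
  # one-sample KS against the numerically integrated Exwald CDF
  x <- sample_exwald_intervals(12.7, 1000, 10, 1e4, seed = 70)
  cdf <- numeric_cdf(function(t) dexwald(t, 12.7, 1000, 10), upper = 200)
  ks <- stats::ks.test(x, cdf)
  expect_gt(ks$p.value, 0.01)
  # tau -> 0: indistinguishable from the pure Wald sampler
  y <- sample_exwald_intervals(12.7, 1000, 1e-9, 4000, seed = 71)
  set.seed(72)
  w <- rwald(4000, 12.7, 1000)
  expect_gt(stats::ks.test(y, w)$p.value, 0.01)
  # censoring identity: component order does not matter
  set.seed(73)
  a <- rwald(4000, 12.7, 800) + stats::rexp(4000, 1 / 20)
  b <- stats::rexp(4000, 1 / 20) + rwald(4000, 12.7, 800)
  expect_gt(stats::ks.test(a, b)$p.value, 0.01)
  expect_error(sample_exwald_intervals(-1, 1, 1, 10), "positive")
})

test_that("identical seeds give bit-identical draws and records", {
  expect_identical(sample_exwald_intervals(12.7, 1000, 10, 100, seed = 5),
                   sample_exwald_intervals(12.7, 1000, 10, 100, seed = 5))
  r1 <- generate_record(12.7, 1000, 10, seed = 6)
  r2 <- generate_record(12.7, 1000, 10, seed = 6)
  expect_identical(r1$spike_times, r2$spike_times)
  m1 <- simulate_mechanism(mechanism_config(10, 500, 10, duration = 2, seed = 8))
  m2 <- simulate_mechanism(mechanism_config(10, 500, 10, duration = 2, seed = 8))
  expect_identical(m1$spike_times, m2$spike_times)
})

test_that("the noiseless mechanism ticks like a clock at the Wald mean", {
  cfg <- mechanism_config(mu = 10, lam = 1e8, tau = 0.01, duration = 0.35,
                          seed = 80)
  iv <- attr(simulate_mechanism(cfg), "intervals_ms")
  expect_gt(length(iv), 20)
  expect_lt(max(abs(iv - 10)) / 10, 0.02)
})

test_that("mechanism intervals match the direct sampler distribution", {
  cfg <- mechanism_config(12.7, 1000, 10, duration = 60, seed = 81)
  iv <- attr(simulate_mechanism(cfg), "intervals_ms")
  ref <- sample_exwald_intervals(12.7, 1000, 10, length(iv), seed = 82)
  expect_gt(suppressWarnings(stats::ks.test(iv, ref))$p.value, 0.01)
  # dt guard
  expect_error(mechanism_config(10, 100, 10, dt = 1), "too coarse")
})

test_that("refractory censoring decimates the trigger process as expected", {
  # event-level censored-Poisson simulation, expectation (mu + tau)/tau
  f <- decimation_factor(10, 1000, 0.1, n = 2e4, seed = 83)
  expect_lt(abs(f / 101 - 1), 0.1)
  # the Euler mechanism's own trigger count tells the same story
  cfg <- mechanism_config(10, 1000, 0.1, duration = 2, seed = 84)
  rec <- simulate_mechanism(cfg)
  ratio <- attr(rec, "n_trigger_events") / attr(rec, "n_emitted")
  expect_lt(abs(ratio / 101 - 1), 0.15)
})

test_that("kinematic modulation reduces to stationarity at zero input", {
  cfg <- mechanism_config(12.7, 1000, 10, duration = 40, seed = 85)
  base <- attr(simulate_mechanism(cfg), "intervals_ms")
  mod0 <- modulate_by_input(cfg, rep(0, 8), input_gain = 0.5)
  iv0 <- attr(simulate_mechanism(mod0), "intervals_ms")
  expect_gt(suppressWarnings(stats::ks.test(base, iv0))$p.value, 0.01)
})

test_that("positive kinematic input raises the firing rate", {
  rates <- vapply(1:6, function(s) {
    cfg <- mechanism_config(12.7, 1000, 10, duration = 15, seed = 200 + s)
    cfgc <- modulate_by_input(cfg, rep(1, 8), input_gain = 0.3)
    length(attr(simulate_mechanism(cfgc), "intervals_ms")) / cfg$duration
  }, numeric(1))
  base <- vapply(1:6, function(s) {
    cfg <- mechanism_config(12.7, 1000, 10, duration = 15, seed = 200 + s)
    length(attr(simulate_mechanism(cfg), "intervals_ms")) / cfg$duration
  }, numeric(1))
  expect_true(all(rates > base))
})

test_that("a constant operating point leaves the output an Exwald process", {
  # an acceleration pulse establishes a constant velocity; afterwards the
  # integrator drift is scaled by a constant and the train is stationary
  cfg <- mechanism_config(12.7, 1000, 10, duration = 40, seed = 86)
  n_pulse <- 100
  accel <- c(rep(1 / (n_pulse * cfg$dt), n_pulse), 0) # velocity settles at 1
  cfgm <- modulate_by_input(cfg, accel, input_gain = 0.4)
  ivm <- attr(simulate_mechanism(cfgm), "intervals_ms")
  # drift is scaled by 1.4, so the blocking mean shrinks to mu/1.4
  fit_m <- fit_model(ivm, "exwald", seed = 87)
  ref <- sample_exwald_intervals(12.7 / 1.4, 1000, 10, length(ivm), seed = 88)
  fit_r <- fit_model(ref, "exwald", seed = 87)
  expect_lt(abs(fit_m$params[["mu"]] / (12.7 / 1.4) - 1), 0.15)
  expect_lt(abs(fit_m$dkl_bits -
                  dkl_particle(empirical_distribution(ivm), "exwald", fit_r$params)),
            0.05)
})

test_that("records are quantized, truncated and reproducible", {
  r <- generate_record(12.7, 1000, 10, seed = 90)
  q <- r$spike_times / r$resolution
  expect_lt(max(abs(q - round(q))), 1e-9)
  expect_lte(max(r$spike_times), r$duration)
  expect_gt(length(r$spike_times), 500)
  # collision accounting with a coarse quantum
  rc <- generate_record(1, 50, 0.2, duration = 2, resolution = 2e-3, seed = 91)
  expect_gt(attr(rc, "n_collisions_dropped"), 0)
  d <- diff(round(rc$spike_times / rc$resolution))
  expect_true(all(d >= 1))
  expect_error(generate_record(0.001, 10, 0.001, duration = 20), "degenerate")
})

test_that("the default population reproduces the designed cloud geometry", {
  pop <- generate_population(population_config(seed = 92), emit_records = FALSE)
  cl <- pop$cloud
  expect_equal(nrow(cl), 300)
  # Wald means cluster tightly at 12.7 ms (geometric mean within 5%)
  expect_lt(abs(exp(mean(log(cl$mu))) / 12.7 - 1), 0.05)
  # Poisson means span ~4 decades, Wald shapes ~2
  expect_gt(log10(max(cl$tau) / min(cl$tau)), 3.5)
  lam_span <- log10(max(cl$lam) / min(cl$lam))
  expect_gt(lam_span, 1.5)
  expect_lt(lam_span, 2.5)
})

test_that("population output round-trips through the directory layout", {
  pop <- generate_population(population_config(n_records = 3, seed = 93,
                                               log_tau_range = c(0, 1)))
  dir <- file.path(tempdir(), "popdir")
  write_population(pop, dir)
  man <- utils::read.csv(file.path(dir, "manifest.csv"))
  expect_equal(nrow(man), 3)
  recs <- load_population_dir(dir)
  expect_named(recs, pop$cloud$record_id)
  expect_identical(recs[[1]]$spike_times, pop$records[[1]]$spike_times)
  gt <- utils::read.csv(file.path(dir, "ground_truth.csv"))
  expect_equal(gt$mu, pop$cloud$mu)
})
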