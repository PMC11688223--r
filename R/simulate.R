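# Synthetic spike-train generation.
#
# Two routes produce Exwald interval samples: direct sampling (Wald draw +
# Exponential draw) and simulation of the physical mechanism itself -- a
# Poisson trigger in noise that is blocked, after each emitted spike, by an
# integrate-and-fire (drift-diffusion to threshold) refractory process.  The
# direct sampler is the reference; the mechanism simulator must converge to
# it as the Euler step shrinks.

#' Sample Exwald intervals reproducibly
#'
#' Thin wrapper around [rexwald()] that seeds the generator, so synthetic
#' records are bit-reproducible.
#'
#' @inheritParams rexwald
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @return numeric vector of `n` intervals (ms).
#' @export
sample_exwald_intervals <- function(mu, lambda, tau, n, seed = NULL) {
  if (n < 1) stop("n must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  rexwald(n, mu, lambda, tau)
}

#' Configuration for the physical spike-generation mechanism
#'
#' @param mu mean first-passage time of the integrate-and-fire (refractory)
#'   component (ms).
#' @param lam first-passage shape parameter (ms); the drift-diffusion has
#'   drift `1/mu` and diffusion variance `1/lam` against a threshold at 1.
#' @param tau Poisson trigger mean interval (ms).
#' @param dt Euler integration step (ms); default `min(tau, mu) / 1000`,
#'   must be at most `min(tau, mu) / 100`.
#' @param duration simulated time (s).
#' @param seed integer seed.
#' @param input_gain dimensionless gain applied to the kinematic input
#'   (0 = stationary).
#' @param resolution acquisition quantum (s) used when the simulated train
#'   is emitted as a record.
#' @param allow_coarse_dt permit `dt` coarser than `min(tau, mu)/100`; only
#'   for discretization-convergence studies, where the deliberately biased
#'   coarse-step simulation is compared against finer steps.
#' @return a `"mechanism_config"` list.
#' @seealso [simulate_mechanism()], [modulate_by_input()]
#' @export
mechanism_config <- function(mu, lam, tau, dt = NULL, duration = 20,
                             seed = 1, input_gain = 0, resolution = 3e-4,
                             allow_coarse_dt = FALSE) {
  .check_pos(mu = mu, lam = lam, tau = tau)
  if (is.null(dt)) dt <- min(tau, mu) / 1000
  if (dt > min(tau, mu) / 100 && !allow_coarse_dt) {
    stop(sprintf("dt = %g ms too coarse; need dt <= min(tau, mu)/100 = %g ms",
                 dt, min(tau, mu) / 100))
  }
  if (duration <= 0) stop("duration must be positive")
  structure(list(mu = mu, lam = lam, tau = tau, dt = dt,
                 duration = duration, seed = seed,
                 input_gain = input_gain, resolution = resolution,
                 accel = NULL, vel = NULL),
            class = "mechanism_config")
}

#' Attach a kinematic input to a mechanism configuration
#'
#' Interprets the input series as head angular acceleration sampled on the
#' Euler step grid.  During simulation the Poisson trigger rate `1/tau`
#' scales by `(1 + input_gain * a(t))` and the integrate-and-fire drift
#' `1/mu` by `(1 + input_gain * v(t))`, where `v` is the running integral of
#' `a`; both factors are clipped at 0.  A zero series (or zero gain) reduces
#' exactly to the stationary mechanism.
#'
#' @param cfg a `"mechanism_config"`.
#' @param accel numeric vector of acceleration samples, one per Euler step
#'   (recycled/truncated to the simulated duration; the last value is held
#'   beyond the series end), or a function of time (ms).
#' @param input_gain optional override of the config's gain.
#' @return the configuration with the input attached.
#' @export
modulate_by_input <- function(cfg, accel, input_gain = NULL) {
  stopifnot(inherits(cfg, "mechanism_config"))
  if (!is.null(input_gain)) cfg$input_gain <- input_gain
  n_steps <- ceiling(cfg$duration * 1000 / cfg$dt)
  if (is.function(accel)) {
    accel <- accel(seq_len(n_steps) * cfg$dt)
  }
  accel <- as.numeric(accel)
  if (length(accel) < n_steps) {
    accel <- c(accel, rep(accel[length(accel)], n_steps - length(accel)))
  }
  cfg$accel <- accel[seq_len(n_steps)]
  cfg$vel <- cumsum(cfg$accel) * cfg$dt
  cfg
}

#' Simulate the spike-generation mechanism
#'
#' Event loop: after each spike the drift-diffusion integral
#' `dX = (1/mu) dt + sqrt(1/lam) dB` runs from 0 until it reaches the
#' threshold at 1 (the blocking / refractory phase); the Poisson trigger
#' then fires with per-step probability `dt/tau` and the first trigger event
#' after the block is emitted as the next spike.  Trigger events arriving
#' during the block are counted (they are censored, not emitted), so the
#' refractory decimation ratio of the train is observable.  The Poisson wait
#' is drawn as a geometric step count, which is exact for the per-step
#' Bernoulli process; the blocking phase is chunked vectorized
#' Euler-Maruyama.
#'
#' @param cfg a `"mechanism_config"`.
#' @return a `"spike_train_record"` (times quantized to `cfg$resolution`)
#'   with attributes `n_trigger_events` (all trigger events, censored or
#'   emitted), `n_emitted` (spike count) and `intervals_ms` (the exact,
#'   unquantized simulated intervals).
#' @export
simulate_mechanism <- function(cfg) {
  stopifnot(inherits(cfg, "mechanism_config"))
  set.seed(cfg$seed)
  dt <- cfg$dt
  total_ms <- cfg$duration * 1000
  gain <- cfg$input_gain
  modulated <- !is.null(cfg$accel) && gain != 0
  sd_step <- sqrt(dt / cfg$lam)
  p0 <- dt / cfg$tau
  exp_steps <- cfg$mu / dt
  chunk <- ceiling(exp_steps + 6 * sqrt(cfg$mu^3 / cfg$lam) / dt + 100)
  chunk <- min(chunk, 5e6)
  step_at <- 0 # global Euler step counter (for input lookup)
  n_steps_total <- ceiling(total_ms / dt)
  times <- numeric(0)
  n_spikes <- 0L
  n_triggers <- 0
  t_ms <- 0
  intervals <- numeric(0)
  repeat {
    # blocking phase: integrate to threshold
    x <- 0
    n_block <- 0L
    repeat {
      if (modulated) {
        ix <- pmin(step_at + n_block + seq_len(chunk), n_steps_total)
        drift <- pmax(0, 1 + gain * cfg$vel[ix]) * dt / cfg$mu
      } else {
        drift <- dt / cfg$mu
      }
      inc <- stats::rnorm(chunk, drift, sd_step)
      cs <- x + cumsum(inc)
      hit <- which(cs >= 1)
      if (length(hit)) {
        n_block <- n_block + hit[1]
        break
      }
      x <- cs[chunk]
      n_block <- n_block + chunk
      if ((n_block + step_at) * dt > 10 * total_ms) {
        stop("integrate-and-fire phase failed to reach threshold; check parameters")
      }
    }
    # trigger events censored during the block
    if (modulated) {
      ix <- pmin(step_at + seq_len(n_block), n_steps_total)
      pb <- pmin(1, pmax(0, 1 + gain * cfg$accel[ix]) * p0)
      n_triggers <- n_triggers + sum(stats::runif(n_block) < pb)
      # waiting phase: step until the first trigger
      n_wait <- 0L
      repeat {
        m <- 1000L
        ix <- pmin(step_at + n_block + n_wait + seq_len(m), n_steps_total)
        pw <- pmin(1, pmax(0, 1 + gain * cfg$accel[ix]) * p0)
        fire <- which(stats::runif(m) < pw)
        if (length(fire)) {
          n_wait <- n_wait + fire[1]
          break
        }
        n_wait <- n_wait + m
        if ((step_at + n_block + n_wait) * dt > 10 * total_ms) break
      }
    } else {
      n_triggers <- n_triggers + stats::rbinom(1L, n_block, p0)
      n_wait <- stats::rgeom(1L, p0) + 1L
    }
    n_triggers <- n_triggers + 1 # the emitted trigger
    dt_spike <- (n_block + n_wait) * dt
    t_ms <- t_ms + dt_spike
    step_at <- step_at + n_block + n_wait
    if (t_ms > total_ms) break
    n_spikes <- n_spikes + 1L
    times[n_spikes] <- t_ms
    intervals[n_spikes] <- dt_spike
  }
  rec <- .quantize_times(times / 1000, cfg$resolution, cfg$duration,
                         record_id = sprintf("mech_%g", cfg$seed))
  attr(rec, "n_trigger_events") <- n_triggers
  attr(rec, "n_emitted") <- n_spikes
  attr(rec, "intervals_ms") <- if (n_spikes >= 2) diff(times) else numeric(0)
  rec
}

# quantize spike times (s) to multiples of the resolution, dropping the
# later of any pair that collides in one quantum
.quantize_times <- function(times_s, resolution, duration, record_id) {
  q <- round(times_s / resolution) * resolution
  q <- q[q <= duration + resolution / 2]
  keep <- !duplicated(round(q / resolution))
  dropped <- sum(!keep)
  rec <- spike_train_record(q[keep], record_id = record_id,
                            duration = duration, resolution = resolution)
  attr(rec, "n_collisions_dropped") <- dropped
  rec
}

#' Generate an acquisition-realistic synthetic record
#'
#' Samples Exwald intervals, cumulative-sums them from time zero, truncates
#' at the record duration, and quantizes the spike times to the acquisition
#' resolution (spikes colliding in one quantum keep only the earlier one;
#' the number dropped is recorded as an attribute).
#'
#' @inheritParams dexwald
#' @param duration record length (s).
#' @param resolution acquisition quantum (s).
#' @param seed integer seed.
#' @param record_id identifier.
#' @return a `"spike_train_record"` with attribute `n_collisions_dropped`.
#' @export
generate_record <- function(mu, lambda, tau, duration = 20,
                            resolution = 3e-4, seed = 1,
                            record_id = sprintf("syn_%d", seed)) {
  .check_pos(mu = mu, lambda = lambda, tau = tau)
  stopifnot(duration > 0, resolution > 0)
  expected <- duration * 1000 / (mu + tau)
  if (expected > 1e6) {
    stop(sprintf("degenerate parameters: ~%.2g expected spikes", expected))
  }
  set.seed(seed)
  n <- ceiling(expected + 6 * sqrt(expected) + 10)
  t_ms <- cumsum(rexwald(n, mu, lambda, tau))
  while (t_ms[length(t_ms)] < duration * 1000) {
    t_ms <- c(t_ms, t_ms[length(t_ms)] +
                cumsum(rexwald(n, mu, lambda, tau)))
  }
  t_ms <- t_ms[t_ms <= duration * 1000]
  .quantize_times(t_ms / 1000, resolution, duration, record_id)
}

#' Configuration of a synthetic afferent population
#'
#' Defaults reproduce the structure of the fitted-parameter cloud: the Wald
#' mean tightly log-normally clustered at 12.7 ms, the Poisson mean spanning
#' four decades, and the Wald shape following a log-log line of slope -0.5
#' against the Poisson mean (lambda = 10^3 ms at tau = 10 ms) with mild
#' scatter, so that lambda spans about two decades.
#'
#' @param n_records number of records.
#' @param mu_log_mean center of log10 mu (default `log10(12.7)`).
#' @param mu_log_sd spread of log10 mu.
#' @param log_tau_range range of log10 tau (uniform draw), in log10 ms.
#' @param slope log-log slope of lambda on tau.
#' @param lam_log_intercept log10 lambda at log10 tau = 0.
#' @param lam_log_noise_sd scatter of log10 lambda about the line.
#' @param duration record length (s).
#' @param resolution acquisition quantum (s).
#' @param seed integer seed.
#' @return a `"population_config"` list.
#' @export
population_config <- function(n_records = 300,
                              mu_log_mean = log10(12.7), mu_log_sd = 0.05,
                              log_tau_range = c(-1.5, 2.5), slope = -0.5,
                              lam_log_intercept = 3.5, lam_log_noise_sd = 0.15,
                              duration = 20, resolution = 3e-4, seed = 1) {
  stopifnot(n_records >= 1, length(log_tau_range) == 2,
            log_tau_range[1] < log_tau_range[2])
  structure(list(n_records = n_records, mu_log_mean = mu_log_mean,
                 mu_log_sd = mu_log_sd, log_tau_range = log_tau_range,
                 slope = slope, lam_log_intercept = lam_log_intercept,
                 lam_log_noise_sd = lam_log_noise_sd, duration = duration,
                 resolution = resolution, seed = seed),
            class = "population_config")
}

#' Generate a synthetic afferent population
#'
#' Draws one (mu, lam, tau) triple per record from the population model in
#' [population_config()] and emits one quantized spike-train record per
#' triple.  The ground-truth cloud is returned alongside the records for
#' recovery studies.
#'
#' @param cfg a `"population_config"` (or arguments for one via `...`).
#' @param emit_records generate the spike-train records (set `FALSE` to draw
#'   only the ground-truth parameter cloud).
#' @param ... passed to [population_config()] when `cfg` is missing.
#' @return list with `cloud` (data frame: `record_id`, `mu`, `lam`, `tau`,
#'   `seed`) and `records` (list of `"spike_train_record"`, or `NULL`).
#' @export
generate_population <- function(cfg = NULL, emit_records = TRUE, ...) {
  if (is.null(cfg)) cfg <- population_config(...)
  stopifnot(inherits(cfg, "population_config"))
  set.seed(cfg$seed)
  n <- cfg$n_records
  log_mu <- stats::rnorm(n, cfg$mu_log_mean, cfg$mu_log_sd)
  log_tau <- stats::runif(n, cfg$log_tau_range[1], cfg$log_tau_range[2])
  log_lam <- cfg$lam_log_intercept + cfg$slope * log_tau +
    stats::rnorm(n, 0, cfg$lam_log_noise_sd)
  seeds <- sample.int(.Machine$integer.max - 1L, n)
  cloud <- data.frame(record_id = sprintf("syn_%03d", seq_len(n)),
                      mu = 10^log_mu, lam = 10^log_lam, tau = 10^log_tau,
                      seed = seeds, stringsAsFactors = FALSE)
  records <- if (emit_records) {
    lapply(seq_len(n), function(i) {
      generate_record(cloud$mu[i], cloud$lam[i], cloud$tau[i],
                      duration = cfg$duration, resolution = cfg$resolution,
                      seed = cloud$seed[i], record_id = cloud$record_id[i])
    })
  }
  list(cloud = cloud, records = records)
}

#' Write a synthetic population to a directory
#'
#' One plain-text record file per neuron plus `manifest.csv`
#' (`record_id, path`) and `ground_truth.csv` (`record_id, mu, lam, tau,
#' seed`).
#'
#' @param population result of [generate_population()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_population <- function(population, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(population$records, function(r) {
    p <- file.path(dir, paste0(r$record_id, ".txt"))
    write_record(r, p)
    p
  }, character(1))
  utils::write.csv(data.frame(record_id = population$cloud$record_id,
                              path = paths, stringsAsFactors = FALSE),
                   file.path(dir, "manifest.csv"), row.names = FALSE)
  utils::write.csv(population$cloud, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Refractory decimation factor of a censored Poisson process
#'
#' Event-level simulation of the censoring identity: each emitted interval
#' consists of a Wald(\eqn{\mu}, \eqn{\lambda}) blocking time, during which
#' trigger events arrive as a Poisson count with mean (blocking time)/tau
#' and are censored, followed by one emitted trigger.  The decimation factor
#' is (all trigger events)/(emitted spikes); its expectation is
#' \eqn{(\mu + \tau)/\tau}.
#'
#' @inheritParams dexwald
#' @param n number of emitted intervals to simulate.
#' @param seed integer seed.
#' @return the simulated decimation factor (a single number).
#' @export
decimation_factor <- function(mu, lambda, tau, n = 1e5, seed = 1) {
  .check_pos(mu = mu, lambda = lambda, tau = tau)
  set.seed(seed)
  w <- rwald(n, mu, lambda)
  censored <- stats::rpois(n, w / tau)
  (sum(censored) + n) / n
}
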