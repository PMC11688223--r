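# Minimum Kullback-Leibler fitting of candidate interval models.
#
# With the empirical distribution represented as particles at the observed
# intervals t_1..t_N, the divergence from model q reduces to
#   D_KL = -(1/N) sum log2 q(t_k) + log2 N,
# so the per-record argmin coincides with maximum likelihood while the
# divergence scale remains comparable across records of different size and
# entropy.  Optimization is a bounded Nelder-Mead simplex: parameters are
# mapped into the bounding box with a sine transform (log10 space for
# positive scale parameters), and integer shape parameters are profiled.

#' Empirical interval distribution
#'
#' Wraps an interval sample in its particle representation, optionally with
#' a normalized frequency histogram (Freedman-Diaconis bin width by default;
#' the histogram is used for reporting, never for fitting).
#'
#' @param intervals interval sample (ms) or an `"isi_sequence"`.
#' @param record_id identifier; taken from the sequence when available.
#' @param histogram if `TRUE`, attach `hist_edges` and `hist_p`
#'   (`p_k = n_k / N`).
#' @param breaks optional explicit bin edges (ms), implies `histogram`.
#' @return an object of class `"empirical_distribution"`.
#' @export
empirical_distribution <- function(intervals, record_id = NULL,
                                   histogram = FALSE, breaks = NULL) {
  if (inherits(intervals, "isi_sequence")) {
    if (is.null(record_id)) record_id <- intervals$record_id
    intervals <- intervals$intervals
  }
  intervals <- as.numeric(intervals)
  if (!length(intervals) || anyNA(intervals) || any(intervals <= 0)) {
    stop("intervals must be a non-empty vector of positive times (ms)")
  }
  out <- list(record_id = if (is.null(record_id)) "sample" else record_id,
              intervals = intervals, N = length(intervals),
              hist_edges = NULL, hist_p = NULL)
  if (!is.null(breaks) || isTRUE(histogram)) {
    if (is.null(breaks)) {
      bw <- 2 * stats::IQR(intervals) / length(intervals)^(1 / 3)
      if (bw <= 0) bw <- diff(range(intervals)) / 30 + 1e-9
      breaks <- seq(min(intervals) - bw / 2, max(intervals) + bw, by = bw)
    }
    h <- graphics::hist(intervals, breaks = breaks, plot = FALSE)
    out$hist_edges <- h$breaks
    out$hist_p <- h$counts / length(intervals)
  }
  structure(out, class = "empirical_distribution")
}

.as_empirical <- function(x) {
  if (inherits(x, "empirical_distribution")) x
  else empirical_distribution(.sample_intervals(x),
                              record_id = if (inherits(x, "isi_sequence")) x$record_id else NULL)
}

#' Kullback-Leibler divergence of a model from a particle sample
#'
#' \deqn{D_{KL} = -\frac{1}{N}\sum_k \log_2 q(t_k) + \log_2 N} in bits.  Any
#' observation with zero model density makes the divergence infinite.
#'
#' @param sample an `"empirical_distribution"` (or intervals).
#' @param model a `"model_spec"` or name.
#' @param params named parameter vector.
#' @return divergence in bits (may be `Inf`).
#' @seealso [dkl_histogram()], [fit_model()]
#' @export
dkl_particle <- function(sample, model, params) {
  ed <- .as_empirical(sample)
  ld <- model_logdensity(model, ed$intervals, params) / log(2)
  if (any(!is.finite(ld))) return(Inf)
  -sum(ld) / ed$N + log2(ed$N)
}

#' Kullback-Leibler divergence of a model from a histogram
#'
#' \eqn{\sum_k p_k \log_2 (p_k / q_k)} over populated bins, where
#' \eqn{q_k} is the model density at the bin center times the bin width.
#'
#' @inheritParams dkl_particle
#' @return divergence in bits (`Inf` if any populated bin has zero model
#'   mass).
#' @export
dkl_histogram <- function(sample, model, params) {
  ed <- .as_empirical(sample)
  if (is.null(ed$hist_p)) stop("sample has no histogram; see empirical_distribution()")
  mids <- (ed$hist_edges[-1] + ed$hist_edges[-length(ed$hist_edges)]) / 2
  widths <- diff(ed$hist_edges)
  q <- exp(model_logdensity(model, mids, params)) * widths
  p <- ed$hist_p
  keep <- p > 0
  if (any(q[keep] <= 0)) return(Inf)
  sum(p[keep] * log2(p[keep] / q[keep]))
}

# ---- bounded sine transform ---------------------------------------------

# free parameters (non-integer) are optimized as unconstrained u with
#   value = lo + (hi - lo) (1 + sin u) / 2      (log10 space if log_scale)
.to_unbounded <- function(par, spec, free) {
  lo <- spec$lower[free]
  hi <- spec$upper[free]
  v <- par[free]
  ls <- spec$log_scale[free]
  v[ls] <- log10(v[ls])
  lo[ls] <- log10(lo[ls])
  hi[ls] <- log10(hi[ls])
  asin(pmin(1, pmax(-1, 2 * (v - lo) / (hi - lo) - 1)))
}

.to_bounded <- function(u, spec, free) {
  lo <- spec$lower[free]
  hi <- spec$upper[free]
  ls <- spec$log_scale[free]
  lo[ls] <- log10(lo[ls])
  hi[ls] <- log10(hi[ls])
  v <- lo + (hi - lo) * (1 + sin(u)) / 2
  v[ls] <- 10^v[ls]
  v
}

# fitting objective: D_KL in bits with a -1000 bits/observation floor so the
# simplex can climb out of zero-density regions instead of seeing Inf
.dkl_objective <- function(t, model, params) {
  ld <- model_logdensity(model, t, params) / log(2)
  ld[!is.finite(ld) | ld < -1000] <- -1000
  -sum(ld) / length(t) + log2(length(t))
}

.optim_free <- function(t, spec, start, fixed = NULL,
                        maxit = 5000, reltol = 1e-6) {
  free <- setdiff(seq_len(spec$n_params), which(spec$integer))
  fn <- function(u) {
    par <- numeric(spec$n_params)
    names(par) <- spec$param_names
    par[free] <- .to_bounded(u, spec, free)
    if (!is.null(fixed)) par[names(fixed)] <- fixed
    .dkl_objective(t, spec, par)
  }
  u0 <- .to_unbounded(start, spec, free)
  fit <- stats::optim(u0, fn, method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = reltol))
  par <- numeric(spec$n_params)
  names(par) <- spec$param_names
  par[free] <- .to_bounded(fit$par, spec, free)
  if (!is.null(fixed)) par[names(fixed)] <- fixed
  list(par = par, value = fit$value, converged = fit$convergence == 0)
}

# profile over the integer shape of erlang-type models; the plain Erlang has
# a closed-form inner solution (ML scale = mean / kappa), the 3-parameter
# variants run an inner simplex for each profiled kappa
.fit_profile_kappa <- function(t, spec, start, maxit, reltol) {
  kmax <- spec$upper[spec$param_names == "kappa"]
  if (spec$name == "erlang") {
    m <- mean(t)
    best <- NULL
    for (k in seq_len(kmax)) {
      par <- c(kappa = k, mu = max(m / k, spec$lower[2] * (1 + 1e-6)))
      val <- .dkl_objective(t, spec, par[spec$param_names])
      if (is.null(best) || val < best$value) {
        best <- list(par = par[spec$param_names], value = val, converged = TRUE)
      }
    }
    return(best)
  }
  # coarse geometric grid, then refine around the winner
  coarse <- unique(pmin(kmax, c(1, 2, 3, 4, 6, 8, 12, 16, 24, 32, 48, 64, 96, 128, 200)))
  eval_k <- function(k) {
    st <- start
    st["kappa"] <- k
    # rescale the stage mean so the Erlang-component mean is preserved
    if ("mu" %in% names(st)) {
      st["mu"] <- st["mu"] * start["kappa"] / k
    }
    st <- .clip_to_bounds(st[spec$param_names], spec)
    names(st) <- spec$param_names
    .optim_free(t, spec, st, fixed = c(kappa = k),
                maxit = maxit, reltol = reltol)
  }
  fits <- lapply(coarse, eval_k)
  vals <- vapply(fits, `[[`, numeric(1), "value")
  kbest <- coarse[which.min(vals)]
  best <- fits[[which.min(vals)]]
  for (k in setdiff(intersect(seq(kbest - 3, kbest + 3), seq_len(kmax)), coarse)) {
    f <- eval_k(k)
    if (f$value < best$value) best <- f
  }
  best
}

# second structured start for the convolution families: estimate the
# refractory dead time from the low quantiles and give the Exponential
# component the remaining mean.  Essential for irregular records, where the
# Exponential dominates and the moment split misattributes variance.
.init_params_deadtime <- function(t, spec) {
  if (!spec$name %in% c("exwald", "exerlang", "exgaussian")) return(NULL)
  m <- mean(t)
  v <- stats::var(t)
  mu0 <- max(stats::quantile(t, 0.01, names = FALSE), 1e-3)
  if (mu0 >= 0.95 * m) mu0 <- 0.95 * m
  tau0 <- m - mu0
  v2 <- max(v - tau0^2, 0.05 * v)
  par <- switch(spec$name,
    exwald = c(mu = mu0, lam = mu0^3 / v2, tau = tau0),
    exgaussian = c(mu = mu0, sigma = sqrt(v2), tau = tau0),
    exerlang = {
      k <- max(1, min(.KAPPA_MAX, round(mu0^2 / v2)))
      c(kappa = k, mu = mu0 / k, tau = tau0)
    })
  out <- .clip_to_bounds(par[spec$param_names], spec)
  names(out) <- spec$param_names
  out
}

#' Fit a candidate model to an interval sample by minimum K-L divergence
#'
#' Runs a bounded Nelder-Mead simplex from a method-of-moments start plus
#' `n_restarts` multiplicatively jittered restarts (log-space jitter factor
#' `exp(N(0, 0.5))` on positive parameters) and keeps the best minimum.
#' The Exponential-convolution families additionally start from a
#' dead-time-based split (refractory mean from the 1st percentile of the
#' sample) so that Exponential-dominated records reach the censored-Poisson
#' basin, and the winning minimum is polished by one simplex restart.
#' Integer shape parameters are profiled over a grid rather than moved by the
#' simplex.  Minimizing the particle-form divergence is equivalent to
#' maximum likelihood for a single record.
#'
#' @param sample an `"empirical_distribution"`, `"isi_sequence"` or interval
#'   vector with at least 10 intervals.
#' @param model a `"model_spec"` or name from [list_models()].
#' @param seed integer seed controlling the restart jitter (recorded in the
#'   result); `NULL` leaves the RNG state alone.
#' @param n_restarts jittered restarts in addition to the moment start.
#' @param maxit maximum simplex evaluations per start.
#' @param reltol simplex relative convergence tolerance.
#' @return object of class `"isi_fit"`: `record_id`, `model`, `params`,
#'   `dkl_bits`, `nll_bits` (\eqn{-\sum \log_2 q(t_k)}), `converged`,
#'   `n_restarts`, `seed`.  `dkl_bits = nll_bits / N + log2 N` by
#'   construction.
#' @export
fit_model <- function(sample, model, seed = NULL, n_restarts = 5,
                      maxit = 5000, reltol = 1e-6) {
  ed <- .as_empirical(sample)
  if (ed$N < 10) stop("need at least 10 intervals to fit a model")
  spec <- .as_model_spec(model)
  if (!is.null(seed)) set.seed(seed)
  t <- ed$intervals
  start0 <- init_params(ed, spec)
  has_int <- any(spec$integer)
  run_one <- function(st) {
    if (has_int) .fit_profile_kappa(t, spec, st, maxit, reltol)
    else .optim_free(t, spec, st, maxit = maxit, reltol = reltol)
  }
  starts <- list(start0)
  alt <- .init_params_deadtime(t, spec)
  if (!is.null(alt)) starts <- c(starts, list(alt))
  best <- NULL
  for (s0 in starts) {
    f <- run_one(s0)
    if (is.null(best) || f$value < best$value) best <- f
  }
  for (r in seq_len(n_restarts)) {
    st <- starts[[1 + (r - 1) %% length(starts)]]
    jit <- exp(stats::rnorm(spec$n_params, 0, 0.5))
    pos <- spec$log_scale
    st[pos] <- st[pos] * jit[pos]
    st[!pos] <- st[!pos] + (jit[!pos] - 1) * pmax(abs(st[!pos]), 1)
    st <- .clip_to_bounds(st, spec)
    names(st) <- spec$param_names
    f <- run_one(st)
    if (f$value < best$value) best <- f
  }
  # polish: restart the simplex at the winning minimum
  if (!has_int) {
    f <- .optim_free(t, spec, .clip_to_bounds(best$par, spec),
                     maxit = maxit, reltol = reltol)
    if (f$value < best$value) best <- f
  }
  ld2 <- model_logdensity(spec, t, best$par) / log(2)
  nll <- -sum(ld2)
  structure(list(record_id = ed$record_id, model = spec$name,
                 params = best$par,
                 dkl_bits = nll / ed$N + log2(ed$N),
                 nll_bits = nll,
                 converged = best$converged && is.finite(nll),
                 n_restarts = n_restarts,
                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed)),
            class = "isi_fit")
}

#' @export
print.isi_fit <- function(x, ...) {
  cat(sprintf("<isi_fit> %s ~ %s: D_KL = %.4f bits%s\n", x$record_id,
              x$model, x$dkl_bits,
              if (x$converged) "" else " (not converged)"))
  print(signif(x$params, 5))
  invisible(x)
}

#' Fit one or more models to a collection of records
#'
#' @param samples list of interval samples (any form accepted by
#'   [fit_model()]).
#' @param models character vector of model names.
#' @param seed integer; per-(record, model) seeds are derived from it so the
#'   whole table is reproducible.
#' @param ... passed to [fit_model()].
#' @return data frame with one row per (record, model): identifier, model,
#'   one column per parameter name in use (NA where a family lacks it),
#'   `nll_bits`, `dkl_bits`, `converged`, `n_restarts`, `seed`.
#' @export
fit_records <- function(samples, models = "exwald", seed = 1, ...) {
  stopifnot(length(samples) >= 1)
  all_par <- unique(unlist(lapply(models, function(m) model_spec(m)$param_names)))
  rows <- list()
  for (i in seq_along(samples)) {
    for (m in models) {
      sub_seed <- (seed + 7919L * i + 104729L * match(m, models)) %% .Machine$integer.max
      fit <- fit_model(samples[[i]], m, seed = sub_seed, ...)
      row <- as.list(rep(NA_real_, length(all_par)))
      names(row) <- all_par
      row[names(fit$params)] <- fit$params
      rows[[length(rows) + 1L]] <- data.frame(
        record_id = fit$record_id, model = fit$model, row,
        nll_bits = fit$nll_bits, dkl_bits = fit$dkl_bits,
        converged = fit$converged, n_restarts = fit$n_restarts,
        seed = fit$seed, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Rank candidate models across a population of records
#'
#' Identifies the overall best family (lowest mean divergence over records),
#' then reports for every family the mean and standard error of
#' \eqn{\Delta D_{KL} = D_{KL}(\mathrm{model}) - D_{KL}(\mathrm{best})}
#' computed record by record against that best family's fit of the same
#' record.
#'
#' @param fits data frame from [fit_records()]; every record must have been
#'   fitted by every model being compared.
#' @return data frame with one row per model: `model`,
#'   `mean_delta_dkl_bits`, `sem`, `n_records`, sorted ascending; the best
#'   family has mean 0 by construction.
#' @export
rank_models <- function(fits) {
  stopifnot(all(c("record_id", "model", "dkl_bits") %in% names(fits)))
  tab <- table(fits$record_id, fits$model)
  if (any(tab != 1)) {
    gaps <- which(tab != 1, arr.ind = TRUE)
    stop(sprintf("missing or duplicated (record, model) fits, e.g. record '%s' x model '%s'",
                 rownames(tab)[gaps[1, 1]], colnames(tab)[gaps[1, 2]]))
  }
  models <- unique(fits$model)
  mean_dkl <- vapply(models, function(m) mean(fits$dkl_bits[fits$model == m]),
                     numeric(1))
  best <- models[which.min(mean_dkl)]
  base <- fits[fits$model == best, c("record_id", "dkl_bits")]
  names(base)[2] <- "base_dkl"
  merged <- merge(fits, base, by = "record_id")
  merged$delta <- merged$dkl_bits - merged$base_dkl
  out <- do.call(rbind, lapply(models, function(m) {
    d <- merged$delta[merged$model == m]
    data.frame(model = m, mean_delta_dkl_bits = mean(d),
               sem = stats::sd(d) / sqrt(length(d)), n_records = length(d),
               stringsAsFactors = FALSE)
  }))
  out[order(out$mean_delta_dkl_bits), , drop = FALSE]
}
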