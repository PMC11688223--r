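# Candidate-model registry.  Each candidate family is described by a model
# spec: ordered parameter names, fitting bounds, and which parameters live on
# a log scale (optimized in log10) or are integers (profiled, since a simplex
# cannot move on an integer lattice).
#
# Families come in three groups: bare renewal densities (weibull, lognormal,
# erlang, damage, wald), the same with a fixed time offset (offset_*), and
# Exponential convolutions (exerlang, exwald, exgaussian).

.TIME_LO <- 1e-3
.TIME_HI <- 1e4
.LAM_HI <- 1e5 # Wald shape ranges wider across the population
.SHAPE_LO <- 1e-2
.SHAPE_HI <- 1e2
.KAPPA_MAX <- 200L
.OFFSET_LO <- -50
.OFFSET_HI <- 200

.model_table <- list(
  weibull = list(
    param_names = c("lam", "kappa"),
    lower = c(.TIME_LO, .SHAPE_LO), upper = c(.TIME_HI, .SHAPE_HI),
    log_scale = c(TRUE, TRUE), integer = c(FALSE, FALSE), group = 1L),
  lognormal = list(
    param_names = c("mu", "sigma"),
    lower = c(log(.TIME_LO), .SHAPE_LO), upper = c(log(.TIME_HI), .SHAPE_HI),
    log_scale = c(FALSE, TRUE), integer = c(FALSE, FALSE), group = 1L),
  erlang = list(
    param_names = c("kappa", "mu"),
    lower = c(1, .TIME_LO), upper = c(.KAPPA_MAX, .TIME_HI),
    log_scale = c(FALSE, TRUE), integer = c(TRUE, FALSE), group = 1L),
  damage = list(
    param_names = c("beta", "gamma"),
    lower = c(.TIME_LO, .SHAPE_LO), upper = c(.TIME_HI, .SHAPE_HI),
    log_scale = c(TRUE, TRUE), integer = c(FALSE, FALSE), group = 1L),
  wald = list(
    param_names = c("mu", "lam"),
    lower = c(.TIME_LO, .TIME_LO), upper = c(.TIME_HI, .LAM_HI),
    log_scale = c(TRUE, TRUE), integer = c(FALSE, FALSE), group = 1L),
  offset_erlang = list(
    param_names = c("kappa", "mu", "tau0"),
    lower = c(1, .TIME_LO, .OFFSET_LO), upper = c(.KAPPA_MAX, .TIME_HI, .OFFSET_HI),
    log_scale = c(FALSE, TRUE, FALSE), integer = c(TRUE, FALSE, FALSE),
    group = 2L, base = "erlang"),
  offset_wald = list(
    param_names = c("mu", "lam", "tau0"),
    lower = c(.TIME_LO, .TIME_LO, .OFFSET_LO), upper = c(.TIME_HI, .LAM_HI, .OFFSET_HI),
    log_scale = c(TRUE, TRUE, FALSE), integer = c(FALSE, FALSE, FALSE),
    group = 2L, base = "wald"),
  offset_damage = list(
    param_names = c("beta", "gamma", "tau0"),
    lower = c(.TIME_LO, .SHAPE_LO, .OFFSET_LO), upper = c(.TIME_HI, .SHAPE_HI, .OFFSET_HI),
    log_scale = c(TRUE, TRUE, FALSE), integer = c(FALSE, FALSE, FALSE),
    group = 2L, base = "damage"),
  exerlang = list(
    param_names = c("kappa", "mu", "tau"),
    lower = c(1, .TIME_LO, .TIME_LO), upper = c(.KAPPA_MAX, .TIME_HI, .TIME_HI),
    log_scale = c(FALSE, TRUE, TRUE), integer = c(TRUE, FALSE, FALSE),
    group = 3L, base = "erlang"),
  exwald = list(
    param_names = c("mu", "lam", "tau"),
    lower = c(.TIME_LO, .TIME_LO, .TIME_LO), upper = c(.TIME_HI, .LAM_HI, .TIME_HI),
    log_scale = c(TRUE, TRUE, TRUE), integer = c(FALSE, FALSE, FALSE),
    group = 3L, base = "wald"),
  exgaussian = list(
    param_names = c("mu", "sigma", "tau"),
    lower = c(.TIME_LO, .TIME_LO, .TIME_LO), upper = c(.TIME_HI, .TIME_HI, .TIME_HI),
    log_scale = c(TRUE, TRUE, TRUE), integer = c(FALSE, FALSE, FALSE),
    group = 3L, base = "gaussian")
)

#' Names of the candidate interspike-interval model families
#'
#' @return character vector of registered model names.
#' @export
list_models <- function() names(.model_table)

#' Retrieve a candidate-model specification
#'
#' A spec records the ordered parameter names, the fitting bounds for each
#' parameter, which parameters are optimized on a log10 scale, which are
#' integers (profiled rather than moved by the simplex), and the model group
#' (1 = bare density, 2 = fixed time offset, 3 = Exponential convolution).
#'
#' @param name one of [list_models()].
#' @return an object of class `"model_spec"`.
#' @examples
#' model_spec("exwald")
#' @export
model_spec <- function(name) {
  name <- match.arg(name, names(.model_table))
  spec <- .model_table[[name]]
  spec$name <- name
  spec$n_params <- length(spec$param_names)
  structure(spec, class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> %s (group %d, %d parameters)\n",
              x$name, x$group, x$n_params))
  for (i in seq_len(x$n_params)) {
    cat(sprintf("  %-6s in [%g, %g]%s%s\n", x$param_names[i],
                x$lower[i], x$upper[i],
                if (x$log_scale[i]) " (log scale)" else "",
                if (x$integer[i]) " (integer)" else ""))
  }
  invisible(x)
}

.as_model_spec <- function(model) {
  if (inherits(model, "model_spec")) model else model_spec(model)
}

#' Evaluate a candidate model's log density
#'
#' Dispatches to the closed-form density of the named family.  `params` must
#' be a named vector matching the spec's `param_names` (order-insensitive).
#'
#' @param model a `"model_spec"` or model name.
#' @param t evaluation times (ms).
#' @param params named numeric vector of parameter values.
#' @return vector of natural-log densities (`-Inf` outside support).
#' @export
model_logdensity <- function(model, t, params) {
  spec <- .as_model_spec(model)
  missing <- setdiff(spec$param_names, names(params))
  if (length(missing)) {
    stop(sprintf("model '%s' needs parameter(s): %s", spec$name,
                 paste(missing, collapse = ", ")))
  }
  p <- as.list(params[spec$param_names])
  switch(spec$name,
    weibull = stats::dweibull(pmax(t, 0), shape = p$kappa, scale = p$lam, log = TRUE) +
      ifelse(t >= 0, 0, -Inf),
    lognormal = ifelse(t > 0,
      stats::dlnorm(pmax(t, .Machine$double.xmin), meanlog = p$mu, sdlog = p$sigma, log = TRUE),
      -Inf),
    erlang = derlang(t, kappa = p$kappa, mu = p$mu, log = TRUE),
    damage = ddamage(t, beta = p$beta, gamma = p$gamma, log = TRUE),
    wald = dwald(t, mu = p$mu, lambda = p$lam, log = TRUE),
    offset_erlang = derlang(t - p$tau0, kappa = p$kappa, mu = p$mu, log = TRUE),
    offset_wald = dwald(t - p$tau0, mu = p$mu, lambda = p$lam, log = TRUE),
    offset_damage = ddamage(t - p$tau0, beta = p$beta, gamma = p$gamma, log = TRUE),
    exerlang = dexerlang(t, kappa = p$kappa, mu = p$mu, tau = p$tau, log = TRUE),
    exwald = dexwald(t, mu = p$mu, lambda = p$lam, tau = p$tau, log = TRUE),
    exgaussian = dexgauss(t, mu = p$mu, sigma = p$sigma, tau = p$tau, log = TRUE),
    stop("unknown model: ", spec$name))
}

# Method-of-moments start point, always strictly inside the bounds.
.clip_to_bounds <- function(par, spec) {
  lo <- spec$lower
  hi <- spec$upper
  w <- hi - lo
  # keep strictly interior so the bounded sine transform is well defined
  lo_s <- ifelse(spec$log_scale, lo * (1 + 1e-6), lo + 1e-9 * w)
  hi_s <- ifelse(spec$log_scale, hi / (1 + 1e-6), hi - 1e-9 * w)
  pmin(pmax(par, lo_s), hi_s)
}

#' Method-of-moments starting parameters for fitting
#'
#' Inverts the closed-form moment identities of each family to place the
#' simplex start near the sample's mean/variance structure.  For the Exwald
#' the Exponential mean is seeded as `min(sd, mean/2)`, the Wald mean as the
#' remainder of the sample mean, and the Wald shape from the variance
#' identity with a 5 percent variance floor.  The returned vector is always
#' strictly inside the spec's bounds.
#'
#' @param sample an [empirical_distribution()] or numeric vector of
#'   intervals (ms); at least 10 values.
#' @param model a `"model_spec"` or model name.
#' @return named numeric start vector.
#' @export
init_params <- function(sample, model) {
  x <- .sample_intervals(sample)
  if (length(x) < 10) stop("need at least 10 intervals to initialize a fit")
  spec <- .as_model_spec(model)
  m <- mean(x)
  s <- stats::sd(x)
  s <- max(s, 1e-6 * m) # degenerate near-constant samples
  v <- s^2
  cv <- s / m
  par <- switch(spec$name,
    weibull = {
      k <- min(max(cv^(-1.086), .SHAPE_LO * 2), .SHAPE_HI / 2)
      c(lam = m / gamma(1 + 1 / k), kappa = k)
    },
    lognormal = {
      sig <- sqrt(log1p(cv^2))
      c(mu = log(m) - sig^2 / 2, sigma = sig)
    },
    erlang = {
      k <- max(1, min(.KAPPA_MAX, round(1 / cv^2)))
      c(kappa = k, mu = m / k)
    },
    damage = {
      g <- min(max(cv, .SHAPE_LO * 2), .SHAPE_HI / 2)
      c(beta = m / (1 + g^2 / 2), gamma = g)
    },
    wald = c(mu = m, lam = m^3 / v),
    offset_erlang = {
      t0 <- 0.5 * stats::quantile(x, 0.01, names = FALSE)
      m2 <- m - t0
      k <- max(1, min(.KAPPA_MAX, round(m2^2 / v)))
      c(kappa = k, mu = m2 / k, tau0 = t0)
    },
    offset_wald = {
      t0 <- 0.5 * stats::quantile(x, 0.01, names = FALSE)
      m2 <- m - t0
      c(mu = m2, lam = m2^3 / v, tau0 = t0)
    },
    offset_damage = {
      t0 <- 0.5 * stats::quantile(x, 0.01, names = FALSE)
      m2 <- m - t0
      g <- min(max(s / m2, .SHAPE_LO * 2), .SHAPE_HI / 2)
      c(beta = m2 / (1 + g^2 / 2), gamma = g, tau0 = t0)
    },
    exerlang = {
      tau0 <- min(s, m / 2)
      m2 <- m - tau0
      v2 <- max(v - tau0^2, 0.05 * v)
      k <- max(1, min(.KAPPA_MAX, round(m2^2 / v2)))
      c(kappa = k, mu = m2 / k, tau = tau0)
    },
    exwald = {
      tau0 <- min(s, m / 2)
      mu0 <- m - tau0
      c(mu = mu0, lam = mu0^3 / max(v - tau0^2, 0.05 * v), tau = tau0)
    },
    exgaussian = {
      tau0 <- min(s, m / 2)
      c(mu = m - tau0, sigma = sqrt(max(v - tau0^2, 0.05 * v)), tau = tau0)
    },
    stop("unknown model: ", spec$name))
  out <- .clip_to_bounds(par[spec$param_names], spec)
  names(out) <- spec$param_names
  out
}
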