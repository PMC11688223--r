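---
title: "Renewal-process models of vestibular afferent spike trains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Renewal-process models of vestibular afferent spike trains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exwald)
```

## The model

Spontaneous discharge of a semicircular-canal afferent neuron is treated as
a stationary renewal process: successive interspike intervals (ISIs) are
independent draws from one fixed density on positive times.  The working
model is the **Exwald** distribution, the convolution of

* a **Wald (inverse Gaussian)** component with mean first-passage time
  $\mu$ (ms) and shape $\lambda$ (ms) — the first-passage time of a
  drift-diffusion integrator with drift $1/\mu$ and diffusion variance
  $1/\lambda$ against a threshold at 1.  It models the stochastic
  refractory period; its mean is $\mu$, variance $\mu^3/\lambda$,
  CV $\sqrt{\mu/\lambda}$;
* an **Exponential** component with mean $\tau$ (ms) — the memoryless wait
  of a Poisson trigger process.

Because a Poisson process is memoryless, blocking it for a Wald-distributed
time after each emitted event and then waiting for the next trigger yields
intervals distributed as the *sum* of the two components.  The same neuron
can therefore be read as a high-rate Poisson process, left-censored by an
integrate-and-fire refractory mechanism, transmitting a randomly decimated
subsample of trigger events: with $\tau = 0.1$ ms and a $\sim$10 ms
refractory period the decimation factor is $(\mu+\tau)/\tau \approx 101$
(`decimation_factor()`).

Closed-form moments: mean $\mu + \tau$, variance $\mu^3/\lambda + \tau^2$
(`exwald_moments()`).  Small $\tau/\mu$ gives clock-like ("regular")
trains with near-Gaussian ISI densities; large $\tau/\mu$ gives irregular,
Poisson-like trains whose densities resemble right-shifted Exponentials.
The continuum between the two is one-dimensional to a good approximation,
which is what the population analysis quantifies.

Ten rival candidate families are carried alongside for model comparison
(`list_models()`): Weibull, Lognormal, Erlang, Birnbaum–Saunders
("Damage") and Wald; the same with a fixed time offset; and the Erlang and
Gaussian analogues of the Exwald (Exerlang, exGaussian).

## Evaluating the Exwald density

With $a = \lambda/(2\mu^2) - 1/\tau$ and $b = \sqrt{\lambda/(2t)}$ the
density has two closed-form branches (`dexwald()`), derived here from the
Wald-CDF representation of the convolution integral:

$$f(t) = \frac{e^{-\lambda(t-\mu)^2/(2\mu^2 t)}}{2\tau}
  \left[\operatorname{erfcx}(b-c) + \operatorname{erfcx}(b+c)\right],
  \qquad a \ge 0,\; c = \sqrt{at},$$

$$f(t) = \frac{e^{-\lambda(t-\mu)^2/(2\mu^2 t)}}{\tau}
  \,\mathrm{Re}\,w\!\left(-\sqrt{-at} + ib\right), \qquad a < 0,$$

where $w$ is the Faddeeva function.  Published renderings of this density
are frequently garbled (mismatched scale factors, undefined symbols), so
the package treats a numerical convolution oracle
(`convolve_with_exp()`, adaptive quadrature at relative tolerance
$10^{-9}$) as authoritative: the test suite requires every closed form to
track the oracle to a relative error below $10^{-4}$ on wide log grids,
and in practice agreement is near machine precision.

Numerical choices:

* Both branches share the Wald-like Gaussian exponent, so neither can
  overflow; the bracketed factors are bounded.  All densities are computed
  in log space and return exactly 0 outside their support.
* $w(z)$ is evaluated with Weideman's 64-term rational expansion, accurate
  to $\sim 10^{-15}$ on the upper half plane; $\operatorname{erfcx}$ is
  obtained from $w(ix)$, avoiding the overflow of the naive
  $e^{x^2}\mathrm{erfc}(x)$ product.
* The two branches agree identically in the limit $a \to 0$; a test
  straddles the boundary at $\tau = 2\mu^2/\lambda(1 \pm 10^{-8})$ and
  requires relative jumps below $10^{-6}$.
* Two guarded approximations take over in degenerate corners that an
  unconstrained search may visit: an Exponential with fixed offset $\mu$
  when the diffusion variance is negligible
  ($\mu^3/\lambda < 10^{-6}(\mu+\tau)^2$), and the pure Wald when
  $\tau < 10^{-6}\mu$.  The thresholds trigger only where the neglected
  component contributes under $10^{-6}$ of the total variance.
* The Exerlang (`dexerlang()`) uses the regularized incomplete gamma
  function when $1/\mu > 1/\tau$; in the opposite ordering, where that
  special function would need a negative argument, the same integral is
  evaluated exactly with a 64-node Gauss–Legendre rule in log space.
  $\mu = \tau$ collapses analytically to an Erlang with shape
  $\kappa + 1$.  The exGaussian switches to an
  $\operatorname{erfcx}$ form in the Gaussian-dominated tail.

## Records and screening

Spike times live in seconds on disk (one time per line, or
`record_id,time_s` CSV); intervals and parameters are milliseconds
throughout the modeling layer.  Records are validated against their
acquisition geometry: 20-second epochs, 300 µs quantization, strictly
increasing times at least one quantum apart.

Screening (`screen_records()`) replaces visual inspection with two
automatable surrogates, applied after minimum-size (10 intervals) and
degeneracy checks:

* a **Wald–Wolfowitz runs test** on the interval sequence dichotomized
  around its sample mean (ties with the mean dropped; normal
  approximation; $\alpha = 0.05$).  Its false-positive rate on simulated
  stationary renewal records is confirmed to sit at $\alpha$ within
  binomial error, so screening a stationary population removes about 5% of
  records by construction;
* an **artifact screen** flagging any record whose longest interval
  exceeds 10 times its own 99th percentile (missed triggers produce
  implausibly long gaps).

Summary statistics (`summary_stats()`) are the sample mean, SD,
CV $= s/\bar x$ and the bias-uncorrected moment skewness
$m_3/m_2^{3/2}$; a zero-variance record reports CV 0 and undefined
skewness.

## Fitting by minimum Kullback–Leibler divergence

Representing the empirical distribution as particles at the observed
intervals $t_1,\dots,t_N$, the divergence from a model density $q$
reduces to

$$D_{KL} = -\frac{1}{N}\sum_k \log_2 q(t_k) + \log_2 N \quad\text{bits},$$

so the per-record argmin is exactly the maximum-likelihood fit while the
scale stays comparable across records of different size and entropy
(`dkl_particle()`; the histogram form `dkl_histogram()` is kept for
reporting, with Freedman–Diaconis bins, and is never used for fitting).

Optimization (`fit_model()`) is a Nelder–Mead simplex in a bounded box:

* free parameters are mapped through a sine transform, in $\log_{10}$
  space for positive scale parameters, so the simplex moves on an
  unconstrained, well-scaled surface;
* bounds: time parameters $[10^{-3}, 10^4]$ ms, Wald shapes up to
  $10^5$ ms (the population model itself places $\lambda$ near
  $10^{4.3}$ for the most regular units, so the box must contain it),
  dimensionless shapes $[10^{-2}, 10^2]$, fixed offsets $[-50, 200]$ ms;
* integer Erlang shapes cannot be moved by a simplex and are profiled: an
  exhaustive scan for the plain Erlang (whose inner scale fit is the
  closed form $\hat\mu = \bar x/\kappa$), a coarse geometric grid with
  local refinement for the three-parameter variants;
* starts: a method-of-moments point (`init_params()`; for the Exwald
  $\tau_0 = \min(s, \bar x/2)$, $\mu_0 = \bar x - \tau_0$, $\lambda_0$
  from the variance identity with a 5% variance floor), plus — for the
  convolution families — a dead-time start that reads $\mu_0$ off the 1st
  percentile and gives the Exponential the remaining mean.  The second
  start matters for irregular records, where the moment split
  misattributes nearly all variance;  five additional restarts jitter
  these starts by $e^{N(0,0.5)}$ factors, and the winner is polished by
  one simplex restart.  All restart randomness is governed by the
  recorded seed;
* the objective floors each observation's log-density at $-1000$ bits so
  the simplex can walk out of zero-density regions instead of meeting
  $+\infty$; reported divergences are unfloored;
* simplex relative tolerance $10^{-6}$, at most 5000 evaluations per
  start.

`rank_models()` compares families across a population the way the model
comparison is usually drawn: the family with the lowest mean divergence is
the baseline, and every family reports the mean and standard error of its
per-record excess $\Delta D_{KL}$ over that baseline.  On synthetic Exwald
populations the Exwald attains the lowest mean, with the exGaussian a
close second — the expected ordering, since the two differ only in the
skewness of the refractory component.

## Population analysis

`log_pca()` centers the $(\log_{10}\mu, \log_{10}\lambda, \log_{10}\tau)$
triples and eigendecomposes their covariance — no per-axis rescaling,
matching equal-decade log-log axes.  The first principal axis is oriented
so its $\log\tau$ loading is positive (an otherwise arbitrary eigenvector
sign), making increasing score mean increasing irregularity.
`convex_hull_2d()` wraps the planar hull with counterclockwise vertices
and a degeneracy flag for collinear clouds; a brute-force all-triples
membership oracle validates it in the tests.  `pc1_model_at()` exponentiates
center-plus-score back to an Exwald parameter triple, and `pc1_curve()`
solves, by bisection over the observed score range extended 20% on each
side (tolerance $10^{-12}$ on the coordinate), for the axis point whose
mean ISI, CV, or raw parameter matches a requested value — projecting the
population axis into, e.g., the mean-ISI/CV plane.  Grid values
unattainable on the segment are dropped with a warning rather than
extrapolated.

## The synthetic-data generator

No public recordings exist, so the generator is a first-class module that
emulates the acquisition and the population:

* **Records** (`generate_record()`): Exwald intervals (Wald draw via the
  Michael–Schucany–Haas transform plus an Exponential draw),
  cumulative-summed from zero, truncated at 20 s, quantized to 300 µs;
  when two spikes collide in one quantum the later one is dropped (the
  hardware cannot represent both) and the count is recorded.
* **Population** (`generate_population()`): per record,
  $\log_{10}\mu \sim N(\log_{10} 12.7, 0.05)$ — the refractory mean
  clusters tightly near 12.7 ms; $\log_{10}\tau \sim U(-1.5, 2.5)$ —
  the Poisson mean sweeps four decades, microseconds-scale to
  hundreds of milliseconds; $\log_{10}\lambda = 3.5 - 0.5\log_{10}\tau +
  N(0, 0.15)$ — a log-log line of slope $-0.5$ ($\lambda \propto
  1/\sqrt{\tau}$, equivalently $\tau \propto \lambda^{-2}$) pinned so
  $\lambda = 10^3$ ms at $\tau = 10$ ms, giving $\lambda$ about two
  decades of range.  The spreads (0.05 and 0.15 decades) are the
  package's calibration of "tightly clustered" and "mild scatter"; they
  reproduce the intended cloud geometry (verified by tests on the
  ground-truth cloud: first variance fraction above 0.85, smallest PC1
  loading on $\mu$) without attempting to match any particular dataset's
  moments.
* **Mechanism** (`simulate_mechanism()`): the physical reading of the
  model, simulated directly — after each spike a drift-diffusion
  integrator (Euler–Maruyama, step $dt = \min(\tau,\mu)/1000$ by default)
  climbs to threshold while trigger events (per-step probability
  $dt/\tau$) are censored and counted; the first trigger after the block
  is emitted.  Poisson waits are drawn as geometric step counts, which is
  exact for the discretized trigger, so the only discretization error is
  the first-passage overshoot of the Euler integrator.  That bias is not
  bridge-corrected; instead the tests require the two-sample KS statistic
  against the direct sampler to fall monotonically as $dt$ shrinks
  tenfold twice, and indistinguishability (KS $p > 0.01$) at the default
  step.  A `dt` coarser than $\min(\tau,\mu)/100$ is refused unless
  explicitly allowed for such convergence studies.
* **Kinematic modulation** (`modulate_by_input()`): one concrete
  realization of the head-motion reading of the mechanism — the trigger
  rate $1/\tau$ scales with $(1 + g\,a(t))$ (acceleration) and the
  integrator drift with $(1 + g\,{\textstyle\int}a\,dt)$ (velocity), both
  clipped at zero.  Zero input reduces exactly to the stationary
  mechanism; a constant velocity operating point leaves the output an
  Exwald train with the refractory mean rescaled.  The mapping is
  deliberately isolated so alternatives can swap in; no claim is made
  that it reproduces real rotational responses.

What the generator does **not** emulate: slow nonstationarities, serial
interval correlations, detection/triggering artifacts (beyond what the
artifact screen is designed to catch), bursting, or the strong sampling
bias toward regular units typical of real afferent surveys ($\tau$ is
swept uniformly in log to exercise the whole continuum).  Green tests
therefore demonstrate internal consistency of model, fitter and
generator — not fidelity to any particular animal's data.

## Problem sizes

The test suite and the acceptance script use: 20,000 intervals for the
Poisson-CV check; $2\times 10^5$ intervals for the decimation factor; 10
parameter draws × 50-point grids per convolution family for the oracle
comparison; 100 records of 2000 intervals for parameter recovery; a
50-record population × 6 families for model ranking; the full 300-record
default population for the end-to-end PCA; and five parameter sets (5000
intervals each) plus a three-step $dt$ sweep for mechanism equivalence.

## Known limitations

* **The Wald shape is degenerate under maximum likelihood on short
  irregular records.**  For records dominated by the Exponential
  component (roughly $\tau \gtrsim 30$ ms, i.e. only 60–300 intervals in
  a 20-s epoch), the profile divergence *decreases monotonically in
  $\lambda$ without bound*: the likelihood is always improved by making
  the refractory edge sharper and sliding it toward the sample minimum, a
  classic threshold-estimation degeneracy that interval quantization
  aggravates.  A simplex started at the generating parameters slides to
  the $\lambda$ bound, gaining only $\sim 0.003$ bits per decade.  The
  consequence is visible in the end-to-end recovery study: fitted
  $\log_{10}\lambda$ carries $\sim 0.75$ decades of noise in the
  irregular regime (versus $\sim 0.04$ for regular records), which drags
  the fitted cloud's first variance fraction to $\sim$0.74 and tilts the
  fitted principal-axis slope to $\sim -0.44$, even though the
  ground-truth cloud yields $0.99$ and $-0.50$.  This is an
  identifiability limit of exact maximum likelihood at these record
  lengths, not an optimizer deficiency; an optimizer with loose absolute
  tolerances and a single start would mask it by stalling near its
  initialization, at the price of answers that depend on the
  initialization.  Population-level conclusions about $\lambda$ from
  20-second epochs of irregular units should be treated with caution, or
  drawn from longer records.
* CV and skewness of the most regular records are limited by the 300 µs
  quantization (interval SDs approach the quantum).
* The runs-test screen removes more than $\alpha$ of genuinely stationary
  records once interval SDs approach the acquisition quantum: quantizing
  spike times makes consecutive intervals share a quantization error, a
  real MA(1) anti-correlation that the test detects (about a quarter of
  the most regular synthetic records are excluded, versus $\approx\alpha$
  of irregular ones).  Exclusion counts are therefore not comparable to a
  visual screen's.
* The Erlang family is parameterized so the printed density has mean
  $\kappa\mu$; descriptions that quote a mean waiting time of $\mu$ for
  the same formula refer to the per-stage mean.  The fitted $\kappa$ is
  capped at 200, which is reached only for records more regular than the
  quantization can resolve.
* Likelihoods treat quantized times as exact, so sub-quantum structure in
  $\tau$ (the bottom half-decade of the population sweep) is recovered
  only through the location shift it induces.
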