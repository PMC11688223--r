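# exwald

Renewal-process modeling of spontaneous spike trains from vestibular
semicircular-canal afferent neurons.

Spontaneous interspike intervals (ISIs) of these neurons range from
clock-like regular firing to Poisson-like irregular firing along a single
continuum. This package implements the generative account of that
continuum: each interval is the sum of a **Wald (inverse Gaussian)**
first-passage time — a stochastic refractory period produced by an
integrate-and-fire mechanism with drift 1/μ and diffusion variance 1/λ —
and an **Exponential** wait with mean τ from a high-rate Poisson trigger
process. The resulting ISI density is the **Exwald** distribution (the
convolution of the two), with mean μ + τ, variance μ³/λ + τ², and

```
f(t) = exp(-λ(t-μ)²/(2μ²t)) / (2τ) · [erfcx(b-c) + erfcx(b+c)],   a ≥ 0
f(t) = exp(-λ(t-μ)²/(2μ²t)) / τ  · Re w(-√(-at) + ib),            a < 0
```

where `a = λ/(2μ²) - 1/τ`, `b = √(λ/2t)`, `c = √(at)` and `w` is the
Faddeeva function. Equivalently the spike train is a left-censored Poisson
process: a trigger process with mean interval τ, decimated by refractory
blocking times of mean μ (decimation factor (μ+τ)/τ ≈ 101 for τ = 0.1 ms,
μ = 10 ms).

The package covers the full analysis pipeline:

* **Densities** — `dexwald()`, `dwald()`, `dexerlang()`, `dexgauss()`,
  `ddamage()`, `derlang()` and fixed-offset variants (eleven candidate
  families via `model_spec()`/`model_logdensity()`), all validated against
  an independent quadrature convolution oracle (`convolve_with_exp()`).
* **Records** — reading/writing spike-time files (seconds; 20-s epochs at
  300 µs resolution), ISI extraction, summary statistics, and screening by
  a Wald–Wolfowitz runs test plus an artifact screen
  (`load_record()`, `summary_stats()`, `screen_records()`).
* **Fitting** — minimum Kullback–Leibler divergence (≡ per-record maximum
  likelihood, in bits with a log₂N offset) by bounded Nelder–Mead with
  multi-start and integer-shape profiling; candidate ranking across a
  population (`fit_model()`, `fit_records()`, `rank_models()`).
* **Population analysis** — PCA of fitted (μ, λ, τ) in log₁₀ space,
  convex hulls of the planar projections, and prediction curves along the
  first principal axis (`log_pca()`, `convex_hull_2d()`, `pc1_curve()`).
* **Synthetic data** — direct Exwald sampling, acquisition-realistic
  record generation, whole populations with the observed cloud structure
  (μ clustered at 12.7 ms, τ spanning 4 decades, λ following a slope −0.5
  log-log line against τ), and an Euler–Maruyama simulation of the
  physical mechanism itself (`generate_population()`,
  `simulate_mechanism()`, `decimation_factor()`).

## Worked example

Generate one synthetic 20-second record, screen it, fit the Exwald model,
and read off the implied moments:

```r
library(exwald)

rec <- generate_record(mu = 12.7, lambda = 1000, tau = 10, seed = 7,
                       record_id = "demo")
rec
#> <spike_train_record> demo: 884 spikes over 20 s (quantum 300 us)

isi <- intervals_from_spikes(rec)
st <- summary_stats(isi)
sprintf("mean %.2f ms, CV %.3f, skewness %.2f", st$mean, st$cv, st$skewness)
#> [1] "mean 22.62 ms, CV 0.450, skewness 1.73"

runs_test(isi)$runs_p   # stationarity screen: large p = no serial trend
#> [1] 0.5100042

fit <- fit_model(isi, "exwald", seed = 42)
fit
#> <isi_fit> demo ~ exwald: D_KL = 14.7391 bits
#>       mu      lam      tau
#>   12.280 1330.200   10.336

exwald_moments(fit$params[["mu"]], fit$params[["lam"]], fit$params[["tau"]])
#>     mean variance       cv
#>   22.616  108.230    0.460
```

The fitted refractory mean (12.3 ms), shape (1330 ms) and Poisson mean
(10.3 ms) recover the generating values (12.7, 1000, 10) from a single
record; the divergence of 14.74 bits is the information lost per interval
when this three-parameter model stands in for the 884-interval empirical
distribution (of which log₂ N ≈ 9.8 bits is the particle-representation
offset shared by all candidates on this record).

Population-level use is the same pattern over many records:
`generate_population()` → `screen_records()` → `fit_records()` →
`rank_models()` / `log_pca()` → `pc1_curve()`.

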