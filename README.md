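# fedgamlss

Exact distributed fitting of GAMLSS reference charts across sites that
cannot share subject-level data.

## The problem

Population reference charts — centile curves of an outcome against age,
stratified by sex — are built with Generalized Additive Models for
Location, Scale, and Shape (GAMLSS). A GAMLSS family has up to four
parameters (location μ, scale σ, skewness ν, kurtosis τ), each with its own
additive predictor and monotone link:

    g_k(θ_k) = η_k = X_k β_k + Z_k γ_k,   k = 1, …, p

where `X_k` holds fixed-effect terms and `Z_k` an optional penalized
B-spline smooth. Accurate extreme centiles need large multi-site samples,
but privacy rules often forbid pooling the rows.

The key observation: the Rigby–Stasinopoulos (RS) fitting algorithm updates
one parameter at a time by weighted least squares on the adjusted dependent
vector `z_k = η_k + W_k⁻¹ u_k`, and the normal equations

    (Σᵢ XᵢᵀWᵢXᵢ + λP̃) b = Σᵢ XᵢᵀWᵢzᵢ

decompose into per-site cross-products `M_{i1} = XᵢᵀWᵢXᵢ` (q×q) and
`M_{i2} = XᵢᵀWᵢzᵢ` (q×1). If every site sends only these aggregates, the
central solve is *exactly* the pooled solve — one communication round per
inner-cycle Newton–Raphson iteration, no subject-level data transferred.
This package implements that protocol end to end: distribution families
(normal, Box–Cox power exponential, zero-inflated beta, generalized gamma),
penalized B-spline smooths in three regimes (fixed-effect, fixed-penalty,
automated BIC/GAIC/GCV selection over a broadcast λ grid), distributed Wald
and likelihood-ratio inference from summed site Hessians, centile chart
generation, and a seeded multi-site synthetic data generator. Federation is
simulated in process with a strict message contract; raw rows never cross
the site/aggregator boundary.

Intended users: biostatisticians building normative charts (growth curves,
brain charts, clinical reference ranges) over consortia or distributed
research networks.

## Worked example

Nine sites with a BMI-like outcome (Box–Cox power exponential, hump-shaped
location over age), fitted with fixed-effect age smooths (knot counts
6/5/2/2) plus a sex effect on every parameter:

```r
library(fedgamlss)

scn   <- scenario("bmi_like", n_total = 2000, seed = 7)
sites <- generate_sites(scn)          # list of site_data objects
spec  <- scenario_spec(scn)           # BCPE; mu ~ bs(age,6)+sex; ...
fit   <- fit_distributed(sites, spec)
fit
#> GAMLSS distributed fit, family BCPE
#>   n = 2000, global deviance = 11306.952
#>   converged: TRUE (5 outer cycles, 37 inner iterations)
#>   mu: 9 coefficients, EDF 9
#>   sigma: 8 coefficients, EDF 8
#>   nu: 5 coefficients, EDF 5
#>   tau: 5 coefficients, EDF 5
#>   communication rounds: 39 (basis_setup=1, inference=1, update=37)
```

One round established the shared spline basis (global age range exchange),
37 update rounds carried the `M_{i1}, M_{i2}` aggregates (one per
Newton–Raphson iteration), and one round returned site Hessians and
deviances for inference:

```r
head(fit$inference$table, 4)
#>   parameter     term estimate    se    t         p
#> 1        mu bs(age)1     22.9 1.459 15.7  1.84e-55
#> 2        mu bs(age)2     23.6 1.000 23.6 3.88e-123
#> 3        mu bs(age)3     26.7 0.676 39.5  0.00e+00
#> 4        mu bs(age)4     29.2 0.546 53.5  0.00e+00

reference_chart(fit, list(age = c(30, 50, 70), sex = "F"),
                centiles = c(2.5, 50, 97.5))
#>   age sex  c2.5   c50 c97.5
#> 1  30   F 19.98 25.33 34.08
#> 2  50   F 21.81 28.53 40.14
#> 3  70   F 20.57 27.24 37.37

predict_quantile(fit, data.frame(age = 40, sex = "M"), 31)
#> [1] 0.7247
```

The centile table reads: at age 50 the central 95% of females span BMI
21.8–40.1 with median 28.5; the chart's upper tail widens in mid-life
because σ and ν are themselves modeled over age. The last call flags an
observed BMI of 31 at the 72nd centile of its predicted distribution.

`fit_pooled()` runs the identical RS algorithm on the concatenated rows and
is the oracle the distributed fit is tested against: coefficient
trajectories agree iteration by iteration to ~1e-12.

A thin command-line wrapper is provided in `exec/fedgamlss`
(`simulate-data` and `run` subcommands over a JSON configuration).

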