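---
title: "Methods: garbage-code redistribution, mixed-model rate ratios, and the synthetic study design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: garbage-code redistribution, mixed-model rate ratios, and the synthetic study design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its statistical machinery:
the models and procedures, the tunable parameters and their defaults, what
the synthetic data generator does and does not emulate, and the numerical
choices that a maintainer or reviewer would want spelled out. It states no
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## The scientific problem

Motorcyclist deaths are identified in vital-registration data by ICD-10
codes V20–V39. Two data-quality problems stand between raw records and
valid city-level mortality rates:

* **Garbage coding.** A share of external-cause deaths carries codes too
  unspecific to assign a road-user group (partially defined road traffic:
  V87–V89, V99) or even a mechanism (ill-defined external: X59, Y10–Y34).
  Ignoring them understates cause-specific rates; worse, coding quality
  varies across places, so the understatement is differential.
* **Incomplete registration.** Not all deaths are registered; demographic
  completeness estimates yield year- and city-specific correction factors
  applied to the population denominator.

The package's pipeline mirrors the standard epidemiological treatment:
stochastic redistribution of garbage codes (multiple draws, like multiple
imputation), completeness-corrected person-years, direct age
standardization, a count regression with a city random intercept, and
Rubin's rule to combine estimates across redistribution draws.

## Redistribution

Redistribution probabilities are estimated within (country, sex, 5-year
age group, 3-year period) strata — country-specific because the garbage
fraction and the road-user mix differ strongly by country. Two stages:

1. Ill-defined external deaths in a stratum are split binomially between
   road traffic and other external causes using the stratum's observed
   composition of *specifically* coded external deaths (`p_rt`). A config
   flag (`two_stage = FALSE`) instead keeps all ill-defined deaths in road
   traffic, for comparison with analyses that make that assumption.
2. The partially defined road-traffic pool (original plus stage-1
   arrivals) is allocated multinomially across the five road-user groups
   with probabilities proportional to observed specific counts.

Pooling periods are calendar blocks 2010–12, 2013–15, 2016–18, with 2019
merged into the last full block; the block length is a parameter
(`pooling_years`, default 3). Strata with zero specific road-traffic
deaths fall back along the ladder (country, sex, age, period) to (country,
sex, age), (country, sex), (country), then the full margin; the rung used
is recorded per stratum. The ladder never drops deaths; a stratum with
garbage deaths but no probability vector anywhere is a hard error because
conservation would silently break.

Each of the `M` draws (default 100; scaled-down studies in the test suite
use M = 20 or fewer, as noted below) is sampled on its own RNG substream,
derived from the master seed and the draw index by a deterministic integer
hash, with strata processed in a fixed canonical order. Draw *d* is
therefore reproducible in isolation — `redistribute_deaths(..., M = 3)`
and `M = 100` agree on draw 3. We chose draw-level rather than
per-(draw, stratum) substreams: it delivers the reproducibility property
that matters while keeping the sampling vectorized (per-stratum stream
re-seeding over ~10^5 strata × 100 draws costs more than the sampling
itself in R).

## Person-years, rates, standardization

Person-years per (city, sex, age group) are the sum over calendar years of
the population count times that city-year's correction factor. Rates are
1e5 × deaths / person-years. City rates are directly standardized with the
WHO 2000–2025 world standard population; the packaged weights collapse
80–84 and older groups into 80+ to match the 17-group age scheme, and are
renormalized to sum to 1 (the 0–4 weight is 0.0886 after normalization).
Alternative standards can be passed as a two-column tibble or edited in
the YAML copy shipped under `extdata/` and loaded with
`read_standard_population()`. Quantiles
(medians, IQRs) use the type-7 linear-interpolation rule throughout.

Per-draw city rates are averaged across draws before summarization. Since
denominators are draw-invariant, averaging rates equals computing rates
from draw-averaged counts; the test suite asserts this identity.

## The negative binomial mixed model

Stratum counts (city × sex × age group, pooled 2010–2019) are modelled as
NB2 — variance mu + alpha·mu² — with log person-years offset, fixed
effects for country, sex, age group and standardized exposures, and a
Gaussian city random intercept. Reference levels are the first country
alphabetically, female, and the youngest age group; since only exposure
rate ratios are reported, this choice is inert. Exposures are z-scored
(sample SD, n−1) over the analysis city set once — not per draw — except
the binary transit indicator. Note that `alpha` in the *generator* acts at
the city-year level; counts pooled over the 10 study years have roughly
alpha/10 effective dispersion, which is what the model fitted to pooled
strata estimates.

The marginal likelihood integrates each city's NB2 likelihood over the
random intercept by adaptive Gauss–Hermite quadrature: the integrand's
mode is found by a safeguarded 1-D Newton search (the log-integrand is
strictly concave), the quadrature is centered and scaled there, and 15
nodes are used by default. Plain (non-adaptive) quadrature is inaccurate
for large city totals because the integrand becomes extremely narrow. With
sigma = 0 the code path collapses exactly to the sum of NB2 log-pmfs. The
implementation is in C++ (Rcpp) and is verified in the test suite against
brute-force trapezoid integration on a 2001-point grid (relative error
below 1e-6) and against independent implementations (MASS::glm.nb at
sigma = 0 to 1e-5; glmmTMB's Laplace fit on a clean fixture).

**Optimization.** The objective is maximized over (beta, log alpha,
log sigma). Cold fits start from a fixed-effects NB fit (MASS::glm.nb,
with a Poisson + moment-estimator fallback), run L-BFGS-B, then refine by
damped Newton steps on the analytic observed information; warm-started
fits (draws 2..M share a design matrix and change only the outcome) go
straight to Newton with an L-BFGS-B fallback. There is no randomness
anywhere in the optimization. Bounds keep log alpha in [log 1e-8, log 100]
and log sigma in [log 1e-6, log 5].

**Gradients, Hessian, scores.** The gradient, Hessian and per-city score
vectors are computed analytically with the adaptive quadrature points
*frozen* at the current centering. Because the centering is a stationary
point of the integrand, the omitted adaptation terms cancel to the same
order as the quadrature error itself; the practical consequence is that
the terminal gradient norm cannot be driven below the adaptation error.
Newton iterations stop at a relative gradient norm of 1e-7; a fit is
declared converged when the scaled gradient norm is below 1e-3 (achieved
terminal values are typically far smaller). On failure the optimizer
restarts once from a deterministically perturbed point and reports
diagnostics (gradient norm, iteration count, restart flag) rather than a
silent estimate.

**Variances.** The model-based variance is the inverse observed
information. The cluster-robust variance is the sandwich A⁻¹BA⁻¹ on the
marginal likelihood, with A the observed information, B the sum of
per-city score outer products, and the finite-cluster correction g/(g−1).
The robust variance is the default for reported CIs; a flag switches to
model-based. Strata with zero person-years are dropped with a message and
listed on the fit object.

## Pooling across draws

Per draw, the exposure log rate ratio and its (robust) variance are
extracted; Rubin's rule pools them: Qbar = mean estimate, W = mean
within-draw variance, B = between-draw sample variance,
T = W + (1 + 1/M)B, df = (M−1)(1 + W/((1+1/M)B))² (infinite when B = 0).
We use the classic Rubin df rather than the Barnard–Rubin small-sample
version: at M = 100 the difference is negligible, and the classic form is
what the pooled-variance identity tests verify. CIs are built on the
log-RR scale with the t quantile and exponentiated. If fewer than 90% of
draws converge the run fails loudly; otherwise pooling proceeds over
converged draws with the count reported — a quorum chosen so one
pathological draw cannot kill a 100-fit run while silent exclusion remains
impossible.

Model 1 fits one exposure at a time (adjusted for country, sex, age);
Model 2 includes all 11 exposures, with collinearity diagnostics attached
(condition number, VIFs) because patch density and intersection density
are strongly correlated by design. The registration subanalysis restricts
to cities with motorcycle registration data, restandardizes all exposures
on that subset, and reruns both model forms with the motorization rate
added; it refuses below 10 cities. The sensitivity analysis reruns Model 2
with subsets of the four street-layout variables, keeping all non-street
exposures. The city random intercept is retained in every fit, including
single-exposure Model 1 fits for countries with few cities — uniformity
was preferred over per-country special-casing.

## Descriptive surfaces

* **Quartile table.** Cities are split into quartiles of the standardized
  rate by rank, sizes differing by at most one with the remainder in the
  top quartile (337 cities → 84/84/84/85); ties break by order of
  appearance, making membership invariant under strictly monotone
  transforms of the ranking variable. The "Wald P value" is
  operationalized as follows (the test is named but not specified in the
  literature this mirrors, so the choice is documented prominently): the
  exposure is rank-based inverse-normal transformed (Blom), regressed on
  quartile indicators, and the three quartile coefficients are jointly
  tested with an HC1 heteroskedasticity-robust Wald chi-square. Binary
  exposures skip the transform. Alternatives (ANOVA F, trend tests) exist;
  the robust joint test matches the notion of "differences between
  quartiles" without assuming equal variances.
* **Correlations.** Pairwise-complete Pearson correlations, banded at 0.3
  and 0.6 into weak/moderate/strong; zero-variance columns are reported as
  absent, not zero.
* **ICC.** One-way random-effects ANOVA ICC of city standardized rates:
  between-country variance share, components from mean squares with the
  unbalanced-design n0, negative components truncated at zero. Computed on
  log rates by default (variance stabilization; rates span more than an
  order of magnitude), with a flag for the natural scale. Note this
  estimand is the *between-country* share: under country heterogeneity
  mirroring published country medians it is large (~0.7); a model-based
  residual ICC after country adjustment is a different, much smaller
  quantity.
* **Rate profiles.** City-level rate quartiles by sex and age group, peak
  age-group detection with ties reported as sets, and the male/female
  ratio of median standardized rates.

## The synthetic data generator

The generator's role is to produce complete study inputs with *known,
recoverable* ground truth. Defaults define the study conditions: 337
cities in 7 countries (33/152/21/35/1/92/3), years 2010–2019, 17 age
groups, male baseline motorcyclist mortality piecewise-constant in age
with its peak at 20–24 (17 per 100,000 per year) and a male/female ratio
of 8 (within the 7–10 range typical of the literature), country fixed
log-offsets spanning low- to high-mortality countries, city random
intercept SD 0.3, NB2 dispersion alpha 0.5 at the city-year level, and
planted exposure effects (per SD): mean nearest-neighbor distance 1.07,
circuity 0.97, intersection density 0.91, population density 0.92, transit
0.94, social environment index 0.88, motorization rate 1.20.

**Exposures** are drawn from a Gaussian copula with lognormal/normal
marginals whose medians and spreads resemble published city-level
descriptive tables; the transit indicator is Bernoulli(0.16). Target
Pearson correlations are configured pairwise (defaults: patch density ×
intersection density 0.7, GDP × social index 0.45, street length × street
node average 0.3); for lognormal pairs the latent correlation is adjusted
in closed form so the *observed-scale* Pearson correlation hits the
target. A non-positive-semi-definite target matrix is rejected with the
offending variables named. Because the marginals are a design choice, the
generator's quartile descriptive tables are not expected to match any
published Table's absolute values — only structural behavior (quartile
sizes, correlation bands, separation tests) is comparable.

**Deaths.** Motorcyclist counts are NB2 draws around
mu = PY × baseline(age, sex) × exp(country + x'beta + b_city) at the
city-year-sex-age level. The other external-cause classes (pedestrian,
bicyclist, car occupant, other road traffic, non-road-traffic external)
are Poisson with class multipliers (1.0, 0.15, 0.8, 0.4, 3.0) on the same
city-level log-linear surface. Sharing the exposure effects and the city
intercept across classes is deliberate: it makes the cause composition
homogeneous within country-sex-age strata, which is exactly the condition
under which stratified redistribution is mean-preserving — so the planted
coefficients are a clean target for validating the machinery. In real
data, composition varies across cities within strata, and redistribution
smooths that variation toward the country stratum mean; with effects
planted on motorcyclist deaths only, this attenuates recovered city-level
coefficients by roughly the garbage fraction (~10%). Passing recovery
tests therefore validates the pipeline's correctness, not the absence of
this smoothing effect in real data — a known limitation of the method
itself, not of the implementation.

**Garbage coding.** Ill-defined coding (mechanism lost) hits every
external-cause class with equal propensity — the uniformity that makes the
stage-1 composition estimator unbiased — while partially defined
road-traffic codes can only arise from road-traffic deaths (a drowning
cannot receive a V code). With the default 50/50 split
(`garbage_split_partial`), a road-traffic death is garbage-coded with
probability `p_illdefined` (default 0.11) and a non-road-traffic external
death with half that, so the realized overall garbage share is ~8–9% at
the default. An optional `garbage_social_gradient` makes coding propensity
worsen with the social environment index, emulating differential data
quality; the test suite uses it to demonstrate that redistribution has
smaller exposure-coefficient bias than complete-case (garbage-dropped)
analysis precisely when coding is differential (under uniform coding,
dropping garbage is a pure thinning the model intercept absorbs).

**Registration.** Per-city completeness is drawn uniformly from
[0.8, 1] by default. Deaths are thinned binomially at completeness c; the
emitted population carries the same shortfall (registration-anchored
projections share the undercount), and the correction-factor file stores
1/c, so corrected person-years equal the true person-years exactly while
observed counts remain thinned. The thinning term log(c) is a city-level
shift independent of the exposures, absorbed by the random intercept;
exposure rate ratios remain recoverable. Motorcycle registrations are
present only for the four countries mirroring the 300-of-337 subset, but
the motorization effect acts in every city (the variable exists even where
unobserved).

Everything is generated under a single master seed with derived
substreams; identical configs and seeds give byte-identical output files.

## Problem sizes used in validation

The test suite scales simulation studies to keep the default run practical
while preserving each check's statistical meaning: coefficient recovery
uses 100 replicates of 300 cities with M = 20 redistribution draws
(planted RR 0.88/SD, sigma 0.3, alpha 0.5, p_illdefined 0.11); the type-I
error check uses 200 replicates of 100 cities with M = 5 and a null
exposure; the redistribution-vs-complete-case comparison uses 15
replicates of 63 cities with M = 3 under differential coding; determinism
is verified by running the full pipeline twice at 42 cities with M = 20
and comparing result files byte for byte. The acceptance script runs the
full default scenario: 337 cities, M = 100, all model families.

## Known limitations

* Redistribution smooths within-country variation in cause composition
  (see above); city-level effect estimates inherit a small conservative
  bias in real data with composition heterogeneity.
* The generator does not simulate spatial structure, individual risk
  factors (helmets, alcohol), time-varying exposures, or non-external
  garbage codes (R chapter); redistribution of R codes is out of scope.
* The NB mixed model has a single random intercept — no random slopes,
  zero-inflation, or spatial correlation.
* Correction factors are taken as given (the generator produces them from
  a known completeness process); estimating completeness from death
  distribution methods is out of scope.
* The frozen-adaptive analytic derivatives bound the achievable terminal
  gradient norm; see the optimization section.
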