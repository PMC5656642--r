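---
title: "Methods: car-mediated tiger-mosquito flux estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: car-mediated tiger-mosquito flux estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of its models, the numerical
choices behind them, and what the test suite does and does not establish.

## 1. The transport-probability model

Each sampled car is treated as a Bernoulli trial with success probability
θ, the probability that the car carries at least one adult tiger mosquito.
Two logistic regressions are supported:

* **naive**: `logit(θ) = α` (intercept only);
* **covariate**: `logit(θᵢ) = α + β·xᵢ`, where `xᵢ ∈ [0, 1]` is the
  bi-weekly alert probability of the origin municipality — the posterior
  probability, from an upstream citizen-science model, of receiving a
  reliable tiger-mosquito report from that area, used as a proxy for
  relative mosquito prevalence.

Detections are rare (order 0.5%), where maximum likelihood is biased and
fragile. Coefficients therefore get independent Cauchy priors on the logit
scale, location 0 and scale 2.5 — the standard weakly informative choice
for sparse logistic regression. Scales are applied literally by default;
`logistic_prior(autoscale = TRUE)` divides covariate scales by the
predictor standard deviation for users who want the alternative
convention. An informative-prior variant (intercept location 0.013,
slope location 1) is supported for robustness checking; the intercept
location is interpreted on the logit scale exactly as stated, because the
alternative (probability-scale) reading is available by passing
`qlogis(0.013)`. By quadrature, the informative intercept prior moves the
naive θ median by well under 10% relative — the estimate is data-dominated
even with 4 events.

### Sampler

No Hamiltonian Monte Carlo backend is assumed. `fit_bayes_logistic()` uses
adaptive random-walk Metropolis: Robbins–Monro tuning of the global step
size toward 35% acceptance and Haario-style covariance adaptation from the
warm-up history, both frozen after warm-up. Five percent of proposals are
independence draws from the Cauchy prior. That component matters in two
regimes a plain random walk handles poorly: prior-dominated posteriors
(few or no observations), where the heavy Cauchy tails are otherwise
explored too slowly, and tail quantiles generally. For a prior-only target
the independence proposals are always accepted, so sampling is exact.

Defaults are 4 chains × 2000 retained draws after 1000 warm-up iterations,
all seeded; quantiles are linear-interpolation (type 7) on the pooled
draws. Convergence is reported per coefficient as split-R̂ and an
autocorrelation-based effective sample size (Geyer initial monotone
sequence); R̂ ≥ 1.01 or ESS ≤ 400 attaches and emits a warning rather than
failing, since downstream code may legitimately run short exploratory
chains.

### The quadrature oracle

For intercept-only models the posterior is one-dimensional, and
`quadrature_posterior()` integrates it deterministically. The grid is
placed at prior quantiles (equal prior-mass cells), i.e. the integral is
computed in `u = F_prior(α)` space. This is what makes the Cauchy tails
tractable: a uniform α-grid wide enough to hold 99.999% of a Cauchy simply
does not exist at useful resolution, while the u-grid covers all but
`2 × 1e-7` of the prior mass by construction. The mass-coverage
contract (≥ 99.999% of *posterior* mass) is enforced with an analytic
bound: outside the grid the likelihood is bounded by its value at the grid
edge, or by its supremum if the mode lies outside (s = 0 or s = n push the
mode to ±∞ where the likelihood tends to its supremum). Doubling the grid
resolution moves the reported quantiles by < 1e-6, which the tests assert.

The MCMC path is validated against this oracle at several (successes,
trials) configurations, with tolerances of three Monte Carlo standard
errors computed from the oracle's local quantile density and the fit's
measured ESS — not from fixed constants, because the θ-scale posterior for
extreme cases (e.g. 0 successes) spans tens of orders of magnitude.

### Maximum likelihood and PSIS-LOO

`fit_ml_logistic()` is iteratively reweighted least squares written
in-package (deliberately not delegating to `glm`, so the Bayesian/ML
consistency checks compare genuinely independent code paths), with Wald
standard errors and separation detection (diverging coefficients or
vanishing curvature → `converged = FALSE` plus a warning, never a crash).

`psis_loo()` implements Pareto-smoothed importance sampling from scratch:
per observation, the largest 20% of importance ratios `1/p(yᵢ|θₗ)` are
replaced by expected order statistics of a generalized Pareto distribution
fitted by the Zhang–Stephens profile-likelihood method with the standard
weak prior pulling the shape toward 0.5. Shape estimates k > 0.7 trigger a
warning. The identity LOOIC = −2·ELPD holds exactly by construction, and
the estimator is tested against exact leave-one-out computed by
deterministic quadrature refits at n = 20.

## 2. Sampling-efficiency adjustment

The recapture experiment releases mosquitoes into a test car under three
conditions — vacuuming after 5 minutes (T5, N = 18), after 10 minutes
(T10, N = 14), and after 10 minutes with air conditioning (T10AC, N = 16)
— with outcomes captured / escaped / lost. `recapture_summary()` reports
the three rates overall and per condition; "lost" individuals are folded
into escapes only on request, keeping the three printed categories by
default.

`adjust_for_efficiency()` divides each posterior draw of θ by the point
recapture rate r and caps at 1. The cap is the only non-linearity; below
it, adjustment commutes exactly with quantile computation, which the tests
verify. Propagating the binomial uncertainty of r itself (dividing each
draw by an independent Beta(captured + 1, missed + 1) draw) is available
via `method = "beta"` but off by default, matching the deterministic
rescaling convention of the headline estimates.

Treatment-effect regressions (`fit_treatment_effects()`) run both the
Bayesian and the ML route on designs derived from the condition factor
(three-level factor, elapsed time, AC indicator, or both). One calibration
subtlety: under a null world with identical capture probability across
conditions, each treatment coefficient's posterior sign probability lands
in (0.05, 0.95) about 90% of the time — but the *joint* event for two
coefficients necessarily happens only ≈ 0.9² ≈ 81–85% of the time. The
test suite therefore checks calibration per coefficient, the statistically
meaningful statement (measured: 91 of 100 coefficient-replicates in band).

## 3. Prevalence downscaling

Cell-level posterior draws live on a grid of 0.05° cells × 26 bi-weekly
periods. The bi-week grid is anchored at day-of-year 1, with period 26
absorbing days 351–366 (the anchor is a convention; nothing upstream pins
it). Municipal prevalence samples are drawn by first picking an
overlapping cell with probability equal to its area weight, then drawing
uniformly from that cell's stored draws — with replacement, 1000 samples
per municipality-period by default (the resampling scheme is specified;
the sample size is our choice and only controls Monte Carlo resolution).
The construction is equivalent to evaluating the alert probability at
spatially random points in the municipality, so municipal values can never
leave the convex hull of the contributing cells' supports — a property the
tests check, along with exact recovery of mixture weights and
distributions.

The confirmation mask zeroes the prevalence samples of municipalities
without officially confirmed presence *and* all their downstream outgoing
flux. Zeroing only the covariate would leave `inv_logit(α) > 0` flowing
out of unconfirmed areas through the intercept; the flux-level zero is
what the headline aggregates assume, so the masked-municipality set
travels with the prevalence object into the transport field and the flux
computation drops those origins entirely.

## 4. The flux model

Province-level commuter counts F_AB are downscaled to municipality pairs
by population shares, F_ij = F_AB · (pop_i/pop_A) · (pop_j/pop_B), which
conserves every province-pair total exactly. Intra-province and
same-municipality flows are not modelled (the commuter source records
inter-province movement only).

For each origin municipality i and day k, L transport-probability samples
P_ikl are built by pairing an independently drawn coefficient draw with an
independently drawn prevalence draw for the day's bi-week, and flux is
M_ijkl = (F_ij + F_ji) · P_ikl — the bidirectional commuter volume times
the origin's transport probability. L defaults to 400. Draws are
independent across municipality-days and aligned only by the sample index
l during aggregation, matching the "sums of independent random variables"
interpretation; `shared_coef = TRUE` switches to common coefficient draws
(inducing cross-unit correlation) for sensitivity analysis. Aggregations —
province pairs, gross out/in flows, net flow, months (non-leap calendar),
and the season window ("year", default March–December, days 60–365) — sum
per sample index, and quantiles are computed last. Mass conservation at
every level, the zero-sum property of net flows, and equality with a
brute-force nested-loop oracle on a two-province toy are all asserted
exactly in the tests.

`trips_with_mosquitoes()` multiplies a daily trip count by the interval
endpoints rounded to 4 decimals first (the printed precision of the
source quantiles), because that is the arithmetic behind the published
trip ranges; `decimals = Inf` disables the rounding. The published
efficiency-adjusted trip range is inconsistent with the published adjusted
quantiles (it evidently used unrounded values), so that particular pair of
numbers is not a reproduction target.

## 5. The synthetic world

The generator's defaults encode the study's stated conditions: 770 car
stops with baseline detection intercept `logit(4/770)`; recapture trials
of size 18/14/16 with capture probabilities 0.60/0.70/0.78 (rising with
waiting time and AC, averaging 0.689 ≈ 33/48, the non-captured mass split
40/60 between observed escapes and losses to match the printed 6:9
margin); 26 bi-weekly periods with a raised-cosine seasonal prevalence
curve peaking at period 17 (late summer) and cell amplitudes uniform on
(0.02, 0.30); 3 provinces × 30 municipalities × 50 cells — large enough
that most municipalities are covered by several cells (Poisson(5)+1,
Dirichlet weights), small enough for fast tests; log-normal municipal
populations (median ≈ 8000, a typical municipality); car origins drawn
proportional to population (the simplest defensible traffic proxy); and
gravity-like commuter counts, Poisson with intensity proportional to the
product of province population shares scaled so `od_scale` is roughly the
total inter-province commuter volume. The default covariate slope is 2.85,
the midpoint of the credible interval reported for the real-data effect.
The last province is generated entirely unconfirmed so the zero-outflow
guarantee is always exercised.

What a green test establishes — and does not. The synthetic world has
exactly the dependence structure the model assumes: Bernoulli detections
conditionally independent given origin prevalence, stationary commuting,
no vacation mobility, no diel-activity modulation, no spatial correlation
beyond shared cells. Recovery and calibration results on it validate the
*inference machinery*, not the substantive model of real mosquito
transport.

One deliberate choice concerns the slope-sign acceptance gate. With the
generator's covariate spread during the sampling window (sd ≈ 0.04) and a
4/770 baseline rate, a slope at the reported effect size (≈ 2.85) yields a positive
posterior sign in only ~83% of replicates — an honest mirror of the real
study's 86% posterior sign mass, but not a usable pass/fail gate. The gate
world therefore uses slope 14, where sign recovery is essentially certain;
the generator default keeps the reported effect size.

## 6. Numerical conventions and degenerate inputs

* Quantiles everywhere: linear interpolation (type 7) on pooled samples.
* Quadrature: 200001 equal-prior-mass cells, 1e-7 prior mass excluded per
  side, inverse-CDF interpolation for quantiles; mass-coverage failure is
  an error, never silent.
* IRLS: weights floored at 1e-10; |coefficient| > 15 or vanishing
  curvature is treated as separation.
* Empty inputs: zero car stops produce an empty but fully typed table;
  zero-length outcomes with a prior sample the prior; empty summaries,
  recapture tables, and flow sample sets are errors.
* Rounding of reported percentages follows the printed precision of each
  source quantity (one decimal for the vehicle-report share, whole
  percents for the survey).
* All randomness flows from explicit integer seeds; per-stream seeds are
  derived multiplicatively and stay below 2³¹. Identical config + seed
  gives byte-identical pipeline output, which the tests assert.

## 7. Known limitations

* The MCMC is random-walk based; for models much larger than the two
  coefficients used here, HMC would be preferable. The contract is
  correctness (verified against quadrature), not sampling efficiency.
* PSIS-LOO is implemented for the Bernoulli-logit likelihood only.
* The flux model inherits the study's assumptions: commuting constant over
  the season, transport probability depending on origin prevalence only,
  no within-trip mortality or escape. Estimates are conservative
  lower-bound-style quantities, not full dispersal kernels.
* Cell posteriors are consumed as given; the upstream citizen-science
  model that produces them is out of scope by design.
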