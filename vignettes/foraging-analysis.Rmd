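---
title: "Bimodal central-place foraging: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bimodal central-place foraging: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpforage)
```

## The scientific problem

Chick-rearing seabirds are central-place foragers: every foraging bout
ends back at the nest. When good feeding patches close to the colony
cannot cover both chick provisioning and the adult's own energy budget,
individuals may alternate short trips (provisioning) with long trips to
distant, higher-quality patches (self-maintenance). In a glacial-fjord
system this contrast is spatial and binary: trips can stay inside the
fjord (short, near tidewater glacier fronts) or leave it for the
continental shelf (long). `cpforage` implements the full analysis chain
for such a study: GPS trip segmentation, a test for bimodality of the
foraging-range distribution, body-condition metrics, four hierarchical
Bayesian models linking foraging decisions to body condition and mass
change, and a zooplankton biomass index describing prey availability
inside the fjord. A synthetic-data generator emulates the whole study so
that every stage can be tested without field data.

## Trip segmentation

Raw GPS fixes (2–10 min cadence) are first subsampled to a standard
10-min resolution by a greedy forward pass that keeps observed positions
only. A foraging trip is a maximal run of consecutive fixes farther than
0.2 km from the colony centre lasting at least 50 minutes, measured as
elapsed time from the first to the last above-threshold fix; this makes
the rule robust to the varying raw cadence. Colony-attendance fixes are
never part of a trip. Two filters follow:

* **Land rule.** Trips with strictly more than 50 % of fixes on land are
  discarded (bathing, nest-material collection). Exactly half on land is
  retained — "more than" is read strictly.
* **Return rule.** A trip cut off by battery failure is retained only if
  the bird had covered at least 75 % of the maximum distance reached,
  i.e. its final fix lies within 25 % of the maximum range from the
  colony. The clause could also be read as cumulative path length ≥ 75 %
  of twice the maximum range; we implement that alternative behind
  `filter_incomplete(method = "path_length")` but default to the
  final-distance reading, which matches the phrase "returned towards the
  colony". Boundary cases (final fix at exactly 25 %) count as returned.

A trip is labelled *outside-fjord* when at least one fix falls strictly
outside the fjord polygon; fixes exactly on the boundary count as
inside, because remaining inside the fjord is the 0-coded default state.
Distances are haversine on a 6371.0-km sphere — trips reach hundreds of
kilometres, where planar approximations degrade. Point-in-polygon tests
are performed in raw lon/lat (even-odd rule, `sp`); this is fine for the
synthetic rectangular geometry and a documented approximation for real
high-latitude coastlines.

## Bimodality of maximum foraging ranges

The yearly unit of analysis is one value per individual: the maximum
range over all retained trips of the bird's first deployment that year
(repeat deployments would pseudo-replicate). Unimodality is tested with
Hartigans' dip statistic: the smallest sup-norm distance between the
sample ECDF and any unimodal CDF. Our implementation is exact. For every
possible placement of the mode — at an order statistic, with an upward
jump allowed (a point mass at the mode is legal in the unimodal class) —
the minimal fit error decomposes into a convex band-fit on the left, a
concave band-fit on the right, and a monotone junction condition. The
one-sided errors come from greatest-convex-minorant sweeps over the ECDF
corner points; placements interior to a gap between order statistics are
dominated by an adjacent-knot placement because convexity forces the
segment entering the mode to be at least as steep as every earlier
chord. On the rare samples where the junction constraint binds, the
value is refined by bisection on the band width. The implementation is
validated against an independent linear-programming formulation of the
same minimisation (100 frozen oracle values ship with the test suite,
agreement to 1e-9) and against closed forms: equally spaced samples give
exactly 1/(2n), two equal point masses give 1/4.

p-values are Monte-Carlo: the dip of `n_null` Uniform(0,1) samples of
the same size (the classical least-favourable unimodal null), with
p = (1 + #{D* ≥ D})/(n_null + 1). Null tables are cached per sample
size, which makes the one-trip-per-individual resampling check (999
iterations of "draw one trip per bird, recompute the p-value") cost one
table plus 999 dip evaluations. We summarise that check by the fraction
of p-values below 0.05 — the original procedure inspected the p-value
distribution visually, and a numeric stand-in is needed for automated
testing; the full vector is returned for plotting.

Mode locations use the critical bandwidth: the smallest Gaussian-kernel
bandwidth at which the KDE, evaluated on a 512-point grid over 0–200 km,
has at most k local maxima (k = 2 if the dip test rejects at α = 0.05,
else 1 — the source analysis reports one mode for non-significant years
and two otherwise without stating the linkage, so we tie k to the dip
decision). The 0–200 km window suppresses artificial modes in the far
right tail; grid-endpoint maxima and ripple in regions of negligible
density are not counted. Note that mode *location* at the critical
bandwidth is a noisy estimator: for a balanced lognormal mixture with
modes at 10 and 116 km and n = 2000, the larger mode's sampling sd is
about 6 km, because the upper component's density is flat-topped.

## Condition metrics

Body condition is the residual of an OLS regression of capture mass on
total head-bill length, pooled across years and colonies (a single fit,
matching the single reported regression with df = 76; per-year fits are
available by subsetting). Sex is molecular where available, otherwise
the 90.5-mm head-bill cutoff (female ≤ 90.5 < male). Relative body-mass
change is BMC = (Mr − Mc)/Mc. The population outside-trip proportion is
the trip-count-weighted mean of individual proportions — algebraically
the pooled outside/total trips ratio — with a percentile bootstrap CI
resampling birds (proportion and weight jointly) over 999 iterations via
the `boot` package.

## The four hierarchical models

All models carry an individual random intercept (birds tracked twice
share one intercept).

* **M1** log(maximum range) ~ year + colony, gaussian; treatment
  contrasts with the first year and colony as reference. Fitted
  separately to inside- and outside-fjord trips. Predictions are
  back-transformed by exponentiating the linear predictor, which is the
  *median* of the response on the km scale.
* **M2** trip outside the fjord (0/1) ~ year + colony, Bernoulli-logit,
  on all retained trips.
* **M3** first trip after release outside (0/1) ~ body condition + year
  + colony, Bernoulli-logit, one row per bird.
* **M4** BMC ~ outside-trip proportion + year + colony, gaussian, one
  row per bird.

M3 and M4 are written in the source analysis with an intercept *and* all
three year indicators — an over-parameterised design. We drop the
intercept column and keep the indicators (cell-means coding), which
reproduces the per-year-level interpretation of the printed
coefficients. Effects are "supported" when the central 95 % posterior
interval excludes zero.

Priors are weakly informative and auto-scaled in the convention of
mainstream Bayesian regression software: slopes N(0, 2.5·sd(y)/sd(x))
for gaussian models and N(0, 2.5/sd(x)) for logit models,
intercept-like columns N(mean(y), 2.5·sd(y)) (N(0, 2.5) for logit),
σ ~ Exponential(1/sd(y)), random-intercept sd half-normal with scale
2.5·sd(y) (2.5 for logit). The original software's exact constants are
not published; the mimic is approximate by design.

### The MCMC engine

The package ships its own sampler rather than an external probabilistic
language. The design goal was high effective sample size per iteration
on random-intercept models of this size (≤ ~80 groups), including the
awkward designs M3/M4 where each bird contributes a single observation
and σ and τ are only jointly identified.

For gaussian models the intercepts are marginalised analytically (each
group's covariance σ²I + τ²J inverts in closed form), so there is no
funnel: β is drawn from its conjugate GLS conditional, and (log σ,
log τ) by univariate slice sampling on the marginal posterior plus a
rotated slice that moves along the σ²+τ² ridge. The GLS precision is
assembled from within-group-centred covariates plus group means — a sum
of positive semidefinite terms that remains well-conditioned as σ → 0.
Intercepts are re-drawn from their exact conditional for storage and
posterior predictive checks.

For logit models the intercepts cannot be marginalised exactly. The
fixed-effect block uses independence Metropolis–Hastings with a Laplace
proposal recomputed each iteration (the conditional is log-concave, so a
few Newton steps find its mode reliably); intercepts are updated by
vectorised per-group Laplace-proposal MH; τ by slice sampling plus two
joint moves that break the τ–|u| coupling: a scale move (τ, u) → (cτ,
cu) whose intercept-prior factor cancels its Jacobian exactly, and a
random-walk proposal on log τ with the intercepts refreshed from their
τ-conditional Laplace proposal. A recentring move trades a shift between
the intercept-like fixed effects and all random intercepts
(likelihood-invariant). Two full update cycles are run per stored
iteration.

Defaults are 5 chains of 6,000 iterations with 3,000 warmup — a tenfold
reduction of the original analysis's run length, chosen for desk-scale
runtimes while passing the same convergence gates (split-R̂ < 1.1 and
effective sample size > 1000 for every reported parameter; both
statistics are computed in-package, ESS by Geyer's initial monotone
sequence, and cross-checked against `coda` in the tests). With the
samplers above, default fits of all four models on a full synthetic
study pass both gates in a few minutes.

Validation is two-route throughout: gaussian fits against closed-form
least squares when the random-intercept variance is negligible, logit
fits against a maximum-likelihood logistic oracle, parameter recovery on
data generated from the models at the reported coefficient values, and
posterior predictive checks (200 draws; mean, sd, min, max, and the
outside proportion for binary models).

## Zooplankton biomass index

Per station and year, each taxon's abundance (ind m⁻³) is averaged over
depth strata — unweighted, as in the monitoring protocol; a
thickness-weighted option exists — and converted to dry biomass via a
per-taxon dry-mass table supplied as data (the diet list is an input,
not hard-coded). The yearly index is the mean over stations with a
station-resampling percentile bootstrap (999 iterations).

## The synthetic-data generator

The generator is first-class, tested code; its defaults *are* the study
conditions being emulated. Where the source analysis prints a value we
use it directly: bird numbers per colony and season, trip counts
(discretised normal, mean 5.3, sd 3.3, clipped to 1–16), yearly
outside-trip probabilities (7 %, 2 %, 31 %), inside/outside trip-range
medians (5.2/6.7/5.6 and 75.1/23.3/90.2 km), the condition regression
(5.96 g/mm), and the mass-change model (proportion slope 0.054, year
levels −2.1 %/−7.9 %/−3.4 %, bird sd 0.01, residual sd 0.04). The fjord
is a ~230 km² rectangle at high latitude with two colonies in the inner
half, land strips along both shores, and open sea beyond the western
mouth; trips are out-and-back tracks at 35 km h⁻¹ with a foraging dwell
at the apex, which keeps the generated maximum range exact and the
delineation rules fully exercised. Battery failure truncates the last
trip in 45 % of deployments (reproducing the reported ~8 % incomplete
trips), and 5 % of trips are land excursions with > 50 % of fixes
ashore.

Quantities the study does not print were fixed once, by calibration to
its printed *outcomes*, and are deliberate generator choices:

* within-year log-scale spreads: inside trips 0.35; outside trips 0.55
  in the two unimodal years and 0.15 in the bimodal year (shelf-break
  trips concentrate at a fixed distance, scattered destinations
  otherwise);
* bird-level random intercepts: 0.10 on log range, and 2.5 on the logit
  outside-propensity scale, *centred* so the trip-level outside
  probability still equals the yearly target. Strong, centred
  specialisation is what reproduces the printed pattern: a detectably
  bimodal per-individual range distribution in the 31 %-outside year
  (dip test rejects in ≳ 90 % of seeds at the study's sample sizes) and
  unimodal distributions in the 7 %/2 % years, with modes near 10 and
  ~110 km versus ~10–14 km.

What the generator does *not* emulate: behaviourally realistic movement
(no area-restricted search or correlated random walks), real coastline
geometry, within-season environmental trends, or chick state. Passing
tests therefore demonstrate that the pipeline's rules and estimators are
correct and recover generating parameters — not that the ecological
conclusions would replicate on other field data.

## Numerical choices and degenerate inputs

* Dip statistic: exact; junction-binding samples solved by bisection to
  1e-12. Samples with all values identical return the floor 1/(2n);
  fewer than 3 values is an error.
* Critical bandwidth: bisection to 1e-3 on [span/1e5, span]; an error is
  raised if even the widest bandwidth keeps more than k modes. Constant
  samples are an error (no KDE scale).
* OLS condition regression requires ≥ 3 complete birds and non-constant
  head-bill lengths.
* MCMC: scale parameters floored nine log-units below the data scale so
  constant responses cannot collapse σ to numerical zero; non-finite
  logit starting points are re-drawn up to 10 times.
* The incomplete-trip return test uses a 1e-9 relative tolerance so that
  a final fix at exactly 25 % of the maximum range counts as returned.

## Worked example

A complete run on synthetic data (reduced bootstrap/null sizes for
speed):

```{r pipeline, eval = FALSE}
cfg <- run_config(stages = c("segment", "bimodality", "condition", "zooplankton"),
                  iterations = 199, n_null = 999, n_boot = 499)
report <- run_pipeline(cfg)
report
```

Model fits are run separately because of their cost:

```{r models, eval = FALSE}
st <- simulate_study(sim_config(), seed = 1)
trips <- filter_incomplete(exclude_land_trips(
  segment_trips(st$fixes, st$deployments, st$area)), st$area)
fit <- fit_model("M1_logrange", trips[trips$label == "inside", ], seed = 1)
fit_summary(fit)
backtransform_median(fit, year = 2016, colony_id = "OBS")
```

## Known limitations

* Point-in-polygon in raw lon/lat distorts at high latitude; supply
  projected or finely vertexed polygons for real coastlines.
* The dip test has low power at ~20 individuals per year unless the two
  foraging modes are tight relative to their separation; this matches
  the behaviour of the original test, not a limitation of the
  implementation.
* Critical-bandwidth mode locations carry sampling noise of several km
  even at n = 2000 (flat-topped mixture components).
* The logit sampler's effective sample sizes, while passing the gates,
  are an order of magnitude below the gaussian sampler's; very small or
  very unbalanced binary datasets may need longer runs.
* M3/M4 with one observation per bird cannot separate σ from τ; the
  marginalised sampler keeps their sum well-identified and the priors
  regularise the split, mirroring the original modelling choice.
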