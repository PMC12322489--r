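# cpforage

Analysis of **bimodal central-place foraging** in colonial seabirds
tracked with GPS loggers, built around a three-season, two-colony
glacial-fjord study system: do chick-rearing adults alternate short
inside-fjord trips (offspring provisioning) with long outside-fjord
trips (self-maintenance), and does that decision relate to body
condition and pay off in body mass?

The package implements the complete chain:

* **Trip segmentation** — subsample raw fixes to 10 min; a trip is a
  maximal run of fixes > 0.2 km from the colony lasting ≥ 50 min;
  trips with > 50 % of fixes on land are dropped, and battery-truncated
  trips are kept only if the bird had covered ≥ 75 % of its maximum
  range (final fix within 25 % of max range from the colony).
* **Bimodality** — per-year distributions of per-individual maximum
  foraging ranges are tested with an exact, from-scratch implementation
  of Hartigans' dip statistic
  (D = min over unimodal CDFs G of sup|F̂n − G|) with Monte-Carlo
  p-values from the Uniform(0,1) null; modes are located by the
  critical bandwidth (smallest Gaussian KDE bandwidth with ≤ k modes on
  a 0–200 km window), with k tied to the dip decision; a
  one-trip-per-individual resampling guards against unequal trip
  counts.
* **Condition metrics** — size-corrected body condition (OLS residual
  of mass on head-bill length), relative body-mass change
  BMC = (Mr − Mc)/Mc, and trip-count-weighted outside-trip proportions
  with bootstrap CIs.
* **Four Bayesian mixed models** (individual random intercepts,
  weakly informative auto-scaled priors, built-in MCMC engine with
  split-R̂/ESS gates): log-range ~ year + colony (gaussian);
  trip-outside ~ year + colony (logit); first-trip-outside ~ condition
  + year + colony (logit); BMC ~ outside proportion + year + colony
  (gaussian).
* **Zooplankton biomass index** — depth-strata-averaged abundances ×
  per-taxon dry mass, station-averaged per year with a station
  bootstrap.
* **Synthetic-data generator** — emulates the full study (trip
  mixtures, body-mass dynamics, battery failure, land excursions, net
  samples) so every stage is testable end to end; a clean configuration
  round-trips exactly through segmentation.

See the vignette (`vignettes/foraging-analysis.Rmd`) for the models,
priors, sampler design and generator calibration.

## Worked example

```r
library(cpforage)

st    <- simulate_study(sim_config(), seed = 1)
trips <- filter_incomplete(exclude_land_trips(
           segment_trips(st$fixes, st$deployments, st$area)), st$area)

imr <- individual_max_range(trips)                 # one value per bird-year
mode_locations(imr$max_range_km[imr$year == 2018], n_null = 2000, seed = 42)
#> Mode estimate: k = 2 at h_crit = 6.765; modes at 6.7, 97.5 km (dip p = 0.0005)

ct <- condition_table(st$morpho, trips)
cc <- ct[ct$year == 2018 & !is.na(ct$n_trips), ]
weighted_outside_proportion(cc$prop_outside, cc$n_trips, seed = 42)
#> Weighted outside-trip proportion: 0.224 [0.118, 0.364] (999 bootstrap iterations)
```

The 2018-like season is detected as bimodal (dip p = 0.0005): a short
mode at ~7 km (inside-fjord, glacier-front foraging) and a long mode
near 100 km (outside-fjord, shelf foraging), and roughly a quarter of
this realisation's trips left the fjord. Model fits work the same way:

```r
fit <- fit_model("M1_logrange", trips[trips$label == "inside", ], seed = 1)
fit_summary(fit)                                    # means, 95% PI, R-hat, Neff
backtransform_median(fit, year = 2016, colony_id = "OBS")  # km-scale median
```

A full orchestrated run (segmentation through zooplankton, with logs of
every filtering decision) is `run_pipeline(run_config())`; a thin CLI
wrapper lives in `inst/scripts/cpforage.R`.

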