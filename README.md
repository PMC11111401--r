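# paleoresil

Resistance and resilience of past human populations, measured from
radiocarbon time–frequency data.

Archaeological radiocarbon dates, aggregated into summed probability
distributions (SPDs), proxy relative levels of past human activity.
`paleoresil` implements a comparative pipeline for *population downturns* —
episodes when a regional SPD falls significantly below an expected growth
trajectory — and for the metrics that make downturns comparable across
regions:

- **Calibration & aggregation**: read IntCal-style `.14c` curves
  (`load_curve`), calibrate conventional radiocarbon ages
  (`calibrate_date`), pool same-site dates within 50 radiocarbon years by
  complete-linkage binning (`bin_dates`), and build regional SPDs
  (`build_spd`).
- **Growth model**: a bounded exponential null,
  `f(t) = r e^{r(a−t)} / (e^{r(a−b)} − 1)` on `[b, a]` cal BP, fitted by
  random-walk Metropolis over a per-bin marginal likelihood that accounts
  for measurement and sampling error simultaneously (`prepare_bins`,
  `fit_mcmc`), with rank-normalized split-R̂/ESS diagnostics
  (`diagnostics`).
- **Downturn detection**: posterior-predictive simulation of SPDs from the
  fitted model yields pointwise 90% critical envelopes
  (`posterior_predictive_envelope`); maximal runs below the lower bound
  longer than 10 years are downturns (`detect_downturns`).
- **Metrics** (per downturn, with baseline `b`, minimum `x`, end value `e`):
  resistance `1 − 2|b−x|/(|b|+|b−x|)`, resilience
  `2|b−x|/(|b−x|+|b−e|) − 1`, pace `time-to-minimum/duration`, and the
  per-millennium downturn frequency (`downturn_frequency`,
  `assemble_table`).
- **Synthesis**: descriptive statistics (`describe`) and random-intercept
  mixed models such as `resistance ~ (1|region) + log-frequency`
  (`fit_mixed`, `stepwise_ic`, `fit_frequency_model`) via `lme4`.
- **Synthetic truth**: `scenario`/`generate_region`/`generate_study` create
  regional datasets from known growth trajectories with injected V-shaped
  "busts", so every stage is testable against ground truth; `run_study`
  orchestrates the whole pipeline across regions.

See the vignette `vignettes/downturn-resilience-methods.Rmd` for the model,
its assumptions, parameter choices and known limitations.

## Worked example

A synthetic region with a known 50% bust, run end to end:

```r
library(paleoresil)

curve <- synth_curve(7000, 0)                     # identity curve
busts <- data.frame(T_start = 2100, T_end = 1800,
                    depth = 0.5, recovery = 0.2)
sc <- scenario(region = "demo", a = 6000, b = 1000, r = 0.002,
               busts = busts, n_dates = 800, n_sites = 100, seed = 2101)
gr <- generate_region(sc, curve)

bins <- bin_dates(gr$dates)
cb   <- prepare_bins(gr$dates, curve, c(6000, 1000), bins = bins)
post <- fit_mcmc(cb, mcmc_config(n_iter = 1500, burn_in = 300, seed = 2201))
post
#> Posterior sample: 3 chains x 600 draws; mean r = 0.001743,
#>   95% CrI [0.001603, 0.001895]

env <- posterior_predictive_envelope(post, cb$n_bins, gr$dates$error,
                                     curve, c(6000, 1000), n_sim = 150,
                                     seed = 2301)
dens <- lapply(seq_len(nrow(gr$dates)), function(i)
  calibrate_date(gr$dates$cra[i], gr$dates$error[i], curve))
spd <- build_spd(dens, bins, c(6000, 1000), region = "demo")
detect_downturns(spd, env)
#>   region T_start T_end t_min        b         x        e duration time_to_min
#> 1   demo    3144  3053  3108 0.004022 0.0007671 0.006662       91          36
#> 2   demo    2011  1809  1986 0.121261 0.1068033 0.200374      202          25
```

The injected bust (2100–1800 cal BP) surfaces as the large downturn at
2011–1809 cal BP, 202 years long with its minimum at 1986 cal BP; its
resistance is `resistance(0.1213, 0.1068) = 0.79` (a fairly shallow dip
relative to baseline). The detected onset sits inside the true interval because
pointwise envelopes flag a gradual decline only once it exceeds the
envelope width (see the vignette's limitations); the short 91-year event
near 3100 cal BP is the kind of chance excursion the calibration
experiments quantify. The posterior mean growth rate (0.0017) sits close
to the true `r = 0.002`, slightly shrunk by site-level binning of a
densely dated record. Passing the resulting table
through `downturn_frequency`, `assemble_table` and `fit_mixed` yields the
cross-regional analysis; `run_study` does all of the above per region from
one configuration.

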