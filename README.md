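# farrec

Climate attribution statistics for fish recruitment analysis.

## The problem

When an ecosystem warms past the envelope of its natural variability,
historical experience stops being a guide to how exploited fish stocks will
behave. `farrec` is for fisheries scientists who want to frame that
transition quantitatively: it measures how anomalous each year's ocean
temperature was relative to a preindustrial baseline, asks how recruitment
(the production of young fish, the key driver of future catches) has
responded to those anthropogenic extremes within the observational record,
and compares backward-looking and forward-looking expectations of
recruitment as the extremes become the mean state.

The central statistic is the Fraction of Attributable Risk,

    FAR = 1 − P(anomaly | preindustrial) / P(anomaly | current),

the proportion of the risk of an extreme that is attributable to human
influence, with both probabilities measured as empirical exceedance
proportions against climate-model control runs and (for the current
climate) observations or scenario projections. Around it sit the models a
full analysis needs:

* a Bayesian beta regression pooling per-year, per-climate-model FAR values
  into an annual posterior (fixed year effects, climate-model random
  intercept, shared precision; FAR = 1 reset to 0.9999 beforehand);
* Dynamic Factor Analysis (EM + Kalman smoother, exact handling of missing
  survey years) extracting one shared latent recruitment trend from a
  multi-survey panel;
* Bayesian zero-inflated negative binomial models of set-level beach-seine
  counts with nested bay/site random effects, annual abundance indices, and
  a two-level categorical-FAR contrast of catch rates;
* penalized thin-plate spline models of standardized log recruitment on
  FAR (3 or 5 basis functions), with a latent-variable variant propagating
  FAR measurement error, Bayesian R², and PSIS-LOO model comparison;
* decadal projection of recruitment under historical versus
  scenario-projected FAR, with percent declines of the median reported in
  original (not log) units.

Every input can be simulated (`simulate_climate`, `simulate_recruitment`,
`simulate_seine`, `simulate_survey_panel`), so the whole pipeline is
testable end to end without any external data. MCMC runs on JAGS via
`rjags`.

## A worked example

Simulate a warming ocean against a five-model preindustrial ensemble,
estimate annual FAR, fit the recruitment response, and project it forward:

```r
library(farrec)

# 1. synthetic climate ensemble: 51 observed years, 5 pseudo models
ens <- simulate_climate(climate_sim_params(seed = 1))
ft  <- build_far_table(ens, "hindcast")
#> build_far_table: 79 of 255 FAR values clamped into [0.0001, 0.9999]
head(ft, 3)
#>   year model_id        far     p_pre     p_cur
#> 1 1970  model01 0.51704545 0.4166667 0.8627451
#> 2 1971  model01 0.31630435 0.6166667 0.9019608
#> 3 1972  model01 0.08333333 0.9166667 1.0000000

# 2. Bayesian ensemble FAR posterior (per-year mean, SE, credible ribbons)
fe <- fit_far_model(ft, seed = 1)
tail(as.data.frame(fe)[, c("year", "mean", "se", "lo95", "hi95")], 3)
#>    year  mean    se  lo95  hi95
#> 49 2018 0.991 0.004 0.983 0.997
#> 50 2019 0.994 0.003 0.988 0.998
#> 51 2020 0.991 0.004 0.982 0.997

# 3. recruitment with a step response at FAR >= 0.98, spline fit that
#    carries the FAR posterior SE as measurement error
far_yr <- aggregate(far ~ year, data = ft, FUN = mean)
rec <- simulate_recruitment(far_yr$far, recruit_sim_params(seed = 1),
                            years = far_yr$year, standardize_output = TRUE)
fit <- fit_far_gam_me(rec, fe, k = 5, seed = 1)
bayes_r2(fit)$median
#> [1] 0.28

# 4. decadal projection under scenario FAR
fp <- far_projection_series(ens, seed = 1)
proj <- summarize_projection(fit, fe, fp,
                             periods = list(historical = far_yr$year,
                                            "2020s" = 2020:2029,
                                            "2030s" = 2030:2039,
                                            "2040s" = 2040:2046),
                             center = attr(rec$log_anomaly, "center"),
                             scale = attr(rec$log_anomaly, "scale"),
                             seed = 1)
proj[, c("period", "median", "lo95", "hi95", "pct_decline_vs_historical")]
#>       period median lo95 hi95 pct_decline_vs_historical
#> 1 historical   0.69 0.10 4.82                      0.00
#> 2      2020s   0.35 0.06 1.98                     49.59
#> 3      2030s   0.35 0.06 2.02                     49.19
#> 4      2040s   0.35 0.06 2.00                     48.87
```

Reading the output: by the late 2010s the posterior mean FAR is ≈ 0.99
with a tight interval — those anomalies essentially do not occur in the
preindustrial realizations. The projected decades sit almost entirely
beyond the attribution threshold, so the predicted recruitment median
drops from 0.69 to 0.35 (original units of the back-transformed index),
a ~49% decline relative to the historical period, with wide predictive
intervals because year-to-year recruitment variability is carried through.
Fits print convergence warnings when the split-R̂/ESS bar (1.05 / 1000) is
not met — lengthen `iter` to tighten them.

`run_pipeline()` chains all stages (attribution → DFA → annual seine index
→ recruitment bridge → measurement-error spline → projection) from CSV
inputs described by a `pipeline_config()`, writing per-stage outputs and a
JSON manifest; `write_synthetic_dataset()` produces a complete synthetic
input set.

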