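---
title: "Methods: climate attribution statistics and fish recruitment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: climate attribution statistics and fish recruitment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Overview

`farrec` implements a probabilistic workflow for asking how a fish
population's recruitment (the production of young fish) has behaved when
ocean temperatures moved outside the envelope of natural variability, and
what recruitment should be expected as that envelope is left behind. The
chain has five statistical stages:

1. **Attribution.** Annual sea-surface-temperature anomalies are converted
   into the Fraction of Attributable Risk,
   \(\mathrm{FAR} = 1 - p_{\mathrm{pre}} / p_{\mathrm{cur}}\), where both
   probabilities are empirical exceedance proportions (the share of a
   reference sample at or above the focal anomaly). A Bayesian beta
   regression pools the per-year, per-climate-model FAR values into an
   annual posterior.
2. **Latent recruitment trend.** Several survey indices (each noisy, each
   with missing years) are reduced to one shared trend by Dynamic Factor
   Analysis, i.e. a linear-Gaussian state-space model estimated by EM with
   a Kalman smoother.
3. **Set-level catch models.** Beach-seine counts of age-0 fish are modelled
   with Bayesian zero-inflated negative binomial (ZINB) regressions with
   nested bay/site random intercepts, yielding annual abundance indices and
   a two-level (categorical FAR) contrast of catch rates.
4. **Recruitment–FAR response.** Standardized log recruitment is regressed
   on FAR with a low-rank thin-plate spline; a latent-variable variant
   treats each year's FAR as measured with error. Candidate models are
   compared by PSIS-LOO.
5. **Projection.** The fitted response is pushed through historical and
   scenario-projected FAR posteriors to compare backward-looking and
   forward-looking recruitment distributions, decade by decade, with
   percent declines of the median reported in original (not
   log-transformed) units.

# The attribution statistic

For a year with standardized anomaly \(a\), the preindustrial probability is
the proportion of a climate model's control-run anomalies \(\ge a\) (ties
count as exceedances), and the current probability is the proportion of the
observed window (hindcast) or of that model's scenario realization
(projection) \(\ge a\). Because the focal year belongs to its own reference
sample, \(p_{\mathrm{cur}} \ge 1/n\) and the ratio is always defined.

Raw FAR values of 1 (anomalies never reached under preindustrial
conditions) are reset to 0.9999 so that the beta likelihood downstream is
defined; symmetrically, values \(\le 0\) (anomalies *more* likely under
preindustrial conditions) are clamped to 0.0001. Clamping is reported via a
message whenever it occurs. Note a subtlety of the empirical statistic:
FAR is monotone in the anomaly only while \(p_{\mathrm{cur}}\) is constant;
at anomalies crossing a current-sample order statistic it can step down.
In the idealized continuous limit (current distribution stochastically
larger than preindustrial) FAR is globally monotone.

The ensemble model is
\(y_{tm} \sim \mathrm{Beta}(\mu_{tm}\phi, (1-\mu_{tm})\phi)\) with
\(\operatorname{logit} \mu_{tm} = a_t + u_m\): fixed year effects plus a
climate-model random intercept absorbing between-model spread, and one
precision \(\phi\) shared across years. Priors are weakly informative:
Normal(0, 3) on year effects — the prior must reach
\(\operatorname{logit}(0.9999) \approx 9.2\), the value the clamping rule
itself creates, so a tighter prior would silently cap the achievable
posterior mean well below the clamp — half-Normal(0, 1) on the
random-effect SD, and half-Normal(0, 100) on \(\phi\). The model effects
are sweep-centered (each draw of \(u\) has its mean moved into the year
effects), which removes the additive ridge between \(a_t\) and the mean of
\(u\) without changing the likelihood; without it the year means mix an
order of magnitude more slowly. Reported per-year summaries are the
posterior mean, SD (the "SE" used by the measurement-error model), and
equal-tailed 80/90/95% intervals.

# Dynamic Factor Analysis

The one-trend DFA model is
\(x_t = x_{t-1} + w_t\), \(w_t \sim N(0, 1)\) (process variance fixed at 1
for identifiability), \(y_{it} = Z_i x_t + v_{it}\),
\(v_{it} \sim N(0, r_i)\) with a diagonal, unequal observation covariance.
Each series is standardized over its observed entries before fitting, so
loadings are on the unitless figure scale. Estimation is EM: the E-step is
an exact Kalman smoother in which missing observations simply drop out of
the update, and the M-step updates loadings, observation variances and the
initial state mean in closed form. The log-likelihood is checked to be
non-decreasing at every iteration and an apparent decrease is treated as a
bug, not a data problem. Convergence is declared at a relative
log-likelihood change below 1e-6 (at most 5000 iterations). The sign
convention fixes the mean loading to be non-negative. Loading confidence
intervals come from the observed-information Hessian (central finite
differences of the Kalman-filter likelihood); a parametric bootstrap is
available for small samples. Trend intervals come from the smoother
variance.

DFA loadings are identified only up to the latent-trend scale. For
comparisons against a known generating process the result also carries
`loadings_scaled`: loadings rescaled to a unit-variance trend on the
original data scale, the scale-free quantity simulation studies can check
against truth.

# Count models

Set-level counts are a two-part mixture: a logit-linear structural-zero
probability and a log-linear negative binomial mean with a log-link shape.
Continuous covariates (egg/larval temperature anomaly, day of year,
spawning stock biomass) are standardized internally and reported back on
their original scales. Bay and site-within-bay intercepts enter both parts,
hierarchically centered: site around its bay mean, bay around the global
intercept. Hierarchical centering keeps the sampler's graph local (a
sweep-centering formulation recomputed every likelihood node per
random-effect update and was an order of magnitude slower) and removes the
intercept/random-effect ridge. Priors: Normal(0, 2) on fixed effects,
half-Normal(0, 1) on random-effect SDs, Normal(0, 1) on the log shape.
The mixture likelihood is evaluated explicitly (a zeros-trick construction),
which also makes the pointwise log-likelihood matrix for PSIS-LOO exact.

The annual index is the posterior of expected catch per set by year with
covariates at their sample means and random effects marginalized at zero:
\((1-\pi_y)\mu_y\). The categorical-FAR model is a Gaussian model of
set-level catch with a single two-level covariate (year FAR above/below the
threshold, default 0.98) and positive-truncated Normal priors on the class
means, exactly as the analysis it reproduces states it; a log-scale variant
sits behind a flag because a Gaussian on raw counts is an odd choice that
the source leaves unexplained. Its pooled residual variance understates the
high-variance class's uncertainty, which is why recovery checks should
target the class means rather than strict interval coverage.

# Recruitment–FAR splines

The smooth is a low-rank thin-plate spline: radial basis \(|x - x_j|^3\) on
the standardized covariate with knots at the observed values, the \{1, x\}
null space projected out, and the leading eigenvectors of the projected
penalty retained. A smooth with \(k\) basis functions has an intercept, a
linear term and \(k-2\) penalized columns; \(k \in \{3, 5\}\). Penalized
coefficients get hierarchical Normal priors whose precision is the
normalized penalty eigenvalue times a smoothing precision with a
half-Normal(0, 1) SD prior. Because the basis functions are explicit
combinations of \(|x - \text{knot}|^3\), the design matrix can be evaluated
at arbitrary covariate values — including latent ones, which is what the
measurement-error variant needs.

In the measurement-error model each year's FAR is latent:
\(f_t \sim N(\hat f_t, \hat{se}_t^2)\) truncated to (0, 1), with the spline
applied to \(f_t\). As \(\hat{se} \to 0\) the fit converges to the
error-free model (and all-zero SEs fall back to it explicitly). Covariate
uncertainty propagates into the fitted curve, predictions, and the
projection stage.

On basis size: \(k = 3\) is the default for FAR smooths on 40–50-year
series. For study designs whose truth is a sharp step at the attribution
threshold, \(k = 3\) is provably too stiff — on a step of 2 log units it
predicts only about \(-1.1\) at FAR 0.999 (the mgcv thin-plate smooth of the
same rank does the same), biasing projected declines low — so the
end-to-end analyses in this package use \(k = 5\) for the FAR smooth.

Bayesian \(R^2\) is the per-draw ratio
\(\mathrm{var}(\hat y)/(\mathrm{var}(\hat y) + \sigma^2)\), always in
\([0, 1]\). Model comparison uses PSIS-LOO: raw importance ratios
\(1/p(y_i\mid\theta^{(s)})\) are tail-smoothed with a generalized Pareto
fit (Zhang–Stephens estimator) to the largest 20% (capped at
\(3\sqrt{S}\)); \(\mathrm{LOOIC} = -2\,\widehat{\mathrm{elpd}}\); Pareto
\(k > 0.7\) is flagged. Ties within \(2\,\mathrm{SE}\) of the LOOIC
difference favour the simpler model. Recruitment failure is classified as a
standardized log anomaly strictly below \(-1\).

The bridge for recent, assessment-poor year classes is an ordinary linear
regression of assessment log-recruitment anomalies on the survey-derived
annual index over their overlap years (at least 3 required); predictions
carry the closed-form OLS predictive standard error, and the merged series
is tagged by source. Predictive uncertainty of bridged years is plugged in,
not propagated into the spline fit.

# Projection and percent declines

For each posterior draw of the measurement-error fit, a year is drawn
uniformly from the period, its FAR is drawn from the posterior summary
(truncated Normal), the spline mean is evaluated and residual noise added;
pooling over draws gives the period's predictive recruitment distribution
on the standardized log scale. Percent decline back-transforms with the
recorded standardization constants, exponentiates, takes medians, and
reports \(100(1 - \mathrm{med}_{\mathrm{period}}/\mathrm{med}_{\mathrm{hist}})\);
increases come out negative and are not clamped. The decline's credible
interval is built per posterior draw (each draw yields one median per
period, hence one decline). No lognormal bias correction is applied in the
back-transform; the quantity is a median, which commutes with monotone
transforms. Years within a decade are weighted equally.

# The synthetic-data generators

Every input has a generator whose defaults are the study conditions the
package is tested under:

* **Climate** (`climate_sim_params`): 51 observed years warming at 0.045
  anomaly-units/yr with AR(1) noise (coefficient 0.5, innovation SD 0.6,
  stationary initialization), five pseudo climate models each contributing
  one 60-year stationary preindustrial realization and one 41-year
  projection realization (trend 0.05/yr) that continues from the observed
  end level. These sizes mirror the ensemble design the analysis assumes
  (five downscaled models, single 60-year control runs, a 2006–2046
  scenario horizon).
* **Recruitment** (`recruit_sim_params`): a step of \(-2\) log units at FAR
  0.98 with residual SD 0.6, so threshold years are unambiguous failures
  (log anomaly below \(-1\)) against realistic interannual variability.
* **Seine catch** (`seine_sim_params`): 15 bays of 6 fixed sites sampled in
  July–August; ZINB counts with temperature (\(-0.5\)/°C), day-of-year and
  SSB effects in the abundance part and nested bay/site intercepts
  (SD 0.5 each) in both parts; mean catch ~42 fish/set collapsing to ~2 in
  years at or beyond the attribution threshold.
* **Survey panel** (`simulate_survey_panel`): series = loading × latent
  trend + Gaussian noise with per-series missing-completely-at-random gaps;
  the reference design uses loadings (0.8, 0.6, 0.4, 0.0) — three
  informative surveys and one uninformative one.

One master seed expands into named sub-streams (`substream_seed`), so
adding a generator never perturbs the draws of another. What the generators
do **not** emulate: spatially structured survey gaps (real surveys miss
blocks of years, not random ones), collinear environmental drivers
(salinity, transport) that co-vary with FAR in the real system, serial
correlation in recruitment residuals, and any ocean-physics realism.
Passing tests therefore demonstrate statistical correctness of the
machinery, not oceanographic fidelity.

# Numerical choices and problem sizes

MCMC runs on 2 chains with a few thousand retained draws by default;
convergence is summarized by split-\(\widehat R\) (< 1.05) and effective
sample size (target 1000, via within-chain autocovariances with Geyer's
monotone pair truncation), and failures warn rather than stop — short
exploratory chains are legitimate, silent non-convergence is not. Gibbs
samplers have no divergent transitions, so the divergence count is reported
as zero for interface compatibility. The test-suite study sizes — 20
calibration ensembles of 5 models × 50 years, 50 DFA panels of 4 series ×
40 years with 20% missingness, one 3000-set ZINB recovery, 25 end-to-end
projection replicates — were chosen so each check has enough replication
to be meaningful while the whole suite stays comfortably runnable on a
laptop. Observation variances in the DFA are floored at 1e-8; FAR clamps
are 1e-4 and 0.9999 throughout; spline penalty eigenvalues are normalized
to a maximum of 1 so the smoothing prior has a consistent scale.

# Known limitations

* The beta ensemble model's shared precision cannot represent years whose
  between-model spread differs wildly from the rest; the random effect
  absorbs level differences only.
* A rank-5 spline still smooths a hard threshold; projected declines under
  genuinely discontinuous responses are mildly conservative.
* The categorical-FAR Gaussian model inherits the equal-variance assumption
  from the analysis it mirrors; its interval for the high-variance class is
  slightly anticonservative.
* The DFA supports a single latent trend; multi-trend rotation is out of
  scope.
* PSIS-LOO is unreliable where Pareto \(k > 0.7\); the package flags but
  does not refit those observations.
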