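# Synthetic-data generators
#
# Every input the attribution-to-recruitment pipeline consumes can be
# generated here with the statistical structure the analysis assumes:
# a trended AR(1) observed SST series against stationary preindustrial
# realizations; survey panels sharing one latent trend with heterogeneous
# noise and missing years; overdispersed zero-inflated seine counts with
# nested bay/site effects; and recruitment series whose mean declines with
# FAR, linearly or as a step near the attribution threshold.

#' Parameters for the synthetic climate ensemble
#'
#' @param n_years_obs Number of observed years.
#' @param trend_obs Linear warming trend of the observed series
#'   (anomaly units per year).
#' @param ar1_coef AR(1) coefficient of the interannual noise, in (-1, 1).
#' @param noise_sd Innovation standard deviation of the AR(1) noise
#'   (anomaly units).
#' @param n_models Number of pseudo climate models in the ensemble.
#' @param n_years_pi Length of each model's preindustrial realization
#'   (default 60, one 60-year control run per model).
#' @param n_years_proj Length of each model's projection realization.
#' @param trend_proj Linear trend of the projection realizations
#'   (anomaly units per year).
#' @param obs_start First observed calendar year.
#' @param proj_start First projection calendar year.
#' @param seed Integer master seed; sub-streams are derived per component.
#' @return An object of class `climate_sim_params`.
#' @export
climate_sim_params <- function(n_years_obs = 51, trend_obs = 0.045,
                               ar1_coef = 0.5, noise_sd = 0.6,
                               n_models = 5, n_years_pi = 60,
                               n_years_proj = 41, trend_proj = 0.05,
                               obs_start = 1970, proj_start = 2006,
                               seed = 1) {
  check_count(n_years_obs, "n_years_obs", min = 2)
  check_scalar(trend_obs, "trend_obs")
  check_scalar(ar1_coef, "ar1_coef", lower = -1, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  check_scalar(noise_sd, "noise_sd", lower = 0, strict_lower = TRUE)
  check_count(n_models, "n_models", min = 1)
  check_count(n_years_pi, "n_years_pi", min = 2)
  check_count(n_years_proj, "n_years_proj", min = 2)
  check_scalar(trend_proj, "trend_proj")
  check_count(seed, "seed", min = 0)
  structure(list(n_years_obs = n_years_obs, trend_obs = trend_obs,
                 ar1_coef = ar1_coef, noise_sd = noise_sd,
                 n_models = n_models, n_years_pi = n_years_pi,
                 n_years_proj = n_years_proj, trend_proj = trend_proj,
                 obs_start = obs_start, proj_start = proj_start, seed = seed),
            class = "climate_sim_params")
}

# AR(1) path with stationary initialization; `sd` is the innovation SD, so
# the stationary marginal SD is sd / sqrt(1 - phi^2)
ar1_path <- function(n, phi, sd) {
  x <- numeric(n)
  x[1] <- stats::rnorm(1, 0, sd / sqrt(1 - phi^2))
  if (n > 1) {
    e <- stats::rnorm(n - 1, 0, sd)
    for (t in 2:n) x[t] <- phi * x[t - 1] + e[t - 1]
  }
  x
}

#' Simulate a climate-model ensemble
#'
#' Generates an observed annual anomaly series (linear trend plus AR(1)
#' noise), and for each pseudo model one stationary preindustrial AR(1)
#' realization and one trended projection realization. The projection
#' continues from the warming level reached at the end of the observed
#' period, so with zero trends all three components share population mean 0.
#'
#' @param params A [climate_sim_params()] object.
#' @return A `climate_ensemble`: list with elements `observed` (data.frame
#'   `year`, `value`) and `models` (list of `model_id`, `preindustrial`,
#'   `projection` data.frames).
#' @export
simulate_climate <- function(params) {
  stopifnot(inherits(params, "climate_sim_params"))
  p <- params
  withr_seed <- substream_seed(p$seed, "climate-observed")
  set.seed(withr_seed)
  obs_years <- p$obs_start + seq_len(p$n_years_obs) - 1
  obs <- p$trend_obs * (seq_len(p$n_years_obs) - 1) +
    ar1_path(p$n_years_obs, p$ar1_coef, p$noise_sd)
  observed <- data.frame(year = obs_years, value = obs)

  end_level <- p$trend_obs * (p$n_years_obs - 1)
  proj_years <- p$proj_start + seq_len(p$n_years_proj) - 1
  models <- lapply(seq_len(p$n_models), function(m) {
    set.seed(substream_seed(p$seed, paste0("climate-model-", m)))
    pre <- ar1_path(p$n_years_pi, p$ar1_coef, p$noise_sd)
    proj <- end_level + p$trend_proj * (seq_len(p$n_years_proj) - 1) +
      ar1_path(p$n_years_proj, p$ar1_coef, p$noise_sd)
    list(model_id = sprintf("model%02d", m),
         preindustrial = data.frame(year = seq_len(p$n_years_pi),
                                    value = pre),
         projection = data.frame(year = proj_years, value = proj))
  })
  structure(list(observed = observed, models = models, params = p),
            class = "climate_ensemble")
}

#' Parameters for synthetic recruitment series
#'
#' Defaults are chosen to emulate a stock in which years beyond the
#' attribution threshold show recruitment failure (standardized log anomaly
#' below -1): a step of -2 log units at FAR 0.98 against residual
#' variability of 0.6 log units.
#'
#' @param far_effect_shape `"linear"` or `"threshold"` response of mean log
#'   recruitment to FAR.
#' @param threshold FAR value at which the step occurs (default 0.98).
#' @param effect_size Size of the FAR effect in log-recruitment units
#'   (slope per unit FAR for `"linear"`, step height for `"threshold"`).
#' @param resid_sd Residual SD of log recruitment.
#' @param seed Integer seed.
#' @return A `recruit_sim_params` object.
#' @export
recruit_sim_params <- function(far_effect_shape = c("threshold", "linear"),
                               threshold = 0.98, effect_size = -2,
                               resid_sd = 0.6, seed = 1) {
  far_effect_shape <- match.arg(far_effect_shape)
  check_scalar(threshold, "threshold", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  check_scalar(effect_size, "effect_size")
  check_scalar(resid_sd, "resid_sd", lower = 0, strict_lower = TRUE)
  check_count(seed, "seed", min = 0)
  structure(list(far_effect_shape = far_effect_shape, threshold = threshold,
                 effect_size = effect_size, resid_sd = resid_sd, seed = seed),
            class = "recruit_sim_params")
}

#' Simulate an annual log-recruitment-anomaly series driven by FAR
#'
#' @param far_by_year Numeric vector of FAR values in \[0, 1\], one per year.
#' @param params A [recruit_sim_params()] object.
#' @param years Optional calendar years (default `seq_along(far_by_year)`).
#' @param standardize_output If `TRUE`, standardize to zero mean and unit
#'   variance; the centering/scaling constants are stored as attributes
#'   `center` and `scale` of the `log_anomaly` column for back-transformation.
#' @return A data.frame with columns `year` and `log_anomaly`.
#' @export
simulate_recruitment <- function(far_by_year, params,
                                 years = seq_along(far_by_year),
                                 standardize_output = FALSE) {
  stopifnot(inherits(params, "recruit_sim_params"))
  if (any(!is.finite(far_by_year)) || any(far_by_year < 0 | far_by_year > 1)) {
    stop("FAR values must be finite and in [0, 1]")
  }
  set.seed(substream_seed(params$seed, "recruitment"))
  mu <- switch(params$far_effect_shape,
    linear = params$effect_size * far_by_year,
    threshold = params$effect_size * (far_by_year >= params$threshold)
  )
  y <- mu + stats::rnorm(length(far_by_year), 0, params$resid_sd)
  if (standardize_output) y <- standardize(y)
  out <- data.frame(year = years, log_anomaly = as.numeric(y))
  if (standardize_output) {
    attr(out$log_anomaly, "center") <- attr(y, "center")
    attr(out$log_anomaly, "scale") <- attr(y, "scale")
  }
  attr(out, "true_mean") <- mu
  out
}

#' Parameters for synthetic beach-seine catch data
#'
#' The design emulates a nearshore age-0 survey: multiple bays each holding
#' several fixed sites, each site visited a small number of times per year
#' during mid-summer. Counts are zero-inflated negative binomial with
#' covariates (egg/larval temperature anomaly, day of year, spawning stock
#' biomass) and nested bay/site random intercepts entering both the
#' zero (logit) and abundance (log) parts.
#'
#' @param n_years,n_bays,n_sites_per_bay,sets_per_site_year Design sizes.
#' @param zero_prob_intercept Intercept of the zero part (logit scale).
#' @param mean_intercept Intercept of the abundance part (log scale).
#' @param temp_effect,doy_effect,ssb_effect Abundance-part coefficients
#'   (per deg C anomaly, per day, per SSB unit; log scale).
#' @param zero_temp_effect,zero_doy_effect,zero_ssb_effect Zero-part
#'   coefficients (logit scale; default 0).
#' @param far_step_effect Additional log-scale drop in mean abundance in
#'   years whose FAR value is at or above `far_threshold`. The default drops
#'   mean catch from ~42 to ~2 fish per set, the magnitude of the collapse
#'   the survey design is meant to emulate; it only acts when `far_by_year`
#'   is supplied to [simulate_seine()].
#' @param far_threshold Threshold used with `far_step_effect`.
#' @param bay_sd,site_sd SDs of the nested random intercepts (log/logit
#'   scale; shared by both model parts).
#' @param shape Negative binomial shape (size) parameter, > 0.
#' @param first_year First calendar year.
#' @param seed Integer seed.
#' @return A `seine_sim_params` object.
#' @export
seine_sim_params <- function(n_years = 15, n_bays = 15, n_sites_per_bay = 6,
                             sets_per_site_year = 1,
                             zero_prob_intercept = -1, mean_intercept = log(42),
                             temp_effect = -0.5, doy_effect = -0.02,
                             ssb_effect = 0.3,
                             zero_temp_effect = 0, zero_doy_effect = 0,
                             zero_ssb_effect = 0,
                             far_step_effect = log(2 / 42), far_threshold = 0.98,
                             bay_sd = 0.5, site_sd = 0.5, shape = 1.5,
                             first_year = 2006, seed = 1) {
  check_count(n_years, "n_years"); check_count(n_bays, "n_bays")
  check_count(n_sites_per_bay, "n_sites_per_bay")
  check_count(sets_per_site_year, "sets_per_site_year")
  check_scalar(shape, "shape", lower = 0, strict_lower = TRUE)
  check_scalar(bay_sd, "bay_sd", lower = 0)
  check_scalar(site_sd, "site_sd", lower = 0)
  for (nm in c("zero_prob_intercept", "mean_intercept", "temp_effect",
               "doy_effect", "ssb_effect", "zero_temp_effect",
               "zero_doy_effect", "zero_ssb_effect", "far_step_effect")) {
    check_scalar(get(nm), nm)
  }
  check_count(seed, "seed", min = 0)
  structure(as.list(environment())[c(
    "n_years", "n_bays", "n_sites_per_bay", "sets_per_site_year",
    "zero_prob_intercept", "mean_intercept", "temp_effect", "doy_effect",
    "ssb_effect", "zero_temp_effect", "zero_doy_effect", "zero_ssb_effect",
    "far_step_effect", "far_threshold", "bay_sd", "site_sd", "shape",
    "first_year", "seed")],
    class = "seine_sim_params")
}

#' Simulate set-level beach-seine catch records
#'
#' @param params A [seine_sim_params()] object.
#' @param far_by_year Optional FAR values (length `n_years`) used with
#'   `far_step_effect` to depress mean abundance in high-FAR years.
#' @return A data.frame (`seine_catch`) with columns `year`, `day_of_year`,
#'   `bay`, `site`, `count`, `temperature`, `ssb`.
#' @export
simulate_seine <- function(params, far_by_year = NULL) {
  stopifnot(inherits(params, "seine_sim_params"))
  p <- params
  if (!is.null(far_by_year)) {
    stopifnot(length(far_by_year) == p$n_years)
    if (any(far_by_year < 0 | far_by_year > 1)) stop("FAR values must be in [0, 1]")
  } else {
    far_by_year <- rep(0, p$n_years)
  }
  set.seed(substream_seed(p$seed, "seine"))
  n_sites <- p$n_bays * p$n_sites_per_bay
  bay_of_site <- rep(seq_len(p$n_bays), each = p$n_sites_per_bay)
  bay_c <- stats::rnorm(p$n_bays, 0, p$bay_sd)
  site_c <- stats::rnorm(n_sites, bay_c[bay_of_site], p$site_sd)
  bay_z <- stats::rnorm(p$n_bays, 0, p$bay_sd)
  site_z <- stats::rnorm(n_sites, bay_z[bay_of_site], p$site_sd)
  temp_year <- stats::rnorm(p$n_years, 0, 1)
  ssb_year <- stats::rnorm(p$n_years, 0, 1)

  grid <- expand.grid(rep_set = seq_len(p$sets_per_site_year),
                      site = seq_len(n_sites), yr = seq_len(p$n_years))
  n <- nrow(grid)
  doy <- round(stats::runif(n, 182, 243))  # July-August sampling window
  temp <- temp_year[grid$yr]
  ssb <- ssb_year[grid$yr]
  far_hi <- as.numeric(far_by_year[grid$yr] >= p$far_threshold)

  eta_count <- p$mean_intercept + p$temp_effect * temp +
    p$doy_effect * (doy - 212) + p$ssb_effect * ssb +
    p$far_step_effect * far_hi + site_c[grid$site]
  eta_zero <- p$zero_prob_intercept + p$zero_temp_effect * temp +
    p$zero_doy_effect * (doy - 212) + p$zero_ssb_effect * ssb +
    site_z[grid$site]
  pi <- ilogit(eta_zero)
  mu <- exp(eta_count)
  structural_zero <- stats::rbinom(n, 1, pi) == 1
  count <- stats::rnbinom(n, size = p$shape, mu = mu)
  count[structural_zero] <- 0L

  out <- data.frame(
    year = p$first_year + grid$yr - 1,
    day_of_year = doy,
    bay = sprintf("bay%02d", bay_of_site[grid$site]),
    site = sprintf("bay%02d_s%02d", bay_of_site[grid$site], grid$site),
    count = as.integer(count),
    temperature = temp,
    ssb = ssb
  )
  class(out) <- c("seine_catch", "data.frame")
  attr(out, "params") <- p
  out
}

#' Simulate a random-walk latent trend scaled to unit variance
#'
#' @param n_years Series length.
#' @param seed Integer seed.
#' @return Numeric vector, mean 0 and SD 1 over the series.
#' @export
simulate_latent_trend <- function(n_years, seed = 1) {
  check_count(n_years, "n_years", min = 2)
  set.seed(substream_seed(seed, "latent-trend"))
  x <- cumsum(stats::rnorm(n_years))
  as.numeric(scale(x))
}

#' Simulate a multi-survey annual index panel around one latent trend
#'
#' Each series is `loading * trend` plus independent Gaussian observation
#' noise, with entries removed completely at random at the stated per-series
#' missingness rate. Values are on the log-index scale.
#'
#' @param trend Latent annual series (e.g. from [simulate_latent_trend()]).
#' @param loadings Numeric vector, one loading per survey series.
#' @param obs_sd Numeric vector of observation SDs, same length as `loadings`.
#' @param missing_frac Per-series missingness fractions in \[0, 1).
#' @param seed Integer seed.
#' @param years Optional calendar years.
#' @return Long data.frame (`year`, `series_id`, `value`) with `NA` values
#'   marking missing entries.
#' @export
simulate_survey_panel <- function(trend, loadings, obs_sd,
                                  missing_frac = rep(0, length(loadings)),
                                  seed = 1, years = seq_along(trend)) {
  stopifnot(length(loadings) == length(obs_sd),
            length(loadings) == length(missing_frac))
  if (any(obs_sd < 0)) stop("'obs_sd' must be non-negative")
  if (any(missing_frac < 0 | missing_frac >= 1)) {
    stop("'missing_frac' must be in [0, 1)")
  }
  set.seed(substream_seed(seed, "survey-panel"))
  n <- length(trend)
  out <- do.call(rbind, lapply(seq_along(loadings), function(i) {
    v <- loadings[i] * trend + stats::rnorm(n, 0, obs_sd[i])
    miss <- stats::runif(n) < missing_frac[i]
    v[miss] <- NA_real_
    data.frame(year = years, series_id = sprintf("series%d", i), value = v)
  }))
  rownames(out) <- NULL
  out
}
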