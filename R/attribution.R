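# Attribution statistics: standardized anomalies, empirical exceedance
# probabilities, and the Fraction of Attributable Risk (FAR),
#   FAR = 1 - P(anomaly | preindustrial) / P(anomaly | current),
# with probabilities measured as empirical exceedance proportions.

#' Standardize a raw annual series into anomalies
#'
#' The anomaly for each year is the raw value minus the mean over the
#' centering window, divided by the SD over the scaling window (the two
#' windows may differ, e.g. a recent-period mean against a century-scale SD).
#'
#' @param raw_series data.frame with columns `year` and `value`.
#' @param center_window Length-2 year range used for the mean.
#' @param scale_window Length-2 year range used for the SD.
#' @return data.frame (`anomaly_series`) with columns `year`, `value`
#'   (dimensionless standardized anomaly).
#' @export
standardize_anomalies <- function(raw_series,
                                  center_window = range(raw_series$year),
                                  scale_window = range(raw_series$year)) {
  stopifnot(is.data.frame(raw_series),
            all(c("year", "value") %in% names(raw_series)))
  if (any(diff(raw_series$year) <= 0)) stop("years must be strictly increasing")
  in_win <- function(w) raw_series$year >= w[1] & raw_series$year <= w[2]
  ci <- in_win(center_window); si <- in_win(scale_window)
  if (!any(ci)) stop("centering window does not overlap the series")
  if (!any(si)) stop("scaling window does not overlap the series")
  s <- stats::sd(raw_series$value[si])
  if (!is.finite(s) || s == 0) {
    stop(sprintf("scaling window [%s, %s] has zero SD",
                 scale_window[1], scale_window[2]))
  }
  data.frame(year = raw_series$year,
             value = (raw_series$value - mean(raw_series$value[ci])) / s)
}

#' Empirical exceedance probability
#'
#' Proportion of a reference sample greater than or equal to the focal
#' anomaly (ties count as exceedances).
#'
#' @param anomaly Focal anomaly value.
#' @param sample Non-empty numeric reference sample.
#' @return Probability in \[0, 1\].
#' @export
exceedance_probability <- function(anomaly, sample) {
  if (length(sample) == 0) stop("reference sample is empty")
  stopifnot(is.finite(anomaly), all(is.finite(sample)))
  sum(sample >= anomaly) / length(sample)
}

#' Fraction of Attributable Risk for one anomaly
#'
#' `1 - p_pre / p_cur` with both probabilities computed by
#' [exceedance_probability()], then clamped into `[clamp_lo, clamp_hi]`.
#' The upper clamp resets FAR values of 1 (anomalies never reached in the
#' preindustrial sample) to 0.9999 so downstream beta-distribution models
#' remain defined; the lower clamp keeps values inside the open unit
#' interval symmetrically.
#'
#' @param anomaly Focal anomaly.
#' @param preindustrial_sample Anomalies from the preindustrial realization.
#' @param current_sample Anomalies defining current-climate probability;
#'   must contain values >= `anomaly` (include the focal year in its own
#'   reference sample to guarantee this).
#' @param clamp_lo,clamp_hi Clamping bounds (defaults 1e-4 and 0.9999).
#' @return FAR value in `[clamp_lo, clamp_hi]`.
#' @export
compute_far <- function(anomaly, preindustrial_sample, current_sample,
                        clamp_lo = 1e-4, clamp_hi = 0.9999) {
  p_pre <- exceedance_probability(anomaly, preindustrial_sample)
  p_cur <- exceedance_probability(anomaly, current_sample)
  if (p_cur == 0) {
    stop("current-climate probability is 0; include the focal year in its own reference sample")
  }
  min(max(1 - p_pre / p_cur, clamp_lo), clamp_hi)
}

#' Per-year, per-model FAR table
#'
#' For the hindcast period the focal anomalies are the observed series and
#' the current-climate sample is the full observed window (so every focal
#' year is a member of its own reference sample); for the projection period
#' the focal anomalies are each model's projection realization, compared
#' against that same realization. In both cases the preindustrial
#' probability is computed against each model's own preindustrial
#' realization, preserving the between-model spread that the ensemble model
#' later absorbs as a random effect.
#'
#' @param ensemble A `climate_ensemble` (see [simulate_climate()] or
#'   [read_climate_ensemble()]).
#' @param period `"hindcast"` or `"projection"`.
#' @param clamp_lo,clamp_hi Passed to [compute_far()].
#' @return data.frame (`far_table`) with columns `year`, `model_id`, `far`,
#'   `p_pre`, `p_cur`.
#' @export
build_far_table <- function(ensemble, period = c("hindcast", "projection"),
                            clamp_lo = 1e-4, clamp_hi = 0.9999) {
  period <- match.arg(period)
  stopifnot(!is.null(ensemble$observed), length(ensemble$models) >= 1)
  rows <- lapply(ensemble$models, function(m) {
    if (is.null(m$preindustrial) || nrow(m$preindustrial) < 2) {
      stop(sprintf("model '%s' is missing its preindustrial realization",
                   m$model_id))
    }
    cur <- if (period == "hindcast") ensemble$observed else m$projection
    if (is.null(cur)) {
      stop(sprintf("model '%s' is missing its projection realization",
                   m$model_id))
    }
    pre <- m$preindustrial$value
    data.frame(
      year = cur$year,
      model_id = m$model_id,
      far = vapply(cur$value, compute_far, numeric(1),
                   preindustrial_sample = pre, current_sample = cur$value,
                   clamp_lo = clamp_lo, clamp_hi = clamp_hi),
      p_pre = vapply(cur$value, exceedance_probability, numeric(1),
                     sample = pre),
      p_cur = vapply(cur$value, exceedance_probability, numeric(1),
                     sample = cur$value)
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  n_clamped <- sum(out$far %in% c(clamp_lo, clamp_hi))
  if (n_clamped > 0) {
    message(sprintf("build_far_table: %d of %d FAR values clamped into [%g, %g]",
                    n_clamped, nrow(out), clamp_lo, clamp_hi))
  }
  class(out) <- c("far_table", "data.frame")
  out
}

#' Bayesian ensemble model for annual FAR
#'
#' Beta regression on the per-year, per-model FAR values: the mean has a
#' logit link with fixed year effects and a climate-model random intercept
#' (absorbing the between-model spread), and the precision is shared across
#' years. Priors: Normal(0, 3) on logit-scale year effects (wide enough to reach the 0.9999 clamp on the logit scale), half-Normal(0, 1)
#' on the model random-effect SD, half-Normal(0, 100) on the precision.
#'
#' @param table A `far_table` from [build_far_table()] (all FAR strictly
#'   inside (0, 1); values outside indicate missing clamping upstream).
#' @param chains,iter,burn,adapt MCMC settings (post-burn iterations per
#'   chain = `iter`).
#' @param seed Integer seed.
#' @return A `far_estimate`: data.frame with per-year posterior `mean`, `se`
#'   (posterior SD) and equal-tailed 80/90/95% interval bounds, with the
#'   posterior draws of the year means in `attr(, "draws")` and convergence
#'   diagnostics in `attr(, "convergence")`.
#' @export
fit_far_model <- function(table, chains = 2, iter = 2500, burn = 1000,
                          adapt = 500, seed = 1) {
  stopifnot(all(c("year", "model_id", "far") %in% names(table)))
  if (any(table$far <= 0 | table$far >= 1)) {
    stop("FAR values must lie strictly in (0, 1); clamp them first (see compute_far)")
  }
  years <- sort(unique(table$year))
  models <- unique(table$model_id)
  jd <- list(
    y = as.numeric(table$far),
    year = match(table$year, years),
    mod = match(table$model_id, models),
    N = nrow(table), NY = length(years), NM = length(models)
  )
  ms <- "
  model {
    for (i in 1:N) {
      y[i] ~ dbeta(mu[i] * phi, (1 - mu[i]) * phi)
      logit(mu[i]) <- a[year[i]] + u[mod[i]]
    }
    for (t in 1:NY) {
      a[t] ~ dnorm(0, 0.1111111)   # SD 3: must reach logit(0.9999) = 9.2
      far_mean[t] <- ilogit(a[t])
    }
    # sweep-centered model effects: removes the additive ridge with the
    # year effects while keeping the exchangeable between-model spread
    for (j in 1:NM) {
      u_raw[j] ~ dnorm(0, tau_u)
      u[j] <- u_raw[j] - mean(u_raw[])
    }
    sd_u ~ dnorm(0, 1) T(0,)
    tau_u <- pow(sd_u + 1.0E-6, -2)
    phi ~ dnorm(0, 1.0E-4) T(0,)
  }"
  fit <- run_jags(ms, jd, monitor = c("far_mean", "sd_u", "phi"),
                  chains = chains, adapt = adapt, burn = burn, iter = iter,
                  seed = seed)
  conv <- check_convergence(fit$draws)
  if (!conv$pass) {
    far_warn("fit_far_model: convergence diagnostics failed (max Rhat %.3f, min ESS %.0f)",
             conv$max_rhat, conv$min_ess)
  }
  dm <- flatten_draws(fit$draws)
  fm <- indexed_cols(dm, "far_mean")
  summ <- data.frame(
    year = years,
    mean = colMeans(fm),
    se = apply(fm, 2, stats::sd),
    lo80 = apply(fm, 2, function(x) equal_tailed(x, 0.80)[1]),
    hi80 = apply(fm, 2, function(x) equal_tailed(x, 0.80)[2]),
    lo90 = apply(fm, 2, function(x) equal_tailed(x, 0.90)[1]),
    hi90 = apply(fm, 2, function(x) equal_tailed(x, 0.90)[2]),
    lo95 = apply(fm, 2, function(x) equal_tailed(x, 0.95)[1]),
    hi95 = apply(fm, 2, function(x) equal_tailed(x, 0.95)[2])
  )
  rownames(summ) <- NULL
  attr(summ, "draws") <- fm
  attr(summ, "convergence") <- conv
  class(summ) <- c("far_estimate", "data.frame")
  summ
}
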