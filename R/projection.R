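# Backward- vs forward-looking recruitment: posterior predictive
# distributions of recruitment under historical observed FAR and under
# scenario-projected FAR, pooled by decade, with percent declines of the
# median reported in original (back-transformed) units.

#' Posterior predictive recruitment sample for a period
#'
#' For each posterior draw of the fitted recruitment-FAR model: sample a
#' year (equal weights) from the period, draw that year's latent FAR from
#' its posterior summary (Normal truncated to (0, 1)), evaluate the spline
#' mean, and add residual noise. Pooling across years gives the period's
#' predictive recruitment distribution on the standardized log-anomaly
#' scale.
#'
#' @param fit A `recruit_fit` (the measurement-error variant is the
#'   intended input, since its predictions carry FAR uncertainty).
#' @param far_estimates A `far_estimate` (per-year `mean` and `se`).
#' @param period_years Years defining the period; must all be covered by
#'   `far_estimates`.
#' @param include_resid Include residual (process) noise in the draws
#'   (default TRUE: distributional comparison, not mean comparison).
#' @param n_per_draw Predictive values sampled per posterior draw.
#' @param seed Optional integer seed for the predictive sampling.
#' @return Numeric vector of predictive draws (log-anomaly scale), with the
#'   draws x `n_per_draw` matrix in `attr(, "by_draw")`.
#' @export
predict_distribution <- function(fit, far_estimates, period_years,
                                 include_resid = TRUE, n_per_draw = 20,
                                 seed = NULL) {
  stopifnot(inherits(fit, "recruit_fit"), length(period_years) > 0)
  if (!is.null(seed)) set.seed(substream_seed(seed, "predict-distribution"))
  miss <- setdiff(period_years, far_estimates$year)
  if (length(miss)) {
    stop("period years outside FAR coverage: ", paste(miss, collapse = ", "))
  }
  idx <- match(period_years, far_estimates$year)
  fm <- far_estimates$mean[idx]
  fs <- pmax(far_estimates$se[idx], 1e-6)
  S <- nrow(fit$coef)
  yr <- matrix(sample.int(length(period_years), S * n_per_draw, replace = TRUE),
               S, n_per_draw)
  far <- rtruncnorm_mat(matrix(fm[yr], S, n_per_draw),
                        matrix(fs[yr], S, n_per_draw), 1e-4, 0.9999)
  eta <- matrix(NA_real_, S, n_per_draw)
  k_main <- fit$basis$k
  for (j in seq_len(n_per_draw)) {
    X <- tps_design(fit$basis, far[, j])
    eta[, j] <- rowSums(X * fit$coef[, seq_len(k_main), drop = FALSE])
  }
  if (include_resid) {
    eta <- eta + stats::rnorm(length(eta), 0, fit$sigma)
  }
  out <- as.numeric(eta)
  attr(out, "by_draw") <- eta
  out
}

# elementwise truncated-normal draws via inverse-CDF
rtruncnorm_mat <- function(mean, sd, lo, hi) {
  pl <- stats::pnorm(lo, mean, sd)
  ph <- stats::pnorm(hi, mean, sd)
  u <- stats::runif(length(mean), pl, ph)
  m <- stats::qnorm(u, mean, sd)
  dim(m) <- dim(mean)
  pmin(pmax(m, lo), hi)
}

#' Percent decline of median recruitment, in original units
#'
#' Both samples are back-transformed from the standardized log-anomaly
#' scale (invert the zero-mean/unit-variance standardization with the
#' recorded constants, then exponentiate), medians are taken in original
#' units, and the decline is `100 * (1 - median_period / median_historical)`.
#' An increase yields a negative value; the sign is never clamped.
#'
#' @param historical_sample,period_sample Predictive samples on the
#'   log-anomaly scale.
#' @param center,scale Standardization constants of the recruitment series
#'   (log-recruitment mean and SD over the reference years).
#' @return Percent decline (scalar).
#' @export
percent_decline <- function(historical_sample, period_sample,
                            center = 0, scale = 1) {
  mh <- stats::median(exp(unstandardize(historical_sample, center, scale)))
  mp <- stats::median(exp(unstandardize(period_sample, center, scale)))
  if (mh == 0) stop("historical median recruitment is zero")
  100 * (1 - mp / mh)
}

#' FAR posterior series for the projection horizon
#'
#' Builds the projection-period FAR table (each model's projection
#' realization against its own preindustrial realization) and fits the
#' Bayesian beta ensemble model, giving the per-year FAR posterior with
#' 80/90/95% ribbons over the projection horizon.
#'
#' @param ensemble A `climate_ensemble` with projection realizations for
#'   every model.
#' @param ... Passed to [fit_far_model()] (chains, iter, seed, ...).
#' @return A `far_estimate` over the projection years.
#' @export
far_projection_series <- function(ensemble, ...) {
  fit_far_model(build_far_table(ensemble, period = "projection"), ...)
}

#' Summarize predicted recruitment by period, with percent declines
#'
#' Runs [predict_distribution()] for a historical period and a set of
#' forward periods, and summarizes each: median and 95% CI on both the
#' log-anomaly and original scales, and the percent decline of the median
#' (original units) relative to the historical period. Decline uncertainty
#' is computed per posterior draw (each draw yields a median for every
#' period, hence one decline value).
#'
#' @param fit A `recruit_fit`.
#' @param far_hist `far_estimate` covering the historical years.
#' @param far_proj `far_estimate` covering the projection years.
#' @param periods Named list of year vectors; the first entry is the
#'   historical reference (its FAR comes from `far_hist`, the others from
#'   `far_proj`).
#' @param center,scale Standardization constants of the recruitment series.
#' @param n_per_draw Predictive values per posterior draw and period.
#' @param seed Optional integer seed for the predictive sampling.
#' @return A `projection_summary` data.frame: `period`, `median_log`,
#'   `lo95_log`, `hi95_log`, `median`, `lo95`, `hi95` (original units),
#'   `pct_decline_vs_historical`, `pct_lo95`, `pct_hi95`.
#' @export
summarize_projection <- function(fit, far_hist, far_proj, periods,
                                 center = 0, scale = 1, n_per_draw = 40,
                                 seed = NULL) {
  stopifnot(length(periods) >= 2, !is.null(names(periods)))
  samples <- lapply(seq_along(periods), function(i) {
    fe <- if (i == 1) far_hist else far_proj
    predict_distribution(fit, fe, periods[[i]], n_per_draw = n_per_draw,
                         seed = if (is.null(seed)) NULL else seed + i)
  })
  names(samples) <- names(periods)
  med_by_draw <- lapply(samples, function(s) {
    apply(exp(unstandardize(attr(s, "by_draw"), center, scale)), 1,
          stats::median)
  })
  hist_med <- med_by_draw[[1]]
  rows <- lapply(seq_along(periods), function(i) {
    s <- samples[[i]]
    orig <- exp(unstandardize(s, center, scale))
    dec <- 100 * (1 - med_by_draw[[i]] / hist_med)
    data.frame(
      period = names(periods)[i],
      median_log = stats::median(s),
      lo95_log = equal_tailed(s, 0.95)[1],
      hi95_log = equal_tailed(s, 0.95)[2],
      median = stats::median(orig),
      lo95 = equal_tailed(orig, 0.95)[1],
      hi95 = equal_tailed(orig, 0.95)[2],
      pct_decline_vs_historical = stats::median(dec),
      pct_lo95 = equal_tailed(dec, 0.95)[1],
      pct_hi95 = equal_tailed(dec, 0.95)[2]
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("projection_summary", "data.frame")
  out
}
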