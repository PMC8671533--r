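# Bayesian penalized-spline models of standardized log recruitment on FAR,
# with an optional latent-variable treatment of FAR measurement error and
# an optional spawning-stock-biomass smooth. Smoothing penalties act as
# hierarchical Gaussian priors on the penalized basis coefficients, with a
# half-Normal prior on the smoothing SD.

align_recruit_far <- function(recruitment, far) {
  if (is.data.frame(recruitment)) {
    y <- recruitment$log_anomaly; ry <- recruitment$year
  } else {
    y <- as.numeric(recruitment); ry <- seq_along(y)
  }
  if (is.data.frame(far)) {
    fx <- if ("mean" %in% names(far)) far$mean else far$far
    fy <- far$year
  } else {
    fx <- as.numeric(far); fy <- ry
  }
  common <- intersect(ry, fy)
  if (length(common) < 5) stop("too few aligned years between recruitment and FAR")
  list(year = common,
       y = y[match(common, ry)],
       x = fx[match(common, fy)])
}

new_recruit_fit <- function(coefs, sigma_draws, basis, x, y, years, fitted,
                            log_lik, conv, me, extra = list()) {
  loo <- psis_loo(log_lik)
  r2 <- apply(fitted, 1, stats::var) / (apply(fitted, 1, stats::var) + sigma_draws^2)
  out <- c(list(coef = coefs, sigma = sigma_draws, basis = basis,
                x = x, y = y, years = years, fitted = fitted,
                log_lik = log_lik, loo = loo, looic = loo$looic,
                r2 = r2, convergence = conv, me = me), extra)
  class(out) <- "recruit_fit"
  out
}

#' Bayesian spline model of recruitment on FAR
#'
#' Fits standardized log-recruitment anomalies as a penalized thin-plate
#' spline function of FAR (k = 3 or 5 basis functions), optionally with an
#' additional spawning-stock-biomass smooth. Gaussian likelihood; priors:
#' Normal(0, 2) on unpenalized coefficients, hierarchical Normal with
#' half-Normal(0, 1) smoothing SD on penalized coefficients, half-Normal(0, 1)
#' residual SD (the response is standardized).
#'
#' @param recruitment data.frame (`year`, `log_anomaly`) or numeric vector.
#' @param far Per-year FAR values: data.frame (`year`, `mean` or `far`) or
#'   numeric vector aligned with `recruitment`.
#' @param extra Optional list with element `ssb` (numeric, aligned years)
#'   entered as a second k = 3 smooth.
#' @param k Basis functions for the FAR smooth: 3 or 5.
#' @param chains,iter,burn,adapt,seed MCMC settings.
#' @return A `recruit_fit`: posterior coefficient and sigma draws, fitted
#'   values, pointwise log-likelihood, PSIS-LOO (`looic`), Bayesian R-squared
#'   draws (`r2`), and the basis needed to predict at new FAR values.
#' @export
fit_far_gam <- function(recruitment, far, extra = NULL, k = 3,
                        chains = 2, iter = 1500, burn = 500, adapt = 500,
                        seed = 1) {
  al <- align_recruit_far(recruitment, far)
  if (k > length(al$y) - 2) stop("'k' exceeds n - 2")
  basis <- tps_basis(al$x, k = k)
  X <- tps_design(basis, al$x)
  pen_idx <- seq(3, ncol(X))
  extra_basis <- NULL
  if (!is.null(extra$ssb)) {
    stopifnot(length(extra$ssb) == length(al$y))
    extra_basis <- tps_basis(extra$ssb, k = 3)
    Xe <- tps_design(extra_basis, extra$ssb)[, -1, drop = FALSE]  # no 2nd intercept
    X <- cbind(X, Xe)
  }
  np <- ncol(X)
  n_pen <- k - 2
  pen <- basis$penalty
  ms <- sprintf("
  model {
    for (i in 1:N) {
      y[i] ~ dnorm(eta[i], tau)
      eta[i] <- inprod(X[i,], b[])
    }
    b[1] ~ dnorm(0, 0.25)
    b[2] ~ dnorm(0, 0.25)
    for (j in 1:NPEN) { b[2 + j] ~ dnorm(0, pen[j] * tau_s) }
    %s
    sd_s ~ dnorm(0, 1) T(0,)
    tau_s <- pow(sd_s + 1.0E-4, -2)
    sigma ~ dnorm(0, 1) T(0,)
    tau <- pow(sigma + 1.0E-6, -2)
  }",
  if (!is.null(extra_basis)) "
    b[2 + NPEN + 1] ~ dnorm(0, 0.25)
    b[2 + NPEN + 2] ~ dnorm(0, pen_e[1] * tau_se)
    sd_se ~ dnorm(0, 1) T(0,)
    tau_se <- pow(sd_se + 1.0E-4, -2)" else "")
  jd <- list(y = al$y, N = length(al$y), X = X, NPEN = n_pen, pen = pen)
  if (!is.null(extra_basis)) jd$pen_e <- extra_basis$penalty
  fit <- run_jags(ms, jd, monitor = c("b", "sigma", "sd_s"),
                  chains = chains, adapt = adapt, burn = burn, iter = iter,
                  seed = seed)
  conv <- check_convergence(fit$draws, ess_min = 400)
  if (!conv$pass) {
    far_warn("fit_far_gam: convergence diagnostics failed (max Rhat %.3f, min ESS %.0f)",
             conv$max_rhat, conv$min_ess)
  }
  dm <- flatten_draws(fit$draws)
  coefs <- indexed_cols(dm, "b")
  sigma_draws <- dm[, "sigma"]
  fitted <- coefs %*% t(X)
  log_lik <- matrix(stats::dnorm(rep(al$y, each = nrow(fitted)),
                                 mean = fitted, sd = sigma_draws, log = TRUE),
                    nrow = nrow(fitted))
  new_recruit_fit(coefs, sigma_draws, basis, al$x, al$y, al$year, fitted,
                  log_lik, conv, me = FALSE,
                  extra = list(extra_basis = extra_basis, k = k))
}

#' Recruitment-FAR spline with FAR measurement error
#'
#' As [fit_far_gam()], but each year's FAR enters as a latent variable with
#' a Gaussian measurement model (SD = that year's posterior SE from the
#' ensemble FAR model), truncated to (0, 1). The spline is applied to the
#' latent FAR, so covariate uncertainty propagates into the fitted curve
#' and all predictions.
#'
#' @param recruitment data.frame (`year`, `log_anomaly`) or numeric vector.
#' @param far_mean,far_se Per-year FAR posterior means and SEs: data.frames
#'   (`year`, value column) or numeric vectors. A `far_estimate` may be
#'   passed as `far_mean` with `far_se = NULL`.
#' @param k Basis functions (3 or 5).
#' @param chains,iter,burn,adapt,seed MCMC settings.
#' @return A `recruit_fit` with `me = TRUE` and latent-FAR draws in
#'   `$far_latent`.
#' @export
fit_far_gam_me <- function(recruitment, far_mean, far_se = NULL, k = 3,
                           chains = 2, iter = 1500, burn = 500, adapt = 500,
                           seed = 1) {
  if (inherits(far_mean, "far_estimate") && is.null(far_se)) {
    far_se <- data.frame(year = far_mean$year, se = far_mean$se)
  }
  al <- align_recruit_far(recruitment, far_mean)
  se <- if (is.data.frame(far_se)) {
    fs <- if ("se" %in% names(far_se)) far_se$se else far_se[[2]]
    fs[match(al$year, far_se$year)]
  } else {
    as.numeric(far_se)
  }
  if (length(se) != length(al$y) || anyNA(se)) {
    stop("'far_se' must provide one SE per aligned year")
  }
  if (any(se < 0)) stop("'far_se' must be non-negative")
  if (all(se == 0)) {
    message("all FAR standard errors are zero; fitting the error-free model")
    return(fit_far_gam(recruitment, far_mean, k = k, chains = chains,
                       iter = iter, burn = burn, adapt = adapt, seed = seed))
  }
  se <- pmax(se, 1e-4)
  if (k > length(al$y) - 2) stop("'k' exceeds n - 2")
  basis <- tps_basis(al$x, k = k)
  n_pen <- k - 2
  ms <- "
  model {
    for (t in 1:N) {
      farl[t] ~ dnorm(far_mean[t], prec_far[t]) T(1.0E-4, 0.9999)
      z[t] <- (farl[t] - xc) / xs
      for (j in 1:NK) { e[t, j] <- pow(abs(z[t] - knot[j]), 3) }
      for (q in 1:NPEN) {
        phi[t, q] <- (inprod(e[t, ], W[, q]) - phic[q]) / phis[q]
      }
      eta[t] <- b[1] + b[2] * z[t] + inprod(phi[t, ], bp[])
      y[t] ~ dnorm(eta[t], tau)
    }
    b[1] ~ dnorm(0, 0.25)
    b[2] ~ dnorm(0, 0.25)
    for (q in 1:NPEN) { bp[q] ~ dnorm(0, pen[q] * tau_s) }
    sd_s ~ dnorm(0, 1) T(0,)
    tau_s <- pow(sd_s + 1.0E-4, -2)
    sigma ~ dnorm(0, 1) T(0,)
    tau <- pow(sigma + 1.0E-6, -2)
  }"
  jd <- list(y = al$y, N = length(al$y), far_mean = al$x,
             prec_far = 1 / se^2, knot = basis$knots,
             NK = length(basis$knots), W = basis$W,
             phic = basis$phi_center, phis = basis$phi_scale,
             NPEN = n_pen, pen = basis$penalty,
             xc = basis$x_center, xs = basis$x_scale)
  fit <- run_jags(ms, jd, monitor = c("b", "bp", "sigma", "sd_s", "farl"),
                  chains = chains, adapt = adapt, burn = burn, iter = iter,
                  seed = seed,
                  inits = function(c) list(farl = pmin(pmax(al$x, 1e-3), 0.999)))
  conv <- check_convergence(fit$draws, ess_min = 400)
  if (!conv$pass) {
    far_warn("fit_far_gam_me: convergence diagnostics failed (max Rhat %.3f, min ESS %.0f)",
             conv$max_rhat, conv$min_ess)
  }
  dm <- flatten_draws(fit$draws)
  coefs <- cbind(indexed_cols(dm, "b"), indexed_cols(dm, "bp"))
  sigma_draws <- dm[, "sigma"]
  farl <- indexed_cols(dm, "farl")
  # fitted values at the latent FAR, per draw
  S <- nrow(coefs); n <- length(al$y)
  fitted <- matrix(NA_real_, S, n)
  for (t in seq_len(n)) {
    Xt <- tps_design(basis, farl[, t])       # S x k, rowwise per-draw design
    fitted[, t] <- rowSums(Xt * coefs)
  }
  log_lik <- matrix(stats::dnorm(rep(al$y, each = S), mean = fitted,
                                 sd = sigma_draws, log = TRUE), nrow = S)
  new_recruit_fit(coefs, sigma_draws, basis, al$x, al$y, al$year, fitted,
                  log_lik, conv, me = TRUE,
                  extra = list(far_latent = farl, far_se = se, k = k))
}

#' Posterior mean-curve draws at new FAR values
#'
#' @param object A `recruit_fit`.
#' @param far_new FAR values at which to evaluate the fitted curve.
#' @param ... Unused.
#' @return Draws x length(far_new) matrix of the posterior mean curve
#'   (log-anomaly scale, no residual noise).
#' @export
predict.recruit_fit <- function(object, far_new, ...) {
  X <- tps_design(object$basis, far_new)
  k_main <- ncol(X)
  object$coef[, seq_len(k_main), drop = FALSE] %*% t(X)
}

#' Bayesian R-squared of a fit
#'
#' Per-draw ratio var(fitted) / (var(fitted) + residual variance), always
#' in \[0, 1\].
#'
#' @param fit A `recruit_fit` (or any object with draws x n `fitted` matrix
#'   and `sigma` draws).
#' @return List with `draws`, `median`, and `ci95`.
#' @export
bayes_r2 <- function(fit) {
  fitted <- fit$fitted; sigma <- fit$sigma
  if (is.null(fitted) || is.null(sigma) || nrow(fitted) < 2) {
    stop("bayes_r2 needs multiple posterior draws of fitted values and residual SD")
  }
  vf <- apply(fitted, 1, stats::var)
  draws <- vf / (vf + sigma^2)
  list(draws = draws, median = stats::median(draws),
       ci95 = equal_tailed(draws, 0.95))
}

#' Classify recruitment failure
#'
#' A year is a failure when its standardized log-recruitment anomaly is
#' strictly below -1.
#'
#' @param log_anomaly Numeric vector of standardized log anomalies.
#' @return Logical vector.
#' @export
classify_failure <- function(log_anomaly) {
  log_anomaly < -1
}

#' Bridge recent recruitment from a survey index
#'
#' Ordinary linear regression of assessment log-recruitment anomalies on a
#' survey-derived annual index over their overlap years, used to predict
#' the most recent (assessment-poor) year classes. Predictions carry the
#' closed-form OLS predictive standard error.
#'
#' @param seine_index data.frame (`year`, `estimate`): annual index (e.g.
#'   log posterior-median CPUE from [annual_index()]).
#' @param assessment data.frame (`year`, `log_anomaly`): assessment
#'   recruitment series.
#' @param overlap Length-2 year range used for fitting.
#' @param predict_years Years to predict (disjoint from `overlap`).
#' @return data.frame (`year`, `log_anomaly`, `source`, `pred_se`) merging
#'   the assessment series (source `"assessment"`) with predictions
#'   (source `"seine_bridge"`); the fitted `lm` is in `attr(, "fit")`.
#' @export
bridge_recent_recruitment <- function(seine_index, assessment, overlap,
                                      predict_years) {
  ov_years <- intersect(seine_index$year[seine_index$year >= overlap[1] &
                                           seine_index$year <= overlap[2]],
                        assessment$year)
  if (length(ov_years) < 3) stop("need at least 3 overlap years")
  if (length(intersect(ov_years, predict_years)) > 0) {
    stop("'predict_years' must be disjoint from the overlap window")
  }
  df <- data.frame(
    rec = assessment$log_anomaly[match(ov_years, assessment$year)],
    idx = seine_index$estimate[match(ov_years, seine_index$year)]
  )
  fit <- stats::lm(rec ~ idx, data = df)
  keep <- !assessment$year %in% predict_years
  out <- data.frame(year = assessment$year[keep],
                    log_anomaly = assessment$log_anomaly[keep],
                    source = "assessment", pred_se = 0)
  if (length(predict_years) > 0) {
    newd <- data.frame(idx = seine_index$estimate[match(predict_years,
                                                        seine_index$year)])
    if (anyNA(newd$idx)) stop("survey index missing for some prediction years")
    pr <- stats::predict(fit, newdata = newd, se.fit = TRUE)
    pred_se <- sqrt(pr$se.fit^2 + summary(fit)$sigma^2)
    out <- rbind(out,
      data.frame(year = predict_years, log_anomaly = as.numeric(pr$fit),
                 source = "seine_bridge", pred_se = pred_se))
  }
  out <- out[order(out$year), ]
  rownames(out) <- NULL
  attr(out, "fit") <- fit
  out
}
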