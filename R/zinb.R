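# Bayesian zero-inflated negative binomial models for set-level seine
# counts. Mixture likelihood: with probability pi (logit-linear) a set is a
# structural zero; otherwise the count is negative binomial with log-linear
# mean mu and shape r (log link). Continuous covariates are standardized
# internally; bay and site-within-bay random intercepts (site drawn around
# its bay mean) enter both model parts. Priors: Normal(0, 2) fixed effects,
# half-Normal(0, 1) random-effect SDs, Normal(0, 1) on log shape.

zinb_model_string <- function(zero_inflation, year_effect, has_covars,
                              pin_zero = FALSE) {
  # hierarchically centered nested intercepts: site ~ N(bay, sd_site),
  # bay ~ N(global intercept, sd_bay); the site term carries the intercept,
  # which keeps the sampler graph local and avoids an additive ridge
  count_terms <- paste(c(if (has_covars) "inprod(Xc[i,], bc[])",
                         if (year_effect) "ac[yr[i]]",
                         "uc[site[i]]"), collapse = " + ")
  zero_terms <- paste(c(if (has_covars) "inprod(Xz[i,], bz[])",
                        if (year_effect) "az[yr[i]]",
                        "uz[site[i]]"), collapse = " + ")
  lik <- if (zero_inflation) sprintf("
      %s
      log(mu[i]) <- %s
      p[i] <- r / (r + mu[i])
      lognb[i] <- loggam(y[i] + r) - loggam(r) - logfact(y[i]) +
                  r * log(p[i]) + y[i] * log(1 - p[i])
      ll[i] <- z0[i] * log(pz[i] + (1 - pz[i]) * exp(lognb[i])) +
               (1 - z0[i]) * (log(1 - pz[i]) + lognb[i])
      zeros[i] ~ dpois(BIG - ll[i])",
      if (pin_zero) "pz[i] <- 1.0E-7"
      else sprintf("logit(pz[i]) <- %s", zero_terms),
      count_terms)
  else sprintf("
      log(mu[i]) <- %s
      p[i] <- r / (r + mu[i])
      y[i] ~ dnegbin(p[i], r)", count_terms)

  zero_priors <- if (zero_inflation && !pin_zero) paste(c(
    "bz0 ~ dnorm(0, 0.25)",
    if (has_covars) "for (j in 1:NC) { bz[j] ~ dnorm(0, 0.25) }",
    if (year_effect) "az[1] <- 0
    for (t in 2:NY) { az[t] ~ dnorm(0, 0.25) }",
    "for (s in 1:NS) { uz[s] ~ dnorm(vz[bay_of_site[s]], tau_sz) }
    for (b in 1:NB) { vz[b] ~ dnorm(bz0, tau_bz) }
    sd_sz ~ dnorm(0, 1) T(0,) ; tau_sz <- pow(sd_sz + 1.0E-4, -2)
    sd_bz ~ dnorm(0, 1) T(0,) ; tau_bz <- pow(sd_bz + 1.0E-4, -2)"),
    collapse = "\n    ") else ""

  sprintf("
  model {
    for (i in 1:N) {%s
    }
    bc0 ~ dnorm(0, 0.25)
    %s
    %s
    for (s in 1:NS) { uc[s] ~ dnorm(vc[bay_of_site[s]], tau_sc) }
    for (b in 1:NB) { vc[b] ~ dnorm(bc0, tau_bc) }
    sd_sc ~ dnorm(0, 1) T(0,) ; tau_sc <- pow(sd_sc + 1.0E-4, -2)
    sd_bc ~ dnorm(0, 1) T(0,) ; tau_bc <- pow(sd_bc + 1.0E-4, -2)
    lr ~ dnorm(0, 1)
    r <- exp(lr)
  }",
  lik,
  paste(c(if (has_covars) "for (j in 1:NC) { bc[j] ~ dnorm(0, 0.25) }",
          if (year_effect) "ac[1] <- 0
    for (t in 2:NY) { ac[t] ~ dnorm(0, 0.25) }"), collapse = "\n    "),
  zero_priors)
}

#' Fit a Bayesian zero-inflated negative binomial seine-catch model
#'
#' @param data A `seine_catch` data.frame (columns `year`, `day_of_year`,
#'   `bay`, `site`, `count`, and any covariates used).
#' @param covariates Character subset of
#'   `c("temperature", "day_of_year", "ssb")`, standardized internally and
#'   entered in both model parts.
#' @param year_effect Enter year as a categorical fixed effect (first year
#'   as reference), as used for annual abundance indices.
#' @param zero_inflation If `FALSE`, fit a plain negative binomial.
#' @param pin_zero If `TRUE`, keep the ZINB likelihood but pin the
#'   zero-inflation probability to (effectively) zero; useful for verifying
#'   that the degenerate ZINB matches the plain NB fit.
#' @param chains,iter,burn,adapt,seed MCMC settings.
#' @return A `zinb_fit`: flattened posterior draws, the draws x observations
#'   pointwise `log_lik` matrix, coefficient summaries on the original
#'   covariate scale (`coef_natural`), convergence diagnostics, and the
#'   design bookkeeping needed by [annual_index()].
#' @export
fit_zinb <- function(data, covariates = c("temperature", "day_of_year", "ssb"),
                     year_effect = FALSE, zero_inflation = TRUE,
                     pin_zero = FALSE,
                     chains = 2, iter = 1000, burn = 500, adapt = 500,
                     seed = 1) {
  stopifnot(is.data.frame(data), all(c("year", "bay", "site", "count") %in% names(data)))
  y <- data$count
  if (any(y < 0) || any(y != round(y))) stop("counts must be non-negative integers")
  covariates <- if (length(covariates)) match.arg(covariates, several.ok = TRUE) else character(0)
  missing_cov <- setdiff(covariates, names(data))
  if (length(missing_cov)) stop("covariates absent from data: ", paste(missing_cov, collapse = ", "))

  Xc <- NULL; cov_center <- cov_scale <- NULL
  if (length(covariates)) {
    Xraw <- as.matrix(data[covariates])
    cov_center <- colMeans(Xraw); cov_scale <- apply(Xraw, 2, stats::sd)
    cov_scale[cov_scale == 0] <- 1
    Xc <- sweep(sweep(Xraw, 2, cov_center), 2, cov_scale, "/")
  }
  sites <- sort(unique(data$site))
  bays <- sort(unique(data$bay))
  bay_of_site <- match(vapply(sites, function(s) data$bay[match(s, data$site)],
                              character(1)), bays)
  years <- sort(unique(data$year))

  jd <- list(y = as.integer(y), N = length(y),
             site = match(data$site, sites), NS = length(sites),
             bay_of_site = bay_of_site, NB = length(bays))
  has_covars <- length(covariates) > 0
  if (has_covars) { jd$Xc <- Xc; jd$Xz <- Xc; jd$NC <- ncol(Xc) }
  if (year_effect) { jd$yr <- match(data$year, years); jd$NY <- length(years) }
  if (zero_inflation) {
    jd$z0 <- as.numeric(y == 0); jd$BIG <- 10000
    jd$zeros <- rep(0L, length(y))
  }
  if (pin_zero && !zero_inflation) stop("'pin_zero' requires the ZINB likelihood")

  ms <- zinb_model_string(zero_inflation, year_effect, has_covars, pin_zero)
  free_zero <- zero_inflation && !pin_zero
  monitor <- c("bc0", "lr", "sd_sc", "sd_bc", "uc", "vc",
               if (has_covars) "bc",
               if (year_effect) "ac",
               if (free_zero) c("bz0", "sd_sz", "sd_bz", "uz", "vz"),
               if (free_zero && has_covars) "bz",
               if (free_zero && year_effect) "az")
  fit <- run_jags(ms, jd, monitor = monitor, chains = chains, adapt = adapt,
                  burn = burn, iter = iter, seed = seed)
  conv <- check_convergence(fit$draws, ess_min = 200)
  if (!conv$pass) {
    far_warn("fit_zinb: convergence diagnostics failed (max Rhat %.3f, min ESS %.0f)",
             conv$max_rhat, conv$min_ess)
  }
  dm <- flatten_draws(fit$draws)

  get_cols <- function(prefix) indexed_cols(dm, prefix)
  S <- nrow(dm)
  eta_c <- get_cols("uc")[, jd$site, drop = FALSE]
  if (has_covars) eta_c <- eta_c + get_cols("bc") %*% t(Xc)
  if (year_effect) eta_c <- eta_c + get_cols("ac")[, jd$yr, drop = FALSE]
  mu <- exp(eta_c)
  r <- exp(dm[, "lr"])
  if (zero_inflation) {
    pz <- if (pin_zero) matrix(1e-7, S, length(y)) else {
      ez <- get_cols("uz")[, jd$site, drop = FALSE]
      if (has_covars) ez <- ez + get_cols("bz") %*% t(Xc)
      if (year_effect) ez <- ez + get_cols("az")[, jd$yr, drop = FALSE]
      ilogit(ez)
    }
    nb <- stats::dnbinom(rep(y, each = S), size = r, mu = mu)
    dim(nb) <- dim(mu)
    lik <- (1 - pz) * nb
    lik[, y == 0] <- lik[, y == 0, drop = FALSE] + pz[, y == 0, drop = FALSE]
    log_lik <- log(pmax(lik, 1e-300))
  } else {
    log_lik <- stats::dnbinom(rep(y, each = S), size = r, mu = mu, log = TRUE)
    dim(log_lik) <- dim(mu)
  }

  coef_natural <- NULL
  if (has_covars) {
    bc_std <- get_cols("bc")
    nat <- sweep(bc_std, 2, cov_scale, "/")
    coef_natural <- data.frame(
      covariate = covariates,
      mean = colMeans(nat),
      lo95 = apply(nat, 2, function(x) equal_tailed(x, 0.95)[1]),
      hi95 = apply(nat, 2, function(x) equal_tailed(x, 0.95)[2])
    )
  }
  out <- list(draws = dm, log_lik = log_lik, convergence = conv,
              covariates = covariates, cov_center = cov_center,
              cov_scale = cov_scale, years = years, sites = sites,
              bays = bays, year_effect = year_effect,
              zero_inflation = zero_inflation, pin_zero = pin_zero,
              coef_natural = coef_natural, n_obs = length(y))
  class(out) <- "zinb_fit"
  out
}

#' @export
print.zinb_fit <- function(x, ...) {
  cat(sprintf("Bayesian %s model: %d sets, %d bays, %d sites\n",
              if (x$zero_inflation) "zero-inflated negative binomial"
              else "negative binomial",
              x$n_obs, length(x$bays), length(x$sites)))
  if (!is.null(x$coef_natural)) {
    cat("Abundance-part coefficients (original covariate scale):\n")
    print(x$coef_natural, row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' Annual abundance index from a year-effect ZINB fit
#'
#' Expected catch per set for each year, with continuous covariates fixed at
#' their sample means and random effects marginalized at zero:
#' `(1 - pi_year) * mu_year` per posterior draw.
#'
#' @param fit A `zinb_fit` fitted with `year_effect = TRUE`.
#' @return data.frame (`year`, `median`, `lo95`, `hi95`) with per-year
#'   posterior draws in `attr(, "draws")`.
#' @export
annual_index <- function(fit) {
  stopifnot(inherits(fit, "zinb_fit"))
  if (!fit$year_effect) stop("annual_index needs a fit with year as a categorical covariate")
  dm <- fit$draws
  ac <- indexed_cols(dm, "ac")
  eta_c <- ac + dm[, "bc0"]
  idx <- exp(eta_c)
  if (fit$zero_inflation) {
    az <- indexed_cols(dm, "az")
    pz <- ilogit(az + dm[, "bz0"])
    idx <- (1 - pz) * idx
  }
  out <- data.frame(
    row.names = NULL,
    year = fit$years,
    median = apply(idx, 2, stats::median),
    lo95 = apply(idx, 2, function(x) equal_tailed(x, 0.95)[1]),
    hi95 = apply(idx, 2, function(x) equal_tailed(x, 0.95)[2])
  )
  attr(out, "draws") <- idx
  out
}

#' Two-level (categorical FAR) model of catch per set
#'
#' Bayesian Gaussian model of set-level catch with a single two-level
#' covariate: whether the year's FAR is at or above the threshold. Class
#' means are constrained positive by a truncated-Normal prior. A log-scale
#' variant (`scale = "log"`, modelling `log(count + 1)`) is available.
#'
#' @param data A `seine_catch` data.frame.
#' @param far_by_year data.frame (`year`, `far` or `mean`) or named numeric
#'   vector of FAR values covering the data years.
#' @param threshold Class boundary (default 0.98).
#' @param scale `"natural"` (Gaussian on counts, as stated) or `"log"`.
#' @param chains,iter,burn,adapt,seed MCMC settings.
#' @return A `far_categorical_fit`: per-class posterior medians and 95% CIs
#'   (`summary`), draws of the class difference, and Bayesian R-squared.
#' @export
fit_categorical_far <- function(data, far_by_year, threshold = 0.98,
                                scale = c("natural", "log"),
                                chains = 2, iter = 1000, burn = 500,
                                adapt = 500, seed = 1) {
  scale <- match.arg(scale)
  if (is.data.frame(far_by_year)) {
    fv <- if ("far" %in% names(far_by_year)) far_by_year$far else far_by_year$mean
    far <- fv[match(data$year, far_by_year$year)]
  } else {
    far <- far_by_year[match(as.character(data$year), names(far_by_year))]
  }
  if (anyNA(far)) stop("FAR values missing for some data years")
  cls <- ifelse(far >= threshold, 2L, 1L)
  if (length(unique(cls)) < 2) stop("both FAR classes must be non-empty")
  y <- if (scale == "log") log(data$count + 1) else as.numeric(data$count)
  ms <- "
  model {
    for (i in 1:N) { y[i] ~ dnorm(mu[cls[i]], tau) }
    for (k in 1:2) { mu[k] ~ dnorm(0, 1.0E-4) T(0,) }
    sigma ~ dnorm(0, 1.0E-4) T(0,)
    tau <- pow(sigma + 1.0E-6, -2)
  }"
  jd <- list(y = y, cls = cls, N = length(y))
  fit <- run_jags(ms, jd, monitor = c("mu", "sigma"), chains = chains,
                  adapt = adapt, burn = burn, iter = iter, seed = seed)
  conv <- check_convergence(fit$draws, ess_min = 400)
  dm <- flatten_draws(fit$draws)
  mu <- dm[, c("mu[1]", "mu[2]")]
  sigma <- dm[, "sigma"]
  fitted <- mu[, cls]
  vf <- apply(fitted, 1, stats::var)
  r2 <- vf / (vf + sigma^2)
  summ <- data.frame(
    class = c(sprintf("FAR < %g", threshold), sprintf("FAR >= %g", threshold)),
    n_sets = as.integer(table(cls)),
    median = apply(mu, 2, stats::median),
    lo95 = apply(mu, 2, function(x) equal_tailed(x, 0.95)[1]),
    hi95 = apply(mu, 2, function(x) equal_tailed(x, 0.95)[2])
  )
  out <- list(summary = summ, diff_draws = mu[, 2] - mu[, 1],
              mu_draws = mu, sigma = sigma,
              r2 = list(draws = r2, median = stats::median(r2),
                        ci95 = equal_tailed(r2, 0.95)),
              threshold = threshold, scale = scale, convergence = conv)
  class(out) <- "far_categorical_fit"
  out
}

#' @export
print.far_categorical_fit <- function(x, ...) {
  cat(sprintf("Categorical-FAR Gaussian model (threshold %g, %s scale)\n",
              x$threshold, x$scale))
  print(x$summary, row.names = FALSE, digits = 3)
  cat(sprintf("Bayesian R2 = %.2f [95%% CI %.2f-%.2f]\n",
              x$r2$median, x$r2$ci95[1], x$r2$ci95[2]))
  invisible(x)
}
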