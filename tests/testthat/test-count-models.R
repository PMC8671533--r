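# Unit-scale checks of the seine count models; the full 3000-set parameter
# recovery lives in the acceptance suite.

test_that("fit_zinb validates inputs", {
  p <- seine_sim_params(n_years = 2, n_bays = 2, n_sites_per_bay = 2,
                        sets_per_site_year = 3, seed = 1)
  d <- simulate_seine(p)
  d_bad <- d; d_bad$count[1] <- 2.5
  expect_error(fit_zinb(d_bad), "non-negative integers")
  expect_error(fit_zinb(d, covariates = "salinity"))
  expect_error(fit_zinb(d, zero_inflation = FALSE, pin_zero = TRUE),
               "requires the ZINB likelihood")
})

test_that("ZINB with zero inflation pinned to zero matches the plain NB fit", {
  p <- seine_sim_params(n_years = 4, n_bays = 3, n_sites_per_bay = 3,
                        sets_per_site_year = 10, zero_prob_intercept = -30,
                        temp_effect = -0.4, seed = 19)
  d <- simulate_seine(p)
  f_nb <- quiet_fit(fit_zinb(d, covariates = "temperature",
                             zero_inflation = FALSE, seed = 3))
  f_pin <- quiet_fit(fit_zinb(d, covariates = "temperature", pin_zero = TRUE,
                              seed = 3))
  elpd_nb <- mean(quiet_fit(psis_loo(f_nb$log_lik))$pointwise)
  elpd_pin <- mean(quiet_fit(psis_loo(f_pin$log_lik))$pointwise)
  expect_lt(abs(elpd_nb - elpd_pin), 0.01)
  # true zero inflation absent: free ZINB puts the zero intercept far negative
  f_zi <- quiet_fit(fit_zinb(d, covariates = "temperature", seed = 3))
  expect_lt(mean(f_zi$draws[, "bz0"]), -2)
})

test_that("posterior predictive zero fraction matches the data on a well-specified simulation", {
  p <- seine_sim_params(n_years = 4, n_bays = 3, n_sites_per_bay = 3,
                        sets_per_site_year = 15, zero_prob_intercept = -0.5,
                        temp_effect = 0, doy_effect = 0, ssb_effect = 0,
                        bay_sd = 0.3, site_sd = 0.3, seed = 23)
  d <- simulate_seine(p)
  fit <- quiet_fit(fit_zinb(d, covariates = character(0), seed = 5))
  dm <- fit$draws
  # simulate replicate zero-fractions from the posterior
  S <- min(400, nrow(dm))
  uc <- farrec:::indexed_cols(dm, "uc")
  uz <- farrec:::indexed_cols(dm, "uz")
  site_idx <- match(d$site, fit$sites)
  zf <- vapply(seq_len(S), function(s) {
    mu <- exp(uc[s, site_idx])
    pz <- plogis(uz[s, site_idx])
    yrep <- ifelse(runif(nrow(d)) < pz, 0L,
                   rnbinom(nrow(d), size = exp(dm[s, "lr"]), mu = mu))
    mean(yrep == 0)
  }, numeric(1))
  obs_zf <- mean(d$count == 0)
  expect_true(obs_zf >= quantile(zf, 0.025) && obs_zf <= quantile(zf, 0.975))
})

test_that("annual index recovers a ten-fold collapse and handles identical years", {
  p <- seine_sim_params(n_years = 3, n_bays = 4, n_sites_per_bay = 3,
                        sets_per_site_year = 25, mean_intercept = log(50),
                        temp_effect = 0, doy_effect = 0, ssb_effect = 0,
                        zero_prob_intercept = -2,
                        far_step_effect = log(1 / 10), far_threshold = 0.98,
                        bay_sd = 0.2, site_sd = 0.2, seed = 8)
  d <- simulate_seine(p, far_by_year = c(0.5, 0.5, 0.999))
  fit <- quiet_fit(fit_zinb(d, covariates = character(0), year_effect = TRUE,
                            seed = 2))
  idx <- annual_index(fit)
  dr <- attr(idx, "draws")
  ratio_ci <- quantile(dr[, 3] / ((dr[, 1] + dr[, 2]) / 2), c(0.025, 0.975))
  expect_true(ratio_ci[1] <= 0.1 && 0.1 <= ratio_ci[2] + 0.05)
  expect_lt(idx$hi95[3], idx$lo95[1])
  # identically generated years: overlapping CIs
  expect_gt(idx$hi95[1], idx$lo95[2])
  expect_gt(idx$hi95[2], idx$lo95[1])
  expect_error(annual_index(quiet_fit(
    fit_zinb(d, covariates = character(0), seed = 2))), "categorical")
})

test_that("categorical-FAR model separates collapsed and normal classes", {
  p <- seine_sim_params(n_years = 4, n_bays = 3, n_sites_per_bay = 3,
                        sets_per_site_year = 20, mean_intercept = log(40),
                        temp_effect = 0, doy_effect = 0, ssb_effect = 0,
                        zero_prob_intercept = -2, far_step_effect = log(2 / 40),
                        bay_sd = 0.2, site_sd = 0.2, shape = 2, seed = 14)
  far <- data.frame(year = 2006:2009, far = c(0.5, 0.7, 0.999, 0.999))
  d <- simulate_seine(p, far_by_year = far$far)
  fit <- quiet_fit(fit_categorical_far(d, far, seed = 6))
  expect_lt(fit$summary$hi95[2], fit$summary$lo95[1])
  expect_true(all(fit$summary$median > 0))
  expect_true(all(fit$r2$draws >= 0 & fit$r2$draws <= 1))
  # single-class data rejected
  far1 <- data.frame(year = 2006:2009, far = rep(0.5, 4))
  expect_error(fit_categorical_far(d, far1), "non-empty")

  # identical generative means in both classes: difference CI spans 0
  p0 <- seine_sim_params(n_years = 4, n_bays = 3, n_sites_per_bay = 3,
                         sets_per_site_year = 20, temp_effect = 0,
                         doy_effect = 0, ssb_effect = 0, far_step_effect = 0,
                         seed = 15)
  d0 <- simulate_seine(p0, far_by_year = far$far)
  f0 <- quiet_fit(fit_categorical_far(d0, far, seed = 7))
  ci <- quantile(f0$diff_draws, c(0.025, 0.975))
  expect_true(ci[1] < 0 && ci[2] > 0)
})

test_that("interval coverage for the temperature coefficient is calibrated", {
  # simulation-based check at reduced scale: 90% intervals should cover the
  # true coefficient at roughly the nominal rate
  hits <- vapply(1:20, function(r) {
    p <- seine_sim_params(n_years = 4, n_bays = 3, n_sites_per_bay = 3,
                          sets_per_site_year = 12, temp_effect = -0.5,
                          doy_effect = 0, ssb_effect = 0,
                          zero_prob_intercept = -1.5, seed = 100 + r)
    d <- simulate_seine(p)
    fit <- quiet_fit(fit_zinb(d, covariates = "temperature", chains = 2,
                              iter = 500, burn = 300, adapt = 200,
                              seed = 200 + r))
    draws <- farrec:::indexed_cols(fit$draws, "bc")[, 1] / fit$cov_scale["temperature"]
    ci <- quantile(draws, c(0.05, 0.95))
    ci[1] <= -0.5 && -0.5 <= ci[2]
  }, logical(1))
  expect_gte(mean(hits), 0.7)
})
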