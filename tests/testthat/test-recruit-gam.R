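test_that("classify_failure uses a strict -1 threshold", {
  expect_identical(classify_failure(c(-1.01, -1.0, 0.3)),
                   c(TRUE, FALSE, FALSE))
})

test_that("constant recruitment gives a flat fitted function", {
  set.seed(3)
  far <- runif(30, 0.05, 0.95)
  y <- rnorm(30, 0, 0.05)          # no FAR signal
  fit <- quiet_fit(fit_far_gam(y, far, k = 3, chains = 2, iter = 800,
                               burn = 400, adapt = 300, seed = 1))
  pr <- predict(fit, c(0.2, 0.5, 0.8))
  rng <- apply(pr, 1, function(z) max(z) - min(z))
  # effect excluded: pointwise CI of curve differences spans 0
  d <- pr[, 3] - pr[, 1]
  ci <- quantile(d, c(0.025, 0.975))
  expect_true(ci[1] < 0 && ci[2] > 0)
})

test_that("linear truth is recovered across the FAR range", {
  set.seed(9)
  far <- runif(50, 0.05, 0.95)
  rec <- simulate_recruitment(far, recruit_sim_params("linear",
                                                      effect_size = -2,
                                                      resid_sd = 0.1,
                                                      seed = 12))
  fit <- quiet_fit(fit_far_gam(rec$log_anomaly, far, k = 3, seed = 2))
  grid <- seq(0.1, 0.9, length.out = 9)
  est <- colMeans(predict(fit, grid))
  truth <- -2 * grid - mean(-2 * far) + mean(rec$log_anomaly)
  expect_lt(max(abs(est - (-2 * grid + (mean(rec$log_anomaly) + 2 * mean(far))))), 0.2)
})

test_that("threshold truth: prediction at FAR 0.999 is below FAR 0.5 with high posterior probability", {
  set.seed(1)
  far <- c(runif(40, 0.05, 0.95), runif(5, 0.985, 0.9995))
  rec <- simulate_recruitment(far, recruit_sim_params("threshold",
                                                      effect_size = -2,
                                                      resid_sd = 0.6,
                                                      seed = 3),
                              standardize_output = TRUE)
  fit <- quiet_fit(fit_far_gam(rec$log_anomaly, far, k = 3, seed = 2))
  pr <- predict(fit, c(0.5, 0.999))
  expect_gte(mean(pr[, 2] < pr[, 1]), 0.95)
  expect_true(is.finite(fit$looic))
  expect_error(fit_far_gam(rec$log_anomaly[1:6], far[1:6], k = 5), "exceeds")
})

test_that("measurement-error fit converges to the error-free fit as SE -> 0", {
  set.seed(4)
  far <- runif(35, 0.1, 0.95)
  y <- -1.5 * far + rnorm(35, 0, 0.3)
  f0 <- quiet_fit(fit_far_gam(y, far, k = 3, seed = 5))
  fme <- quiet_fit(fit_far_gam_me(y, far, rep(1e-4, 35), k = 3, seed = 5))
  grid <- seq(0.15, 0.9, length.out = 8)
  d <- abs(colMeans(predict(f0, grid)) - colMeans(predict(fme, grid)))
  expect_lt(max(d), 0.05 * sd(y) + 0.05)
  # all-zero SEs fall back to the error-free model with a notice
  expect_message(ffb <- suppressWarnings(
    fit_far_gam_me(y, far, rep(0, 35), k = 3, chains = 2, iter = 400,
                   burn = 200, adapt = 200, seed = 5)),
    "error-free")
  expect_false(ffb$me)
})

test_that("large FAR uncertainty attenuates the effect and widens the latent posterior", {
  set.seed(8)
  far <- runif(40, 0.1, 0.95)
  y <- -2 * far + rnorm(40, 0, 0.2)
  f0 <- quiet_fit(fit_far_gam(y, far, k = 3, seed = 6))
  se <- c(0.3, rep(0.01, 39))
  fme <- quiet_fit(fit_far_gam_me(y, far, se, k = 3, seed = 6))
  # classical attenuation: slope magnitude not larger than the error-free fit
  slope <- function(f) mean(predict(f, 0.9) - predict(f, 0.2)) / 0.7
  expect_lte(abs(slope(fme)), abs(slope(f0)) + 0.1)
  # the noisy year's latent FAR posterior is much wider than the precise ones
  sds <- apply(fme$far_latent, 2, sd)
  expect_gt(sds[1], 5 * median(sds[-1]))
  # ME predictive variance is not smaller than the error-free one
  v0 <- var(as.numeric(predict(f0, 0.5))) + mean(f0$sigma^2)
  vme <- var(as.numeric(predict(fme, 0.5))) + mean(fme$sigma^2)
  expect_gte(vme, v0 * 0.9)
})

test_that("bayes_r2 stays in [0,1] and matches an analytic signal-to-noise design", {
  set.seed(2)
  n <- 200
  x <- runif(n, 0, 1)
  sig <- sd(-1 * x)
  y <- -1 * x + rnorm(n, 0, sig)   # signal:noise 1:1 -> R2 ~ 0.5
  fit <- quiet_fit(fit_far_gam(y, x, k = 3, seed = 3))
  r2 <- bayes_r2(fit)
  expect_true(all(r2$draws >= 0 & r2$draws <= 1))
  expect_lt(abs(r2$median - 0.5), 0.1)
  expect_error(bayes_r2(list(fitted = matrix(1, 1, 3), sigma = 1)),
               "multiple posterior draws")
})

test_that("bridge_recent_recruitment: exact proportional case and predictive SE", {
  idx <- data.frame(year = 2006:2016, estimate = seq(1, 2, length.out = 11))
  assess <- data.frame(year = 1990:2016,
                       log_anomaly = c(rnorm(16), 2 * seq(1, 2, length.out = 11) - 3))
  out <- suppressWarnings(  # lm warns on the deliberately exact fit
    bridge_recent_recruitment(idx, assess, overlap = c(2006, 2015),
                              predict_years = 2016))
  # perfectly linear overlap: R^2 = 1 and the prediction is the exact
  # linear extrapolation
  expect_gt(suppressWarnings(summary(attr(out, "fit"))$r.squared), 0.9999)
  expect_equal(out$log_anomaly[out$year == 2016], 2 * 2 - 3, tolerance = 1e-8)

  set.seed(7)
  idx2 <- data.frame(year = 2006:2016, estimate = rnorm(11))
  assess2 <- data.frame(year = 2006:2013,
                        log_anomaly = 0.8 * idx2$estimate[1:8] + rnorm(8, 0, 0.4))
  out2 <- bridge_recent_recruitment(idx2, assess2, overlap = c(2006, 2013),
                                    predict_years = 2014:2016)
  expect_identical(out2$source[out2$year >= 2014], rep("seine_bridge", 3))
  resid_se <- summary(attr(out2, "fit"))$sigma
  expect_true(all(out2$pred_se[out2$year >= 2014] > resid_se))
  expect_error(bridge_recent_recruitment(idx2, assess2[1:2, ],
                                         overlap = c(2006, 2013),
                                         predict_years = 2014:2016),
               "3 overlap years")
  expect_error(bridge_recent_recruitment(idx2, assess2, overlap = c(2006, 2013),
                                         predict_years = 2012:2014),
               "disjoint")
})

test_that("adding an irrelevant SSB covariate does not win the LOOIC comparison", {
  set.seed(21)
  far <- runif(40, 0.05, 0.95)
  ssb <- rnorm(40)
  y <- -1.5 * far + rnorm(40, 0, 0.4)
  f1 <- quiet_fit(fit_far_gam(y, far, k = 3, seed = 9))
  f2 <- quiet_fit(fit_far_gam(y, far, extra = list(ssb = ssb), k = 3, seed = 9))
  cmp <- quiet_fit(loo_compare(list(far_only = f1, far_ssb = f2)))
  row <- cmp[cmp$model == "far_only", ]
  expect_lte(row$delta_looic, 2 * max(cmp$se_delta) + 2)
})
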