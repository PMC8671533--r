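test_that("generators are deterministic under a fixed seed", {
  p <- climate_sim_params(seed = 21)
  expect_identical(simulate_climate(p), simulate_climate(p))
  rp <- recruit_sim_params(seed = 21)
  far <- runif(30)
  expect_identical(simulate_recruitment(far, rp), simulate_recruitment(far, rp))
  sp <- seine_sim_params(n_years = 3, n_bays = 2, n_sites_per_bay = 2, seed = 21)
  expect_identical(simulate_seine(sp), simulate_seine(sp))
  tr <- simulate_latent_trend(20, seed = 21)
  expect_identical(simulate_survey_panel(tr, c(1, 0.5), c(0.1, 0.2), seed = 21),
                   simulate_survey_panel(tr, c(1, 0.5), c(0.1, 0.2), seed = 21))
})

test_that("seed substreams are independent of generator order", {
  s1 <- substream_seed(99, "climate-observed")
  s2 <- substream_seed(99, "seine")
  expect_true(s1 != s2)
  expect_true(s1 >= 1 && s1 < 2^31)
})

test_that("null climate: observed and preindustrial share population mean", {
  p <- climate_sim_params(trend_obs = 0, trend_proj = 0, n_years_obs = 3000,
                          n_years_pi = 3000, n_models = 1, ar1_coef = 0.3,
                          noise_sd = 0.5, seed = 2)
  ens <- simulate_climate(p)
  marg_sd <- 0.5 / sqrt(1 - 0.3^2)
  se <- marg_sd / sqrt(3000 * (1 - 0.3) / (1 + 0.3))  # AR(1)-adjusted MC error
  expect_lt(abs(mean(ens$observed$value)), 4 * se)
  expect_lt(abs(mean(ens$models[[1]]$preindustrial$value)), 4 * se)
  # stationary marginal SD of the AR(1) noise
  expect_lt(abs(sd(ens$models[[1]]$preindustrial$value) - marg_sd), 0.1)
})

test_that("trended climate: final-decade exceedance of the preindustrial 95th percentile matches direct Monte Carlo", {
  p <- climate_sim_params(n_years_obs = 60, trend_obs = 0.05, ar1_coef = 0.4,
                          noise_sd = 0.5, n_models = 1, seed = 31)
  # direct Monte Carlo of the same generative process, written independently
  mc_frac <- function(n_rep, seed) {
    set.seed(seed)
    marg <- 0.5 / sqrt(1 - 0.4^2)
    hits <- 0; tot <- 0
    q95 <- qnorm(0.95, 0, marg)  # stationary AR(1) is marginally normal
    for (r in seq_len(n_rep)) {
      x <- numeric(60); x[1] <- rnorm(1, 0, marg)
      for (t in 2:60) x[t] <- 0.4 * x[t - 1] + rnorm(1, 0, 0.5)
      obs <- 0.05 * (0:59) + x
      hits <- hits + sum(obs[51:60] > q95); tot <- tot + 10
    }
    hits / tot
  }
  expected <- mc_frac(2000, 77)
  got <- replicate(60, {
    pp <- p; pp$seed <- sample.int(1e6, 1)
    ens <- simulate_climate(pp)
    q95 <- qnorm(0.95, 0, 0.5 / sqrt(1 - 0.4^2))
    mean(ens$observed$value[51:60] > q95)
  })
  set.seed(11)
  se <- sqrt(expected * (1 - expected) / (60 * 10)) + 0.02
  expect_lt(abs(mean(got) - expected), 3 * se)
})

test_that("recruitment generator: null effect, threshold flatness, linear slope", {
  far <- seq(0.05, 0.95, length.out = 50)
  r0 <- simulate_recruitment(far, recruit_sim_params(effect_size = 0,
                                                     resid_sd = 0.5, seed = 3))
  sl <- summary(lm(r0$log_anomaly ~ far))$coefficients["far", ]
  expect_lt(abs(sl["Estimate"]), 3 * sl["Std. Error"])

  # threshold shape with all FAR below the threshold: identical means
  rt <- simulate_recruitment(far, recruit_sim_params("threshold",
                                                     effect_size = -5,
                                                     resid_sd = 0.3, seed = 4))
  expect_identical(attr(rt, "true_mean"), rep(0, 50))

  rl <- simulate_recruitment(far, recruit_sim_params("linear", effect_size = -2,
                                                     resid_sd = 0.1, seed = 5))
  sl2 <- summary(lm(rl$log_anomaly ~ far))$coefficients["far", ]
  expect_lt(abs(sl2["Estimate"] - (-2)), 3 * sl2["Std. Error"])

  expect_error(simulate_recruitment(c(0.5, 1.2), recruit_sim_params()),
               "\\[0, 1\\]")
  rs <- simulate_recruitment(far, recruit_sim_params(seed = 6),
                             standardize_output = TRUE)
  expect_lt(abs(mean(rs$log_anomaly)), 1e-10)
  expect_equal(sd(rs$log_anomaly), 1)
})

test_that("seine generator matches analytic ZINB moments", {
  p <- seine_sim_params(n_years = 5, n_bays = 5, n_sites_per_bay = 5,
                        sets_per_site_year = 40,  # 5000 sets
                        zero_prob_intercept = 0, mean_intercept = log(10),
                        temp_effect = 0, doy_effect = 0, ssb_effect = 0,
                        bay_sd = 0, site_sd = 0, shape = 1.5, seed = 17)
  d <- simulate_seine(p)
  expect_true(all(d$count >= 0 & d$count == round(d$count)))
  n <- nrow(d)
  pi <- 0.5; mu <- 10; r <- 1.5
  ey <- (1 - pi) * mu
  vy <- (1 - pi) * mu * (1 + mu / r) + pi * (1 - pi) * mu^2
  p0 <- pi + (1 - pi) * (r / (r + mu))^r
  expect_lt(abs(mean(d$count) - ey), 3 * sqrt(vy / n))
  expect_lt(abs(mean(d$count == 0) - p0), 3 * sqrt(p0 * (1 - p0) / n))
})

test_that("seine generator limits: all-zero and no between-bay variance", {
  pz <- seine_sim_params(n_years = 2, n_bays = 2, n_sites_per_bay = 2,
                         sets_per_site_year = 5, zero_prob_intercept = 30,
                         seed = 2)
  expect_true(all(simulate_seine(pz)$count == 0))

  p0 <- seine_sim_params(n_years = 2, n_bays = 8, n_sites_per_bay = 4,
                         sets_per_site_year = 40, bay_sd = 0, site_sd = 0,
                         zero_prob_intercept = -30, temp_effect = 0,
                         doy_effect = 0, ssb_effect = 0, shape = 50, seed = 3)
  d0 <- simulate_seine(p0)
  bay_means <- tapply(log(d0$count + 1), d0$bay, mean)
  expect_lt(var(bay_means), 0.01)
  expect_error(seine_sim_params(shape = -1), "shape")
})

test_that("survey panel generator: noiseless identity, zero loading, missingness", {
  tr <- simulate_latent_trend(30, seed = 9)
  pan <- simulate_survey_panel(tr, loadings = c(1, 1, 1), obs_sd = rep(1e-12, 3),
                               seed = 5)
  w <- panel <- matrix(pan$value, nrow = 30)
  expect_equal(w[, 1], tr, tolerance = 1e-6)
  expect_equal(w[, 2], w[, 3], tolerance = 1e-6)

  pan2 <- simulate_survey_panel(tr, loadings = c(1, 0), obs_sd = c(0.1, 0.5),
                                seed = 6)
  m <- matrix(pan2$value, nrow = 30)
  expect_gt(cor(m[, 1], tr), 0.95)
  expect_lt(abs(cor(m[, 2], tr)), 0.5)

  pan3 <- simulate_survey_panel(tr, loadings = c(1, 1), obs_sd = c(0.1, 0.1),
                                missing_frac = c(0.3, 0), seed = 7)
  m3 <- matrix(pan3$value, nrow = 30)
  expect_true(sum(is.na(m3[, 1])) > 0)
  expect_true(all(!is.na(m3[, 2])))
  expect_error(simulate_survey_panel(tr, c(1, 1), c(-0.1, 0.1)),
               "non-negative")
})
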