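test_that("standardize_anomalies matches direct z-scores and handles windows", {
  s <- data.frame(year = 2001:2010, value = 1:10)
  z <- standardize_anomalies(s)
  expect_equal(z$value, (1:10 - mean(1:10)) / sd(1:10))

  # a year equal to the center-window mean gets anomaly exactly 0
  z2 <- standardize_anomalies(s, center_window = c(2001, 2009),
                              scale_window = c(2001, 2010))
  expect_equal(z2$value[5], 0)  # value 5 = mean(1:9)

  const <- data.frame(year = 1:5, value = rep(2, 5))
  expect_error(standardize_anomalies(const), "zero SD")
  expect_error(standardize_anomalies(s, center_window = c(1900, 1950)),
               "does not overlap")
})

test_that("exceedance probability counts ties as exceedances", {
  smp <- c(-1, -0.5, 0, 0.5, 1)
  expect_equal(exceedance_probability(0.6, smp), 0.2)
  expect_equal(exceedance_probability(-2, smp), 1)    # below min
  expect_equal(exceedance_probability(1, smp), 0.2)   # tie counted
  expect_equal(exceedance_probability(1.5, smp), 0)   # above max
  expect_error(exceedance_probability(0, numeric(0)), "empty")
})

test_that("compute_far matches the worked example and applies clamps", {
  pre <- c(-1, -0.5, 0, 0.5, 1)
  cur <- c(-0.5, 0, 0.6, 1.2)
  expect_equal(compute_far(0.6, pre, cur), 0.6)
  # equal risk -> 0, clamped to the lower bound
  expect_equal(compute_far(0, pre, pre), 1e-4)
  # anomaly above every preindustrial value -> raw FAR 1 -> reset to 0.9999
  expect_equal(compute_far(2, pre, c(0, 2)), 0.9999)
  expect_error(compute_far(5, pre, cur), "include the focal year")
})

test_that("compute_far agrees exactly with the exhaustive-count oracle", {
  set.seed(42)
  for (rep in 1:200) {
    n_pre <- sample(2:20, 1); n_cur <- sample(2:20, 1)
    pre <- round(rnorm(n_pre), 2)
    cur <- round(rnorm(n_cur), 2)
    a <- sample(cur, 1)  # member of current sample: p_cur > 0 guaranteed
    expect_identical(compute_far(a, pre, cur), far_oracle(a, pre, cur))
  }
})

test_that("FAR is monotone non-decreasing in the anomaly while p_cur is constant", {
  # the empirical FAR can only fall where the current-sample exceedance
  # probability itself steps down; between those jump points it is monotone
  set.seed(7)
  for (r in 1:20) {
    pre <- rnorm(15); cur <- sort(rnorm(12))
    a_grid <- sort(c(pre, cur[1] - 0.5, seq(min(cur), max(cur), length.out = 40)))
    a_grid <- a_grid[a_grid <= max(cur)]  # keep p_cur > 0
    vals <- vapply(a_grid, compute_far, numeric(1),
                   preindustrial_sample = pre, current_sample = cur)
    pcur <- vapply(a_grid, exceedance_probability, numeric(1), sample = cur)
    same <- diff(pcur) == 0
    expect_true(all(diff(vals)[same] >= 0))
  }
})

test_that("build_far_table is complete and near the clamp under strong trends", {
  ens <- simulate_climate(climate_sim_params(trend_obs = 0.09, seed = 3))
  ft <- suppressMessages(build_far_table(ens, "hindcast"))
  p <- ens$params
  expect_equal(nrow(ft), p$n_years_obs * p$n_models)
  expect_true(all(ft$far >= 1e-4 & ft$far <= 0.9999))
  # strongly trended observations: late-period rows approach the 0.9999 clamp
  late <- ft$far[ft$year >= max(ft$year) - 4]
  expect_true(mean(late >= 0.99) > 0.8)

  # identical preindustrial and current distribution -> all FAR at clamp_lo
  ens0 <- list(observed = ens$models[[1]]$preindustrial,
               models = list(list(model_id = "m1",
                                  preindustrial = ens$models[[1]]$preindustrial,
                                  projection = NULL)))
  ft0 <- suppressMessages(build_far_table(ens0, "hindcast"))
  expect_true(all(ft0$far == 1e-4))

  ens_bad <- ens; ens_bad$models[[2]]$preindustrial <- NULL
  expect_error(suppressMessages(build_far_table(ens_bad, "hindcast")),
               "model02")
})

test_that("no-forcing null gives FAR posterior with no trend", {
  ens <- simulate_climate(climate_sim_params(trend_obs = 0, trend_proj = 0,
                                             n_years_obs = 40, seed = 12))
  ft <- suppressMessages(build_far_table(ens, "hindcast"))
  fe <- quiet_fit(fit_far_model(ft, chains = 2, iter = 600, burn = 300,
                                adapt = 300, seed = 5))
  sl <- summary(lm(mean ~ year, data = fe))$coefficients["year", ]
  ci <- sl["Estimate"] + c(-2, 2) * sl["Std. Error"]
  expect_true(ci[1] < 0 && ci[2] > 0)
  expect_true(all(fe$mean > 0 & fe$mean < 1))
})

test_that("fit_far_model: degenerate constant table gives means near truth", {
  tab <- expand.grid(year = 2001:2005, model_id = sprintf("m%d", 1:4))
  set.seed(8)
  tab$far <- plogis(rnorm(nrow(tab), qlogis(0.5), 0.05))
  fe <- quiet_fit(fit_far_model(tab, chains = 2, iter = 600, burn = 300,
                                adapt = 300, seed = 9))
  expect_true(all(abs(fe$mean - 0.5) < 0.1))
  # nested equal-tailed intervals
  expect_true(all(fe$lo95 <= fe$lo90 & fe$lo90 <= fe$lo80))
  expect_true(all(fe$hi80 <= fe$hi90 & fe$hi90 <= fe$hi95))
})

test_that("fit_far_model rejects values outside the open unit interval", {
  tab <- data.frame(year = rep(2001:2002, 2), model_id = rep(c("a", "b"), each = 2),
                    far = c(0.5, 1.0, 0.5, 0.5))
  expect_error(fit_far_model(tab), "clamp")
})
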