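# Shared fixtures built in code. All MCMC fits in the unit tests use short
# chains; non-convergence warnings from deliberately short runs are
# suppressed at the call sites that expect them.

quiet_fit <- function(expr) suppressWarnings(suppressMessages(expr))

small_ensemble <- function(seed = 3) {
  simulate_climate(climate_sim_params(seed = seed))
}

# exhaustive-counting oracle for FAR on small samples, independent of the
# package implementation (plain loops, no shared helpers)
far_oracle <- function(anomaly, pre, cur, clamp_lo = 1e-4, clamp_hi = 0.9999) {
  n_pre <- 0
  for (v in pre) if (v >= anomaly) n_pre <- n_pre + 1
  n_cur <- 0
  for (v in cur) if (v >= anomaly) n_cur <- n_cur + 1
  p_pre <- n_pre / length(pre)
  p_cur <- n_cur / length(cur)
  stopifnot(p_cur > 0)
  raw <- 1 - p_pre / p_cur
  if (raw < clamp_lo) raw <- clamp_lo
  if (raw > clamp_hi) raw <- clamp_hi
  raw
}

# brute-force multivariate normal log-density via cholesky (oracle for the
# Kalman-filter likelihood)
dmvnorm_log <- function(y, mu, Sigma) {
  ch <- chol(Sigma)
  z <- backsolve(ch, y - mu, transpose = TRUE)
  -0.5 * (length(y) * log(2 * pi) + sum(z^2)) - sum(log(diag(ch)))
}
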