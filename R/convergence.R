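# MCMC convergence diagnostics: split potential-scale-reduction factor
# (split-Rhat) and effective sample size from combined within-chain
# autocorrelations, with Geyer's initial monotone positive-sequence
# truncation. Both follow the standard multi-chain formulation.

# split each chain in half along iterations: n x C -> floor(n/2) x 2C
split_chains <- function(m) {
  n <- nrow(m)
  h <- floor(n / 2)
  cbind(m[seq_len(h), , drop = FALSE],
        m[(n - h + 1):n, , drop = FALSE])
}

rhat_split <- function(m) {
  s <- split_chains(m)
  n <- nrow(s)
  w <- mean(apply(s, 2, stats::var))
  b <- n * stats::var(colMeans(s))
  if (w == 0) return(if (b == 0) 1 else Inf)
  sqrt(((n - 1) / n * w + b / n) / w)
}

ess_multichain <- function(m) {
  s <- split_chains(m)
  n <- nrow(s); c <- ncol(s)
  if (n < 4) return(NA_real_)
  chain_var <- apply(s, 2, stats::var)
  w <- mean(chain_var)
  b <- n * stats::var(colMeans(s))
  var_plus <- (n - 1) / n * w + b / n
  if (var_plus == 0) return(NA_real_)
  # within-chain autocovariances, averaged across chains
  acov <- sapply(seq_len(c), function(j) {
    stats::acf(s[, j], lag.max = n - 1, type = "covariance",
               plot = FALSE, demean = TRUE)$acf[, 1, 1]
  })
  mean_acov <- rowMeans(acov)
  rho <- 1 - (w - mean_acov) / var_plus
  rho[1] <- 1
  # Geyer: sum consecutive lag pairs (P_k = rho_{2k} + rho_{2k+1}) while
  # positive, enforce monotone decrease; tau = -1 + 2 * sum_k P_k
  max_pairs <- floor((n - 2) / 2)
  pair_sums <- numeric(0)
  for (k in 0:max_pairs) {
    ps <- rho[2 * k + 1] + rho[2 * k + 2]
    if (ps <= 0) break
    pair_sums <- c(pair_sums, ps)
  }
  if (length(pair_sums) > 1) pair_sums <- cummin(pair_sums)
  tau <- max(-1 + 2 * sum(pair_sums), 1e-8)
  (n * c) / tau
}

#' Convergence diagnostics for posterior draws
#'
#' Computes split-Rhat and effective sample size per parameter. The pass
#' flag requires Rhat below `rhat_max` and ESS at least `ess_min` for every
#' parameter. Gibbs/slice samplers (JAGS) have no divergent transitions; the
#' divergence count is reported as 0 for interface compatibility with
#' Hamiltonian samplers.
#'
#' @param draws Iterations x chains x parameters array (>= 2 chains), or an
#'   iterations x chains matrix for a single parameter.
#' @param rhat_max Maximum acceptable split-Rhat (default 1.05).
#' @param ess_min Minimum acceptable effective sample size (default 1000).
#' @return List with `summary` (per-parameter `rhat`, `ess`), `max_rhat`,
#'   `min_ess`, `divergences`, and logical `pass`.
#' @export
check_convergence <- function(draws, rhat_max = 1.05, ess_min = 1000) {
  if (is.matrix(draws)) draws <- array(draws, dim = c(dim(draws), 1))
  stopifnot(length(dim(draws)) == 3)
  if (dim(draws)[2] < 2) {
    stop("at least 2 chains are required for split-Rhat")
  }
  pn <- dimnames(draws)[[3]]
  if (is.null(pn)) pn <- sprintf("par%d", seq_len(dim(draws)[3]))
  rhat <- vapply(seq_len(dim(draws)[3]),
                 function(p) rhat_split(draws[, , p]), numeric(1))
  ess <- vapply(seq_len(dim(draws)[3]),
                function(p) ess_multichain(draws[, , p]), numeric(1))
  summary <- data.frame(parameter = pn, rhat = rhat, ess = ess)
  list(summary = summary,
       max_rhat = max(rhat),
       min_ess = min(ess, na.rm = TRUE),
       divergences = 0L,
       pass = all(rhat < rhat_max) && all(ess >= ess_min, na.rm = TRUE))
}
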