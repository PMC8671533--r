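# Pareto-smoothed importance-sampling leave-one-out cross-validation
# (PSIS-LOO). Raw importance ratios 1/p(y_i | theta_s) are tail-smoothed by
# replacing the largest 20% (capped at 3*sqrt(S)) with quantiles of a
# generalized Pareto distribution fitted to them; the fitted shape k is the
# reliability diagnostic (k > 0.7 flagged).

# Zhang & Stephens (2009) estimator for the generalized Pareto
# distribution, profile over the transformed parameter theta = xi/sigma
# given exceedances x > 0. Returns shape k (loo convention: k > 0 =
# heavy tail) and scale sigma.
gpd_fit <- function(x) {
  x <- sort(x)
  n <- length(x)
  if (n < 5) return(list(k = NA_real_, sigma = NA_real_))
  prior_adj <- TRUE
  m <- 30 + floor(sqrt(n))
  q1 <- x[max(1, floor(n / 4 + 0.5))]
  theta <- 1 / x[n] + (1 - sqrt(m / (seq_len(m) - 0.5))) / (3 * q1)
  prof <- vapply(theta, function(th) {
    k <- -mean(log1p(-th * x))
    n * (log(th / k) + k - 1)
  }, numeric(1))
  w <- 1 / vapply(seq_len(m), function(j) sum(exp(prof - prof[j])), numeric(1))
  th_hat <- sum(theta * w)
  k_hat <- mean(log1p(-th_hat * x))    # tail index xi: > 0 = heavy tail
  sigma <- -k_hat / th_hat
  if (prior_adj) k_hat <- (n * k_hat + 5) / (n + 10)  # weak prior toward 0.5
  list(k = k_hat, sigma = sigma)
}

# inverse CDF of GPD(k, sigma): q(p) = sigma/k * ((1-p)^(-k) - 1)
gpd_qf <- function(p, k, sigma) {
  if (abs(k) < 1e-12) -sigma * log1p(-p) else sigma / k * ((1 - p)^(-k) - 1)
}

# smooth one vector of log importance weights; returns list(lw, k)
psis_smooth <- function(lw) {
  s <- length(lw)
  lw <- lw - max(lw)
  n_tail <- min(ceiling(0.2 * s), ceiling(3 * sqrt(s)))
  if (n_tail < 5) return(list(lw = lw - logsumexp(lw), k = NA_real_))
  ord <- order(lw)
  tail_idx <- ord[(s - n_tail + 1):s]
  cutoff <- lw[ord[s - n_tail]]
  exc <- exp(lw[tail_idx]) - exp(cutoff)
  fit <- gpd_fit(exc[exc > 0])
  k <- fit$k
  if (is.finite(k)) {
    p <- (seq_len(n_tail) - 0.5) / n_tail
    smoothed <- log(exp(cutoff) + gpd_qf(p, fit$k, fit$sigma))
    lw[tail_idx[order(lw[tail_idx])]] <- pmin(smoothed, 0)
  }
  list(lw = lw - logsumexp(lw), k = k)
}

#' PSIS-LOO for a fitted Bayesian model
#'
#' @param log_lik Draws x observations matrix of pointwise log-likelihoods.
#' @return A `psis_loo` object: `elpd_loo`, `se_elpd_loo`, `looic`
#'   (`-2 * elpd_loo`), `pointwise` (per-observation elpd), and `pareto_k`
#'   diagnostics.
#' @export
psis_loo <- function(log_lik) {
  stopifnot(is.matrix(log_lik), nrow(log_lik) >= 10)
  n <- ncol(log_lik)
  elpd <- k <- numeric(n)
  for (i in seq_len(n)) {
    sm <- psis_smooth(-log_lik[, i])
    elpd[i] <- logsumexp(sm$lw + log_lik[, i])
    k[i] <- sm$k
  }
  n_bad <- sum(k > 0.7, na.rm = TRUE)
  if (n_bad > 0) {
    far_warn("psis_loo: %d of %d observations have Pareto k > 0.7; elpd may be unreliable", n_bad, n)
  }
  out <- list(elpd_loo = sum(elpd),
              se_elpd_loo = sqrt(n * stats::var(elpd)),
              looic = -2 * sum(elpd),
              pointwise = elpd,
              pareto_k = k)
  class(out) <- "psis_loo"
  out
}

#' Compare fitted models by LOOIC
#'
#' Computes PSIS-LOO for each fit and tabulates LOOIC and the difference
#' from the best (smallest-LOOIC) model, with the standard error of each
#' difference from the paired pointwise elpd values.
#'
#' @param fits Named list of fitted objects that carry a draws x
#'   observations `log_lik` matrix (element `log_lik`), or of raw matrices.
#' @return data.frame with columns `model`, `looic`, `delta_looic`,
#'   `se_delta`, `max_pareto_k`, ordered by LOOIC.
#' @export
loo_compare <- function(fits) {
  ll <- lapply(fits, function(f) if (is.matrix(f)) f else f$log_lik)
  if (any(vapply(ll, is.null, logical(1)))) {
    stop("every fit must carry a pointwise log-likelihood matrix")
  }
  n_obs <- vapply(ll, ncol, integer(1))
  if (length(unique(n_obs)) != 1) {
    stop("fits were computed on different observation sets; LOOIC is not comparable")
  }
  loos <- lapply(ll, psis_loo)
  looic <- vapply(loos, `[[`, numeric(1), "looic")
  best <- which.min(looic)
  se_delta <- vapply(seq_along(loos), function(j) {
    d <- loos[[j]]$pointwise - loos[[best]]$pointwise
    sqrt(length(d) * stats::var(d))
  }, numeric(1))
  out <- data.frame(
    model = names(fits) %||% sprintf("model%d", seq_along(fits)),
    looic = looic,
    delta_looic = looic - looic[best],
    se_delta = se_delta,
    max_pareto_k = vapply(loos, function(l) max(l$pareto_k, na.rm = TRUE),
                          numeric(1))
  )
  out <- out[order(out$looic), ]
  rownames(out) <- NULL
  attr(out, "loos") <- loos
  out
}
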