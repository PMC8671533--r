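# Exact Gaussian inference for the one-trend dynamic factor model
#
#   x_t = x_{t-1} + w_t,        w_t ~ N(0, q)   (q fixed = 1: identifiability)
#   y_it = Z_i x_t + v_it,      v_it ~ N(0, r_i), R diagonal and unequal
#   x_1 ~ N(mu1, P1)
#
# Missing observations simply drop out of the update step, which is what
# makes the model robust to survey years with no data.

# long (year, series_id, value) -> years x series matrix with NA for missing
panel_to_matrix <- function(panel) {
  if (is.matrix(panel)) return(panel)
  stopifnot(all(c("year", "series_id", "value") %in% names(panel)))
  years <- sort(unique(panel$year))
  sids <- unique(panel$series_id)
  m <- matrix(NA_real_, length(years), length(sids),
              dimnames = list(years, sids))
  m[cbind(match(panel$year, years), match(panel$series_id, sids))] <- panel$value
  m
}

#' Kalman filter and smoother for the one-trend DFA model
#'
#' Runs the exact Gaussian filter/smoother for a random-walk latent trend
#' observed through per-series loadings with diagonal observation noise.
#' Missing entries contribute nothing to the update step.
#'
#' @param params List with `Z` (loadings), `r` (observation variances, >= 0),
#'   `mu1` (initial state mean), and optionally `P1` (initial variance,
#'   default 1) and `q` (process variance, default 1).
#' @param panel Years x series numeric matrix (NA = missing), or a long
#'   data.frame with columns `year`, `series_id`, `value`.
#' @return List with smoothed states `x_smooth`, variances `p_smooth`,
#'   lag-one smoothed covariances `p_lag1`, filtered moments, and the exact
#'   marginal `loglik`.
#' @export
kalman_smoother <- function(params, panel) {
  y <- panel_to_matrix(panel)
  Z <- params$Z; r <- params$r
  mu1 <- params$mu1 %||% 0
  P1 <- params$P1 %||% 1
  q <- params$q %||% 1
  stopifnot(length(Z) == ncol(y), length(r) == ncol(y))
  if (any(r < 0) || P1 < 0 || q < 0) stop("non-PSD variance encountered")
  n <- nrow(y)
  xp <- xf <- pp <- pf <- numeric(n)
  kz <- numeric(n)  # K %*% Z_o (scalar), for reference
  ll <- 0
  for (t in seq_len(n)) {
    if (t == 1) { xp[t] <- mu1; pp[t] <- P1 }
    else { xp[t] <- xf[t - 1]; pp[t] <- pf[t - 1] + q }
    o <- which(!is.na(y[t, ]))
    if (length(o) == 0) { xf[t] <- xp[t]; pf[t] <- pp[t]; next }
    zo <- Z[o]
    e <- y[t, o] - zo * xp[t]
    S <- pp[t] * tcrossprod(zo) + diag(r[o], nrow = length(o))
    cS <- tryCatch(chol(S), error = function(e) stop("non-PSD variance encountered"))
    Sinv_e <- backsolve(cS, forwardsolve(t(cS), e))
    K <- pp[t] * as.numeric(crossprod(zo, backsolve(cS, forwardsolve(t(cS), diag(length(o))))))
    # K is 1 x |o| gain; update
    xf[t] <- xp[t] + sum(K * e)
    kz[t] <- sum(K * zo)
    pf[t] <- (1 - kz[t]) * pp[t]
    ll <- ll - 0.5 * (length(o) * log(2 * pi) + 2 * sum(log(diag(cS))) +
                        sum(e * Sinv_e))
  }
  # Rauch-Tung-Striebel smoother (scalar state)
  xs <- xf; ps <- pf
  J <- numeric(n)
  for (t in (n - 1):1) {
    J[t] <- if (pp[t + 1] > 0) pf[t] / pp[t + 1] else 0
    xs[t] <- xf[t] + J[t] * (xs[t + 1] - xp[t + 1])
    ps[t] <- pf[t] + J[t]^2 * (ps[t + 1] - pp[t + 1])
  }
  # lag-one smoothed covariance: cov(x_t, x_{t-1} | y) = J_{t-1} * P^s_t
  p_lag1 <- c(NA_real_, J[seq_len(n - 1)] * ps[2:n])
  list(x_smooth = xs, p_smooth = ps, p_lag1 = p_lag1,
       x_filter = xf, p_filter = pf, x_pred = xp, p_pred = pp,
       loglik = ll)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
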