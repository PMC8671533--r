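# Dynamic Factor Analysis: one shared latent trend extracted from a panel
# of (log) survey indices by EM, with exact Kalman smoothing in the E-step.
# Identifiability: process variance fixed at 1, sign fixed so the mean
# loading is non-negative. Each series is standardized to zero mean / unit
# variance over its observed entries before fitting (the figure-scale
# convention); loadings are also reported rescaled to a unit-variance trend
# on the original data scale, which is the scale-free quantity simulation
# studies can compare against a known truth.

dfa_negloglik <- function(theta, y, n_series) {
  Z <- theta[seq_len(n_series)]
  r <- exp(theta[n_series + seq_len(n_series)])
  mu1 <- theta[2 * n_series + 1]
  -kalman_smoother(list(Z = Z, r = r, mu1 = mu1), y)$loglik
}

numeric_hessian <- function(f, x, h = 1e-4 * (1 + abs(x))) {
  p <- length(x)
  H <- matrix(NA_real_, p, p)
  for (i in seq_len(p)) {
    for (j in i:p) {
      ei <- ej <- numeric(p); ei[i] <- h[i]; ej[j] <- h[j]
      H[i, j] <- H[j, i] <-
        (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
        (4 * h[i] * h[j])
    }
  }
  H
}

#' Fit a one-trend Dynamic Factor Analysis model
#'
#' EM estimation (Kalman smoother E-step, closed-form M-step) of a shared
#' random-walk latent trend with per-series loadings and unequal,
#' uncorrelated observation variances. Missing values are handled exactly by
#' the smoother. The EM log-likelihood is checked to be non-decreasing at
#' every iteration; a decrease aborts with an error since it indicates a
#' broken E/M step rather than a data problem.
#'
#' @param panel Long data.frame (`year`, `series_id`, `value`) or a years x
#'   series matrix; NA marks missing survey years.
#' @param n_trends Number of latent trends; only 1 is supported.
#' @param standardize Standardize each series over its observed entries
#'   before fitting (default TRUE).
#' @param em_tol Relative log-likelihood convergence tolerance.
#' @param em_maxit Maximum EM iterations.
#' @param ci_method `"hessian"` (observed-information SEs for loadings) or
#'   `"bootstrap"` (parametric bootstrap, for small samples).
#' @param n_boot Bootstrap replicates when `ci_method = "bootstrap"`.
#' @param seed Seed for the bootstrap.
#' @return A `dfa_result` with elements `trend` (year, estimate, lo95, hi95),
#'   `loadings` (standardized-scale estimate, se, lo95, hi95),
#'   `loadings_scaled` (original-scale loadings on a unit-variance trend),
#'   `obs_variance`, `loglik`, `loglik_trace`, `converged`, `iterations`.
#' @export
fit_dfa <- function(panel, n_trends = 1, standardize = TRUE,
                    em_tol = 1e-6, em_maxit = 5000,
                    ci_method = c("hessian", "bootstrap"), n_boot = 100,
                    seed = 1) {
  ci_method <- match.arg(ci_method)
  if (n_trends != 1) stop("only one latent trend is supported")
  y_raw <- panel_to_matrix(panel)
  years <- suppressWarnings(as.numeric(rownames(y_raw)))
  if (anyNA(years)) years <- seq_len(nrow(y_raw))

  n_obs_per_series <- colSums(!is.na(y_raw))
  drop <- n_obs_per_series < 2
  if (any(drop)) {
    far_warn("fit_dfa: dropping series with <2 observations: %s",
             paste(colnames(y_raw)[drop], collapse = ", "))
    y_raw <- y_raw[, !drop, drop = FALSE]
  }
  if (ncol(y_raw) < 2) stop("at least 2 usable series are required")

  centers <- colMeans(y_raw, na.rm = TRUE)
  scales <- apply(y_raw, 2, stats::sd, na.rm = TRUE)
  if (standardize) {
    if (any(scales == 0)) stop("cannot standardize a constant series")
    y <- sweep(sweep(y_raw, 2, centers), 2, scales, "/")
  } else {
    y <- y_raw
    centers <- rep(0, ncol(y)); scales <- rep(1, ncol(y))
  }

  m <- ncol(y); n <- nrow(y)
  Z <- rep(0.5, m)
  r <- rep(0.5, m)
  mu1 <- 0
  ll_trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(em_maxit)) {
    sm <- kalman_smoother(list(Z = Z, r = r, mu1 = mu1), y)
    ll <- sm$loglik
    if (length(ll_trace) > 0) {
      if (ll < ll_trace[length(ll_trace)] - 1e-8 * (1 + abs(ll))) {
        stop(sprintf("EM log-likelihood decreased at iteration %d (%.8f -> %.8f)",
                     it, ll_trace[length(ll_trace)], ll))
      }
      if (abs(ll - ll_trace[length(ll_trace)]) <
          em_tol * (abs(ll_trace[length(ll_trace)]) + em_tol)) {
        ll_trace <- c(ll_trace, ll)
        converged <- TRUE
        break
      }
    }
    ll_trace <- c(ll_trace, ll)
    xs <- sm$x_smooth
    St <- sm$p_smooth + xs^2   # E[x_t^2 | y]
    for (i in seq_len(m)) {
      o <- which(!is.na(y[, i]))
      Z[i] <- sum(y[o, i] * xs[o]) / sum(St[o])
      r[i] <- max(mean(y[o, i]^2 - 2 * y[o, i] * Z[i] * xs[o] + Z[i]^2 * St[o]),
                  1e-8)
    }
    mu1 <- xs[1]
  }
  if (!converged) {
    far_warn("fit_dfa: EM did not converge within %d iterations", em_maxit)
  }

  # sign convention: mean loading non-negative
  if (mean(Z) < 0) { Z <- -Z; mu1 <- -mu1 }
  sm <- kalman_smoother(list(Z = Z, r = r, mu1 = mu1), y)

  se <- rep(NA_real_, m)
  if (ci_method == "hessian") {
    theta <- c(Z, log(r), mu1)
    H <- numeric_hessian(function(th) dfa_negloglik(th, y, m), theta)
    V <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(V) && all(diag(V)[seq_len(m)] > 0)) {
      se <- sqrt(diag(V)[seq_len(m)])
    } else {
      far_warn("fit_dfa: observed-information matrix not invertible; loading SEs unavailable (try ci_method = 'bootstrap')")
    }
  } else {
    set.seed(substream_seed(seed, "dfa-bootstrap"))
    bz <- matrix(NA_real_, n_boot, m)
    for (b in seq_len(n_boot)) {
      xb <- cumsum(c(stats::rnorm(1, mu1, 1), stats::rnorm(n - 1)))
      yb <- sapply(seq_len(m), function(i) Z[i] * xb + stats::rnorm(n, 0, sqrt(r[i])))
      yb[is.na(y)] <- NA
      fb <- tryCatch(
        fit_dfa(yb, standardize = FALSE, em_tol = 1e-5, em_maxit = 500,
                ci_method = "hessian"),
        error = function(e) NULL)
      if (!is.null(fb)) bz[b, ] <- fb$loadings$estimate
    }
    se <- apply(bz, 2, stats::sd, na.rm = TRUE)
  }

  xs <- sm$x_smooth
  trend_sd <- stats::sd(xs)
  loadings <- data.frame(
    series_id = colnames(y) %||% sprintf("series%d", seq_len(m)),
    estimate = Z, se = se,
    lo95 = Z - 1.96 * se, hi95 = Z + 1.96 * se
  )
  loadings_scaled <- data.frame(
    series_id = loadings$series_id,
    estimate = Z * scales * trend_sd,
    lo95 = loadings$lo95 * scales * trend_sd,
    hi95 = loadings$hi95 * scales * trend_sd
  )
  out <- list(
    trend = data.frame(year = years, estimate = xs,
                       lo95 = xs - 1.96 * sqrt(sm$p_smooth),
                       hi95 = xs + 1.96 * sqrt(sm$p_smooth)),
    loadings = loadings,
    loadings_scaled = loadings_scaled,
    obs_variance = stats::setNames(r, loadings$series_id),
    series_center = centers, series_scale = scales,
    loglik = sm$loglik, loglik_trace = ll_trace,
    converged = converged, iterations = length(ll_trace)
  )
  class(out) <- "dfa_result"
  out
}

#' @export
print.dfa_result <- function(x, ...) {
  cat("Dynamic Factor Analysis (1 shared trend)\n")
  cat(sprintf("  %d years x %d series, logLik %.2f, EM iterations %d%s\n",
              nrow(x$trend), nrow(x$loadings), x$loglik, x$iterations,
              if (x$converged) "" else " (not converged)"))
  cat("  Loadings (standardized series):\n")
  print(x$loadings, row.names = FALSE, digits = 3)
  invisible(x)
}
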