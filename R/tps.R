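# Low-rank thin-plate spline basis for one covariate.
#
# Construction: radial basis |x - x_j|^3 on the (standardized) observed
# covariate values, with the order-2 polynomial null space {1, x} removed by
# projection (Q2 = orthogonal complement of [1, x]); the projected penalty
# Q2' E Q2 is positive semi-definite and its leading eigenvectors give the
# low-rank penalized basis. A smooth with k total basis functions has an
# intercept, a linear term, and k - 2 penalized columns; the supported
# sizes are k = 3 (short annual series, e.g. FAR) and k = 5 (e.g. day of
# year). Basis functions are explicit linear combinations of |x - knot|^3,
# so they can be evaluated at arbitrary (including latent) covariate values.

#' Build a low-rank thin-plate spline basis
#'
#' @param x Observed covariate values (used as knots and for scaling).
#' @param k Total number of basis functions (3 or 5).
#' @return A `tps_basis` object used by [tps_design()].
#' @export
tps_basis <- function(x, k = 3) {
  if (!k %in% c(3, 5)) stop("'k' must be 3 or 5 basis functions")
  x <- as.numeric(x)
  if (length(unique(x)) < k) stop(sprintf("need at least %d distinct covariate values", k))
  if (k > length(x) - 2) stop("'k' exceeds n - 2")
  xc <- mean(x); xs <- stats::sd(x)
  z <- (x - xc) / xs
  knots <- z
  E <- abs(outer(z, z, "-"))^3
  Tm <- cbind(1, z)
  qrT <- qr(Tm)
  Q2 <- qr.Q(qrT, complete = TRUE)[, -(1:2), drop = FALSE]
  P <- crossprod(Q2, E %*% Q2)
  P <- (P + t(P)) / 2
  eg <- eigen(P, symmetric = TRUE)
  nk <- k - 2
  V <- eg$vectors[, seq_len(nk), drop = FALSE]
  lambda <- pmax(eg$values[seq_len(nk)], 1e-10)
  W <- Q2 %*% V                       # knot weights: phi(x) = e(x)' W
  phi <- E %*% W
  phi_center <- colMeans(phi)
  phi_scale <- apply(phi, 2, stats::sd)
  phi_scale[phi_scale == 0] <- 1
  # penalty on the rescaled coefficients, normalized to max 1
  pen <- lambda / phi_scale^2
  pen <- pen / max(pen)
  structure(list(knots = knots, W = W, x_center = xc, x_scale = xs,
                 phi_center = phi_center, phi_scale = phi_scale,
                 penalty = pen, k = k),
            class = "tps_basis")
}

#' Evaluate a thin-plate spline design matrix
#'
#' @param basis A [tps_basis()] object.
#' @param x Covariate values at which to evaluate.
#' @return Matrix with `basis$k` columns: intercept, linear term, and
#'   centered/scaled penalized columns.
#' @export
tps_design <- function(basis, x) {
  z <- (as.numeric(x) - basis$x_center) / basis$x_scale
  E <- abs(outer(z, basis$knots, "-"))^3
  phi <- E %*% basis$W
  phi <- sweep(sweep(phi, 2, basis$phi_center), 2, basis$phi_scale, "/")
  cbind(intercept = 1, linear = z, phi)
}
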