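#' @keywords internal
"_PACKAGE"

logit <- function(p) log(p / (1 - p))

ilogit <- function(x) 1 / (1 + exp(-x))

#' Derive a reproducible sub-stream seed
#'
#' Expands one global seed into independent per-generator seeds, so adding a
#' new generator to a workflow never perturbs the draws of existing ones.
#'
#' @param seed Integer master seed.
#' @param stream Character label of the random stream (e.g. `"climate"`).
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((abs(seed) * 48271 + h * 69621) %% 2147483587 + 1)
}

# Standardize to zero mean / unit variance over non-missing entries,
# recording the constants needed to invert the transform.
standardize <- function(x) {
  m <- mean(x, na.rm = TRUE)
  s <- stats::sd(x, na.rm = TRUE)
  if (!is.finite(s) || s <= 0) {
    stop("cannot standardize: standard deviation is zero or undefined")
  }
  z <- (x - m) / s
  attr(z, "center") <- m
  attr(z, "scale") <- s
  z
}

unstandardize <- function(z, center, scale) z * scale + center

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
  if (if (strict_lower) x <= lower else x < lower) {
    stop(sprintf("'%s' must be %s %s", name,
                 if (strict_lower) ">" else ">=", lower), call. = FALSE)
  }
  if (if (strict_upper) x >= upper else x > upper) {
    stop(sprintf("'%s' must be %s %s", name,
                 if (strict_upper) "<" else "<=", upper), call. = FALSE)
  }
  invisible(x)
}

check_count <- function(x, name, min = 1) {
  check_scalar(x, name, lower = min)
  if (x != round(x)) stop(sprintf("'%s' must be an integer", name), call. = FALSE)
  invisible(as.integer(x))
}

# warning-level log line; all clamps, dropped series and non-converged fits
# pass through here so they are visible but summarized
far_warn <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

equal_tailed <- function(x, level) {
  a <- (1 - level) / 2
  unname(stats::quantile(x, c(a, 1 - a), names = FALSE, type = 7))
}
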