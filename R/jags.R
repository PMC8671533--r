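# Thin wrapper around rjags: compile, adapt, burn, sample, and return the
# posterior as an iterations x chains x parameters array (the layout the
# convergence diagnostics expect). Chain RNGs are seeded deterministically
# from one integer seed.

run_jags <- function(model_string, data, monitor, chains = 2, adapt = 500,
                     burn = 500, iter = 1000, thin = 1, seed = 1,
                     inits = NULL) {
  stopifnot(chains >= 1)
  init_list <- lapply(seq_len(chains), function(c) {
    ini <- list(.RNG.name = "base::Mersenne-Twister",
                .RNG.seed = (seed * 7 + c * 104729) %% 2147483647)
    if (!is.null(inits)) ini <- c(inits(c), ini)
    ini
  })
  con <- textConnection(model_string)
  on.exit(close(con), add = TRUE)
  jm <- rjags::jags.model(con, data = data, inits = init_list,
                          n.chains = chains, n.adapt = adapt, quiet = TRUE)
  if (burn > 0) stats::update(jm, n.iter = burn, progress.bar = "none")
  samp <- rjags::coda.samples(jm, variable.names = monitor, n.iter = iter,
                              thin = thin, progress.bar = "none")
  draws <- mcmc_to_array(samp)
  list(draws = draws, model = jm)
}

# coda::mcmc.list -> iterations x chains x parameters array
mcmc_to_array <- function(samp) {
  mats <- lapply(samp, as.matrix)
  pn <- colnames(mats[[1]])
  arr <- array(NA_real_, dim = c(nrow(mats[[1]]), length(mats), length(pn)),
               dimnames = list(NULL, NULL, pn))
  for (c in seq_along(mats)) arr[, c, ] <- mats[[c]]
  arr
}

# extract the columns of an indexed JAGS variable in numeric index order
indexed_cols <- function(dm, prefix) {
  idx <- grep(paste0("^", prefix, "\\["), colnames(dm))
  if (length(idx) == 0) {
    idx <- which(colnames(dm) == prefix)
    return(dm[, idx, drop = FALSE])
  }
  nums <- as.integer(sub(".*\\[(\\d+)\\]$", "\\1", colnames(dm)[idx]))
  dm[, idx[order(nums)], drop = FALSE]
}

# iterations x chains x parameters array -> (iterations*chains) x parameters
flatten_draws <- function(draws) {
  d <- dim(draws)
  out <- matrix(aperm(draws, c(1, 2, 3)), nrow = d[1] * d[2], ncol = d[3])
  colnames(out) <- dimnames(draws)[[3]]
  out
}
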