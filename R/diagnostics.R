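as_chain_list <- function(chains) {
  if (is.matrix(chains)) chains <- lapply(seq_len(ncol(chains)),
                                          function(j) chains[, j])
  if (!is.list(chains)) stop("chains must be a list or a matrix", call. = FALSE)
  n <- unique(vapply(chains, length, integer(1)))
  if (length(n) != 1) stop("all chains must have equal length", call. = FALSE)
  chains
}

#' Gelman-Rubin potential scale reduction factor
#'
#' The original (non-split) PSRF: with `m` chains of length `n`, within-
#' chain variance `W` (mean of the per-chain variances) and between-chain
#' variance `B/n` (variance of the chain means), the pooled variance
#' estimate is `V = (n-1)/n * W + B/n` and the PSRF is `sqrt(V / W)`.
#' The upper confidence limit uses the standard F-quantile interval on
#' the between/within variance ratio.
#'
#' @param chains List of equal-length numeric vectors (one per chain) or
#'   a matrix with one chain per column; at least two chains of length
#'   >= 10.
#' @param conf Confidence level of the upper limit (default 0.975
#'   quantile).
#' @return Named vector `c(psrf, upper)`.
#' @export
gelman_rubin <- function(chains, conf = 0.975) {
  chains <- as_chain_list(chains)
  m <- length(chains)
  if (m < 2) stop("Gelman-Rubin diagnostic needs at least 2 chains",
                  call. = FALSE)
  n <- length(chains[[1]])
  if (n < 10) stop("chains are too short (need length >= 10)", call. = FALSE)
  means <- vapply(chains, mean, numeric(1))
  vars <- vapply(chains, stats::var, numeric(1))
  W <- mean(vars)
  B_over_n <- stats::var(means)               # = B/n
  V <- (n - 1) / n * W + B_over_n
  if (W == 0) {
    # constant chains: PSRF undefined; degenerate agreement
    return(c(psrf = 1, upper = 1))
  }
  psrf <- sqrt(V / W)
  # F-based upper limit on the variance-ratio term
  var_w <- stats::var(vars) / m
  df_w <- if (var_w > 0) 2 * W^2 / var_w else Inf
  upper2 <- (n - 1) / n + stats::qf(conf, m - 1, df_w) * B_over_n / W
  c(psrf = psrf, upper = sqrt(upper2))
}

# truncated-autocorrelation ESS of a single chain: 1 + 2 * sum of the
# initial positive sequence of sample autocorrelations
ess_one <- function(x) {
  n <- length(x)
  if (stats::var(x) == 0) {
    warning("constant chain: autocorrelation undefined, reporting ESS = n")
    return(n)
  }
  lag_max <- min(n - 1, max(50, floor(10 * log10(n))))
  rho <- stats::acf(x, lag.max = lag_max, plot = FALSE,
                    demean = TRUE)$acf[-1]
  neg <- which(rho < 0)
  if (length(neg)) rho <- rho[seq_len(neg[1] - 1)]
  n / (1 + 2 * sum(rho))
}

#' Effective sample size of MCMC chains
#'
#' Autocorrelation-based ESS: per chain, `n / (1 + 2 * sum(rho_k))` with
#' the sample autocorrelations truncated at the first negative value
#' (initial positive sequence), then summed across chains. White noise
#' gives ESS close to the total number of draws; an AR(1) chain with
#' lag-1 correlation `rho` gives roughly `n * (1 - rho) / (1 + rho)`.
#'
#' @param chains As in [gelman_rubin()]; a single chain (numeric vector)
#'   is also accepted.
#' @return The combined effective sample size (a single number).
#' @export
effective_sample_size <- function(chains) {
  if (is.numeric(chains) && !is.matrix(chains)) chains <- list(chains)
  chains <- as_chain_list(chains)
  sum(vapply(chains, ess_one, numeric(1)))
}
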