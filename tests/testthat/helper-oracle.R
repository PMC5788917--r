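# Brute-force grid quadrature of the no-random-effect posterior over
# (beta, phi) for a handful of trials. Written independently of the
# package internals (density spelled out with dbeta/plogis directly) so
# it can serve as an oracle for the MCMC sampler.
grid_posterior_means <- function(trials_u, beta_grid, phi_grid,
                                 beta_sd = 1, phi_rate = 1) {
  li <- qlogis(trials_u$initial_u)
  ls <- qlogis(trials_u$social_u)
  y <- trials_u$final_u
  logpost <- matrix(NA_real_, length(beta_grid), length(phi_grid))
  for (i in seq_along(beta_grid)) {
    mu <- plogis(li + beta_grid[i] * (ls - li))
    for (j in seq_along(phi_grid)) {
      phi <- phi_grid[j]
      logpost[i, j] <- sum(dbeta(y, mu * phi, (1 - mu) * phi, log = TRUE)) +
        dnorm(beta_grid[i], 0, beta_sd, log = TRUE) +
        dexp(phi, phi_rate, log = TRUE)
    }
  }
  w <- exp(logpost - max(logpost))
  list(beta = sum(outer(beta_grid, rep(1, length(phi_grid))) * w) / sum(w),
       phi = sum(outer(rep(1, length(beta_grid)), phi_grid) * w) / sum(w),
       weight = w)
}
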