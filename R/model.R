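#' Specify the social-influence model
#'
#' Configures the likelihood, link and priors of the hierarchical beta
#' model of social influence. Final ratings (on the unit scale) are
#' beta-distributed, `final_u ~ Beta(mu * phi, (1 - mu) * phi)`, with mean
#' `mu` interpolating between the initial and the social rating by the
#' participant-and-condition-specific influence `s` (see
#' [predicted_mean()]). Condition effects get `N(0, 1)` priors (variance
#' 100 under `flat_priors`), the random-effect variance(s) and the
#' precision `phi` get `Exp(1)` priors.
#'
#' @param link `"logit"` (default): interpolation on the log-odds scale,
#'   which keeps `mu` inside (0,1) for any real `s`; `"raw"`:
#'   interpolation on the unit scale, clamped away from the boundary.
#' @param random_effects `"shared"` (default): one deviation `u_p` per
#'   participant applied in every condition; `"per_condition"`: a
#'   deviation `u_{p,c}` per participant and condition, each condition
#'   with its own variance; `"none"`: no random effects (used e.g. for
#'   single-participant data where `s` and `u` are confounded).
#' @param flat_priors Logical; widen the condition-effect priors to
#'   variance 100 for prior-robustness checks.
#' @param beta_prior_sd Standard deviation of the condition-effect prior
#'   (default 1, or 10 under `flat_priors`).
#' @param re_var_rate,phi_rate Rates of the exponential priors on the
#'   random-effect variance(s) and on the precision.
#' @return An object of class `influence_spec`.
#' @export
influence_spec <- function(link = c("logit", "raw"),
                           random_effects = c("shared", "per_condition",
                                              "none"),
                           flat_priors = FALSE,
                           beta_prior_sd = if (flat_priors) 10 else 1,
                           re_var_rate = 1,
                           phi_rate = 1) {
  link <- match.arg(link)
  random_effects <- match.arg(random_effects)
  stopifnot(beta_prior_sd > 0, re_var_rate > 0, phi_rate > 0)
  structure(list(link = link, random_effects = random_effects,
                 flat_priors = flat_priors, beta_prior_sd = beta_prior_sd,
                 re_var_rate = re_var_rate, phi_rate = phi_rate),
            class = "influence_spec")
}

#' Predicted mean final rating under a given social influence
#'
#' The model's mean function: with influence `s = 0` the predicted final
#' rating equals the initial rating; with `s = 1` it equals the displayed
#' social rating; intermediate `s` interpolates, and `s < 0`
#' ("contrariness") or `s > 1` ("over-adjustment") extrapolate. Under the
#' default logit link the interpolation happens on the log-odds scale:
#' `mu = plogis(qlogis(I) + s * (qlogis(S) - qlogis(I)))`.
#'
#' @param initial_u,social_u Unit-interval initial and social ratings,
#'   strictly inside (0, 1) (see [rating_to_unit()]).
#' @param s Social influence value(s); any real number.
#' @param link `"logit"` or `"raw"`.
#' @return The predicted mean final rating on the unit scale.
#' @examples
#' predicted_mean(0.5, 0.8, c(0, 0.5, 1))
#' @export
predicted_mean <- function(initial_u, social_u, s, link = "logit") {
  link <- match.arg(link, c("logit", "raw"))
  if (any(initial_u <= 0 | initial_u >= 1 | social_u <= 0 | social_u >= 1)) {
    stop("initial_u and social_u must lie strictly inside (0, 1)",
         call. = FALSE)
  }
  if (link == "logit") {
    li <- stats::qlogis(initial_u)
    ls <- stats::qlogis(social_u)
    stats::plogis(li + s * (ls - li))
  } else {
    eps <- 1e-6
    pmin(pmax(initial_u + s * (social_u - initial_u), eps), 1 - eps)
  }
}

# s for every trial given a parameter list (reference implementation).
trial_influence <- function(params, trials, spec) {
  s <- params$beta[trials$condition]
  if (spec$random_effects == "shared") {
    s <- s + params$u[trials$participant_id]
  } else if (spec$random_effects == "per_condition") {
    s <- s + params$u[paste(trials$participant_id, trials$condition,
                            sep = ".")]
  }
  unname(s)
}

#' Log likelihood and log prior of the social-influence model
#'
#' Reference implementations of the model's joint density, summing the
#' `Beta(mu * phi, (1 - mu) * phi)` log density over trials
#' (`influence_loglik`) and the parameter priors (`influence_logprior`).
#' The MCMC sampler uses an equivalent compiled kernel; these functions
#' exist for direct evaluation, quadrature and testing.
#'
#' @param params List with elements `beta` (named vector, one per
#'   condition), `u` (named participant deviations; omit under
#'   `random_effects = "none"`), `sigma2` (random-effect variance(s)),
#'   and `phi` (precision > 0).
#' @param trials Trial data frame containing `initial_u`, `social_u`,
#'   `final_u`, `condition`, `participant_id` (see the transformed
#'   columns added during fitting, or build them with [rating_to_unit()]).
#' @param spec An [influence_spec()].
#' @return A single log density. `influence_logprior` returns `-Inf` for
#'   `phi <= 0` or nonpositive variances rather than erroring.
#' @export
influence_loglik <- function(params, trials, spec = influence_spec()) {
  s <- trial_influence(params, trials, spec)
  mu <- predicted_mean(trials$initial_u, trials$social_u, s, spec$link)
  ll <- sum(stats::dbeta(trials$final_u, mu * params$phi,
                         (1 - mu) * params$phi, log = TRUE))
  if (!is.finite(ll)) {
    bad <- which(!is.finite(stats::dbeta(trials$final_u, mu * params$phi,
                                         (1 - mu) * params$phi, log = TRUE)))
    stop(sprintf("non-finite log likelihood at trial %d", bad[1]),
         call. = FALSE)
  }
  ll
}

#' @rdname influence_loglik
#' @export
influence_logprior <- function(params, spec = influence_spec()) {
  if (params$phi <= 0) return(-Inf)
  lp <- sum(stats::dnorm(params$beta, 0, spec$beta_prior_sd, log = TRUE)) +
    stats::dexp(params$phi, spec$phi_rate, log = TRUE)
  if (spec$random_effects != "none") {
    if (any(params$sigma2 <= 0)) return(-Inf)
    lp <- lp + sum(stats::dexp(params$sigma2, spec$re_var_rate, log = TRUE))
    if (spec$random_effects == "shared") {
      lp <- lp + sum(stats::dnorm(params$u, 0, sqrt(params$sigma2), log = TRUE))
    } else {
      # u named "<pid>.<condition>", sigma2 named by condition
      cond <- sub("^.*\\.", "", names(params$u))
      lp <- lp + sum(stats::dnorm(params$u, 0,
                                  sqrt(params$sigma2[cond]), log = TRUE))
    }
  }
  lp
}

derive_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Fit the hierarchical social-influence model by MCMC
#'
#' Draws from the posterior of the social-influence model with an
#' adaptive random-walk Metropolis-within-Gibbs sampler: one block per
#' condition effect, per participant deviation, per random-effect
#' variance, and for the precision `phi` (the last two on the log scale).
#' Step sizes adapt toward ~44% acceptance during burn-in only. Chains
#' start from overdispersed initial values (condition effects drawn from
#' their prior per chain) so that the Gelman-Rubin diagnostic is
#' meaningful, and are seeded from independent substreams of `seed`, so
#' the same call reproduces identical draws.
#'
#' @param data A [social_dataset()] or a trial data frame with the columns
#'   of [social_dataset()].
#' @param spec An [influence_spec()].
#' @param chains Number of parallel chains (default 3).
#' @param iter Iterations per chain (default 50,000).
#' @param burnin Burn-in iterations discarded per chain (default 5,000).
#' @param thin Keep every `thin`-th post-burn-in draw (default 10).
#' @param seed Master seed; per-chain seeds are derived from it.
#' @return An object of class `influence_fit` with per-chain draw
#'   matrices (columns named `beta[<condition>]`, `u[<participant>]`,
#'   `sigma2_u`, `phi`), the model spec, the MCMC configuration and the
#'   (transformed) data. Use [summary.influence_fit()], [coef()],
#'   [predict()], [contrast()], [fit_check()].
#' @examples
#' d <- simulate_experiment(experiment_design(n_groups = 1, group_sizes = 5),
#'                          true_parameters(), seed = 3)
#' fit <- influence_fit(d, chains = 2, iter = 2000, burnin = 500, thin = 5)
#' coef(fit)
#' @export
influence_fit <- function(data, spec = influence_spec(), chains = 3,
                          iter = 50000, burnin = 5000, thin = 10, seed = 1) {
  trials <- if (inherits(data, "social_dataset")) data$trials else
    as.data.frame(data)
  validate_trials(trials)
  if (nrow(trials) == 0) stop("no trials to fit", call. = FALSE)
  stopifnot(inherits(spec, "influence_spec"))
  if (burnin >= iter) stop("burnin must be smaller than iter", call. = FALSE)
  if (thin < 1) stop("thin must be >= 1", call. = FALSE)
  n_keep <- length(seq(burnin + thin, iter, by = thin))
  if (n_keep < 1) stop("no kept draws: increase iter or reduce thin",
                       call. = FALSE)

  trials <- transform_trials(trials)
  conditions <- CONDITIONS[CONDITIONS %in% unique(trials$condition)]
  participants <- sort(unique(trials$participant_id))
  cond_idx <- match(trials$condition, conditions) - 1L
  pid_idx <- match(trials$participant_id, participants) - 1L
  n_cond <- length(conditions)
  n_part <- length(participants)
  re_mode <- match(spec$random_effects, c("shared", "per_condition", "none")) - 1L
  n_u <- switch(spec$random_effects, shared = n_part,
                per_condition = n_part * n_cond, none = 0L)
  n_s2 <- switch(spec$random_effects, shared = 1L,
                 per_condition = n_cond, none = 0L)

  par_names <- c(sprintf("beta[%s]", conditions),
                 if (n_u > 0 && spec$random_effects == "shared")
                   sprintf("u[%s]", participants)
                 else if (n_u > 0)
                   sprintf("u[%s,%s]",
                           rep(participants, each = n_cond),
                           rep(conditions, n_part)),
                 if (n_s2 == 1) "sigma2_u"
                 else if (n_s2 > 1) sprintf("sigma2_u[%s]", conditions),
                 "phi")

  li <- stats::qlogis(trials$initial_u)
  ls <- stats::qlogis(trials$social_u)
  ly <- log(trials$final_u)
  l1y <- log1p(-trials$final_u)

  chain_seeds <- derive_seeds(seed, chains)
  draws <- vector("list", chains)
  accept <- vector("list", chains)
  for (ch in seq_len(chains)) {
    set.seed(chain_seeds[ch])
    beta0 <- stats::rnorm(n_cond, 0, spec$beta_prior_sd)
    u0 <- rep(0, max(n_u, 1))
    s20 <- rep(0, max(n_s2, 1)) + stats::rnorm(max(n_s2, 1), 0, 0.1)
    lphi0 <- stats::rnorm(1, 0, 0.1)
    res <- mwg_sampler(li, ls, trials$initial_u, trials$social_u, ly, l1y,
                       cond_idx, pid_idx, n_cond, n_part,
                       if (spec$link == "logit") 0L else 1L, re_mode,
                       spec$beta_prior_sd, spec$re_var_rate, spec$phi_rate,
                       iter, burnin, thin, beta0, u0, s20, lphi0)
    colnames(res$draws) <- par_names
    draws[[ch]] <- res$draws
    accept[[ch]] <- res$accept
  }

  structure(list(draws = draws, par_names = par_names,
                 conditions = conditions, participants = participants,
                 spec = spec,
                 mcmc = list(chains = chains, iter = iter, burnin = burnin,
                             thin = thin, seed = seed,
                             chain_seeds = chain_seeds),
                 trials = trials, accept = accept,
                 call = match.call()),
            class = "influence_fit")
}

#' Pool posterior draws across chains
#'
#' @param x An `influence_fit`.
#' @param ... Unused.
#' @return A matrix of kept draws (rows) by parameters (columns), chains
#'   stacked in order.
#' @export
as.matrix.influence_fit <- function(x, ...) {
  do.call(rbind, x$draws)
}

#' @export
print.influence_fit <- function(x, ...) {
  cat("Hierarchical beta model of social influence\n")
  cat(sprintf("  link: %s interpolation; random effects: %s%s\n",
              x$spec$link, x$spec$random_effects,
              if (x$spec$flat_priors) "; flat priors" else ""))
  cat(sprintf("  %d trials, %d participants, conditions: %s\n",
              nrow(x$trials), length(x$participants),
              paste(x$conditions, collapse = ", ")))
  cat(sprintf("  %d chains x %d kept draws (iter %d, burn-in %d, thin %d)\n",
              x$mcmc$chains, nrow(x$draws[[1]]), x$mcmc$iter,
              x$mcmc$burnin, x$mcmc$thin))
  cat("Posterior medians (social influence):\n")
  print(round(coef(x), 3))
  invisible(x)
}

#' Posterior medians of the social-influence parameters
#'
#' @param object An `influence_fit`.
#' @param ... Unused.
#' @return Named vector of posterior medians of the condition-level
#'   influence parameters.
#' @export
coef.influence_fit <- function(object, ...) {
  pooled <- as.matrix(object)
  cols <- sprintf("beta[%s]", object$conditions)
  stats::setNames(apply(pooled[, cols, drop = FALSE], 2, stats::median),
                  object$conditions)
}

# posterior-mean predicted final_u per trial, using each participant's own
# random-effect draws (conditional, in-sample predictions)
posterior_mean_prediction <- function(object, trials = object$trials) {
  pooled <- as.matrix(object)
  li <- stats::qlogis(trials$initial_u)
  ls <- stats::qlogis(trials$social_u)
  beta_d <- pooled[, sprintf("beta[%s]", object$conditions), drop = FALSE]
  pred <- numeric(nrow(trials))
  for (i in seq_len(nrow(trials))) {
    s <- beta_d[, match(trials$condition[i], object$conditions)]
    if (object$spec$random_effects == "shared") {
      s <- s + pooled[, sprintf("u[%s]", trials$participant_id[i])]
    } else if (object$spec$random_effects == "per_condition") {
      s <- s + pooled[, sprintf("u[%s,%s]", trials$participant_id[i],
                                trials$condition[i])]
    }
    pred[i] <- if (object$spec$link == "logit") {
      mean(stats::plogis(li[i] + s * (ls[i] - li[i])))
    } else {
      eps <- 1e-6
      mean(pmin(pmax(trials$initial_u[i] +
                       s * (trials$social_u[i] - trials$initial_u[i]),
                     eps), 1 - eps))
    }
  }
  pred
}

#' Posterior-mean predicted final ratings
#'
#' Averages the model's mean function over the kept posterior draws,
#' including each participant's own random-effect draws (conditional,
#' in-sample predictions).
#'
#' @param object An `influence_fit`.
#' @param newdata Optional trial data frame (schema of
#'   [social_dataset()] trials); defaults to the fitted data. Its
#'   participants must be among those the model was fitted to (predictions
#'   are conditional on the participant effects).
#' @param scale `"unit"` (default) or `"raw"` (0--100 slider scale).
#' @param ... Unused.
#' @return Numeric vector of predicted final ratings.
#' @export
predict.influence_fit <- function(object, newdata = NULL,
                                  scale = c("unit", "raw"), ...) {
  scale <- match.arg(scale)
  trials <- if (is.null(newdata)) object$trials else {
    nd <- as.data.frame(newdata)
    validate_trials(nd)
    unknown <- setdiff(nd$participant_id, object$participants)
    if (length(unknown) && object$spec$random_effects != "none") {
      stop(sprintf("participant(s) not in the fitted model: %s",
                   paste(utils::head(unknown, 5), collapse = ", ")),
           call. = FALSE)
    }
    transform_trials(nd)
  }
  pred <- posterior_mean_prediction(object, trials)
  if (scale == "raw") unit_to_rating(pmin(pmax(pred, UNIT_OFFSET),
                                          1 - UNIT_OFFSET)) else pred
}

#' @export
fitted.influence_fit <- function(object, ...) {
  predict.influence_fit(object)
}

#' Response residuals on the unit scale
#'
#' @param object An `influence_fit`.
#' @param ... Unused.
#' @return Observed minus posterior-mean predicted final ratings
#'   (unit scale).
#' @export
residuals.influence_fit <- function(object, ...) {
  object$trials$final_u - fitted(object)
}

#' Posterior histograms of the social-influence parameters
#'
#' One histogram per condition with the posterior median (heavy dashed
#' line) and equal-tailed credible bounds (light dashed lines), draws
#' pooled across chains.
#'
#' @param x An `influence_fit`.
#' @param level Credible level (default 0.95).
#' @param ... Passed to [graphics::hist()].
#' @export
plot.influence_fit <- function(x, level = 0.95, ...) {
  pooled <- as.matrix(x)
  old <- graphics::par(mfrow = c(1, length(x$conditions)))
  on.exit(graphics::par(old))
  a <- (1 - level) / 2
  for (cn in x$conditions) {
    d <- pooled[, sprintf("beta[%s]", cn)]
    graphics::hist(d, breaks = 40, main = cn,
                   xlab = "social influence", ...)
    graphics::abline(v = stats::median(d), lty = 2, lwd = 2)
    graphics::abline(v = stats::quantile(d, c(a, 1 - a)), lty = 3)
  }
  invisible(x)
}

#' Posterior-predictive simulation of final ratings
#'
#' For each requested replicate, picks one kept posterior draw at random
#' and simulates final ratings for every fitted trial from the beta
#' observation law at that draw.
#'
#' @param object An `influence_fit`.
#' @param nsim Number of posterior-predictive replicates.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return A data frame with `nsim` columns of simulated `final_u`
#'   values, one row per fitted trial.
#' @export
simulate.influence_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  pooled <- as.matrix(object)
  li <- stats::qlogis(object$trials$initial_u)
  ls <- stats::qlogis(object$trials$social_u)
  n <- nrow(object$trials)
  out <- matrix(NA_real_, n, nsim)
  rows <- sample.int(nrow(pooled), nsim, replace = TRUE)
  for (j in seq_len(nsim)) {
    par <- pooled[rows[j], ]
    s <- par[sprintf("beta[%s]", object$trials$condition)]
    if (object$spec$random_effects == "shared") {
      s <- s + par[sprintf("u[%s]", object$trials$participant_id)]
    } else if (object$spec$random_effects == "per_condition") {
      s <- s + par[sprintf("u[%s,%s]", object$trials$participant_id,
                           object$trials$condition)]
    }
    mu <- if (object$spec$link == "logit") {
      stats::plogis(li + s * (ls - li))
    } else {
      eps <- 1e-6
      pmin(pmax(object$trials$initial_u +
                  s * (object$trials$social_u - object$trials$initial_u),
                eps), 1 - eps)
    }
    out[, j] <- stats::rbeta(n, mu * par["phi"], (1 - mu) * par["phi"])
  }
  as.data.frame(out, col.names = paste0("sim_", seq_len(nsim)))
}
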