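test_that("predicted mean interpolates between initial and social ratings", {
  expect_equal(predicted_mean(0.5, 0.8, 0), 0.5)
  expect_equal(predicted_mean(0.5, 0.8, 1), 0.8)
  # logistic(0.5 * ln 4) = 2/3 by hand
  expect_equal(predicted_mean(0.5, 0.8, 0.5), 2 / 3, tolerance = 1e-12)
  expect_equal(predicted_mean(0.5, 0.8, c(0, 1), link = "raw"), c(0.5, 0.8))
  expect_equal(predicted_mean(0.2, 0.6, 0.5, link = "raw"), 0.4)
  expect_error(predicted_mean(0, 0.5, 0.3), "inside")
})

test_that("log likelihood matches hand-computed beta densities", {
  tr <- transform_socinf <- toy_trials(50, 80, 50)
  tr$initial_u <- 0.5; tr$social_u <- 0.8; tr$final_u <- 0.5
  spec <- influence_spec(random_effects = "none")
  # s = 0 forces mu = 0.5; phi = 2 gives Beta(1, 1), the uniform density
  p <- list(beta = c(face = 0), phi = 2)
  expect_equal(influence_loglik(p, tr, spec), 0)
  # phi = 4 gives Beta(2, 2); density at 1/2 is 6/4
  p$phi <- 4
  expect_equal(influence_loglik(p, tr, spec), log(1.5))
})

test_that("log likelihood is invariant to trial ordering", {
  set.seed(31)
  tr <- toy_trials(runif(10, 5, 95), runif(10, 5, 95), runif(10, 5, 95))
  tr$initial_u <- rating_to_unit(tr$initial_raw)
  tr$social_u <- rating_to_unit(tr$social_raw)
  tr$final_u <- rating_to_unit(tr$final_raw)
  spec <- influence_spec(random_effects = "none")
  p <- list(beta = c(face = 0.3), phi = 7)
  expect_equal(influence_loglik(p, tr[sample.int(10), ], spec),
               influence_loglik(p, tr, spec))
})

test_that("log prior terms follow the stated prior laws", {
  spec <- influence_spec()
  base <- list(beta = c(face = 0, hand = 0, art = 0),
               u = c(P1 = 0), sigma2 = 1, phi = 1)
  lp0 <- influence_logprior(base, spec)
  # each zero-valued condition effect contributes the N(0,1) mode density
  two <- base; two$beta <- c(face = 0, hand = 0)
  expect_equal(lp0 - influence_logprior(two, spec), log(1 / sqrt(2 * pi)))
  # phi = 1 contributes exactly -1 under Exp(1)
  p2 <- base; p2$phi <- 2
  expect_equal(influence_logprior(base, spec) -
                 influence_logprior(p2, spec), 1)
  # doubling sigma2 from 1 to 2 changes its own Exp(1) term by -1
  # (the conditional normal term of u = 0 also shifts by -log(sqrt(2)))
  s2 <- base; s2$sigma2 <- 2
  expect_equal(influence_logprior(s2, spec) - lp0, -1 - 0.5 * log(2))
  # invalid states are rejected with -Inf, not an error
  bad <- base; bad$phi <- -1
  expect_identical(influence_logprior(bad, spec), -Inf)
  bad2 <- base; bad2$sigma2 <- 0
  expect_identical(influence_logprior(bad2, spec), -Inf)
})

test_that("flat-prior variant widens only the condition-effect priors", {
  flat <- influence_spec(flat_priors = TRUE)
  expect_equal(flat$beta_prior_sd, 10)
  p <- list(beta = c(face = 3), phi = 1)
  tight <- influence_spec(random_effects = "none")
  flat_none <- influence_spec(random_effects = "none", flat_priors = TRUE)
  expect_gt(influence_logprior(p, flat_none), influence_logprior(p, tight))
})

test_that("fitting is bit-reproducible under a fixed seed", {
  d <- simulate_experiment(experiment_design(n_groups = 1, group_sizes = 5),
                           true_parameters(), seed = 3)
  f1 <- influence_fit(d, chains = 2, iter = 1500, burnin = 300, thin = 5,
                      seed = 77)
  f2 <- influence_fit(d, chains = 2, iter = 1500, burnin = 300, thin = 5,
                      seed = 77)
  expect_identical(f1$draws, f2$draws)
  expect_equal(nrow(f1$draws[[1]]), (1500 - 300) / 5)
  expect_true(all(as.matrix(f1)[, "phi"] > 0))
  expect_true(all(as.matrix(f1)[, "sigma2_u"] > 0))
})

test_that("an uninformative design leaves the influence posterior at its prior", {
  tr <- uninformative_trials(n_participants = 5, n_trials = 8)
  fit <- influence_fit(tr, spec = influence_spec(random_effects = "none"),
                       chains = 2, iter = 27500, burnin = 2500, thin = 5,
                       seed = 19)
  draws <- as.matrix(fit)[, "beta[face]"]
  expect_length(draws, 10000)
  ks <- suppressWarnings(ks.test(draws, "pnorm"))
  expect_lt(unname(ks$statistic), 0.1)
})

test_that("prediction and simulation methods respect the model structure", {
  d <- simulate_experiment(experiment_design(n_groups = 1, group_sizes = 5),
                           true_parameters(), seed = 3)
  fit <- influence_fit(d, chains = 2, iter = 1500, burnin = 300, thin = 5,
                       seed = 7)
  pred <- predict(fit)
  expect_length(pred, nrow(d$trials))
  expect_true(all(pred > 0 & pred < 1))
  praw <- predict(fit, scale = "raw")
  expect_true(all(praw >= 0 & praw <= 100))
  expect_equal(residuals(fit), fit$trials$final_u - fitted(fit))
  sims <- simulate(fit, nsim = 3, seed = 5)
  expect_equal(dim(sims), c(nrow(d$trials), 3))
  expect_true(all(sims > 0 & sims < 1))
  nd <- d$trials[1:4, ]
  nd$participant_id <- "nobody"
  expect_error(predict(fit, nd), "nobody")
})
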