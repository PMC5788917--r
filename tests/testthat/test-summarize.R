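fit_small <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) {
      d <- simulate_experiment(experiment_design(n_groups = 1,
                                                 group_sizes = 6),
                               true_parameters(), seed = 15)
      memo <<- influence_fit(d, chains = 3, iter = 3000, burnin = 500,
                             thin = 5, seed = 23)
    }
    memo
  }
})

test_that("posterior summaries use pooled type-7 quantiles", {
  # draws 1..100: median 50.5, central 95% interval (3.475, 97.525)
  s <- socinf:::summarize_chains(list(1:50, 51:100))
  expect_equal(s$median, 50.5)
  expect_equal(s$lower, 3.475)
  expect_equal(s$upper, 97.525)
  # degenerate draws collapse the interval
  sc <- socinf:::summarize_chains(list(rep(4, 50), rep(4, 50)))
  expect_equal(c(sc$median, sc$lower, sc$upper), c(4, 4, 4))
})

test_that("summaries are invariant to chain relabeling and nest across levels", {
  fit <- fit_small()
  s1 <- summary(fit)
  relabeled <- fit
  relabeled$draws <- rev(relabeled$draws)
  s2 <- summary(relabeled)
  expect_equal(s1$median, s2$median)
  expect_equal(s1$lower, s2$lower)
  expect_true(all(s1$lower <= s1$median & s1$median <= s1$upper))
  expect_true(all(s1$ess <= 3 * nrow(fit$draws[[1]]) + 1e-9))
  s90 <- summary(fit, level = 0.90)
  s99 <- summary(fit, level = 0.99)
  expect_true(all(s90$lower >= s1$lower & s90$upper <= s1$upper))
  expect_true(all(s1$lower >= s99$lower & s1$upper <= s99$upper))
})

test_that("contrasts are draw-wise differences with the usual identities", {
  fit <- fit_small()
  self <- contrast(fit, "face", "face")
  expect_equal(c(self$median, self$lower, self$upper), c(0, 0, 0))
  ab <- contrast(fit, "face", "hand")
  ba <- contrast(fit, "hand", "face")
  expect_equal(ab$median, -ba$median)
  expect_equal(ab$lower, -ba$upper)
  # identical to summarizing the difference series directly
  diff_chains <- lapply(fit$draws, function(d) {
    d[, "beta[face]"] - d[, "beta[hand]"]
  })
  direct <- socinf:::summarize_chains(diff_chains)
  expect_equal(ab$median, direct$median)
  expect_equal(ab$ess, direct$ess)
  expect_error(contrast(fit, "face", "voice"), "voice")
})

test_that("fit check reports the Pearson correlation and its square", {
  fit <- fit_small()
  fc <- fit_check(fit)
  expect_equal(fc$pseudo_r2, fc$correlation^2, tolerance = 1e-12)
  expect_equal(fc$n, nrow(fit$trials))
  expect_equal(fc$correlation, cor(fc$predicted, fc$observed))
})

test_that("fit check refuses zero-variance observations", {
  fit <- fit_small()
  fit$trials$final_u <- 0.5
  expect_error(fit_check(fit), "zero variance")
})
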