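test_that("PSRF behaves at its degenerate and separated extremes", {
  x <- rnorm(500)
  # identical non-constant chains: B = 0, so PSRF = sqrt((n-1)/n) < 1
  gr <- gelman_rubin(list(x, x))
  expect_equal(unname(gr["psrf"]), sqrt(499 / 500))
  expect_lt(gr["psrf"], 1)
  # far-separated chain means blow the diagnostic up
  set.seed(8)
  far <- gelman_rubin(list(rnorm(200, 0), rnorm(200, 10)))
  expect_gt(far["psrf"], 3)
  expect_gte(far["upper"], far["psrf"])
  expect_error(gelman_rubin(list(x)), "2 chains")
})

test_that("PSRF is close to one for independent well-mixed chains", {
  set.seed(99)
  chains <- replicate(3, rnorm(10000), simplify = FALSE)
  gr <- gelman_rubin(chains)
  expect_gt(gr["psrf"], 0.99)
  expect_lt(gr["psrf"], 1.01)
})

test_that("PSRF reacts monotonically to chain separation", {
  set.seed(12)
  base <- replicate(3, rnorm(1000), simplify = FALSE)
  shifted <- base
  shifted[[2]] <- shifted[[2]] + 2
  expect_gt(gelman_rubin(shifted)["psrf"], gelman_rubin(base)["psrf"])
})

test_that("effective sample size of white noise is about the draw count", {
  set.seed(4)
  chains <- replicate(3, rnorm(5000), simplify = FALSE)
  ess <- effective_sample_size(chains)
  expect_gt(ess, 13500)
  expect_lt(ess, 16500)
})

test_that("effective sample size matches the AR(1) closed form", {
  set.seed(6)
  rho <- 0.9
  chains <- replicate(2, as.numeric(arima.sim(list(ar = rho), 10000)),
                      simplify = FALSE)
  ess <- effective_sample_size(chains)
  expected <- 20000 * (1 - rho) / (1 + rho)
  expect_gt(ess, expected * 0.75)
  expect_lt(ess, expected * 1.25)
})

test_that("effective sample size is invariant to time reversal", {
  set.seed(14)
  x <- as.numeric(arima.sim(list(ar = 0.5), 4000))
  expect_equal(effective_sample_size(list(x)),
               effective_sample_size(list(rev(x))))
})

test_that("a constant chain reports ESS = n with a warning", {
  expect_warning(ess <- effective_sample_size(list(rep(2, 100))),
                 "constant")
  expect_equal(ess, 100)
})
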