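test_that("social information implements the three peer-rating rules", {
  peers <- c(10, 20, 30, 40)
  expect_equal(social_information(peers, "all"), 25)
  expect_equal(social_information(peers, "top2"), 35)
  expect_equal(social_information(peers, "bottom2"), 15)
  expect_error(social_information(50, "all"), "at least 2")
})

test_that("top2 >= all >= bottom2 for arbitrary peer sets", {
  set.seed(11)
  for (rep in 1:50) {
    peers <- runif(sample(2:9, 1), 0, 100)
    expect_gte(social_information(peers, "top2"),
               social_information(peers, "all"))
    expect_gte(social_information(peers, "all"),
               social_information(peers, "bottom2"))
  }
})

test_that("the simulator is deterministic under a fixed seed", {
  des <- experiment_design(n_groups = 1, group_sizes = 6)
  d1 <- simulate_experiment(des, true_parameters(), seed = 7)
  d2 <- simulate_experiment(des, true_parameters(), seed = 7)
  expect_identical(d1, d2)
  d3 <- simulate_experiment(des, true_parameters(), seed = 8)
  expect_false(identical(d1$trials$final_raw, d3$trials$final_raw))
})

test_that("every simulated participant rates 10 images per condition", {
  d <- simulate_experiment(experiment_design(), true_parameters(), seed = 5)
  counts <- table(d$trials$participant_id, d$trials$condition)
  expect_true(all(counts == 10))
  expect_true(all(table(d$trials$participant_id) == 30))
})

test_that("simulated social information is reproducible from peer ratings", {
  d <- simulate_experiment(experiment_design(n_groups = 2,
                                             group_sizes = c(5, 8)),
                           true_parameters(), seed = 13)
  expect_equal(nrow(audit_social_information(d)), 0)
  # the audit localizes a single perturbed trial
  d$trials$social_raw[17] <- d$trials$social_raw[17] + 1
  flagged <- audit_social_information(d)
  expect_equal(nrow(flagged), 1)
  expect_equal(flagged$image_id, d$trials$image_id[17])
  expect_equal(flagged$participant_id, d$trials$participant_id[17])
})

test_that("peer rating table handles empty input and missing raters", {
  expect_length(peer_rating_table(data.frame()[0, ]), 0)
  d <- simulate_experiment(experiment_design(n_groups = 1, group_sizes = 5),
                           true_parameters(), seed = 3)
  holed <- d$trials[-1, ]
  expect_error(peer_rating_table(holed),
               paste0("image ", d$trials$image_id[1]))
})

test_that("rule frequencies over many trials match their probabilities", {
  des <- experiment_design(n_groups = 34, group_sizes = rep(10, 34))
  d <- simulate_experiment(des, true_parameters(), seed = 21)
  counts <- table(factor(d$trials$social_rule,
                         levels = c("all", "top2", "bottom2")))
  expect_gte(sum(counts), 10000)
  p <- chisq.test(counts, p = rep(1 / 3, 3))$p.value
  expect_gt(p, 0.01)
})

test_that("with zero influence and vanishing noise, final ratings track initial ratings", {
  truth <- true_parameters(beta = c(face = 0, hand = 0, art = 0),
                           sigma_u = 0, phi = 1e6)
  d <- simulate_experiment(experiment_design(n_groups = 1, group_sizes = 6),
                           true_parameters(beta = truth$beta,
                                           sigma_u = 0, phi = 1e6),
                           seed = 2)
  tr <- d$trials
  diff_u <- abs(rating_to_unit(tr$final_raw) - rating_to_unit(tr$initial_raw))
  expect_lt(mean(diff_u), 0.01)
})
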