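test_that("trial CSV round trip preserves every field exactly", {
  d <- toy_dataset()
  tp <- withr::local_tempfile(fileext = ".csv")
  pp <- withr::local_tempfile(fileext = ".csv")
  write_dataset(d, tp, pp)
  d2 <- read_dataset(tp, pp)
  expect_identical(d2$trials, d$trials)
  expect_identical(d2$participants, d$participants)
})

test_that("loading rejects malformed trial tables with a located error", {
  d <- toy_dataset()
  tp <- withr::local_tempfile(fileext = ".csv")
  write_trials(d$trials, tp)

  broken <- read.csv(tp, colClasses = c(participant_id = "character",
                                        group_id = "character",
                                        image_id = "character"))
  broken$final_raw <- NULL
  bp <- withr::local_tempfile(fileext = ".csv")
  write.csv(broken, bp, row.names = FALSE)
  expect_error(read_trials(bp), "final_raw")

  broken2 <- read.csv(tp, colClasses = c(participant_id = "character",
                                         group_id = "character",
                                         image_id = "character"))
  broken2$final_raw[3] <- 101
  bp2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(broken2, bp2, row.names = FALSE)
  expect_error(read_trials(bp2), "final_raw.*3")
})

test_that("dataset construction enforces cross-references and uniqueness", {
  d <- toy_dataset()
  orphan <- d$trials
  orphan$participant_id[1] <- "ZZ"
  expect_error(social_dataset(orphan, d$participants), "ZZ")
  dup <- rbind(d$trials, d$trials[1, ])
  expect_error(social_dataset(dup, d$participants), "duplicate")
})

test_that("heterosexual filter keeps participants at or below the threshold", {
  d <- toy_dataset(scores = c(A = 0, B = 1, C = 3, D = 6))
  f <- filter_heterosexual(d, max_score = 1)
  expect_setequal(f$participants$participant_id, c("A", "B"))
  expect_setequal(unique(f$trials$participant_id), c("A", "B"))
  # no-op bound keeps everyone
  expect_identical(filter_heterosexual(d, 6)$participants, d$participants)
  # original unchanged
  expect_equal(nrow(d$participants), 4)
})

test_that("heterosexual filter is monotone in its threshold", {
  d <- toy_dataset(scores = c(A = 0, B = 1, C = 2, D = 3, E = 5, F = 6))
  kept <- lapply(0:6, function(k) {
    filter_heterosexual(d, k)$participants$participant_id
  })
  for (k in 1:6) {
    expect_true(all(kept[[k]] %in% kept[[k + 1]]))
  }
})
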