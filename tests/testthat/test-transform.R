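test_that("rating transform maps the slider scale onto the open unit interval", {
  expect_equal(rating_to_unit(0), 0.0005)
  expect_equal(rating_to_unit(50), 0.5)
  expect_equal(rating_to_unit(100), 0.9995)
  x <- seq(0, 100, by = 0.25)
  y <- rating_to_unit(x)
  expect_true(all(y >= 0.0005 & y <= 0.9995))
  expect_true(all(diff(y) > 0))          # strictly increasing
})

test_that("inverse transform undoes the rating transform", {
  expect_equal(unit_to_rating(0.5), 50)
  expect_equal(unit_to_rating(0.0005), 0)
  expect_equal(unit_to_rating(0.9995), 100)
  x <- runif(200, 0, 100)
  expect_equal(unit_to_rating(rating_to_unit(x)), x, tolerance = 1e-9)
  y <- runif(200, 0.0005, 0.9995)
  expect_equal(rating_to_unit(unit_to_rating(y)), y, tolerance = 1e-9)
})

test_that("out-of-range ratings are rejected with the offending value", {
  expect_error(rating_to_unit(101), "101")
  expect_error(rating_to_unit(-0.5), "-0.5")
  expect_error(unit_to_rating(0.0004), "4e-04")
  expect_error(unit_to_rating(1), "1")
})
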