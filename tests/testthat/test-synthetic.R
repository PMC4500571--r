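test_that("expression fixtures are pure functions of (spec, seed)", {
  spec <- default_fixture_spec(noise_sd = 0)
  fx0 <- make_expression_fixture(spec, seed = 1)
  expect_equal(as.matrix(fx0), as.matrix(spec$factors))  # sd 0: exact means

  f1 <- make_expression_fixture(seed = 10)
  f2 <- make_expression_fixture(seed = 10)
  f3 <- make_expression_fixture(seed = 11)
  expect_identical(f1, f2)
  expect_false(identical(f1, f3))
  # different seeds keep the direction pattern of the means
  dir1 <- sign(f1$LMPP - f1$proB)[1:5]
  dir3 <- sign(f3$LMPP - f3$proB)[1:5]
  expect_identical(dir1, dir3)
  expect_error(make_expression_fixture(default_fixture_spec()), "seed")
})

test_that("fixture directions follow the spec means with high probability", {
  spec <- default_fixture_spec(noise_sd = 0.05)
  varying <- c("FLT3", "ZNF521", "EBF1", "PAX5", "CD19")
  want <- sign(spec$factors[varying, "LMPP"] - spec$factors[varying, "proB"])
  flips <- 0L
  for (s in 1:300) {
    fx <- make_expression_fixture(spec, seed = s)
    got <- sign(fx[varying, "LMPP"] - fx[varying, "proB"])
    flips <- flips + sum(got != want)
  }
  expect_equal(flips, 0L)
})

test_that("DE toy tables honour their planting contract", {
  t0 <- make_de_table(n = 10, n_planted = 0, seed = 5)
  expect_equal(nrow(de_filter(t0)$kept), 0)
  ta <- make_de_table(n = 200, n_planted = 30, seed = 6)
  tb <- make_de_table(n = 200, n_planted = 30, seed = 6)
  expect_identical(ta, tb)
  expect_equal(sum(ta$planted), 30)
  expect_error(make_de_table(n = 5, n_planted = 6, seed = 1), "n_planted")
})

test_that("random parameter sets are seeded, bounded and distributed", {
  base <- nominal
  # degenerate ranges collapse to the point
  sets <- sample_parameter_sets(base, list(b4 = c(0.7, 0.7)), n = 5,
                                seed = 2)
  expect_true(all(vapply(sets, function(s) s[["b4"]], 0) == 0.7))
  # log-uniform draws over [0.1, 10]: median near 1
  draws <- sample_parameter_sets(base, list(a2 = c(0.1, 10)), n = 1000,
                                 distribution = "log-uniform", seed = 3)
  a2 <- vapply(draws, function(s) s[["a2"]], 0)
  expect_true(all(a2 >= 0.1 & a2 <= 10))
  med <- stats::median(a2)
  expect_gt(med, 0.8); expect_lt(med, 1.25)
  # reproducibility and input validation
  again <- sample_parameter_sets(base, list(a2 = c(0.1, 10)), n = 1000,
                                 distribution = "log-uniform", seed = 3)
  expect_identical(vapply(again, function(s) s[["a2"]], 0), a2)
  expect_error(sample_parameter_sets(base, list(a2 = c(2, 1)), n = 1,
                                     seed = 1), "inverted")
  expect_error(sample_parameter_sets(base, list(a2 = c(0, 1)), n = 1,
                                     distribution = "log-uniform", seed = 1),
               "positive")
})
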