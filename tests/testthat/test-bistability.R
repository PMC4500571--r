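test_that("the bistability predicate tracks the switch on the reduced
          3-node module", {
  expect_true(is_bistable("ebf1_pax5_znf521", nominal))
  # without ZNF521 repression of EBF1 the module is a monotone cascade:
  # a single committed state, no switch
  p0 <- nominal; p0["a4"] <- 1e-9
  expect_false(is_bistable("ebf1_pax5_znf521", p0))
})

test_that("bistability_interval refines sound, log2-consistent boundaries
          on the 3-node module", {
  iv <- bistability_interval("ebf1_pax5_znf521", nominal, param = "b4",
                             n_scan = 17)
  expect_identical(iv$classification, "bistable_interval")
  expect_true(iv$min <= iv$nominal && iv$nominal <= iv$max)
  # log2 values recompute exactly from the stored bounds
  expect_lt(abs(iv$log2_min - log2(iv$min / iv$nominal)), 1e-9)
  expect_lt(abs(iv$log2_max - log2(iv$max / iv$nominal)), 1e-9)
  # interval soundness at the uncensored boundaries
  eps <- 2e-3  # 2x the relative refinement tolerance
  probe <- function(v) {
    p2 <- nominal; p2["b4"] <- v
    is_bistable("ebf1_pax5_znf521", p2)
  }
  if (!iv$min_censored) {
    expect_true(probe(iv$min * (1 + eps)))
    expect_false(probe(iv$min * (1 - eps)))
  }
  if (!iv$max_censored) {
    expect_true(probe(iv$max * (1 - eps)))
    expect_false(probe(iv$max * (1 + eps)))
  }
})

test_that("a scale parameter of the cubic normal form recovers its analytic
          fold-collision boundary", {
  # dx/dt = p + x - s x^3: folds exist for every s > 0 at
  # p = -+ 2/(3 sqrt(3 s)); over a fixed window p in [-1, 1] the fold pair
  # leaves the window when 2/(3 sqrt(3 s)) > 1, i.e. below s* = 4/27.
  # Bisection on "both folds inside the window" must find s*.
  window_bistable <- function(s) {
    r0 <- uniroot(function(x) -1 + x - s * x^3, c(-1e3, 0), tol = 1e-13,
                  extendInt = "yes")$root
    br <- continue_curve(function(x, p) p + x - s * x^3,
                         function(x, p) matrix(1 - 3 * s * x^2, 1, 1),
                         function(x, p) 1,
                         x0 = r0, p0 = -1, range = c(-1, 1),
                         admissible_min = -1)
    nrow(br$folds) == 2
  }
  s_star <- 4 / 27
  expect_true(window_bistable(s_star * 1.05))
  expect_false(window_bistable(s_star * 0.95))
  lo <- s_star * 0.8; hi <- s_star * 1.2
  while (hi / lo - 1 > 1e-3) {
    mid <- sqrt(lo * hi)
    if (window_bistable(mid)) hi <- mid else lo <- mid
  }
  expect_lt(abs(hi - s_star) / s_star, 1e-3)
})

test_that("the genetic algorithm hits immediately on collapsed ranges and
          is seed-reproducible", {
  ranges <- list(b4 = c(nominal[["b4"]], nominal[["b4"]]))
  sr <- search_bistable_parameters("ebf1_pax5_znf521", nominal, ranges,
                                   objective = "bistable",
                                   population = 4, generations = 2,
                                   seed = 7)
  expect_gte(length(sr$hits), 1)
  expect_equal(sr$hits[[1]]$generation, 0)
  expect_equal(sr$hits[[1]]$params[["b4"]], nominal[["b4"]])

  # every reported hit re-verifies to its recorded classification
  for (h in sr$hits) {
    ver <- bswitch:::verify_objective("ebf1_pax5_znf521", h$params, IV0,
                                      "bistable")
    expect_true(ver$ok)
    expect_identical(ver$classification, h$classification)
  }

  sr2 <- search_bistable_parameters("ebf1_pax5_znf521", nominal, ranges,
                                    objective = "bistable",
                                    population = 4, generations = 2,
                                    seed = 7)
  expect_identical(sr$fitness_trace, sr2$fitness_trace)
  expect_identical(lapply(sr$hits, `[[`, "params"),
                   lapply(sr2$hits, `[[`, "params"))
})

test_that("the GA discovers verified bistable sets in a widened box", {
  ranges <- list(b4 = nominal[["b4"]] * c(0.25, 4),
                 a4 = nominal[["a4"]] * c(0.25, 4))
  sr <- search_bistable_parameters("ebf1_pax5_znf521", nominal, ranges,
                                   objective = "bistable",
                                   population = 10, generations = 4,
                                   seed = 21)
  expect_gte(length(sr$hits), 1)
  for (h in sr$hits)
    expect_true(is_bistable("ebf1_pax5_znf521", h$params))

  # invalid inputs
  expect_error(search_bistable_parameters("ebf1_pax5_znf521", nominal,
                                          list(), seed = 1), "empty")
  expect_error(search_bistable_parameters("ebf1_pax5_znf521", nominal,
                                          list(b4 = c(2, 1)), seed = 1),
               "invalid range")
})
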