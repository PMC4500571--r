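test_that("a linear system continues to a straight fold-free branch", {
  br <- continue_curve(lin_f, lin_jx, lin_jp, x0 = 0, p0 = 0,
                       range = c(-1, 2))
  expect_equal(nrow(br$folds), 0)
  expect_lt(max(abs(br$points$x1 - 2 * br$points$param)), 1e-9)
  expect_true(all(br$points$stability == "stable"))
  expect_equal(nrow(suppressWarnings(hopf_scan(br))), 0)
})

test_that("cubic normal-form folds are located to closed-form accuracy", {
  r0 <- uniroot(function(x) cubic_f(x, -1), c(-2, 0), tol = 1e-14)$root
  br <- continue_curve(cubic_f, cubic_jx, cubic_jp, x0 = r0, p0 = -1,
                       range = c(-1, 1), admissible_min = -1)
  expect_equal(nrow(br$folds), 2)
  expect_lt(max(abs(sort(br$folds$param) - c(-CUBIC_FOLD_P, CUBIC_FOLD_P))),
            1e-6)
  expect_lt(max(abs(sort(br$folds$x1) - c(-CUBIC_FOLD_X, CUBIC_FOLD_X))),
            1e-6)
  # single connected S-shaped branch: stable / unstable / stable
  expect_identical(rle(br$points$stability)$values,
                   c("stable", "unstable", "stable"))
  # every accepted point is an equilibrium to tolerance
  resid <- vapply(seq_len(nrow(br$points)), function(i)
    abs(cubic_f(br$points$x1[i], br$points$param[i])), 0)
  expect_lt(max(resid), 1e-8)
  # classification: reversible bistable between the folds
  cls <- bswitch:::classify_switch_points(list(br), "x1", -1, c(-1, 1))
  expect_identical(cls$class, "reversible_bistable")
  expect_equal(cls$intervals[1, ], c(lo = -CUBIC_FOLD_P, hi = CUBIC_FOLD_P),
               tolerance = 1e-6)
  # starting point must be an equilibrium
  expect_error(continue_curve(cubic_f, cubic_jx, cubic_jp, x0 = 0.5,
                              p0 = -1, range = c(-1, 1)), "not an equilibrium")
})

test_that("full-model branches satisfy residual, fold-singularity and
          reversal invariants", {
  att <- nominal_attractors()
  br_a <- continue_branch("full_A", nominal, IV0, "T_EBF1",
                          att$LMPP$state, c(-2, 3))
  br_b <- continue_branch("full_A", nominal, IV0, "T_EBF1",
                          att$proB$state, c(-2, 3))
  m <- model_spec("full_A")
  p <- bswitch:::params_full(nominal)
  for (br in list(br_a, br_b)) {
    pts <- br$points
    idx <- unique(round(seq(1, nrow(pts), length.out = 40)))
    for (i in idx) {
      x <- as.numeric(pts[i, m$states])
      v <- c(x, c(T_EBF1 = pts$param[i], T_ZNF521 = 0))
      expect_lt(max(abs(bswitch:::rhs_eval(m, v, p))), 1e-8)
    }
    # refined folds are rank-deficient in the state Jacobian
    for (k in seq_len(nrow(br$folds))) {
      x <- as.numeric(br$folds[k, m$states])
      v <- c(x, c(T_EBF1 = br$folds$param[k], T_ZNF521 = 0))
      sv <- svd(bswitch:::jac_eval(m, v, p))$d
      expect_lt(min(sv), 1e-6)
    }
  }
  # the two traversal directions find the same folds
  fa <- sort(br_a$folds$param)
  fb <- sort(br_b$folds$param)
  expect_equal(length(fa), length(fb))
  expect_lt(max(abs(fa - fb)), 1e-6)
  # irreversibility geometry: one fold on each side of zero
  expect_lt(min(fa), 0)
  expect_gt(max(fa), 0)
})

test_that("diagram assembly matches dense equilibrium counting", {
  d <- build_diagram("full_A", nominal, IV0, range = c(-2, 3),
                     n_starts = 40, seed = 1)
  expect_identical(d$classification, "irreversible_bistable")
  grid <- seq(0, 1.2, length.out = 25)
  for (tv in grid) {
    eqs <- suppressWarnings(
      find_equilibria("full_A", nominal, c(T_EBF1 = tv, T_ZNF521 = 0),
                      n_starts = 60, seed = 3))
    n_stable <- sum(vapply(eqs, function(e)
      e$stability == "stable" && e$admissible, NA))
    # count stable physical diagram points near tv across branches
    n_diag <- 0
    for (br in d$branches) {
      pts <- br$points
      phys <- apply(as.matrix(pts[, br$state_names]), 1, min) >= -1e-6
      segs <- bswitch:::stable_segments(
        structure(list(points = pts, folds = br$folds,
                       state_names = br$state_names, state_physical = TRUE),
                  class = "bswitch_branch"), span = 5)
      n_diag <- n_diag + sum(vapply(segs, function(s)
        tv >= s[1] - 1e-9 && tv <= s[2] + 1e-9, NA))
    }
    expect_equal(n_diag, n_stable, label = sprintf("T_EBF1 = %.3f", tv))
  }
})

test_that("hopf_scan flags the analytic crossing of a rotational normal
          form and nothing on fold-only branches", {
  hs <- hopf_system()
  br <- continue_curve(hs$f, hs$jx, hs$jp, x0 = c(0, 0), p0 = -0.5,
                      range = c(-0.5, 0.5), admissible_min = -1)
  expect_warning(cross <- hopf_scan(br), "Hopf")
  expect_equal(nrow(cross), 1)
  expect_lt(abs(cross$param[1]), 1e-4)
  expect_equal(cross$im[1], 1.7, tolerance = 1e-3)

  att <- nominal_attractors()
  br_m <- continue_branch("full_A", nominal, IV0, "T_EBF1",
                          att$LMPP$state, c(-2, 3))
  expect_equal(nrow(hopf_scan(br_m)), 0)
})

test_that("diagram TSV artifacts round-trip the classification", {
  d <- build_diagram("ebf1_pax5_znf521", nominal, IV0, range = c(-2, 3),
                     n_starts = 30, seed = 1)
  stem <- file.path(withr::local_tempdir(), "diag")
  paths <- write_diagram_tsv(d, stem)
  expect_true(all(file.exists(paths)))
  summ <- utils::read.delim(paths[3])
  expect_identical(summ$classification, d$classification)
  br <- utils::read.delim(paths[1])
  expect_true(all(c("branch", "param", "stability", "admissible") %in%
                    names(br)))
})
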