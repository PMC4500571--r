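test_that("IKAROS relaxes along its closed-form exponential", {
  # component 1 of the full model is autonomous: x(t) = i0/mu1 +
  # (x0 - i0/mu1) exp(-mu1 t)
  ps <- nominal
  x0 <- c(3, rep(0.5, 9))
  tr <- simulate_model("full_A", ps, IV0, x0, t_end = 100, n_points = 400)
  i0 <- ps[["i0"]]; mu1 <- ps[["mu1"]]
  analytic <- i0 / mu1 + (x0[1] - i0 / mu1) * exp(-mu1 * tr$times)
  expect_lt(max(abs(tr$states[, "IKAROS"] - analytic)), 1e-6)
})

test_that("integration settings behave: preconditions, convergence flag,
          tolerance halving", {
  expect_error(simulate_model("full_A", nominal, IV0, rep(0.1, 10), t_end = -1),
               "t_end")
  expect_error(simulate_model("full_A", nominal, IV0, c(-1, rep(0.1, 9)),
                              t_end = 1), "non-negative")
  tr <- simulate_model("full_A", nominal, IV0, rep(0.2, 10), t_end = 3000)
  expect_true(tr$converged)
  # halving tolerances moves the final state by less than the coarser tol
  tr1 <- simulate_model("full_A", nominal, IV0, rep(0.2, 10), t_end = 50,
                        rtol = 1e-8, atol = 1e-10)
  tr2 <- simulate_model("full_A", nominal, IV0, rep(0.2, 10), t_end = 50,
                        rtol = 5e-9, atol = 5e-11)
  expect_lt(max(abs(tr1$final_state - tr2$final_state)),
            1e-8 * max(1, max(abs(tr1$final_state))))
})

test_that("multi-start equilibrium search finds and labels the nominal
          attractors", {
  eqs <- suppressWarnings(find_equilibria("full_A", nominal, IV0,
                                          n_starts = 150, seed = 1))
  expect_gt(length(eqs), 0)
  for (e in eqs) expect_lt(e$residual, 1e-9)
  st <- Filter(function(e) e$stability == "stable" && e$admissible, eqs)
  expect_length(st, 2)
  lmpp <- st[[1]]$state; prob <- st[[2]]$state
  expect_gt(lmpp[["ZNF521"]], prob[["ZNF521"]])
  expect_gt(lmpp[["FLT3"]], prob[["FLT3"]])
  expect_lt(lmpp[["EBF1"]], prob[["EBF1"]])
  expect_lt(lmpp[["PAX5"]], prob[["PAX5"]])
  expect_lt(lmpp[["CD19"]], prob[["CD19"]])
})

test_that("integrator and root solver agree on the committed equilibrium", {
  att <- nominal_attractors()
  prob <- att$proB$state
  tr <- simulate_model("full_A", nominal, IV0, pmax(prob * 0.95, 0),
                       t_end = 4000)
  expect_lt(max(abs(tr$final_state - prob)), 1e-4)
})

test_that("stability classification is eigenvalue-based with simulation
          backing", {
  att <- nominal_attractors()
  for (lab in c("LMPP", "proB")) {
    e <- classify_stability("full_A", nominal, IV0, att[[lab]]$state)
    expect_identical(e$stability, "stable")
    expect_true(all(Re(e$eigenvalues) < 0))
    # a small perturbation relaxes back to the equilibrium
    tr <- simulate_model("full_A", nominal, IV0,
                         pmax(att[[lab]]$state + 1e-3, 0), t_end = 3000)
    expect_lt(max(abs(tr$final_state - att[[lab]]$state)), 1e-4)
  }
  expect_error(classify_stability("full_A", nominal, IV0, rep(5, 10)),
               "not an equilibrium")
})

test_that("equilibrium count is stable under more starts (2-node module)", {
  adm <- function(eqs) Filter(function(e) e$admissible, eqs)
  e1 <- adm(suppressWarnings(find_equilibria("ebf1_znf521", nominal, IV0,
                                             n_starts = 200, seed = 4)))
  e2 <- adm(suppressWarnings(find_equilibria("ebf1_znf521", nominal, IV0,
                                             n_starts = 2000, seed = 9)))
  expect_equal(length(e1), length(e2))
  s1 <- do.call(rbind, lapply(e1, `[[`, "state"))
  s2 <- do.call(rbind, lapply(e2, `[[`, "state"))
  s1 <- s1[order(s1[, 1]), , drop = FALSE]
  s2 <- s2[order(s2[, 1]), , drop = FALSE]
  expect_lt(max(abs(s1 - s2)), 1e-6)
})

test_that("multi-start roots match a brute-force sign-change grid oracle on
          the 2-node module", {
  # oracle: scan 50 x 50 cells of the box; where both derivative components
  # change sign across a cell, polish a root by fixed-point bisection on
  # the cell; compare against find_equilibria
  m <- model_spec("ebf1_znf521")
  ub <- 1.5 * model_state_bounds(m, nominal)
  g1 <- seq(0, ub[1], length.out = 51)
  g2 <- seq(0, ub[2], length.out = 51)
  f1 <- outer(g1, g2, function(a, b)
    vapply(seq_along(a), function(i)
      model_rhs(m, c(a[i], b[i]), nominal, IV0)[1], 0))
  f2 <- outer(g1, g2, function(a, b)
    vapply(seq_along(a), function(i)
      model_rhs(m, c(a[i], b[i]), nominal, IV0)[2], 0))
  cells <- which(
    (f1[-51, -51] * f1[-1, -51] <= 0 | f1[-51, -51] * f1[-51, -1] <= 0 |
       f1[-51, -51] * f1[-1, -1] <= 0) &
      (f2[-51, -51] * f2[-1, -51] <= 0 | f2[-51, -51] * f2[-51, -1] <= 0 |
         f2[-51, -51] * f2[-1, -1] <= 0), arr.ind = TRUE)
  oracle <- list()
  for (r in seq_len(nrow(cells))) {
    x0 <- c(mean(g1[cells[r, 1] + 0:1]), mean(g2[cells[r, 2] + 0:1]))
    root <- bswitch:::newton_root(m, bswitch:::inputs_vec(IV0),
                                  bswitch:::params_full(nominal), x0)
    if (is.null(root) || any(root < -1e-9)) next
    dup <- FALSE
    for (q in oracle) if (max(abs(q - root)) < 1e-4) dup <- TRUE
    if (!dup) oracle[[length(oracle) + 1L]] <- root
  }
  eqs <- suppressWarnings(find_equilibria(m, nominal, IV0,
                                          n_starts = 200, seed = 2))
  adm <- Filter(function(e) e$admissible, eqs)
  expect_equal(length(adm), length(oracle))
  om <- do.call(rbind, oracle)
  for (e in adm) {
    d <- apply(abs(sweep(om, 2, e$state, `-`)), 1, max)
    expect_lt(min(d), 1e-4)
  }
})

test_that("2-node nullclines satisfy their defining equations and intersect
          at the equilibria", {
  nc <- nullclines_2d("ebf1_znf521", nominal, IV0)
  m <- model_spec("ebf1_znf521")
  for (i in 1:2) {
    pts <- as.matrix(nc$nullclines[[m$states[i]]])
    resid <- vapply(seq_len(nrow(pts)), function(k)
      abs(model_rhs(m, pts[k, ], nominal, IV0)[i]), 0)
    expect_lt(max(resid), 1e-8)
  }
  # a single admissible intersection: the multipotent (LMPP) point
  adm <- nc$intersections[apply(nc$intersections, 1, min) >= -1e-9, ,
                          drop = FALSE]
  expect_equal(nrow(adm), 1)
  expect_gt(adm[1, "ZNF521"], adm[1, "EBF1"])  # ZNF521-high, EBF1-low
  eqs <- suppressWarnings(find_equilibria(m, nominal, IV0,
                                          n_starts = 100, seed = 1))
  adm_eq <- Filter(function(e) e$admissible, eqs)
  expect_equal(length(adm_eq), 1)
  expect_lt(max(abs(adm_eq[[1]]$state - adm[1, ])), 1e-4)
  expect_error(nullclines_2d("full_A", nominal, IV0), "2 states")
})
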