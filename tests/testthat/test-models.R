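test_that("the model catalogue enumerates all network variants", {
  ids <- list_models()
  expect_length(ids, 11)
  expect_equal(model_spec("full_A")$n, 10)
  expect_equal(model_spec("ebf1_pax5_znf521")$n, 3)
  expect_equal(model_spec("ebf1_znf521")$n, 2)
  expect_equal(model_spec("znf521_ebf1_pax5_flt3_il7r")$n, 5)
  # every model's required parameters are a subset of the canonical symbols
  for (id in ids) {
    m <- model_spec(id)
    expect_true(all(m$parameters %in% param_symbols()), label = id)
    expect_identical(m$states, intersect(bswitch:::STATE_ORDER, m$states),
                     label = paste(id, "state order"))
  }
  # the ablation does not require the removed repression strength
  expect_false("b4" %in% model_spec("full_no_pax5_znf521")$parameters)
  expect_true("b4" %in% model_spec("full_A")$parameters)
})

test_that("rhs closed forms hold: zero basal production and IKAROS balance", {
  ps <- random_params(11)
  p0 <- ps
  for (s in c("a0", "b0", "c0", "d0", "e0", "f0", "g0", "h0", "i0", "j0"))
    p0[s] <- 0
  r <- model_rhs("full_A", rep(0, 10), p0, IV0)
  expect_true(all(r == 0))

  # IKAROS: di/dt = i0 - mu1 * x, zero at x = i0/mu1
  p2 <- ps; p2["i0"] <- 2; p2["mu1"] <- 1
  x <- runif(10, 0, 5); x[1] <- 2
  expect_equal(unname(model_rhs("full_A", x, p2, IV0)[1]), 0)

  # missing parameter is named; dimension mismatch rejected
  expect_error(model_rhs("full_A", rep(0.1, 10), ps[-which(names(ps) == "a4")]),
               "a4")
  expect_error(model_rhs("full_A", rep(0.1, 9), ps), "states")
})

test_that("analytic Jacobians match central finite differences", {
  h <- 1e-6
  for (id in c("full_A", "full_B", "ebf1_znf521", "ebf1_pax5_znf521",
               "znf521_ebf1_e2a_pax5")) {
    m <- model_spec(id)
    set.seed(42)
    for (k in 1:20) {
      ps <- random_params(100 + k)
      x <- runif(m$n, 0, 4)
      iv <- c(T_EBF1 = runif(1, 0, 2), T_ZNF521 = runif(1, 0, 2))
      J <- model_jacobian(m, x, ps, iv)
      fd <- matrix(0, m$n, m$n)
      for (j in seq_len(m$n)) {
        xp <- x; xm <- x; xp[j] <- xp[j] + h; xm[j] <- xm[j] - h
        fd[, j] <- (model_rhs(m, xp, ps, iv) - model_rhs(m, xm, ps, iv)) / (2 * h)
      }
      scale <- max(abs(fd), 1)
      expect_lt(max(abs(J - fd)) / scale, 1e-5)
    }
  }
  # Eq 1a structure: d(dIKAROS/dt)/dIKAROS = -mu1, zero off-diagonal
  ps <- random_params(3)
  J <- model_jacobian("full_A", runif(10, 0, 3), ps, IV0)
  expect_equal(unname(J["IKAROS", "IKAROS"]), -unname(ps["mu1"]))
  expect_true(all(J["IKAROS", colnames(J) != "IKAROS"] == 0))
})

test_that("two-node module is symmetric under state swap at a symmetric
          parameterization", {
  ps <- random_params(7)
  ps["b0"] <- ps["a0"]; ps["b1"] <- ps["a1"]; ps["b2"] <- ps["a2"]
  ps["b3"] <- ps["a4"]; ps["mu7"] <- ps["mu8"]
  iv <- c(T_EBF1 = 0.4, T_ZNF521 = 0.4)
  for (z in c(0.3, 1.7)) {
    x <- c(z, z)  # symmetric state
    J <- model_jacobian("ebf1_znf521", x, ps, iv)
    expect_equal(J[1, 1], J[2, 2])
    expect_equal(J[1, 2], J[2, 1])
    r <- model_rhs("ebf1_znf521", x, ps, iv)
    expect_equal(unname(r[1]), unname(r[2]))
  }
})

test_that("production keeps the non-negative orthant forward invariant", {
  # at any boundary state (some x_i = 0) the i-th derivative is >= 0
  for (k in 1:30) {
    ps <- random_params(200 + k)
    for (id in c("full_A", "ebf1_pax5_znf521")) {
      m <- model_spec(id)
      x <- runif(m$n, 0, 5)
      zero <- sample(m$n, sample(m$n, 1))
      x[zero] <- 0
      r <- model_rhs(m, x, ps, c(T_EBF1 = runif(1, 0, 1), T_ZNF521 = 0))
      expect_true(all(r[zero] >= 0),
                  label = sprintf("%s boundary seed %d", id, k))
    }
  }
})

test_that("trajectories stay inside the invariant box", {
  ps <- nominal
  bounds <- model_state_bounds("full_A", ps)
  set.seed(5)
  x0 <- pmin(runif(10, 0, 1.4) * bounds, bounds * 1.45)
  tr <- simulate_model("full_A", ps, IV0, x0, t_end = 500, n_points = 100)
  slack <- 1e-6
  for (j in seq_len(10)) {
    expect_true(all(tr$states[, j] >= -slack))
    expect_true(all(tr$states[, j] <= max(1.5 * bounds[j], x0[j]) + slack))
  }
})

test_that("sub-module equations coincide with the printed reduced forms", {
  # the EBF1/PAX5/ZNF521 module's PAX5 equation equals the full model's
  # PAX5 equation with the E2A couplings silenced
  ps <- random_params(31)
  ps["c2"] <- 0; ps["c3"] <- 0
  x3 <- c(ZNF521 = 1.2, EBF1 = 0.8, PAX5 = 0.5)
  x10 <- stats::setNames(runif(10, 0, 2), model_spec("full_A")$states)
  x10[c("ZNF521", "EBF1", "PAX5")] <- x3
  r3 <- model_rhs("ebf1_pax5_znf521", x3, ps, IV0)
  r10 <- model_rhs("full_A", x10, ps, IV0)
  expect_equal(unname(r3["PAX5"]), unname(r10["PAX5"]))

  # the 2-node module's ZNF521 equation (with its saturating ZNF521*EBF1
  # repression) equals the full model's with the PAX5 arm silenced and no
  # other couplings active
  psz <- random_params(32); psz["b4"] <- 0
  x2 <- c(ZNF521 = 0.9, EBF1 = 1.4)
  x10 <- stats::setNames(rep(0, 10), model_spec("full_A")$states)
  x10[c("ZNF521", "EBF1")] <- x2
  r2 <- model_rhs("ebf1_znf521", x2, psz, IV0)
  r10 <- model_rhs("full_A", x10, psz, IV0)
  expect_equal(unname(r2["ZNF521"]), unname(r10["ZNF521"]))
})
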