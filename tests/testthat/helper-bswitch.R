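# shared fixtures for the suite: the nominal parameter set, default input
# conditions, and closed-form toy systems used as continuation oracles

nominal <- bswitch::nominal_parameters()
IV0 <- c(T_EBF1 = 0, T_ZNF521 = 0)

# uniform random parameter set, seeded
random_params <- function(seed, lo = 0.1, hi = 2) {
  set.seed(seed)
  parameter_set(stats::setNames(runif(length(param_symbols()), lo, hi),
                                param_symbols()))
}

# cubic normal form dx/dt = p + x - x^3: folds at p = -+ 2/(3 sqrt 3),
# x = +- 1/sqrt 3 (where 1 - 3 x^2 = 0)
cubic_f  <- function(x, p) p + x - x^3
cubic_jx <- function(x, p) matrix(1 - 3 * x^2, 1, 1)
cubic_jp <- function(x, p) 1
CUBIC_FOLD_P <- 2 / (3 * sqrt(3))
CUBIC_FOLD_X <- 1 / sqrt(3)

# linear toy dx/dt = p - 0.5 x: equilibrium line x = 2 p, no folds
lin_f  <- function(x, p) p - 0.5 * x
lin_jx <- function(x, p) matrix(-0.5, 1, 1)
lin_jp <- function(x, p) 1

# supercritical Hopf normal form (planar, rotation omega): the origin is an
# equilibrium for all p with eigenvalues p +- i omega
hopf_system <- function(omega = 1.7) {
  list(
    f = function(x, p) c(p * x[1] - omega * x[2] - x[1] * sum(x^2),
                         omega * x[1] + p * x[2] - x[2] * sum(x^2)),
    jx = function(x, p) matrix(c(p - 3 * x[1]^2 - x[2]^2,
                                 -omega - 2 * x[1] * x[2],
                                 omega - 2 * x[1] * x[2],
                                 p - x[1]^2 - 3 * x[2]^2), 2, 2, byrow = TRUE),
    jp = function(x, p) c(x[1], x[2]))
}

# the two nominal attractors, computed once per test run
nominal_attractors <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- find_attractors("full_A", nominal, IV0, seed = 1)
    cache
  }
})
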