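# Seeded generators for every input the analysis needs without downloads:
# two-condition expression fixtures following the canonical LMPP/pro-B
# program, planted-truth differential-expression toy tables, and random
# kinetic parameter sets.

#' Default two-condition fixture specification
#'
#' Encodes the canonical expression program of the commitment switch:
#' FLT3 and ZNF521 high in the multipotent (LMPP) condition, EBF1, PAX5
#' and CD19 high in the committed (proB) condition, and the remaining
#' factors at intermediate, condition-independent levels (exercising the
#' flat pathway of [concordance()]).
#'
#' @param noise_sd Log-scale standard deviation of the multiplicative
#'   log-normal noise (microarray-style intensities are positive and
#'   right-skewed).
#' @return List with `factors` (data frame of per-factor LMPP and proB
#'   means) and `noise_sd`.
#' @export
default_fixture_spec <- function(noise_sd = 0.05) {
  factors <- data.frame(
    LMPP = c(FLT3 = 8, ZNF521 = 9, EBF1 = 0.5, PAX5 = 0.6, CD19 = 0.8,
             IKAROS = 2, GFI1 = 3, PU1 = 2, E2A = 3, IL7R = 4),
    proB = c(FLT3 = 1.2, ZNF521 = 0.4, EBF1 = 9, PAX5 = 8.5, CD19 = 7.5,
             IKAROS = 2, GFI1 = 3, PU1 = 2, E2A = 3, IL7R = 4))
  list(factors = factors, noise_sd = noise_sd)
}

#' Generate a synthetic two-condition expression fixture
#'
#' Draws a seeded expression table around the spec's per-factor condition
#' means with multiplicative log-normal noise: a synthetic stand-in for
#' two-condition progenitor profiling data, structured after the
#' commitment-switch expression programs.
#'
#' @param spec Fixture specification as returned by
#'   [default_fixture_spec()]: list with `factors` (data frame, columns
#'   `LMPP`, `proB`, non-negative means) and `noise_sd`.
#' @param seed Integer seed (mandatory: fixtures are pure functions of
#'   `(spec, seed)`).
#' @return Data frame with columns `LMPP` and `proB`, factor rownames.
#' @export
make_expression_fixture <- function(spec = default_fixture_spec(), seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  means <- as.matrix(spec$factors)
  if (any(means < 0)) stop("fixture means must be non-negative", call. = FALSE)
  sd <- spec$noise_sd
  withr_seed(seed, {
    noise <- matrix(exp(stats::rnorm(length(means), 0, sd)),
                    nrow(means), ncol(means))
    out <- means * noise
    dimnames(out) <- dimnames(means)
    as.data.frame(out)
  })
}

#' Generate a planted-truth differential-expression toy table
#'
#' Seeded table of `n` genes of which `n_planted` are true positives for
#' the fold-change/p-value filter of [de_filter()]: planted rows get
#' `|fold| >= planted_fc` (random sign) and `p <= planted_p_max`; null rows
#' get fold changes inside the dead zone or large p-values, so the filter
#' recovers exactly the planted set by construction.
#'
#' @param n Number of rows.
#' @param n_planted Number of planted differentially expressed rows
#'   (`<= n`).
#' @param planted_fc Minimum fold-change magnitude of planted rows
#'   (default 2.5).
#' @param planted_p_max Maximum p-value of planted rows (default 0.01).
#' @param seed Integer seed (mandatory).
#' @return Data frame with columns `gene`, `fold_change_linear`,
#'   `p_value`, `planted`.
#' @export
make_de_table <- function(n, n_planted, planted_fc = 2.5,
                          planted_p_max = 0.01, seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  if (n_planted > n) stop("n_planted must be <= n", call. = FALSE)
  withr_seed(seed, {
    planted <- rep(FALSE, n)
    if (n_planted > 0) planted[sample.int(n, n_planted)] <- TRUE
    fc <- numeric(n); pv <- numeric(n)
    k <- sum(planted)
    if (k > 0) {
      fc[planted] <- sample(c(-1, 1), k, replace = TRUE) *
        stats::runif(k, planted_fc, planted_fc * 4)
      pv[planted] <- stats::runif(k, 1e-6, planted_p_max)
    }
    m <- n - k
    if (m > 0) {
      # null rows fail the filter by fold change, p-value or both
      mode <- sample.int(3, m, replace = TRUE)
      fc[!planted] <- ifelse(mode < 3,
                             stats::runif(m, -1.5, 1.5),
                             sample(c(-1, 1), m, TRUE) * stats::runif(m, 2, 6))
      pv[!planted] <- ifelse(mode == 2 | mode == 3,
                             stats::runif(m, 0.2, 1),
                             stats::runif(m, 0.001, 0.19))
      # mode 1: small fold, small p; mode 2: small fold, big p;
      # mode 3: big fold, big p
    }
    data.frame(gene = sprintf("gene%04d", seq_len(n)),
               fold_change_linear = fc, p_value = pv, planted = planted)
  })
}

#' Draw random kinetic parameter sets
#'
#' Seeded draws of complete parameter sets with selected symbols sampled
#' uniformly or log-uniformly within given ranges and the remaining symbols
#' held at `base`.
#'
#' @param base Parameter set supplying unsampled symbols.
#' @param ranges Named list of length-2 numeric ranges (min, max).
#' @param n Number of draws.
#' @param distribution `"log-uniform"` (default; ranges must be positive)
#'   or `"uniform"`.
#' @param seed Integer seed (mandatory).
#' @return List of `n` [parameter_set()] objects.
#' @export
sample_parameter_sets <- function(base, ranges, n,
                                  distribution = c("log-uniform", "uniform"),
                                  seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  distribution <- match.arg(distribution)
  if (is.null(names(ranges)) || any(!names(ranges) %in% param_symbols()))
    stop("ranges must be named by parameter symbols", call. = FALSE)
  for (nm in names(ranges)) {
    r <- ranges[[nm]]
    if (length(r) != 2 || r[1] > r[2])
      stop("invalid (inverted) range for ", nm, call. = FALSE)
    if (distribution == "log-uniform" && r[1] <= 0)
      stop("log-uniform range for ", nm, " must be positive", call. = FALSE)
  }
  withr_seed(seed, {
    lapply(seq_len(n), function(i) {
      p2 <- base
      for (nm in names(ranges)) {
        r <- ranges[[nm]]
        p2[[nm]] <- if (distribution == "log-uniform")
          exp(stats::runif(1, log(r[1]), log(r[2])))
        else stats::runif(1, r[1], r[2])
      }
      parameter_set(unclass(p2))
    })
  })
}
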