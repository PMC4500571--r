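# One-parameter-at-a-time sensitivity sweeps for preservation of
# bistability, and genetic-algorithm discovery of bistable parameter sets.

#' Bistability predicate for a parameter configuration
#'
#' A configuration is called bistable when the equilibrium diagram against
#' `T_EBF1` (at `T_ZNF521 = 0` unless overridden) exhibits at least one
#' admissible bistable interval, i.e. classifies as reversible or
#' irreversible bistable. This is the predicate underlying the sensitivity
#' sweeps: the sweeps ask over what range of a kinetic parameter the
#' commitment switch survives.
#'
#' @inheritParams model_rhs
#' @param range Continuation range for `T_EBF1`.
#' @param n_starts,seed Multi-start settings for the diagram's equilibrium
#'   searches (kept modest: the diagram is rebuilt at every probed value).
#' @return Logical scalar.
#' @export
is_bistable <- function(model, params, inputs = c(T_EBF1 = 0, T_ZNF521 = 0),
                        range = c(-0.5, 2.5), n_starts = 24, seed = 1) {
  d <- tryCatch(
    build_diagram(model, params, inputs, free_param = "T_EBF1", range = range,
                  n_starts = n_starts, seed = seed, n_probes = 3),
    error = function(e) NULL)
  !is.null(d) && d$classification != "monostable"
}

#' Admissible range of one parameter preserving bistability
#'
#' Scans a log-spaced grid around the nominal value of one kinetic
#' parameter (33 points over nominal/64 .. nominal*64 by default), finds
#' the contiguous bistable run containing the nominal value, and refines
#' both boundaries by bisection on the bistability predicate to a relative
#' tolerance. Results are reported as the admissible `[min, max]` and the
#' log2 fold changes `log2(min/nominal)`, `log2(max/nominal)`. Parameters
#' for which no scanned value is bistable are classified `"unimodal"`
#' (every value of the parameter yields a single homeostatic CD19 level).
#'
#' @inheritParams is_bistable
#' @param param Name of the kinetic parameter to sweep.
#' @param scan_lo,scan_hi Scan bounds as multiples of the nominal value.
#' @param n_scan Number of log-spaced scan points.
#' @param rel_tol Relative bisection tolerance on the boundaries.
#' @return Object of class `bswitch_interval`: list with `param`,
#'   `nominal`, `classification` (`"bistable_interval"` or `"unimodal"`),
#'   `min`, `max`, `log2_min`, `log2_max`, censoring flags `min_censored`
#'   and `max_censored` (`TRUE` when the bistable run extends to the scan
#'   edge, so the true boundary lies outside the scanned window), and the
#'   scan `grid` with its predicate values.
#' @export
bistability_interval <- function(model, params,
                                 inputs = c(T_EBF1 = 0, T_ZNF521 = 0),
                                 param, scan_lo = 1 / 64, scan_hi = 64,
                                 n_scan = 33, rel_tol = 1e-3,
                                 range = c(-0.5, 2.5), n_starts = 24, seed = 1) {
  if (!param %in% names(params))
    stop("unknown parameter: ", param, call. = FALSE)
  nominal <- as.numeric(params[[param]])
  if (nominal <= 0)
    stop("parameter ", param, " has non-positive nominal value; ",
         "log-scale sweep undefined", call. = FALSE)
  grid <- exp(seq(log(nominal * scan_lo), log(nominal * scan_hi),
                  length.out = n_scan))
  probe <- function(v) {
    p2 <- params; p2[[param]] <- v
    is_bistable(model, p2, inputs, range = range, n_starts = n_starts,
                seed = seed)
  }
  hits <- vapply(grid, probe, NA)
  res <- list(param = param, nominal = nominal,
              grid = data.frame(value = grid, bistable = hits))
  if (!any(hits)) {
    res$classification <- "unimodal"
    res$min <- NA_real_; res$max <- NA_real_
    res$min_censored <- NA; res$max_censored <- NA
    res$log2_min <- NA_real_; res$log2_max <- NA_real_
    return(structure(res, class = "bswitch_interval"))
  }
  # contiguous bistable run: prefer the one containing (or nearest) nominal
  runs <- rle(hits)
  ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1L
  bist_runs <- which(runs$values)
  near <- which.min(vapply(bist_runs, function(r) {
    lo <- grid[starts[r]]; hi <- grid[ends[r]]
    if (nominal >= lo && nominal <= hi) 0 else min(abs(log(nominal / lo)),
                                                   abs(log(nominal / hi)))
  }, 0))
  r <- bist_runs[near]
  i_lo <- starts[r]; i_hi <- ends[r]

  bisect <- function(inside, outside) {
    # inside is bistable, outside is not; returns the refined boundary.
    # A run touching the scan edge is censored: the true boundary (if any)
    # lies outside the scanned window.
    if (is.na(outside)) return(list(bound = inside, censored = TRUE))
    repeat {
      mid <- sqrt(inside * outside)  # bisection on the log scale
      if (abs(log(inside / outside)) < rel_tol)
        return(list(bound = inside, censored = FALSE))
      if (probe(mid)) inside <- mid else outside <- mid
    }
  }
  lo_b <- bisect(grid[i_lo], if (i_lo > 1) grid[i_lo - 1L] else NA)
  hi_b <- bisect(grid[i_hi], if (i_hi < n_scan) grid[i_hi + 1L] else NA)
  res$classification <- "bistable_interval"
  res$min <- lo_b$bound; res$max <- hi_b$bound
  res$min_censored <- lo_b$censored; res$max_censored <- hi_b$censored
  res$log2_min <- log2(lo_b$bound / nominal)
  res$log2_max <- log2(hi_b$bound / nominal)
  structure(res, class = "bswitch_interval")
}

#' @export
print.bswitch_interval <- function(x, ...) {
  cat("<bswitch_interval> ", x$param, " (nominal ", format(x$nominal), "): ",
      x$classification, "\n", sep = "")
  if (x$classification == "bistable_interval")
    cat("  bistable for [", format(x$min, digits = 6),
        if (x$min_censored) " (censored)", ", ", format(x$max, digits = 6),
        if (x$max_censored) " (censored)", "]  log2 fold change [",
        sprintf("%.3f", x$log2_min), ", ", sprintf("%.3f", x$log2_max),
        "]\n", sep = "")
  invisible(x)
}

#' Parameter-sensitivity table for bistability
#'
#' Runs [bistability_interval()] for each listed parameter and collects one
#' row per parameter. A row that errors is marked `"failed"` rather than
#' aborting the table.
#'
#' @inheritParams bistability_interval
#' @param parameters Character vector of kinetic symbols to sweep.
#' @return Data frame with columns `param`, `nominal`, `classification`,
#'   `min`, `max`, `log2_min`, `log2_max`.
#' @export
sensitivity_table <- function(model, params,
                              inputs = c(T_EBF1 = 0, T_ZNF521 = 0),
                              parameters, ...) {
  rows <- lapply(parameters, function(pp) {
    iv <- tryCatch(bistability_interval(model, params, inputs, pp, ...),
                   error = function(e) NULL)
    if (is.null(iv))
      return(data.frame(param = pp, nominal = NA_real_,
                        classification = "failed", min = NA_real_,
                        max = NA_real_, log2_min = NA_real_,
                        log2_max = NA_real_, min_censored = NA,
                        max_censored = NA))
    data.frame(param = iv$param, nominal = iv$nominal,
               classification = iv$classification,
               min = iv$min, max = iv$max,
               log2_min = iv$log2_min, log2_max = iv$log2_max,
               min_censored = iv$min_censored, max_censored = iv$max_censored)
  })
  do.call(rbind, rows)
}

#' Write a sensitivity table as TSV
#'
#' @param tab A [sensitivity_table()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sensitivity_tsv <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# graded fitness for the genetic algorithm: how close a configuration is to
# bistable switching. Counts admissible stable equilibria at probe values of
# T_EBF1 (2+ anywhere is a hit) and rewards multiplicity and fold presence.
bistability_fitness <- function(model, params, inputs, probes = c(0, 0.25, 0.5, 1),
                                n_starts = 25, seed = 1, objective = "bistable") {
  iv <- inputs_vec(inputs)
  counts <- vapply(probes, function(tv) {
    iv2 <- iv; iv2[["T_EBF1"]] <- tv
    eqs <- tryCatch(
      suppressWarnings(find_equilibria(model, params, iv2,
                                       n_starts = n_starts, seed = seed)),
      error = function(e) list())
    sum(vapply(eqs, function(e) e$stability == "stable" && e$admissible, NA))
  }, 0L)
  if (all(counts == 0)) return(-1)
  score <- max(counts) + 0.25 * sum(counts >= 2) / length(probes)
  if (max(counts) >= 2 && objective %in% c("irreversible_bistable", "fold_exists")) {
    d <- tryCatch(build_diagram(model, params, iv, range = c(-2, 3),
                                n_starts = n_starts, seed = seed),
                  error = function(e) NULL)
    if (!is.null(d)) {
      if (objective == "fold_exists" && nrow(d$folds) > 0) score <- score + 1
      if (objective == "irreversible_bistable" &&
          d$classification == "irreversible_bistable") score <- score + 2
    }
  }
  score
}

# classification of a configuration at the requested rigor, used to verify
# GA hits
verify_objective <- function(model, params, inputs, objective,
                             range = c(-2, 3), n_starts = 40, seed = 1) {
  d <- tryCatch(build_diagram(model, params, inputs, range = range,
                              n_starts = n_starts, seed = seed),
                error = function(e) NULL)
  if (is.null(d)) return(list(ok = FALSE, classification = "error"))
  ok <- switch(objective,
    bistable = d$classification != "monostable",
    irreversible_bistable = d$classification == "irreversible_bistable",
    fold_exists = nrow(d$folds) > 0,
    stop("unknown objective: ", objective, call. = FALSE))
  list(ok = ok, classification = d$classification,
       folds = d$folds$param, intervals = d$bistable_intervals)
}

#' Genetic-algorithm search for bistable parameter sets
#'
#' Explores a box in (log) parameter space for configurations whose
#' `T_EBF1` diagram realises the requested behaviour, in the spirit of
#' bifurcation-discovery tools: a seeded genetic algorithm with tournament
#' selection, blend (BLX-alpha) crossover and log-uniform mutation, scored
#' by a graded distance-to-bistability fitness (admissible stable
#' equilibrium counts at probe values, plus diagram-level rewards). Every
#' returned hit is re-verified with [build_diagram()] and
#' [classify_switch()] at higher rigor.
#'
#' @inheritParams model_rhs
#' @param ranges Named list of length-2 numeric ranges (min, max), one per
#'   searched parameter; parameters not listed stay at their value in
#'   `params`.
#' @param objective One of `"bistable"`, `"irreversible_bistable"`,
#'   `"fold_exists"`.
#' @param population,generations GA size and budget.
#' @param seed Integer seed (mandatory; the GA is fully reproducible).
#' @param elite Number of top individuals copied unchanged each generation.
#' @param p_mut Per-gene mutation probability.
#' @param early_stop Stop after this many verified hits (Inf to disable).
#' @return Object of class `bswitch_search`: list with `hits` (list of
#'   verified parameter sets with their classifications), `best` (best
#'   parameter set seen), `fitness_trace` (best fitness per generation),
#'   `seed`, `objective`.
#' @export
search_bistable_parameters <- function(model, params, ranges,
                                       inputs = c(T_EBF1 = 0, T_ZNF521 = 0),
                                       objective = "bistable",
                                       population = 24, generations = 10,
                                       seed = 1, elite = 2, p_mut = 0.15,
                                       early_stop = 1) {
  model <- as_model(model)
  if (length(ranges) == 0) stop("empty ranges", call. = FALSE)
  if (is.null(names(ranges)) || any(!nzchar(names(ranges))))
    stop("ranges must be a named list", call. = FALSE)
  bad <- !names(ranges) %in% param_symbols()
  if (any(bad))
    stop("unknown parameter(s) in ranges: ",
         paste(names(ranges)[bad], collapse = ", "), call. = FALSE)
  for (nm in names(ranges)) {
    r <- ranges[[nm]]
    if (length(r) != 2 || any(!is.finite(r)) || r[1] > r[2] || r[1] < 0)
      stop("invalid range for ", nm, call. = FALSE)
  }
  objective <- match.arg(objective,
                         c("bistable", "irreversible_bistable", "fold_exists"))
  genes <- names(ranges)
  lo <- vapply(ranges, `[`, 0, 1L)
  hi <- vapply(ranges, `[`, 0, 2L)
  # log-scale representation; degenerate (zero-width or zero-valued) ranges
  # are held fixed
  eps <- 1e-12
  llo <- log(pmax(lo, eps)); lhi <- log(pmax(hi, eps))
  fixed <- (hi - lo) <= 0

  make_params <- function(g) {
    p2 <- params
    for (k in seq_along(genes)) p2[[genes[k]]] <- g[k]
    p2
  }
  fit_of <- function(g) {
    bistability_fitness(model, make_params(g), inputs, seed = seed,
                        objective = objective)
  }

  withr_seed(seed, {
    pop <- t(vapply(seq_len(population), function(i) {
      g <- exp(stats::runif(length(genes), llo, lhi))
      g[fixed] <- lo[fixed]
      g
    }, numeric(length(genes))))
    if (length(genes) == 1) pop <- matrix(pop, ncol = 1)

    trace <- numeric(0)
    hits <- list()
    best <- NULL; best_fit <- -Inf

    for (gen in seq_len(generations)) {
      fits <- apply(pop, 1, fit_of)
      ord <- order(fits, decreasing = TRUE)
      if (fits[ord[1]] > best_fit) {
        best_fit <- fits[ord[1]]; best <- pop[ord[1], ]
      }
      trace <- c(trace, fits[ord[1]])

      # verify promising individuals (2+ stable states seen)
      for (i in ord[fits[ord] >= 2]) {
        cand <- make_params(pop[i, ])
        ver <- verify_objective(model, cand, inputs, objective, seed = seed)
        if (ver$ok) {
          dupl <- any(vapply(hits, function(h) {
            max(abs(log(pmax(unlist(h$params[genes]), eps) /
                          pmax(unlist(cand[genes]), eps)))) < 1e-9
          }, NA))
          if (!dupl)
            hits[[length(hits) + 1L]] <- list(params = cand,
                                              classification = ver$classification,
                                              generation = gen - 1L)
        }
        if (length(hits) >= early_stop) break
      }
      if (length(hits) >= early_stop || gen == generations) break

      # next generation: elitism + tournament/blend/mutation
      newpop <- pop[ord[seq_len(min(elite, population))], , drop = FALSE]
      while (nrow(newpop) < population) {
        tourn <- function() {
          c2 <- sample.int(population, 2)
          c2[which.max(fits[c2])]
        }
        pa <- log(pmax(pop[tourn(), ], eps)); pb <- log(pmax(pop[tourn(), ], eps))
        alpha <- 0.3
        u <- stats::runif(length(genes), -alpha, 1 + alpha)
        child <- pa + u * (pb - pa)
        mut <- stats::runif(length(genes)) < p_mut
        child[mut] <- stats::runif(sum(mut), llo[mut], lhi[mut])
        child <- pmin(pmax(child, llo), lhi)
        g <- exp(child); g[fixed] <- lo[fixed]
        newpop <- rbind(newpop, g)
      }
      pop <- newpop
    }

    structure(list(hits = hits, best = make_params(best),
                   best_fitness = best_fit, fitness_trace = trace,
                   seed = seed, objective = objective, genes = genes),
              class = "bswitch_search")
  })
}

#' @export
print.bswitch_search <- function(x, ...) {
  cat("<bswitch_search> objective ", x$objective, ", seed ", x$seed, "\n",
      sep = "")
  cat("  generations run: ", length(x$fitness_trace), ", best fitness ",
      format(x$best_fitness, digits = 4), "\n", sep = "")
  cat("  verified hits: ", length(x$hits), "\n", sep = "")
  for (h in x$hits)
    cat("   - generation ", h$generation, ": ", h$classification, "\n", sep = "")
  invisible(x)
}
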