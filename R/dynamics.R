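# Time integration, equilibrium finding, stability classification and 2-D
# nullclines for the commitment-network models.

#' Integrate a model forward in time
#'
#' Solves the ODE with a stiff-capable integrator (`deSolve::lsoda`) using
#' the analytic Jacobian. The saturating kinetics are mildly stiff near
#' saturation, hence the tight default tolerances.
#'
#' @inheritParams model_rhs
#' @param x0 Non-negative initial state (model state order).
#' @param t_end Final time (dimensionless, > 0).
#' @param n_points Number of output time points (including t = 0).
#' @param rtol,atol Relative and absolute integrator tolerances.
#' @return An object of class `bswitch_trajectory`: list with `times`,
#'   `states` (matrix, one row per time point, columns named by state),
#'   `model`, `inputs`, `final_state`, `final_residual` (infinity norm of
#'   dx/dt at the final time) and `converged` (`final_residual < 1e-6`).
#' @export
simulate_model <- function(model, params, inputs = c(T_EBF1 = 0, T_ZNF521 = 0),
                           x0, t_end, n_points = 200,
                           rtol = 1e-8, atol = 1e-10) {
  model <- as_model(model)
  if (!is.numeric(t_end) || t_end <= 0) stop("t_end must be > 0", call. = FALSE)
  x0 <- check_model_args(model, x0, params, inputs)
  if (any(x0 < 0)) stop("initial state must be non-negative", call. = FALSE)
  p <- params_full(params)
  iv <- inputs_vec(inputs)
  v_extra <- iv
  times <- seq(0, t_end, length.out = max(2L, n_points))
  f <- function(t, y, parms) list(rhs_eval(model, c(y, v_extra), p))
  jf <- function(t, y, parms) jac_eval(model, c(y, v_extra), p)
  sol <- deSolve::lsoda(y = stats::setNames(x0, model$states), times = times,
                        func = f, parms = NULL, jacfunc = jf, jactype = "fullusr",
                        rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0)
    stop("integration failed near t = ", max(sol[, 1]), " for model '",
         model$id, "'", call. = FALSE)
  states <- unname(sol[, -1, drop = FALSE])
  colnames(states) <- model$states
  final <- states[nrow(states), ]
  res <- max(abs(rhs_eval(model, c(final, v_extra), p)))
  structure(list(times = sol[, 1], states = states, model = model$id,
                 inputs = iv, final_state = final, final_residual = res,
                 converged = res < 1e-6),
            class = "bswitch_trajectory")
}

#' @export
print.bswitch_trajectory <- function(x, ...) {
  cat("<bswitch_trajectory> model ", x$model, ", ", length(x$times),
      " points on [0, ", format(max(x$times)), "]\n", sep = "")
  cat("  final state: ", paste(sprintf("%s=%.4g", names(x$final_state),
                                       x$final_state), collapse = ", "), "\n", sep = "")
  cat("  final |dx/dt|_inf = ", format(x$final_residual),
      if (x$converged) " (steady)" else " (not steady)", "\n", sep = "")
  invisible(x)
}

#' Write a trajectory as TSV
#'
#' One row per time point; columns `time` then the state names.
#'
#' @param traj A [simulate_model()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_tsv <- function(traj, path) {
  df <- data.frame(time = traj$times, traj$states, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# damped Newton iteration for rhs(x) = 0 from one starting point
newton_root <- function(model, v_extra, p, x0, tol = 1e-11, maxit = 60) {
  x <- x0
  n <- length(x)
  f <- rhs_eval(model, c(x, v_extra), p)
  for (it in seq_len(maxit)) {
    nf <- max(abs(f))
    if (!is.finite(nf)) return(NULL)
    if (nf < tol) return(x)
    J <- jac_eval(model, c(x, v_extra), p)
    step <- tryCatch(solve(J, -f), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) return(NULL)
    lam <- 1
    repeat {
      xn <- x + lam * step
      fn <- rhs_eval(model, c(xn, v_extra), p)
      if (all(is.finite(fn)) && max(abs(fn)) < nf) break
      lam <- lam / 2
      if (lam < 1e-10) return(if (nf < 1e-9) x else NULL)
    }
    x <- xn; f <- fn
  }
  if (max(abs(f)) < 1e-9) x else NULL
}

#' Locate equilibria by multi-start Newton search
#'
#' Damped Newton iterations are launched from a seeded Latin-hypercube
#' sample of the invariant box `[0, box_scale * bound/mu]` (see
#' [model_state_bounds()]) plus the box corners and centre. Converged roots
#' are deduplicated at `dedup_tol` in the infinity norm and classified by
#' the eigenvalues of the analytic Jacobian. Roots with negative
#' coordinates are retained but flagged inadmissible.
#'
#' @inheritParams model_rhs
#' @param n_starts Number of Latin-hypercube starting points (>= 1).
#' @param seed Integer seed for the start sample (mandatory for
#'   reproducibility).
#' @param box Optional 2-row matrix (min, max) per state overriding the
#'   default search box.
#' @param box_scale Multiplier applied to the invariant-box upper bounds.
#' @param dedup_tol Infinity-norm tolerance below which two roots are the
#'   same equilibrium.
#' @return Object of class `bswitch_equilibria`: list of equilibria, each a
#'   list with `state`, `eigenvalues`, `stability` (`"stable"`,
#'   `"unstable"` or `"marginal"`), `residual` and `admissible`. Stable
#'   equilibria come first, ordered by EBF1 (or first state) level. If no
#'   start converges an empty set is returned with a warning.
#' @export
find_equilibria <- function(model, params, inputs = c(T_EBF1 = 0, T_ZNF521 = 0),
                            n_starts = 200, seed = 1, box = NULL,
                            box_scale = 1.5, dedup_tol = 1e-5) {
  model <- as_model(model)
  if (n_starts < 1) stop("n_starts must be >= 1", call. = FALSE)
  p <- params_full(params)
  iv <- inputs_vec(inputs)
  n <- model$n
  if (is.null(box)) {
    ub <- box_scale * model_state_bounds(model, params)
    box <- rbind(rep(0, n), pmax(ub, 1e-3))
  }
  if (any(box[1, ] < 0)) stop("search box must lie in the non-negative orthant",
                              call. = FALSE)
  starts <- withr_seed(seed, {
    u <- lhs::randomLHS(n_starts, n)
    sweep(u, 2, box[2, ] - box[1, ], `*`) + matrix(box[1, ], n_starts, n, byrow = TRUE)
  })
  starts <- rbind(starts, box[1, ], box[2, ], colMeans(box))
  roots <- list()
  for (k in seq_len(nrow(starts))) {
    r <- newton_root(model, iv, p, starts[k, ])
    if (is.null(r)) next
    dup <- FALSE
    for (q in roots) if (max(abs(q - r)) <= dedup_tol) { dup <- TRUE; break }
    if (!dup) roots[[length(roots) + 1L]] <- r
  }
  if (length(roots) == 0) {
    warning("no Newton start converged for model '", model$id, "'")
    return(structure(list(), class = "bswitch_equilibria"))
  }
  eqs <- lapply(roots, function(r) {
    as_equilibrium(model, r, p, iv)
  })
  stab_rank <- vapply(eqs, function(e) e$stability == "stable", NA)
  lev <- vapply(eqs, function(e) {
    if ("EBF1" %in% model$states) e$state[["EBF1"]] else e$state[[1]]
  }, 0)
  eqs <- eqs[order(-stab_rank, lev)]
  structure(eqs, class = "bswitch_equilibria")
}

# package equilibrium record from a root
as_equilibrium <- function(model, x, p, iv) {
  ev <- eigen(jac_eval(model, c(x, iv), p), only.values = TRUE)$values
  list(state = stats::setNames(x, model$states),
       eigenvalues = ev,
       stability = stability_label(ev),
       residual = max(abs(rhs_eval(model, c(x, iv), p))),
       admissible = all(x >= -1e-9))
}

# marginal band around Re = 0 (fold neighbourhoods); marginal points are
# treated as unstable for branch bookkeeping
stability_label <- function(ev, marginal_band = 1e-7) {
  mre <- max(Re(ev))
  if (abs(mre) < marginal_band) "marginal"
  else if (mre < 0) "stable"
  else "unstable"
}

#' @export
print.bswitch_equilibria <- function(x, ...) {
  cat("<bswitch_equilibria> ", length(x), " equilibria\n", sep = "")
  for (e in x) {
    cat("  [", e$stability, if (!e$admissible) ", inadmissible", "] ",
        paste(sprintf("%s=%.4g", names(e$state), e$state), collapse = ", "),
        "  (|res| = ", format(e$residual, digits = 2), ")\n", sep = "")
  }
  invisible(x)
}

#' Write an equilibrium set as TSV
#'
#' @param eqs A [find_equilibria()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_equilibria_tsv <- function(eqs, path) {
  if (length(eqs) == 0) {
    writeLines("stability\tadmissible\tresidual", path)
    return(invisible(path))
  }
  df <- do.call(rbind, lapply(eqs, function(e) {
    data.frame(t(e$state), stability = e$stability,
               admissible = e$admissible, residual = e$residual,
               check.names = FALSE)
  }))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Classify the linear stability of an equilibrium
#'
#' Eigenvalue-based classification: stable iff every eigenvalue of the
#' Jacobian has strictly negative real part (with a margin); real parts
#' within `1e-7` of zero are flagged `"marginal"` and treated as unstable
#' for branch bookkeeping.
#'
#' @inheritParams model_rhs
#' @param eq Equilibrium state vector (must satisfy `|rhs|_inf <= 1e-6`).
#' @return An equilibrium record (list with `state`, `eigenvalues`,
#'   `stability`, `residual`, `admissible`).
#' @export
classify_stability <- function(model, params, inputs = c(T_EBF1 = 0, T_ZNF521 = 0), eq) {
  model <- as_model(model)
  x <- check_model_args(model, eq, params, inputs)
  p <- params_full(params)
  iv <- inputs_vec(inputs)
  res <- max(abs(rhs_eval(model, c(x, iv), p)))
  if (res > 1e-6)
    stop("state is not an equilibrium (|rhs|_inf = ", format(res), ")",
         call. = FALSE)
  as_equilibrium(model, x, p, iv)
}

#' Nullclines of a two-species model
#'
#' For a model with exactly two states (the EBF1/ZNF521 feedback module),
#' computes the loci where each state's derivative vanishes, by scanning a
#' grid along one coordinate and root-solving the scalar equation along the
#' other (all sign-change brackets are resolved, so folded nullclines are
#' captured). Intersections of the two loci are polished by Newton
#' iteration on the full 2-D system.
#'
#' @inheritParams model_rhs
#' @param box 2-column matrix `rbind(min, max)` for the two states; defaults
#'   to the invariant box scaled by 1.5.
#' @param n_grid Number of scan points per coordinate.
#' @return List with elements `nullclines` (list of two data.frames of
#'   points, named by state, each satisfying its equation to 1e-8) and
#'   `intersections` (matrix of polished crossings, one row per
#'   intersection).
#' @export
nullclines_2d <- function(model, params, inputs = c(T_EBF1 = 0, T_ZNF521 = 0),
                          box = NULL, n_grid = 201) {
  model <- as_model(model)
  if (model$n != 2)
    stop("nullclines_2d requires a model with exactly 2 states", call. = FALSE)
  p <- params_full(params)
  iv <- inputs_vec(inputs)
  if (is.null(box)) {
    ub <- 1.5 * model_state_bounds(model, params)
    box <- rbind(c(0, 0), pmax(ub, 1e-3))
  }
  scan <- function(i_zero, i_scan) {
    i_solve <- 3L - i_scan
    grid <- seq(box[1, i_scan], box[2, i_scan], length.out = n_grid)
    fine <- seq(box[1, i_solve], box[2, i_solve], length.out = 4 * n_grid)
    pts <- list()
    for (g in grid) {
      fval <- function(z) {
        x <- numeric(2); x[i_scan] <- g; x[i_solve] <- z
        rhs_eval(model, c(x, iv), p)[i_zero]
      }
      fv <- vapply(fine, fval, 0)
      sc <- which(fv[-1] * fv[-length(fv)] <= 0 & is.finite(fv[-1]))
      for (k in sc) {
        root <- stats::uniroot(fval, c(fine[k], fine[k + 1]), tol = 1e-12)$root
        x <- numeric(2); x[i_scan] <- g; x[i_solve] <- root
        pts[[length(pts) + 1L]] <- x
      }
    }
    if (length(pts) == 0) return(NULL)
    out <- do.call(rbind, pts)
    colnames(out) <- model$states
    as.data.frame(out)
  }
  # scan each nullcline along the other species' axis (derivative of state i
  # vanishes on a curve that is single-valued, or nearly so, in x_{3-i})
  nc <- list(scan(1L, 2L), scan(2L, 1L))
  names(nc) <- model$states

  # intersections: nearby point pairs across the two loci, polished by Newton
  inter <- list()
  if (!is.null(nc[[1]]) && !is.null(nc[[2]])) {
    a <- as.matrix(nc[[1]]); b <- as.matrix(nc[[2]])
    scale <- pmax(box[2, ] - box[1, ], 1e-9)
    d2 <- outer(a[, 1] / scale[1], b[, 1] / scale[1], `-`)^2 +
      outer(a[, 2] / scale[2], b[, 2] / scale[2], `-`)^2
    cell <- (2 / n_grid)^2 * 4
    cand <- which(d2 < cell, arr.ind = TRUE)
    for (r in seq_len(nrow(cand))) {
      x0 <- (a[cand[r, 1], ] + b[cand[r, 2], ]) / 2
      root <- newton_root(model, iv, p, as.numeric(x0))
      if (is.null(root)) next
      dup <- FALSE
      for (q in inter) if (max(abs(q - root)) <= 1e-6) { dup <- TRUE; break }
      if (!dup) inter[[length(inter) + 1L]] <- root
    }
  }
  inter <- if (length(inter) > 0) {
    m <- do.call(rbind, inter); colnames(m) <- model$states; m
  } else matrix(numeric(0), ncol = 2, dimnames = list(NULL, model$states))
  list(nullclines = nc, intersections = inter)
}

# evaluate a seeded expression without disturbing the caller's RNG state
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(seed)
  expr
}
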