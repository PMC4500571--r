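# Pseudo-arclength continuation of equilibrium branches, fold (limit point)
# detection, diagram assembly and switch classification.
#
# The core operates on a generic algebraic system f(x, p) = 0 with supplied
# state Jacobian and parameter derivative, so that the same code is
# exercised on closed-form normal forms in the tests and on the network
# models in the analysis.

# tangent of the extended system at (x, p): null vector of [Jx | Jp],
# normalised to unit length, oriented along `orient` if given
branch_tangent <- function(Jx, Jp, orient = NULL) {
  n <- nrow(Jx)
  A <- cbind(Jx, Jp)
  # null space via QR of t(A): last column of Q spans ker(A) for full-rank A
  qr_t <- qr(t(A))
  t_vec <- qr.Q(qr_t, complete = TRUE)[, n + 1]
  t_vec <- t_vec / sqrt(sum(t_vec^2))
  if (!is.null(orient) && sum(t_vec * orient) < 0) t_vec <- -t_vec
  t_vec
}

# one predictor-corrector step; returns NULL on failure. A step is also
# rejected when the corrector lands far from the predictor relative to the
# step length (loss of contraction near sharp turns can silently hop onto a
# neighbouring branch).
pa_step <- function(f, jx, jp, u, t_vec, h, tol = 1e-10, maxit = 12) {
  n <- length(u) - 1L
  pred <- u + h * t_vec
  uk <- pred
  for (it in seq_len(maxit)) {
    fv <- f(uk[seq_len(n)], uk[n + 1L])
    g <- c(fv, sum(t_vec * (uk - pred)))
    if (!all(is.finite(g))) return(NULL)
    if (max(abs(g)) < tol && it > 1) break
    Jx <- jx(uk[seq_len(n)], uk[n + 1L])
    Jp <- jp(uk[seq_len(n)], uk[n + 1L])
    A <- rbind(cbind(Jx, Jp), t_vec)
    step <- tryCatch(solve(A, -g), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) return(NULL)
    uk <- uk + step
    if (max(abs(step)) < 1e-14) break
  }
  fv <- f(uk[seq_len(n)], uk[n + 1L])
  if (max(abs(fv)) > 1e-8) return(NULL)
  if (sqrt(sum((uk - pred)^2)) > 2 * max(h, 1e-8)) return(NULL)
  uk
}

#' Pseudo-arclength continuation of a generic equilibrium curve
#'
#' Traces the solution set of `f(x, p) = 0` from a starting equilibrium,
#' using a tangent predictor and a Newton corrector constrained orthogonally
#' to the tangent (Moore--Penrose-style), with adaptive step control. Folds
#' (limit points) are detected by a sign change of the parameter component
#' of the unit tangent and refined by bisection on the step length until the
#' fold parameter is bracketed to `1e-8`.
#'
#' @param f Function `f(x, p)` returning the n-vector of residuals.
#' @param jx Function returning the n x n state Jacobian at `(x, p)`.
#' @param jp Function returning the n-vector of parameter derivatives.
#' @param x0 Starting state (must satisfy `|f|_inf <= 1e-8` at `p0`).
#' @param p0 Starting parameter value.
#' @param range Length-2 numeric: parameter interval to cover.
#' @param direction +1 or -1: initial orientation of the parameter component
#'   of the tangent.
#' @param h0,h_min,h_max Initial, minimum and maximum arclength steps.
#' @param max_steps Cap on the number of accepted points.
#' @param admissible_min Parameter values below this are flagged
#'   inadmissible (the curve is still traced through them).
#' @return Object of class `bswitch_branch`: list with `points` (data.frame
#'   of `param`, one column per state, `stability`, `admissible`),
#'   `eigenvalues` (list per point), `folds` (data.frame of refined fold
#'   `param` and state columns), `stop_reason`, and metadata fields.
#' @export
continue_curve <- function(f, jx, jp, x0, p0, range, direction = 1,
                           h0 = 1e-2, h_min = 1e-6, h_max = 1e-1,
                           max_steps = 2000, admissible_min = 0,
                           state_names = NULL, jx_stability = NULL) {
  n <- length(x0)
  if (is.null(jx_stability)) jx_stability <- jx
  if (is.null(state_names)) state_names <- paste0("x", seq_len(n))
  fv <- f(x0, p0)
  if (max(abs(fv)) > 1e-8)
    stop("starting point is not an equilibrium (|f|_inf = ",
         format(max(abs(fv))), ")", call. = FALSE)
  u <- c(x0, p0)
  t_vec <- branch_tangent(jx(x0, p0), jp(x0, p0),
                          orient = c(rep(0, n), direction))
  # if the tangent is state-dominated (near-vertical branch), keep direction
  # sign convention on its largest component instead
  if (abs(t_vec[n + 1L]) < 1e-12) {
    t_vec <- branch_tangent(jx(x0, p0), jp(x0, p0))
  }

  pts <- list(u)
  tans <- list(t_vec)
  h <- h0
  stop_reason <- "max_steps"
  for (k in seq_len(max_steps)) {
    res <- NULL
    while (is.null(res) && h >= h_min) {
      res <- pa_step(f, jx, jp, u, t_vec, h)
      if (is.null(res)) h <- h / 2
    }
    if (is.null(res)) { stop_reason <- "step_underflow"; break }
    t_new <- branch_tangent(jx(res[seq_len(n)], res[n + 1L]),
                            jp(res[seq_len(n)], res[n + 1L]), orient = t_vec)
    u <- res
    t_vec <- t_new
    pts[[length(pts) + 1L]] <- u
    tans[[length(tans) + 1L]] <- t_vec
    h <- min(h * 1.3, h_max)
    if (u[n + 1L] < range[1] - 1e-9 || u[n + 1L] > range[2] + 1e-9) {
      stop_reason <- "range_exit"; break
    }
  }

  P <- do.call(rbind, pts)
  tp <- vapply(tans, function(t) t[n + 1L], 0)

  # fold refinement: bisection on the arclength step between sign changes
  folds <- list()
  sc <- which(tp[-1] * tp[-length(tp)] < 0)
  for (k in sc) {
    ua <- pts[[k]]; ta <- tans[[k]]
    hb <- sqrt(sum((pts[[k + 1L]] - ua)^2))
    lo <- 0; hi <- hb
    tp_lo <- tp[k]
    u_mid <- pts[[k + 1L]]
    for (it in 1:60) {
      mid <- (lo + hi) / 2
      res <- pa_step(f, jx, jp, ua, ta, mid)
      if (is.null(res)) { hi <- mid; next }  # corrector failed: shrink
      tm <- branch_tangent(jx(res[seq_len(n)], res[n + 1L]),
                           jp(res[seq_len(n)], res[n + 1L]), orient = ta)
      u_mid <- res
      if (tm[n + 1L] * tp_lo < 0) hi <- mid else lo <- mid
      if (hi - lo < 1e-12 || abs(tm[n + 1L]) < 1e-10) break
    }
    folds[[length(folds) + 1L]] <- u_mid
  }

  stab <- character(nrow(P))
  evs <- vector("list", nrow(P))
  for (i in seq_len(nrow(P))) {
    ev <- eigen(jx_stability(P[i, seq_len(n)], P[i, n + 1L]),
                only.values = TRUE)$values
    evs[[i]] <- ev
    stab[i] <- stability_label(ev)
  }

  points <- data.frame(param = P[, n + 1L], P[, seq_len(n), drop = FALSE])
  names(points) <- c("param", state_names)
  points$stability <- stab
  points$admissible <- points$param >= admissible_min - 1e-9

  fold_df <- if (length(folds) > 0) {
    Fm <- do.call(rbind, folds)
    fd <- data.frame(param = Fm[, n + 1L], Fm[, seq_len(n), drop = FALSE])
    names(fd) <- c("param", state_names)
    fd$admissible <- fd$param >= admissible_min - 1e-9
    fd
  } else {
    fd <- data.frame(param = numeric(0))
    for (s in state_names) fd[[s]] <- numeric(0)
    fd$admissible <- logical(0)
    fd
  }

  structure(list(points = points, eigenvalues = evs, folds = fold_df,
                 stop_reason = stop_reason, state_names = state_names,
                 admissible_min = admissible_min),
            class = "bswitch_branch")
}

#' @export
print.bswitch_branch <- function(x, ...) {
  cat("<bswitch_branch> ", nrow(x$points), " points, param in [",
      format(min(x$points$param), digits = 4), ", ",
      format(max(x$points$param), digits = 4), "], ",
      nrow(x$folds), " fold(s); stop: ", x$stop_reason, "\n", sep = "")
  if (nrow(x$folds) > 0)
    cat("  folds at param = ",
        paste(format(x$folds$param, digits = 6), collapse = ", "), "\n", sep = "")
  invisible(x)
}

# wrap a network model as (f, jx, jp) closures in the free parameter
model_closures <- function(model, params, inputs, free_param) {
  model <- as_model(model)
  p <- params_full(params)
  iv <- inputs_vec(inputs)
  free_is_input <- free_param %in% INPUT_NAMES
  if (!free_is_input && !(free_param %in% param_symbols()))
    stop("unknown free parameter: ", free_param, call. = FALSE)
  ci <- if (!free_is_input) match(free_param, param_symbols()) else NA_integer_
  at <- function(pv) {
    if (free_is_input) { iv2 <- iv; iv2[[free_param]] <- pv; list(p = p, iv = iv2) }
    else { p2 <- p; p2[ci] <- pv; list(p = p2, iv = iv) }
  }
  list(
    f = function(x, pv) { a <- at(pv); rhs_eval(model, c(x, a$iv), a$p) },
    jx = function(x, pv) { a <- at(pv); jac_eval(model, c(x, a$iv), a$p) },
    jp = function(x, pv) { a <- at(pv); dp_eval(model, c(x, a$iv), a$p, free_param) }
  )
}

#' Continue an equilibrium branch of a network model
#'
#' Traces the equilibrium branch of the chosen model against a free
#' parameter (an environmental input such as `T_EBF1`, or any kinetic
#' symbol) by pseudo-arclength continuation, in both directions from the
#' starting equilibrium. The free parameter may go negative; such points
#' are flagged inadmissible (mathematical branch tracing only).
#'
#' @inheritParams model_rhs
#' @param free_param Name of the free parameter (input or kinetic symbol).
#' @param start Starting equilibrium state at the current value of the free
#'   parameter (e.g. from [find_equilibria()]).
#' @param range Parameter interval to cover.
#' @param admissible_min Lower bound of the physically admissible domain
#'   for the free parameter (default 0).
#' @param ... Step-control arguments passed to [continue_curve()].
#' @return A `bswitch_branch` (see [continue_curve()]) with metadata fields
#'   `model` and `free_param`.
#' @export
continue_branch <- function(model, params, inputs = c(T_EBF1 = 0, T_ZNF521 = 0),
                            free_param, start, range, admissible_min = 0, ...) {
  model <- as_model(model)
  cl <- model_closures(model, params, inputs, free_param)
  iv <- inputs_vec(inputs)
  p0 <- if (free_param %in% INPUT_NAMES) iv[[free_param]]
        else params_full(params)[[free_param]]
  x0 <- check_model_args(model, start, params, inputs)
  n <- model$n

  # continue in scaled coordinates y = x / s (s: invariant-box magnitudes),
  # so arclength steps are commensurate across states of different size;
  # stability is always classified from the unscaled Jacobian
  s <- pmax(model_state_bounds(model, params), 1e-3)
  fs <- function(y, pv) cl$f(y * s, pv)
  jxs <- function(y, pv) sweep(cl$jx(y * s, pv), 2, s, `*`)
  jps <- function(y, pv) cl$jp(y * s, pv)
  jstab <- function(y, pv) cl$jx(y * s, pv)

  fwd <- continue_curve(fs, jxs, jps, x0 / s, p0, range, direction = 1,
                        admissible_min = admissible_min,
                        state_names = model$states, jx_stability = jstab, ...)
  bwd <- continue_curve(fs, jxs, jps, x0 / s, p0, range, direction = -1,
                        admissible_min = admissible_min,
                        state_names = model$states, jx_stability = jstab, ...)
  unscale <- function(df) {
    if (nrow(df) > 0)
      df[model$states] <- sweep(as.matrix(df[, model$states, drop = FALSE]),
                                2, s, `*`)
    df
  }
  points <- rbind(bwd$points[rev(seq_len(nrow(bwd$points)))[-nrow(bwd$points)], ],
                  fwd$points)
  evs <- c(rev(bwd$eigenvalues)[-length(bwd$eigenvalues)], fwd$eigenvalues)
  folds <- rbind(bwd$folds, fwd$folds)
  rownames(points) <- NULL
  structure(list(points = unscale(points), eigenvalues = evs,
                 folds = unscale(folds),
                 stop_reason = paste0("backward:", bwd$stop_reason,
                                      "; forward:", fwd$stop_reason),
                 state_names = model$states, admissible_min = admissible_min,
                 state_physical = TRUE,
                 model = model$id, free_param = free_param),
            class = "bswitch_branch")
}

#' Build a bifurcation diagram for a model
#'
#' Finds equilibria at the range endpoints, midpoint and quarter points of
#' the free parameter, launches branch continuation from every distinct
#' equilibrium not already covered by an existing branch, merges duplicate
#' branches, and attaches the switch classification of [classify_switch()].
#'
#' @inheritParams continue_branch
#' @param n_starts,seed Multi-start settings for the per-value equilibrium
#'   searches.
#' @param merge_tol Points closer than this (in combined parameter/state
#'   infinity norm) to an existing branch mark a duplicate start.
#' @return Object of class `bswitch_diagram`: list with `branches` (list of
#'   `bswitch_branch`), `classification`, `bistable_intervals` (matrix with
#'   columns `lo`, `hi`), `folds` (combined fold table), `model`,
#'   `free_param`, `admissible_min`.
#' @export
build_diagram <- function(model, params, inputs = c(T_EBF1 = 0, T_ZNF521 = 0),
                          free_param = "T_EBF1", range = c(-1, 3),
                          admissible_min = 0, n_starts = 60, seed = 1,
                          n_probes = 5, ...) {
  model <- as_model(model)
  iv <- inputs_vec(inputs)
  probe_vals <- seq(range[1], range[2], length.out = max(2L, n_probes))
  set_free <- function(pv) {
    if (free_param %in% INPUT_NAMES) { iv2 <- iv; iv2[[free_param]] <- pv
      list(params = params, inputs = iv2) }
    else { p2 <- params; p2[[free_param]] <- pv; list(params = p2, inputs = iv) }
  }
  branches <- list()
  covered <- function(x, pv) {
    for (br in branches) {
      pts <- br$points
      near_p <- abs(pts$param - pv) < 0.05 * max(1, diff(range))
      if (!any(near_p)) next
      sub <- as.matrix(pts[near_p, model$states, drop = FALSE])
      d <- apply(abs(sweep(sub, 2, x, `-`)), 1, max)
      if (min(d) < 0.05 * max(1, max(abs(x)))) return(TRUE)
    }
    FALSE
  }
  for (pv in probe_vals) {
    a <- set_free(pv)
    eqs <- suppressWarnings(find_equilibria(model, a$params, a$inputs,
                                            n_starts = n_starts, seed = seed))
    for (e in eqs) {
      if (!e$admissible) next  # nonphysical roots are not branch seeds
      if (covered(e$state, pv)) next
      br <- tryCatch(
        continue_branch(model, a$params, a$inputs, free_param = free_param,
                        start = e$state, range = range,
                        admissible_min = admissible_min, ...),
        error = function(err) NULL)
      if (!is.null(br)) branches[[length(branches) + 1L]] <- br
    }
  }
  branches <- merge_branches(branches, model$states)
  folds <- do.call(rbind, c(lapply(branches, `[[`, "folds"),
                            list(make.row.names = FALSE)))
  cls <- classify_switch_points(branches, model$states, admissible_min, range)
  structure(list(branches = branches, classification = cls$class,
                 bistable_intervals = cls$intervals, folds = folds,
                 model = model$id, free_param = free_param,
                 admissible_min = admissible_min, range = range),
            class = "bswitch_diagram")
}

# drop branches whose points all lie within merge tolerance of an earlier
# branch (same curve traced from a different start)
merge_branches <- function(branches, states, tol = 1e-3) {
  if (length(branches) <= 1) return(branches)
  keep <- list(branches[[1]])
  for (br in branches[-1]) {
    dup <- FALSE
    for (kb in keep) {
      A <- as.matrix(br$points[, c("param", states)])
      B <- as.matrix(kb$points[, c("param", states)])
      # subsample for the containment test
      idx <- unique(round(seq(1, nrow(A), length.out = 25)))
      contained <- all(vapply(idx, function(i) {
        min(apply(abs(sweep(B, 2, A[i, ], `-`)), 1, max)) < max(tol, 1e-2)
      }, NA))
      if (contained) { dup <- TRUE; break }
    }
    if (!dup) keep[[length(keep) + 1L]] <- br
  }
  keep
}

#' @export
print.bswitch_diagram <- function(x, ...) {
  cat("<bswitch_diagram> model ", x$model, ", free ", x$free_param, " in [",
      format(x$range[1]), ", ", format(x$range[2]), "]\n", sep = "")
  cat("  ", length(x$branches), " branch(es), ",
      nrow(x$folds), " fold(s); classification: ", x$classification, "\n", sep = "")
  if (nrow(x$bistable_intervals) > 0)
    for (i in seq_len(nrow(x$bistable_intervals)))
      cat("  bistable interval: [",
          format(x$bistable_intervals[i, 1], digits = 6), ", ",
          format(x$bistable_intervals[i, 2], digits = 6), "]\n", sep = "")
  invisible(x)
}

# stable-segment p-intervals of a branch: maximal runs of stable points.
# Segment bounds are snapped to the branch's refined fold parameters when a
# fold lies just beyond the last stable point (stability flips exactly at
# the fold, so the refined fold location is the true segment boundary).
stable_segments <- function(br, span) {
  points <- br$points
  # for network models negative expression levels are nonphysical and do
  # not count towards bistability; generic curves carry no such constraint
  if (isTRUE(br$state_physical)) {
    xs <- as.matrix(points[, br$state_names, drop = FALSE])
    physical <- apply(xs, 1, min) >= -1e-6
  } else physical <- TRUE
  runs <- rle(points$stability == "stable" & physical)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  snap_tol <- 0.15 * max(1, span)
  segs <- list()
  for (i in seq_along(runs$values)) {
    if (!runs$values[i]) next
    pr <- range(points$param[starts[i]:ends[i]])
    if (nrow(br$folds) > 0) {
      for (k in seq_len(nrow(br$folds))) {
        fp <- br$folds$param[k]
        if (fp < pr[1] && pr[1] - fp < snap_tol) pr[1] <- fp
        if (fp > pr[2] && fp - pr[2] < snap_tol) pr[2] <- fp
      }
    }
    segs[[length(segs) + 1L]] <- pr
  }
  segs
}

# classification from branch point sets: bistable intervals are pairwise
# overlaps of distinct stable segments
classify_switch_points <- function(branches, states, admissible_min, range) {
  segs <- list()
  span <- diff(range)
  for (br in branches) {
    for (s in stable_segments(br, span)) segs[[length(segs) + 1L]] <- s
  }
  intervals <- matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("lo", "hi")))
  if (length(segs) >= 2) {
    for (i in seq_along(segs)) for (j in seq_along(segs)) {
      if (j <= i) next
      lo <- max(segs[[i]][1], segs[[j]][1])
      hi <- min(segs[[i]][2], segs[[j]][2])
      if (hi - lo > 1e-7) intervals <- rbind(intervals, c(lo, hi))
    }
  }
  if (nrow(intervals) > 0) {
    # merge overlapping intervals
    o <- order(intervals[, 1])
    intervals <- intervals[o, , drop = FALSE]
    merged <- intervals[1, , drop = FALSE]
    for (i in seq_len(nrow(intervals))[-1]) {
      k <- nrow(merged)
      if (intervals[i, 1] <= merged[k, 2] + 1e-9)
        merged[k, 2] <- max(merged[k, 2], intervals[i, 2])
      else merged <- rbind(merged, intervals[i, ])
    }
    intervals <- merged
    colnames(intervals) <- c("lo", "hi")
  }
  admissible <- intervals[intervals[, "hi"] > admissible_min, , drop = FALSE]
  if (nrow(admissible) == 0) {
    cls <- "monostable"
  } else if (any(admissible[, "lo"] < admissible_min)) {
    cls <- "irreversible_bistable"
  } else {
    cls <- "reversible_bistable"
  }
  list(class = cls, intervals = intervals)
}

#' Classify a bifurcation diagram as a commitment switch
#'
#' A diagram is `monostable` if no admissible value of the free parameter
#' carries two or more stable equilibria; `reversible_bistable` if a
#' bistable interval exists and both of its bounding folds lie in the
#' admissible domain; `irreversible_bistable` if bistability exists but
#' extends below the admissible bound, so that the two stable branches are
#' disconnected on the admissible domain (the lower fold cannot be reached).
#'
#' @param diagram A [build_diagram()] result.
#' @param admissible_min Lower bound of the admissible domain (default 0;
#'   expression-activating inputs cannot be negative).
#' @return List with `classification` and `bistable_intervals` (matrix of
#'   `lo`, `hi` columns, on the full traced domain).
#' @export
classify_switch <- function(diagram, admissible_min = diagram$admissible_min) {
  if (!inherits(diagram, "bswitch_diagram"))
    stop("diagram must be a bswitch_diagram", call. = FALSE)
  if (length(diagram$branches) == 0)
    stop("empty diagram", call. = FALSE)
  states <- diagram$branches[[1]]$state_names
  cls <- classify_switch_points(diagram$branches, states, admissible_min,
                                diagram$range)
  list(classification = cls$class, bistable_intervals = cls$intervals)
}

#' Scan a branch for Hopf-type eigenvalue crossings
#'
#' Walks the stored eigenvalues along a branch and flags points where a
#' complex-conjugate pair crosses the imaginary axis (sign change of the
#' largest complex real part with nonzero imaginary part). The crossing
#' parameter is located by linear interpolation between adjacent points.
#' For this model family only folds are expected; any nonempty result is
#' accompanied by a warning, not an error.
#'
#' @param branch A `bswitch_branch`.
#' @return Data frame with columns `param` and `im` (imaginary part of the
#'   crossing pair); zero rows if no crossing.
#' @export
hopf_scan <- function(branch) {
  if (!inherits(branch, "bswitch_branch"))
    stop("branch must be a bswitch_branch", call. = FALSE)
  evs <- branch$eigenvalues
  pv <- branch$points$param
  cross <- data.frame(param = numeric(0), im = numeric(0))
  if (length(evs) < 2) return(cross)
  cmax <- vapply(evs, function(ev) {
    cc <- ev[abs(Im(ev)) > 1e-8]
    if (length(cc) == 0) NA_real_ else max(Re(cc))
  }, 0)
  cim <- vapply(evs, function(ev) {
    cc <- ev[abs(Im(ev)) > 1e-8]
    if (length(cc) == 0) NA_real_ else max(abs(Im(cc)))
  }, 0)
  for (i in seq_len(length(evs) - 1L)) {
    if (is.na(cmax[i]) || is.na(cmax[i + 1])) next
    if (cmax[i] * cmax[i + 1] < 0) {
      w <- abs(cmax[i]) / (abs(cmax[i]) + abs(cmax[i + 1]))
      cross <- rbind(cross, data.frame(
        param = (1 - w) * pv[i] + w * pv[i + 1],
        im = (1 - w) * cim[i] + w * cim[i + 1]))
    }
  }
  if (nrow(cross) > 0)
    warning("Hopf-type eigenvalue crossing(s) detected; this model family ",
            "is expected to exhibit only folds")
  cross
}

#' Write a bifurcation diagram as TSV files
#'
#' Writes `<stem>_branches.tsv` (columns: branch id, free parameter, state
#' columns, stability, admissible flag), `<stem>_folds.tsv` and
#' `<stem>_summary.tsv` (classification and bistable intervals).
#'
#' @param diagram A [build_diagram()] result.
#' @param stem Output path stem.
#' @return Character vector of the three paths, invisibly.
#' @export
write_diagram_tsv <- function(diagram, stem) {
  states <- diagram$branches[[1]]$state_names
  rows <- list()
  for (i in seq_along(diagram$branches)) {
    pts <- diagram$branches[[i]]$points
    pts$branch <- i
    rows[[i]] <- pts[, c("branch", "param", states, "stability", "admissible")]
  }
  br_path <- paste0(stem, "_branches.tsv")
  fold_path <- paste0(stem, "_folds.tsv")
  sum_path <- paste0(stem, "_summary.tsv")
  utils::write.table(do.call(rbind, rows), br_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(diagram$folds, fold_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  iv <- diagram$bistable_intervals
  summary <- data.frame(
    model = diagram$model, free_param = diagram$free_param,
    classification = diagram$classification,
    bistable_lo = if (nrow(iv) > 0) iv[1, 1] else NA_real_,
    bistable_hi = if (nrow(iv) > 0) iv[1, 2] else NA_real_)
  utils::write.table(summary, sum_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(br_path, fold_path, sum_path))
}
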