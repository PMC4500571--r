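# Model-comparison screens: alternative-topology variants, the core
# feedback-loop ladder, reversibility mapping over T_ZNF521, and
# reprogramming-schedule simulation.

SUBMODULES <- c("ebf1_znf521", "ebf1_e2a_pax5", "ebf1_pax5_flt3_il7r",
                "ebf1_e2a_pax5_flt3_il7r", "znf521_ebf1_pax5_flt3_il7r",
                "znf521_ebf1_e2a_pax5", "ebf1_pax5_znf521")

#' Locate and label the commitment attractors
#'
#' Finds the stable admissible equilibria of a model and labels them by the
#' canonical expression programs: the LMPP (multipotent) attractor has FLT3
#' and ZNF521 above their cross-attractor midpoints and EBF1, PAX5, CD19
#' below; the pro-B (committed) attractor has the reverse pattern. Labels
#' are assigned by the sign pattern, not by fixed thresholds.
#'
#' @inheritParams model_rhs
#' @param n_starts,seed Multi-start search settings.
#' @return Named list of labelled equilibrium records; names among
#'   `"LMPP"`, `"proB"` when the pattern is recognised, otherwise
#'   `"state1"`, `"state2"`, ... ordered by EBF1 level.
#' @export
find_attractors <- function(model = "full_A", params,
                            inputs = c(T_EBF1 = 0, T_ZNF521 = 0),
                            n_starts = 150, seed = 1) {
  model <- as_model(model)
  eqs <- suppressWarnings(find_equilibria(model, params, inputs,
                                          n_starts = n_starts, seed = seed))
  st <- Filter(function(e) e$stability == "stable" && e$admissible, eqs)
  if (length(st) == 0) return(list())
  if (length(st) == 1) {
    names(st) <- label_single_attractor(st[[1]]$state, model)
    return(st)
  }
  # order by EBF1 (ascending); label the extremes by the sign pattern
  lev <- vapply(st, function(e)
    if ("EBF1" %in% model$states) e$state[["EBF1"]] else e$state[[1]], 0)
  st <- st[order(lev)]
  nm <- paste0("state", seq_along(st))
  lo <- st[[1]]$state; hi <- st[[length(st)]]$state
  up_lmpp <- intersect(c("FLT3", "ZNF521"), model$states)
  up_prob <- intersect(c("EBF1", "PAX5", "CD19"), model$states)
  mid <- (lo + hi) / 2
  if (length(up_prob) > 0 &&
      all(lo[up_lmpp] > mid[up_lmpp]) && all(hi[up_lmpp] < mid[up_lmpp]) &&
      all(lo[up_prob] < mid[up_prob]) && all(hi[up_prob] > mid[up_prob])) {
    nm[1] <- "LMPP"; nm[length(st)] <- "proB"
  }
  names(st) <- nm
  st
}

# single-attractor label: committed if the pro-B markers sit in the upper
# part of their invariant range, multipotent if the LMPP markers do
label_single_attractor <- function(state, model) {
  if (!"EBF1" %in% model$states) return("state1")
  if (state[["EBF1"]] > 1) "proB-like" else "LMPP-like"
}

#' Screen alternative network hypotheses
#'
#' Builds a `T_EBF1` bifurcation diagram for each topology variant at the
#' reversible-switch condition (`T_ZNF521 = 0.12` by default) and reports
#' the switch class of each: the nominal network (variant A), the variants
#' with ZNF521 repressed through E2A (B) or IKAROS (C) in place of the
#' PAX5-mediated repression, and the plain ablation of that repression.
#' A variant supports the commitment switch when its diagram is not
#' monostable.
#'
#' @param variant_params Named list mapping model identifiers to parameter
#'   sets. Defaults to the four full-network variants, all at `params`.
#' @param params Parameter set used for variants not listed in
#'   `variant_params`.
#' @param inputs Environmental inputs for the screen.
#' @param range,n_starts,seed Diagram settings.
#' @return Data frame of class `bswitch_screen`: one row per variant with
#'   `model`, `classification`, `n_folds`, `fold_params`,
#'   `bistable_lo`, `bistable_hi`, `supports_switch`.
#' @export
screen_variants <- function(params, variant_params = NULL,
                            inputs = c(T_EBF1 = 0, T_ZNF521 = 0.12),
                            range = c(-2, 3), n_starts = 40, seed = 1) {
  if (is.null(variant_params)) {
    ids <- c("full_A", "full_B", "full_C", "full_no_pax5_znf521")
    variant_params <- stats::setNames(rep(list(params), length(ids)), ids)
  }
  rows <- lapply(names(variant_params), function(id) {
    d <- tryCatch(
      build_diagram(id, variant_params[[id]], inputs, range = range,
                    n_starts = n_starts, seed = seed),
      error = function(e) NULL)
    if (is.null(d))
      return(data.frame(model = id, classification = "unevaluated",
                        n_folds = NA_integer_, fold_params = "",
                        bistable_lo = NA_real_, bistable_hi = NA_real_,
                        supports_switch = NA))
    iv <- d$bistable_intervals
    data.frame(model = id, classification = d$classification,
               n_folds = nrow(d$folds),
               fold_params = paste(sprintf("%.6g", d$folds$param),
                                   collapse = ","),
               bistable_lo = if (nrow(iv) > 0) iv[1, 1] else NA_real_,
               bistable_hi = if (nrow(iv) > 0) iv[1, 2] else NA_real_,
               supports_switch = d$classification != "monostable")
  })
  structure(do.call(rbind, rows), class = c("bswitch_screen", "data.frame"))
}

#' Classify the seven core feedback sub-modules
#'
#' Builds the `T_EBF1` diagram for each feedback sub-module at shared
#' nominal parameters and collects the switch class and fold inventory,
#' reproducing the feedback-loop ladder: the two-node EBF1/ZNF521 mutual
#' inhibition admits a single steady state with one inaccessible fold at
#' negative `T_EBF1`; the intermediate modules are monostable; only the
#' EBF1/PAX5/ZNF521 module (which adds the PAX5-mediated repression of
#' ZNF521) realises the irreversible bistable switch.
#'
#' @inheritParams screen_variants
#' @return Data frame (class `bswitch_screen`): one row per sub-module with
#'   the same columns as [screen_variants()] plus `n_admissible_folds`.
#' @export
submodule_ladder <- function(params, inputs = c(T_EBF1 = 0, T_ZNF521 = 0),
                             range = c(-2, 3), n_starts = 40, seed = 1) {
  rows <- lapply(SUBMODULES, function(id) {
    d <- tryCatch(
      build_diagram(id, params, inputs, range = range,
                    n_starts = n_starts, seed = seed),
      error = function(e) NULL)
    if (is.null(d))
      return(data.frame(model = id, classification = "unevaluated",
                        n_folds = NA_integer_, n_admissible_folds = NA_integer_,
                        fold_params = "", bistable_lo = NA_real_,
                        bistable_hi = NA_real_, supports_switch = NA))
    iv <- d$bistable_intervals
    # folds on physical branch segments only (all fold states non-negative)
    states <- d$branches[[1]]$state_names
    phys <- if (nrow(d$folds) > 0)
      apply(as.matrix(d$folds[, states, drop = FALSE]), 1, min) >= -1e-6
    else logical(0)
    data.frame(model = id, classification = d$classification,
               n_folds = sum(phys),
               n_admissible_folds = sum(phys & d$folds$param >= 0),
               fold_params = paste(sprintf("%.6g", d$folds$param[phys]),
                                   collapse = ","),
               bistable_lo = if (nrow(iv) > 0) iv[1, 1] else NA_real_,
               bistable_hi = if (nrow(iv) > 0) iv[1, 2] else NA_real_,
               supports_switch = d$classification != "monostable")
  })
  structure(do.call(rbind, rows), class = c("bswitch_screen", "data.frame"))
}

#' Switch class as a function of ZNF521 transcriptional activation
#'
#' Rebuilds the `T_EBF1` bifurcation diagram at each requested `T_ZNF521`
#' level and reports the switch class, fold locations and the midpoint of
#' the EBF1 transition (the `T_EBF1` value at which the stable EBF1
#' response crosses half its range), quantifying how ZNF521 activation
#' converts the irreversible switch into a reversible one and then delays
#' commitment.
#'
#' @inheritParams screen_variants
#' @param tznf521_values Numeric vector of ZNF521 activation levels.
#' @param model Model identifier (default the full network).
#' @return Data frame: one row per level with `t_znf521`,
#'   `classification`, `bistable_lo`, `bistable_hi`, `fold_params`,
#'   `transition_midpoint`.
#' @export
reversibility_map <- function(params, tznf521_values = c(0, 0.12, 0.3),
                              model = "full_A", range = c(-2, 3),
                              n_starts = 40, seed = 1) {
  rows <- lapply(tznf521_values, function(tz) {
    d <- build_diagram(model, params, c(T_EBF1 = 0, T_ZNF521 = tz),
                       range = range, n_starts = n_starts, seed = seed)
    iv <- d$bistable_intervals
    data.frame(t_znf521 = tz, classification = d$classification,
               bistable_lo = if (nrow(iv) > 0) iv[1, 1] else NA_real_,
               bistable_hi = if (nrow(iv) > 0) iv[1, 2] else NA_real_,
               fold_params = paste(sprintf("%.6g", d$folds$param),
                                   collapse = ","),
               transition_midpoint = ebf1_transition_midpoint(d))
  })
  do.call(rbind, rows)
}

# T_EBF1 at which the stable EBF1 response first reaches half its overall
# range when sweeping upwards (a proxy for the commitment threshold)
ebf1_transition_midpoint <- function(diagram) {
  pts <- do.call(rbind, lapply(diagram$branches, function(br)
    br$points[br$points$stability == "stable" & br$points$admissible &
                br$points$param >= 0, c("param", "EBF1")]))
  if (is.null(pts) || nrow(pts) == 0 || !"EBF1" %in% names(pts))
    return(NA_real_)
  half <- (min(pts$EBF1) + max(pts$EBF1)) / 2
  # lowest admissible T at which only high-EBF1 stable states remain
  lowset <- pts$param[pts$EBF1 < half]
  if (length(lowset) == 0) return(min(pts$param))
  max(lowset)
}

#' Simulate a reprogramming schedule
#'
#' Integrates the model through a piecewise-constant schedule of the
#' environmental inputs, starting from a computed attractor, and labels the
#' final state by the nearest attractor (infinity-norm) of the
#' end-condition equilibrium set. A final state whose distance ratio
#' between the two nearest attractors is below 2 is labelled
#' `"undecided"`. Used to test reversion of committed pro-B progenitors to
#' the multipotent state via ZNF521 overexpression plus EBF1 silencing.
#'
#' @inheritParams model_rhs
#' @param plan Data frame with columns `duration`, `T_EBF1`, `T_ZNF521`;
#'   one row per schedule segment, applied in order. Input levels must be
#'   non-negative and durations positive.
#' @param start Starting state: an attractor label (`"LMPP"`, `"proB"`)
#'   resolved against the attractors at the baseline `start_inputs`, or a
#'   numeric state vector lying on one of those attractors.
#' @param start_inputs Environmental inputs of the pre-schedule baseline
#'   condition at which the starting attractor is computed (default: both
#'   inputs off).
#' @param n_points Output points per segment.
#' @param n_starts,seed Settings for the attractor searches.
#' @return List of class `bswitch_reprogram`: `trajectory` (times and
#'   states across all segments), `start_label`, `final_label`,
#'   `final_state`, `distances` (to each end-condition attractor),
#'   `reverted` (`TRUE` when a proB start is relabelled LMPP).
#' @export
reprogram <- function(model = "full_A", params, plan, start = "proB",
                      start_inputs = c(T_EBF1 = 0, T_ZNF521 = 0),
                      n_points = 60, n_starts = 150, seed = 1) {
  model <- as_model(model)
  if (!is.data.frame(plan) ||
      !all(c("duration", "T_EBF1", "T_ZNF521") %in% names(plan)))
    stop("plan must be a data.frame with duration, T_EBF1, T_ZNF521",
         call. = FALSE)
  if (any(plan$duration <= 0)) stop("durations must be positive", call. = FALSE)
  if (any(plan$T_EBF1 < 0) || any(plan$T_ZNF521 < 0))
    stop("input levels must be non-negative", call. = FALSE)

  att0 <- find_attractors(model, params, start_inputs, n_starts = n_starts,
                          seed = seed)
  if (is.character(start)) {
    if (!start %in% names(att0))
      stop("starting attractor '", start, "' not found at the baseline ",
           "inputs (available: ",
           paste(names(att0), collapse = ", "), ")", call. = FALSE)
    start_label <- start
    x <- att0[[start]]$state
  } else {
    x <- check_model_args(model, start, params, start_inputs)
    d0 <- vapply(att0, function(a) max(abs(a$state - x)), 0)
    if (length(d0) == 0 || min(d0) > 1e-3)
      stop("numeric start must lie on a computed attractor", call. = FALSE)
    start_label <- names(att0)[which.min(d0)]
    x <- stats::setNames(x, model$states)
  }

  times <- numeric(0); states <- NULL; t_off <- 0
  for (k in seq_len(nrow(plan))) {
    iv <- c(T_EBF1 = plan$T_EBF1[k], T_ZNF521 = plan$T_ZNF521[k])
    tr <- simulate_model(model, params, iv, pmax(x, 0),
                         t_end = plan$duration[k], n_points = n_points)
    times <- c(times, t_off + tr$times)
    states <- rbind(states, tr$states)
    x <- tr$final_state
    t_off <- t_off + plan$duration[k]
  }

  last_iv <- c(T_EBF1 = plan$T_EBF1[nrow(plan)],
               T_ZNF521 = plan$T_ZNF521[nrow(plan)])
  att1 <- find_attractors(model, params, last_iv, n_starts = n_starts,
                          seed = seed)
  if (length(att1) == 0) {
    final_label <- "unknown"
    dists <- numeric(0)
  } else {
    dists <- vapply(att1, function(a) max(abs(a$state - x)), 0)
    ord <- order(dists)
    final_label <- names(att1)[ord[1]]
    if (length(dists) >= 2 && dists[ord[2]] / max(dists[ord[1]], 1e-12) < 2)
      final_label <- "undecided"
  }
  structure(list(
    trajectory = list(times = times, states = states),
    start_label = start_label, final_label = final_label,
    final_state = x, distances = dists,
    reverted = identical(start_label, "proB") &&
      identical(final_label, "LMPP")),
    class = "bswitch_reprogram")
}

#' @export
print.bswitch_reprogram <- function(x, ...) {
  cat("<bswitch_reprogram> ", x$start_label, " -> ", x$final_label,
      if (isTRUE(x$reverted)) "  (reversion to multipotency)", "\n", sep = "")
  cat("  final state: ",
      paste(sprintf("%s=%.3g", names(x$final_state), x$final_state),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}
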