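# Model family for the B-lymphoid commitment network.
#
# Every equation in the family has the same shape: a saturating production
# term, which is a ratio of two multilinear forms in the state variables and
# the environmental inputs, minus first-order degradation,
#
#     dx_i/dt = N_i(x, T) / (1 + D_i(x, T)) - mu_i * x_i ,
#
# where N_i and D_i are sums of terms coef * v1 * v2 with coef a kinetic
# parameter and v1, v2 drawn from states and inputs (at most heterodimeric
# products; never a squared variable). Each model is therefore written down
# as a table of such terms, and one generic evaluator supplies the
# right-hand side and the analytic Jacobian for all models.

STATE_ORDER <- c("IKAROS", "GFI1", "PU1", "FLT3", "IL7R",
                 "E2A", "ZNF521", "EBF1", "PAX5", "CD19")
INPUT_NAMES <- c("T_EBF1", "T_ZNF521")

# one production term: coefficient symbol times up to two variables
tm <- function(coef, ...) list(coef = coef, vars = c(...))

# equation: state name, numerator terms, denominator terms (the implicit
# "+ 1" of the denominator is added by the evaluator), degradation symbol
eqn <- function(state, num, den, mu) list(state = state, num = num, den = den, mu = mu)

# --- equation building blocks shared between the full model and sub-modules ---

eq_ikaros <- function() eqn("IKAROS", list(tm("i0")), list(), "mu1")
eq_gfi1   <- function() eqn("GFI1",
  list(tm("h0"), tm("h1", "IKAROS")),
  list(tm("h1", "IKAROS")), "mu2")
eq_pu1    <- function() eqn("PU1",
  list(tm("g0"), tm("g1", "PU1")),
  list(tm("g1", "PU1"), tm("g2", "PU1", "GFI1")), "mu3")
eq_flt3_full <- function() eqn("FLT3",
  list(tm("e0"), tm("e1", "PU1"), tm("e2", "IKAROS"), tm("e3", "PU1", "IKAROS")),
  list(tm("e1", "PU1"), tm("e2", "IKAROS"), tm("e3", "PU1", "IKAROS"),
       tm("e4", "PAX5"), tm("e5", "PU1", "PAX5"), tm("e6", "IKAROS", "PAX5")), "mu4")
eq_il7r_full <- function() eqn("IL7R",
  list(tm("f0"), tm("f1", "FLT3"), tm("f2", "PU1"), tm("f3", "FLT3", "PU1")),
  list(tm("f1", "FLT3"), tm("f2", "PU1"), tm("f3", "FLT3", "PU1")), "mu5")
eq_e2a    <- function() eqn("E2A",
  list(tm("j0"), tm("j1", "EBF1")),
  list(tm("j1", "EBF1")), "mu6")
eq_pax5_full <- function() eqn("PAX5",
  list(tm("c0"), tm("c1", "EBF1"), tm("c2", "E2A"), tm("c3", "EBF1", "E2A")),
  list(tm("c1", "EBF1"), tm("c2", "E2A"), tm("c3", "EBF1", "E2A")), "mu9")
eq_cd19   <- function() eqn("CD19",
  list(tm("d0"), tm("d1", "PAX5")),
  list(tm("d1", "PAX5")), "mu10")

# ZNF521 equation of the full model; `extra_den` swaps in the repression term
# of the topology variants (nominal: heterodimeric EBF1:PAX5 repression b4)
eq_znf521_full <- function(extra_den = list(tm("b4", "EBF1", "PAX5"))) eqn("ZNF521",
  list(tm("b0"), tm("b1", "T_ZNF521"), tm("b2", "ZNF521")),
  c(list(tm("b1", "T_ZNF521"), tm("b2", "ZNF521"), tm("b3", "ZNF521", "EBF1")),
    extra_den), "mu7")

eq_ebf1_full <- function() eqn("EBF1",
  list(tm("a0"), tm("a1", "T_EBF1"), tm("a2", "EBF1"), tm("a3", "PAX5"),
       tm("a5", "IL7R"), tm("a6", "EBF1", "IL7R"), tm("a7", "PU1"),
       tm("a8", "PAX5", "PU1"), tm("a10", "E2A"), tm("a11", "E2A", "EBF1"),
       tm("a12", "E2A", "IL7R")),
  list(tm("a1", "T_EBF1"), tm("a2", "EBF1"), tm("a3", "PAX5"),
       tm("a4", "ZNF521"), tm("a5", "IL7R"), tm("a6", "EBF1", "IL7R"),
       tm("a7", "PU1"), tm("a8", "PAX5", "PU1"), tm("a9", "PU1", "ZNF521"),
       tm("a10", "E2A"), tm("a11", "E2A", "EBF1"), tm("a12", "E2A", "IL7R")),
  "mu8")

# reduced equations used by the sub-modules
eq_flt3_sub <- function() eqn("FLT3", list(tm("e0")), list(tm("e4", "PAX5")), "mu4")
eq_il7r_sub <- function() eqn("IL7R",
  list(tm("f0"), tm("f1", "FLT3")), list(tm("f1", "FLT3")), "mu5")
eq_pax5_sub <- function() eqn("PAX5",
  list(tm("c0"), tm("c1", "EBF1")), list(tm("c1", "EBF1")), "mu9")

model_definitions <- function() {
  full_eqs <- function(znf_extra = list(tm("b4", "EBF1", "PAX5"))) list(
    eq_ikaros(), eq_gfi1(), eq_pu1(), eq_flt3_full(), eq_il7r_full(),
    eq_e2a(), eq_znf521_full(znf_extra), eq_ebf1_full(), eq_pax5_full(),
    eq_cd19())

  list(
    # full ten-species network with the hypothesised PAX5 -| ZNF521 repression
    full_A = full_eqs(),
    # ablation: PAX5 -| ZNF521 removed (b4 term dropped)
    full_no_pax5_znf521 = full_eqs(znf_extra = list()),
    # variant B: ZNF521 repressed by a heterodimeric EBF1:E2A term instead of
    # EBF1:PAX5 (reconstruction; the repression strength reuses symbol b4)
    full_B = full_eqs(znf_extra = list(tm("b4", "EBF1", "E2A"))),
    # variant C: ZNF521 directly repressed by IKAROS (reconstruction;
    # strength reuses symbol b4)
    full_C = full_eqs(znf_extra = list(tm("b4", "IKAROS"))),

    # EBF1/ZNF521 mutual inhibition with autoregulation. The printed form of
    # the ZNF521 equation ends with degradation of EBF1; this is corrected
    # here to degradation of ZNF521 (an equation's degradation term must act
    # on its own state).
    ebf1_znf521 = list(
      eqn("ZNF521",
          list(tm("b0"), tm("b1", "T_ZNF521"), tm("b2", "ZNF521")),
          list(tm("b1", "T_ZNF521"), tm("b2", "ZNF521"), tm("b3", "ZNF521", "EBF1")),
          "mu7"),
      eqn("EBF1",
          list(tm("a0"), tm("a1", "T_EBF1"), tm("a2", "EBF1")),
          list(tm("a1", "T_EBF1"), tm("a2", "EBF1"), tm("a4", "EBF1", "ZNF521")),
          "mu8")),

    # EBF1/E2A/PAX5 positive feedback
    ebf1_e2a_pax5 = list(
      eq_e2a(),
      eqn("EBF1",
          list(tm("a0"), tm("a1", "T_EBF1"), tm("a2", "EBF1"),
               tm("a10", "E2A"), tm("a11", "E2A", "EBF1")),
          list(tm("a1", "T_EBF1"), tm("a2", "EBF1"),
               tm("a10", "E2A"), tm("a11", "E2A", "EBF1")),
          "mu8"),
      eq_pax5_full()),

    # EBF1/PAX5/FLT3/IL-7R negative feedback
    ebf1_pax5_flt3_il7r = list(
      eq_flt3_sub(), eq_il7r_sub(),
      eqn("EBF1",
          list(tm("a0"), tm("a1", "T_EBF1"), tm("a2", "EBF1"), tm("a3", "PAX5"),
               tm("a5", "IL7R"), tm("a6", "EBF1", "IL7R")),
          list(tm("a1", "T_EBF1"), tm("a2", "EBF1"), tm("a3", "PAX5"),
               tm("a5", "IL7R"), tm("a6", "EBF1", "IL7R")),
          "mu8"),
      eq_pax5_sub()),

    # EBF1/E2A/PAX5/FLT3/IL-7R combined feedback
    ebf1_e2a_pax5_flt3_il7r = list(
      eq_flt3_sub(), eq_il7r_sub(), eq_e2a(),
      eqn("EBF1",
          list(tm("a0"), tm("a1", "T_EBF1"), tm("a2", "EBF1"), tm("a3", "PAX5"),
               tm("a5", "IL7R"), tm("a6", "EBF1", "IL7R"), tm("a10", "E2A"),
               tm("a11", "E2A", "EBF1"), tm("a12", "E2A", "IL7R")),
          list(tm("a1", "T_EBF1"), tm("a2", "EBF1"), tm("a3", "PAX5"),
               tm("a5", "IL7R"), tm("a6", "EBF1", "IL7R"), tm("a10", "E2A"),
               tm("a11", "E2A", "EBF1"), tm("a12", "E2A", "IL7R")),
          "mu8"),
      eq_pax5_full()),

    # ZNF521/EBF1/PAX5/FLT3/IL-7R: mutual inhibition plus the FLT3/IL-7R
    # negative loop. The printed EBF1 production multiplies numerator and
    # bracketed denominator; it is implemented as the saturating ratio, like
    # every other equation. Here ZNF521 repression by EBF1 is the printed
    # plain b3*EBF1 (no ZNF521 factor).
    znf521_ebf1_pax5_flt3_il7r = list(
      eq_flt3_sub(), eq_il7r_sub(),
      eqn("ZNF521",
          list(tm("b0"), tm("b1", "T_ZNF521"), tm("b2", "ZNF521")),
          list(tm("b1", "T_ZNF521"), tm("b2", "ZNF521"), tm("b3", "EBF1")),
          "mu7"),
      eqn("EBF1",
          list(tm("a0"), tm("a1", "T_EBF1"), tm("a2", "EBF1"), tm("a3", "PAX5"),
               tm("a5", "IL7R"), tm("a6", "EBF1", "IL7R")),
          list(tm("a1", "T_EBF1"), tm("a2", "EBF1"), tm("a3", "PAX5"),
               tm("a4", "EBF1", "ZNF521"), tm("a5", "IL7R"), tm("a6", "EBF1", "IL7R")),
          "mu8"),
      eq_pax5_sub()),

    # ZNF521/EBF1/E2A/PAX5: mutual inhibition plus the E2A/PAX5 loop
    znf521_ebf1_e2a_pax5 = list(
      eq_e2a(),
      eqn("ZNF521",
          list(tm("b0"), tm("b1", "T_ZNF521"), tm("b2", "ZNF521")),
          list(tm("b1", "T_ZNF521"), tm("b2", "ZNF521"), tm("b3", "EBF1")),
          "mu7"),
      eqn("EBF1",
          list(tm("a0"), tm("a1", "T_EBF1"), tm("a2", "EBF1"), tm("a3", "PAX5"),
               tm("a10", "E2A"), tm("a11", "EBF1", "E2A")),
          list(tm("a1", "T_EBF1"), tm("a2", "EBF1"), tm("a3", "PAX5"),
               tm("a4", "EBF1", "ZNF521"), tm("a10", "E2A"), tm("a11", "EBF1", "E2A")),
          "mu8"),
      eq_pax5_full()),

    # EBF1/PAX5/ZNF521: the mutual inhibition enriched by the PAX5-mediated
    # second feedback loop (the module that makes the switch irreversible)
    ebf1_pax5_znf521 = list(
      eqn("ZNF521",
          list(tm("b0"), tm("b1", "T_ZNF521"), tm("b2", "ZNF521")),
          list(tm("b1", "T_ZNF521"), tm("b2", "ZNF521"), tm("b3", "EBF1"),
               tm("b4", "EBF1", "PAX5")),
          "mu7"),
      eqn("EBF1",
          list(tm("a0"), tm("a1", "T_EBF1"), tm("a2", "EBF1"), tm("a3", "PAX5")),
          list(tm("a1", "T_EBF1"), tm("a2", "EBF1"), tm("a3", "PAX5"),
               tm("a4", "EBF1", "ZNF521")),
          "mu8"),
      eq_pax5_sub())
  )
}

# compile an equation list into index tables for fast evaluation
compile_model <- function(id, eqs) {
  states <- vapply(eqs, `[[`, "", "state")
  ord <- order(match(states, STATE_ORDER))
  eqs <- eqs[ord]
  states <- states[ord]
  n <- length(states)
  vars <- c(states, INPUT_NAMES)
  syms <- param_symbols()

  flat <- function(which) {
    rows <- list()
    for (i in seq_len(n)) {
      for (t in eqs[[i]][[which]]) {
        v <- match(t$vars, vars)
        if (anyNA(v)) stop("unknown variable in model ", id, ": ",
                           paste(t$vars, collapse = ","))
        rows[[length(rows) + 1L]] <-
          c(i, match(t$coef, syms), if (length(v) >= 1) v[1] else 0L,
            if (length(v) >= 2) v[2] else 0L)
      }
    }
    if (length(rows) == 0) matrix(integer(0), ncol = 4)
    else do.call(rbind, rows)
  }
  num <- flat("num")
  den <- flat("den")
  mu_idx <- match(vapply(eqs, `[[`, "", "mu"), syms)
  coef_syms <- unique(syms[c(num[, 2], den[, 2], mu_idx)])
  used_inputs <- INPUT_NAMES[match(INPUT_NAMES, vars) %in% c(num[, 3], num[, 4], den[, 3], den[, 4])]
  basal <- syms[num[num[, 3] == 0L & num[, 4] == 0L, 2]]

  # precomputed evaluation structures. The combined value vector is
  # c(states, inputs, 1): variable index 0 (absent factor) maps to the
  # trailing constant 1, so term values are plain indexed products.
  sent <- n + length(INPUT_NAMES) + 1L
  map0 <- function(ix) ifelse(ix == 0L, sent, ix)
  assembly <- function(tab) {
    k <- nrow(tab)
    A <- matrix(0, n, k)
    if (k > 0) A[cbind(tab[, 1], seq_len(k))] <- 1
    A
  }
  # Jacobian assembly: one row per (term, state-slot) pair; contribution of
  # coef * other-factor lands at flat position (j - 1) * n + i of the n x n
  # derivative matrix of the multilinear form
  jparts <- function(tab) {
    li <- integer(0); coef <- integer(0); oth <- integer(0)
    if (nrow(tab) > 0) for (r in seq_len(nrow(tab))) {
      i <- tab[r, 1]; ci <- tab[r, 2]; v1 <- tab[r, 3]; v2 <- tab[r, 4]
      if (v1 > 0L && v1 <= n) {
        li <- c(li, (v1 - 1L) * n + i); coef <- c(coef, ci)
        oth <- c(oth, map0(v2))
      }
      if (v2 > 0L && v2 <= n) {
        li <- c(li, (v2 - 1L) * n + i); coef <- c(coef, ci)
        oth <- c(oth, map0(v1))
      }
    }
    m <- length(li)
    Asm <- matrix(0, n * n, m)
    if (m > 0) Asm[cbind(li, seq_len(m))] <- 1
    list(A = Asm, coef = coef, oth = oth)
  }

  structure(list(
    id = id, states = states, n = n, inputs = used_inputs,
    parameters = syms[sort(match(coef_syms, syms))],
    num = num, den = den, mu_idx = mu_idx, basal = basal,
    sent = sent,
    num_coef = num[, 2], num_v1 = map0(num[, 3]), num_v2 = map0(num[, 4]),
    den_coef = den[, 2], den_v1 = map0(den[, 3]), den_v2 = map0(den[, 4]),
    Anum = assembly(num), Aden = assembly(den),
    jnum = jparts(num), jden = jparts(den),
    eqs = eqs), class = "bswitch_model")
}

.model_cache <- new.env(parent = emptyenv())

#' List the model catalogue
#'
#' @return Character vector of the identifiers of all eleven models: the full
#'   ten-species network (`full_A`), its PAX5--ZNF521 ablation
#'   (`full_no_pax5_znf521`), the alternative-topology variants (`full_B`,
#'   `full_C`) and the seven core feedback sub-modules.
#' @export
list_models <- function() {
  names(model_definitions())
}

#' Retrieve a compiled model specification
#'
#' @param id Model identifier, one of [list_models()].
#' @return An object of class `bswitch_model` with elements `id`, `states`
#'   (ordered state names), `inputs` (which environmental inputs the model
#'   uses), and `parameters` (the kinetic symbols its equations require).
#' @export
model_spec <- function(id) {
  if (!is.character(id) || length(id) != 1)
    stop("model id must be a single string", call. = FALSE)
  if (!exists(id, envir = .model_cache, inherits = FALSE)) {
    defs <- model_definitions()
    if (!id %in% names(defs))
      stop("unknown model id: ", id, " (see list_models())", call. = FALSE)
    assign(id, compile_model(id, defs[[id]]), envir = .model_cache)
  }
  get(id, envir = .model_cache, inherits = FALSE)
}

#' @export
print.bswitch_model <- function(x, ...) {
  cat("<bswitch_model> ", x$id, "\n", sep = "")
  cat("  states (", x$n, "): ", paste(x$states, collapse = ", "), "\n", sep = "")
  cat("  inputs: ", if (length(x$inputs)) paste(x$inputs, collapse = ", ") else "none",
      "\n", sep = "")
  cat("  parameters (", length(x$parameters), "): ",
      paste(x$parameters, collapse = ", "), "\n", sep = "")
  invisible(x)
}

as_model <- function(model) {
  if (inherits(model, "bswitch_model")) model else model_spec(model)
}

check_model_args <- function(model, state, params, inputs) {
  if (length(state) != model$n)
    stop("state has length ", length(state), " but model '", model$id,
         "' has ", model$n, " states", call. = FALSE)
  if (!is.null(names(state)) && all(nzchar(names(state))) &&
      !identical(names(state), model$states)) {
    if (!setequal(names(state), model$states))
      stop("state names do not match model states", call. = FALSE)
    state <- state[model$states]
  }
  missing <- setdiff(model$parameters, names(params))
  if (length(missing) > 0)
    stop("missing parameter(s) for model '", model$id, "': ",
         paste(missing, collapse = ", "), call. = FALSE)
  as.numeric(state)
}

inputs_vec <- function(inputs) {
  v <- c(T_EBF1 = 0, T_ZNF521 = 0)
  if (length(inputs) > 0) {
    inputs <- unlist(inputs)
    unknown <- setdiff(names(inputs), INPUT_NAMES)
    if (is.null(names(inputs)) || length(unknown) > 0)
      stop("inputs must be named among: ", paste(INPUT_NAMES, collapse = ", "),
           call. = FALSE)
    v[names(inputs)] <- as.numeric(inputs)
  }
  v
}

# full-length parameter lookup vector (unvalidated access path kept internal)
params_full <- function(params) {
  p <- rep(NA_real_, length(param_symbols()))
  names(p) <- param_symbols()
  p[names(params)] <- as.numeric(params)
  p
}

#' Right-hand side of a model
#'
#' Evaluates the time derivative dx/dt of the chosen network model: each
#' state's saturating production ratio minus its first-order degradation.
#'
#' @param model Model identifier or a [model_spec()] object.
#' @param state Numeric state vector in the model's state order (names, if
#'   present, are checked).
#' @param params A [parameter_set()] (or any named vector covering the
#'   model's required symbols).
#' @param inputs Named numeric vector of environmental inputs (`T_EBF1`,
#'   `T_ZNF521`); missing inputs default to 0.
#' @return Named numeric vector dx/dt in model state order.
#' @export
model_rhs <- function(model, state, params, inputs = c(T_EBF1 = 0, T_ZNF521 = 0)) {
  model <- as_model(model)
  s <- check_model_args(model, state, params, inputs)
  p <- params_full(params)
  v <- c(s, inputs_vec(inputs))
  stats::setNames(rhs_eval(model, v, p), model$states)
}

# core evaluator on the combined (state, input) value vector
rhs_eval <- function(model, v, p) {
  n <- model$n
  ve <- c(v, 1)
  N <- drop(model$Anum %*% (p[model$num_coef] * ve[model$num_v1] * ve[model$num_v2]))
  D <- 1 + drop(model$Aden %*% (p[model$den_coef] * ve[model$den_v1] * ve[model$den_v2]))
  N / D - p[model$mu_idx] * v[seq_len(n)]
}

#' Analytic Jacobian of a model right-hand side
#'
#' Entry (i, j) is the partial derivative of dx_i/dt with respect to x_j.
#' Because every production term is a ratio of multilinear forms, the
#' Jacobian is assembled exactly from the term tables (quotient rule); no
#' numerical differentiation is involved.
#'
#' @inheritParams model_rhs
#' @return An n x n numeric matrix with dimnames equal to the model states.
#' @export
model_jacobian <- function(model, state, params, inputs = c(T_EBF1 = 0, T_ZNF521 = 0)) {
  model <- as_model(model)
  s <- check_model_args(model, state, params, inputs)
  p <- params_full(params)
  v <- c(s, inputs_vec(inputs))
  jac_eval(model, v, p)
}

jac_eval <- function(model, v, p) {
  n <- model$n
  ve <- c(v, 1)
  N <- drop(model$Anum %*% (p[model$num_coef] * ve[model$num_v1] * ve[model$num_v2]))
  D <- 1 + drop(model$Aden %*% (p[model$den_coef] * ve[model$den_v1] * ve[model$den_v2]))
  dN <- matrix(drop(model$jnum$A %*% (p[model$jnum$coef] * ve[model$jnum$oth])), n, n)
  dD <- matrix(drop(model$jden$A %*% (p[model$jden$coef] * ve[model$jden$oth])), n, n)
  J <- (dN * D - N * dD) / D^2
  diag(J) <- diag(J) - p[model$mu_idx]
  dimnames(J) <- list(model$states, model$states)
  J
}

# partial derivative of the rhs w.r.t. a single parameter symbol or
# environmental input, used by continuation (free-parameter column of the
# extended Jacobian). Exact: coefficients enter the multilinear forms
# linearly and inputs are just extra variables.
model_dp <- function(model, state, params, inputs, free_param) {
  model <- as_model(model)
  s <- check_model_args(model, state, params, inputs)
  p <- params_full(params)
  v <- c(s, inputs_vec(inputs))
  dp_eval(model, v, p, free_param)
}

dp_eval <- function(model, v, p, free_param) {
  n <- model$n
  ve <- c(v, 1)
  tvn <- p[model$num_coef] * ve[model$num_v1] * ve[model$num_v2]
  tvd <- p[model$den_coef] * ve[model$den_v1] * ve[model$den_v2]
  N <- drop(model$Anum %*% tvn)
  D <- 1 + drop(model$Aden %*% tvd)

  if (free_param %in% INPUT_NAMES) {
    vi <- n + match(free_param, INPUT_NAMES)
    dtab <- function(A, coef, v1, v2) {
      contr <- numeric(length(coef))
      hit1 <- v1 == vi; hit2 <- v2 == vi
      contr[hit1] <- p[coef[hit1]] * ve[v2[hit1]]
      contr[hit2] <- contr[hit2] + p[coef[hit2]] * ve[v1[hit2]]
      drop(A %*% contr)
    }
    dN <- dtab(model$Anum, model$num_coef, model$num_v1, model$num_v2)
    dD <- dtab(model$Aden, model$den_coef, model$den_v1, model$den_v2)
    return((dN * D - N * dD) / D^2)
  }

  ci <- match(free_param, param_symbols())
  if (is.na(ci)) stop("unknown free parameter: ", free_param, call. = FALSE)
  mono <- function(A, coef, v1, v2) {
    hit <- coef == ci
    contr <- numeric(length(coef))
    contr[hit] <- ve[v1[hit]] * ve[v2[hit]]
    drop(A %*% contr)
  }
  dN <- mono(model$Anum, model$num_coef, model$num_v1, model$num_v2)
  dD <- mono(model$Aden, model$den_coef, model$den_v1, model$den_v2)
  out <- (dN * D - N * dD) / D^2
  mu_hit <- model$mu_idx == ci
  if (any(mu_hit)) out[mu_hit] <- out[mu_hit] - v[seq_len(n)][mu_hit]
  out
}

#' Invariant-box upper bounds for the model states
#'
#' Every production ratio N/(1+D) in the family is bounded above by
#' max(basal, 1) because each non-basal numerator term also appears in the
#' denominator; a state produced at constant rate is bounded by that rate.
#' Each state is therefore eventually confined to `[0, bound/mu]`, which is
#' used to size equilibrium search boxes.
#'
#' @inheritParams model_rhs
#' @return Named numeric vector of per-state upper bounds.
#' @export
model_state_bounds <- function(model, params) {
  model <- as_model(model)
  p <- params_full(params)
  basal_val <- vapply(seq_len(model$n), function(i) {
    rows <- model$num[model$num[, 1] == i & model$num[, 3] == 0L, , drop = FALSE]
    if (nrow(rows) == 0) 0 else sum(p[rows[, 2]])
  }, 0)
  has_den <- vapply(seq_len(model$n), function(i) any(model$den[, 1] == i), NA)
  prod_max <- ifelse(has_den, pmax(basal_val, 1), basal_val)
  stats::setNames(prod_max / p[model$mu_idx], model$states)
}
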