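#' Canonical kinetic-parameter symbols
#'
#' The model family shares a single fixed symbol set: basal production rates
#' (`a0`, `b0`, `c0`, `d0`, `e0`, `f0`, `g0`, `h0`, `i0`, `j0`), interaction
#' strengths (the remaining `a`--`j` symbols) and first-order degradation
#' rates `mu1`..`mu10`. Kinetic constants are in units of 1/s; interaction
#' strengths and Michaelis--Menten-like constants are dimensionless.
#'
#' @return Character vector of all 53 parameter symbols, in canonical order.
#' @export
param_symbols <- function() {
  c(paste0("a", 0:12),
    paste0("b", 0:4),
    paste0("c", 0:3),
    paste0("d", 0:1),
    paste0("e", 0:6),
    paste0("f", 0:3),
    paste0("g", 0:2),
    paste0("h", 0:1),
    "i0",
    paste0("j", 0:1),
    paste0("mu", 1:10))
}

#' Construct and validate a kinetic parameter set
#'
#' A parameter set is a complete named numeric vector over [param_symbols()].
#' All values must be finite and non-negative, and every degradation rate
#' `mu1`..`mu10` must be strictly positive.
#'
#' @param values Named numeric vector or list covering every symbol in
#'   [param_symbols()]. No defaults are filled in: missing symbols are an
#'   error, as are unknown ones.
#' @return A named numeric vector of class `bswitch_params`, in canonical
#'   symbol order.
#' @export
parameter_set <- function(values) {
  values <- unlist(values)
  if (is.null(names(values)) || any(!nzchar(names(values))))
    stop("parameter values must be named", call. = FALSE)
  syms <- param_symbols()
  unknown <- setdiff(names(values), syms)
  if (length(unknown) > 0)
    stop("unknown parameter symbol(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(names(values)))
    stop("duplicated parameter symbol(s): ",
         paste(unique(names(values)[duplicated(names(values))]), collapse = ", "),
         call. = FALSE)
  missing <- setdiff(syms, names(values))
  if (length(missing) > 0)
    stop("missing parameter symbol(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  values <- values[syms]
  storage.mode(values) <- "double"
  bad <- !is.finite(values) | values < 0
  if (any(bad))
    stop("non-finite or negative parameter value(s): ",
         paste(syms[bad], collapse = ", "), call. = FALSE)
  mus <- grepl("^mu", syms)
  if (any(values[mus] <= 0))
    stop("degradation rate(s) must be strictly positive: ",
         paste(syms[mus][values[mus] <= 0], collapse = ", "), call. = FALSE)
  structure(values, class = "bswitch_params")
}

#' Read a kinetic parameter file
#'
#' The on-disk format is one `symbol = value` assignment per line; blank
#' lines and `#` comments are ignored. Symbols are case sensitive
#' (`mu1`..`mu10` for the degradation rates). The file must be complete:
#' every symbol in [param_symbols()] must be assigned exactly once.
#'
#' @param path Path to a flat text parameter file.
#' @return A validated [parameter_set()].
#' @seealso [write_parameter_file()]
#' @export
read_parameter_file <- function(path) {
  if (!file.exists(path))
    stop("parameter file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  parts <- regmatches(lines, regexec("^([A-Za-z][A-Za-z0-9_.]*)\\s*=\\s*(\\S+)$", lines))
  bad <- vapply(parts, length, 1L) != 3L
  if (any(bad))
    stop("unparseable line(s) in ", path, ": ",
         paste(shQuote(lines[bad]), collapse = ", "), call. = FALSE)
  nm <- vapply(parts, `[`, "", 2L)
  val <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 3L)))
  if (anyNA(val))
    stop("non-numeric value(s) for: ", paste(nm[is.na(val)], collapse = ", "),
         call. = FALSE)
  parameter_set(stats::setNames(val, nm))
}

#' Write a kinetic parameter file
#'
#' Writes the flat `symbol = value` format read by [read_parameter_file()].
#' Values are written with 17 significant digits so that a write/read
#' round trip is exact.
#'
#' @param params A [parameter_set()].
#' @param path Output path.
#' @param header Optional character vector of comment lines (written with a
#'   leading `#`).
#' @return `path`, invisibly.
#' @export
write_parameter_file <- function(params, path, header = NULL) {
  params <- parameter_set(params)
  lines <- character(0)
  if (!is.null(header)) lines <- paste0("# ", header)
  lines <- c(lines, sprintf("%s = %.17g", names(params), as.numeric(params)))
  writeLines(lines, path)
  invisible(path)
}

#' Nominal kinetic parameter set
#'
#' The package's reference point in parameter space: a complete kinetic
#' parameter set for which the full ten-species network behaves as an
#' irreversible bistable commitment switch with the canonical LMPP and
#' pro-B expression programs (FLT3/ZNF521 high in the multipotent attractor,
#' EBF1/PAX5/CD19 high in the committed one). The set is synthetic: it was
#' discovered with the package's own bifurcation-search tooling
#' ([search_bistable_parameters()]) under those qualitative constraints and
#' frozen into `inst/extdata/params_synthetic_nominal.txt`.
#'
#' @return A validated [parameter_set()].
#' @export
nominal_parameters <- function() {
  path <- system.file("extdata", "params_synthetic_nominal.txt",
                      package = "bswitch", mustWork = TRUE)
  read_parameter_file(path)
}
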