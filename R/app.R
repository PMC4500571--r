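# Configuration-driven runner binding the analysis stages into
# reproducible runs with TSV artifacts and a machine-readable manifest.

#' Validate a run configuration
#'
#' Checks a configuration (a named list, or a path to a YAML file holding
#' one) against the requirements of a subcommand without executing
#' anything. Problems are returned as data, not raised.
#'
#' @param config Named list or YAML file path. Common fields: `model`,
#'   `params` (parameter-file path), `tebf1`, `tznf521`, `out`
#'   (output directory), `seed`; subcommand-specific fields as documented
#'   in [run_analysis()].
#' @param subcommand The subcommand the configuration is for.
#' @return Character vector of problems (length 0 when valid).
#' @export
validate_config <- function(config, subcommand = "diagram") {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) return(paste("config file not found:", config))
    if (!requireNamespace("yaml", quietly = TRUE))
      return("yaml package required to read config files")
    config <- yaml::read_yaml(config)
  }
  problems <- character(0)
  note <- function(...) problems <<- c(problems, paste0(...))

  known <- c("simulate", "equilibria", "diagram", "classify", "sweep",
             "search", "screen", "ladder", "reprogram", "compare", "fixtures")
  if (!subcommand %in% known)
    note("unknown subcommand: ", subcommand)

  if (!is.null(config$model) && !config$model %in% list_models())
    note("unknown model: ", config$model)
  if (!is.null(config$params)) {
    if (!file.exists(config$params)) {
      note("parameter file not found: ", config$params)
    } else {
      ps <- tryCatch(read_parameter_file(config$params),
                     error = function(e) conditionMessage(e))
      if (is.character(ps)) note("parameter file invalid: ", ps)
    }
  } else if (!subcommand %in% c("fixtures", "compare")) {
    note("missing 'params' (parameter file path)")
  }
  for (f in c("tebf1", "tznf521")) {
    if (!is.null(config[[f]]) &&
        (!is.numeric(config[[f]]) || config[[f]] < 0))
      note("'", f, "' must be a non-negative number")
  }
  stochastic <- c("equilibria", "diagram", "classify", "sweep", "search",
                  "screen", "ladder", "reprogram", "fixtures")
  if (subcommand %in% stochastic && is.null(config$seed))
    note("missing 'seed' for stochastic subcommand '", subcommand, "'")
  if (subcommand == "sweep" && is.null(config$param))
    note("missing 'param' (symbol to sweep)")
  if (subcommand == "search" && is.null(config$ranges))
    note("missing 'ranges' for search")
  if (subcommand == "reprogram" && is.null(config$plan))
    note("missing 'plan' (schedule file or table) for reprogram")
  if (subcommand == "compare" && is.null(config$expression))
    note("missing 'expression' (expression TSV path) for compare")
  problems
}

#' Run an analysis subcommand
#'
#' Executes one stage of the pipeline from a validated configuration and
#' writes its TSV artifacts plus a `manifest.txt` (configuration echo,
#' seed, package version, wall time) into the output directory.
#'
#' Subcommands: `simulate` (trajectory TSV), `equilibria` (equilibrium set
#' TSV), `diagram` (branches/folds/summary TSVs), `classify` (summary TSV
#' only), `sweep` (single-parameter bistability interval TSV), `search`
#' (GA hits TSV), `screen` (variant screen TSV), `ladder` (sub-module
#' ladder TSV), `reprogram` (trajectory + outcome TSVs), `compare`
#' (concordance TSV), `fixtures` (expression fixture + DE table TSVs).
#'
#' @inheritParams validate_config
#' @return Invisibly, a list with `status` (0 ok, 1 invalid configuration,
#'   2 computation failure), `artifacts` (paths written) and `result` (the
#'   main in-memory result object).
#' @export
run_analysis <- function(subcommand, config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  problems <- validate_config(config, subcommand)
  if (length(problems) > 0) {
    message("invalid configuration:\n  - ", paste(problems, collapse = "\n  - "))
    return(invisible(list(status = 1L, artifacts = character(0),
                          result = NULL)))
  }
  out_dir <- config$out %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  model <- config$model %||% "full_A"
  seed <- config$seed %||% 1L
  inputs <- c(T_EBF1 = config$tebf1 %||% 0, T_ZNF521 = config$tznf521 %||% 0)
  params <- if (!is.null(config$params)) read_parameter_file(config$params)

  artifacts <- character(0)
  art <- function(p) artifacts <<- c(artifacts, p)
  result <- tryCatch({
    switch(subcommand,
      simulate = {
        x0 <- as.numeric(config$x0 %||% rep(0.1, model_spec(model)$n))
        tr <- simulate_model(model, params, inputs, x0,
                             t_end = config$t_end %||% 2000,
                             n_points = config$n_points %||% 200)
        art(write_trajectory_tsv(tr, file.path(out_dir, "trajectory.tsv")))
        tr
      },
      equilibria = {
        eqs <- find_equilibria(model, params, inputs,
                               n_starts = config$n_starts %||% 200,
                               seed = seed)
        art(write_equilibria_tsv(eqs, file.path(out_dir, "equilibria.tsv")))
        eqs
      },
      diagram = ,
      classify = {
        rng <- as.numeric(config$range %||% c(-2, 3))
        d <- build_diagram(model, params, inputs,
                           free_param = config$free_param %||% "T_EBF1",
                           range = rng, n_starts = config$n_starts %||% 40,
                           seed = seed)
        if (subcommand == "diagram")
          for (p in write_diagram_tsv(d, file.path(out_dir, "diagram"))) art(p)
        else {
          cls <- classify_switch(d)
          utils::write.table(
            data.frame(model = model, classification = cls$classification),
            file.path(out_dir, "classification.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
          art(file.path(out_dir, "classification.tsv"))
        }
        d
      },
      sweep = {
        iv <- bistability_interval(model, params, inputs,
                                   param = config$param, seed = seed)
        tab <- sensitivity_table(model, params, inputs, config$param,
                                 seed = seed)
        art(write_sensitivity_tsv(tab, file.path(out_dir, "sweep.tsv")))
        iv
      },
      search = {
        sr <- search_bistable_parameters(
          model, params, ranges = config$ranges, inputs = inputs,
          objective = config$objective %||% "bistable",
          population = config$population %||% 24,
          generations = config$generations %||% 10, seed = seed)
        hits <- data.frame(
          hit = seq_along(sr$hits),
          classification = vapply(sr$hits, `[[`, "", "classification"))
        utils::write.table(hits, file.path(out_dir, "search_hits.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        art(file.path(out_dir, "search_hits.tsv"))
        for (i in seq_along(sr$hits))
          art(write_parameter_file(sr$hits[[i]]$params,
                                   file.path(out_dir,
                                             sprintf("hit_%02d_params.txt", i))))
        sr
      },
      screen = {
        sc <- screen_variants(params, inputs = inputs, seed = seed)
        utils::write.table(sc, file.path(out_dir, "screen.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        art(file.path(out_dir, "screen.tsv"))
        sc
      },
      ladder = {
        ld <- submodule_ladder(params, inputs = inputs, seed = seed)
        utils::write.table(ld, file.path(out_dir, "ladder.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        art(file.path(out_dir, "ladder.tsv"))
        ld
      },
      reprogram = {
        plan <- config$plan
        if (is.character(plan)) plan <- utils::read.delim(plan)
        rp <- reprogram(model, params, plan,
                        start = config$start %||% "proB", seed = seed)
        utils::write.table(
          data.frame(time = rp$trajectory$times, rp$trajectory$states),
          file.path(out_dir, "reprogram_trajectory.tsv"),
          sep = "\t", quote = FALSE, row.names = FALSE)
        art(file.path(out_dir, "reprogram_trajectory.tsv"))
        utils::write.table(
          data.frame(start = rp$start_label, final = rp$final_label,
                     reverted = rp$reverted),
          file.path(out_dir, "reprogram_outcome.tsv"),
          sep = "\t", quote = FALSE, row.names = FALSE)
        art(file.path(out_dir, "reprogram_outcome.tsv"))
        rp
      },
      compare = {
        data_tab <- read_expression_tsv(config$expression)
        att <- find_attractors("full_A",
                               params %||% nominal_parameters(),
                               seed = seed)
        cc <- concordance(attractor_table(att), data_tab)
        utils::write.table(cc$per_factor,
                           file.path(out_dir, "concordance.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        art(file.path(out_dir, "concordance.tsv"))
        cc
      },
      fixtures = {
        fx <- make_expression_fixture(default_fixture_spec(), seed = seed)
        art(write_expression_tsv(fx, file.path(out_dir, "expression_fixture.tsv")))
        de <- make_de_table(n = config$n_genes %||% 1000,
                            n_planted = config$n_planted %||% 100,
                            seed = seed)
        utils::write.table(de, file.path(out_dir, "de_table.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        art(file.path(out_dir, "de_table.tsv"))
        fx
      })
  }, error = function(e) e)

  if (inherits(result, "error")) {
    message("computation failed: ", conditionMessage(result))
    status <- 2L
  } else status <- 0L

  manifest <- c(
    paste0("subcommand: ", subcommand),
    paste0("package: bswitch ",
           tryCatch(as.character(utils::packageVersion("bswitch")),
                    error = function(e) "dev")),
    paste0("seed: ", seed),
    paste0("status: ", status),
    paste0("wall_time_s: ",
           sprintf("%.2f", as.numeric(difftime(Sys.time(), t0, units = "secs")))),
    "config:",
    paste0("  ", names(config), ": ",
           vapply(config, function(x) paste(format(x), collapse = " "), "")))
  writeLines(manifest, file.path(out_dir, "manifest.txt"))

  invisible(list(status = status, artifacts = artifacts,
                 result = if (status == 0L) result else NULL))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
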