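# Attractor/expression comparison: per-factor max normalization, direction
# concordance, and the generic fold-change/p-value differential filter.

#' Per-factor maximum normalization of a two-condition expression table
#'
#' Divides each factor's values by that factor's maximum across conditions,
#' so every row lies in [0, 1] and reaches 1 in its higher condition. This
#' is the normalization used when comparing computed attractors with
#' measured two-condition profiles (each condition normalized with respect
#' to the given maximum). All-zero factors are left at zero with a warning.
#'
#' @param table Data frame or matrix: rows = factors (rownames = gene
#'   symbols), columns = conditions, non-negative values.
#' @return Normalized table of the same shape.
#' @export
normalize_max <- function(table) {
  m <- as.matrix(table)
  if (any(m < 0, na.rm = TRUE))
    stop("expression values must be non-negative", call. = FALSE)
  mx <- apply(m, 1, max)
  zero <- mx <= 0
  if (any(zero)) {
    warning("all-zero factor(s) left unnormalized: ",
            paste(rownames(m)[zero], collapse = ", "))
    mx[zero] <- 1
  }
  out <- sweep(m, 1, mx, `/`)
  if (is.data.frame(table)) out <- as.data.frame(out)
  out
}

# per-factor cross-condition direction after max-normalization:
# +1 up in the first condition, -1 up in the second, 0 flat
expression_direction <- function(table, flat_tol = 0.1) {
  nm <- normalize_max(table)
  d <- nm[, 1] - nm[, 2]
  ifelse(abs(d) < flat_tol, 0L, ifelse(d > 0, 1L, -1L))
}

#' Direction concordance between model attractors and expression data
#'
#' Compares, factor by factor, the cross-condition direction (up in the
#' first condition / up in the second / flat) of the model's two attractors
#' against a measured (or synthetic) two-condition expression table, after
#' [normalize_max()] on both. Factors whose normalized difference is below
#' `flat_tol` in either table are called flat and excluded from the
#' concordance denominator (only factors whose expression varies by a
#' significant amount are scored).
#'
#' @param model_table Two-column table of model attractor levels (rows =
#'   factors, columns = conditions, e.g. LMPP and proB).
#' @param data_table Two-column expression table with matching condition
#'   order.
#' @param factor_map Optional named character vector mapping model factor
#'   names to data row names (`c(model_name = "data_name", ...)`); by
#'   default shared rownames are compared.
#' @param flat_tol Normalized-difference threshold below which a factor is
#'   flat.
#' @return List of class `bswitch_concordance`: `per_factor` (data frame
#'   with model and data directions and match flags), `n_scored`,
#'   `n_matched`, `fraction`.
#' @export
concordance <- function(model_table, data_table, factor_map = NULL,
                        flat_tol = 0.1) {
  mt <- as.matrix(model_table); dt <- as.matrix(data_table)
  if (ncol(mt) != 2 || ncol(dt) != 2)
    stop("both tables must have exactly two condition columns", call. = FALSE)
  if (is.null(factor_map)) {
    shared <- intersect(rownames(mt), rownames(dt))
    factor_map <- stats::setNames(shared, shared)
  }
  if (length(factor_map) == 0)
    stop("no shared factors between model and data tables", call. = FALSE)
  miss <- !(names(factor_map) %in% rownames(mt)) | !(factor_map %in% rownames(dt))
  if (any(miss))
    stop("factor(s) not present in both tables: ",
         paste(names(factor_map)[miss], collapse = ", "), call. = FALSE)
  mdir <- expression_direction(mt[names(factor_map), , drop = FALSE], flat_tol)
  ddir <- expression_direction(dt[factor_map, , drop = FALSE], flat_tol)
  scored <- mdir != 0L & ddir != 0L
  match <- mdir == ddir
  per <- data.frame(factor = names(factor_map),
                    model_direction = mdir, data_direction = ddir,
                    scored = scored, match = match & scored)
  n_scored <- sum(scored)
  n_matched <- sum(per$match)
  structure(list(per_factor = per, n_scored = n_scored,
                 n_matched = n_matched,
                 fraction = if (n_scored > 0) n_matched / n_scored else NA_real_),
            class = "bswitch_concordance")
}

#' @export
print.bswitch_concordance <- function(x, ...) {
  cat("<bswitch_concordance> ", x$n_matched, "/", x$n_scored,
      " directions agree (fraction ",
      if (is.na(x$fraction)) "NA" else sprintf("%.3f", x$fraction),
      ")\n", sep = "")
  invisible(x)
}

#' Differential-expression filter (linear fold change and p-value)
#'
#' Keeps rows with `|linear fold change| >= 2` and `p < 0.05` (the standard
#' transcriptome-console filter criteria) and partitions the kept rows by
#' fold-change sign into up- and down-regulated sets.
#'
#' @param table Data frame with columns `gene`, `fold_change_linear`,
#'   `p_value`.
#' @param fc_cutoff Linear fold-change magnitude cutoff.
#' @param p_cutoff p-value cutoff (strict inequality).
#' @return List of class `bswitch_de`: `kept` (filtered data frame),
#'   `n_up`, `n_down`, `up`, `down` (gene vectors).
#' @export
de_filter <- function(table, fc_cutoff = 2, p_cutoff = 0.05) {
  need <- c("fold_change_linear", "p_value")
  if (!all(need %in% names(table)))
    stop("table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  keep <- abs(table$fold_change_linear) >= fc_cutoff &
    table$p_value < p_cutoff
  kept <- table[keep, , drop = FALSE]
  up <- kept[kept$fold_change_linear > 0, , drop = FALSE]
  down <- kept[kept$fold_change_linear < 0, , drop = FALSE]
  gene_of <- function(d) if ("gene" %in% names(d)) d$gene else rownames(d)
  structure(list(kept = kept, n_up = nrow(up), n_down = nrow(down),
                 up = gene_of(up), down = gene_of(down)),
            class = "bswitch_de")
}

#' @export
print.bswitch_de <- function(x, ...) {
  cat("<bswitch_de> ", nrow(x$kept), " rows pass (", x$n_up, " up, ",
      x$n_down, " down)\n", sep = "")
  invisible(x)
}

#' Attractor levels as a two-condition expression table
#'
#' Convenience bridge from [find_attractors()] to the comparison
#' operations: rows = factors, columns = the attractor labels.
#'
#' @param attractors Result of [find_attractors()] containing `LMPP` and
#'   `proB` entries.
#' @return Data frame with columns `LMPP` and `proB`.
#' @export
attractor_table <- function(attractors) {
  if (!all(c("LMPP", "proB") %in% names(attractors)))
    stop("attractors must contain LMPP and proB entries", call. = FALSE)
  data.frame(LMPP = attractors$LMPP$state, proB = attractors$proB$state,
             row.names = names(attractors$LMPP$state))
}

#' Read / write two-condition expression tables as TSV
#'
#' The on-disk dialect is TSV with a `factor` column followed by one column
#' per condition.
#'
#' @param path File path.
#' @return `read_expression_tsv`: data frame with factor rownames;
#'   `write_expression_tsv`: `path`, invisibly.
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  if (!"factor" %in% names(df))
    stop("expression TSV must have a 'factor' column", call. = FALSE)
  rn <- df$factor
  df$factor <- NULL
  rownames(df) <- rn
  df
}

#' @param table Expression table (rows = factors).
#' @rdname read_expression_tsv
#' @export
write_expression_tsv <- function(table, path) {
  df <- data.frame(factor = rownames(table), as.data.frame(table),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
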