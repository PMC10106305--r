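# Derivation of analysis variables from raw item-level tables, and
# complete-case filtering.  Composites are aggregated (sum or mean) before any
# transform; the natural log is used where a log transform is requested.

#' Define a derived analysis variable
#'
#' @param name Output column name.
#' @param items Character vector of source item columns (at least one).
#' @param agg Aggregation across items: `"sum"` (scale-composite convention)
#'   or `"mean"`.
#' @param transform `"none"` or `"log"` (natural log; inputs must be strictly
#'   positive).
#' @param standardize Z-standardize (mean 0, SD 1 over non-missing rows) after
#'   aggregation and transform.
#' @return A `variable_def` object.
#' @export
variable_def <- function(name, items, agg = c("sum", "mean"),
                         transform = c("none", "log"), standardize = FALSE) {
  agg <- match.arg(agg)
  transform <- match.arg(transform)
  items <- as.character(items)
  if (length(items) < 1L) {
    rlang::abort("`items` must name at least one source column.",
                 class = "causalpaths_bad_vardef")
  }
  structure(list(name = name, items = items, agg = agg,
                 transform = transform, standardize = standardize),
            class = c("variable_def", "list"))
}

#' Derive analysis variables from a raw table
#'
#' Applies, per definition: aggregation across the source items (row-wise sum
#' or mean), then the optional natural-log transform, then optional
#' z-standardization.  Rows with a missing source item propagate `NA` (handled
#' later by [complete_case_filter()]).
#'
#' @param raw_table Data frame of item-level columns.
#' @param defs List of [variable_def()]s.
#' @return A tibble with one column per definition, rows aligned with
#'   `raw_table`.
#' @examples
#' raw <- data.frame(q13 = c(4, 2), q14 = c(5, 3), q15 = c(6, 1))
#' defs <- list(variable_def("Mot_BL", c("q13", "q14", "q15"), agg = "sum"))
#' derive_variables(raw, defs)
#' @export
derive_variables <- function(raw_table, defs) {
  raw_table <- tibble::as_tibble(raw_table)
  if (inherits(defs, "variable_def")) defs <- list(defs)
  out <- list()
  for (d in defs) {
    miss <- setdiff(d$items, names(raw_table))
    if (length(miss)) {
      rlang::abort(paste0("Missing source column(s) for `", d$name, "`: ",
                          paste(miss, collapse = ", ")),
                   class = "causalpaths_missing_column")
    }
    m <- as.matrix(raw_table[, d$items, drop = FALSE])
    v <- if (d$agg == "sum") rowSums(m) else rowMeans(m)
    if (d$transform == "log") {
      if (any(v <= 0, na.rm = TRUE)) {
        rlang::abort(paste0("Non-positive value under log transform for `", d$name, "`."),
                     class = "causalpaths_bad_log")
      }
      v <- log(v)
    }
    if (isTRUE(d$standardize)) {
      v <- as.numeric(scale(v))
    }
    out[[d$name]] <- v
  }
  tibble::as_tibble(out)
}

#' Complete-case filter
#'
#' Removes every row with a missing value in any analysis column, preserving
#' the order of retained rows, and reports how many rows were excluded.
#'
#' @param table Data frame.
#' @param analysis_columns Columns to require complete (default: all).
#' @return A list with `data` (the filtered tibble) and `n_excluded`.
#' @export
complete_case_filter <- function(table, analysis_columns = names(table)) {
  table <- tibble::as_tibble(table)
  miss <- setdiff(analysis_columns, names(table))
  if (length(miss)) {
    rlang::abort(paste0("Unknown analysis column(s): ", paste(miss, collapse = ", ")),
                 class = "causalpaths_missing_column")
  }
  keep <- stats::complete.cases(table[, analysis_columns, drop = FALSE])
  list(data = table[keep, , drop = FALSE], n_excluded = sum(!keep))
}
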