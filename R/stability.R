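# Graph stability by resampling: re-run the full discovery pipeline on
# jackknifed (a fraction of rows, without replacement) or bootstrapped (n rows
# with replacement) datasets and tally, per graph feature, the percentage of
# replicate graphs agreeing with the reference PAG.

#' Resampling parameters
#'
#' @param mode `"jackknife"` (draw `floor(frac * n)` rows without replacement)
#'   or `"bootstrap"` (draw `n` rows with replacement).
#' @param reps Number of replicates (reference analysis used 1000).
#' @param frac Jackknife subsample fraction (reference: 0.9).
#' @param seed Master seed; per-replicate seeds are derived by counter so the
#'   result does not depend on execution order.
#' @return A `stability_params` object.
#' @export
stability_params <- function(mode = c("jackknife", "bootstrap"), reps = 1000,
                             frac = 0.9, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(reps >= 1, frac > 0, frac <= 1)
  structure(list(mode = mode, reps = as.integer(reps), frac = frac,
                 seed = as.integer(seed)),
            class = c("stability_params", "list"))
}

#' Edge concordance between a reference PAG and replicate graphs
#'
#' Features per node pair: `presence` — fraction of replicates containing a
#' reference adjacency; `absence` — fraction lacking a reference-absent
#' adjacency; `orientation` — fraction whose edge matches both endpoint marks
#' exactly (strict); `orientation_lenient` — adjacency-only agreement for
#' reference edges.
#'
#' @param reference A `mixed_graph`.
#' @param replicates List of `mixed_graph`s over the same node set.
#' @param feature One of `"presence"`, `"absence"`, `"orientation"`,
#'   `"orientation_lenient"`, or `"all"`.
#' @return A tibble: `from`, `to`, `feature`, `percent`, `n_reps`.
#' @export
edge_concordance <- function(reference, replicates,
                             feature = c("all", "presence", "absence",
                                         "orientation", "orientation_lenient")) {
  feature <- match.arg(feature)
  nodes <- reference$nodes
  for (g in replicates) {
    if (!identical(g$nodes, nodes)) {
      rlang::abort("Replicate graphs must share the reference node set.",
                   class = "causalpaths_bad_graph")
    }
  }
  R <- length(replicates)
  p <- length(nodes)
  rows <- list()
  add <- function(i, j, feat, pct) {
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      from = nodes[i], to = nodes[j], feature = feat,
      percent = pct, n_reps = R)
  }
  for (i in seq_len(p - 1L)) {
    for (j in seq(i + 1L, p)) {
      present_ref <- reference$M[i, j] != MARK_NONE
      pres <- vapply(replicates, function(g) g$M[i, j] != MARK_NONE, logical(1))
      if (present_ref) {
        if (feature %in% c("all", "presence")) {
          add(i, j, "presence", 100 * mean(pres))
        }
        if (feature %in% c("all", "orientation")) {
          same <- vapply(replicates, function(g) {
            g$M[i, j] == reference$M[i, j] && g$M[j, i] == reference$M[j, i]
          }, logical(1))
          add(i, j, "orientation", 100 * mean(same))
        }
        if (feature %in% c("all", "orientation_lenient")) {
          add(i, j, "orientation_lenient", 100 * mean(pres))
        }
      } else if (feature %in% c("all", "absence")) {
        add(i, j, "absence", 100 * mean(!pres))
      }
    }
  }
  if (!length(rows)) {
    return(tibble::tibble(from = character(), to = character(),
                          feature = character(), percent = double(),
                          n_reps = integer()))
  }
  dplyr::bind_rows(rows)
}

#' Stability of a discovered PAG under resampling
#'
#' Re-runs [gfci()] on `reps` resampled datasets with identical parameters and
#' knowledge, and tallies per-feature agreement with the reference PAG.
#' Replicate failures are logged and excluded from the denominator.
#'
#' @param data The analysis data frame.
#' @param params An [analysis_params()].
#' @param k A [knowledge()] object.
#' @param sp A [stability_params()].
#' @param reference The reference PAG (default: `gfci()` on the full data).
#' @return A `stability_report`: list with `table` (per-feature tibble),
#'   `summary` (per-feature aggregate percentages), `reps_used`, `failures`,
#'   `params`.
#' @export
resample_stability <- function(data, params = analysis_params(), k = knowledge(),
                               sp = stability_params(), reference = NULL) {
  data <- tibble::as_tibble(data)
  n <- nrow(data)
  if (is.null(reference)) reference <- gfci(data, params, k)
  m <- if (sp$mode == "jackknife") floor(sp$frac * n) else n
  replicates <- list()
  failures <- 0L
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  for (r in seq_len(sp$reps)) {
    set.seed((sp$seed + r) %% 2147483647L)
    idx <- if (sp$mode == "jackknife") sample.int(n, m, replace = FALSE)
           else sample.int(n, n, replace = TRUE)
    g <- tryCatch(gfci(data[idx, , drop = FALSE], params, k),
                  error = function(e) NULL)
    if (is.null(g)) failures <- failures + 1L else replicates[[length(replicates) + 1L]] <- g
  }
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  tab <- edge_concordance(reference, replicates, "all")
  summ <- dplyr::summarise(dplyr::group_by(tab, .data$feature),
                           percent = mean(.data$percent), .groups = "drop")
  structure(list(table = tab, summary = summ, reference = reference,
                 reps_used = length(replicates), failures = failures,
                 params = sp),
            class = c("stability_report", "list"))
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("<stability_report> %s, %d replicates used (%d failed)\n",
              x$params$mode, x$reps_used, x$failures))
  print(x$summary)
  invisible(x)
}

#' @rdname resample_stability
#' @param x A `stability_report`.
#' @param ... Unused.
#' @method tidy stability_report
#' @export
tidy.stability_report <- function(x, ...) x$table

#' @rdname resample_stability
#' @method glance stability_report
#' @export
glance.stability_report <- function(x, ...) {
  out <- tidyr::pivot_wider(x$summary, names_from = "feature", values_from = "percent")
  dplyr::bind_cols(out, tibble::tibble(reps_used = x$reps_used, failures = x$failures))
}
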