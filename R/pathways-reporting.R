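# Reporting artifacts: causal pathways into an outcome node, the
# cross-timepoint ("rolled") causal cycles, and graph file I/O.

#' Causal pathways into an outcome
#'
#' Enumerates all simple paths composed solely of fully directed edges
#' (tail -> arrow) ending at `outcome`, longest first.  Paths through edges
#' with a circle endpoint are not licensed as causal; they are listed
#' separately as possible-causal paths when `include_possible = TRUE`
#' (traversing o-> edges in the direction of the arrowhead).
#'
#' @param pag A `mixed_graph`.
#' @param outcome Outcome node name.
#' @param include_possible Also enumerate possible-causal paths.
#' @return A tibble: `path` (list of node vectors), `length`, `label`,
#'   `status` (`"causal"` or `"possible"`).
#' @export
causal_paths_to <- function(pag, outcome, include_possible = FALSE) {
  o <- node_index(pag, outcome)
  M <- pag$M
  p <- nrow(M)
  enumerate <- function(pred) {
    acc <- list()
    walk <- function(path) {
      head_ <- path[1L]
      ext <- FALSE
      for (x in seq_len(p)) {
        if (x %in% path) next
        if (pred(x, head_)) {
          ext <- TRUE
          walk(c(x, path))
        }
      }
      if (length(path) > 1L) acc[[length(acc) + 1L]] <<- path
      invisible()
    }
    walk(o)
    acc
  }
  directed_in <- function(x, y) mg_is_directed(M, x, y)
  paths <- enumerate(directed_in)
  out <- path_tibble(paths, pag$nodes, "causal")
  if (include_possible) {
    possible_in <- function(x, y) M[x, y] == MARK_ARROW && M[y, x] != MARK_ARROW
    allp <- enumerate(possible_in)
    lbl <- vapply(allp, function(pp) paste(pag$nodes[pp], collapse = " -> "), character(1))
    keep <- !(lbl %in% out$label)
    out <- dplyr::bind_rows(out, path_tibble(allp[keep], pag$nodes, "possible"))
  }
  dplyr::arrange(out, dplyr::desc(.data$length), .data$label)
}

path_tibble <- function(paths, nodes, status) {
  if (!length(paths)) {
    return(tibble::tibble(path = list(), length = integer(),
                          label = character(), status = character()))
  }
  tibble::tibble(
    path = lapply(paths, function(pp) nodes[pp]),
    length = vapply(paths, length, integer(1)) - 1L,
    label = vapply(paths, function(pp) paste(nodes[pp], collapse = " -> "), character(1)),
    status = status)
}

#' Cross-timepoint causal cycles (augmented rolled graph)
#'
#' For every matched variable pair (A, B) measured at baseline and at
#' follow-up, reports a rolled cycle when the PAG contains a fully directed
#' baseline edge A_BL -> B_BL and a fully directed follow-up edge
#' B_6M -> A_6M: the effect runs A -> B at baseline and feeds back B -> A over
#' the follow-up window.  Each constituent edge is annotated with its raw
#' effect size when a fitted SEM is supplied.
#'
#' @param pag A `mixed_graph`.
#' @param pairs Data frame mapping concepts to node names: columns `concept`,
#'   `baseline`, `followup`.
#' @param es Optional `sem_fit` whose path estimates annotate the cycles.
#' @return A tibble: `var_a`, `var_b`, `baseline_edge`, `baseline_es`,
#'   `followup_edge`, `followup_es`, `cycle`.
#' @export
rolled_graph <- function(pag, pairs, es = NULL) {
  pairs <- tibble::as_tibble(as.data.frame(pairs))
  stopifnot(all(c("concept", "baseline", "followup") %in% names(pairs)))
  lookup_es <- function(from, to) {
    if (is.null(es)) return(NA_real_)
    e <- es$estimates
    hit <- e$op == "path" & e$from == from & e$to == to
    if (any(hit)) e$estimate[which(hit)[1L]] else NA_real_
  }
  M <- pag$M
  directed <- function(a, b) {
    ia <- match(a, pag$nodes); ib <- match(b, pag$nodes)
    !is.na(ia) && !is.na(ib) && mg_is_directed(M, ia, ib)
  }
  out <- list()
  for (i in seq_len(nrow(pairs))) {
    for (j in seq_len(nrow(pairs))) {
      if (i == j) next
      A <- pairs[i, ]; B <- pairs[j, ]
      if (directed(A$baseline, B$baseline) && directed(B$followup, A$followup)) {
        out[[length(out) + 1L]] <- tibble::tibble(
          var_a = A$concept, var_b = B$concept,
          baseline_edge = paste(A$baseline, "->", B$baseline),
          baseline_es = lookup_es(A$baseline, B$baseline),
          followup_edge = paste(B$followup, "->", A$followup),
          followup_es = lookup_es(B$followup, A$followup),
          cycle = paste0(A$concept, " -> ", B$concept, " (baseline); ",
                         B$concept, " -> ", A$concept, " (+6M)"))
      }
    }
  }
  if (!length(out)) {
    return(tibble::tibble(var_a = character(), var_b = character(),
                          baseline_edge = character(), baseline_es = double(),
                          followup_edge = character(), followup_es = double(),
                          cycle = character()))
  }
  dplyr::bind_rows(out)
}

# --- graph file I/O ----------------------------------------------------------

#' Write a mixed graph to a file
#'
#' The edge-list text format round-trips losslessly: a `nodes:` declaration
#' line followed by one `X --> Y` / `X o-> Y` / `X o-o Y` / `X <-> Y` line per
#' edge.  GraphML and DOT are export-only, with endpoint marks as edge
#' attributes (DOT colours fully directed edges differently from
#' circle/bidirected edges).
#'
#' @param g A `mixed_graph`.
#' @param path Output file.
#' @param format `"edges"`, `"graphml"` or `"dot"`.
#' @return `path`, invisibly.
#' @export
write_graph <- function(g, path, format = c("edges", "graphml", "dot")) {
  format <- match.arg(format)
  ed <- tidy(g)
  lines <- switch(
    format,
    edges = c(paste("nodes:", paste(g$nodes, collapse = " ")),
              if (nrow(ed)) paste(ed$from, ed$type, ed$to)),
    graphml = graphml_lines(g, ed),
    dot = dot_lines(g, ed))
  writeLines(lines, path)
  invisible(path)
}

graphml_lines <- function(g, ed) {
  esc <- function(x) gsub("&", "&amp;", gsub("<", "&lt;", gsub(">", "&gt;", x)))
  c('<?xml version="1.0" encoding="UTF-8"?>',
    '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
    '  <key id="end_from" for="edge" attr.name="end_from" attr.type="string"/>',
    '  <key id="end_to" for="edge" attr.name="end_to" attr.type="string"/>',
    '  <graph edgedefault="undirected">',
    sprintf('    <node id="%s"/>', esc(g$nodes)),
    if (nrow(ed)) sprintf(
      '    <edge source="%s" target="%s"><data key="end_from">%s</data><data key="end_to">%s</data></edge>',
      esc(ed$from), esc(ed$to), ed$end_from, ed$end_to),
    "  </graph>", "</graphml>")
}

dot_lines <- function(g, ed) {
  arrow_of <- function(mark) switch(mark, arrow = "normal", circle = "odot", tail = "none")
  body <- if (nrow(ed)) {
    vapply(seq_len(nrow(ed)), function(i) {
      col <- if (ed$type[i] == "-->") "forestgreen" else "steelblue"
      sprintf('  "%s" -> "%s" [dir=both, arrowtail=%s, arrowhead=%s, color=%s];',
              ed$from[i], ed$to[i], arrow_of(ed$end_from[i]),
              arrow_of(ed$end_to[i]), col)
    }, character(1))
  } else character(0)
  c("digraph pag {", sprintf('  "%s";', g$nodes), body, "}")
}

#' Read a mixed graph from the edge-list format
#'
#' @param path File written by [write_graph()] with `format = "edges"`.
#' @return A `mixed_graph`.
#' @export
read_graph <- function(path) {
  lines <- readLines(path)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  idx <- which(keep)
  if (!length(idx) || !startsWith(trimws(lines[idx[1L]]), "nodes:")) {
    rlang::abort("Expected a `nodes:` declaration on the first non-comment line.",
                 class = "causalpaths_parse_error")
  }
  nodes <- strsplit(trimws(sub("^\\s*nodes:", "", lines[idx[1L]])), "[[:space:],]+")[[1L]]
  nodes <- nodes[nzchar(nodes)]
  g <- mixed_graph(nodes)
  for (li in idx[-1L]) {
    toks <- strsplit(trimws(lines[li]), "\\s+")[[1L]]
    ok <- length(toks) == 3L && toks[2L] %in% .edge_type_all$type
    if (!ok) {
      rlang::abort(sprintf("Malformed edge on line %d: `%s`", li, trimws(lines[li])),
                   class = "causalpaths_parse_error")
    }
    g <- tryCatch(add_edge(g, toks[1L], toks[3L], toks[2L]),
                  error = function(e) {
                    rlang::abort(sprintf("Bad edge on line %d: %s", li, conditionMessage(e)),
                                 class = "causalpaths_parse_error")
                  })
  }
  g
}
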