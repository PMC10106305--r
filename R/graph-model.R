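# Mixed graphs with per-end endpoint marks (tail / arrow / circle).
#
# A single structure represents DAGs, CPDAGs and PAGs.  Internally a graph is
# an integer matrix M with M[i, j] = the mark at node j's end of the edge
# between i and j (0 = no edge).  An edge exists iff both M[i, j] and M[j, i]
# are non-zero.  Named edge types ("-->", "o->", "o-o", "<->", "---", "--o")
# are derived views over the two endpoint marks.

MARK_NONE   <- 0L
MARK_CIRCLE <- 1L
MARK_ARROW  <- 2L
MARK_TAIL   <- 3L

mark_label <- function(m) c("none", "circle", "arrow", "tail")[m + 1L]

# canonical (end_from, end_to) -> display token
.edge_type_tab <- data.frame(
  type     = c("-->", "o->", "o-o", "<->", "---", "--o"),
  end_from = c(MARK_TAIL, MARK_CIRCLE, MARK_CIRCLE, MARK_ARROW, MARK_TAIL, MARK_TAIL),
  end_to   = c(MARK_ARROW, MARK_ARROW, MARK_CIRCLE, MARK_ARROW, MARK_TAIL, MARK_CIRCLE),
  stringsAsFactors = FALSE
)

# all tokens accepted on input (reversed spellings map to swapped marks)
.edge_type_all <- rbind(
  .edge_type_tab,
  data.frame(type = c("<--", "<-o", "o--"),
             end_from = c(MARK_ARROW, MARK_ARROW, MARK_CIRCLE),
             end_to   = c(MARK_TAIL, MARK_CIRCLE, MARK_TAIL),
             stringsAsFactors = FALSE)
)

edge_type_marks <- function(type) {
  i <- match(type, .edge_type_all$type)
  if (is.na(i)) {
    rlang::abort(paste0("Unknown edge type `", type, "`."), class = "causalpaths_bad_edge_type")
  }
  c(.edge_type_all$end_from[i], .edge_type_all$end_to[i])
}

marks_to_type <- function(end_from, end_to) {
  i <- which(.edge_type_tab$end_from == end_from & .edge_type_tab$end_to == end_to)
  if (length(i) == 1L) {
    list(type = .edge_type_tab$type[i], flipped = FALSE)
  } else {
    j <- which(.edge_type_tab$end_from == end_to & .edge_type_tab$end_to == end_from)
    list(type = .edge_type_tab$type[j[1L]], flipped = TRUE)
  }
}

new_mixed_graph <- function(nodes, M = NULL, subclass = character()) {
  p <- length(nodes)
  if (is.null(M)) {
    M <- matrix(MARK_NONE, p, p, dimnames = list(nodes, nodes))
  } else {
    # keep only structural attributes so graph equality is well defined
    M <- matrix(as.integer(M), p, p, dimnames = list(nodes, nodes))
  }
  structure(list(nodes = nodes, M = M),
            class = c(subclass, "mixed_graph", "list"))
}

#' Create a mixed graph
#'
#' A mixed graph stores, for every edge, one endpoint mark per end: `tail`,
#' `arrow` or `circle`.  Fully directed edges (`X --> Y`), partially directed
#' edges (`X o-> Y`), nondirected edges (`X o-o Y`), bidirected edges
#' (`X <-> Y`) and undirected edges (`X --- Y`) are all views over these marks,
#' so the same structure represents DAGs, CPDAGs and partial ancestral graphs
#' (PAGs).  Node order is fixed at construction and used for all deterministic
#' iteration and tie-breaking.
#'
#' @param nodes Character vector of unique variable names.
#' @param edges Optional data frame with columns `from`, `to` and `type`
#'   (one of `"-->"`, `"o->"`, `"o-o"`, `"<->"`, `"---"`, `"--o"` or a
#'   reversed spelling).
#' @return A `mixed_graph` object.
#' @examples
#' g <- mixed_graph(c("X", "Y", "Z"),
#'                  edges = data.frame(from = "X", to = "Y", type = "-->"))
#' tidy(g)
#' @export
mixed_graph <- function(nodes, edges = NULL) {
  nodes <- as.character(nodes)
  if (length(nodes) < 1L || anyDuplicated(nodes) || any(!nzchar(nodes))) {
    rlang::abort("`nodes` must be a non-empty vector of unique, non-empty names.",
                 class = "causalpaths_bad_nodes")
  }
  g <- new_mixed_graph(nodes)
  if (!is.null(edges) && nrow(as.data.frame(edges)) > 0L) {
    edges <- as.data.frame(edges)
    for (i in seq_len(nrow(edges))) {
      g <- add_edge(g, edges$from[i], edges$to[i],
                    if ("type" %in% names(edges)) edges$type[i] else "-->")
    }
  }
  g
}

node_index <- function(g, x) {
  i <- match(x, g$nodes)
  if (anyNA(i)) {
    rlang::abort(paste0("Unknown node(s): ", paste(x[is.na(i)], collapse = ", ")),
                 class = "causalpaths_unknown_node")
  }
  i
}

#' Add an edge to a mixed graph
#'
#' @param g A [mixed_graph()].
#' @param from,to Node names.
#' @param type Edge type token; see [mixed_graph()].
#' @return The modified graph.
#' @export
add_edge <- function(g, from, to, type = "-->") {
  i <- node_index(g, from)
  j <- node_index(g, to)
  if (i == j) {
    rlang::abort("Self-loops are not allowed.", class = "causalpaths_self_loop")
  }
  mk <- edge_type_marks(type)
  g$M[j, i] <- mk[1L]  # mark at `from` end
  g$M[i, j] <- mk[2L]  # mark at `to` end
  g
}

#' Look up the edge between two nodes
#'
#' Marks are reported relative to the query order: `end_from` is the mark at
#' `a`'s end, `end_to` at `b`'s end, so `edge_between(g, a, b)` and
#' `edge_between(g, b, a)` describe the same edge with swapped marks.
#'
#' @param graph A [mixed_graph()].
#' @param a,b Node names.
#' @return A one-row tibble (`from`, `to`, `end_from`, `end_to`, `type`) or
#'   `NULL` when the nodes are not adjacent.
#' @export
edge_between <- function(graph, a, b) {
  i <- node_index(graph, a)
  j <- node_index(graph, b)
  if (i == j) rlang::abort("`a` and `b` must differ.", class = "causalpaths_self_loop")
  if (graph$M[i, j] == MARK_NONE) return(NULL)
  ef <- graph$M[j, i]
  et <- graph$M[i, j]
  tt <- marks_to_type(ef, et)
  tibble::tibble(from = a, to = b,
                 end_from = mark_label(ef), end_to = mark_label(et),
                 type = if (tt$flipped) marks_to_type(et, ef)$type else tt$type)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a mixed graph into an edge tibble
#'
#' One row per edge.  Asymmetric edge types are displayed with the tail or
#' circle end first (`X --> Y`, never `Y <-- X`); symmetric types keep node
#' order.
#'
#' @param x A [mixed_graph()].
#' @param ... Unused.
#' @return A tibble with columns `from`, `to`, `end_from`, `end_to`, `type`.
#' @method tidy mixed_graph
#' @export
tidy.mixed_graph <- function(x, ...) {
  p <- length(x$nodes)
  out <- list()
  for (i in seq_len(p)) {
    for (j in seq_len(p)) {
      if (j <= i || x$M[i, j] == MARK_NONE) next
      ef <- x$M[j, i]; et <- x$M[i, j]
      tt <- marks_to_type(ef, et)
      if (tt$flipped) {
        out[[length(out) + 1L]] <- list(from = x$nodes[j], to = x$nodes[i],
                                        end_from = mark_label(et), end_to = mark_label(ef),
                                        type = tt$type)
      } else {
        out[[length(out) + 1L]] <- list(from = x$nodes[i], to = x$nodes[j],
                                        end_from = mark_label(ef), end_to = mark_label(et),
                                        type = tt$type)
      }
    }
  }
  if (length(out) == 0L) {
    return(tibble::tibble(from = character(), to = character(),
                          end_from = character(), end_to = character(),
                          type = character()))
  }
  dplyr::bind_rows(out)
}

#' @export
print.mixed_graph <- function(x, ...) {
  ed <- tidy(x)
  cat(sprintf("<mixed_graph> %d nodes, %d edges\n", length(x$nodes), nrow(ed)))
  cat("nodes:", paste(x$nodes, collapse = ", "), "\n")
  if (nrow(ed) > 0L) {
    apply(ed, 1L, function(r) cat(" ", r[["from"]], r[["type"]], r[["to"]], "\n"))
  }
  invisible(x)
}

#' @export
format.mixed_graph <- function(x, ...) {
  ed <- tidy(x)
  c(sprintf("%d nodes, %d edges", length(x$nodes), nrow(ed)),
    if (nrow(ed)) paste(ed$from, ed$type, ed$to))
}

n_edges <- function(g) sum(g$M != MARK_NONE) / 2L

# --- fast internal predicates (index based) ----------------------------------

mg_adjacent <- function(M, i, j) M[i, j] != MARK_NONE
mg_adj <- function(M, i) which(M[i, ] != MARK_NONE)
mg_parents <- function(M, y) which(M[, y] == MARK_ARROW & M[y, ] == MARK_TAIL)
mg_children <- function(M, x) which(M[x, ] == MARK_ARROW & M[, x] == MARK_TAIL)
mg_neighbors <- function(M, y) which(M[, y] == MARK_TAIL & M[y, ] == MARK_TAIL)
mg_is_directed <- function(M, i, j) M[i, j] == MARK_ARROW && M[j, i] == MARK_TAIL
mg_is_undirected <- function(M, i, j) M[i, j] == MARK_TAIL && M[j, i] == MARK_TAIL

# skeleton clique check
mg_is_clique <- function(M, idx) {
  if (length(idx) <= 1L) return(TRUE)
  for (a in seq_along(idx)) {
    for (b in seq_along(idx)) {
      if (a < b && M[idx[a], idx[b]] == MARK_NONE) return(FALSE)
    }
  }
  TRUE
}

# directed cycle check over the fully directed part
mg_has_directed_cycle <- function(M) {
  p <- nrow(M)
  A <- (M == MARK_ARROW) & (t(M) == MARK_TAIL)  # A[i, j]: i -> j
  indeg <- colSums(A)
  active <- rep(TRUE, p)
  repeat {
    src <- which(active & indeg == 0)
    if (length(src) == 0L) break
    for (s in src) {
      indeg[A[s, ]] <- indeg[A[s, ]] - 1L
      active[s] <- FALSE
    }
  }
  any(active)
}

# --- background knowledge ----------------------------------------------------

#' Temporal and structural background knowledge
#'
#' Knowledge constrains the search in two ways: *tiers* give a temporal
#' ordering (a variable in a later tier may never cause a variable in an
#' earlier tier — e.g. 6-month measures cannot cause baseline measures), and
#' *forbidden causes* are explicit ordered pairs `X` may-not-cause `Y` (e.g.
#' nothing may cause age).  Untiered variables are unconstrained by tiers.
#'
#' @param tiers List of character vectors, earlier tiers first.  A variable may
#'   appear in at most one tier.
#' @param forbidden Optional data frame with columns `from`, `to`: `from` may
#'   not cause `to`.
#' @return A `causal_knowledge` object.
#' @examples
#' k <- knowledge(tiers = list(c("Mot_BL", "SF_BL"), c("Mot_6M", "SF_6M")))
#' knowledge_forbids(k, "Mot_6M", "Mot_BL")
#' @export
knowledge <- function(tiers = list(), forbidden = NULL) {
  tiers <- lapply(tiers, as.character)
  all_tiered <- unlist(tiers)
  if (anyDuplicated(all_tiered)) {
    rlang::abort("A variable may appear in only one tier.",
                 class = "causalpaths_bad_knowledge")
  }
  if (is.null(forbidden)) {
    forbidden <- tibble::tibble(from = character(), to = character())
  } else {
    forbidden <- tibble::as_tibble(as.data.frame(forbidden))[, c("from", "to")]
    forbidden$from <- as.character(forbidden$from)
    forbidden$to <- as.character(forbidden$to)
  }
  structure(list(tiers = tiers, forbidden = forbidden),
            class = c("causal_knowledge", "list"))
}

#' @export
print.causal_knowledge <- function(x, ...) {
  cat("<causal_knowledge>\n")
  for (i in seq_along(x$tiers)) {
    cat(sprintf("  tier %d: %s\n", i, paste(x$tiers[[i]], collapse = ", ")))
  }
  if (nrow(x$forbidden)) {
    cat(sprintf("  %d forbidden cause pair(s)\n", nrow(x$forbidden)))
  }
  invisible(x)
}

#' Forbid every listed variable from causing an effect
#'
#' Convenience for constraints such as "no variable may cause age": adds one
#' forbidden pair per candidate cause.
#'
#' @param k A [knowledge()] object.
#' @param effect The variable that may not be caused.
#' @param causes Character vector of variables to forbid as causes (typically
#'   all other analysis variables).
#' @return The updated knowledge object.
#' @export
forbid_all_causes <- function(k, effect, causes) {
  causes <- setdiff(as.character(causes), effect)
  k$forbidden <- dplyr::distinct(dplyr::bind_rows(
    k$forbidden, tibble::tibble(from = causes, to = effect)))
  k
}

tier_of <- function(k, v) {
  for (i in seq_along(k$tiers)) if (v %in% k$tiers[[i]]) return(i)
  NA_integer_
}

#' Does knowledge forbid a causal direction?
#'
#' True iff `cause` sits in a strictly later tier than `effect`, or the ordered
#' pair is explicitly forbidden.  Untiered variables are unconstrained by
#' tiers.
#'
#' @param k A [knowledge()] object.
#' @param cause,effect Variable names.
#' @return Logical scalar.
#' @export
knowledge_forbids <- function(k, cause, effect) {
  tc <- tier_of(k, cause)
  te <- tier_of(k, effect)
  if (!is.na(tc) && !is.na(te) && tc > te) return(TRUE)
  if (nrow(k$forbidden) &&
      any(k$forbidden$from == cause & k$forbidden$to == effect)) {
    return(TRUE)
  }
  FALSE
}

# matrix of forbidden orientations for a node set: F[i, j] TRUE iff i may not cause j
knowledge_matrix <- function(k, nodes) {
  p <- length(nodes)
  F <- matrix(FALSE, p, p, dimnames = list(nodes, nodes))
  tiers <- vapply(nodes, function(v) tier_of(k, v), integer(1))
  for (i in seq_len(p)) {
    for (j in seq_len(p)) {
      if (i == j) next
      if (!is.na(tiers[i]) && !is.na(tiers[j]) && tiers[i] > tiers[j]) F[i, j] <- TRUE
    }
  }
  if (nrow(k$forbidden)) {
    for (r in seq_len(nrow(k$forbidden))) {
      i <- match(k$forbidden$from[r], nodes)
      j <- match(k$forbidden$to[r], nodes)
      if (!is.na(i) && !is.na(j)) F[i, j] <- TRUE
    }
  }
  F
}

#' Validate a PAG against endpoint and knowledge constraints
#'
#' Checks that the endpoint matrix is structurally sound (marks legal and
#' paired, no self-loops) and that no fully directed edge `X --> Y` asserts a
#' knowledge-forbidden cause.  Violations are returned, not raised; a graph
#' emitted by the search functions always validates cleanly.
#'
#' @param graph A [mixed_graph()].
#' @param k A [knowledge()] object.
#' @return A tibble of violations (zero rows when the graph is valid) with
#'   columns `from`, `to`, `problem`.
#' @export
validate_pag <- function(graph, k = knowledge()) {
  M <- graph$M
  nodes <- graph$nodes
  bad <- list()
  if (any(diag(M) != MARK_NONE)) {
    for (i in which(diag(M) != MARK_NONE)) {
      bad[[length(bad) + 1L]] <- list(from = nodes[i], to = nodes[i],
                                      problem = "self-loop")
    }
  }
  if (!all(M %in% c(MARK_NONE, MARK_CIRCLE, MARK_ARROW, MARK_TAIL))) {
    bad[[length(bad) + 1L]] <- list(from = NA_character_, to = NA_character_,
                                    problem = "illegal endpoint mark")
  }
  p <- length(nodes)
  for (i in seq_len(p)) {
    for (j in seq_len(p)) {
      if (i == j) next
      if ((M[i, j] == MARK_NONE) != (M[j, i] == MARK_NONE)) {
        bad[[length(bad) + 1L]] <- list(from = nodes[i], to = nodes[j],
                                        problem = "half-specified edge")
      }
      if (mg_is_directed(M, i, j) && knowledge_forbids(k, nodes[i], nodes[j])) {
        bad[[length(bad) + 1L]] <- list(from = nodes[i], to = nodes[j],
                                        problem = "directed edge violates knowledge")
      }
    }
  }
  if (length(bad) == 0L) {
    return(tibble::tibble(from = character(), to = character(), problem = character()))
  }
  dplyr::distinct(dplyr::bind_rows(bad))
}
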