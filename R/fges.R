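# Stage 1 of the hybrid search: fast greedy equivalence search (FGES) over
# CPDAGs, assuming no latent confounders.  Forward phase repeatedly applies
# the best-scoring valid single-edge insertion, backward phase the best valid
# deletion; after every operator the graph is re-completed (consistent DAG
# extension -> v-structures -> Meek closure with background knowledge), so the
# state is always a knowledge-respecting completed pattern.
#
# CPDAG encoding: directed edge i -> j has TAIL at i and ARROW at j;
# undirected edges carry TAIL at both ends.

# --- pattern machinery -------------------------------------------------------

# Dor-Tarsi: extend a PDAG (directed + undirected edges) to a consistent DAG.
# Returns the DAG matrix or NULL if no extension exists.
pdag_to_dag_M <- function(M) {
  p <- nrow(M)
  W <- M
  out <- M
  active <- rep(TRUE, p)
  remaining <- p
  while (remaining > 0L) {
    found <- FALSE
    for (x in seq_len(p)) {
      if (!active[x]) next
      ch <- which(active & W[x, ] == MARK_ARROW & W[, x] == MARK_TAIL)
      if (length(ch)) next  # x has outgoing directed edges
      nb <- which(active & W[x, ] == MARK_TAIL & W[, x] == MARK_TAIL)
      adjx <- which(active & W[x, ] != MARK_NONE)
      ok <- TRUE
      for (y in nb) {
        others <- setdiff(adjx, y)
        if (length(others) && any(W[y, others] == MARK_NONE)) { ok <- FALSE; break }
      }
      if (!ok) next
      # orient all undirected neighbours into x, then remove x
      for (y in nb) { out[y, x] <- MARK_ARROW; out[x, y] <- MARK_TAIL }
      W[x, ] <- MARK_NONE; W[, x] <- MARK_NONE
      active[x] <- FALSE
      remaining <- remaining - 1L
      found <- TRUE
      break
    }
    if (!found) return(NULL)
  }
  out
}

# DAG -> completed pattern: skeleton undirected, v-structures directed,
# then Meek closure under knowledge.
dag_to_cpdag_M <- function(Mdag, Fb = NULL) {
  p <- nrow(Mdag)
  M <- Mdag
  M[M != MARK_NONE] <- MARK_TAIL  # undirect everything
  for (z in seq_len(p)) {
    pa <- which(Mdag[, z] == MARK_ARROW & Mdag[z, ] == MARK_TAIL)
    if (length(pa) >= 2L) {
      for (a in seq_along(pa)) {
        for (b in seq_along(pa)) {
          if (a < b && Mdag[pa[a], pa[b]] == MARK_NONE) {
            M[pa[a], z] <- MARK_ARROW; M[z, pa[a]] <- MARK_TAIL
            M[pa[b], z] <- MARK_ARROW; M[z, pa[b]] <- MARK_TAIL
          }
        }
      }
    }
  }
  meek_closure_M(M, Fb)
}

# Meek orientation rules + knowledge-forced orientations, to fixpoint.
# Fb[i, j] TRUE means i may not cause j.  Conflicting forced orientations are
# collected on the returned attribute "conflicts".
meek_closure_M <- function(M, Fb = NULL) {
  p <- nrow(M)
  conflicts <- list()
  orient <- function(a, b) {  # a -> b
    M[a, b] <<- MARK_ARROW; M[b, a] <<- MARK_TAIL
  }
  allowed <- function(a, b) is.null(Fb) || !Fb[a, b]
  # knowledge-forced orientations on undirected edges
  if (!is.null(Fb)) {
    for (i in seq_len(p)) {
      for (j in seq_len(p)) {
        if (i >= j || !mg_is_undirected(M, i, j)) next
        if (Fb[i, j] && Fb[j, i]) {
          conflicts[[length(conflicts) + 1L]] <- c(i, j)
        } else if (Fb[i, j]) {
          orient(j, i)
        } else if (Fb[j, i]) {
          orient(i, j)
        }
      }
    }
  }
  repeat {
    changed <- FALSE
    for (b in seq_len(p)) {
      for (c in seq_len(p)) {
        if (b == c || !mg_is_undirected(M, b, c)) next
        # R1: a -> b - c, a and c nonadjacent  =>  b -> c
        pa_b <- which(M[, b] == MARK_ARROW & M[b, ] == MARK_TAIL)
        if (any(M[pa_b, c] == MARK_NONE)) {
          if (allowed(b, c)) { orient(b, c); changed <- TRUE; next }
          conflicts[[length(conflicts) + 1L]] <- c(b, c)
        }
        # R2: b -> k -> c with b - c  =>  b -> c
        k_mid <- which(M[b, ] == MARK_ARROW & M[, b] == MARK_TAIL &
                         M[, c] == MARK_ARROW & M[c, ] == MARK_TAIL)
        if (length(k_mid)) {
          if (allowed(b, c)) { orient(b, c); changed <- TRUE; next }
          conflicts[[length(conflicts) + 1L]] <- c(b, c)
        }
        # R3: b - c, b - k1 -> c, b - k2 -> c, k1/k2 nonadjacent  =>  b -> c
        nb <- which(M[, b] == MARK_TAIL & M[b, ] == MARK_TAIL)
        ks <- nb[M[nb, c] == MARK_ARROW & M[c, nb] == MARK_TAIL]
        if (length(ks) >= 2L) {
          hit <- FALSE
          for (a in seq_along(ks)) {
            for (d in seq_along(ks)) {
              if (a < d && M[ks[a], ks[d]] == MARK_NONE) { hit <- TRUE; break }
            }
            if (hit) break
          }
          if (hit) {
            if (allowed(b, c)) { orient(b, c); changed <- TRUE; next }
            conflicts[[length(conflicts) + 1L]] <- c(b, c)
          }
        }
        # R4: b - c, exists chain a1 -> a2 -> c with b adjacent a1,
        #     a1 and c nonadjacent  =>  b -> c
        for (a2 in which(M[, c] == MARK_ARROW & M[c, ] == MARK_TAIL)) {
          a1s <- which(M[, a2] == MARK_ARROW & M[a2, ] == MARK_TAIL &
                         M[b, ] != MARK_NONE & M[, c] == MARK_NONE)
          # note: M[,c] == MARK_NONE ensures a1 nonadjacent to c
          if (length(a1s)) {
            if (allowed(b, c)) { orient(b, c); changed <- TRUE } else {
              conflicts[[length(conflicts) + 1L]] <- c(b, c)
            }
            break
          }
        }
      }
    }
    if (!changed) break
  }
  attr(M, "conflicts") <- conflicts
  M
}

rebuild_pattern <- function(M, Fb) {
  dag <- pdag_to_dag_M(M)
  if (is.null(dag)) return(M)  # defensive; valid operators always extend
  dag_to_cpdag_M(dag, Fb)
}

# total score of (a consistent DAG extension of) a pattern
pattern_score <- function(M, scorer) {
  dag <- pdag_to_dag_M(M)
  if (is.null(dag)) return(NA_real_)
  p <- nrow(M)
  tot <- 0
  for (y in seq_len(p)) tot <- tot + scorer(y, mg_parents(dag, y))
  tot
}

# any semidirected path from `from` to `to` avoiding `blocked`?
semidirected_reachable <- function(M, from, to, blocked) {
  p <- nrow(M)
  seen <- rep(FALSE, p)
  seen[blocked] <- TRUE
  queue <- from
  seen[from] <- TRUE
  while (length(queue)) {
    u <- queue[1L]; queue <- queue[-1L]
    step <- which(!seen &
                    ((M[u, ] == MARK_ARROW & M[, u] == MARK_TAIL) |
                       (M[u, ] == MARK_TAIL & M[, u] == MARK_TAIL)))
    if (to %in% step) return(TRUE)
    seen[step] <- TRUE
    queue <- c(queue, step)
  }
  FALSE
}

# utils::combn(x, k) with scalar x means seq_len(x); always pass a vector set
combn_sets <- function(set, k) {
  if (k == 0L) return(list(integer(0)))
  if (length(set) < k) return(list())
  if (length(set) == 1L) return(list(set))
  utils::combn(set, k, simplify = FALSE)
}

subsets_increasing <- function(set) {
  out <- list(integer(0))
  if (length(set) == 0L) return(out)
  for (k in seq_along(set)) {
    out <- c(out, combn_sets(set, k))
  }
  out
}

# --- forward / backward phases ----------------------------------------------

fges_run <- function(stats, Fb, c_pen) {
  nodes <- stats$vars
  p <- length(nodes)
  scorer <- make_scorer(stats, c_pen)
  M <- matrix(MARK_NONE, p, p, dimnames = list(nodes, nodes))
  trace <- pattern_score(M, scorer)

  # forward: best valid insertion until no improvement
  repeat {
    best <- NULL; best_delta <- 0
    for (x in seq_len(p)) {
      for (y in seq_len(p)) {
        if (x == y || M[x, y] != MARK_NONE || (!is.null(Fb) && Fb[x, y])) next
        nb_y <- mg_neighbors(M, y)
        adj_x <- mg_adj(M, x)
        nayx <- intersect(nb_y, adj_x)
        t0 <- setdiff(nb_y, adj_x)
        pa_y <- mg_parents(M, y)
        for (T in subsets_increasing(t0)) {
          if (!is.null(Fb) && length(T) && any(Fb[T, y])) next
          cl <- union(nayx, T)
          if (!mg_is_clique(M, cl)) next
          if (semidirected_reachable(M, y, x, cl)) next
          old <- scorer(y, union(pa_y, cl))
          new <- scorer(y, union(union(pa_y, cl), x))
          delta <- new - old
          if (is.finite(delta) && delta > best_delta + 1e-10) {
            best_delta <- delta
            best <- list(x = x, y = y, T = T)
          }
        }
      }
    }
    if (is.null(best)) break
    M[best$x, best$y] <- MARK_ARROW; M[best$y, best$x] <- MARK_TAIL
    for (t in best$T) { M[t, best$y] <- MARK_ARROW; M[best$y, t] <- MARK_TAIL }
    M <- rebuild_pattern(M, Fb)
    trace <- c(trace, pattern_score(M, scorer))
  }

  # backward: best valid deletion until no improvement
  repeat {
    best <- NULL; best_delta <- 0
    for (x in seq_len(p)) {
      for (y in seq_len(p)) {
        if (x == y || M[x, y] == MARK_NONE) next
        if (!(mg_is_directed(M, x, y) || mg_is_undirected(M, x, y))) next
        nayx <- intersect(mg_neighbors(M, y), mg_adj(M, x))
        pa_y <- mg_parents(M, y)
        for (H in subsets_increasing(nayx)) {
          if (!mg_is_clique(M, setdiff(nayx, H))) next
          if (!is.null(Fb) && length(H)) {
            hy <- H[M[H, y] == MARK_TAIL & M[y, H] == MARK_TAIL]
            hx <- H[M[H, x] == MARK_TAIL & M[x, H] == MARK_TAIL]
            if ((length(hy) && any(Fb[y, hy])) ||
                (length(hx) && any(Fb[x, hx]))) next
          }
          base <- setdiff(union(pa_y, setdiff(nayx, H)), x)
          old <- scorer(y, union(base, x))
          new <- scorer(y, base)
          delta <- new - old
          if (is.finite(delta) && delta > best_delta + 1e-10) {
            best_delta <- delta
            best <- list(x = x, y = y, H = H)
          }
        }
      }
    }
    if (is.null(best)) break
    x <- best$x; y <- best$y
    M[x, y] <- MARK_NONE; M[y, x] <- MARK_NONE
    for (h in best$H) {
      if (M[h, y] == MARK_TAIL && M[y, h] == MARK_TAIL) {
        M[y, h] <- MARK_ARROW; M[h, y] <- MARK_TAIL
      }
      if (M[h, x] != MARK_NONE && M[h, x] == MARK_TAIL && M[x, h] == MARK_TAIL) {
        M[x, h] <- MARK_ARROW; M[h, x] <- MARK_TAIL
      }
    }
    M <- rebuild_pattern(M, Fb)
    trace <- c(trace, pattern_score(M, scorer))
  }

  attr(M, "score_trace") <- trace
  M
}

#' Greedy equivalence search (stage 1)
#'
#' Score-based search over completed patterns (CPDAGs) assuming no latent
#' confounders: a forward phase of best-first single-edge insertions followed
#' by a backward phase of deletions, maximising the decomposable SEM-BIC
#' score.  Background knowledge is enforced both as operator filtering and
#' inside Meek closure.  Deterministic given input column order; ties are
#' broken toward the lexicographically smallest (source, target) pair.
#'
#' @param data Data frame of numeric columns (complete cases).
#' @param params An [analysis_params()].
#' @param k A [knowledge()] object.
#' @return A `mixed_graph` of class `cpdag` whose edges are directed
#'   (tail/arrow) or undirected (tail/tail), with attribute `score_trace`
#'   (total score after each accepted operator).
#' @examples
#' spec <- build_published_model(n = 2000, seed = 7)
#' cp <- fges_search(simulate(spec), knowledge = published_model_knowledge())
#' tidy(cp)
#' @export
fges_search <- function(data, params = analysis_params(), knowledge = NULL) {
  st <- gauss_stats(data)
  if (length(st$vars) < 2L) {
    rlang::abort("Need at least two variables.", class = "causalpaths_bad_data")
  }
  k <- knowledge %||% causalpaths::knowledge()
  Fb <- knowledge_matrix(k, st$vars)
  M <- fges_run(st, Fb, params$penalty_discount)
  g <- new_mixed_graph(st$vars, M, subclass = "cpdag")
  attr(g, "score_trace") <- attr(M, "score_trace")
  g
}

#' Meek closure of a pattern under background knowledge
#'
#' Iteratively applies the four Meek orientation rules plus knowledge-forced
#' orientations until fixpoint.  The input may contain only directed and
#' undirected (tail/tail) edges.  Conflicting forced orientations are reported
#' on the `conflicts` attribute (first orientation wins).
#'
#' @param g A `mixed_graph` without circle marks.
#' @param k A [knowledge()] object.
#' @return The closed graph.
#' @export
meek_closure <- function(g, k = knowledge()) {
  if (any(g$M == MARK_CIRCLE)) {
    rlang::abort("meek_closure() expects a pattern without circle marks.",
                 class = "causalpaths_bad_graph")
  }
  Fb <- knowledge_matrix(k, g$nodes)
  M <- meek_closure_M(g$M, Fb)
  cf <- attr(M, "conflicts")
  out <- new_mixed_graph(g$nodes, M, subclass = "cpdag")
  attr(out, "conflicts") <- lapply(cf, function(ij) g$nodes[ij])
  out
}

# --- exhaustive oracle -------------------------------------------------------

#' Exhaustive best-scoring equivalence class (test oracle)
#'
#' Enumerates every DAG over at most five variables that is consistent with
#' the background knowledge, scores each by its summed local SEM-BIC scores,
#' and returns the completed pattern of the best-scoring class.  Used as an
#' independent oracle for the greedy search; not part of the pipeline.
#'
#' @inheritParams fges_search
#' @return A `mixed_graph` of class `cpdag`, with attribute `best_score`.
#' @export
exhaustive_best_dag <- function(data, params = analysis_params(), knowledge = NULL) {
  st <- gauss_stats(data)
  p <- length(st$vars)
  if (p > 5L) {
    rlang::abort("Exhaustive search is limited to five variables.",
                 class = "causalpaths_too_large")
  }
  k <- knowledge %||% causalpaths::knowledge()
  Fb <- knowledge_matrix(k, st$vars)
  scorer <- make_scorer(st, params$penalty_discount)
  pairs <- if (p >= 2) utils::combn(p, 2, simplify = FALSE) else list()
  npairs <- length(pairs)
  best_score <- -Inf
  best_dag <- NULL
  state <- integer(npairs)  # 0 none, 1 i->j, 2 j->i
  M <- matrix(MARK_NONE, p, p, dimnames = list(st$vars, st$vars))
  recurse <- function(level) {
    if (level > npairs) {
      if (mg_has_directed_cycle(M)) return(invisible())
      tot <- 0
      for (y in seq_len(p)) {
        tot <- tot + scorer(y, mg_parents(M, y))
        if (!is.finite(tot)) return(invisible())
      }
      if (tot > best_score + 1e-10) {
        best_score <<- tot
        best_dag <<- M
      }
      return(invisible())
    }
    ij <- pairs[[level]]
    i <- ij[1]; j <- ij[2]
    # none
    recurse(level + 1L)
    # i -> j
    if (!Fb[i, j]) {
      M[i, j] <<- MARK_ARROW; M[j, i] <<- MARK_TAIL
      recurse(level + 1L)
      M[i, j] <<- MARK_NONE; M[j, i] <<- MARK_NONE
    }
    # j -> i
    if (!Fb[j, i]) {
      M[j, i] <<- MARK_ARROW; M[i, j] <<- MARK_TAIL
      recurse(level + 1L)
      M[i, j] <<- MARK_NONE; M[j, i] <<- MARK_NONE
    }
    invisible()
  }
  recurse(1L)
  out_M <- dag_to_cpdag_M(best_dag, Fb)
  g <- new_mixed_graph(st$vars, out_M, subclass = "cpdag")
  attr(g, "best_score") <- best_score
  g
}
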