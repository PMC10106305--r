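# Stage 2 of the hybrid search: drop the no-latents assumption.  Adjacencies
# of the stage-1 CPDAG are pruned with Fisher-Z conditional-independence tests
# (adjacency subsets first, then Possible-D-Sep sets), then the remaining
# skeleton is re-oriented from scratch: circles everywhere, unshielded
# colliders from separating sets (or stage-1 colliders), background-knowledge
# arrowheads, and the FCI orientation rules R1-R4 and R8-R10 to fixpoint.
# The selection-bias rules R5-R7 are omitted (no selection bias assumed).

pair_key <- function(i, j) paste(min(i, j), max(i, j), sep = "|")

# --- pruning -----------------------------------------------------------------

prune_run <- function(A, stats, params, cpdagM = NULL, sepsets = NULL) {
  # A: logical adjacency matrix (modified in place); returns list(A, sepsets)
  p <- nrow(A)
  S <- stats$S; n <- stats$n
  sepsets <- sepsets %||% new.env(parent = emptyenv(), hash = TRUE)
  alpha <- params$alpha
  max_depth <- min(params$max_cond_size, p - 2L)

  test_remove <- function(i, j, cond) {
    res <- tryCatch(citest_from_stats(S, n, i, j, cond, alpha),
                    error = function(e) NULL)  # singular: uninformative, skip
    if (!is.null(res) && res$independent) {
      A[i, j] <<- FALSE; A[j, i] <<- FALSE
      sepsets[[pair_key(i, j)]] <- cond
      TRUE
    } else FALSE
  }

  depth <- 0L
  repeat {
    if (depth > max_depth) break
    any_candidates <- FALSE
    for (i in seq_len(p - 1L)) {
      for (j in seq(i + 1L, p)) {
        if (!A[i, j]) next
        removed <- FALSE
        for (side in c(i, j)) {
          other <- if (side == i) j else i
          cand <- setdiff(which(A[side, ]), other)
          if (length(cand) < depth) next
          any_candidates <- TRUE
          if (depth == 0L) {
            removed <- test_remove(i, j, integer(0))
          } else {
            for (cond in combn_sets(cand, depth)) {
              if (test_remove(i, j, cond)) { removed <- TRUE; break }
            }
          }
          if (removed) break
        }
      }
    }
    if (!any_candidates && depth > 0L) break
    depth <- depth + 1L
  }

  # Possible-D-Sep stage: orient colliders on a working copy to define
  # reachability, then test subsets of each endpoint's Possible-D-Sep set.
  Mtmp <- circles_from_adjacency(A)
  Mtmp <- orient_colliders_M(Mtmp, sepsets, cpdagM)$M
  pd_cap <- min(params$pdsep_max, p - 2L)
  for (i in seq_len(p - 1L)) {
    for (j in seq(i + 1L, p)) {
      if (!A[i, j]) next
      removed <- FALSE
      for (side in c(i, j)) {
        other <- if (side == i) j else i
        pd <- setdiff(possible_d_sep(Mtmp, side), c(i, j))
        if (length(pd) == 0L) next
        for (size in seq_len(min(length(pd), pd_cap))) {
          for (cond in combn_sets(pd, size)) {
            if (test_remove(i, j, cond)) { removed <- TRUE; break }
          }
          if (removed) break
        }
        if (removed) break
      }
    }
  }
  list(A = A, sepsets = sepsets)
}

circles_from_adjacency <- function(A) {
  M <- matrix(MARK_NONE, nrow(A), ncol(A), dimnames = dimnames(A))
  M[A] <- MARK_CIRCLE
  M
}

# nodes reachable from x along paths whose every interior vertex is either a
# collider on the path or part of a triangle with its path neighbours
possible_d_sep <- function(M, x) {
  p <- nrow(M)
  # state: (prev, cur); expand while legal
  seen <- matrix(FALSE, p, p)
  out <- logical(p)
  queue <- lapply(which(M[x, ] != MARK_NONE), function(v) c(x, v))
  for (q in queue) { seen[q[1], q[2]] <- TRUE; out[q[2]] <- TRUE }
  while (length(queue)) {
    st <- queue[[1L]]; queue <- queue[-1L]
    u <- st[1L]; v <- st[2L]
    for (w in which(M[v, ] != MARK_NONE)) {
      if (w == u || seen[v, w]) next
      collider_at_v <- M[u, v] == MARK_ARROW && M[w, v] == MARK_ARROW
      triangle <- M[u, w] != MARK_NONE
      if (collider_at_v || triangle) {
        seen[v, w] <- TRUE
        out[w] <- TRUE
        queue[[length(queue) + 1L]] <- c(v, w)
      }
    }
  }
  out[x] <- FALSE
  which(out)
}

#' Prune CPDAG adjacencies with conditional-independence tests (stage 2a)
#'
#' For each adjacency X - Y of the stage-1 pattern, tests X independent of Y
#' given subsets of the adjacency sets of X and of Y (sizes 0 upward), then
#' given subsets of each endpoint's Possible-D-Sep set; the edge is removed on
#' the first independence found and the separating set recorded.
#'
#' @param g A `cpdag` from [fges_search()] on the same data.
#' @param data The data frame used for the search.
#' @param params An [analysis_params()].
#' @return A list with `skeleton` (a `mixed_graph` with circle marks at every
#'   endpoint) and `sepsets` (named list, keys `"A|B"`, values character
#'   vectors of separating variables).
#' @export
prune_adjacencies <- function(g, data, params = analysis_params()) {
  st <- gauss_stats(data)
  stopifnot(identical(st$vars, g$nodes))
  A <- g$M != MARK_NONE
  res <- prune_run(A, st, params, cpdagM = g$M)
  skeleton <- new_mixed_graph(g$nodes, circles_from_adjacency(res$A))
  list(skeleton = skeleton, sepsets = sepsets_to_names(res$sepsets, g$nodes))
}

sepsets_to_names <- function(env, nodes) {
  out <- list()
  for (key in ls(env)) {
    ij <- as.integer(strsplit(key, "|", fixed = TRUE)[[1L]])
    out[[paste(nodes[ij[1L]], nodes[ij[2L]], sep = "|")]] <- nodes[env[[key]]]
  }
  out
}

sepsets_to_idx <- function(lst, nodes) {
  env <- new.env(parent = emptyenv(), hash = TRUE)
  for (key in names(lst)) {
    ab <- strsplit(key, "|", fixed = TRUE)[[1L]]
    i <- match(ab[1L], nodes); j <- match(ab[2L], nodes)
    env[[pair_key(i, j)]] <- match(lst[[key]], nodes)
  }
  env
}

# --- orientation -------------------------------------------------------------

orient_colliders_M <- function(M, sepsets, cpdagM = NULL) {
  p <- nrow(M)
  for (z in seq_len(p)) {
    nbrs <- which(M[z, ] != MARK_NONE)
    if (length(nbrs) < 2L) next
    for (ai in seq_along(nbrs)) {
      for (bi in seq_along(nbrs)) {
        if (ai >= bi) next
        x <- nbrs[ai]; y <- nbrs[bi]
        if (M[x, y] != MARK_NONE) next  # shielded
        sep <- sepsets[[pair_key(x, y)]]
        collider <- if (!is.null(sep)) {
          !(z %in% sep)
        } else if (!is.null(cpdagM)) {
          cpdagM[x, y] == MARK_NONE &&
            mg_is_directed(cpdagM, x, z) && mg_is_directed(cpdagM, y, z)
        } else FALSE
        if (collider) {
          M[x, z] <- MARK_ARROW
          M[y, z] <- MARK_ARROW
        }
      }
    }
  }
  list(M = M)
}

# mark setter with conflict log: circles may be overwritten, anything else
# conflicting keeps its first value
make_orient_ctx <- function(M, nodes) {
  ctx <- new.env(parent = emptyenv())
  ctx$M <- M
  ctx$nodes <- nodes
  ctx$conflicts <- list()
  ctx$changed <- FALSE
  ctx
}

ctx_set <- function(ctx, i, j, mark) {
  cur <- ctx$M[i, j]
  if (cur == mark) return(invisible(FALSE))
  if (cur == MARK_CIRCLE) {
    ctx$M[i, j] <- mark
    ctx$changed <- TRUE
    return(invisible(TRUE))
  }
  ctx$conflicts[[length(ctx$conflicts) + 1L]] <-
    list(edge = c(ctx$nodes[i], ctx$nodes[j]),
         kept = mark_label(cur), rejected = mark_label(mark))
  invisible(FALSE)
}

# potentially directed step u -> v: no arrow back at u, no tail at v
is_pd_step <- function(M, u, v) {
  M[u, v] != MARK_NONE && M[v, u] != MARK_ARROW && M[u, v] != MARK_TAIL
}

# uncovered potentially-directed path from a to target whose first vertex is
# `first` (optionally constrained); returns TRUE/FALSE
upd_path_exists <- function(M, a, target, first = NULL, second_nonadjacent_to = NULL) {
  p <- nrow(M)
  starts <- if (is.null(first)) which(vapply(seq_len(p), function(v) {
    v != a && is_pd_step(M, a, v)
  }, logical(1))) else first
  for (b in starts) {
    if (!is_pd_step(M, a, b)) next
    if (!is.null(second_nonadjacent_to) && b != target &&
        M[b, second_nonadjacent_to] != MARK_NONE) next
    if (!is.null(second_nonadjacent_to) && b == target) next
    if (b == target) return(TRUE)
    # DFS with uncovered constraint
    found <- FALSE
    dfs <- function(prev, cur, visited) {
      if (found) return()
      for (nxt in which(M[cur, ] != MARK_NONE)) {
        if (visited[nxt] || !is_pd_step(M, cur, nxt)) next
        if (M[prev, nxt] != MARK_NONE) next  # covered triple
        if (nxt == target) { found <<- TRUE; return() }
        v2 <- visited; v2[nxt] <- TRUE
        dfs(cur, nxt, v2)
        if (found) return()
      }
    }
    visited <- logical(p); visited[a] <- TRUE; visited[b] <- TRUE
    dfs(a, b, visited)
    if (found) return(TRUE)
  }
  FALSE
}

apply_fci_rules <- function(ctx, sepset_fn) {
  M <- function() ctx$M
  p <- nrow(ctx$M)
  repeat {
    ctx$changed <- FALSE
    m <- ctx$M
    for (b in seq_len(p)) {
      for (c in seq_len(p)) {
        if (b == c || m[b, c] == MARK_NONE) next
        # R1: a *-> b o-* c, a/c nonadjacent  =>  b -> c
        if (m[c, b] == MARK_CIRCLE) {
          as <- which(m[, b] == MARK_ARROW & seq_len(p) != c)
          if (any(m[as, c] == MARK_NONE & m[c, as] == MARK_NONE)) {
            ctx_set(ctx, c, b, MARK_TAIL)
            ctx_set(ctx, b, c, MARK_ARROW)
          }
        }
        m <- ctx$M
        # R2: (a -> b *-> c) or (a *-> b -> c), with a *-o c  =>  a *-> c
        for (a in seq_len(p)) {
          if (a == b || a == c) next
          if (m[a, c] != MARK_CIRCLE || m[c, a] == MARK_NONE) next
          cond1 <- mg_is_directed(m, a, b) && m[b, c] == MARK_ARROW
          cond2 <- m[a, b] == MARK_ARROW && mg_is_directed(m, b, c)
          if (cond1 || cond2) ctx_set(ctx, a, c, MARK_ARROW)
          m <- ctx$M
        }
      }
    }
    m <- ctx$M
    # R3: a *-> b <-* c, a *-o d o-* c, a/c nonadjacent, d *-o b  =>  d *-> b
    for (d in seq_len(p)) {
      for (b in seq_len(p)) {
        if (d == b || m[d, b] != MARK_CIRCLE) next
        for (a in seq_len(p)) {
          if (a == d || a == b || m[a, b] != MARK_ARROW || m[a, d] != MARK_CIRCLE) next
          for (c in seq_len(p)) {
            if (c %in% c(a, b, d)) next
            if (m[c, b] != MARK_ARROW || m[c, d] != MARK_CIRCLE) next
            if (m[a, c] != MARK_NONE) next
            ctx_set(ctx, d, b, MARK_ARROW)
            m <- ctx$M
            break
          }
        }
      }
    }
    # R4: discriminating paths
    r4_apply(ctx, sepset_fn)
    m <- ctx$M
    # R8: a -> b -> c and a o-> c  =>  a -> c
    for (a in seq_len(p)) {
      for (c in seq_len(p)) {
        if (a == c || m[a, c] != MARK_ARROW || m[c, a] != MARK_CIRCLE) next
        for (b in seq_len(p)) {
          if (b == a || b == c) next
          if (mg_is_directed(m, a, b) && mg_is_directed(m, b, c)) {
            ctx_set(ctx, c, a, MARK_TAIL)
            m <- ctx$M
            break
          }
        }
      }
    }
    # R9: a o-> c with an uncovered p.d. path <a, b, ..., c>, b nonadjacent c
    for (a in seq_len(p)) {
      for (c in seq_len(p)) {
        if (a == c || m[a, c] != MARK_ARROW || m[c, a] != MARK_CIRCLE) next
        if (upd_path_exists(m, a, c, second_nonadjacent_to = c)) {
          ctx_set(ctx, c, a, MARK_TAIL)
          m <- ctx$M
        }
      }
    }
    # R10: a o-> c, b -> c <- d, uncovered p.d. paths a..b and a..d whose
    # first vertices are distinct and nonadjacent
    for (a in seq_len(p)) {
      for (c in seq_len(p)) {
        if (a == c || m[a, c] != MARK_ARROW || m[c, a] != MARK_CIRCLE) next
        pars <- setdiff(which(m[, c] == MARK_ARROW & m[c, ] == MARK_TAIL), a)
        if (length(pars) < 2L) next
        starts <- which(vapply(seq_len(p), function(v) v != a && is_pd_step(m, a, v), logical(1)))
        done <- FALSE
        for (bb in pars) {
          for (dd in pars) {
            if (bb == dd || done) next
            for (mu in starts) {
              for (om in starts) {
                if (mu == om || m[mu, om] != MARK_NONE) next
                if (upd_path_exists(m, a, bb, first = mu) &&
                    upd_path_exists(m, a, dd, first = om)) {
                  ctx_set(ctx, c, a, MARK_TAIL)
                  m <- ctx$M
                  done <- TRUE
                  break
                }
              }
              if (done) break
            }
          }
        }
      }
    }
    if (!ctx$changed) break
  }
  invisible(ctx)
}

r4_apply <- function(ctx, sepset_fn) {
  m <- ctx$M
  p <- nrow(m)
  for (b in seq_len(p)) {
    for (c in seq_len(p)) {
      if (b == c || m[b, c] == MARK_NONE || m[c, b] != MARK_CIRCLE) next
      # path <d, ..., v, b, c>: interior vertices are colliders and parents of c
      # start from v: v *-> b and v -> c
      vs <- which(m[, b] == MARK_ARROW & m[, c] == MARK_ARROW & m[c, ] == MARK_TAIL)
      vs <- setdiff(vs, c(b, c))
      for (v in vs) {
        # BFS backwards: states are paths ending ... d' -> current front
        queue <- list(c(v))
        while (length(queue)) {
          path <- queue[[1L]]; queue <- queue[-1L]
          front <- path[1L]
          # candidates d with d *-> front
          ds <- setdiff(which(m[, front] == MARK_ARROW), c(path, b, c))
          for (d in ds) {
            if (m[d, c] == MARK_NONE && m[c, d] == MARK_NONE) {
              # discriminating path found: <d, path..., b, c>
              sep <- sepset_fn(d, c)
              if (!is.null(sep) && b %in% sep) {
                ctx_set(ctx, c, b, MARK_TAIL)
                ctx_set(ctx, b, c, MARK_ARROW)
              } else {
                ctx_set(ctx, path[length(path)], b, MARK_ARROW)
                ctx_set(ctx, c, b, MARK_ARROW)
                ctx_set(ctx, b, c, MARK_ARROW)
              }
              if (ctx$changed) return(invisible(ctx))
            } else if (m[front, d] == MARK_ARROW &&
                         mg_is_directed(m, d, c)) {
              # d is a collider on the path and a parent of c: extend
              queue[[length(queue) + 1L]] <- c(d, path)
            }
          }
        }
      }
    }
  }
  invisible(ctx)
}

#' Orient a pruned skeleton into a PAG (stage 2b)
#'
#' Resets every endpoint to a circle, orients unshielded colliders from the
#' recorded separating sets (falling back to stage-1 colliders for pairs that
#' were never adjacent after stage 1), applies background-knowledge
#' arrowheads (a forbidden cause X of Y receives an arrowhead at X on the
#' X - Y edge), and closes under the FCI rules R1-R4 and R8-R10.  Orientation
#' conflicts are logged on the `conflicts` attribute; the first orientation
#' wins.
#'
#' @param skeleton A `mixed_graph` (only its adjacencies are used).
#' @param sepsets Named list as returned by [prune_adjacencies()].
#' @param k A [knowledge()] object.
#' @param cpdag Optional stage-1 `cpdag` (for collider fallback).
#' @param data,params Optional data and [analysis_params()]; used to compute
#'   separating sets on demand for the discriminating-path rule.
#' @return A `mixed_graph` of class `pag`.
#' @export
orient_pag <- function(skeleton, sepsets, k = knowledge(), cpdag = NULL,
                       data = NULL, params = analysis_params()) {
  nodes <- skeleton$nodes
  A <- skeleton$M != MARK_NONE
  sep_env <- sepsets_to_idx(sepsets, nodes)
  M <- circles_from_adjacency(A)
  M <- orient_colliders_M(M, sep_env, if (!is.null(cpdag)) cpdag$M else NULL)$M
  ctx <- make_orient_ctx(M, nodes)

  # background knowledge: forbidden cause i of j  =>  arrowhead at i's end
  Fb <- knowledge_matrix(k, nodes)
  p <- length(nodes)
  for (i in seq_len(p)) {
    for (j in seq_len(p)) {
      if (i == j || !A[i, j]) next
      if (Fb[i, j]) ctx_set(ctx, j, i, MARK_ARROW)
    }
  }

  st <- if (!is.null(data)) gauss_stats(data) else NULL
  sepset_fn <- local({
    cache <- new.env(parent = emptyenv(), hash = TRUE)
    function(d, c) {
      key <- pair_key(d, c)
      got <- sep_env[[key]]
      if (!is.null(got)) return(got)
      if (!is.null(cache[[key]])) return(if (length(cache[[key]]) == 1L && cache[[key]][1L] == -1L) NULL else cache[[key]])
      if (is.null(st)) return(NULL)
      found <- NULL
      for (side in c(d, c)) {
        other <- if (side == d) c else d
        cand <- setdiff(which(A[side, ]), other)
        for (size in 0:length(cand)) {
          if (size > length(cand)) break
          sets <- combn_sets(cand, size)
          for (cond in sets) {
            res <- tryCatch(
              citest_from_stats(st$S, st$n, d, c, cond, params$alpha),
              error = function(e) NULL)
            if (!is.null(res) && res$independent) { found <- cond; break }
          }
          if (!is.null(found)) break
        }
        if (!is.null(found)) break
      }
      cache[[key]] <- if (is.null(found)) -1L else found
      found
    }
  })

  apply_fci_rules(ctx, sepset_fn)
  g <- new_mixed_graph(nodes, ctx$M, subclass = "pag")
  attr(g, "conflicts") <- ctx$conflicts
  g
}

#' Hybrid causal discovery producing a PAG
#'
#' Runs the full two-stage search: greedy equivalence search under a
#' no-latents assumption ([fges_search()]), conditional-independence pruning
#' of its adjacencies including the Possible-D-Sep stage
#' ([prune_adjacencies()]), and FCI re-orientation ([orient_pag()]).
#' Deterministic given the data, parameters and knowledge.
#'
#' @param data Data frame of numeric complete-case columns.
#' @param params An [analysis_params()] (`alpha = 0.01`,
#'   `penalty_discount = 1` are the reference defaults).
#' @param knowledge A [knowledge()] object (temporal tiers, forbidden causes).
#' @return A `mixed_graph` of class `pag`, with attributes `cpdag` (the
#'   stage-1 pattern), `sepsets`, `conflicts` and `params`.
#' @examples
#' spec <- build_published_model(n = 5000, seed = 11)
#' pag <- gfci(simulate(spec), knowledge = published_model_knowledge())
#' tidy(pag)
#' @export
gfci <- function(data, params = analysis_params(), knowledge = NULL) {
  if (nrow(as.data.frame(data)) == 0L) {
    rlang::abort("Empty input data.", class = "causalpaths_bad_data")
  }
  st <- gauss_stats(data)
  sds <- sqrt(diag(st$S))
  if (any(sds <= 0) || any(!is.finite(sds))) {
    rlang::abort("Constant column in input.", class = "causalpaths_bad_data")
  }
  cors <- stats::cov2cor(st$S)
  diag(cors) <- 0
  if (any(abs(cors) > 1 - 1e-12)) {
    rlang::abort("Duplicated/collinear columns in input.", class = "causalpaths_singular")
  }
  k <- knowledge %||% causalpaths::knowledge()
  cp <- fges_search(data, params, k)
  pr <- prune_run(cp$M != MARK_NONE, st, params, cpdagM = cp$M)
  skeleton <- new_mixed_graph(cp$nodes, circles_from_adjacency(pr$A))
  sepsets <- sepsets_to_names(pr$sepsets, cp$nodes)
  pag <- orient_pag(skeleton, sepsets, k, cpdag = cp, data = data, params = params)
  attr(pag, "cpdag") <- cp
  attr(pag, "sepsets") <- sepsets
  attr(pag, "params") <- params
  pag
}
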