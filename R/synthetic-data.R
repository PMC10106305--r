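# Linear-Gaussian recursive simulator.
#
# A simulation spec is a DAG with real edge coefficients, per-node Gaussian
# disturbance SDs and optional latent flags.  Sampling proceeds in topological
# order: each node is the coefficient-weighted sum of its parents plus
# independent noise.  Noise streams are keyed by sorted node name, so the
# joint distribution is invariant to the order in which nodes were declared.

#' Define a linear-Gaussian simulation
#'
#' @param nodes Data frame with columns `name`, and optionally `latent`
#'   (logical, default `FALSE`) and `timepoint` (`"baseline"`, `"six_month"`
#'   or `"static"`, default `"static"`); or a character vector of names.
#' @param edges Data frame with columns `from`, `to`, `coef`.  Must be acyclic.
#' @param noise_sd Disturbance standard deviation: a single positive number or
#'   a named vector (one entry per node).
#' @param n Number of observations to draw.
#' @param seed Integer RNG seed stored with the spec for reproducibility.
#' @return A `sim_spec` object.
#' @seealso [build_published_model()], [random_model()], [simulate.sim_spec()]
#' @export
simulation_spec <- function(nodes, edges, noise_sd = 1, n = 100, seed = 1L) {
  if (is.character(nodes)) nodes <- tibble::tibble(name = nodes)
  nodes <- tibble::as_tibble(nodes)
  if (!"latent" %in% names(nodes)) nodes$latent <- FALSE
  if (!"timepoint" %in% names(nodes)) nodes$timepoint <- "static"
  if (anyDuplicated(nodes$name)) {
    rlang::abort("Node names must be unique.", class = "causalpaths_bad_nodes")
  }
  edges <- tibble::as_tibble(as.data.frame(edges))
  if (nrow(edges)) {
    miss <- setdiff(c(edges$from, edges$to), nodes$name)
    if (length(miss)) {
      rlang::abort(paste0("Edge references unknown node(s): ", paste(miss, collapse = ", ")),
                   class = "causalpaths_unknown_node")
    }
    if (!all(is.finite(edges$coef))) {
      rlang::abort("Edge coefficients must be finite.", class = "causalpaths_bad_spec")
    }
  } else {
    edges <- tibble::tibble(from = character(), to = character(), coef = double())
  }
  if (length(noise_sd) == 1L && is.null(names(noise_sd))) {
    noise_sd <- stats::setNames(rep(noise_sd, nrow(nodes)), nodes$name)
  }
  if (!all(nodes$name %in% names(noise_sd)) || any(noise_sd[nodes$name] <= 0)) {
    rlang::abort("`noise_sd` must give a positive SD for every node.",
                 class = "causalpaths_bad_spec")
  }
  spec <- structure(
    list(nodes = nodes, edges = edges,
         noise_sd = noise_sd[nodes$name], n = as.integer(n), seed = as.integer(seed)),
    class = c("sim_spec", "list"))
  if (is.null(topological_order(spec))) {
    rlang::abort("Edge set must be acyclic.", class = "causalpaths_cyclic")
  }
  spec
}

#' @export
print.sim_spec <- function(x, ...) {
  cat(sprintf("<sim_spec> %d nodes (%d latent), %d edges, n = %d, seed = %d\n",
              nrow(x$nodes), sum(x$nodes$latent), nrow(x$edges), x$n, x$seed))
  invisible(x)
}

# Kahn topological sort; NULL if cyclic
topological_order <- function(spec) {
  nm <- spec$nodes$name
  p <- length(nm)
  indeg <- stats::setNames(integer(p), nm)
  if (nrow(spec$edges)) {
    tab <- table(spec$edges$to)
    indeg[names(tab)] <- as.integer(tab)
  }
  out <- character(0)
  avail <- sort(nm[indeg == 0])
  while (length(avail)) {
    v <- avail[1L]
    avail <- avail[-1L]
    out <- c(out, v)
    ch <- spec$edges$to[spec$edges$from == v]
    for (w in ch) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) avail <- sort(c(avail, w))
    }
  }
  if (length(out) < p) NULL else out
}

#' The published functional-outcome model
#'
#' The nine-variable linear-Gaussian system over baseline (BL) and six-month
#' (6M) clinical composites — negative symptoms, socio-affective capacity
#' (SaC), motivation (Mot), social functioning (SF) and occupational
#' functioning (OF) — with the reported raw effect sizes as path coefficients:
#' NegSx_BL -> SaC_BL (-0.27), SaC_BL -> Mot_BL (0.77), Mot_BL -> SF_BL (1.5),
#' Mot_BL -> OF_BL (0.96), SF_BL -> SF_6M (0.6), OF_BL -> OF_6M (0.36),
#' SF_6M -> Mot_6M (0.21), Mot_6M -> OF_6M (0.92), Mot_6M -> SaC_6M (0.24).
#' All disturbances are unit-variance Gaussians and there are no latent nodes.
#'
#' @param n Sample size.
#' @param seed Integer seed.
#' @return A `sim_spec`; simulate from it with [simulate.sim_spec()].
#' @examples
#' spec <- build_published_model(n = 500, seed = 1)
#' head(simulate(spec))
#' @export
build_published_model <- function(n, seed = 1L) {
  stopifnot(n >= 1)
  nodes <- tibble::tibble(
    name = c("NegSx_BL", "SaC_BL", "Mot_BL", "SF_BL", "OF_BL",
             "SF_6M", "OF_6M", "Mot_6M", "SaC_6M"),
    latent = FALSE,
    timepoint = c(rep("baseline", 5), rep("six_month", 4)))
  edges <- tibble::tribble(
    ~from,      ~to,       ~coef,
    "NegSx_BL", "SaC_BL",  -0.27,
    "SaC_BL",   "Mot_BL",   0.77,
    "Mot_BL",   "SF_BL",    1.5,
    "Mot_BL",   "OF_BL",    0.96,
    "SF_BL",    "SF_6M",    0.6,
    "OF_BL",    "OF_6M",    0.36,
    "SF_6M",    "Mot_6M",   0.21,
    "Mot_6M",   "OF_6M",    0.92,
    "Mot_6M",   "SaC_6M",   0.24)
  simulation_spec(nodes, edges, noise_sd = 1, n = n, seed = seed)
}

#' Temporal knowledge matching the published model's variables
#'
#' Two tiers: all baseline variables before all six-month variables.
#'
#' @param spec A `sim_spec` with `timepoint` tags (default: the published
#'   model's layout).
#' @return A [knowledge()] object.
#' @export
published_model_knowledge <- function(spec = build_published_model(n = 1)) {
  obs <- spec$nodes[!spec$nodes$latent, ]
  knowledge(tiers = list(obs$name[obs$timepoint == "baseline"],
                         obs$name[obs$timepoint == "six_month"]))
}

#' Simulate observations from a linear-Gaussian spec
#'
#' Nodes are sampled in topological order as the coefficient-weighted sum of
#' their parents plus independent Gaussian noise; latent columns are dropped
#' from the output.  Identical `(spec, seed)` give identical data, and the
#' noise stream is keyed by sorted node name so the joint distribution does
#' not depend on node declaration order.
#'
#' @param object A `sim_spec`.
#' @param nsim Optional override of `object$n`.
#' @param seed Optional override of `object$seed`.
#' @param ... Unused.
#' @return A tibble of observed columns with attributes `timepoints` (named
#'   character vector) carried for downstream reporting.
#' @export
simulate.sim_spec <- function(object, nsim = NULL, seed = NULL, ...) {
  spec <- object
  n <- if (is.null(nsim)) spec$n else as.integer(nsim)
  sd_seed <- if (is.null(seed)) spec$seed else as.integer(seed)
  nm <- spec$nodes$name
  ord <- topological_order(spec)
  eps <- matrix(0, n, length(nm), dimnames = list(NULL, nm))
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(sd_seed)
  for (v in sort(nm)) eps[, v] <- stats::rnorm(n, 0, spec$noise_sd[[v]])
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  X <- eps
  for (v in ord) {
    pa <- spec$edges[spec$edges$to == v, , drop = FALSE]
    if (nrow(pa)) {
      X[, v] <- X[, v] + as.numeric(X[, pa$from, drop = FALSE] %*% pa$coef)
    }
  }
  obs <- nm[!spec$nodes$latent]
  out <- tibble::as_tibble(as.data.frame(X[, obs, drop = FALSE]))
  attr(out, "timepoints") <- stats::setNames(spec$nodes$timepoint[!spec$nodes$latent], obs)
  out
}

#' Analytic implied covariance of a simulation spec
#'
#' For the recursive system `x = B x + e` the implied covariance is
#' `(I - B)^-1 Psi (I - B)^-T`; the result is restricted to observed
#' (non-latent) nodes.
#'
#' @param spec A `sim_spec`.
#' @return A covariance matrix over the observed nodes.
#' @export
implied_covariance <- function(spec) {
  nm <- spec$nodes$name
  p <- length(nm)
  B <- matrix(0, p, p, dimnames = list(nm, nm))  # B[i, j]: coef of j in eq for i
  if (nrow(spec$edges)) {
    for (r in seq_len(nrow(spec$edges))) {
      B[spec$edges$to[r], spec$edges$from[r]] <- spec$edges$coef[r]
    }
  }
  Psi <- diag(spec$noise_sd[nm]^2, p)
  A <- solve(diag(p) - B)
  S <- A %*% Psi %*% t(A)
  dimnames(S) <- list(nm, nm)
  obs <- nm[!spec$nodes$latent]
  S[obs, obs, drop = FALSE]
}

#' Random linear-Gaussian benchmark system
#'
#' Draws a random DAG over a uniformly random node order with edge probability
#' `expected_degree / (p - 1)` per ordered pair, coefficients uniform on
#' `±[0.3, 1.0]`, unit disturbances, and optionally flags `n_latent` nodes as
#' latent, each constrained to have at least two observed children (edges are
#' added if the random draw left a latent under-connected).
#'
#' @param p Number of nodes (>= 2).
#' @param expected_degree Expected number of parents+children per node.
#' @param n_latent Number of latent confounders (>= 0).
#' @param n Sample size stored in the spec.
#' @param seed Integer seed; identical arguments give identical specs.
#' @return A `sim_spec`.
#' @export
random_model <- function(p, expected_degree = 2, n_latent = 0, n = 1000, seed = 1L) {
  stopifnot(p >= 2, n_latent >= 0)
  if (n_latent > 0 && p - n_latent < 2) {
    rlang::abort("Need at least two observed nodes per latent confounder.",
                 class = "causalpaths_bad_spec")
  }
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  nm <- sprintf("V%02d", seq_len(p))
  latent <- rep(FALSE, p)
  if (n_latent > 0) latent[seq_len(n_latent)] <- TRUE  # first in causal order: valid ancestors
  ord <- sample(p)  # ord[k] = node index in causal position k
  # keep latents first in causal order so their children can be observed
  ord <- c(ord[latent[ord]], ord[!latent[ord]])
  prob <- min(1, expected_degree / (p - 1))
  from <- character(0); to <- character(0)
  for (a in seq_len(p - 1L)) {
    for (b in seq(a + 1L, p)) {
      if (stats::runif(1) < prob) {
        from <- c(from, nm[ord[a]]); to <- c(to, nm[ord[b]])
      }
    }
  }
  # latent constraint: >= 2 observed children each
  obs_nm <- nm[!latent]
  for (li in which(latent)) {
    lv <- nm[li]
    ch <- unique(to[from == lv & to %in% obs_nm])
    need <- 2L - length(ch)
    if (need > 0) {
      cand <- setdiff(obs_nm, ch)
      pick <- sample(cand, need)
      from <- c(from, rep(lv, need)); to <- c(to, pick)
    }
  }
  k <- length(from)
  coef <- if (k) stats::runif(k, 0.3, 1.0) * sample(c(-1, 1), k, replace = TRUE) else double()
  edges <- tibble::tibble(from = from, to = to, coef = coef)
  edges <- dplyr::distinct(edges, .data$from, .data$to, .keep_all = TRUE)
  spec <- simulation_spec(tibble::tibble(name = nm, latent = latent), edges,
                          noise_sd = 1, n = n, seed = seed)
  spec
}

#' The true DAG of a simulation spec as a mixed graph
#'
#' @param spec A `sim_spec`.
#' @param observed_only Drop latent nodes (and their edges) from the view.
#' @return A [mixed_graph()] with fully directed edges.
#' @export
sim_spec_graph <- function(spec, observed_only = TRUE) {
  nodes <- if (observed_only) spec$nodes$name[!spec$nodes$latent] else spec$nodes$name
  ed <- spec$edges[spec$edges$from %in% nodes & spec$edges$to %in% nodes, , drop = FALSE]
  g <- mixed_graph(nodes)
  for (r in seq_len(nrow(ed))) g <- add_edge(g, ed$from[r], ed$to[r], "-->")
  g
}

#' Write / read a simulation spec as YAML
#'
#' @param spec A `sim_spec`.
#' @param path File path.
#' @return `write_sim_spec()` returns `path` invisibly; `read_sim_spec()`
#'   returns the `sim_spec`.
#' @export
write_sim_spec <- function(spec, path) {
  obj <- list(
    nodes = lapply(seq_len(nrow(spec$nodes)), function(i) {
      list(name = spec$nodes$name[i],
           latent = spec$nodes$latent[i],
           timepoint = spec$nodes$timepoint[i],
           noise_sd = as.numeric(spec$noise_sd[[spec$nodes$name[i]]]))
    }),
    edges = lapply(seq_len(nrow(spec$edges)), function(i) {
      list(from = spec$edges$from[i], to = spec$edges$to[i],
           coef = spec$edges$coef[i])
    }),
    n = spec$n, seed = spec$seed)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_sim_spec
#' @export
read_sim_spec <- function(path) {
  obj <- yaml::read_yaml(path)
  nodes <- dplyr::bind_rows(lapply(obj$nodes, function(x) {
    tibble::tibble(name = x$name, latent = isTRUE(x$latent),
                   timepoint = x$timepoint %||% "static")
  }))
  noise_sd <- stats::setNames(
    vapply(obj$nodes, function(x) as.numeric(x$noise_sd %||% 1), double(1)),
    nodes$name)
  edges <- if (length(obj$edges)) {
    dplyr::bind_rows(lapply(obj$edges, function(x) {
      tibble::tibble(from = x$from, to = x$to, coef = as.numeric(x$coef))
    }))
  } else NULL
  simulation_spec(nodes, edges %||%
                    tibble::tibble(from = character(), to = character(), coef = double()),
                  noise_sd = noise_sd, n = obj$n %||% 100, seed = obj$seed %||% 1)
}

#' @importFrom rlang %||% .data
NULL
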