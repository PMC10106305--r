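test_that("pruning removes an extra chain edge with the right separating set", {
  d <- simulate(chain_spec(1e5, b = 0.9, seed = 51))
  # stage-1 pattern artificially left X - Z in place
  cp <- mixed_graph(c("X", "Y", "Z"),
                    edges = data.frame(from = c("X", "Y", "X"),
                                       to = c("Y", "Z", "Z"),
                                       type = "---"))
  class(cp) <- c("cpdag", class(cp))
  pr <- prune_adjacencies(cp, d)
  expect_null(edge_between(pr$skeleton, "X", "Z"))
  expect_equal(pr$sepsets[["X|Z"]], "Y")
  # true edges survive
  expect_false(is.null(edge_between(pr$skeleton, "X", "Y")))
  expect_false(is.null(edge_between(pr$skeleton, "Y", "Z")))
})

test_that("an empty graph passes through pruning unchanged", {
  set.seed(52)
  d <- data.frame(a = rnorm(500), b = rnorm(500))
  cp <- mixed_graph(c("a", "b"))
  class(cp) <- c("cpdag", class(cp))
  pr <- prune_adjacencies(cp, d)
  expect_equal(nrow(tidy(pr$skeleton)), 0)
  expect_equal(length(pr$sepsets), 0)
})

test_that("a hidden common cause leaves no tail on the induced edge", {
  for (s in 1:5) {
    d <- simulate(latent_pair_spec(1e5, seed = 500 + s, with_isolated = TRUE))
    pag <- gfci(d)
    ed <- tidy(pag)
    expect_equal(nrow(ed), 1)
    expect_setequal(c(ed$from, ed$to), c("X", "Y"))
    expect_false(any(c(ed$end_from, ed$end_to) == "tail"))
    # the isolated variable stays isolated
    expect_false("W" %in% c(ed$from, ed$to))
  }
})

test_that("unshielded non-colliders keep non-arrow marks at the middle node", {
  d <- simulate(chain_spec(1e5, seed = 53))
  pag <- gfci(d)
  e_xy <- edge_between(pag, "X", "Y")
  e_yz <- edge_between(pag, "Y", "Z")
  expect_false(is.null(e_xy))
  expect_false(is.null(e_yz))
  expect_false(e_xy$end_to == "arrow" && e_yz$end_from == "arrow")
  expect_null(edge_between(pag, "X", "Z"))
})

test_that("gfci recovers the published structure at scale", {
  spec <- build_published_model(n = 20000, seed = 54)
  k <- published_model_knowledge()
  pag <- gfci(simulate(spec), knowledge = k)
  ed <- tidy(pag)
  truth <- paste(spec$edges$from, spec$edges$to)
  found <- paste(ed$from, ed$to)
  found_rev <- paste(ed$to, ed$from)
  # every recovered adjacency is a generating edge and vice versa
  expect_setequal(union(found[found %in% truth], found_rev[found_rev %in% truth]), truth)
  expect_equal(nrow(ed), 9)
  # fully directed edges are a subset of generating directions
  directed <- ed[ed$type == "-->", ]
  expect_true(all(paste(directed$from, directed$to) %in% truth))
  # the PAG skeleton is a subset of the stage-1 pattern's skeleton
  cp <- attr(pag, "cpdag")
  expect_true(all(pag$M[cp$M == 0L] == 0L))
})

test_that("no arrowhead claims a six-month cause of a baseline variable", {
  spec <- build_published_model(n = 5000, seed = 55)
  k <- published_model_knowledge()
  pag <- gfci(simulate(spec), knowledge = k)
  ed <- tidy(pag)
  for (i in seq_len(nrow(ed))) {
    if (ed$type[i] != "-->") next
    expect_false(knowledge_forbids(k, ed$from[i], ed$to[i]))
  }
})

test_that("degenerate inputs fail loudly, not silently", {
  set.seed(56)
  d <- data.frame(x = rnorm(300), y = rnorm(300))
  d$x_copy <- d$x
  expect_error(gfci(d), class = "causalpaths_singular")
  expect_error(gfci(d[0, ]), class = "causalpaths_bad_data")
  set.seed(57)
  ind <- data.frame(a = rnorm(1000), b = rnorm(1000), c = rnorm(1000))
  expect_equal(nrow(tidy(gfci(ind))), 0)
})

test_that("directed PAG edges are sound on faithful latent-free systems", {
  # Soundness of endpoint orientation is guaranteed only under faithfulness
  # and when every true dependence is detectable at the sample size.  Random
  # +/-[0.3, 1] coefficients occasionally draw near-cancelling path systems
  # whose population partial correlations sit below the n = 1e5 detection
  # limit (|r| ~ 0.008 at alpha = 0.01); those systems are screened out by
  # inspecting the implied covariance, and soundness is asserted on the rest.
  detectable <- function(sp, eps = 1e-8, delta = 0.01) {
    S <- implied_covariance(sp)
    p <- ncol(S)
    for (i in seq_len(p - 1)) {
      for (j in seq(i + 1, p)) {
        rest <- setdiff(seq_len(p), c(i, j))
        for (k in 0:length(rest)) {
          for (cond in causalpaths:::combn_sets(rest, k)) {
            r <- abs(causalpaths:::pcor_from_cov(S, i, j, cond))
            if (r > eps && r < delta) return(FALSE)
          }
        }
      }
    }
    TRUE
  }
  n_edges_total <- 0
  n_correct <- 0
  n_kept <- 0
  for (s in 1:40) {
    sp <- random_model(p = 6, expected_degree = 2, n_latent = 0, n = 1e5, seed = 900 + s)
    if (!detectable(sp)) next
    n_kept <- n_kept + 1
    pag <- gfci(simulate(sp))
    ed <- tidy(pag)
    directed <- ed[ed$type == "-->", ]
    if (!nrow(directed)) next
    # ancestor matrix of the generating DAG
    g <- sim_spec_graph(sp)
    A <- (g$M == 2L) & (t(g$M) == 3L)
    anc <- A
    for (k in seq_len(ncol(A))) anc <- anc | (anc %*% A > 0)
    for (i in seq_len(nrow(directed))) {
      fi <- match(directed$from[i], g$nodes)
      ti <- match(directed$to[i], g$nodes)
      n_edges_total <- n_edges_total + 1
      if (anc[fi, ti]) n_correct <- n_correct + 1
    }
  }
  expect_gte(n_kept, 15)
  expect_gt(n_edges_total, 0)
  expect_gte(n_correct / n_edges_total, 0.98)
})
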