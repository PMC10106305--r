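test_that("published model carries the reported coefficients and structure", {
  spec <- build_published_model(n = 10, seed = 1)
  coef_of <- function(from, to) {
    spec$edges$coef[spec$edges$from == from & spec$edges$to == to]
  }
  expect_equal(coef_of("SaC_BL", "Mot_BL"), 0.77)
  expect_equal(coef_of("Mot_6M", "SaC_6M"), 0.24)
  expect_equal(coef_of("NegSx_BL", "SaC_BL"), -0.27)
  expect_equal(coef_of("Mot_BL", "SF_BL"), 1.5)
  expect_equal(coef_of("Mot_BL", "OF_BL"), 0.96)
  expect_equal(coef_of("SF_BL", "SF_6M"), 0.6)
  expect_equal(coef_of("OF_BL", "OF_6M"), 0.36)
  expect_equal(coef_of("SF_6M", "Mot_6M"), 0.21)
  expect_equal(coef_of("Mot_6M", "OF_6M"), 0.92)
  expect_equal(nrow(spec$edges), 9)
  expect_equal(nrow(spec$nodes), 9)
  expect_false(any(spec$nodes$latent))
  # acyclic by construction (baseline tiers precede six-month tiers)
  g <- sim_spec_graph(spec)
  expect_false(causalpaths:::mg_has_directed_cycle(g$M))
})

test_that("simulate is deterministic and respects a zero coefficient", {
  spec0 <- simulation_spec(c("X", "Y"),
                           data.frame(from = "X", to = "Y", coef = 0),
                           n = 10000, seed = 4)
  d1 <- simulate(spec0)
  d2 <- simulate(spec0)
  expect_identical(d1, d2)
  expect_lt(abs(cor(d1$X, d1$Y)), 0.05)
})

test_that("sample covariance matches the closed-form implied covariance", {
  # X -> Y with b = 0.77, unit noise: Cov(X, Y) = b * Var(X) = 0.77
  spec <- simulation_spec(c("X", "Y"),
                          data.frame(from = "X", to = "Y", coef = 0.77),
                          n = 1e6, seed = 11)
  d <- simulate(spec)
  expect_lt(abs(cov(d$X, d$Y) - 0.77), 0.01)

  # latent L -> X, L -> Y (coefs 1): L dropped, Cov(X, Y) = Var(L) = 1
  dl <- simulate(latent_pair_spec(1e6, seed = 12))
  expect_false("L" %in% names(dl))
  expect_lt(abs(cov(dl$X, dl$Y) - 1.0), 0.01)
})

test_that("implied covariance formula agrees with simulation elementwise", {
  spec <- random_model(p = 5, expected_degree = 2, n_latent = 0, n = 1e6, seed = 21)
  d <- simulate(spec)
  S_hat <- cov(as.matrix(d))
  S_imp <- implied_covariance(spec)[colnames(S_hat), colnames(S_hat)]
  expect_lt(max(abs(S_hat - S_imp)), 0.02)
})

test_that("the joint distribution ignores node declaration order", {
  e <- data.frame(from = c("A", "B"), to = c("B", "C"), coef = c(0.5, -0.7))
  s1 <- simulation_spec(c("A", "B", "C"), e, n = 500, seed = 8)
  s2 <- simulation_spec(c("C", "A", "B"), e, n = 500, seed = 8)
  d1 <- as.data.frame(simulate(s1))
  d2 <- as.data.frame(simulate(s2))
  expect_equal(d1[, c("A", "B", "C")], d2[, c("A", "B", "C")])
})

test_that("random_model honours degree, latents and determinism", {
  empty <- random_model(p = 5, expected_degree = 0, n_latent = 0, seed = 1)
  expect_equal(nrow(empty$edges), 0)

  lat <- random_model(p = 4, expected_degree = 1, n_latent = 1, seed = 5)
  lv <- lat$nodes$name[lat$nodes$latent]
  obs <- lat$nodes$name[!lat$nodes$latent]
  ch <- unique(lat$edges$to[lat$edges$from == lv & lat$edges$to %in% obs])
  expect_gte(length(ch), 2)
  expect_true(all(abs(lat$edges$coef) >= 0.3 & abs(lat$edges$coef) <= 1.0))

  a <- random_model(p = 6, expected_degree = 2, n_latent = 1, seed = 9)
  b <- random_model(p = 6, expected_degree = 2, n_latent = 1, seed = 9)
  expect_identical(a$edges, b$edges)
})

test_that("cyclic specs are rejected", {
  expect_error(
    simulation_spec(c("X", "Y"),
                    data.frame(from = c("X", "Y"), to = c("Y", "X"), coef = c(1, 1))),
    class = "causalpaths_cyclic")
})

test_that("simulation specs round-trip through YAML", {
  spec <- build_published_model(n = 50, seed = 3)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_sim_spec(spec, path)
  back <- read_sim_spec(path)
  expect_equal(back$edges, spec$edges)
  expect_equal(back$nodes$name, spec$nodes$name)
  expect_identical(simulate(back), simulate(spec))
})
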