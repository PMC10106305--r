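test_that("partial correlation matches the regression-residual oracle", {
  d <- simulate(chain_spec(1e5, b = 0.9, seed = 31))
  r_pkg <- partial_correlation(d, "X", "Z", "Y")
  # independent oracle: correlation of OLS residuals
  rx <- residuals(lm(X ~ Y, data = d))
  rz <- residuals(lm(Z ~ Y, data = d))
  expect_equal(r_pkg, cor(rx, rz), tolerance = 1e-8)
  expect_lt(abs(r_pkg), 0.02)  # d-separated given the mediator
  # symmetry
  expect_equal(r_pkg, partial_correlation(d, "Z", "X", "Y"))
})

test_that("perfect and degenerate correlations behave", {
  d <- data.frame(x = rnorm(50))
  d$y <- d$x
  expect_equal(partial_correlation(d, "x", "y"), 1.0)
  res <- fisher_z_test(d, "x", "y")
  expect_equal(res$p, 0)
  expect_false(res$independent)
})

test_that("Fisher-Z statistic and p-value match direct evaluation", {
  # contrived data with exact r = 0.3 at n = 100 given one conditioning column
  # checked against the closed form z = atanh(r) sqrt(n - |S| - 3)
  n <- 100
  set.seed(5)
  x <- rnorm(n); s <- rnorm(n)
  y0 <- rnorm(n)
  # construct y with exact partial correlation 0.3 with x given s
  rx <- residuals(lm(x ~ s))
  ry <- residuals(lm(y0 ~ s + rx))
  rxs <- rx / sd(rx); rys <- ry / sd(ry)
  y <- 0.3 * rxs + sqrt(1 - 0.09) * rys
  d <- data.frame(x = x, y = y, s = s)
  res <- fisher_z_test(d, "x", "y", "s")
  expect_equal(res$r, 0.3, tolerance = 1e-10)
  expect_equal(res$z, 3.0326604, tolerance = 1e-4)
  expect_equal(res$p, 0.0024241, tolerance = 1e-4)
  expect_false(res$independent)  # dependent at alpha = 0.01
})

test_that("exactly orthogonal columns give z = 0, p = 1", {
  d <- data.frame(x = rep(c(1, -1), 10), y = rep(c(1, 1, -1, -1), 5))
  res <- fisher_z_test(d, "x", "y")
  expect_equal(res$r, 0)
  expect_equal(res$z, 0)
  expect_equal(res$p, 1)
  expect_true(res$independent)
})

test_that("the test decision is invariant to affine rescaling", {
  d <- simulate(chain_spec(2000, seed = 7))
  base <- fisher_z_test(d, "X", "Z", "Y")
  d2 <- d
  d2$X <- 100 * d2$X - 7
  d2$Z <- -0.01 * d2$Z + 3
  res <- fisher_z_test(d2, "X", "Z", "Y")
  expect_equal(res$p, base$p, tolerance = 1e-9)
  expect_equal(res$independent, base$independent)
})

test_that("SEM-BIC local score penalises useless parents and rewards real ones", {
  n <- 1e5
  spec <- simulation_spec(c("U", "V", "W"),
                          data.frame(from = "U", to = "V", coef = 0.77),
                          n = n, seed = 13)
  d <- simulate(spec)
  # W is independent of V: adding it should cost about c * log(n)
  delta_junk <- sem_bic_local(d, "V", c("U", "W")) - sem_bic_local(d, "V", "U")
  expect_lt(delta_junk, 0)
  expect_lt(abs(delta_junk + log(n)), 10)
  # U is a real parent: likelihood gain ~ n * log(1 + 0.77^2) dwarfs the penalty
  delta_real <- sem_bic_local(d, "V", "U") - sem_bic_local(d, "V")
  expect_gt(delta_real, 0.9 * n * log(1 + 0.77^2) - 100)
})

test_that("score with no parents instantiates the definition", {
  n <- 1e4
  set.seed(2)
  d <- data.frame(x = as.numeric(scale(rnorm(n))))
  s2 <- var(d$x)
  expect_equal(sem_bic_local(d, "x"), -n * log(s2) - log(n), tolerance = 1e-8)
})

test_that("the graph score decomposes over local scores", {
  d <- simulate(collider_spec(3000, seed = 17))
  st <- causalpaths:::gauss_stats(d)
  scorer <- causalpaths:::make_scorer(st, 1)
  # DAG X -> Z <- Y
  total <- scorer(3, c(1, 2)) + scorer(1, integer(0)) + scorer(2, integer(0))
  by_hand <- sem_bic_local(d, "Z", c("X", "Y")) + sem_bic_local(d, "X") +
    sem_bic_local(d, "Y")
  expect_equal(total, by_hand)
})
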