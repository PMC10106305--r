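test_that("pag_to_sem maps edge types to paths and covariances", {
  directed <- mixed_graph(c("X", "Y"), edges = data.frame(from = "X", to = "Y", type = "-->"))
  s1 <- pag_to_sem(directed)
  expect_equal(nrow(s1$paths), 1)
  expect_equal(nrow(s1$covs), 0)

  circles <- mixed_graph(c("X", "Y"), edges = data.frame(from = "X", to = "Y", type = "o-o"))
  s2 <- pag_to_sem(circles)
  expect_equal(nrow(s2$paths), 0)
  expect_equal(nrow(s2$covs), 1)

  empty <- mixed_graph(c("X", "Y", "Z"))
  s3 <- pag_to_sem(empty)
  expect_equal(nrow(s3$paths) + nrow(s3$covs), 0)
})

test_that("a saturated model reproduces the sample covariance", {
  d <- simulate(chain_spec(2000, seed = 61))
  spec <- sem_spec(c("X", "Y", "Z"),
                   paths = data.frame(from = c("X", "Y"), to = c("Y", "Z")),
                   covs = data.frame(a = "X", b = "Z"))
  fit <- fit_sem(spec, d)
  expect_equal(fit$df, 0)
  expect_lt(fit$chisq, 1e-4)
  fi <- fit_indices(fit, fit$baseline)
  expect_equal(fi$cfi, 1)
  expect_equal(fi$rmsea, 0)
  expect_true(fi$saturated)
})

test_that("the independence model matches its closed-form discrepancy", {
  d <- simulate(collider_spec(3000, seed = 62))
  fit <- fit_sem(sem_spec(names(d)), d, baseline = FALSE)
  # F for a diagonal Sigma with free variances is -log|R| (R = sample correlation)
  R <- cor(as.matrix(d))
  expect_equal(fit$discrepancy, -determinant(R, logarithm = TRUE)$modulus[1],
               ignore_attr = TRUE, tolerance = 1e-6)
})

test_that("ML path estimates on a recursive model equal OLS", {
  spec <- build_published_model(n = 5000, seed = 63)
  d <- simulate(spec)
  fit <- fit_sem(sem_spec(names(d), paths = spec$edges[, 1:2]), d, baseline = FALSE)
  est <- tidy(fit)
  # independent oracle: equation-by-equation least squares
  for (v in unique(spec$edges$to)) {
    pa <- spec$edges$from[spec$edges$to == v]
    ols <- coef(lm(stats::reformulate(pa, v), data = d))[pa]
    got <- est$estimate[est$op == "path" & est$to == v]
    names(got) <- est$from[est$op == "path" & est$to == v]
    expect_equal(got[pa], ols, tolerance = 1e-3, ignore_attr = TRUE)
  }
})

test_that("generating coefficients are recovered within sampling error", {
  spec <- build_published_model(n = 1e5, seed = 64)
  d <- simulate(spec)
  fit <- fit_sem(sem_spec(names(d), paths = spec$edges[, 1:2]), d)
  est <- tidy(fit)
  for (i in seq_len(nrow(spec$edges))) {
    got <- est$estimate[est$op == "path" &
                          est$from == spec$edges$from[i] &
                          est$to == spec$edges$to[i]]
    expect_lt(abs(got - spec$edges$coef[i]), 0.02)
  }
  expect_gte(fit$cfi, 0.99)
  expect_lte(fit$rmsea, 0.01)
  # raw and standardized agree if all variances were 1; here they differ
  expect_true(fit$converged)
})

test_that("fit is invariant to data column order", {
  spec <- build_published_model(n = 3000, seed = 65)
  d <- simulate(spec)
  s <- sem_spec(names(d), paths = spec$edges[, 1:2])
  f1 <- fit_sem(s, d, baseline = FALSE)
  f2 <- fit_sem(s, d[, rev(names(d))], baseline = FALSE)
  expect_equal(tidy(f1)$estimate, tidy(f2)$estimate, tolerance = 1e-6)
  expect_equal(f1$chisq, f2$chisq, tolerance = 1e-6)
})

test_that("nested comparison reproduces the chi-square difference test", {
  d <- simulate(chain_spec(2000, seed = 66))
  full <- fit_sem(sem_spec(c("X", "Y", "Z"),
                           paths = data.frame(from = c("X", "Y"), to = c("Y", "Z"))),
                  d, baseline = FALSE)
  expect_equal(compare_nested(full, full)$p.value, 1)

  restricted <- fit_sem(sem_spec(c("X", "Y", "Z"),
                                 paths = data.frame(from = "X", to = "Y")),
                        d, baseline = FALSE)
  cmp <- compare_nested(restricted, full)
  expect_equal(cmp$df_diff, 1)
  expect_lt(cmp$p.value, 1e-10)  # the Y -> Z path is real
  # frozen chi-square tail: Delta chi2 = 10 on 1 df
  expect_equal(stats::pchisq(10, 1, lower.tail = FALSE), 0.001565402,
               tolerance = 1e-6)
})

test_that("directed paths beat a covariance-only variant on path-generated data", {
  spec <- build_published_model(n = 1e4, seed = 67)
  d <- simulate(spec)
  path_fit <- fit_sem(sem_spec(names(d), paths = spec$edges[, 1:2]), d, baseline = FALSE)
  cov_fit <- fit_sem(sem_spec(names(d),
                              covs = data.frame(a = spec$edges$from, b = spec$edges$to)),
                     d, baseline = FALSE)
  expect_lt(path_fit$chisq, cov_fit$chisq)
  # the better-fitting direction analogue of the reported sensitivity test
  expect_lt(pchisq(cov_fit$chisq - path_fit$chisq, 1, lower.tail = FALSE), 1e-4)
})

test_that("unidentified and non-nested inputs are refused", {
  set.seed(68)
  d <- data.frame(x = rnorm(100), y = rnorm(100))
  over <- sem_spec(c("x", "y"),
                   paths = data.frame(from = "x", to = "y"),
                   covs = data.frame(a = "x", b = "y"))
  expect_error(fit_sem(over, d), class = "causalpaths_not_identified")

  f1 <- fit_sem(sem_spec(c("x", "y")), d, baseline = FALSE)
  d2 <- data.frame(x = rnorm(50), y = rnorm(50))
  f2 <- fit_sem(sem_spec(c("x", "y")), d2, baseline = FALSE)
  expect_error(compare_nested(f1, f2), class = "causalpaths_not_nested")
})
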