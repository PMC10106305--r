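# Statistical primitives for both search stages: the penalised Gaussian
# likelihood (SEM-BIC) local score for the greedy stage and the Fisher-Z
# partial-correlation test for the constraint-based refinement.
#
# Both operate on sufficient statistics (covariance matrix + n), so large-n
# runs cost no more than small-n runs once the covariance is computed.

#' Search and test parameters
#'
#' @param alpha Significance level of the Fisher-Z conditional-independence
#'   test (default 0.01, the reference configuration).
#' @param penalty_discount Multiplier `c` on the BIC complexity penalty
#'   (default 1).
#' @param max_cond_size Largest conditioning-set size tried during adjacency
#'   pruning; `Inf` means unlimited.
#' @param pdsep_max Largest conditioning-set size tried inside the
#'   Possible-D-Sep stage; `Inf` means unlimited.
#' @return An `analysis_params` object.
#' @export
analysis_params <- function(alpha = 0.01, penalty_discount = 1,
                            max_cond_size = Inf, pdsep_max = Inf) {
  stopifnot(alpha > 0, alpha < 1, penalty_discount > 0)
  structure(list(alpha = alpha, penalty_discount = penalty_discount,
                 max_cond_size = max_cond_size, pdsep_max = pdsep_max),
            class = c("analysis_params", "list"))
}

# sufficient statistics
gauss_stats <- function(data) {
  m <- as.matrix(data)
  if (!is.numeric(m)) {
    rlang::abort("All analysis columns must be numeric.", class = "causalpaths_bad_data")
  }
  if (anyNA(m)) {
    rlang::abort("Data contain missing values; apply complete_case_filter() first.",
                 class = "causalpaths_bad_data")
  }
  list(S = stats::cov(m), n = nrow(m), vars = colnames(m))
}

# partial correlation from a covariance matrix via the precision sub-matrix;
# the marginal case needs no inversion (and tolerates |r| = 1)
pcor_from_cov <- function(S, i, j, cond) {
  if (length(cond) == 0L) {
    r <- S[i, j] / sqrt(S[i, i] * S[j, j])
    return(max(-1, min(1, r)))
  }
  idx <- c(i, j, cond)
  sub <- S[idx, idx, drop = FALSE]
  P <- tryCatch(solve(sub), error = function(e) NULL)
  if (is.null(P) || !all(is.finite(P))) {
    rlang::abort("Covariance sub-matrix is singular (collinear inputs).",
                 class = "causalpaths_singular")
  }
  r <- -P[1, 2] / sqrt(P[1, 1] * P[2, 2])
  max(-1, min(1, r))
}

#' Sample partial correlation
#'
#' Partial correlation of `x` and `y` given the conditioning set `S`, computed
#' by inverting the covariance sub-matrix (precision-matrix formula).
#'
#' @param data Data frame of numeric columns.
#' @param x,y Column names.
#' @param S Character vector of conditioning column names (possibly empty).
#' @return A number in `[-1, 1]`.
#' @export
partial_correlation <- function(data, x, y, S = character()) {
  st <- gauss_stats(data)
  i <- match(c(x, y, S), st$vars)
  if (anyNA(i)) {
    rlang::abort("Unknown column name(s).", class = "causalpaths_unknown_node")
  }
  pcor_from_cov(st$S, i[1], i[2], i[-(1:2)])
}

citest_from_stats <- function(S, n, i, j, cond, alpha) {
  r <- pcor_from_cov(S, i, j, cond)
  df <- n - length(cond) - 3
  if (abs(r) >= 1) {
    z <- Inf; p <- 0
  } else {
    z <- 0.5 * log((1 + r) / (1 - r)) * sqrt(df)
    p <- 2 * stats::pnorm(abs(z), lower.tail = FALSE)
  }
  list(r = r, z = z, p = p, independent = p > alpha)
}

#' Fisher-Z conditional-independence test
#'
#' Transforms the sample partial correlation `r` of `x, y | S` to
#' `z = 1/2 log((1+r)/(1-r)) sqrt(n - |S| - 3)` and compares it to a standard
#' normal; independence is declared when the two-sided p-value exceeds
#' `alpha`.
#'
#' @inheritParams partial_correlation
#' @param params An [analysis_params()] (supplies `alpha`).
#' @return A one-row tibble: `x`, `y`, `cond`, `r`, `z`, `p`, `independent`,
#'   `n`.
#' @export
fisher_z_test <- function(data, x, y, S = character(), params = analysis_params()) {
  st <- gauss_stats(data)
  idx <- match(c(x, y, S), st$vars)
  if (anyNA(idx)) {
    rlang::abort("Unknown column name(s).", class = "causalpaths_unknown_node")
  }
  if (st$n <= length(S) + 3) {
    rlang::abort("Need n > |S| + 3 observations for the Fisher-Z test.",
                 class = "causalpaths_bad_data")
  }
  res <- citest_from_stats(st$S, st$n, idx[1], idx[2], idx[-(1:2)], params$alpha)
  tibble::tibble(x = x, y = y, cond = paste(S, collapse = ","),
                 r = res$r, z = res$z, p = res$p,
                 independent = res$independent, n = st$n)
}

# local SEM-BIC score from sufficient statistics; -Inf flags a degenerate
# (zero residual variance) local model
score_local_stats <- function(S, n, y, parents, c_pen) {
  if (length(parents) == 0L) {
    s2 <- S[y, y]
  } else {
    Sxx <- S[parents, parents, drop = FALSE]
    Sxy <- S[parents, y]
    b <- tryCatch(solve(Sxx, Sxy), error = function(e) NULL)
    if (is.null(b)) return(-Inf)
    s2 <- S[y, y] - sum(Sxy * b)
  }
  if (!is.finite(s2) || s2 <= .Machine$double.eps * S[y, y]) return(-Inf)
  -n * log(s2) - c_pen * (length(parents) + 1) * log(n)
}

#' Local penalised Gaussian likelihood (SEM-BIC) score
#'
#' The decomposable score used by the greedy stage:
#' `-n log(sigma2_hat) - c (|parents| + 1) log(n)`, where `sigma2_hat` is the
#' residual variance of `node` regressed on `parents` and `c` is the penalty
#' discount.  Constant terms that cancel in score differences are dropped.  A
#' graph's total score is the sum of its local scores.
#'
#' @param data Data frame of numeric columns.
#' @param node Target column name.
#' @param parents Character vector of parent column names.
#' @param params An [analysis_params()] (supplies `penalty_discount`).
#' @return The local score (`-Inf` when the residual variance is degenerate).
#' @export
sem_bic_local <- function(data, node, parents = character(),
                          params = analysis_params()) {
  st <- gauss_stats(data)
  i <- match(c(node, parents), st$vars)
  if (anyNA(i)) {
    rlang::abort("Unknown column name(s).", class = "causalpaths_unknown_node")
  }
  score_local_stats(st$S, st$n, i[1], i[-1], params$penalty_discount)
}

# memoised local score over a fixed stats object
make_scorer <- function(stats, c_pen) {
  cache <- new.env(parent = emptyenv(), hash = TRUE)
  S <- stats$S; n <- stats$n
  function(y, parents) {
    key <- paste0(y, "|", paste(sort(parents), collapse = ","))
    got <- cache[[key]]
    if (!is.null(got)) return(got)
    val <- score_local_stats(S, n, y, parents, c_pen)
    cache[[key]] <- val
    val
  }
}
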