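# Linear SEM estimation on a learned PAG.
#
# Fully directed edges become free regression paths; edges with a circle
# endpoint or bidirected edges are treated as disturbance covariances
# (a possible latent common cause licenses covariation, not a direction).
# Fitting minimises the ML discrepancy
#   F = log|Sigma(theta)| + tr(S Sigma(theta)^-1) - log|S| - p
# with an analytic gradient; chi-square = (n - 1) * F at the optimum
# (Wishart convention), CFI and RMSEA follow from the model and
# independence-baseline chi-squares.

#' Convert a PAG to a linear SEM specification
#'
#' Fully directed edges (tail -> arrow) become free regression paths; every
#' other edge (any circle endpoint, bidirected, undirected) becomes a free
#' covariance between the two variables' disturbances.  Every variable gets a
#' free residual variance.
#'
#' @param pag A `mixed_graph` (typically from [gfci()]) passing
#'   [validate_pag()].
#' @return A `sem_spec` with fields `vars`, `paths` (tibble `from`, `to`) and
#'   `covs` (tibble `a`, `b`).
#' @export
pag_to_sem <- function(pag) {
  ed <- tidy(pag)
  paths <- ed[ed$type == "-->", c("from", "to")]
  covs <- ed[ed$type != "-->", c("from", "to")]
  names(covs) <- c("a", "b")
  spec <- structure(list(vars = pag$nodes,
                         paths = tibble::as_tibble(paths),
                         covs = tibble::as_tibble(covs)),
                    class = c("sem_spec", "list"))
  if (sem_has_cycle(spec)) {
    rlang::abort("Directed part of the SEM has a cycle.", class = "causalpaths_cyclic")
  }
  spec
}

#' Build a SEM specification directly
#'
#' @param vars Character vector of observed variables.
#' @param paths Data frame `from`, `to` of free regression paths (acyclic).
#' @param covs Optional data frame `a`, `b` of free disturbance covariances.
#' @return A `sem_spec`.
#' @export
sem_spec <- function(vars, paths = NULL, covs = NULL) {
  paths <- if (is.null(paths)) tibble::tibble(from = character(), to = character())
           else tibble::as_tibble(as.data.frame(paths))[, c("from", "to")]
  covs <- if (is.null(covs)) tibble::tibble(a = character(), b = character())
          else tibble::as_tibble(stats::setNames(as.data.frame(covs)[, 1:2], c("a", "b")))
  miss <- setdiff(c(paths$from, paths$to, covs$a, covs$b), vars)
  if (length(miss)) {
    rlang::abort(paste0("Unknown variable(s): ", paste(miss, collapse = ", ")),
                 class = "causalpaths_unknown_node")
  }
  spec <- structure(list(vars = as.character(vars), paths = paths, covs = covs),
                    class = c("sem_spec", "list"))
  if (sem_has_cycle(spec)) {
    rlang::abort("`paths` contain a directed cycle.", class = "causalpaths_cyclic")
  }
  spec
}

sem_has_cycle <- function(spec) {
  nm <- spec$vars
  indeg <- stats::setNames(integer(length(nm)), nm)
  tab <- table(spec$paths$to)
  indeg[names(tab)] <- as.integer(tab)
  done <- 0L
  avail <- nm[indeg == 0]
  edges <- spec$paths
  while (length(avail)) {
    v <- avail[1L]; avail <- avail[-1L]; done <- done + 1L
    for (w in edges$to[edges$from == v]) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) avail <- c(avail, w)
    }
  }
  done < length(nm)
}

#' @export
print.sem_spec <- function(x, ...) {
  cat(sprintf("<sem_spec> %d variables, %d paths, %d covariances\n",
              length(x$vars), nrow(x$paths), nrow(x$covs)))
  invisible(x)
}

# internal: fit by ML given the sample covariance S (divisor n - 1) and n
sem_fit_internal <- function(spec, S, n, max_iter = 10000, tol = 1e-9) {
  vars <- spec$vars
  p <- length(vars)
  S <- S[vars, vars, drop = FALSE]
  npath <- nrow(spec$paths)
  ncov <- nrow(spec$covs)
  npar <- npath + ncov + p
  if (npar > p * (p + 1) / 2) {
    rlang::abort("Model has more parameters than covariance moments (not identified).",
                 class = "causalpaths_not_identified")
  }
  pi_ <- match(spec$paths$to, vars)    # row (child)
  pj_ <- match(spec$paths$from, vars)  # col (parent)
  ca_ <- match(spec$covs$a, vars)
  cb_ <- match(spec$covs$b, vars)

  build <- function(theta) {
    B <- matrix(0, p, p)
    if (npath) B[cbind(pi_, pj_)] <- theta[seq_len(npath)]
    Psi <- diag(theta[npath + ncov + seq_len(p)], p)
    if (ncov) {
      v <- theta[npath + seq_len(ncov)]
      Psi[cbind(ca_, cb_)] <- Psi[cbind(ca_, cb_)] + v
      Psi[cbind(cb_, ca_)] <- Psi[cbind(cb_, ca_)] + v
    }
    list(B = B, Psi = Psi)
  }
  ldS <- determinant(S, logarithm = TRUE)$modulus[1]

  fml <- function(theta) {
    bp <- build(theta)
    A <- tryCatch(solve(diag(p) - bp$B), error = function(e) NULL)
    if (is.null(A)) return(1e10)
    Sigma <- A %*% bp$Psi %*% t(A)
    ch <- tryCatch(chol(Sigma), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    ldSig <- 2 * sum(log(diag(ch)))
    tr <- sum(diag(chol2inv(ch) %*% S))
    ldSig + tr - ldS - p
  }
  gml <- function(theta) {
    bp <- build(theta)
    A <- tryCatch(solve(diag(p) - bp$B), error = function(e) NULL)
    if (is.null(A)) return(rep(0, npar))
    Sigma <- A %*% bp$Psi %*% t(A)
    ch <- tryCatch(chol(Sigma), error = function(e) NULL)
    if (is.null(ch)) return(rep(0, npar))
    Si <- chol2inv(ch)
    G <- Si - Si %*% S %*% Si
    grad <- numeric(npar)
    if (npath) {
      SGA <- Sigma %*% G %*% A
      grad[seq_len(npath)] <- 2 * SGA[cbind(pj_, pi_)]
    }
    AGA <- t(A) %*% G %*% A
    if (ncov) grad[npath + seq_len(ncov)] <- 2 * AGA[cbind(ca_, cb_)]
    grad[npath + ncov + seq_len(p)] <- diag(AGA)
    grad
  }

  # start values: OLS per equation, sample (co)variances for the rest
  theta0 <- numeric(npar)
  resid_var <- diag(S)
  for (v in seq_len(p)) {
    pa <- pj_[pi_ == v]
    if (length(pa)) {
      b <- solve(S[pa, pa, drop = FALSE], S[pa, v])
      theta0[which(pi_ == v)] <- b[match(pj_[pi_ == v], pa)]
      resid_var[v] <- max(S[v, v] - sum(S[pa, v] * b), 0.05 * S[v, v])
    }
  }
  theta0[npath + ncov + seq_len(p)] <- resid_var
  if (ncov) theta0[npath + seq_len(ncov)] <- 0

  opt <- stats::optim(theta0, fml, gml, method = "BFGS",
                      control = list(maxit = max_iter, reltol = tol))
  theta <- opt$par
  Fmin <- opt$value
  converged <- opt$convergence == 0 && Fmin < 1e9
  bp <- build(theta)
  A <- solve(diag(p) - bp$B)
  Sigma <- A %*% bp$Psi %*% t(A)
  dimnames(Sigma) <- list(vars, vars)

  # standard errors from the (numeric) Hessian of F
  se <- rep(NA_real_, npar)
  H <- tryCatch(stats::optimHess(theta, fml, gml), error = function(e) NULL)
  if (!is.null(H)) {
    V <- tryCatch(2 / (n - 1) * solve(H), error = function(e) NULL)
    if (!is.null(V)) {
      dv <- diag(V)
      se[dv > 0] <- sqrt(dv[dv > 0])
    }
  }

  sds <- sqrt(diag(Sigma))
  est <- list()
  if (npath) {
    est[[length(est) + 1L]] <- tibble::tibble(
      term = paste(spec$paths$from, "->", spec$paths$to),
      op = "path", from = spec$paths$from, to = spec$paths$to,
      estimate = theta[seq_len(npath)], std.error = se[seq_len(npath)],
      std.estimate = theta[seq_len(npath)] * sds[pj_] / sds[pi_])
  }
  if (ncov) {
    est[[length(est) + 1L]] <- tibble::tibble(
      term = paste(spec$covs$a, "<->", spec$covs$b),
      op = "covariance", from = spec$covs$a, to = spec$covs$b,
      estimate = theta[npath + seq_len(ncov)],
      std.error = se[npath + seq_len(ncov)],
      std.estimate = theta[npath + seq_len(ncov)] / (sds[ca_] * sds[cb_]))
  }
  est[[length(est) + 1L]] <- tibble::tibble(
    term = paste0("var(", vars, ")"), op = "variance", from = vars, to = vars,
    estimate = theta[npath + ncov + seq_len(p)],
    std.error = se[npath + ncov + seq_len(p)],
    std.estimate = theta[npath + ncov + seq_len(p)] / sds[seq_len(p)]^2)

  chisq <- max((n - 1) * Fmin, 0)
  df <- p * (p + 1) / 2 - npar
  structure(list(
    spec = spec, estimates = dplyr::bind_rows(est),
    discrepancy = Fmin, chisq = chisq, df = df,
    p.value = if (df > 0) stats::pchisq(chisq, df, lower.tail = FALSE) else NA_real_,
    n = n, npar = npar, converged = converged,
    implied_cov = Sigma), class = c("sem_fit", "list"))
}

#' Fit a linear SEM by maximum likelihood
#'
#' @param spec A `sem_spec` (from [pag_to_sem()] or [sem_spec()]).
#' @param data Data frame containing at least the spec's variables; only the
#'   covariance matrix is used (mean structure omitted).
#' @param baseline Also fit the independence baseline (no paths, no
#'   covariances) and attach [fit_indices()] results.
#' @param max_iter,tol Optimiser budget and relative convergence tolerance on
#'   the discrepancy.
#' @return A `sem_fit`: parameter estimates (raw and standardized) with
#'   standard errors, the ML discrepancy, chi-square, df, and (when
#'   `baseline = TRUE`) CFI and RMSEA.  Inspect with [tidy()] and [glance()].
#' @examples
#' spec <- build_published_model(n = 5000, seed = 3)
#' dat <- simulate(spec)
#' fit <- fit_sem(sem_spec(names(dat), paths = spec$edges[, 1:2]), dat)
#' glance(fit)
#' @export
fit_sem <- function(spec, data, baseline = TRUE, max_iter = 10000, tol = 1e-9) {
  dat <- as.data.frame(data)[, spec$vars, drop = FALSE]
  st <- gauss_stats(dat)
  if (st$n <= length(spec$vars)) {
    rlang::abort("Need n > p observations.", class = "causalpaths_bad_data")
  }
  fit <- sem_fit_internal(spec, st$S, st$n, max_iter = max_iter, tol = tol)
  if (baseline) {
    base_spec <- sem_spec(spec$vars)
    base <- sem_fit_internal(base_spec, st$S, st$n, max_iter = max_iter, tol = tol)
    fi <- fit_indices(fit, base)
    fit$cfi <- fi$cfi
    fit$rmsea <- fi$rmsea
    fit$baseline <- base
  }
  fit
}

#' @export
print.sem_fit <- function(x, ...) {
  cat(sprintf("<sem_fit> chi-square = %.3f on %d df (n = %d)%s\n",
              x$chisq, x$df, x$n,
              if (!is.null(x$cfi)) sprintf(", CFI = %.3f, RMSEA = %.3f", x$cfi, x$rmsea) else ""))
  print(x$estimates)
  invisible(x)
}

#' @rdname fit_sem
#' @param x A `sem_fit`.
#' @param ... Unused.
#' @method tidy sem_fit
#' @export
tidy.sem_fit <- function(x, ...) x$estimates

#' @rdname fit_sem
#' @method glance sem_fit
#' @export
glance.sem_fit <- function(x, ...) {
  tibble::tibble(chisq = x$chisq, df = x$df, p.value = x$p.value,
                 cfi = x$cfi %||% NA_real_, rmsea = x$rmsea %||% NA_real_,
                 npar = x$npar, nobs = x$n, converged = x$converged)
}

#' Comparative fit index and RMSEA
#'
#' `CFI = 1 - max(chisq_m - df_m, 0) / max(chisq_b - df_b, chisq_m - df_m, 0)`
#' against the independence baseline, and
#' `RMSEA = sqrt(max(chisq_m - df_m, 0) / (df_m (n - 1)))`.  A saturated model
#' (`df = 0`) reports RMSEA 0 with `saturated = TRUE`.
#'
#' @param fit A `sem_fit`.
#' @param baseline The independence-model `sem_fit` on the same data.
#' @return A one-row tibble: `cfi`, `rmsea`, `saturated`.
#' @export
fit_indices <- function(fit, baseline) {
  dm <- fit$chisq - fit$df
  db <- baseline$chisq - baseline$df
  denom <- max(db, dm, 0)
  cfi <- if (denom <= 0) 1 else 1 - max(dm, 0) / denom
  cfi <- min(max(cfi, 0), 1)
  saturated <- fit$df == 0
  rmsea <- if (saturated) 0 else sqrt(max(dm, 0) / (fit$df * (fit$n - 1)))
  tibble::tibble(cfi = cfi, rmsea = rmsea, saturated = saturated)
}

#' Likelihood-ratio test of nested SEMs
#'
#' Chi-square difference test between two fits on identical data; the model
#' with larger df must be the restricted one.
#'
#' @param fit_a,fit_b `sem_fit` objects on the same data (`n` must match).
#' @return A one-row tibble: `chisq_diff`, `df_diff`, `p.value`.
#' @export
compare_nested <- function(fit_a, fit_b) {
  if (fit_a$n != fit_b$n) {
    rlang::abort("Fits are not on the same data (n differs).",
                 class = "causalpaths_not_nested")
  }
  if (fit_a$df == fit_b$df) {
    if (abs(fit_a$chisq - fit_b$chisq) < 1e-8) {
      return(tibble::tibble(chisq_diff = 0, df_diff = 0L, p.value = 1))
    }
    rlang::abort("Models have equal df and differing fit; not nested.",
                 class = "causalpaths_not_nested")
  }
  restricted <- if (fit_a$df > fit_b$df) fit_a else fit_b
  full <- if (fit_a$df > fit_b$df) fit_b else fit_a
  d_chi <- restricted$chisq - full$chisq
  d_df <- restricted$df - full$df
  if (d_chi < -1e-6) {
    rlang::abort("Restricted model fits better than the full model; models are inconsistent.",
                 class = "causalpaths_not_nested")
  }
  d_chi <- max(d_chi, 0)
  tibble::tibble(chisq_diff = d_chi, df_diff = d_df,
                 p.value = stats::pchisq(d_chi, d_df, lower.tail = FALSE))
}
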