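#' @title Maximum-likelihood covariance-structure estimation
#' @description The fitting engine behind the falls models: minimises
#'   the ML discrepancy between a sample covariance and the
#'   model-implied covariance, with chi-square, RMSEA/CFI fit indices,
#'   observed-information standard errors and Wald 95\% confidence
#'   intervals.
#' @name sem_fit
NULL

# F_ML and its analytic gradient in RAM form.
#
# F(theta) = log|Sigma| + tr(S Sigma^-1) - log|S| - p, Sigma as in
# implied_covariance(). With E = Sigma^-1 (Sigma - S) Sigma^-1,
# M = (I - A)^-1, C = M S_m M', and W the embedding of E into the full
# variable set: dF/dS_ij = G[i,j] (doubled off-diagonal) with
# G = M' W M, and dF/dA_ij = 2 (C W M)[j, i].
sem_objective_env <- function(model, S, logdet_S) {
  t_n <- length(model$vars)
  idx <- match(model$obs, model$vars)
  p <- length(idx)
  I_t <- diag(t_n)

  core <- function(theta) {
    m <- sem_matrices(model, theta)
    M <- tryCatch(solve(I_t - m$A), error = function(e) NULL)
    if (is.null(M)) return(NULL)
    C <- M %*% m$S %*% t(M)
    Sig <- (C[idx, idx, drop = FALSE] + t(C[idx, idx, drop = FALSE])) / 2
    ch <- tryCatch(chol(Sig), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    list(m = m, M = M, C = C, Sig = Sig, ch = ch)
  }

  fn <- function(theta) {
    k <- core(theta)
    if (is.null(k)) return(1e10 * (1 + sum(theta^2)))
    Sinv <- chol2inv(k$ch)
    2 * sum(log(diag(k$ch))) + sum(Sinv * S) - logdet_S - p
  }

  gr <- function(theta) {
    k <- core(theta)
    if (is.null(k)) return(2e10 * theta)
    Sinv <- chol2inv(k$ch)
    E <- Sinv - Sinv %*% S %*% Sinv
    W <- matrix(0, t_n, t_n)
    W[idx, idx] <- E
    G <- t(k$M) %*% W %*% k$M
    K <- k$C %*% W %*% k$M
    prm <- model$params
    g <- numeric(nrow(prm))
    for (q in seq_len(nrow(prm))) {
      i <- prm$row[q]
      j <- prm$col[q]
      g[q] <- if (prm$matrix[q] == "A") {
        2 * K[j, i]
      } else if (i == j) {
        G[i, i]
      } else {
        2 * G[i, j]
      }
    }
    g
  }

  list(fn = fn, gr = gr)
}

start_values <- function(model, S) {
  prm <- model$params
  start <- prm$start
  exo <- !model$endogenous
  vn <- model$vars
  for (q in seq_len(nrow(prm))) {
    if (prm$matrix[q] != "S") next
    a <- vn[prm$row[q]]
    b <- vn[prm$col[q]]
    both_obs <- a %in% model$obs && b %in% model$obs
    if (!both_obs) next
    if (exo[prm$row[q]] && exo[prm$col[q]]) {
      start[q] <- S[a, b] # exogenous block: ML solution is the sample value
    } else if (prm$row[q] == prm$col[q]) {
      start[q] <- 0.5 * S[a, a] # endogenous observed residual
    }
  }
  start
}

#' Fit a structural equation model by maximum likelihood
#'
#' Minimises `F_ML(theta) = log|Sigma(theta)| + tr(S Sigma^-1) - log|S|
#' - p` over the free parameters by quasi-Newton iteration with the
#' analytic RAM gradient; the model chi-square is `(N - 1) F_ML` at the
#' optimum. Standard errors come from the inverse of the numerically
#' evaluated Hessian (observed information) of `(N - 1)/2 F_ML`, and
#' 95\% confidence intervals are Wald (`estimate +- 1.96 SE`). A
#' near-singular sample covariance (condition number above
#' `ridge_threshold`, e.g. when the whole-field mean deviation is an
#' exact linear combination of the regional means) is regularised with
#' a logged ridge `S + eps tr(S)/p I` before fitting.
#'
#' After fitting, the sign indeterminacy of each latent is resolved by
#' flipping the latent so its first loading is non-negative; `F_ML` is
#' invariant under the flip.
#'
#' @param model a [sem_model()].
#' @param S sample covariance of the observed variables (dimnames must
#'   cover `model$obs`).
#' @param N number of subjects behind `S`.
#' @param start optional start values (defaults: loadings 0.5, paths 0,
#'   residual variances half the sample variance, exogenous variances
#'   and covariances at their sample values).
#' @param max_iter iteration cap for the optimiser.
#' @param grad_tol convergence tolerance on the gradient infinity norm.
#' @param ridge_threshold,ridge_eps singularity guard, see above.
#' @param se compute standard errors (disable for speed inside
#'   permutation loops).
#' @return An object of class `sem_fit`: the parameter table
#'   (`estimates`), `F_ml`, `chi_square`, `df`, `rmsea`, `cfi`,
#'   baseline statistics, `N`, convergence record and ridge flag.
#' @export
fit_ml <- function(model, S, N, start = NULL, max_iter = 500, grad_tol = 1e-8,
                   ridge_threshold = 1e10, ridge_eps = 1e-6, se = TRUE) {
  stopifnot(inherits(model, "sem_model"))
  p <- length(model$obs)
  if (is.null(dimnames(S))) stop("S must carry variable names")
  if (!all(model$obs %in% rownames(S))) {
    stop(
      "S lacks observed variable(s): ",
      paste(setdiff(model$obs, rownames(S)), collapse = ", ")
    )
  }
  S <- S[model$obs, model$obs, drop = FALSE]
  S <- (S + t(S)) / 2
  if (N <= p) stop("sample size N (", N, ") must exceed the ", p, " observed variables")
  q <- nrow(model$params)
  if (q > p * (p + 1) / 2) {
    stop("model has ", q, " free parameters but only ", p * (p + 1) / 2, " moments")
  }

  ridge <- FALSE
  kappa_S <- kappa(S, exact = TRUE)
  if (kappa_S > ridge_threshold) {
    S <- S + ridge_eps * sum(diag(S)) / p * diag(p)
    ridge <- TRUE
  }
  ch_S <- tryCatch(chol(S), error = function(e) {
    stop("sample covariance is not positive definite even after the ridge guard")
  })
  logdet_S <- 2 * sum(log(diag(ch_S)))

  obj <- sem_objective_env(model, S, logdet_S)
  if (is.null(start)) start <- start_values(model, S)
  # variance parameters are kept non-negative (a tiny positive floor,
  # scaled to the data); Heywood-type solutions land on the bound
  # instead of driving the implied covariance indefinite
  lower <- rep(-Inf, length(start))
  is_var <- model$params$matrix == "S" & model$params$row == model$params$col
  var_floor <- 1e-8 * sum(diag(S)) / p
  lower[is_var] <- var_floor
  start[is_var] <- pmax(start[is_var], var_floor)
  opt <- stats::nlminb(
    start, obj$fn, obj$gr,
    lower = lower,
    control = list(iter.max = max_iter, eval.max = 4 * max_iter)
  )
  # polish: a second pass from the optimum tightens the gradient norm
  opt2 <- stats::nlminb(
    opt$par, obj$fn, obj$gr,
    lower = lower,
    control = list(iter.max = max_iter, eval.max = 4 * max_iter)
  )
  if (opt2$objective <= opt$objective) opt <- opt2
  theta <- opt$par
  g_opt <- obj$gr(theta)
  # components pinned at the variance floor cannot move further down
  blocked <- is_var & (theta <= lower + 1e-10) & (g_opt > 0)
  gnorm <- if (all(blocked)) 0 else max(abs(g_opt[!blocked]))
  converged <- is.finite(gnorm) &&
    (gnorm < max(grad_tol, 1e-6 * (1 + abs(opt$objective))) || opt$convergence == 0)
  if (!converged && gnorm > 1e-3) {
    warning(
      "fit_ml did not reach the gradient tolerance (|grad|_inf = ",
      format(gnorm, digits = 3), ") after ", opt$iterations, " iterations"
    )
  }

  theta <- resolve_latent_signs(model, theta)
  F_ml <- obj$fn(theta)
  if (F_ml < 0 && F_ml > -1e-8) F_ml <- 0
  chi_square <- (N - 1) * F_ml
  df <- p * (p + 1) / 2 - q

  R <- stats::cov2cor(S)
  baseline_chi_square <- -(N - 1) * determinant(R, logarithm = TRUE)$modulus[1]
  baseline_df <- p * (p - 1) / 2
  fi <- fit_indices(chi_square, df, baseline_chi_square, baseline_df, N)

  ses <- rep(NA_real_, q)
  if (se) {
    H <- gradient_jacobian(obj$gr, theta)
    info <- (N - 1) / 2 * (H + t(H)) / 2
    cov_theta <- tryCatch(solve(info), error = function(e) NULL)
    if (!is.null(cov_theta)) {
      d <- diag(cov_theta)
      ses <- ifelse(d > 0, sqrt(pmax(d, 0)), NA_real_)
    }
    if (anyNA(ses)) {
      warning("observed information is singular or indefinite; some SEs are NA")
    }
  }

  est <- model$params[c("label", "type")]
  est$estimate <- theta
  est$se <- ses
  est$ci_lower <- theta - 1.96 * ses
  est$ci_upper <- theta + 1.96 * ses
  est$significant <- !is.na(ses) & (est$ci_lower > 0 | est$ci_upper < 0)

  structure(
    list(
      model = model, estimates = est, theta = theta,
      F_ml = F_ml, chi_square = chi_square, df = df,
      rmsea = fi$rmsea, cfi = fi$cfi, saturated = fi$saturated,
      baseline_chi_square = baseline_chi_square, baseline_df = baseline_df,
      N = N, S = S, ridge = ridge,
      convergence = list(
        iterations = opt$iterations, gradient_norm = gnorm,
        converged = converged
      )
    ),
    class = "sem_fit"
  )
}

# central-difference jacobian of the analytic gradient = Hessian of F_ML
gradient_jacobian <- function(gr, theta, h_rel = 1e-5) {
  q <- length(theta)
  H <- matrix(0, q, q)
  for (k in seq_len(q)) {
    h <- h_rel * (1 + abs(theta[k]))
    up <- theta
    dn <- theta
    up[k] <- up[k] + h
    dn[k] <- dn[k] - h
    H[, k] <- (gr(up) - gr(dn)) / (2 * h)
  }
  H
}

# flip each latent so that its first loading is non-negative
resolve_latent_signs <- function(model, theta) {
  prm <- model$params
  vn <- model$vars
  for (lv in model$latents) {
    li <- match(lv, vn)
    loads <- which(prm$matrix == "A" & prm$col == li & prm$type == "loading")
    first <- if (length(loads)) loads[1] else integer()
    if (length(first) && theta[first] < 0) {
      out_edges <- prm$matrix == "A" & prm$col == li # latent -> *
      in_edges <- prm$matrix == "A" & prm$row == li # * -> latent
      covs <- prm$matrix == "S" & xor(prm$row == li, prm$col == li)
      theta[out_edges | in_edges | covs] <- -theta[out_edges | in_edges | covs]
    }
  }
  theta
}

#' RMSEA and CFI fit indices
#'
#' `rmsea = sqrt(max(chi_square - df, 0) / (df (N - 1)))` — values below
#' 0.05 indicate close fit, 0.05 to 0.10 fair fit, above 0.10 poor fit.
#' `cfi = 1 - max(chi_square - df, 0) / max(baseline excess, model
#' excess, 0)` against the independence baseline (free variances, zero
#' covariances); values above 0.95 indicate good fit. A saturated model
#' (`df = 0`) has no approximation error to measure: RMSEA is reported
#' as 0 with `saturated = TRUE`.
#'
#' @param chi_square,df model chi-square and degrees of freedom.
#' @param chi_square_baseline,df_baseline independence-model statistics.
#' @param N sample size.
#' @return List with `rmsea`, `cfi`, `saturated`.
#' @export
fit_indices <- function(chi_square, df, chi_square_baseline, df_baseline, N) {
  stopifnot(chi_square >= -1e-8, df >= 0, N >= 2)
  saturated <- df == 0
  rmsea <- if (saturated) 0 else sqrt(max(chi_square - df, 0) / (df * (N - 1)))
  denom <- max(chi_square_baseline - df_baseline, chi_square - df, 0)
  cfi <- if (denom == 0) 1 else 1 - max(chi_square - df, 0) / denom
  list(rmsea = rmsea, cfi = cfi, saturated = saturated)
}

#' Fit a model to subject-level data
#'
#' Convenience wrapper: computes the sample covariance of the model's
#' observed variables and calls [fit_ml()].
#'
#' @param model a [sem_model()].
#' @param data data frame containing every observed variable.
#' @param ... passed on to [fit_ml()].
#' @return A `sem_fit`.
#' @export
fit_sem <- function(model, data, ...) {
  miss <- setdiff(model$obs, names(data))
  if (length(miss)) {
    stop("data lacks observed variable(s): ", paste(miss, collapse = ", "))
  }
  X <- as.matrix(data[model$obs])
  if (anyNA(X)) stop("observed variables contain missing values")
  fit_ml(model, stats::cov(X), nrow(X), ...)
}

#' @export
print.sem_fit <- function(x, digits = 3, ...) {
  cat(
    "<sem_fit> N = ", x$N, ", chi-square = ",
    format(x$chi_square, digits = digits), " on ", x$df,
    " df; RMSEA = ", format(x$rmsea, digits = digits),
    ", CFI = ", format(x$cfi, digits = digits),
    if (x$ridge) " (ridge applied)" else "", "\n",
    sep = ""
  )
  if (!x$convergence$converged) {
    cat(
      "  warning: gradient norm at stop ",
      format(x$convergence$gradient_norm, digits = 3), "\n",
      sep = ""
    )
  }
  invisible(x)
}
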