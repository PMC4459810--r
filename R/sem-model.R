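#' Specify a structural equation model
#'
#' Parses a small lavaan-style text syntax into a path model over
#' observed and latent variables, represented internally in RAM form:
#' a directed-coefficient matrix `A` (loadings and regressions) and a
#' symmetric matrix `S` (variances, residual variances and covariances)
#' over the combined variable vector, from which the model-implied
#' covariance of the observed variables is
#' `Sigma = F (I - A)^-1 S (I - A)^-T F'`.
#'
#' Syntax, one statement per line (`#` starts a comment):
#' \describe{
#'   \item{`lat =~ y1 + y2 + y3`}{measurement: `lat` is latent with the
#'     listed indicators; loadings are free unless fixed as `1*y1`.}
#'   \item{`y ~ x1 + x2`}{regression of `y` on the right-hand variables.}
#'   \item{`a ~~ b`}{free (co)variance; `a ~~ 0*a` fixes it.}
#' }
#'
#' Defaults after parsing: every endogenous variable gets a free
#' residual variance; every exogenous latent gets its variance fixed to
#' 1 (the identification convention used throughout — all loadings
#' free); exogenous observed variables get free variances and free
#' pairwise covariances (estimated at their sample values under ML).
#' The directed graph must be acyclic.
#'
#' @param spec character: the model syntax (single string or vector of
#'   lines).
#' @return An object of class `sem_model` with elements `obs`,
#'   `latents`, `A`, `S` (fixed-value matrices), and `params` (the
#'   free-parameter table: matrix, indices, label, type, start value).
#' @examples
#' m <- sem_model("
#'   f =~ y1 + y2 + y3
#' ")
#' m$params$label
#' @export
sem_model <- function(spec) {
  lines <- unlist(strsplit(paste(spec, collapse = "\n"), "\n", fixed = TRUE))
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]

  edges <- list() # directed: from, to, fixed (NA = free), origin
  covs <- list() # symmetric: a, b, fixed (NA = free)
  latents <- character()

  parse_rhs <- function(rhs) {
    terms <- trimws(unlist(strsplit(rhs, "+", fixed = TRUE)))
    lapply(terms, function(tm) {
      if (grepl("*", tm, fixed = TRUE)) {
        parts <- trimws(unlist(strsplit(tm, "*", fixed = TRUE)))
        if (length(parts) != 2 || is.na(suppressWarnings(as.numeric(parts[1])))) {
          stop("cannot parse term '", tm, "'")
        }
        list(var = parts[2], fixed = as.numeric(parts[1]))
      } else {
        list(var = tm, fixed = NA_real_)
      }
    })
  }

  for (ln in lines) {
    if (grepl("=~", ln, fixed = TRUE)) {
      parts <- trimws(unlist(strsplit(ln, "=~", fixed = TRUE)))
      if (length(parts) != 2) stop("cannot parse line '", ln, "'")
      latents <- union(latents, parts[1])
      for (tm in parse_rhs(parts[2])) {
        edges[[length(edges) + 1]] <- list(
          from = parts[1], to = tm$var, fixed = tm$fixed
        )
      }
    } else if (grepl("~~", ln, fixed = TRUE)) {
      parts <- trimws(unlist(strsplit(ln, "~~", fixed = TRUE)))
      if (length(parts) != 2) stop("cannot parse line '", ln, "'")
      for (tm in parse_rhs(parts[2])) {
        covs[[length(covs) + 1]] <- list(
          a = parts[1], b = tm$var, fixed = tm$fixed
        )
      }
    } else if (grepl("~", ln, fixed = TRUE)) {
      parts <- trimws(unlist(strsplit(ln, "~", fixed = TRUE)))
      if (length(parts) != 2) stop("cannot parse line '", ln, "'")
      for (tm in parse_rhs(parts[2])) {
        edges[[length(edges) + 1]] <- list(
          from = tm$var, to = parts[1], fixed = tm$fixed
        )
      }
    } else {
      stop("cannot parse line '", ln, "'")
    }
  }

  evars <- unique(unlist(lapply(edges, function(e) c(e$from, e$to))))
  cvars <- unique(unlist(lapply(covs, function(cv) c(cv$a, cv$b))))
  vars <- unique(c(evars, cvars))
  obs <- setdiff(vars, latents)
  vars <- c(obs, latents)
  t_n <- length(vars)
  if (t_n == 0) stop("empty model specification")

  A <- matrix(0, t_n, t_n, dimnames = list(vars, vars))
  S <- matrix(0, t_n, t_n, dimnames = list(vars, vars))
  A_free <- matrix(FALSE, t_n, t_n, dimnames = list(vars, vars))
  S_free <- matrix(FALSE, t_n, t_n, dimnames = list(vars, vars))
  S_set <- matrix(FALSE, t_n, t_n, dimnames = list(vars, vars))

  for (e in edges) {
    i <- match(e$to, vars)
    j <- match(e$from, vars)
    if (is.na(e$fixed)) A_free[i, j] <- TRUE else A[i, j] <- e$fixed
  }
  for (cv in covs) {
    i <- match(cv$a, vars)
    j <- match(cv$b, vars)
    S_set[i, j] <- S_set[j, i] <- TRUE
    if (is.na(cv$fixed)) {
      S_free[i, j] <- S_free[j, i] <- TRUE
    } else {
      S[i, j] <- S[j, i] <- cv$fixed
    }
  }

  # acyclicity of the directed part (topological elimination)
  adj <- A_free | (A != 0)
  remaining <- rep(TRUE, t_n)
  repeat {
    sinkless <- which(remaining & rowSums(adj[, remaining, drop = FALSE]) == 0)
    if (!length(sinkless)) break
    remaining[sinkless] <- FALSE
  }
  if (any(remaining)) {
    stop(
      "path model is cyclic through: ",
      paste(vars[remaining], collapse = ", ")
    )
  }

  endogenous <- rowSums(adj) > 0
  for (v in seq_len(t_n)) {
    if (S_set[v, v]) next
    if (endogenous[v]) {
      S_free[v, v] <- TRUE # residual variance
    } else if (vars[v] %in% latents) {
      S[v, v] <- 1 # exogenous latent: variance fixed for identification
    } else {
      S_free[v, v] <- TRUE # exogenous observed: variance at sample value
    }
  }
  exo_obs <- which(!endogenous & vars %in% obs)
  if (length(exo_obs) > 1) {
    for (a in exo_obs) {
      for (b in exo_obs) {
        if (a < b && !S_set[a, b]) S_free[a, b] <- S_free[b, a] <- TRUE
      }
    }
  }

  # identification: each latent needs a fixed variance or a fixed loading
  for (lv in latents) {
    i <- match(lv, vars)
    fixed_var <- !endogenous[i] && !S_free[i, i] && S[i, i] > 0
    fixed_load <- any(A[, i] != 0 & !A_free[, i])
    if (!fixed_var && !fixed_load) {
      stop("latent ", lv, " is not identified: fix its variance or a loading")
    }
  }

  params <- build_param_table(vars, latents, A_free, S_free)
  structure(
    list(
      obs = obs, latents = latents, vars = vars,
      A = A, S = S, A_free = A_free, S_free = S_free,
      endogenous = stats::setNames(endogenous, vars),
      params = params
    ),
    class = "sem_model"
  )
}

build_param_table <- function(vars, latents, A_free, S_free) {
  rows <- list()
  for (j in seq_along(vars)) {
    for (i in seq_along(vars)) {
      if (A_free[i, j]) {
        type <- if (vars[j] %in% latents && !(vars[i] %in% latents)) "loading" else "path"
        rows[[length(rows) + 1]] <- data.frame(
          matrix = "A", row = i, col = j,
          label = paste0(vars[i], if (type == "loading") "<~" else "~", vars[j]),
          type = type,
          start = if (type == "loading") 0.5 else 0,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  for (j in seq_along(vars)) {
    for (i in j:length(vars)) {
      if (S_free[i, j]) {
        type <- if (i == j) "variance" else "covariance"
        rows[[length(rows) + 1]] <- data.frame(
          matrix = "S", row = i, col = j,
          label = paste0(vars[i], "~~", vars[j]),
          type = type,
          start = if (type == "variance") 0.5 else 0,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  # lavaan-style labels: indicator<~latent printed as latent=~indicator
  out <- do.call(rbind, rows)
  fix <- out$type == "loading"
  out$label[fix] <- vapply(which(fix), function(k) {
    paste0(vars[out$col[k]], "=~", vars[out$row[k]])
  }, character(1))
  rownames(out) <- NULL
  out
}

#' @export
print.sem_model <- function(x, ...) {
  cat(
    "<sem_model> ", length(x$obs), " observed, ", length(x$latents),
    " latent, ", nrow(x$params), " free parameters\n",
    sep = ""
  )
  invisible(x)
}

# place free-parameter values into the A and S matrices
sem_matrices <- function(model, theta) {
  stopifnot(length(theta) == nrow(model$params))
  A <- model$A
  S <- model$S
  p <- model$params
  for (k in seq_along(theta)) {
    if (p$matrix[k] == "A") {
      A[p$row[k], p$col[k]] <- theta[k]
    } else {
      S[p$row[k], p$col[k]] <- theta[k]
      S[p$col[k], p$row[k]] <- theta[k]
    }
  }
  list(A = A, S = S)
}

#' Model-implied covariance matrix
#'
#' Evaluates `Sigma(theta) = F (I - A)^-1 S (I - A)^-T F'` for a model
#' and a free-parameter vector: the covariance of the observed
#' variables implied by the measurement and structural equations.
#'
#' @param model a [sem_model()].
#' @param theta numeric vector of free-parameter values, in the order of
#'   `model$params`.
#' @return Symmetric `p x p` matrix over `model$obs`.
#' @export
implied_covariance <- function(model, theta) {
  stopifnot(inherits(model, "sem_model"))
  m <- sem_matrices(model, theta)
  t_n <- length(model$vars)
  IA <- diag(t_n) - m$A
  M <- tryCatch(solve(IA), error = function(e) {
    stop("(I - A) is singular: the path model is effectively cyclic")
  })
  C <- M %*% m$S %*% t(M)
  idx <- match(model$obs, model$vars)
  Sig <- C[idx, idx, drop = FALSE]
  dimnames(Sig) <- list(model$obs, model$obs)
  (Sig + t(Sig)) / 2
}
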