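# Covariate schema and design-matrix construction.
#
# Exactness of the distributed algorithm requires every site to build its
# design matrices column-for-column identically. The aggregator therefore
# broadcasts a covariate schema -- factor level dictionaries (treatment
# contrasts against the alphabetically first level) and global covariate
# ranges for smooth terms -- assembled during the setup round.

build_schema <- function(covariate_tables, covariates, smooth_covariates) {
  factors <- list()
  numerics <- character()
  ranges <- list()
  for (nm in covariates) {
    cols <- lapply(covariate_tables, function(tb) {
      if (!nm %in% names(tb)) stop("covariate '", nm, "' missing from a site")
      tb[[nm]]
    })
    is_fac <- any(vapply(cols, function(x)
      is.character(x) || is.factor(x) || is.logical(x), logical(1)))
    if (is_fac) {
      lv <- sort(unique(unlist(lapply(cols, function(x) as.character(x)))))
      factors[[nm]] <- lv
    } else {
      numerics <- c(numerics, nm)
    }
  }
  for (nm in smooth_covariates) {
    if (!is.null(factors[[nm]])) stop("smooth covariate '", nm, "' is categorical")
    rng <- range(unlist(lapply(covariate_tables, function(tb) tb[[nm]])))
    ranges[[nm]] <- rng
  }
  list(factors = factors, numerics = numerics, ranges = ranges)
}

# expand one covariate into design columns under the schema
covariate_columns <- function(nm, data, schema) {
  if (!nm %in% names(data)) stop("covariate '", nm, "' missing from data")
  x <- data[[nm]]
  if (!is.null(schema$factors[[nm]])) {
    lv <- schema$factors[[nm]]
    f <- factor(as.character(x), levels = lv)
    if (anyNA(f) && !anyNA(x)) {
      bad <- setdiff(unique(as.character(x)), lv)
      stop("unseen level(s) for '", nm, "': ", paste(bad, collapse = ", "))
    }
    if (length(lv) < 2) return(NULL)
    M <- stats::model.matrix(~ f)[, -1, drop = FALSE]
    colnames(M) <- paste0(nm, lv[-1])
    M
  } else {
    M <- matrix(as.numeric(x), ncol = 1)
    colnames(M) <- nm
    M
  }
}

# Full design for one distribution parameter. When a smooth is present its
# basis replaces the intercept (partition of unity spans the constant).
build_design <- function(pspec, data, schema, basis = NULL, clamp_warn = TRUE) {
  n <- nrow(data)
  blocks <- list()
  smooth_idx <- integer()
  if (!is.null(pspec$smooth)) {
    if (is.null(basis)) stop("smooth term present but no basis supplied")
    B <- if (clamp_warn) evaluate_basis(basis, data[[pspec$smooth$covariate]])
         else suppressWarnings(evaluate_basis(basis, data[[pspec$smooth$covariate]]))
    colnames(B) <- paste0("bs(", pspec$smooth$covariate, ")",
                          seq_len(ncol(B)))
    blocks[[length(blocks) + 1]] <- B
    smooth_idx <- seq_len(ncol(B))
  } else {
    blocks[[length(blocks) + 1]] <- matrix(1, n, 1,
                                           dimnames = list(NULL, "(Intercept)"))
  }
  for (nm in pspec$fixed) {
    M <- covariate_columns(nm, data, schema)
    if (!is.null(M)) blocks[[length(blocks) + 1]] <- M
  }
  X <- do.call(cbind, blocks)
  list(X = X, smooth_idx = smooth_idx, colnames = colnames(X))
}

# Penalty bookkeeping per parameter: matrix, smooth column indices, mode and
# current lambda. Fixed-effect smooths have lambda 0.
penalty_state <- function(pspec, q, smooth_idx) {
  if (is.null(pspec$smooth) || pspec$smooth$mode == "fixed") {
    return(list(mode = "none", lambda = 0, P = NULL, smooth_idx = smooth_idx,
                target_edf = NULL))
  }
  sm <- pspec$smooth
  P <- difference_penalty(length(smooth_idx), sm$order)
  list(mode = sm$mode,
       lambda = if (!is.null(sm$lambda)) sm$lambda else 0,
       P = P, smooth_idx = smooth_idx,
       target_edf = sm$edf)
}

# penalized symmetric positive-definite solve shared by the pooled WLS and
# the aggregator; ridge jitter guards near-singular systems
solve_penalized <- function(M1, M2, pen, lambda = NULL) {
  q <- ncol(M1)
  A <- M1
  if (!is.null(pen$P) && length(pen$smooth_idx)) {
    lam <- if (is.null(lambda)) pen$lambda else lambda
    if (lam > 0) {
      A <- A + lam * embed_penalty(pen$P, q, pen$smooth_idx)
    }
  }
  ch <- try(chol(A), silent = TRUE)
  if (inherits(ch, "try-error")) {
    A <- A + diag(1e-10 * mean(diag(A)), q)
    ch <- try(chol(A), silent = TRUE)
    if (inherits(ch, "try-error")) {
      stop("Design for this parameter is rank deficient beyond the ridge ",
           "safeguard; check for collinear columns (",
           paste(colnames(M1), collapse = ", "), ")")
    }
  }
  drop(backsolve(ch, forwardsolve(t(ch), M2)))
}

#' Adjusted dependent variable
#'
#' The working response of the Newton-Raphson step:
#' \eqn{z = \eta + u / w}, turning each update into a weighted least-squares
#' solve with weights `w`.
#'
#' @param eta Linear predictor vector.
#' @param scores List with score `u` and positive weights `w`
#'   (from [score_and_weights()]).
#' @return Numeric vector `z`.
#' @export
adjusted_dependent <- function(eta, scores) {
  eta + scores$u / scores$w
}

#' Penalized weighted least squares
#'
#' Solves \eqn{(X^\top W X + \lambda \tilde P) b = X^\top W z} by a
#' symmetric positive-definite (Cholesky) solve, with a small ridge jitter if
#' the penalized system is numerically singular.
#'
#' @param X Design matrix for one distribution parameter.
#' @param w Positive weight vector.
#' @param z Adjusted dependent vector.
#' @param penalty Optional list with `P`, `smooth_idx`, `lambda` (as produced
#'   internally; `NULL` means unpenalized).
#' @return Coefficient vector.
#' @export
wls_solve <- function(X, w, z, penalty = NULL) {
  M1 <- crossprod(X, X * w)
  M2 <- drop(crossprod(X, w * z))
  if (is.null(penalty)) penalty <- list(P = NULL, smooth_idx = integer(), lambda = 0)
  solve_penalized(M1, M2, penalty)
}
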