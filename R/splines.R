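#' Regular-interval B-spline basis
#'
#' Builds a B-spline basis with `n_knots` equally spaced knots spanning
#' `[lower, upper]` (boundary knots included in the count), degree-`degree`
#' polynomial pieces, and boundary knots repeated `degree` times in the
#' augmented knot vector. The resulting basis has
#' `n_knots + degree - 1` columns and satisfies the partition of unity
#' (rows of the evaluated design sum to 1), so a basis evaluated at the same
#' inputs is bit-identical everywhere -- a requirement for exact multi-site
#' agreement. The aggregator serializes the basis (range, knot count, degree)
#' and broadcasts it so all sites evaluate the identical design.
#'
#' @param lower,upper Covariate range; `upper > lower`.
#' @param n_knots Total number of knots defining the regular partition
#'   (boundary + interior); at least 2.
#' @param degree Polynomial degree (default 3, cubic).
#' @return An object of class `fg_basis` with fields `lower`, `upper`,
#'   `n_knots`, `degree`, `knot_vector` (augmented) and `n_cols`.
#' @examples
#' b <- spline_basis(0, 10, n_knots = 6)
#' b$n_cols # 6 + 3 - 1 = 8
#' rowSums(evaluate_basis(b, c(1, 5, 9)))
#' @export
spline_basis <- function(lower, upper, n_knots, degree = 3L) {
  if (!(upper > lower)) stop("upper must exceed lower")
  if (n_knots < 2) stop("n_knots must be at least 2")
  if (degree < 1) stop("degree must be at least 1")
  kn <- seq(lower, upper, length.out = n_knots)
  knot_vector <- c(rep(lower, degree), kn, rep(upper, degree))
  structure(list(
    lower = lower, upper = upper,
    n_knots = as.integer(n_knots), degree = as.integer(degree),
    knot_vector = knot_vector,
    n_cols = as.integer(n_knots + degree - 1L)
  ), class = "fg_basis")
}

#' Evaluate a B-spline basis
#'
#' Out-of-range values are clamped to `[lower, upper]` with a warning:
#' reference predictions are only valid on the covariate range observed
#' during fitting.
#'
#' @param basis An `fg_basis` object.
#' @param x Covariate vector.
#' @return A `length(x) x n_cols` design matrix; each row is nonnegative,
#'   sums to 1, and has at most `degree + 1` nonzero entries.
#' @export
evaluate_basis <- function(basis, x) {
  out_of_range <- x < basis$lower | x > basis$upper
  if (any(out_of_range)) {
    warning(sum(out_of_range),
            " value(s) outside the basis range [", basis$lower, ", ",
            basis$upper, "] were clamped")
    x <- pmin(pmax(x, basis$lower), basis$upper)
  }
  splines::splineDesign(basis$knot_vector, x, ord = basis$degree + 1L)
}

#' @export
print.fg_basis <- function(x, ...) {
  cat("B-spline basis: ", x$n_knots, " regular knots on [", x$lower, ", ",
      x$upper, "], degree ", x$degree, ", ", x$n_cols, " columns\n", sep = "")
  invisible(x)
}

#' Serialize / restore a basis (for broadcast to sites)
#'
#' @param basis An `fg_basis` object.
#' @return `basis_to_list`: a plain list safe to encode as JSON;
#'   `basis_from_list`: the reconstructed `fg_basis`.
#' @export
basis_to_list <- function(basis) {
  list(lower = basis$lower, upper = basis$upper,
       n_knots = basis$n_knots, degree = basis$degree)
}

#' @rdname basis_to_list
#' @param x A list produced by `basis_to_list`.
#' @export
basis_from_list <- function(x) {
  spline_basis(x$lower, x$upper, x$n_knots, x$degree)
}

#' Difference penalty matrix
#'
#' P-spline penalty \eqn{P = D^\top D} where `D` is the order-`order`
#' difference operator on adjacent B-spline coefficients. `P` is symmetric
#' positive semidefinite with null space of dimension `order` (order-2
#' differences annihilate constant and linear coefficient sequences).
#'
#' @param n_cols Number of basis columns.
#' @param order Difference order (default 2).
#' @return An `n_cols x n_cols` penalty matrix.
#' @export
difference_penalty <- function(n_cols, order = 2L) {
  if (n_cols <= order) stop("n_cols must exceed the difference order")
  D <- diff(diag(n_cols), differences = order)
  crossprod(D)
}

# Embed the smooth-term penalty into the full-design block (zeros on
# fixed-effect columns). `smooth_idx` gives the smooth columns.
embed_penalty <- function(P, q, smooth_idx) {
  Pt <- matrix(0, q, q)
  if (length(smooth_idx)) Pt[smooth_idx, smooth_idx] <- P
  Pt
}

#' Effective degrees of freedom of a penalized design
#'
#' \eqn{EDF = \mathrm{tr}[(X^\top W X + \lambda \tilde P)^{-1} X^\top W X]},
#' where \eqn{\tilde P} is the smooth-term penalty embedded in the full design
#' (zero block for fixed-effect columns), so the EDF is inclusive of fixed
#' effects. At \eqn{\lambda = 0} this is the design rank; as
#' \eqn{\lambda \to \infty} it falls to the penalty null-space dimension plus
#' the number of unpenalized columns.
#'
#' @param XtWX Aggregated cross-product for the full parameter design
#'   (fixed + smooth columns), symmetric positive semidefinite.
#' @param P Smooth-term penalty matrix (or the full embedded penalty when
#'   `smooth_idx` is `NULL`).
#' @param lambda Nonnegative penalty weight.
#' @param smooth_idx Indices of the smooth columns inside the full design;
#'   `NULL` means `P` is already full-size.
#' @return Scalar EDF.
#' @export
edf <- function(XtWX, P, lambda, smooth_idx = NULL) {
  q <- ncol(XtWX)
  Pt <- if (is.null(smooth_idx)) P else embed_penalty(P, q, smooth_idx)
  A <- XtWX + lambda * Pt
  sol <- try(solve(A, XtWX), silent = TRUE)
  if (inherits(sol, "try-error")) {
    A <- A + diag(1e-10 * mean(diag(A)), q)
    sol <- try(solve(A, XtWX), silent = TRUE)
    if (inherits(sol, "try-error")) {
      stop("Penalized cross-product is singular even after ridge jitter; ",
           "check the design for collinear columns")
    }
  }
  sum(diag(sol))
}

#' Solve for the penalty weight achieving a target EDF
#'
#' The EDF is continuous and strictly decreasing in \eqn{\lambda} (from the
#' design rank at \eqn{\lambda = 0} down to the unpenalized dimension), so the
#' target is found by root-finding on \eqn{\log \lambda}.
#'
#' @inheritParams edf
#' @param target_edf Desired EDF; must lie strictly between the
#'   infinite-penalty limit and the design rank.
#' @param interval Search interval for \eqn{\lambda} (log-spaced).
#' @return The penalty weight `lambda` with `|edf(lambda) - target_edf| < 1e-4`
#'   (0 if the target equals the full rank).
#' @export
lambda_for_edf <- function(XtWX, P, target_edf, smooth_idx = NULL,
                           interval = c(1e-8, 1e10)) {
  edf0 <- edf(XtWX, P, 0, smooth_idx)
  edf_inf <- edf(XtWX, P, interval[2], smooth_idx)
  if (target_edf >= edf0 - 1e-8) return(0)
  if (target_edf <= edf_inf) {
    # the trace at extreme penalties is only accurate to ~1e-4; targets at or
    # below the maximal-smoothing limit within that noise get the cap
    if (target_edf > edf_inf - 1e-3) return(interval[2])
    stop(sprintf(
      "target EDF %.4f is not attainable; attainable interval is (%.4f, %.4f]",
      target_edf, edf_inf, edf0))
  }
  f <- function(loglam) edf(XtWX, P, exp(loglam), smooth_idx) - target_edf
  r <- stats::uniroot(f, lower = log(interval[1]), upper = log(interval[2]),
                      tol = 1e-10)
  exp(r$root)
}
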