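#' Aggregate site Hessians into Wald inference
#'
#' The joint coefficient covariance is the inverse of the summed site
#' information matrices, \eqn{\Sigma = (\sum_i H_i)^{-1}}; standard errors
#' are the square roots of its diagonal and \eqn{t = \hat b / se} with
#' two-sided normal p-values. Site deviances are summed into the global
#' deviance. If the summed Hessian is not positive definite (expected for
#' nearly unsupported spline tails), a pseudo-inverse is used and the
#' affected coefficients are flagged.
#'
#' @param H_list List of site information matrices (negative log-likelihood
#'   Hessians), one per site.
#' @param deviance_list Numeric vector of site deviances.
#' @param coefficients Named list of fitted per-parameter coefficient
#'   vectors.
#' @return An object of class `fg_inference` with the covariance matrix, a
#'   coefficient table (`parameter`, `term`, `estimate`, `se`, `t`, `p`),
#'   the global deviance and any flagged coefficients.
#' @export
aggregate_inference <- function(H_list, deviance_list, coefficients) {
  H <- Reduce(`+`, H_list)
  q <- ncol(H)
  flagged <- integer()
  ch <- try(chol(H), silent = TRUE)
  if (inherits(ch, "try-error")) {
    warning("summed Hessian is not positive definite; using a ",
            "pseudo-inverse (near-unidentified coefficients flagged)")
    sv <- svd((H + t(H)) / 2)
    pos <- sv$d > max(sv$d) * 1e-12
    Sigma <- sv$v[, pos, drop = FALSE] %*%
      (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
    flagged <- which(diag(Sigma) <= 0 | !is.finite(diag(Sigma)))
  } else {
    Sigma <- chol2inv(ch)
  }
  est <- unlist(coefficients, use.names = FALSE)
  if (length(est) != q) stop("coefficient count does not match Hessian size")
  se <- sqrt(pmax(diag(Sigma), 0))
  tval <- est / se
  param <- rep(names(coefficients), lengths(coefficients))
  term <- unlist(lapply(coefficients, names), use.names = FALSE)
  table <- data.frame(parameter = param, term = term, estimate = est,
                      se = se, t = tval,
                      p = 2 * stats::pnorm(-abs(tval)),
                      row.names = NULL)
  structure(list(covariance = Sigma, table = table,
                 global_deviance = sum(deviance_list),
                 flagged = flagged),
            class = "fg_inference")
}

#' @export
print.fg_inference <- function(x, ...) {
  cat("Distributed Wald inference (global deviance ",
      format(x$global_deviance, digits = 8), ")\n", sep = "")
  print(x$table, digits = 4)
  invisible(x)
}

#' Likelihood-ratio test for a smooth term
#'
#' Compares the global deviance of the full model against a reduced model in
#' which the tested parameter lost its smooth term, with a
#' \eqn{\chi^2_{df}} null (non-integer `df` allowed, e.g. the EDF difference
#' of a fixed-penalty smooth). Only valid for fixed-effect and fixed-penalty
#' smooths: with data-driven penalty selection the test does not account for
#' the choice of the penalty and is refused.
#'
#' @param full_deviance,reduced_deviance Global deviances of the nested
#'   fits.
#' @param df Degrees of freedom of the null distribution.
#' @return List with `statistic`, `df` and `p`.
#' @export
lrt_smooth <- function(full_deviance, reduced_deviance, df) {
  statistic <- reduced_deviance - full_deviance
  if (statistic < -1e-6) {
    stop("reduced-model deviance is smaller than the full-model deviance; ",
         "the models are not nested or one fit did not converge")
  }
  statistic <- max(statistic, 0)
  list(statistic = statistic, df = df,
       p = stats::pchisq(statistic, df, lower.tail = FALSE))
}

#' Reduced specification for smooth-term testing
#'
#' Drops the smooth term of one distribution parameter (the parameter keeps
#' its intercept and fixed-effect terms; all other parameters keep their
#' full smooth terms, as required for a nested comparison).
#'
#' @param spec An [fg_spec()].
#' @param param Parameter name whose smooth is removed.
#' @return A new `fg_spec`.
#' @export
reduced_spec <- function(spec, param) {
  ps <- spec$params[[param]]
  if (is.null(ps$smooth)) stop("parameter '", param, "' has no smooth term")
  spec$params[[param]] <- param_spec(fixed = ps$fixed, smooth = NULL)
  spec
}

#' Fit-and-test wrapper for the smooth-term LRT
#'
#' Fits the reduced model (smooth removed from `param`) on the same sites or
#' data and runs [lrt_smooth()] with `df` equal to the EDF difference
#' between the full and reduced designs for that parameter (for a
#' fixed-effect smooth this is the basis column count minus the intercept it
#' absorbs). Refused for automated-penalty smooths.
#'
#' @param full_fit A converged `fg_fit` of the full model.
#' @param sites_or_data The same list of [site_data()] objects (distributed
#'   fit) or data frame (pooled fit) the full model was fitted on.
#' @param param Parameter whose smooth term is tested.
#' @param outcome Outcome column name (pooled data frame input only).
#' @return List with `statistic`, `df`, `p` and the reduced fit.
#' @export
lrt_smooth_fit <- function(full_fit, sites_or_data, param, outcome = NULL) {
  sm <- full_fit$spec$params[[param]]$smooth
  if (is.null(sm)) stop("parameter '", param, "' has no smooth term")
  if (sm$mode == "auto") {
    stop("likelihood-ratio inference is not offered for automated-penalty ",
         "smooth terms: the test does not account for the data-driven ",
         "penalty choice and may be liberal")
  }
  rspec <- reduced_spec(full_fit$spec, param)
  red <- if (is.data.frame(sites_or_data)) {
    fit_pooled(sites_or_data, outcome, rspec, inference = FALSE)
  } else {
    fit_distributed(sites_or_data, rspec, inference = FALSE)
  }
  df <- full_fit$edf[[param]] - red$edf[[param]]
  out <- lrt_smooth(full_fit$global_deviance, red$global_deviance, df)
  out$reduced_fit <- red
  out
}
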