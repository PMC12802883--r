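#' Predicted distribution parameters for new covariates
#'
#' Builds the design rows for `newdata` under the fit's broadcast schema and
#' spline bases (covariates outside the fitted range are clamped with a
#' warning) and returns the per-subject distribution parameters on their
#' natural scale. A pure function of the fitted coefficients and the new
#' covariates; no site data is touched.
#'
#' @param fit An `fg_fit`.
#' @param newdata Data frame of covariates.
#' @return Named list of parameter vectors (`mu`, `sigma`, ...).
#' @export
predict_theta <- function(fit, newdata) {
  spec <- fit$spec
  fam <- fit$family_obj
  th <- lapply(names(spec$params), function(pn) {
    ps <- spec$params[[pn]]
    d <- build_design(ps, newdata, fit$schema,
                      basis_for(fit$bases, ps$smooth))
    eta <- drop(d$X %*% fit$coefficients[[pn]])
    fam$links[[pn]]$linkinv(eta)
  })
  names(th) <- names(spec$params)
  th
}

#' Predicted quantile of an observed outcome
#'
#' The CDF of each observed outcome under that subject's fitted
#' distribution: the quantity reference charts use to flag atypical
#' measurements. For zero-inflated families a zero outcome returns the
#' fitted zero mass.
#'
#' @param fit An `fg_fit`.
#' @param newdata Data frame of covariates (one row per outcome).
#' @param y Observed outcome vector.
#' @return Vector of probabilities.
#' @export
predict_quantile <- function(fit, newdata, y) {
  theta <- predict_theta(fit, newdata)
  family_cdf(fit$family_obj, y, theta)
}

#' Centile reference table over a covariate grid
#'
#' Evaluates the fitted conditional distribution on a covariate grid and
#' returns the requested centiles (quantiles times 100). Covariates absent
#' from `grid` default to their reference level (alphabetically first factor
#' level); numeric covariates other than the smoothed one must be supplied.
#' Values are nondecreasing in the centile at every grid point.
#'
#' @param fit An `fg_fit`.
#' @param grid Named list of covariate values to cross (e.g.
#'   `list(age = seq(20, 90, 5), sex = c("F", "M"))`).
#' @param centiles Centiles to tabulate; defaults to
#'   `c(2.5, 10, 25, 50, 75, 90, 97.5)` (the inner-95% bounds plus standard
#'   interior lines).
#' @return A data frame of class `fg_chart`: the grid columns followed by
#'   one column per centile (named `c2.5`, `c50`, ...).
#' @export
reference_chart <- function(fit, grid,
                            centiles = c(2.5, 10, 25, 50, 75, 90, 97.5)) {
  if (any(centiles <= 0 | centiles >= 100)) {
    stop("centiles must lie strictly between 0 and 100")
  }
  covs <- spec_covariates(fit$spec)
  missing_covs <- setdiff(covs, names(grid))
  for (nm in missing_covs) {
    lv <- fit$schema$factors[[nm]]
    if (is.null(lv)) {
      stop("grid must supply a value for numeric covariate '", nm, "'")
    }
    grid[[nm]] <- lv[1]   # declared reference level
  }
  gdf <- expand.grid(grid, stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  theta <- predict_theta(fit, gdf)
  vals <- vapply(centiles, function(cc) {
    family_quantile(fit$family_obj, cc / 100, theta)
  }, numeric(nrow(gdf)))
  vals <- matrix(vals, nrow = nrow(gdf))
  colnames(vals) <- paste0("c", centiles)
  out <- cbind(gdf, as.data.frame(vals))
  class(out) <- c("fg_chart", class(out))
  out
}

#' Plot a centile reference chart
#'
#' Base-graphics rendering: centile lines against the smoothed covariate,
#' one line type per level of an optional stratifying factor.
#'
#' @param x An `fg_chart`.
#' @param xvar Covariate for the horizontal axis (defaults to the first
#'   numeric grid column).
#' @param by Optional factor column to stratify line types by.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.fg_chart <- function(x, xvar = NULL, by = NULL, ...) {
  cent_cols <- grep("^c[0-9.]+$", names(x), value = TRUE)
  grid_cols <- setdiff(names(x), cent_cols)
  if (is.null(xvar)) {
    xvar <- grid_cols[vapply(x[grid_cols], is.numeric, logical(1))][1]
  }
  strata <- if (!is.null(by)) split(x, x[[by]]) else list(x)
  yl <- range(unlist(x[cent_cols]))
  first <- TRUE
  for (s in seq_along(strata)) {
    df <- strata[[s]]
    df <- df[order(df[[xvar]]), ]
    graphics::matplot(df[[xvar]], as.matrix(df[cent_cols]), type = "l",
                      lty = s, col = seq_along(cent_cols), add = !first,
                      xlab = xvar, ylab = "outcome", ylim = yl, ...)
    first <- FALSE
  }
  graphics::legend("topright", legend = cent_cols,
                   col = seq_along(cent_cols), lty = 1, cex = 0.7, bty = "n")
  invisible(x)
}
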