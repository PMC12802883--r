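#' Smooth-term description
#'
#' At most one smooth term is allowed per distribution parameter. The three
#' modes mirror the three smooth-term regimes of the distributed fitter:
#' \describe{
#'   \item{`"fixed"`}{an unpenalized fixed-effect smooth (\eqn{\lambda = 0});
#'     flexibility is controlled by the knot count alone.}
#'   \item{`"fixed_penalty"`}{a preset penalty, given either directly as
#'     `lambda` or as a target effective degrees of freedom `edf` (the penalty
#'     weight is then solved from the aggregated cross-product each
#'     iteration).}
#'   \item{`"auto"`}{data-driven penalty selection over a broadcast
#'     \eqn{\lambda} grid by an information criterion (BIC by default).}
#' }
#' When a parameter has a smooth term its design drops the separate
#' intercept column: the B-spline basis sums to one in every row and
#' therefore spans the constant.
#'
#' @param covariate Name of the (numeric) smoothed covariate.
#' @param n_knots Total number of regular-interval knots (boundary +
#'   interior); the basis has `n_knots + degree - 1` columns.
#' @param mode One of `"fixed"`, `"fixed_penalty"`, `"auto"`.
#' @param lambda Penalty weight for `"fixed_penalty"` mode.
#' @param edf Target effective degrees of freedom (inclusive of fixed
#'   effects) for `"fixed_penalty"` mode; alternative to `lambda`.
#' @param degree B-spline degree (default cubic).
#' @param order Difference-penalty order (default 2).
#' @return An object of class `fg_smooth`.
#' @export
smooth_term <- function(covariate, n_knots, mode = c("fixed", "fixed_penalty", "auto"),
                        lambda = NULL, edf = NULL, degree = 3L, order = 2L) {
  mode <- match.arg(mode)
  if (mode == "fixed_penalty" && is.null(lambda) && is.null(edf)) {
    stop("fixed_penalty smooth needs either `lambda` or a target `edf`")
  }
  if (n_knots + degree - 1 <= order) {
    stop("basis too small for an order-", order, " difference penalty")
  }
  structure(list(covariate = covariate, n_knots = as.integer(n_knots),
                 mode = mode, lambda = lambda, edf = edf,
                 degree = as.integer(degree), order = as.integer(order)),
            class = "fg_smooth")
}

#' Per-parameter term list
#'
#' @param fixed Character vector of fixed-effect covariate names. Factors are
#'   detected from the data and expanded to treatment contrasts against the
#'   alphabetically first level; numeric covariates enter as single columns.
#' @param smooth Optional [smooth_term()].
#' @return An object of class `fg_param_spec`. An intercept is always present
#'   unless a smooth term supplies the constant through its basis.
#' @export
param_spec <- function(fixed = character(), smooth = NULL) {
  if (!is.null(smooth) && !inherits(smooth, "fg_smooth")) {
    stop("`smooth` must be built with smooth_term()")
  }
  structure(list(fixed = fixed, smooth = smooth), class = "fg_param_spec")
}

#' Model specification
#'
#' Names the distribution family and describes the additive predictor of each
#' distribution parameter (intercept, fixed-effect terms, and at most one
#' smooth term with its penalty mode). Parameters not given explicitly are
#' intercept-only.
#'
#' @param family Family name (`"NO"`, `"BCPE"`, `"BEZI"`, `"GG"`).
#' @param mu,sigma,nu,tau [param_spec()] objects (or the result of
#'   [parse_formula()]); defaults are intercept-only.
#' @param c Convergence threshold on the proportion change of every
#'   coefficient between successive Newton-Raphson updates (default 0.05, a
#'   balance of stability against communication cost).
#' @param max_inner,max_outer Iteration caps for the inner (per-parameter
#'   Newton-Raphson) and outer (across-parameter) cycles.
#' @param lambda_grid Candidate penalty grid for `"auto"` smooths: 20
#'   log-spaced values spanning 1e-4 to 1e6 by default. Ties are broken
#'   toward the smallest candidate.
#' @param criterion Penalty-selection criterion: `"BIC"`
#'   (deviance + log(n) * total EDF), `"GAIC"`
#'   (deviance + kappa * total EDF) or `"GCV"`
#'   (n * deviance / (n - total EDF)^2).
#' @param kappa GAIC penalty-per-EDF (default 2, i.e. AIC).
#' @return An object of class `fg_spec`.
#' @examples
#' spec <- fg_spec("NO",
#'   mu = param_spec(fixed = "sex", smooth = smooth_term("age", 6)),
#'   sigma = param_spec())
#' @export
fg_spec <- function(family, mu = param_spec(), sigma = param_spec(),
                    nu = param_spec(), tau = param_spec(),
                    c = 0.05, max_inner = 20L, max_outer = 30L,
                    lambda_grid = default_lambda_grid(),
                    criterion = c("BIC", "GAIC", "GCV"), kappa = 2) {
  fam <- if (inherits(family, "fg_family")) family else fg_family(family)
  criterion <- match.arg(criterion)
  all_params <- list(mu = mu, sigma = sigma, nu = nu, tau = tau)
  params <- all_params[fam$param_names]
  for (pn in names(params)) {
    if (!inherits(params[[pn]], "fg_param_spec")) {
      stop("`", pn, "` must be built with param_spec() or parse_formula()")
    }
  }
  structure(list(family = fam$name, family_obj = fam, params = params,
                 c = c, max_inner = as.integer(max_inner),
                 max_outer = as.integer(max_outer),
                 lambda_grid = sort(lambda_grid), criterion = criterion,
                 kappa = kappa),
            class = "fg_spec")
}

#' @rdname fg_spec
#' @export
default_lambda_grid <- function() exp(seq(log(1e-4), log(1e6), length.out = 20))

#' @export
print.fg_spec <- function(x, ...) {
  cat("GAMLSS model specification, family ", x$family, "\n", sep = "")
  for (pn in names(x$params)) {
    ps <- x$params[[pn]]
    terms <- c(if (is.null(ps$smooth)) "1",
               if (!is.null(ps$smooth))
                 sprintf("bs(%s, knots=%d, mode=%s)", ps$smooth$covariate,
                         ps$smooth$n_knots, ps$smooth$mode),
               ps$fixed)
    cat("  ", pn, " ~ ", paste(terms, collapse = " + "), "\n", sep = "")
  }
  cat("  convergence threshold c = ", x$c, "\n", sep = "")
  invisible(x)
}

#' Parse the per-parameter formula mini-language
#'
#' Accepts strings like
#' `"~ bs(age, knots=6, mode=fixed) + cat(sex) + bmi"`:
#' `bs()` declares the smooth term (arguments `knots`, `mode`
#' (`fixed`/`fixed_penalty`/`auto`), `lambda`, `edf`, `degree`), `cat()`
#' declares a categorical covariate, and bare names are numeric covariates.
#' Categorical covariates are also auto-detected from the data, so `cat()` is
#' documentation more than necessity.
#'
#' @param text Formula string (the leading `~` is optional).
#' @return An [param_spec()] object.
#' @export
parse_formula <- function(text) {
  text <- sub("^\\s*~\\s*", "", trimws(text))
  if (text == "" || text == "1") return(param_spec())
  parts <- trimws(strsplit(text, "+", fixed = TRUE)[[1]])
  fixed <- character()
  smooth <- NULL
  for (pt in parts) {
    if (pt == "1" || pt == "") next
    if (grepl("^bs\\(", pt)) {
      if (!is.null(smooth)) stop("at most one smooth term per parameter")
      smooth <- parse_bs_term(pt)
    } else if (grepl("^cat\\(", pt)) {
      fixed <- c(fixed, sub("^cat\\((.*)\\)$", "\\1", pt))
    } else if (grepl("^[A-Za-z.][A-Za-z0-9._]*$", pt)) {
      fixed <- c(fixed, pt)
    } else {
      stop("cannot parse term '", pt, "'")
    }
  }
  param_spec(fixed = fixed, smooth = smooth)
}

parse_bs_term <- function(txt) {
  inner <- sub("^bs\\((.*)\\)$", "\\1", txt)
  args <- trimws(strsplit(inner, ",", fixed = TRUE)[[1]])
  covariate <- args[1]
  kv <- list(knots = NULL, mode = "fixed", lambda = NULL, edf = NULL,
             degree = 3L)
  for (a in args[-1]) {
    m <- strsplit(a, "=", fixed = TRUE)[[1]]
    if (length(m) != 2) stop("cannot parse bs() argument '", a, "'")
    key <- trimws(m[1]); val <- trimws(m[2])
    kv[[key]] <- switch(key,
      knots = as.integer(val),
      degree = as.integer(val),
      mode = val,
      lambda = as.numeric(val),
      edf = as.numeric(val),
      stop("unknown bs() argument '", key, "'"))
  }
  if (is.null(kv$knots)) stop("bs() needs a knots= argument")
  smooth_term(covariate, n_knots = kv$knots, mode = kv$mode,
              lambda = kv$lambda, edf = kv$edf, degree = kv$degree)
}

# all covariate names a spec refers to
spec_covariates <- function(spec) {
  unique(unlist(lapply(spec$params, function(ps) {
    c(ps$fixed, if (!is.null(ps$smooth)) ps$smooth$covariate)
  })))
}

spec_smooth_covariates <- function(spec) {
  unique(unlist(lapply(spec$params, function(ps) {
    if (!is.null(ps$smooth)) ps$smooth$covariate
  })))
}
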