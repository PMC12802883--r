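# The Rigby-Stasinopoulos fitting cycles, shared verbatim by the pooled and
# distributed paths. The outer cycle visits the distribution parameters in
# turn; the inner cycle performs Newton-Raphson updates for one parameter
# (as penalized weighted least squares on the adjusted dependent vector)
# while all other parameters are held fixed. The backend abstracts where the
# cross-products come from: the pooled backend computes X'WX and X'Wz on the
# full data; the distributed backend sums per-site messages. Identical
# control flow on both paths, plus the additivity of the cross-products,
# is what makes the distributed fit exact.

proportion_converged <- function(old, new, c) {
  denom <- abs(old)
  small <- denom <= 1e-8
  rel <- abs(new - old) / ifelse(small, 1e-8, denom)
  all(rel < c)
}

model_criterion <- function(dev, edf_total, n, criterion, kappa) {
  switch(criterion,
         BIC = dev + log(n) * edf_total,
         GAIC = dev + kappa * edf_total,
         GCV = n * dev / (n - edf_total)^2)
}

rs_fit <- function(backend, spec) {
  fam <- spec$family_obj
  p <- fam$p
  pn_all <- fam$param_names
  info <- backend$design_info
  n <- backend$n_total

  # penalty state per parameter
  pens <- lapply(pn_all, function(pn) {
    penalty_state(spec$params[[pn]], info[[pn]]$q, info[[pn]]$smooth_idx)
  })
  names(pens) <- pn_all

  # initialize from round-0 aggregate moments; a basis that sums to one per
  # row carries the constant, so setting all smooth coefficients to the
  # linked initial value reproduces an intercept-only start
  theta0 <- fam$init(backend$stats)
  coefs <- lapply(pn_all, function(pn) {
    q <- info[[pn]]$q
    eta0 <- fam$links[[pn]]$linkfun(theta0[[pn]])
    b <- numeric(q)
    if (length(info[[pn]]$smooth_idx)) {
      b[info[[pn]]$smooth_idx] <- eta0
    } else {
      b[1] <- eta0
    }
    names(b) <- info[[pn]]$colnames
    b
  })
  names(coefs) <- pn_all

  dev_prev <- Inf
  last <- NULL          # last accepted update, for delayed step control
  n_inner <- stats::setNames(integer(p), pn_all)
  M1_store <- stats::setNames(vector("list", p), pn_all)
  history <- list()
  stalled <- character()
  converged <- FALSE
  outer_done <- 0L

  for (outer in seq_len(spec$max_outer)) {
    outer_start <- coefs
    for (k in seq_len(p)) {
      pn <- pn_all[[k]]
      iter <- 0L
      while (iter < spec$max_inner) {
        msg <- backend$update(k, coefs)
        # deviance at the currently broadcast coefficients arrives with this
        # round; if the previous accepted update increased it (or left the
        # likelihood's domain), halve that step and redo (up to 5 times; a
        # non-finite deviance keeps halving as long as it helps)
        worse <- !is.finite(msg$deviance) ||
          msg$deviance > dev_prev + 1e-7 * (abs(dev_prev) + 1)
        if (worse && !is.null(last) &&
            (last$halvings < 5L ||
               (!is.finite(msg$deviance) && last$halvings < 30L))) {
          coefs[[last$pn]] <- (last$old + coefs[[last$pn]]) / 2
          last$halvings <- last$halvings + 1L
          next
        }
        if (!is.finite(msg$deviance)) {
          stop("log-likelihood is not finite at the current coefficients ",
               "for parameter '", pn, "' and step halving did not recover; ",
               "check the model specification against the outcome scale")
        }
        iter <- iter + 1L
        dev_prev <- msg$deviance
        pen <- pens[[pn]]
        M1_store[[pn]] <- msg$M1

        if (pen$mode == "auto") {
          sel <- auto_penalty_step(backend, spec, k, coefs, msg, pen,
                                   M1_store, info, n)
          bnew <- sel$b
          pens[[pn]]$lambda <- sel$lambda
          if (sel$stalled) stalled <- c(stalled, pn)
        } else {
          if (pen$mode == "fixed_penalty" && !is.null(pen$target_edf)) {
            pens[[pn]]$lambda <- lambda_for_edf(msg$M1, pen$P, pen$target_edf,
                                                pen$smooth_idx)
          }
          bnew <- solve_penalized(msg$M1, msg$M2, pens[[pn]])
        }
        names(bnew) <- info[[pn]]$colnames

        old <- coefs[[pn]]
        # a slow inner cycle signals Newton overshoot; damp later updates
        # (deterministically, so pooled and distributed stay in lockstep)
        if (iter > 5L) bnew <- old + 0.5 * (bnew - old)
        halved <- if (is.null(last)) 0L else last$halvings
        last <- list(pn = pn, old = old, halvings = 0L)
        coefs[[pn]] <- bnew
        n_inner[[pn]] <- n_inner[[pn]] + 1L
        history[[length(history) + 1L]] <- list(param = pn, coef = bnew,
                                                deviance = msg$deviance,
                                                prev_halvings = halved)
        if (proportion_converged(old, bnew, spec$c)) break
      }
    }
    outer_done <- outer
    if (all(vapply(pn_all, function(pn) {
      proportion_converged(outer_start[[pn]], coefs[[pn]], spec$c)
    }, logical(1)))) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("fit did not converge within ", spec$max_outer, " outer cycles")
  }

  edfs <- vapply(pn_all, function(pn) {
    pen <- pens[[pn]]
    if (!is.null(pen$P) && pen$lambda > 0 && !is.null(M1_store[[pn]])) {
      edf(M1_store[[pn]], pen$P, pen$lambda, pen$smooth_idx)
    } else {
      as.numeric(info[[pn]]$q)
    }
  }, numeric(1))
  lambdas <- vapply(pn_all, function(pn) pens[[pn]]$lambda, numeric(1))

  list(coefficients = coefs, converged = converged,
       n_inner_iterations = n_inner, outer_cycles = outer_done,
       edf = edfs, lambda = lambdas, history = history,
       stalled = unique(stalled), penalties = pens, xtwx = M1_store)
}

# One automated-penalty selection step: candidate coefficients are solved for
# every grid value from the already-aggregated cross-products; sites then
# return deviances at all candidate coefficient locations in one extra
# penalty-grid round; the criterion (BIC by default) picks the winner, ties
# toward the smallest lambda (the grid is sorted ascending).
auto_penalty_step <- function(backend, spec, k, coefs, msg, pen,
                              M1_store, info, n) {
  pn <- spec$family_obj$param_names[[k]]
  grid <- spec$lambda_grid
  cands <- lapply(grid, function(l) solve_penalized(msg$M1, msg$M2, pen, l))
  devs <- backend$eval_deviance(k, coefs, cands)
  edf_k <- vapply(grid, function(l) edf(msg$M1, pen$P, l, pen$smooth_idx),
                  numeric(1))
  # EDF of the other parameters is unchanged across the candidates, so any
  # consistent value is a constant shift of the criterion; use their column
  # counts (the lambda = 0 EDF)
  edf_other <- sum(vapply(setdiff(names(info), pn),
                          function(on) as.numeric(info[[on]]$q), numeric(1)))
  crit <- model_criterion(devs, edf_k + edf_other, n, spec$criterion,
                          spec$kappa)
  crit[!is.finite(crit)] <- Inf
  current_crit <- model_criterion(
    msg$deviance, edf(msg$M1, pen$P, pen$lambda, pen$smooth_idx) + edf_other,
    n, spec$criterion, spec$kappa)
  j <- which.min(crit)   # grid sorted ascending: first minimum = smallest lambda
  if (crit[j] > current_crit + 1e-8) {
    # no candidate improves on the current state: retain the previous
    # penalty and take a plain update under it
    return(list(b = solve_penalized(msg$M1, msg$M2, pen),
                lambda = pen$lambda, stalled = TRUE))
  }
  list(b = cands[[j]], lambda = grid[j], stalled = FALSE)
}

## ---------------------------------------------------------------------------

#' Fit a GAMLSS model on pooled data
#'
#' The pooled Rigby-Stasinopoulos fit: all rows are available to one process.
#' Serves as the exactness oracle for [fit_distributed()] -- on the same data
#' and spline bases both produce the same coefficient trajectory up to
#' floating-point summation order.
#'
#' @param data Data frame with the outcome and all covariates.
#' @param outcome Name of the outcome column.
#' @param spec An [fg_spec()] model specification.
#' @param inference If `TRUE` (default) compute the joint numerical Hessian,
#'   standard errors and Wald table after convergence.
#' @return An object of class `fg_fit`.
#' @export
fit_pooled <- function(data, outcome, spec, inference = TRUE) {
  backend <- pooled_backend(data, outcome, spec)
  finish_fit(backend, spec, inference)
}

#' Fit a GAMLSS model across sites without sharing rows
#'
#' Runs the distributed Rigby-Stasinopoulos algorithm over in-process sites:
#' one setup round establishes covariate ranges, factor level dictionaries
#' and the shared spline bases; each inner-cycle Newton-Raphson iteration
#' costs one communication round in which every site sends only the
#' aggregate matrices \eqn{M_{i1} = X^\top W X} and
#' \eqn{M_{i2} = X^\top W z} (plus per-candidate deviances in
#' automated-penalty mode); one final round collects site Hessians and
#' deviances for inference. Any site failure aborts the fit (exactness over
#' availability); no partial rounds are used.
#'
#' @param sites List of [site_data()] objects.
#' @param spec An [fg_spec()] model specification.
#' @param inference If `TRUE` (default) run the post-fit inference round.
#' @return An object of class `fg_fit` with a communication `round_log`.
#' @export
fit_distributed <- function(sites, spec, inference = TRUE) {
  if (inherits(sites, "fg_site")) sites <- list(sites)
  backend <- distributed_backend(sites, spec)
  finish_fit(backend, spec, inference)
}

finish_fit <- function(backend, spec, inference) {
  res <- rs_fit(backend, spec)
  inf_round <- backend$inference_round(res$coefficients, hessian = inference)
  global_deviance <- sum(inf_round$deviances)
  infres <- NULL
  if (inference) {
    infres <- aggregate_inference(inf_round$H_list, inf_round$deviances,
                                  res$coefficients)
  }
  structure(list(
    family = spec$family,
    family_obj = spec$family_obj,
    spec = spec,
    coefficients = res$coefficients,
    converged = res$converged,
    n_inner_iterations = res$n_inner_iterations,
    outer_cycles = res$outer_cycles,
    global_deviance = global_deviance,
    edf = res$edf,
    lambda = res$lambda,
    xtwx = res$xtwx,
    stalled = res$stalled,
    history = res$history,
    inference = infres,
    round_log = round_log_df(backend$round_log),
    schema = backend$schema,
    bases = backend$bases,
    design_info = backend$design_info,
    n_total = backend$n_total,
    backend = backend$type
  ), class = "fg_fit")
}

#' @export
print.fg_fit <- function(x, ...) {
  cat("GAMLSS ", x$backend, " fit, family ", x$family, "\n", sep = "")
  cat("  n = ", x$n_total, ", global deviance = ",
      format(x$global_deviance, digits = 8), "\n", sep = "")
  cat("  converged: ", x$converged, " (", x$outer_cycles, " outer cycles, ",
      sum(x$n_inner_iterations), " inner iterations)\n", sep = "")
  for (pn in names(x$coefficients)) {
    cat("  ", pn, ": ", length(x$coefficients[[pn]]), " coefficients, EDF ",
        format(x$edf[[pn]], digits = 4),
        if (x$lambda[[pn]] > 0) paste0(", lambda ",
                                       format(x$lambda[[pn]], digits = 4)),
        "\n", sep = "")
  }
  if (nrow(x$round_log)) {
    cat("  communication rounds: ", nrow(x$round_log), " (",
        paste(names(table(x$round_log$purpose)),
              table(x$round_log$purpose), sep = "=", collapse = ", "),
        ")\n", sep = "")
  }
  invisible(x)
}

#' @export
coef.fg_fit <- function(object, ...) object$coefficients

#' @export
deviance.fg_fit <- function(object, ...) object$global_deviance

#' Penalty weights matching a reference fit's effective degrees of freedom
#'
#' For every parameter with a penalized smooth, inverts the EDF on the
#' reference fit's converged cross-product (via [lambda_for_edf()]) to find
#' the penalty weight reproducing that parameter's EDF. The returned values
#' can be broadcast as fixed penalties to a distributed fit, emulating the
#' workflow where a gold-standard model's degrees of freedom are known.
#'
#' @param fit A converged `fg_fit` whose smooth terms carry penalties.
#' @return Named list of penalty weights (one per penalized parameter).
#' @export
match_penalties <- function(fit) {
  out <- list()
  for (pn in names(fit$spec$params)) {
    sm <- fit$spec$params[[pn]]$smooth
    if (is.null(sm) || sm$mode == "fixed") next
    idx <- fit$design_info[[pn]]$smooth_idx
    P <- difference_penalty(length(idx), sm$order)
    out[[pn]] <- lambda_for_edf(fit$xtwx[[pn]], P, fit$edf[[pn]], idx)
  }
  out
}

#' Total model BIC
#'
#' Global deviance plus `log(n)` times the total effective degrees of
#' freedom (summed over all distribution parameters, inclusive of fixed
#' effects).
#'
#' @param fit An `fg_fit`.
#' @return Scalar BIC.
#' @export
fit_bic <- function(fit) {
  fit$global_deviance + log(fit$n_total) * sum(fit$edf)
}
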