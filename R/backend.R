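# Site-local computation and the site/aggregator message boundary.
#
# SiteData (fg_site) holds raw rows and never crosses the boundary. The only
# objects that do are fg_message lists whose fields are q x q / q aggregates,
# scalars and counts -- this is the privacy contract of the distributed
# algorithm, and it is what the privacy-boundary tests inspect.

MESSAGE_FIELDS <- c("site_id", "k", "M1", "M2", "n_i", "deviance",
                    "dev_candidates", "H", "purpose")

#' Site data container
#'
#' Wraps one site's raw rows. Raw rows live only inside this object; the
#' distributed fitter only ever extracts aggregate messages from it.
#'
#' @param data Data frame with the outcome column and all covariates.
#' @param outcome Name of the outcome column.
#' @param site_id Site label.
#' @return An object of class `fg_site`.
#' @export
site_data <- function(data, outcome, site_id = "site1") {
  if (!outcome %in% names(data)) {
    stop("outcome column '", outcome, "' not found")
  }
  structure(list(site_id = site_id, outcome = outcome, data = data),
            class = "fg_site")
}

#' @export
print.fg_site <- function(x, ...) {
  cat("Site '", x$site_id, "': ", nrow(x$data), " subjects, outcome '",
      x$outcome, "'\n", sep = "")
  invisible(x)
}

## ---------------------------------------------------------------------------
## round-0 site summaries (aggregates only)

site_summary <- function(site, covariates) {
  y <- site$data[[site$outcome]]
  keep <- is.finite(y)
  for (nm in covariates) {
    x <- site$data[[nm]]
    if (is.null(x)) {
      stop("covariate '", nm, "' missing at site '", site$site_id, "'")
    }
    keep <- keep & !is.na(x)
  }
  y <- y[keep]
  pos <- y > 0
  cov_sum <- lapply(covariates, function(nm) {
    x <- site$data[[nm]][keep]
    if (is.character(x) || is.factor(x) || is.logical(x)) {
      list(type = "factor", levels = sort(unique(as.character(x))))
    } else {
      list(type = "numeric", range = range(x))
    }
  })
  names(cov_sum) <- covariates
  list(site_id = site$site_id,
       n = sum(keep), n_dropped = sum(!keep),
       sum_y = sum(y), sum_y2 = sum(y^2),
       n_zero = sum(y == 0),
       sum_pos = sum(y[pos]), sum_pos2 = sum(y[pos]^2),
       covariates = cov_sum)
}

merge_summaries <- function(summaries, covariates, smooth_covariates) {
  n <- sum(vapply(summaries, `[[`, numeric(1), "n"))
  sum_y <- sum(vapply(summaries, `[[`, numeric(1), "sum_y"))
  sum_y2 <- sum(vapply(summaries, `[[`, numeric(1), "sum_y2"))
  n_zero <- sum(vapply(summaries, `[[`, numeric(1), "n_zero"))
  sum_pos <- sum(vapply(summaries, `[[`, numeric(1), "sum_pos"))
  sum_pos2 <- sum(vapply(summaries, `[[`, numeric(1), "sum_pos2"))
  n_pos <- n - n_zero
  stats <- list(
    n = n,
    mean = sum_y / n,
    var = max((sum_y2 - sum_y^2 / n) / n, 1e-12),
    zero_frac = n_zero / n,
    pos_mean = if (n_pos > 0) sum_pos / n_pos else 0.5,
    pos_var = if (n_pos > 1) max((sum_pos2 - sum_pos^2 / n_pos) / n_pos, 1e-12)
              else 1e-4)

  factors <- list()
  ranges <- list()
  for (nm in covariates) {
    entries <- lapply(summaries, function(s) s$covariates[[nm]])
    types <- vapply(entries, `[[`, character(1), "type")
    if (any(types == "factor")) {
      factors[[nm]] <- sort(unique(unlist(lapply(entries, `[[`, "levels"))))
    } else {
      ranges[[nm]] <- range(unlist(lapply(entries, `[[`, "range")))
      if (nm %in% smooth_covariates) check_range_coverage(entries, nm)
    }
  }
  schema <- list(factors = factors,
                 numerics = setdiff(covariates, names(factors)),
                 ranges = ranges)
  list(stats = stats, schema = schema)
}

# warn when per-site covariate ranges leave an uncovered interior gap: the
# spline basis is unsupported there
check_range_coverage <- function(entries, nm) {
  iv <- do.call(rbind, lapply(entries, function(e) e$range))
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  hi <- iv[1, 2]
  for (r in seq_len(nrow(iv))[-1]) {
    if (iv[r, 1] > hi) {
      warning("site ranges for smooth covariate '", nm,
              "' leave a gap (", signif(hi, 4), ", ", signif(iv[r, 1], 4),
              "); the spline basis is unsupported there")
    }
    hi <- max(hi, iv[r, 2])
  }
  invisible(NULL)
}

## ---------------------------------------------------------------------------
## site-local preparation and update messages

prepare_site <- function(site, spec, schema, bases) {
  y <- site$data[[site$outcome]]
  keep <- is.finite(y)
  covs <- spec_covariates(spec)
  for (nm in covs) keep <- keep & !is.na(site$data[[nm]])
  if (any(!keep)) {
    message("site '", site$site_id, "': dropped ", sum(!keep),
            " row(s) with missing outcome or covariates")
  }
  data <- site$data[keep, , drop = FALSE]
  y <- data[[site$outcome]]
  fam <- spec$family_obj
  ok <- fam$support$check(y)
  if (!all(ok)) {
    stop("site '", site$site_id, "': outcome outside the support of family '",
         fam$name, "' (", fam$support$describe, ") at row ",
         which(!ok)[1])
  }
  designs <- lapply(names(spec$params), function(pn) {
    ps <- spec$params[[pn]]
    build_design(ps, data, schema, basis_for(bases, ps$smooth),
                 clamp_warn = FALSE)
  })
  names(designs) <- names(spec$params)
  list(site_id = site$site_id, y = y, n = length(y), designs = designs)
}

# Sites snap the linear predictor to a fixed grid of 2^-30 relative
# precision before any derivative or likelihood evaluation. Arithmetically
# equivalent coefficient representations (e.g. a pooled cross-product versus
# the same cross-product summed site by site) then yield bitwise identical
# per-subject computations, so the distributed iterate sequence cannot drift
# from the pooled one through last-bit noise amplified by the
# finite-difference derivative steps.
quantize_eta <- function(eta) {
  g <- 2^(ceiling(log2(pmax(1, abs(eta)))) - 30L)
  round(eta / g) * g
}

site_etas <- function(prep, coefs, quantize = TRUE) {
  lapply(names(prep$designs), function(pn) {
    eta <- drop(prep$designs[[pn]]$X %*% coefs[[pn]])
    if (quantize) eta <- quantize_eta(eta)
    eta
  }) |> stats::setNames(names(prep$designs))
}

site_thetas <- function(family, etas) {
  th <- lapply(family$param_names, function(pn) {
    family$links[[pn]]$linkinv(etas[[pn]])
  })
  names(th) <- family$param_names
  th
}

#' Site-side inner-cycle update message
#'
#' Computes the link inverses, scores, weights and adjusted dependent vector
#' locally and returns only the aggregate cross-products
#' \eqn{M_{i1} = X_{ik}^\top W_{ik} X_{ik}} and
#' \eqn{M_{i2} = X_{ik}^\top W_{ik} z_{ik}}, the site size, and the site
#' deviance at the broadcast coefficients. No subject-level quantity leaves
#' the site.
#'
#' @param prep Prepared site state (internal).
#' @param family `fg_family` object.
#' @param k Distribution-parameter index being updated.
#' @param coefs Current broadcast coefficients for all parameters.
#' @return An `fg_message`.
#' @keywords internal
site_update <- function(prep, family, k, coefs) {
  etas <- site_etas(prep, coefs)
  theta <- site_thetas(family, etas)
  pn <- family$param_names[[k]]
  X <- prep$designs[[pn]]$X
  q <- ncol(X)
  dev <- -2 * sum(family$loglik(prep$y, theta))
  # an infinite deviance (or a score that cannot be evaluated near this
  # point) marks the broadcast coefficients as unusable; the aggregator
  # reacts by halving the previous step, so the message carries only the
  # flag, not a solveable update
  bad <- structure(list(site_id = prep$site_id, k = k,
                        M1 = matrix(0, q, q), M2 = numeric(q),
                        n_i = prep$n, deviance = Inf, purpose = "update"),
                   class = "fg_message")
  if (!is.finite(dev)) return(bad)
  sw <- try(score_and_weights(family, k, prep$y, theta), silent = TRUE)
  if (inherits(sw, "try-error")) return(bad)
  z <- adjusted_dependent(etas[[pn]], sw)
  w <- sw$w
  structure(list(site_id = prep$site_id, k = k,
                 M1 = crossprod(X, X * w),
                 M2 = drop(crossprod(X, w * z)),
                 n_i = prep$n, deviance = dev, purpose = "update"),
            class = "fg_message")
}

# deviance at candidate coefficient vectors for parameter k (others held at
# the broadcast values); used for delayed deviance monitoring and for
# automated penalty selection
site_eval_deviance <- function(prep, family, k, coefs, candidates) {
  etas <- site_etas(prep, coefs)
  pn <- family$param_names[[k]]
  X <- prep$designs[[pn]]$X
  devs <- vapply(candidates, function(b) {
    etas[[pn]] <- quantize_eta(drop(X %*% b))
    theta <- site_thetas(family, etas)
    d <- -2 * sum(family$loglik(prep$y, theta))
    if (!is.finite(d)) Inf else d   # an unstable candidate simply loses
  }, numeric(1))
  structure(list(site_id = prep$site_id, k = k, dev_candidates = devs,
                 n_i = prep$n, purpose = "penalty_grid"),
            class = "fg_message")
}

#' Site-side numerical Hessian
#'
#' Negative Hessian of the site log-likelihood with respect to the full
#' stacked coefficient vector (all parameters jointly), by central finite
#' differences with per-coordinate step \eqn{h_j = 10^{-4}\max(1, |b_j|)}.
#' Sums of these site matrices equal the pooled information matrix.
#'
#' @inheritParams site_update
#' @param h_scale Relative step size.
#' @return An `fg_message` carrying the site Hessian `H` and deviance.
#' @keywords internal
site_hessian_message <- function(prep, family, coefs, h_scale = 1e-4) {
  pn_all <- names(prep$designs)
  sizes <- vapply(pn_all, function(pn) length(coefs[[pn]]), integer(1))
  b0 <- unlist(coefs[pn_all], use.names = FALSE)
  q <- length(b0)
  unstack <- function(b) {
    out <- list(); at <- 0L
    for (j in seq_along(pn_all)) {
      out[[pn_all[j]]] <- b[(at + 1L):(at + sizes[j])]
      at <- at + sizes[j]
    }
    out
  }
  f <- function(b) {
    # no linear-predictor quantization here: its grid noise would be
    # divided by h^2 in the second differences
    etas <- site_etas(prep, unstack(b), quantize = FALSE)
    theta <- site_thetas(family, etas)
    sum(family$loglik(prep$y, theta))
  }
  h <- h_scale * pmax(1, abs(b0))
  f0 <- f(b0)
  H <- matrix(0, q, q)
  fp <- fm <- numeric(q)
  for (j in seq_len(q)) {
    bp <- bm <- b0
    bp[j] <- b0[j] + h[j]; bm[j] <- b0[j] - h[j]
    fp[j] <- f(bp); fm[j] <- f(bm)
    H[j, j] <- (fp[j] - 2 * f0 + fm[j]) / h[j]^2
  }
  if (q > 1) {
    for (j in seq_len(q - 1)) {
      for (l in (j + 1):q) {
        bpp <- bmm <- bpm <- bmp <- b0
        bpp[j] <- b0[j] + h[j]; bpp[l] <- b0[l] + h[l]
        bmm[j] <- b0[j] - h[j]; bmm[l] <- b0[l] - h[l]
        bpm[j] <- b0[j] + h[j]; bpm[l] <- b0[l] - h[l]
        bmp[j] <- b0[j] - h[j]; bmp[l] <- b0[l] + h[l]
        H[j, l] <- H[l, j] <-
          (f(bpp) - f(bpm) - f(bmp) + f(bmm)) / (4 * h[j] * h[l])
      }
    }
  }
  if (any(!is.finite(H))) {
    idx <- which(!is.finite(H), arr.ind = TRUE)
    stop("non-finite Hessian entry at coefficient indices (",
         idx[1, 1], ", ", idx[1, 2], ") for site '", prep$site_id, "'")
  }
  structure(list(site_id = prep$site_id, H = -H, n_i = prep$n,
                 deviance = -2 * f0, purpose = "inference"),
            class = "fg_message")
}

## ---------------------------------------------------------------------------
## round log

new_round_log <- function() {
  env <- new.env(parent = emptyenv())
  env$rounds <- list()
  env
}

log_round <- function(log, purpose, bytes_per_site) {
  if (is.null(log)) return(invisible(NULL))
  log$rounds[[length(log$rounds) + 1L]] <-
    list(round = length(log$rounds) + 1L, purpose = purpose,
         bytes_per_site = bytes_per_site)
  invisible(NULL)
}

round_log_df <- function(log) {
  if (is.null(log) || !length(log$rounds)) {
    return(data.frame(round = integer(), purpose = character(),
                      bytes_per_site = numeric()))
  }
  data.frame(
    round = vapply(log$rounds, `[[`, integer(1), "round"),
    purpose = vapply(log$rounds, `[[`, character(1), "purpose"),
    bytes_per_site = vapply(log$rounds, `[[`, numeric(1), "bytes_per_site"))
}

## ---------------------------------------------------------------------------
## backends: the engine sees the same interface for pooled and distributed
## fitting; only the distributed backend decomposes every quantity into
## per-site messages and sums them.

#' Aggregate site update messages and solve
#'
#' Sums the site matrices \eqn{M_{i1}, M_{i2}} and solves
#' \eqn{(\sum_i M_{i1} + \lambda \tilde P)\, b = \sum_i M_{i2}} -- identical,
#' to machine precision, to the pooled weighted least-squares solution on the
#' concatenated data.
#'
#' @param messages List of `fg_message` objects for one parameter, one per
#'   site.
#' @param penalty Penalty state list (`P`, `smooth_idx`, `lambda`), or `NULL`.
#' @return New coefficient vector for the parameter.
#' @export
aggregate_and_update <- function(messages, penalty = NULL) {
  ks <- vapply(messages, `[[`, numeric(1), "k")
  if (length(unique(ks)) != 1) stop("messages refer to different parameters")
  qs <- vapply(messages, function(m) ncol(m$M1), integer(1))
  if (length(unique(qs)) != 1) stop("message dimensions disagree across sites")
  M1 <- Reduce(`+`, lapply(messages, `[[`, "M1"))
  M2 <- Reduce(`+`, lapply(messages, `[[`, "M2"))
  if (is.null(penalty)) penalty <- list(P = NULL, smooth_idx = integer(), lambda = 0)
  solve_penalized(M1, M2, penalty)
}

distributed_backend <- function(sites, spec) {
  fam <- spec$family_obj
  covs <- spec_covariates(spec)
  smooth_covs <- spec_smooth_covariates(spec)
  log <- new_round_log()

  summaries <- lapply(sites, site_summary, covariates = covs)
  merged <- merge_summaries(summaries, covs, smooth_covs)
  bases <- make_bases(spec, merged$schema)
  log_round(log, "basis_setup", 64 * (length(covs) + 8))

  preps <- lapply(sites, prepare_site, spec = spec,
                  schema = merged$schema, bases = bases)

  list(
    type = "distributed",
    stats = merged$stats,
    schema = merged$schema,
    bases = bases,
    n_total = sum(vapply(preps, `[[`, integer(1), "n")),
    design_info = design_info_from_prep(preps[[1]]),
    round_log = log,
    update = function(k, coefs) {
      msgs <- lapply(preps, site_update, family = fam, k = k, coefs = coefs)
      q <- ncol(msgs[[1]]$M1)
      log_round(log, "update", 8 * (q^2 + q + 2))
      list(M1 = Reduce(`+`, lapply(msgs, `[[`, "M1")),
           M2 = Reduce(`+`, lapply(msgs, `[[`, "M2")),
           deviance = sum(vapply(msgs, `[[`, numeric(1), "deviance")),
           messages = msgs)
    },
    eval_deviance = function(k, coefs, candidates, purpose = "penalty_grid") {
      msgs <- lapply(preps, site_eval_deviance, family = fam, k = k,
                     coefs = coefs, candidates = candidates)
      log_round(log, purpose, 8 * (length(candidates) + 1))
      Reduce(`+`, lapply(msgs, `[[`, "dev_candidates"))
    },
    inference_round = function(coefs, hessian = TRUE) {
      if (hessian) {
        msgs <- lapply(preps, site_hessian_message, family = fam, coefs = coefs)
        q <- nrow(msgs[[1]]$H)
        log_round(log, "inference", 8 * (q^2 + 2))
        list(H_list = lapply(msgs, `[[`, "H"),
             deviances = vapply(msgs, `[[`, numeric(1), "deviance"))
      } else {
        devs <- vapply(preps, function(pr) {
          etas <- site_etas(pr, coefs)
          -2 * sum(fam$loglik(pr$y, site_thetas(fam, etas)))
        }, numeric(1))
        log_round(log, "inference", 16)
        list(H_list = NULL, deviances = devs)
      }
    }
  )
}

pooled_backend <- function(data, outcome, spec) {
  fam <- spec$family_obj
  covs <- spec_covariates(spec)
  smooth_covs <- spec_smooth_covariates(spec)
  site <- site_data(data, outcome, site_id = "pooled")
  merged <- merge_summaries(list(site_summary(site, covs)), covs, smooth_covs)
  bases <- make_bases(spec, merged$schema)
  prep <- prepare_site(site, spec, merged$schema, bases)

  list(
    type = "pooled",
    stats = merged$stats,
    schema = merged$schema,
    bases = bases,
    n_total = prep$n,
    design_info = design_info_from_prep(prep),
    round_log = NULL,
    update = function(k, coefs) {
      # same site-side code path as the distributed backend; the pooled
      # cross-products are simply computed over all rows at once
      msg <- site_update(prep, fam, k, coefs)
      list(M1 = msg$M1, M2 = msg$M2, deviance = msg$deviance,
           messages = NULL)
    },
    eval_deviance = function(k, coefs, candidates, purpose = "penalty_grid") {
      site_eval_deviance(prep, fam, k, coefs, candidates)$dev_candidates
    },
    inference_round = function(coefs, hessian = TRUE) {
      if (hessian) {
        msg <- site_hessian_message(prep, fam, coefs)
        list(H_list = list(msg$H), deviances = msg$deviance)
      } else {
        etas <- site_etas(prep, coefs)
        list(H_list = NULL,
             deviances = -2 * sum(fam$loglik(prep$y, site_thetas(fam, etas))))
      }
    }
  )
}

make_bases <- function(spec, schema) {
  bases <- list()
  for (ps in spec$params) {
    if (is.null(ps$smooth)) next
    nm <- ps$smooth$covariate
    rng <- schema$ranges[[nm]]
    if (is.null(rng)) stop("no range recorded for smooth covariate '", nm, "'")
    key <- paste0(nm, ":", ps$smooth$n_knots, ":", ps$smooth$degree)
    if (is.null(bases[[key]])) {
      bases[[key]] <- spline_basis(rng[1], rng[2], ps$smooth$n_knots,
                                   ps$smooth$degree)
    }
  }
  bases
}

# bases are keyed by covariate:knots:degree; fetch for a param spec
basis_for <- function(bases, smooth) {
  if (is.null(smooth)) return(NULL)
  bases[[paste0(smooth$covariate, ":", smooth$n_knots, ":", smooth$degree)]]
}

design_info_from_prep <- function(prep) {
  lapply(prep$designs, function(d) {
    list(q = ncol(d$X), smooth_idx = d$smooth_idx, colnames = d$colnames)
  })
}
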