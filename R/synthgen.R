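# Seeded synthetic multi-site generators emulating the statistical structure
# of three reference-chart applications: a BMI-like ICU setting (skewed,
# heavy-tailed positive outcome; BCPE), a microbiome relative-abundance
# setting (unit-interval outcome with a small zero mass; zero-inflated
# beta), and a brain-volume setting (positive outcome with rise-then-decline
# trajectory; generalized gamma). True parameter curves are closed-form
# (logistic/Gaussian-bump mixtures), deliberately not splines, so recovery
# tests also probe basis approximation error. Site effects enter as small
# additive shifts on the location linear predictor.

#' Synthetic multi-site scenario
#'
#' @param name `"bmi_like"` (BCPE outcome, 9 sites of very unequal size,
#'   ages 18-100), `"microbiome_like"` (zero-inflated beta outcome, 11 sites
#'   of 8-89 subjects, ages 0.16-83, zero mass 2.66%), or `"brainvol_like"`
#'   (generalized gamma outcome, 15 sites of strongly unbalanced size, ages
#'   3.2-100).
#' @param n_total Total subjects across sites (defaults: 5000 / 569 / 3000).
#' @param seed Seed; generation is fully reproducible from it.
#' @param site_effect_sd Standard deviation of the per-site additive shift
#'   on the location linear predictor (scenario-specific small default).
#' @return An object of class `fg_scenario`.
#' @export
scenario <- function(name = c("bmi_like", "microbiome_like", "brainvol_like"),
                     n_total = NULL, seed = 1, site_effect_sd = NULL) {
  name <- match.arg(name)
  preset <- switch(name,
    bmi_like = list(
      family = "BCPE", n_sites = 9L, n_total = 5000L,
      site_effect_sd = 0.15,
      # very unequal site sizes, as in ICU-type registries
      share = c(4222, 3522, 2584, 2616, 3102, 8269, 140, 340, 317) / 25112,
      age_range = c(18, 100), log_age = FALSE,
      theta_fun = function(age, sex) list(
        mu = 23 + 6 * exp(-((age - 55) / 28)^2) + 0.8 * (sex == "M"),
        sigma = 0.13 + 0.03 * exp(-((age - 55) / 30)^2),
        nu = -0.3 - 0.2 * exp(-((age - 50) / 30)^2),
        tau = rep_len(2.5, length(age)))
    ),
    microbiome_like = list(
      family = "BEZI", n_sites = 11L, n_total = 569L,
      site_effect_sd = 0.1,
      share = c(8, 22, 31, 40, 47, 52, 57, 63, 75, 85, 89) / 569,
      age_range = c(0.16, 83), log_age = TRUE,
      theta_fun = function(age, sex) list(
        mu = stats::plogis(-2.6 + 1.2 * stats::plogis((age - 45) / 12) +
                             0.12 * (sex == "F")),
        sigma = stats::plogis(-0.2 - 0.5 * stats::plogis((age - 30) / 15)),
        nu = rep_len(0.0266, length(age)))
    ),
    brainvol_like = list(
      family = "GG", n_sites = 15L, n_total = 3000L,
      site_effect_sd = 0.02,
      share = 1.55^(1:15) / sum(1.55^(1:15)),
      age_range = c(3.2, 100), log_age = TRUE,
      theta_fun = function(age, sex) list(
        mu = (0.42 + 0.28 * stats::plogis((age - 7) / 2.5) *
                (1 - 0.55 * stats::plogis((age - 40) / 18))) *
          exp(0.05 * (sex == "M")),
        sigma = 0.085 + 0.05 * exp(-age / 15),
        nu = 1.4 - 0.5 * stats::plogis((age - 40) / 15))
    ))
  if (!is.null(n_total)) preset$n_total <- as.integer(n_total)
  if (!is.null(site_effect_sd)) preset$site_effect_sd <- site_effect_sd
  structure(c(list(name = name, seed = seed), preset),
            class = "fg_scenario")
}

#' @export
print.fg_scenario <- function(x, ...) {
  cat("Synthetic scenario '", x$name, "': family ", x$family, ", ",
      x$n_sites, " sites, n = ", x$n_total, ", seed ", x$seed, "\n", sep = "")
  invisible(x)
}

# largest-remainder allocation of n_total over shares, floored at 5
allocate_sizes <- function(n_total, share, min_n = 5L) {
  raw <- n_total * share
  sizes <- floor(raw)
  rem <- n_total - sum(sizes)
  if (rem > 0) {
    idx <- order(raw - sizes, decreasing = TRUE)[seq_len(rem)]
    sizes[idx] <- sizes[idx] + 1
  }
  pmax(as.integer(sizes), min_n)
}

#' Generate multi-site synthetic data
#'
#' Fully deterministic under the scenario seed: repeated calls return
#' byte-identical data. Sites have heterogeneous age windows (the first site
#' always spans the full range so the global covariate range equals the
#' scenario range). Outcomes are drawn by inverse-CDF sampling from the
#' scenario's true conditional distribution, so zero-inflated scenarios hit
#' their configured zero mass in expectation.
#'
#' @param scn An [scenario()] object.
#' @return List of [site_data()] objects (columns `y`, `age`, `sex`,
#'   `site`).
#' @export
generate_sites <- function(scn) {
  fam <- fg_family(scn$family)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(scn$seed)
  sizes <- allocate_sizes(scn$n_total, scn$share)
  shifts <- stats::rnorm(scn$n_sites, 0, scn$site_effect_sd)
  lo <- scn$age_range[1]; hi <- scn$age_range[2]
  sites <- vector("list", scn$n_sites)
  for (j in seq_len(scn$n_sites)) {
    n <- sizes[j]
    if (j == 1) {
      a_lo <- lo; a_hi <- hi
    } else {
      span <- hi - lo
      a_lo <- lo + stats::runif(1, 0, 0.25 * span)
      a_hi <- hi - stats::runif(1, 0, 0.25 * span)
    }
    age <- if (scn$log_age) {
      exp(stats::runif(n, log(a_lo), log(a_hi)))
    } else {
      stats::runif(n, a_lo, a_hi)
    }
    if (j == 1 && n >= 2) {
      age[1] <- lo; age[2] <- hi   # pin the global range
    }
    sex <- ifelse(stats::runif(n) < 0.5, "F", "M")
    theta <- scn$theta_fun(age, sex)
    # site effect shifts the location linear predictor
    mu_link <- fam$links$mu
    theta$mu <- mu_link$linkinv(mu_link$linkfun(theta$mu) + shifts[j])
    u <- stats::runif(n)
    y <- family_quantile(fam, pmin(pmax(u, 1e-12), 1 - 1e-12), theta)
    df <- data.frame(y = y, age = age, sex = sex,
                     site = sprintf("site%02d", j),
                     stringsAsFactors = FALSE)
    sites[[j]] <- site_data(df, "y", site_id = sprintf("site%02d", j))
  }
  sites
}

#' True conditional quantile of a scenario
#'
#' Analytic quantile of the generating distribution at the given covariates
#' (site effect at zero); the ground truth against which fitted centile
#' curves are scored.
#'
#' @param scn An [scenario()] object.
#' @param covariates Data frame with `age` and `sex` columns.
#' @param q Probability in (0, 1).
#' @return Outcome values.
#' @export
true_quantile <- function(scn, covariates, q) {
  fam <- fg_family(scn$family)
  theta <- scn$theta_fun(covariates$age, covariates$sex)
  family_quantile(fam, q, theta)
}

#' Default model specification for a scenario
#'
#' The model each scenario is meant to be fitted with: smooth age terms for
#' every distribution parameter plus a fixed sex effect. Knot counts follow
#' the scenario regime -- 6/5/2/2 fixed-effect smooths for `bmi_like`,
#' 20-knot penalized smooths for `microbiome_like` and `brainvol_like`.
#'
#' @param scn An [scenario()] object.
#' @param smooth_mode Override the smooth mode for every parameter
#'   (`"fixed"`, `"fixed_penalty"`, `"auto"`); defaults are `"fixed"` for
#'   `bmi_like` and `"auto"` otherwise.
#' @param edf Optional named vector of target EDFs (per parameter) for
#'   `"fixed_penalty"` mode; the penalty is re-solved from the aggregated
#'   cross-product at every iteration.
#' @param lambda Optional named list of fixed penalty weights (per
#'   parameter) for `"fixed_penalty"` mode, e.g. from [match_penalties()].
#' @param ... Passed to [fg_spec()] (e.g. `c`, `criterion`).
#' @return An `fg_spec`.
#' @export
scenario_spec <- function(scn, smooth_mode = NULL, edf = NULL, lambda = NULL,
                          ...) {
  fam <- fg_family(scn$family)
  knots <- switch(scn$name,
                  bmi_like = c(mu = 6, sigma = 5, nu = 2, tau = 2),
                  microbiome_like = c(mu = 20, sigma = 20, nu = 20),
                  brainvol_like = c(mu = 20, sigma = 20, nu = 20))
  mode <- if (!is.null(smooth_mode)) smooth_mode
          else if (scn$name == "bmi_like") "fixed" else "auto"
  args <- list(family = fam, ...)
  for (pn in fam$param_names) {
    # a 2-knot cubic basis has 4 columns and no room for an order-2 penalty
    # worth selecting; small bases stay fixed-effect
    pmode <- if (knots[[pn]] <= 3) "fixed" else mode
    args[[pn]] <- param_spec(
      fixed = "sex",
      smooth = smooth_term("age", n_knots = knots[[pn]], mode = pmode,
                           lambda = if (pmode == "fixed_penalty") lambda[[pn]],
                           edf = if (pmode == "fixed_penalty" &&
                                       is.null(lambda)) edf[[pn]]))
  }
  do.call(fg_spec, args)
}

#' Write scenario sites to CSV files
#'
#' One CSV per site plus a `truth.json` recording the scenario settings, so
#' a simulated federation can be driven from files.
#'
#' @param sites List of [site_data()] objects from [generate_sites()].
#' @param dir Output directory (created if needed).
#' @param scn The generating [scenario()] object.
#' @return Invisibly, the written file paths.
#' @export
write_scenario <- function(sites, dir, scn) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(sites, function(s) {
    p <- file.path(dir, paste0(s$site_id, ".csv"))
    utils::write.csv(s$data, p, row.names = FALSE)
    p
  }, character(1))
  truth <- file.path(dir, "truth.json")
  jsonlite::write_json(
    list(name = scn$name, family = scn$family, n_sites = scn$n_sites,
         n_total = scn$n_total, seed = scn$seed,
         site_effect_sd = scn$site_effect_sd),
    truth, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, truth))
}
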