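#' Read one site's data from CSV
#'
#' Checks the required columns, types them, and drops rows with missing
#' outcome or covariates (with a logged count).
#'
#' @param path CSV file path.
#' @param outcome Outcome column name.
#' @param covariates Character vector of covariate column names.
#' @param site_id Site label (defaults to the file name).
#' @return A [site_data()] object.
#' @export
read_site_csv <- function(path, outcome, covariates,
                          site_id = sub("\\.csv$", "", basename(path))) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(c(outcome, covariates), names(df))
  if (length(missing_cols)) {
    stop("column(s) missing from ", path, ": ",
         paste(missing_cols, collapse = ", "))
  }
  keep <- !is.na(df[[outcome]])
  for (nm in covariates) keep <- keep & !is.na(df[[nm]])
  if (any(!keep)) {
    message("dropped ", sum(!keep), " row(s) with missing values from '",
            site_id, "'")
  }
  site_data(df[keep, , drop = FALSE], outcome, site_id = site_id)
}

#' Parse and validate a run configuration
#'
#' Configurations are JSON with fields: `family`; `formulas`, a named object
#' of per-parameter formula strings (see [parse_formula()]); either
#' `site_csvs` (+ `outcome`, `covariates`) or `scenario` (+ optional
#' `n_total`); optional `c`, `criterion`, `seed`, `centiles`,
#' `grid` (named object of covariate values for the reference chart) and
#' `out_dir`.
#'
#' @param config A file path to a JSON configuration or an equivalent list.
#' @return Validated configuration list of class `fg_config`.
#' @export
read_config <- function(config) {
  if (is.character(config)) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  problems <- character()
  if (is.null(config$family)) {
    problems <- c(problems, "family: required")
  } else if (!config$family %in% family_names()) {
    problems <- c(problems, paste0("family: unknown '", config$family, "'"))
  }
  if (is.null(config$formulas) || is.null(names(config$formulas))) {
    problems <- c(problems, "formulas: required named object of parameter formulas")
  }
  has_files <- !is.null(config$site_csvs)
  has_scn <- !is.null(config$scenario)
  if (!has_files && !has_scn) {
    problems <- c(problems, "site_csvs or scenario: one input source required")
  }
  if (has_files && is.null(config$outcome)) {
    problems <- c(problems, "outcome: required with site_csvs")
  }
  if (length(problems)) {
    stop("invalid configuration:\n  ", paste(problems, collapse = "\n  "))
  }
  config$c <- config$c %||% 0.05
  config$criterion <- config$criterion %||% "BIC"
  config$seed <- config$seed %||% 1
  config$out_dir <- config$out_dir %||% "fedgamlss_out"
  config$centiles <- config$centiles %||% c(2.5, 10, 25, 50, 75, 90, 97.5)
  class(config) <- "fg_config"
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

config_spec <- function(config) {
  fam <- fg_family(config$family)
  args <- list(family = fam, c = config$c, criterion = config$criterion)
  for (pn in names(config$formulas)) {
    if (!pn %in% fam$param_names) {
      stop("formula given for '", pn, "' but family ", fam$name,
           " has parameters ", paste(fam$param_names, collapse = ", "))
    }
    args[[pn]] <- parse_formula(config$formulas[[pn]])
  }
  do.call(fg_spec, args)
}

#' Run a full distributed analysis from a configuration
#'
#' Loads or generates the site data, fits the distributed model, runs the
#' inference round, and writes the artifacts: `coefficients.csv` (Wald
#' table), `fit.json` (coefficients, EDFs, deviance, convergence),
#' `chart.csv` (centile reference table) and `rounds.csv` (communication
#' log).
#'
#' @param config Path to a JSON configuration or a list (see
#'   [read_config()]).
#' @return Invisibly, a list with the fit, the chart and the artifact paths.
#' @export
run_end_to_end <- function(config) {
  config <- read_config(config)
  if (!is.null(config$scenario)) {
    scn <- scenario(config$scenario, n_total = config$n_total,
                    seed = config$seed)
    sites <- generate_sites(scn)
  } else {
    covs <- unique(unlist(lapply(config$formulas, function(f) {
      ps <- parse_formula(f)
      c(ps$fixed, if (!is.null(ps$smooth)) ps$smooth$covariate)
    })))
    sites <- lapply(config$site_csvs, read_site_csv,
                    outcome = config$outcome, covariates = covs)
  }
  spec <- config_spec(config)
  fit <- fit_distributed(sites, spec, inference = TRUE)

  grid <- config$grid
  if (is.null(grid)) {
    smcovs <- spec_smooth_covariates(spec)
    grid <- list()
    for (nm in smcovs) {
      rng <- fit$schema$ranges[[nm]]
      grid[[nm]] <- seq(rng[1], rng[2], length.out = 50)
    }
    for (nm in names(fit$schema$factors)) {
      grid[[nm]] <- fit$schema$factors[[nm]]
    }
  }
  chart <- reference_chart(fit, grid, centiles = config$centiles)

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    coefficients = file.path(config$out_dir, "coefficients.csv"),
    fit = file.path(config$out_dir, "fit.json"),
    chart = file.path(config$out_dir, "chart.csv"),
    rounds = file.path(config$out_dir, "rounds.csv"))
  utils::write.csv(fit$inference$table, paths[["coefficients"]],
                   row.names = FALSE)
  jsonlite::write_json(
    list(family = fit$family,
         coefficients = fit$coefficients,
         edf = as.list(fit$edf), lambda = as.list(fit$lambda),
         global_deviance = fit$global_deviance,
         bic = fit_bic(fit),
         converged = fit$converged,
         n_total = fit$n_total,
         rounds = nrow(fit$round_log),
         seed = config$seed),
    paths[["fit"]], auto_unbox = TRUE, digits = NA)
  utils::write.csv(as.data.frame(chart), paths[["chart"]], row.names = FALSE)
  utils::write.csv(fit$round_log, paths[["rounds"]], row.names = FALSE)
  invisible(list(fit = fit, chart = chart, paths = paths))
}
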