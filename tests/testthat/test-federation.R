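# Distributed protocol: message additivity, aggregation, convergence rule,
# round accounting, automated penalty selection, privacy boundary.

test_that("site cross-products sum to the pooled cross-products exactly", {
  df <- make_gaussian_df(240, seed = 30)
  spec <- fg_spec("NO", mu = param_spec(fixed = "sex",
                                        smooth = smooth_term("age", 6)))
  sites <- partition_sites(df, 3, seed = 31)
  bk_d <- fedgamlss:::distributed_backend(sites, spec)
  bk_p <- fedgamlss:::pooled_backend(df, "y", spec)
  # identical initial coefficients from the moment exchange
  th0 <- spec$family_obj$init(bk_d$stats)
  coefs <- list(
    mu = c(rep(th0$mu, 8), 0),
    sigma = log(th0$sigma))
  for (k in 1:2) {
    md <- bk_d$update(k, coefs)
    mp <- bk_p$update(k, coefs)
    expect_equal(md$M1, mp$M1, tolerance = 1e-12)
    expect_equal(md$M2, mp$M2, tolerance = 1e-12)
    expect_equal(md$deviance, mp$deviance, tolerance = 1e-12)
  }
})

test_that("aggregating messages equals the pooled WLS solve", {
  set.seed(32)
  n <- 90
  X <- cbind(1, runif(n), rnorm(n))
  w <- rexp(n) + 0.05
  z <- rnorm(n)
  idx <- sample(rep(1:3, length.out = n))
  msgs <- lapply(1:3, function(j) {
    Xi <- X[idx == j, , drop = FALSE]
    structure(list(site_id = j, k = 1,
                   M1 = crossprod(Xi, Xi * w[idx == j]),
                   M2 = drop(crossprod(Xi, (w * z)[idx == j])),
                   n_i = sum(idx == j)), class = "fg_message")
  })
  b_agg <- aggregate_and_update(msgs)
  b_pool <- wls_solve(X, w, z)
  expect_lt(max(abs(b_agg - b_pool)), 1e-10)
  # an all-zero-weight dummy site changes nothing
  msgs4 <- c(msgs, list(structure(list(site_id = 4, k = 1,
                                       M1 = matrix(0, 3, 3), M2 = rep(0, 3),
                                       n_i = 5), class = "fg_message")))
  expect_equal(aggregate_and_update(msgs4), b_agg)
  # dimension mismatches abort
  bad <- msgs
  bad[[2]]$M1 <- diag(2); bad[[2]]$M2 <- c(0, 0)
  expect_error(aggregate_and_update(bad), "dimensions")
})

test_that("the coefficient convergence rule follows its definition", {
  conv <- fedgamlss:::proportion_converged
  expect_true(conv(1.00, 1.04, 0.05))
  expect_false(conv(1.00, 1.06, 0.05))
  # absolute fallback at zero
  expect_true(conv(0, 1e-12, 0.05))
  expect_false(conv(0, 1e-3, 0.05))
  # every coefficient must pass
  expect_false(conv(c(1, 1), c(1.01, 1.2), 0.05))
})

test_that("basis setup merges ranges and warns on disjoint site coverage", {
  spec <- fg_spec("NO", mu = param_spec(smooth = smooth_term("age", 5)))
  mk <- function(lo, hi, n = 40, id = "a") {
    set.seed(nchar(id) + lo)
    age <- runif(n, lo, hi)
    site_data(data.frame(y = rnorm(n), age = age), "y", id)
  }
  bk <- fedgamlss:::distributed_backend(list(mk(0, 50, id = "a"),
                                             mk(30, 100, id = "bb")), spec)
  expect_equal(unname(bk$schema$ranges$age),
               range(c(bk$bases[[1]]$lower, bk$bases[[1]]$upper)))
  expect_lt(bk$schema$ranges$age[1], 1)
  expect_gt(bk$schema$ranges$age[2], 99)
  # single site: that site's range
  bk1 <- fedgamlss:::distributed_backend(list(mk(10, 20, id = "c")), spec)
  expect_gte(bk1$schema$ranges$age[1], 10)
  expect_lte(bk1$schema$ranges$age[2], 20)
  # disjoint ranges are allowed but warn about the unsupported gap
  expect_warning(
    fedgamlss:::distributed_backend(list(mk(0, 10, id = "d"),
                                         mk(90, 100, id = "ee")), spec),
    "gap")
  # missing covariate names the site
  bad <- site_data(data.frame(y = rnorm(10), z = 1:10), "y", "nosite")
  expect_error(fedgamlss:::distributed_backend(list(bad), spec),
               "age.*missing|missing.*age")
})

test_that("gaussian intercept-only distributed fit hits the global mean in one update", {
  df <- data.frame(y = rnorm(120, 10, 2))
  sites <- partition_sites(df, 4, seed = 33)
  fit <- fit_distributed(sites, fg_spec("NO"), inference = FALSE)
  expect_equal(unname(fit$coefficients$mu), mean(df$y), tolerance = 1e-9)
  # round accounting: setup + one update round per inner iteration + inference
  expect_equal(nrow(fit$round_log),
               1L + sum(fit$n_inner_iterations) + 1L)
  expect_equal(fit$round_log$purpose[1], "basis_setup")
  expect_equal(fit$round_log$purpose[nrow(fit$round_log)], "inference")
})

test_that("distributed and pooled fits agree for any partition", {
  df <- make_gaussian_df(300, seed = 34)
  spec <- fg_spec("NO",
                  mu = param_spec(fixed = "sex",
                                  smooth = smooth_term("age", 6)),
                  sigma = param_spec(fixed = "sex"))
  pfit <- fit_pooled(df, "y", spec, inference = FALSE)
  for (m in c(1, 2, 5, 8)) {
    sites <- partition_sites(df, m, seed = 40 + m)
    dfit <- fit_distributed(sites, spec, inference = FALSE)
    expect_equal(length(dfit$history), length(pfit$history))
    iters <- seq_len(min(length(dfit$history), length(pfit$history)))
    traj <- max(vapply(iters, function(i) {
      max(abs(dfit$history[[i]]$coef - pfit$history[[i]]$coef))
    }, numeric(1)))
    expect_lt(traj, 1e-10)
    expect_lt(max(abs(unlist(dfit$coefficients) - unlist(pfit$coefficients))),
              1e-6)
  }
})

test_that("messages carry only aggregate payloads (privacy boundary)", {
  df <- make_gaussian_df(160, seed = 35)
  spec <- fg_spec("NO", mu = param_spec(smooth = smooth_term("age", 6)))
  sites <- partition_sites(df, 2, seed = 36)
  bk <- fedgamlss:::distributed_backend(sites, spec)
  th0 <- spec$family_obj$init(bk$stats)
  coefs <- list(mu = rep(th0$mu, 8), sigma = log(th0$sigma))
  upd <- bk$update(1, coefs)
  n_small <- min(vapply(sites, function(s) nrow(s$data), integer(1)))
  q <- length(coefs$mu)
  for (msg in upd$messages) {
    expect_s3_class(msg, "fg_message")
    expect_true(all(names(msg) %in% fedgamlss:::MESSAGE_FIELDS))
    for (fld in setdiff(names(msg), c("site_id", "purpose"))) {
      expect_lte(length(msg[[fld]]), q * q)
    }
    # no per-subject vector can hide in the payload
    expect_false(any(vapply(msg, function(v) length(v) == n_small &&
                              !is.matrix(v) && q * q != n_small, logical(1))))
  }
})

test_that("automated selection smooths hard when the truth is linear", {
  set.seed(37)
  n <- 700
  df <- data.frame(age = runif(n, 0, 10))
  df$y <- 1 + 0.3 * df$age + rnorm(n, 0, 0.4)
  spec <- fg_spec("NO",
                  mu = param_spec(smooth = smooth_term("age", 12, mode = "auto")))
  fit <- fit_pooled(df, "y", spec, inference = FALSE)
  expect_true(fit$converged)
  expect_equal(unname(fit$edf["mu"]), 2, tolerance = 0.15)
  expect_gte(unname(fit$lambda["mu"]), sort(default_lambda_grid())[15])
})

test_that("automated selection keeps flexibility when the truth is wiggly", {
  set.seed(38)
  n <- 1500
  df <- data.frame(age = runif(n, 0, 10))
  df$y <- sin(1.5 * df$age) + rnorm(n, 0, 0.25)
  spec <- fg_spec("NO",
                  mu = param_spec(smooth = smooth_term("age", 12, mode = "auto")))
  fit <- fit_pooled(df, "y", spec, inference = FALSE)
  expect_gt(unname(fit$edf["mu"]), 5)
})

test_that("a single-candidate grid is identical to the fixed-penalty mode", {
  df <- make_gaussian_df(260, seed = 39)
  lam0 <- 3.7
  spec_auto <- fg_spec("NO",
    mu = param_spec(smooth = smooth_term("age", 10, mode = "auto")),
    lambda_grid = lam0)
  spec_fixed <- fg_spec("NO",
    mu = param_spec(smooth = smooth_term("age", 10, mode = "fixed_penalty",
                                         lambda = lam0)))
  fa <- fit_pooled(df, "y", spec_auto, inference = FALSE)
  ff <- fit_pooled(df, "y", spec_fixed, inference = FALSE)
  expect_equal(fa$coefficients, ff$coefficients, tolerance = 1e-10)
  expect_equal(unname(fa$lambda["mu"]), lam0)
})

test_that("automated distributed fit logs penalty-grid rounds and matches pooled", {
  df <- make_gaussian_df(400, seed = 41)
  spec <- fg_spec("NO",
    mu = param_spec(fixed = "sex",
                    smooth = smooth_term("age", 10, mode = "auto")))
  sites <- partition_sites(df, 3, seed = 42)
  dfit <- fit_distributed(sites, spec, inference = FALSE)
  pfit <- fit_pooled(df, "y", spec, inference = FALSE)
  expect_equal(unname(dfit$lambda["mu"]), unname(pfit$lambda["mu"]))
  expect_lt(max(abs(unlist(dfit$coefficients) - unlist(pfit$coefficients))),
            1e-6)
  expect_gt(sum(dfit$round_log$purpose == "penalty_grid"), 0)
})
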