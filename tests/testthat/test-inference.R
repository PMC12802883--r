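# Distributed inference: Hessian additivity, Wald agreement with closed
# forms and with the pooled fit, likelihood-ratio testing.

test_that("gaussian site Hessian for the mean equals the site size", {
  set.seed(50)
  df <- data.frame(y = rnorm(60, 0, 1))
  spec <- fg_spec("NO")
  bk <- fedgamlss:::pooled_backend(df, "y", spec)
  mle <- fit_pooled(df, "y", spec, inference = FALSE)
  inf <- bk$inference_round(mle$coefficients, hessian = TRUE)
  H <- inf$H_list[[1]]
  # information for mu at the MLE is n / sigma^2
  expect_equal(H[1, 1], unname(60 / exp(2 * mle$coefficients$sigma[1])),
               tolerance = 1e-4)
})

test_that("site Hessians add to the pooled Hessian across partitions", {
  df <- make_gaussian_df(220, seed = 51)
  spec <- fg_spec("NO", mu = param_spec(fixed = "sex",
                                        smooth = smooth_term("age", 5)))
  fit <- fit_pooled(df, "y", spec, inference = FALSE)
  bk_p <- fedgamlss:::pooled_backend(df, "y", spec)
  H_pool <- bk_p$inference_round(fit$coefficients)$H_list[[1]]
  for (m in c(2, 4)) {
    sites <- partition_sites(df, m, seed = 52 + m)
    bk_d <- fedgamlss:::distributed_backend(sites, spec)
    H_sum <- Reduce(`+`, bk_d$inference_round(fit$coefficients)$H_list)
    expect_equal(H_sum, H_pool, tolerance = 1e-6)
  }
})

test_that("Hessians still compute away from the optimum", {
  df <- make_gaussian_df(80, seed = 53)
  spec <- fg_spec("NO", mu = param_spec(fixed = "sex"))
  fit <- fit_pooled(df, "y", spec, inference = FALSE)
  shifted <- fit$coefficients
  shifted$mu <- shifted$mu + 2
  bk <- fedgamlss:::pooled_backend(df, "y", spec)
  H <- bk$inference_round(shifted)$H_list[[1]]
  expect_true(all(is.finite(H)))
})

test_that("standard errors match the Gaussian closed form and the pooled fit", {
  set.seed(54)
  n <- 400
  df <- data.frame(x = runif(n), sex = sample(c("F", "M"), n, TRUE))
  df$y <- 1 + 2 * df$x + rnorm(n, 0, 0.7)
  spec <- fg_spec("NO", mu = param_spec(fixed = c("x", "sex")),
                  c = 1e-4, max_outer = 100)
  sites <- partition_sites(df, 3, seed = 55)
  dfit <- fit_distributed(sites, spec)
  pfit <- fit_pooled(df, "y", spec)
  expect_equal(dfit$inference$table$se, pfit$inference$table$se,
               tolerance = 1e-4)
  X <- cbind(1, df$x, df$sex == "M")
  sig2 <- exp(2 * dfit$coefficients$sigma[1])
  se_cf <- sqrt(diag(sig2 * solve(crossprod(X))))
  expect_equal(dfit$inference$table$se[1:3], se_cf, tolerance = 1e-4,
               ignore_attr = TRUE)
  # single site: covariance equals the inverse of that site's Hessian
  one <- fit_distributed(list(site_data(df, "y", "only")), spec)
  expect_equal(one$inference$table$se, pfit$inference$table$se,
               tolerance = 1e-6)
})

test_that("covariance is symmetric with positive diagonal", {
  df <- make_gaussian_df(150, seed = 56)
  spec <- fg_spec("NO", mu = param_spec(smooth = smooth_term("age", 6)))
  fit <- fit_pooled(df, "y", spec)
  S <- fit$inference$covariance
  expect_equal(S, t(S), tolerance = 1e-8)
  expect_true(all(diag(S) > 0))
  expect_equal(fit$inference$table$se, sqrt(diag(S)))
})

test_that("the likelihood-ratio statistic and p-value follow the chi-square null", {
  r0 <- lrt_smooth(100, 100, 4)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p, 1)
  r1 <- lrt_smooth(100, 103.84, 1)
  expect_equal(r1$p, 0.05, tolerance = 1e-3)
  # small negatives clamp, large negatives error
  expect_equal(lrt_smooth(100, 100 - 1e-8, 2)$statistic, 0)
  expect_error(lrt_smooth(100, 99, 2), "not nested")
  # non-integer df (fixed-penalty EDF) is accepted
  expect_equal(lrt_smooth(0, qchisq(0.95, 3.4), 3.4)$p, 0.05,
               tolerance = 1e-10)
})

test_that("the smooth-term LRT wrapper fits the reduced model and refuses auto mode", {
  df <- make_gaussian_df(400, seed = 57, sd = 1)
  spec <- fg_spec("NO", mu = param_spec(smooth = smooth_term("age", 5)))
  full <- fit_pooled(df, "y", spec, inference = FALSE)
  lr <- lrt_smooth_fit(full, df, "mu", outcome = "y")
  # truth has a real age effect: overwhelming evidence
  expect_lt(lr$p, 1e-6)
  expect_equal(lr$df, 6)  # 7 basis columns versus intercept
  spec_auto <- fg_spec("NO",
    mu = param_spec(smooth = smooth_term("age", 8, mode = "auto")))
  full_auto <- fit_pooled(df, "y", spec_auto, inference = FALSE)
  expect_error(lrt_smooth_fit(full_auto, df, "mu", outcome = "y"),
               "not offered|liberal|data-driven")
})
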