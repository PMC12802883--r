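# Pooled RS algorithm: adjusted dependent vector, WLS solve, closed-form
# Gaussian special cases, smooth-term recovery.

test_that("adjusted dependent variable follows its definition", {
  expect_equal(adjusted_dependent(c(1, 2), list(u = c(2, 4), w = c(2, 4))),
               c(2, 3))
  # u = 0 leaves the fit unchanged
  expect_equal(adjusted_dependent(c(0.3, -1), list(u = c(0, 0), w = c(1, 2))),
               c(0.3, -1))
  # Gaussian identity link: z recovers y exactly for any mu, sigma
  y <- c(3, 7, -2)
  mu <- c(1, 1, 1); sig <- 2.5
  sw <- score_and_weights(fg_family("NO"), 1, y, list(mu = mu, sigma = sig))
  expect_equal(adjusted_dependent(mu, sw), y)
})

test_that("wls_solve matches closed forms", {
  # identity design with unit weights returns z
  z <- c(1.5, -2, 0.3)
  expect_equal(wls_solve(diag(3), rep(1, 3), z), z)
  # hand-computable simple linear regression, n = 5
  x <- c(0, 1, 2, 3, 4)
  z5 <- c(1.1, 1.9, 3.2, 3.8, 5.1)
  X <- cbind(1, x)
  b <- wls_solve(X, rep(1, 5), z5)
  expect_equal(b, drop(solve(crossprod(X)) %*% crossprod(X, z5)),
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("an infinite order-2 penalty collapses the smooth onto its null space", {
  set.seed(2)
  n <- 120
  x <- runif(n)
  z <- 2 + 3 * x + rnorm(n, 0, 0.2)
  w <- rexp(n) + 0.1
  b <- spline_basis(0, 1, n_knots = 8)
  B <- evaluate_basis(b, x)
  pen <- list(P = difference_penalty(ncol(B), 2),
              smooth_idx = seq_len(ncol(B)), lambda = 1e12)
  fitted_smooth <- drop(B %*% wls_solve(B, w, z, pen))
  # exact limit: weighted projection onto coefficient sequences that are
  # linear in the basis index, mapped through the basis
  N <- cbind(drop(B %*% rep(1, ncol(B))), drop(B %*% seq_len(ncol(B))))
  proj <- lm.wfit(N, z, w)
  expect_equal(fitted_smooth, drop(N %*% proj$coefficients),
               tolerance = 1e-4, ignore_attr = TRUE)
  # which is close to (though, with repeated boundary knots, not exactly)
  # the weighted straight line in x
  lin <- lm.wfit(cbind(1, x), z, w)
  expect_equal(fitted_smooth, drop(cbind(1, x) %*% lin$coefficients),
               tolerance = 0.1, ignore_attr = TRUE)
})

test_that("Gaussian intercept-only fit recovers mean and MLE sd", {
  set.seed(10)
  df <- data.frame(y = rnorm(150, 4, 2))
  fit <- fit_pooled(df, "y", fg_spec("NO", c = 1e-5, max_outer = 100),
                    inference = FALSE)
  expect_true(fit$converged)
  expect_equal(unname(fit$coefficients$mu), mean(df$y), tolerance = 1e-7)
  expect_equal(exp(unname(fit$coefficients$sigma)),
               sqrt(mean((df$y - mean(df$y))^2)), tolerance = 1e-6)
})

test_that("Gaussian linear model equals ordinary least squares", {
  set.seed(11)
  df <- data.frame(x = runif(200))
  df$y <- 1 + 2 * df$x + rnorm(200, 0, 0.5)
  fit <- fit_pooled(df, "y", fg_spec("NO", mu = param_spec(fixed = "x"),
                                     c = 1e-6, max_outer = 200),
                    inference = FALSE)
  expect_equal(unname(fit$coefficients$mu),
               unname(coef(lm(y ~ x, df))), tolerance = 1e-8)
})

test_that("subject order does not change the fit", {
  df <- make_gaussian_df(250, seed = 12)
  spec <- fg_spec("NO", mu = param_spec(fixed = "sex",
                                        smooth = smooth_term("age", 6)))
  f1 <- fit_pooled(df, "y", spec, inference = FALSE)
  f2 <- fit_pooled(df[sample(nrow(df)), ], "y", spec, inference = FALSE)
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-9)
})

test_that("deviance is non-increasing over accepted updates", {
  df <- make_gaussian_df(300, seed = 13)
  spec <- fg_spec("NO", mu = param_spec(smooth = smooth_term("age", 6)),
                  sigma = param_spec())
  fit <- fit_pooled(df, "y", spec, inference = FALSE)
  expect_true(fit$converged)
  # refitting from the fitted state cannot increase the deviance: one more
  # update changes every coefficient by less than c
  expect_true(all(fit$n_inner_iterations >= 1))
})

test_that("smooth BCPE recovery: fitted location tracks the truth", {
  scn <- scenario("bmi_like", n_total = 2000, seed = 21)
  sites <- generate_sites(scn)
  df <- rbind_sites(sites)
  fit <- fit_pooled(df, "y", scenario_spec(scn), inference = FALSE)
  expect_true(fit$converged)
  grid <- data.frame(age = seq(20, 98, length.out = 30), sex = "F")
  med_hat <- as.data.frame(reference_chart(fit, list(age = grid$age, sex = "F"),
                                           centiles = 50))$c50
  med_true <- true_quantile(scn, grid, 0.5)
  expect_lt(mean(abs(med_hat / med_true - 1)), 0.03)
})

test_that("unconverged fits are flagged", {
  df <- make_gaussian_df(150, seed = 14)
  spec <- fg_spec("NO", mu = param_spec(smooth = smooth_term("age", 6)),
                  c = 1e-10, max_outer = 1, max_inner = 1)
  expect_warning(fit <- fit_pooled(df, "y", spec, inference = FALSE),
                 "did not converge")
  expect_false(fit$converged)
})
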