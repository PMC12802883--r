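# Distribution layer: densities, links, scores/weights, quantiles.

test_that("link functions invert and differentiate correctly", {
  grids <- list(identity = seq(-5, 5, length.out = 11),
                log = seq(-3, 3, length.out = 11),
                logit = seq(-4, 4, length.out = 11))
  for (nm in names(grids)) {
    lk <- fg_link(nm)
    eta <- grids[[nm]]
    expect_equal(lk$linkfun(lk$linkinv(eta)), eta, tolerance = 1e-10)
    fd <- (lk$linkinv(eta + 1e-6) - lk$linkinv(eta - 1e-6)) / 2e-6
    expect_equal(lk$dtheta_deta(eta), fd, tolerance = 1e-6)
  }
})

test_that("reference log-likelihood values hold", {
  no <- fg_family("NO")
  expect_equal(family_loglik(no, 0, list(mu = 0, sigma = 1)),
               -0.5 * log(2 * pi))
  bezi <- fg_family("BEZI")
  # the point mass at zero is the mixing probability, whatever mu and sigma
  expect_equal(family_loglik(bezi, 0, list(mu = 0.4, sigma = 0.3, nu = 0.3)),
               log(0.3))
  expect_equal(family_loglik(bezi, 0, list(mu = 0.7, sigma = 0.6, nu = 0.3)),
               log(0.3))
})

test_that("generalized gamma reduces to the gamma distribution at nu = 1", {
  gg <- fg_family("GG")
  y <- c(0.2, 0.7, 1.3, 2.5, 8)
  th <- list(mu = 1.4, sigma = 0.45, nu = 1)
  shape <- 1 / 0.45^2
  expect_equal(family_loglik(gg, y, th),
               dgamma(y, shape = shape, rate = shape / 1.4, log = TRUE),
               tolerance = 1e-8)
  # and the density normalizes numerically
  I <- integrate(function(v) exp(family_loglik(gg, v, th)), 1e-10, Inf,
                 rel.tol = 1e-10)$value
  expect_equal(I, 1, tolerance = 1e-6)
})

test_that("BCPE at tau = 2 matches an independently coded Box-Cox normal", {
  bcpe <- fg_family("BCPE")
  th <- list(mu = 25, sigma = 0.12, nu = -0.5, tau = 2)
  y <- c(15, 20, 25, 30, 40)
  # Box-Cox normal: z-transform of y, normal kernel, truncation constant
  z <- ((y / th$mu)^th$nu - 1) / (th$nu * th$sigma)
  ll_bcn <- (th$nu - 1) * log(y) - th$nu * log(th$mu) - log(th$sigma) +
    dnorm(z, log = TRUE) - log(pnorm(1 / (th$sigma * abs(th$nu))))
  expect_equal(family_loglik(bcpe, y, th), ll_bcn, tolerance = 1e-8)
})

test_that("densities normalize over the support", {
  for (nm in c("NO", "BCPE", "BEZI", "GG")) {
    r <- validate_family(nm, n_draws = 12, seed = 42)
    expect_lt(r$max_normalization_error, 1e-6)
  }
})

test_that("scores and weights match finite differences of the log-likelihood", {
  for (nm in c("NO", "BEZI")) {
    fam <- fg_family(nm)
    set.seed(7)
    for (rep in 1:25) {
      th <- fedgamlss:::random_theta(fam)
      y <- draw_valid_y(fam, th, n = 10, seed = rep)
      for (k in seq_len(fam$p)) {
        sw <- score_and_weights(fam, k, y, th)
        fd <- fedgamlss:::fd_score(fam, k, y, th)
        expect_equal(sw$u, fd$u, tolerance = 1e-5)
        # weights: compare where the observed information is positive
        # (elsewhere the u^2 safeguard applies by design)
        pos <- fd$w > 1e-6
        expect_equal(sw$w[pos], fd$w[pos], tolerance = 1e-5)
      }
    }
  }
})

test_that("reference score values hold for the Gaussian", {
  no <- fg_family("NO")
  sw <- score_and_weights(no, 1, 2, list(mu = 1, sigma = 1))
  expect_equal(sw$u, 1)
  expect_equal(sw$w, 1)
  # score vanishes at the per-subject optimum
  sw0 <- score_and_weights(no, 1, 5, list(mu = 5, sigma = 2))
  expect_equal(sw0$u, 0)
})

test_that("BCPE scores agree with central finite differences at random draws", {
  fam <- fg_family("BCPE")
  set.seed(11)
  for (rep in 1:20) {
    th <- fedgamlss:::random_theta(fam)
    y <- draw_valid_y(fam, th, n = 5, seed = 100 + rep)
    for (k in 1:4) {
      sw <- score_and_weights(fam, k, y, th)
      fd <- fedgamlss:::fd_score(fam, k, y, th)
      expect_equal(sw$u, fd$u, tolerance = 1e-5)
      expect_true(all(is.finite(sw$u)), info = paste("param", k))
      expect_true(all(sw$w > 0))
    }
  }
})

test_that("quantile and cdf round-trip on the continuous support", {
  for (nm in c("NO", "BCPE", "GG")) {
    r <- validate_family(nm, n_draws = 12, seed = 9)
    expect_lt(r$max_roundtrip_error, 1e-8)
  }
  no <- fg_family("NO")
  expect_equal(family_quantile(no, 0.5, list(mu = 3, sigma = 2)), 3)
  expect_equal(family_cdf(no, 3, list(mu = 3, sigma = 2)), 0.5)
})

test_that("zero-inflated quantiles respect the point mass", {
  bezi <- fg_family("BEZI")
  th <- list(mu = 0.4, sigma = 0.4, nu = 0.3)
  expect_equal(family_quantile(bezi, 0.2, th), 0)
  expect_equal(family_cdf(bezi, 0, th), 0.3)
  # above the mass: continuous round trip
  q <- c(0.35, 0.6, 0.9)
  expect_equal(family_cdf(bezi, family_quantile(bezi, q, th), th), q,
               tolerance = 1e-8)
})

test_that("BCPE tail quantile agrees with adaptive quadrature of its density", {
  bcpe <- fg_family("BCPE")
  th <- list(mu = 24, sigma = 0.15, nu = -0.6, tau = 3)
  x975 <- family_quantile(bcpe, 0.975, th)
  mass <- integrate(function(v) exp(family_loglik(bcpe, v, th)),
                    1e-10, x975, rel.tol = 1e-10)$value
  expect_equal(mass, 0.975, tolerance = 1e-6)
})

test_that("out-of-support outcomes and bad probabilities are rejected", {
  bcpe <- fg_family("BCPE")
  expect_error(family_loglik(bcpe, c(1, -2), list(mu = 1, sigma = 0.1,
                                                  nu = 1, tau = 2)),
               "support.*index 2")
  expect_error(family_quantile(fg_family("NO"), 1.2, list(mu = 0, sigma = 1)),
               "strictly inside")
  expect_error(fg_family("POISSON"), "Unknown family")
})

test_that("a corrupted derivative is flagged by the family validator", {
  fam <- fg_family("NO")
  fam$score$mu <- function(y, theta) {
    list(u = (y - theta$mu) / theta$sigma^2 + 0.05,  # deliberate bias
         w = rep_len(1, length(y)) / theta$sigma^2)
  }
  r <- validate_family(fam, n_draws = 5, seed = 1)
  expect_false(r$ok)
  expect_gt(r$max_score_error, 1e-5)
})
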