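test_that("hurdle log-PMF matches its closed-form pieces and an enumeration oracle", {
  # zero branch is log(1 - pi)
  expect_equal(hurdle_logpmf(0, pi = 0.3, lam = 1.5), log(0.7))
  # as lam -> 0 the truncated mass collapses onto y = 1
  expect_equal(hurdle_logpmf(1, pi = 0.5, lam = 1e-8), log(0.5),
               tolerance = 1e-6)
  # brute-force normalization oracle over y = 1..200
  y <- 1:200
  mass <- exp(-1.5) * 1.5^y / factorial(y)
  p2 <- mass[2] / sum(mass)
  expect_equal(hurdle_logpmf(2, pi = 0.5, lam = 1.5), log(0.5 * p2),
               tolerance = 1e-10)
})

test_that("hurdle PMF normalizes to one across a rate/prevalence grid", {
  for (pi in c(0.1, 0.5, 0.9)) {
    for (lam in c(0.1, 1.5, 10)) {
      total <- sum(exp(hurdle_logpmf(0:500, pi = pi, lam = lam)))
      expect_equal(total, 1, tolerance = 1e-10)
    }
  }
})

test_that("hurdle log-PMF rejects invalid arguments", {
  expect_error(hurdle_logpmf(-1, 0.5, 1), "non-negative")
  expect_error(hurdle_logpmf(1.5, 0.5, 1), "integer")
  expect_error(hurdle_logpmf(1, 1.2, 1), "\\[0, 1\\]")
  expect_error(hurdle_logpmf(2, 0.5, -1), "positive")
  # lam is ignored for y = 0
  expect_equal(hurdle_logpmf(0, 0.3, -5), log(0.7))
})

test_that("logistic log-likelihood matches hand values and a grid-search oracle", {
  d <- make_data(n = 200, seed = 3)
  expect_equal(logistic_loglik(c(0, 0, 0), d), -200 * log(2))

  # 6-row dataset with scalar covariate; grid-search oracle for the maximum
  df <- data.frame(y = c(0, 0, 1, 0, 1, 1), x = c(0, 0, 0, 1, 1, 1))
  d6 <- hurdle_data(df)
  expect_equal(logistic_loglik(c(0, 0), d6), -6 * log(2))
  # dense grid over (b0, b1): w has 1 success of 3 at x = 0, 2 of 3 at x = 1
  grid <- seq(-5, 5, by = 0.01)
  best <- -Inf
  for (b0 in grid) {
    eta1 <- b0 + grid
    ll <- (b0 - 3 * log1p(exp(b0))) + (2 * eta1 - 3 * log1p(exp(eta1)))
    best <- max(best, max(ll))
  }
  opt <- stats::optim(c(0, 0), function(b) -logistic_loglik(b, d6))
  expect_equal(-opt$value, best, tolerance = 1e-3)
})

test_that("ZTP log-likelihood matches limits, the mean equation, and a dpois oracle", {
  # single row, y = 1: P(Y=1 | Y>0) -> 1 as lam -> 0
  d1 <- hurdle_data(data.frame(y = 1, x = 0),
                    logistic_covariates = character(0),
                    ztp_covariates = character(0))
  expect_equal(ztp_loglik(log(1e-8), d1), 0, tolerance = 1e-6)

  # intercept-only maximizer solves the ZTP mean equation m(lam) = ybar
  d3 <- hurdle_data(data.frame(y = c(1, 2, 3), x = c(0, 0, 0)),
                    logistic_covariates = character(0),
                    ztp_covariates = character(0))
  root <- stats::uniroot(function(l) exp(l) / (1 - exp(-exp(l))) - 2,
                         c(-5, 3), tol = 1e-12)$root
  opt <- stats::optimize(function(g) ztp_loglik(g, d3), c(-5, 3),
                         maximum = TRUE, tol = 1e-10)
  expect_equal(opt$maximum, root, tolerance = 1e-6)

  # agreement with an independent dpois-based likelihood
  d <- make_data(n = 300, seed = 11)
  g <- rand_coef(3, 21)
  expect_equal(ztp_loglik(g, d), ztp_loglik_oracle(g, d),
               tolerance = 1e-10)
})

test_that("ZTP likelihood requires positive counts", {
  df <- data.frame(y = c(0, 0, 0), x = c(1, 2, 3))
  expect_error(ztp_loglik(c(0, 0), hurdle_data(df)), "no positive counts")
  expect_error(fit_hurdle(df), "no positive counts")
})

test_that("analytic derivatives agree with finite differences over random cases", {
  for (seed in 1:6) {
    d <- make_data(n = 150, seed = seed)
    b <- rand_coef(3, seed + 100)
    g <- rand_coef(3, seed + 200)

    expect_lt(rel_err(logistic_gradient(b, d),
                      fd_gradient(function(x) logistic_loglik(x, d), b)),
              1e-4)
    expect_lt(rel_err(logistic_hessian(b, d),
                      fd_jacobian(function(x) logistic_gradient(x, d), b)),
              1e-4)
    expect_lt(rel_err(ztp_gradient(g, d),
                      fd_gradient(function(x) ztp_loglik(x, d), g)),
              1e-4)
    expect_lt(rel_err(ztp_hessian(g, d),
                      fd_jacobian(function(x) ztp_gradient(x, d), g)),
              1e-4)
  }
})

test_that("component Hessians have the right definiteness", {
  d <- make_data(n = 200, seed = 5)
  for (seed in 1:3) {
    b <- rand_coef(3, seed)
    ev_l <- eigen(logistic_hessian(b, d), symmetric = TRUE)$values
    ev_z <- eigen(ztp_hessian(b, d), symmetric = TRUE)$values
    expect_lte(max(ev_l), 1e-10)
    expect_lte(max(ev_z), 1e-10)
  }
})

test_that("truncation-correction guard is smooth and accurate near lam = 0", {
  # the small-lam series branch must join the direct formula continuously
  lam <- c(1e-9, 1e-7, 9.9e-7, 1.01e-6, 1e-5, 1e-3, 0.1, 1, 10)
  m <- lam / (-expm1(-lam))                 # high-precision reference
  expect_equal(odah:::ztp_mean(lam), m, tolerance = 1e-12)
  v <- m * (1 + lam - m)
  expect_equal(odah:::ztp_variance(lam), v, tolerance = 1e-7)
  # gradient stays finite for extreme negative linear predictors
  d1 <- hurdle_data(data.frame(y = 1, x = 0), ztp_covariates = character(0),
                    logistic_covariates = character(0))
  expect_true(is.finite(ztp_gradient(-30, d1)))
})

test_that("dimension mismatches are contract violations", {
  d <- make_data(n = 50, seed = 2)
  expect_error(logistic_loglik(c(0, 0), d), "length")
  expect_error(ztp_gradient(rep(0, 5), d), "length")
})
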