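make_sites <- function(K = 3, n = 400, seed = 1,
                       beta = c(-1.2, -0.6, 0.8), gamma = c(0.4, -0.3, 0.5)) {
  lapply(seq_len(K), function(j) {
    hurdle_data(simulate_site(n, beta, gamma, seed = seed + j),
                site_id = sprintf("s%d", j))
  })
}

test_that("meta initialization is the coordinate-wise inverse-variance mean", {
  mk <- function(id, est, var) {
    structure(list(site_id = id, n = 100L, n_pos = 50L,
                   beta_hat = c(a = est), gamma_hat = c(a = est),
                   beta_var_diag = var, gamma_var_diag = var,
                   logistic_converged = TRUE, ztp_converged = TRUE),
              class = "site_summary")
  }
  # single site: unchanged
  expect_equal(meta_initialize(list(mk("a", 1.7, 0.2)))$beta_bar,
               c(a = 1.7))
  # equal variances: plain average
  expect_equal(
    meta_initialize(list(mk("a", 1, 1), mk("b", 3, 1)))$gamma_bar,
    c(a = 2))
  # unequal variances: (2*1 + 0.5*2) / 2.5 = 1.2
  expect_equal(
    meta_initialize(list(mk("a", 1, 0.5), mk("b", 2, 2)))$beta_bar,
    c(a = 1.2))
  # invalid variances rejected
  expect_error(meta_initialize(list(mk("a", 1, 0))), "positive")
  # unconverged sites excluded with a warning
  bad <- mk("bad", 50, 1e-4)
  bad$ztp_converged <- FALSE
  expect_warning(
    init <- meta_initialize(list(mk("a", 1, 1), bad)),
    "excluding.*bad")
  expect_equal(unname(init$gamma_bar), 1)
})

test_that("lead initialization passes through a converged fit and rejects others", {
  fit <- fit_hurdle(make_data(n = 400, seed = 3))
  init <- lead_initialize(fit)
  expect_identical(init$beta_bar, fit$params$beta)
  expect_identical(init$gamma_bar, fit$params$gamma)
  expect_identical(init$source, "lead")
  fit$converged <- FALSE
  expect_error(lead_initialize(fit), "converge")
})

test_that("gradient payloads are average-scale and size-invariant under duplication", {
  d <- make_data(n = 300, seed = 7)
  init <- lead_initialize(fit_hurdle(d))
  p1 <- compute_gradients(d, init)
  d2 <- structure(list(y = c(d$y, d$y), X = rbind(d$X, d$X),
                       Z = rbind(d$Z, d$Z), site_id = d$site_id),
                  class = "hurdle_data")
  p2 <- compute_gradients(d2, init)
  expect_equal(p1$grad1_logistic, p2$grad1_logistic, tolerance = 1e-12)
  expect_equal(p1$hess_ztp, p2$hess_ztp, tolerance = 1e-12)
  expect_identical(p2$n, 2L * p1$n)

  # average-scale first-order blocks match finite differences of the
  # site's average log-likelihood
  fd <- fd_gradient(function(b) logistic_loglik(b, d) / p1$n,
                    init$beta_bar)
  expect_lt(rel_err(p1$grad1_logistic, fd), 1e-4)
  fdz <- fd_gradient(function(g) ztp_loglik(g, d) / p1$n_pos,
                     init$gamma_bar)
  expect_lt(rel_err(p1$grad1_ztp, fdz), 1e-4)
})

test_that("payloads carry only aggregate quantities (privacy contract)", {
  d <- make_data(n = 250, seed = 15)
  init <- lead_initialize(fit_hurdle(d))
  payload <- compute_gradients(d, init)
  p <- ncol(d$X); q <- ncol(d$Z)
  lengths_ok <- c(
    length(payload$grad1_logistic) <= p + q,
    length(payload$grad1_ztp) <= p + q,
    length(payload$hess_logistic) <= max(p, q)^2,
    length(payload$hess_ztp) <= max(p, q)^2)
  expect_true(all(lengths_ok))
  # serialized message exposes no field as long as the data
  tmp <- withr::local_tempfile(fileext = ".json")
  write_gradient_payload(payload, tmp)
  msg <- jsonlite::read_json(tmp, simplifyVector = TRUE)
  flat_lengths <- vapply(rapply(msg, f = length, how = "unlist"), identity, 1)
  expect_true(all(flat_lengths <= max(p, q)^2))

  sm <- site_summary(fit_hurdle(d))
  tmp2 <- withr::local_tempfile(fileext = ".json")
  write_site_summary(sm, tmp2)
  msg2 <- jsonlite::read_json(tmp2, simplifyVector = TRUE)
  expect_true(all(vapply(rapply(msg2, length, how = "unlist"),
                         identity, 1) <= max(p, q)^2))
})

test_that("aggregated gradients equal the pooled-data gradient at the same point", {
  sizes <- c(100, 200, 700)
  sites <- lapply(seq_along(sizes), function(j) {
    hurdle_data(simulate_site(sizes[j], c(-1, -0.6, 0.8), c(0.5, -0.3, 0.5),
                              seed = 40 + j), site_id = paste0("s", j))
  })
  init <- lead_initialize(fit_hurdle(sites[[1]]))
  payloads <- lapply(sites, compute_gradients, init = init)
  agg <- aggregate_gradients(payloads)
  pooled <- odah:::bind_hurdle_data(sites)
  N <- length(pooled$y); N_pos <- sum(pooled$y > 0)
  expect_equal(agg$grad1_logistic,
               logistic_gradient(init$beta_bar, pooled) / N,
               tolerance = 1e-12)
  expect_equal(agg$hess_logistic,
               logistic_hessian(init$beta_bar, pooled) / N,
               tolerance = 1e-12)
  expect_equal(agg$grad1_ztp, ztp_gradient(init$gamma_bar, pooled) / N_pos,
               tolerance = 1e-12)
  expect_equal(agg$hess_ztp, ztp_hessian(init$gamma_bar, pooled) / N_pos,
               tolerance = 1e-12)

  # single payload: aggregate is that payload
  agg1 <- aggregate_gradients(payloads[1])
  expect_equal(agg1$grad1_logistic, payloads[[1]]$grad1_logistic)

  # differing evaluation points are rejected
  init2 <- init
  init2$beta_bar <- init$beta_bar + 0.1
  p_bad <- compute_gradients(sites[[2]], init2)
  expect_error(aggregate_gradients(list(payloads[[1]], p_bad)),
               "evaluation points differ")
})

test_that("surrogate gradient at the initial estimate matches the global gradient exactly", {
  for (seed in c(1, 2, 3, 4, 5)) {
    sites <- make_sites(K = 4, n = 250, seed = 10 * seed)
    fits <- lapply(sites, fit_hurdle)
    init <- meta_initialize(lapply(fits, site_summary))
    payloads <- lapply(sites, compute_gradients, init = init)
    agg <- aggregate_gradients(payloads)
    h <- 1e-6
    grad_b <- fd_gradient(function(b) {
      surrogate_loglik(list(beta = b, gamma = init$gamma_bar),
                       sites[[1]], agg)["logistic"]
    }, init$beta_bar, h = h)
    expect_lt(rel_err(grad_b, agg$grad1_logistic), 1e-4)
    grad_g <- fd_gradient(function(g) {
      surrogate_loglik(list(beta = init$beta_bar, gamma = g),
                       sites[[1]], agg)["ztp"]
    }, init$gamma_bar, h = h)
    expect_lt(rel_err(grad_g, agg$grad1_ztp), 1e-4)
  }
})

test_that("surrogate Hessian is the lead Hessian plus a constant correction", {
  sites <- make_sites(K = 3, n = 300, seed = 77)
  fits <- lapply(sites, fit_hurdle)
  init <- meta_initialize(lapply(fits, site_summary))
  payloads <- lapply(sites, compute_gradients, init = init)
  agg <- aggregate_gradients(payloads)
  lead <- sites[[1]]
  n1 <- length(lead$y)
  b <- init$beta_bar + c(0.05, -0.02, 0.03)   # away from the expansion point
  H_fd <- fd_jacobian(function(bb) {
    fd_gradient(function(b2) {
      surrogate_loglik(list(beta = b2, gamma = init$gamma_bar),
                       lead, agg)["logistic"]
    }, bb, h = 1e-5)
  }, b, h = 1e-5)
  H_expect <- logistic_hessian(b, lead) / n1 +
    (agg$hess_logistic - logistic_hessian(init$beta_bar, lead) / n1)
  expect_lt(rel_err(H_fd, H_expect), 1e-3)
})

test_that("with one site the surrogate is the local likelihood up to a constant", {
  d <- make_data(n = 400, seed = 23)
  init <- lead_initialize(fit_hurdle(d))
  agg <- aggregate_gradients(list(compute_gradients(d, init)))
  n <- length(d$y); n_pos <- sum(d$y > 0)
  th1 <- list(beta = init$beta_bar, gamma = init$gamma_bar)
  th2 <- list(beta = init$beta_bar + 0.1, gamma = init$gamma_bar - 0.1)
  s1 <- surrogate_loglik(th1, d, agg)
  s2 <- surrogate_loglik(th2, d, agg)
  # correction terms vanish, so surrogate differences equal average
  # log-likelihood differences
  expect_equal(s2["logistic"] - s1["logistic"],
               (logistic_loglik(th2$beta, d) -
                  logistic_loglik(th1$beta, d)) / n,
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(s2["ztp"] - s1["ztp"],
               (ztp_loglik(th2$gamma, d) - ztp_loglik(th1$gamma, d)) / n_pos,
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("reduction oracle: K = 1 gives the lead-site MLE", {
  d <- make_data(n = 500, seed = 31)
  fit <- fit_hurdle(d)
  res <- odah(list(d))
  expect_equal(res$params$beta, fit$params$beta, tolerance = 1e-8)
  expect_equal(res$params$gamma, fit$params$gamma, tolerance = 1e-8)
})

test_that("reduction oracle: lead holding all rows gives the pooled MLE", {
  sites <- make_sites(K = 3, n = 300, seed = 55)
  pooled_data <- odah:::bind_hurdle_data(sites)
  pooled <- fit_hurdle(pooled_data)
  # lead site holds every row; collaborators re-send subsets of the same
  # data, but aggregation weights make the total equal the pooled gradient
  fits <- lapply(sites, fit_hurdle)
  init <- meta_initialize(lapply(fits, site_summary))
  res <- odah_solve(pooled_data,
                    aggregate_gradients(list(
                      compute_gradients(pooled_data, init))), init)
  expect_equal(res$params$beta, pooled$params$beta, tolerance = 1e-8)
  expect_equal(res$params$gamma, pooled$params$gamma, tolerance = 1e-8)
})

test_that("ODAH closely tracks the pooled estimate on a homogeneous network", {
  sites <- make_sites(K = 5, n = 600, seed = 90)
  pooled <- pooled_fit(sites)
  res <- odah(sites)
  expect_true(res$converged)
  expect_lt(max(abs(res$params$beta - pooled$params$beta)), 0.02)
  expect_lt(max(abs(res$params$gamma - pooled$params$gamma)), 0.02)
  # covariance comparable to the pooled covariance (same scale)
  po_full <- fit_hurdle(odah:::bind_hurdle_data(sites))
  expect_equal(diag(res$beta_var), diag(po_full$beta_var), tolerance = 0.2)
})

test_that("lead-initialized ODAH agrees with meta-initialized ODAH when the lead is representative", {
  sites <- make_sites(K = 4, n = 500, seed = 120)
  # lead holds 50%: enlarge site 1
  big_lead <- odah:::bind_hurdle_data(sites[c(1, 2)])
  big_lead$site_id <- "lead"
  network <- c(list(big_lead), sites[c(3, 4)])
  res_meta <- odah(network, init = "meta")
  res_lead <- odah(network, init = "lead")
  se <- sqrt(diag(res_meta$gamma_var))
  expect_true(all(abs(res_meta$params$gamma - res_lead$params$gamma) <
                    3 * se))
})

test_that("surrogate concavity failure at the initial estimate is a labelled error", {
  d <- make_data(n = 200, seed = 17)
  init <- lead_initialize(fit_hurdle(d))
  agg <- aggregate_gradients(list(compute_gradients(d, init)))
  # force an indefinite corrected Hessian
  agg$hess_ztp <- -agg$hess_ztp
  expect_error(odah_solve(d, agg, init), "not concave.*eigenvalue")
})

test_that("the in-memory protocol driver is one-shot", {
  # count fit/gradient exchanges by tracing the message-producing steps
  sites <- make_sites(K = 3, n = 250, seed = 61)
  res <- odah(sites, init = "meta")
  expect_s3_class(res, "odah_fit")
  expect_identical(res$K, 3L)
  expect_identical(res$initial$source, "meta")
  res_lead <- odah(sites, init = "lead")
  expect_identical(res_lead$initial$source, "lead")
})
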